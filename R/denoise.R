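#' Configuration for chi-square background denoising
#'
#' The background-noise quality control removes EVs carrying implausibly many
#' distinct proteins and then keeps only matrix cells whose Pearson residual
#' (chi value) against the row-column independence expectation is in the top
#' tail — cells explained by independent random tag collisions are reset to
#' zero.
#'
#' @param max_proteins_per_ev EVs with strictly more distinct proteins than
#'   this are removed before the chi computation (default 5).
#' @param quantile Quantile level q of the chi distribution; cells with chi
#'   at or above the q-quantile are retained (default 0.95, i.e. the top 5%).
#' @param quantile_population Population over which the quantile is taken:
#'   `"nonzero_cells"` (default; structural zeros of a sparse matrix would
#'   otherwise dominate) or `"all_cells"`.
#' @return A list of class `chi_filter_config`.
#' @export
chi_filter_config <- function(max_proteins_per_ev = 5L,
                              quantile = 0.95,
                              quantile_population = c("nonzero_cells", "all_cells")) {
  quantile_population <- match.arg(quantile_population)
  if (max_proteins_per_ev < 1L) abort("max_proteins_per_ev must be >= 1")
  if (quantile <= 0 || quantile > 1) abort("quantile must be in (0, 1]")
  structure(
    list(max_proteins_per_ev = as.integer(max_proteins_per_ev),
         quantile = quantile,
         quantile_population = quantile_population),
    class = "chi_filter_config"
  )
}

#' Remove EVs carrying more than a maximum number of distinct proteins
#'
#' @param profile An `ev_profile`.
#' @param config A [chi_filter_config()] (only `max_proteins_per_ev` is
#'   used). The boundary is strict: an EV with exactly the maximum is kept.
#' @return The filtered `ev_profile`.
#' @export
filter_max_proteins <- function(profile, config = chi_filter_config()) {
  stopifnot(inherits(profile, "ev_profile"))
  k <- Matrix::rowSums(profile$counts > 0)
  keep <- k <= config$max_proteins_per_ev
  if (!any(keep)) {
    abort(sprintf(
      "all %d EVs carry more than %d proteins; nothing left after filtering",
      nrow(profile$counts), config$max_proteins_per_ev
    ))
  }
  out <- profile
  out$counts <- profile$counts[keep, , drop = FALSE]
  out
}

#' Expected counts under row-column independence
#'
#' For an EV matrix D the expected count in cell (i, j) under independence of
#' EV identity and protein identity is `rowsum_i * colsum_j / N` with N the
#' grand total, the classical chi-square expected-count matrix. Its grand
#' total equals that of D.
#'
#' @param D A numeric matrix or sparse Matrix of non-negative counts.
#' @return A dense matrix E of the same dimension with `sum(E) == sum(D)`.
#' @export
expected_matrix <- function(D) {
  N <- sum(D)
  if (N <= 0) abort("grand total of D must be positive")
  r <- Matrix::rowSums(D)
  c_ <- Matrix::colSums(D)
  E <- outer(as.numeric(r), as.numeric(c_)) / N
  dimnames(E) <- dimnames(D)
  E
}

#' Pearson chi residuals of an EV matrix
#'
#' Element-wise `(D - E) / sqrt(E)`. Cells where E is zero (possible only
#' when an entire row or column is zero) are defined as 0.
#'
#' @param D Observed count matrix.
#' @param E Expected matrix from [expected_matrix()] on the same D.
#' @return A dense numeric matrix of chi values.
#' @export
chi_matrix <- function(D, E) {
  if (!all(dim(D) == dim(E))) abort("D and E must have identical dimensions")
  D <- as.matrix(D)
  chi <- (D - E) / sqrt(E)
  chi[E == 0] <- 0
  chi
}

#' Threshold an EV matrix on its chi values
#'
#' Cells whose chi value is at or above the configured quantile of the chi
#' distribution keep their observed read count; all other cells are reset to
#' zero, and EVs left with no proteins are dropped. This removes counts
#' compatible with independent background tag collisions.
#'
#' @param profile An `ev_profile` (typically after [filter_max_proteins()]).
#' @param chi Chi matrix from [chi_matrix()] computed on `profile$counts`;
#'   if `NULL` it is computed internally.
#' @param config A [chi_filter_config()].
#' @param cutoff Optional fixed chi cutoff; when supplied the quantile in
#'   `config` is ignored and cells with `chi >= cutoff` are retained (used
#'   to re-apply a previously realized threshold).
#' @return The thresholded `ev_profile`, with attributes `threshold_value`
#'   (realized chi cutoff), `n_evs_before` and `n_evs_after`.
#' @export
threshold_chi <- function(profile, chi = NULL, config = chi_filter_config(),
                          cutoff = NULL) {
  stopifnot(inherits(profile, "ev_profile"))
  D <- as.matrix(profile$counts)
  if (is.null(chi)) chi <- chi_matrix(D, expected_matrix(D))
  if (!all(dim(chi) == dim(D))) abort("chi and matrix dimensions differ")
  if (is.null(cutoff)) {
    pop <- switch(config$quantile_population,
      nonzero_cells = chi[D > 0],
      all_cells = as.numeric(chi)
    )
    if (length(pop) == 0L) abort("no cells available to compute the chi quantile")
    cutoff <- as.numeric(quantile(pop, config$quantile, names = FALSE))
    if (diff(range(pop)) == 0) {
      warn("all chi values equal; retaining every cell")
      cutoff <- min(pop)
    }
  }
  keep <- chi >= cutoff
  D[!keep] <- 0
  nonempty <- rowSums(D) > 0
  out <- profile
  out$counts <- Matrix::drop0(Matrix::Matrix(D[nonempty, , drop = FALSE], sparse = TRUE))
  attr(out, "threshold_value") <- cutoff
  attr(out, "n_evs_before") <- nrow(profile$counts)
  attr(out, "n_evs_after") <- sum(nonempty)
  out
}

#' Run the full background-denoising quality control
#'
#' Applies, in order: the max-proteins-per-EV filter, the independence
#' expectation and chi residuals, quantile thresholding, and removal of
#' emptied EVs.
#'
#' @param profile An `ev_profile`.
#' @param config A [chi_filter_config()].
#' @return The denoised `ev_profile` (see [threshold_chi()] for attached
#'   diagnostics).
#' @examples
#' sim <- simulate_ev_sample(ev_population_model(n_evs = 500, seed = 1), "s1")
#' prof <- parse_reads(sim$reads, sim$panel, "s1")
#' qc <- denoise_profile(prof)
#' attr(qc, "threshold_value")
#' @export
denoise_profile <- function(profile, config = chi_filter_config()) {
  filtered <- filter_max_proteins(profile, config)
  threshold_chi(filtered, chi = NULL, config = config)
}

#' Denoising report
#'
#' @param denoised Result of [denoise_profile()] or [threshold_chi()].
#' @return A one-row tibble with the sample id, EV counts before and after
#'   thresholding, the realized chi cutoff and the surviving-cell fraction.
#' @export
denoise_report <- function(denoised) {
  tibble(
    sample_id = denoised$sample_id,
    n_evs_before = attr(denoised, "n_evs_before"),
    n_evs_after = attr(denoised, "n_evs_after"),
    threshold_value = attr(denoised, "threshold_value"),
    n_cells_surviving = Matrix::nnzero(denoised$counts)
  )
}
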