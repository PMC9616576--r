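#' Parse a PBA read table into an EV-by-protein count matrix
#'
#' In a proximity barcoding assay every sequenced read links an EV tag (the
#' identity of one vesicle) to a protein tag (one antibody probe). Summing
#' read counts over (EV tag, protein tag) pairs for one sample yields the EV
#' matrix `D` (m EVs by n panel proteins) that all downstream quality control
#' and quantification operates on.
#'
#' @param reads A data frame with columns `sample_id`, `ev_tag`,
#'   `protein_tag`, `read_count` (read counts are positive integers;
#'   duplicate rows are aggregated by summation).
#' @param panel An [ev_panel()]; every `protein_tag` must be a panel protein.
#' @param sample_id Which sample to extract from `reads`.
#'
#' @return An object of class `ev_profile`: a list with elements `sample_id`,
#'   `counts` (a sparse [Matrix::dgCMatrix] of non-negative integers, rows =
#'   EV tags, columns = panel proteins in panel order) and `panel`. Rows with
#'   zero total reads are excluded.
#' @examples
#' panel <- ev_panel(c("P1", "P2"))
#' reads <- tibble::tribble(
#'   ~sample_id, ~ev_tag, ~protein_tag, ~read_count,
#'   "s1", "e1", "P1", 3L,
#'   "s1", "e1", "P2", 1L,
#'   "s1", "e2", "P1", 2L
#' )
#' prof <- parse_reads(reads, panel, "s1")
#' as.matrix(prof$counts)
#' @export
parse_reads <- function(reads, panel, sample_id) {
  panel <- assert_panel(panel)
  required <- c("sample_id", "ev_tag", "protein_tag", "read_count")
  missing_cols <- setdiff(required, names(reads))
  if (length(missing_cols) > 0L) {
    abort(paste0("read table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  sub <- dplyr::filter(reads, .data$sample_id == !!sample_id)
  if (nrow(sub) == 0L) {
    abort(paste0("no reads for sample '", sample_id, "'"))
  }
  if (any(sub$read_count < 1L)) {
    abort("read_count must be >= 1")
  }
  unknown <- setdiff(unique(sub$protein_tag), panel_proteins(panel))
  if (length(unknown) > 0L) {
    abort(paste0("protein tags absent from panel: ",
                 paste(unknown, collapse = ", ")))
  }
  agg <- sub %>%
    group_by(.data$ev_tag, .data$protein_tag) %>%
    summarise(read_count = sum(.data$read_count), .groups = "drop")
  ev_tags <- sort(unique(agg$ev_tag))
  proteins <- panel_proteins(panel)
  counts <- Matrix::sparseMatrix(
    i = match(agg$ev_tag, ev_tags),
    j = match(agg$protein_tag, proteins),
    x = as.numeric(agg$read_count),
    dims = c(length(ev_tags), length(proteins)),
    dimnames = list(ev_tags, proteins)
  )
  new_ev_profile(sample_id, counts, panel)
}

new_ev_profile <- function(sample_id, counts, panel) {
  structure(
    list(sample_id = sample_id, counts = counts, panel = panel),
    class = "ev_profile"
  )
}

#' @export
print.ev_profile <- function(x, ...) {
  cat(sprintf("<ev_profile> sample '%s': %d EVs x %d proteins, %s reads\n",
              x$sample_id, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.ev_profile <- function(x) dim(x$counts)

#' Normalize an EV matrix to per-sample read proportions
#'
#' Sequencing depth differs between libraries, so read counts are divided by
#' the sample's total read count; entries then sum to one over the whole
#' matrix and readouts are comparable across samples as proportions of
#' proteins per sample.
#'
#' @param profile An `ev_profile` from [parse_reads()].
#' @return An `ev_profile` whose `counts` slot holds proportions summing to 1.
#' @export
normalize_reads <- function(profile) {
  stopifnot(inherits(profile, "ev_profile"))
  total <- sum(profile$counts)
  if (total <= 0) {
    abort("cannot normalize an all-zero EV matrix")
  }
  out <- profile
  out$counts <- profile$counts / total
  out
}

#' Summarize an EV profile matrix
#'
#' Computes the population-level summaries used to assess measurement
#' quality: the fraction of singleton EVs (vesicles carrying exactly one
#' protein type), the histogram of distinct proteins per EV, and the fraction
#' of EVs carrying each single protein and each protein pair ("at least"
#' membership: an EV carrying \{A,B,C\} counts towards A, B, C and all three
#' pairs).
#'
#' @param profile An `ev_profile`.
#' @return A list of class `ev_profile_summary` with elements `sample_id`,
#'   `total_evs`, `singleton_fraction`, `proteins_per_ev` (tibble
#'   `n_proteins`, `n_evs`), `per_protein` (tibble `protein`, `n_evs`,
#'   `fraction`) and `per_pair` (tibble `protein_a`, `protein_b`, `n_evs`,
#'   `fraction`; unordered pairs with `protein_a` < `protein_b`).
#' @export
summarize_profile <- function(profile) {
  stopifnot(inherits(profile, "ev_profile"))
  m <- nrow(profile$counts)
  if (m == 0L) abort("empty EV matrix")
  Z <- membership_matrix(profile)
  k <- Matrix::rowSums(Z)
  hist_tbl <- tibble(n_proteins = as.integer(names(table(k))),
                     n_evs = as.integer(table(k)))
  per_protein <- tibble(
    protein = colnames(Z),
    n_evs = as.integer(Matrix::colSums(Z)),
    fraction = as.numeric(Matrix::colSums(Z)) / m
  )
  co <- Matrix::crossprod(Z) # co-membership counts, n x n
  co_t <- as(Matrix::triu(co, k = 1L), "TsparseMatrix")
  per_pair <- tibble(
    protein_a = colnames(Z)[co_t@i + 1L],
    protein_b = colnames(Z)[co_t@j + 1L],
    n_evs = as.integer(co_t@x),
    fraction = as.numeric(co_t@x) / m
  ) %>% arrange(.data$protein_a, .data$protein_b)
  structure(
    list(
      sample_id = profile$sample_id,
      total_evs = m,
      singleton_fraction = mean(k == 1),
      proteins_per_ev = hist_tbl,
      per_protein = per_protein,
      per_pair = per_pair
    ),
    class = "ev_profile_summary"
  )
}

#' @export
print.ev_profile_summary <- function(x, ...) {
  cat(sprintf(
    "<ev_profile_summary> sample '%s': %s EVs, %.1f%% singleton, 1-%d proteins per EV\n",
    x$sample_id, format(x$total_evs, big.mark = ","),
    100 * x$singleton_fraction, max(x$proteins_per_ev$n_proteins)
  ))
  invisible(x)
}

# binary protein-membership matrix (nonzero count = carries the protein)
membership_matrix <- function(profile) {
  Z <- profile$counts
  Z@x <- rep(1, length(Z@x))
  Matrix::drop0(Z)
}

#' Convert an EV profile back to a tidy read table
#'
#' Inverse of [parse_reads()]: emits one row per (EV tag, protein) incidence
#' with its read count, so `parse_reads(profile_to_reads(p), p$panel,
#' p$sample_id)` round-trips exactly.
#'
#' @param profile An `ev_profile` with integer counts.
#' @return A tibble with columns `sample_id`, `ev_tag`, `protein_tag`,
#'   `read_count`.
#' @export
profile_to_reads <- function(profile) {
  stopifnot(inherits(profile, "ev_profile"))
  tm <- as(profile$counts, "TsparseMatrix")
  tibble(
    sample_id = profile$sample_id,
    ev_tag = rownames(tm)[tm@i + 1L],
    protein_tag = colnames(tm)[tm@j + 1L],
    read_count = as.integer(tm@x)
  ) %>% arrange(.data$ev_tag, .data$protein_tag)
}
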