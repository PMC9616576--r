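#' Prepare an EV phenotype for genome-wide association
#'
#' Adjusts the abundance for fixed-effect covariates (sex, age, experimental
#' factors) by ordinary least squares, then inverse-normal transforms the
#' residuals so the analysed phenotype is a standard-normal Z-score. This is
#' also the hook for externally pre-adjusted phenotypes (e.g. mixed-model
#' kinship-corrected residuals): pass them straight to [linear_gwas()].
#'
#' @param abundance Numeric vector of EV-phenotype values.
#' @param covariates Data frame or matrix of covariates (an intercept is
#'   added); must be full rank.
#' @return Numeric Z-score vector (mean 0, sd ~1).
#' @export
prepare_gwas_phenotype <- function(abundance, covariates) {
  X <- cbind(1, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) abort("covariate matrix is rank deficient")
  res <- lm.fit(X, abundance)$residuals
  if (diff(range(res)) < 1e-10) {
    warn("residuals are near-constant; ranks are arbitrary")
  }
  inverse_normal_transform(res)
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs with MAF strictly greater than the threshold. Two defaults
#' are in routine use: 0.05 for general genotype QC, and a stricter 0.2 for
#' small-sample EV scans where rare variants inflate false positives.
#'
#' @param genotypes Individuals x SNPs dosage matrix (values in [0, 2]).
#' @param snp_info Tibble with columns `snp`, `chr`, `pos` (and optionally
#'   `maf`; recomputed from dosages when absent).
#' @param threshold MAF threshold in [0, 0.5).
#' @return A list with filtered `genotypes` and `snp_info` (with `maf`).
#' @export
maf_filter <- function(genotypes, snp_info, threshold = 0.05) {
  if (threshold < 0 || threshold >= 0.5) abort("threshold must be in [0, 0.5)")
  maf <- snp_maf(genotypes)
  keep <- maf > threshold
  list(
    genotypes = genotypes[, keep, drop = FALSE],
    snp_info = snp_info[keep, ] %>% mutate(maf = maf[keep])
  )
}

snp_maf <- function(genotypes) {
  p <- colMeans(genotypes) / 2
  pmin(p, 1 - p)
}

#' Per-SNP linear association scan
#'
#' Simple linear regression of the prepared phenotype on each SNP dosage
#' (with intercept), vectorized in closed form: slope, standard error and
#' two-sided t-test P-value per SNP, plus the genomic-control lambda
#' (median chi-square statistic over its null expectation).
#'
#' @param z Phenotype Z-score vector from [prepare_gwas_phenotype()].
#' @param genotypes Individuals x SNPs dosage matrix (MAF-filtered).
#' @param snp_info Optional tibble with `snp`, `chr`, `pos` to carry along.
#' @return A tibble of class `ev_gwas` with columns `snp`, `chr`, `pos`,
#'   `beta`, `se`, `p`; attribute `lambda_gc` holds the inflation factor.
#'   Constant genotype columns are skipped with a warning (`NA` rows).
#' @export
linear_gwas <- function(z, genotypes, snp_info = NULL) {
  n <- length(z)
  if (nrow(genotypes) != n) abort("phenotype and genotype dimensions differ")
  gc <- scale(genotypes, center = TRUE, scale = FALSE)
  sxx <- unname(colSums(gc^2))
  constant <- sxx == 0
  if (any(constant)) {
    warn(sprintf("%d constant genotype column(s) skipped", sum(constant)))
  }
  yc <- z - mean(z)
  sxy <- as.numeric(crossprod(gc, yc))
  beta <- ifelse(constant, NA_real_, sxy / sxx)
  syy <- sum(yc^2)
  rss <- syy - ifelse(constant, 0, beta^2 * sxx)
  sigma2 <- rss / (n - 2)
  se <- ifelse(constant, NA_real_, sqrt(sigma2 / sxx))
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- median(chisq, na.rm = TRUE) / qchisq(0.5, df = 1)
  out <- tibble(
    snp = if (!is.null(snp_info)) snp_info$snp else colnames(genotypes),
    chr = if (!is.null(snp_info)) snp_info$chr else NA_character_,
    pos = if (!is.null(snp_info)) snp_info$pos else NA_integer_,
    beta = beta, se = se, p = p
  )
  attr(out, "lambda_gc") <- lambda
  class(out) <- c("ev_gwas", class(out))
  out
}

#' @rdname linear_gwas
#' @param x An `ev_gwas` result.
#' @return For `lambda_gc`: the genomic-control inflation factor.
#' @export
lambda_gc <- function(x) attr(x, "lambda_gc")

#' Extract marker-grouped SNP sets from EV genome scans
#'
#' Given per-phenotype GWAS results for pair-type EV phenotypes, builds one
#' SNP set per prioritized marker — the union, over every pair phenotype
#' containing that marker, of SNPs with P below the threshold — plus one
#' set pooled over the marker-marker pair phenotypes, giving `|markers| + 1`
#' sets (13 for 12 markers). Duplicates are removed within each set; empty
#' sets are retained with a warning.
#'
#' @param gwas_results Named list of `ev_gwas` tibbles; names are EV-type
#'   labels of the form `"EV_A & B"` (see [enumerate_ev_types()]).
#' @param markers Character vector of prioritized marker ids.
#' @param p_threshold Inclusion threshold on P (default 1e-6).
#' @return A tibble of class `snp_set_table` with columns `set_label`
#'   (marker id or `"marker_pairs"`), `snp`, `chr`, `pos`.
#' @export
extract_snp_sets <- function(gwas_results, markers, p_threshold = 1e-6) {
  if (p_threshold <= 0 || p_threshold > 1) abort("p_threshold must be in (0, 1]")
  labels <- names(gwas_results)
  if (is.null(labels)) abort("gwas_results must be a named list of scan results")
  label_members <- strsplit(sub("^EV_", "", labels), " & ", fixed = TRUE)
  empty_set <- tibble(snp = character(), chr = character(), pos = integer())
  hits <- purrr::map(gwas_results, ~ dplyr::filter(.x, !is.na(.data$p),
                                                   .data$p < p_threshold))
  union_hits <- function(group) {
    h <- bind_rows(c(list(empty_set), purrr::map(hits[group], as_tibble)))
    distinct(h, .data$snp, .data$chr, .data$pos)
  }
  sets <- purrr::map(markers, function(mk) {
    in_group <- purrr::map_lgl(label_members, ~ mk %in% .x)
    union_hits(in_group) %>% mutate(set_label = mk)
  })
  pair_group <- purrr::map_lgl(label_members,
                               ~ length(.x) == 2L && all(.x %in% markers))
  pair_set <- union_hits(pair_group) %>% mutate(set_label = "marker_pairs")
  out <- bind_rows(c(sets, list(pair_set))) %>%
    select("set_label", "snp", "chr", "pos")
  empty <- setdiff(c(markers, "marker_pairs"), unique(out$set_label))
  if (length(empty) > 0L) {
    warn(paste0("empty SNP set(s): ", paste(empty, collapse = ", ")))
  }
  attr(out, "set_labels") <- c(markers, "marker_pairs")
  class(out) <- c("snp_set_table", class(out))
  out
}

#' Annotate a SNP set with flanking windows
#'
#' Expands each member SNP position to a window of `window_bp` on each side
#' (0-based half-open interval `[pos - w, pos + w + 1)`, clipped at 0),
#' merges overlapping windows per chromosome, and marks every SNP of the
#' genotype panel falling inside a merged interval as annotation-positive.
#'
#' @param set_snps Tibble with columns `snp`, `chr`, `pos` (one SNP set,
#'   e.g. one `set_label` slice of [extract_snp_sets()] output).
#' @param snp_info Tibble of all tested SNPs (`snp`, `chr`, `pos`).
#' @param window_bp Flank size in base pairs (default 1000).
#' @return A list of class `snp_annotation`: `intervals` (tibble `chr`,
#'   `start`, `end`, 0-based half-open), `members` (annotation-positive SNP
#'   ids), `proportion_of_snps`.
#' @export
annotate_flanks <- function(set_snps, snp_info, window_bp = 1000L) {
  if (nrow(set_snps) == 0L) {
    return(structure(list(intervals = tibble(chr = character(),
                                             start = integer(), end = integer()),
                          members = character(), proportion_of_snps = 0),
                     class = "snp_annotation"))
  }
  start0 <- pmax(set_snps$pos - window_bp, 0L)
  end0 <- set_snps$pos + window_bp + 1L
  by_chr <- split(seq_len(nrow(set_snps)), set_snps$chr)
  intervals <- purrr::imap(by_chr, function(idx, chr) {
    merged <- IRanges::reduce(IRanges::IRanges(start = start0[idx] + 1L,
                                               end = end0[idx]))
    tibble(chr = chr, start = IRanges::start(merged) - 1L,
           end = IRanges::end(merged))
  }) %>% bind_rows()
  members <- purrr::imap(split(seq_len(nrow(snp_info)), snp_info$chr),
    function(idx, chr) {
      iv <- dplyr::filter(intervals, .data$chr == !!chr)
      if (nrow(iv) == 0L) return(character())
      q <- IRanges::IRanges(start = snp_info$pos[idx] + 1L, width = 1L)
      s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
      snp_info$snp[idx][IRanges::overlapsAny(q, s)]
    }) %>% unlist(use.names = FALSE)
  structure(
    list(intervals = intervals, members = members,
         proportion_of_snps = length(members) / nrow(snp_info)),
    class = "snp_annotation"
  )
}

#' Heritability enrichment of an annotated SNP set
#'
#' The enrichment score is the proportion of trait heritability explained by
#' annotation-positive SNPs divided by the proportion of SNPs annotated; 1
#' means no enrichment. The standard error is a leave-one-block-out
#' jackknife over contiguous SNP blocks. Heritability contributions come
#' from a known (simulated) architecture, making the estimator exact up to
#' sampling of the architecture itself.
#'
#' @param annotation A `snp_annotation` from [annotate_flanks()], or a
#'   character vector of member SNP ids.
#' @param snp_h2 Tibble `snp`, `h2`: per-SNP heritability contributions for
#'   the trait (e.g. `truth$snp_h2` from [simulate_cohort()]).
#' @param n_blocks Number of jackknife blocks (default 200; reduced to the
#'   number of SNPs when smaller).
#' @return A one-row tibble: `n_snps_annotated`, `proportion_of_snps`,
#'   `proportion_of_h2`, `enrichment`, `se` (jackknife).
#' @export
enrichment_score <- function(annotation, snp_h2, n_blocks = 200L) {
  members <- if (inherits(annotation, "snp_annotation")) {
    annotation$members
  } else {
    as.character(annotation)
  }
  total_h2 <- sum(snp_h2$h2)
  if (total_h2 <= 0) abort("total heritability must be positive")
  if (length(members) == 0L) abort("annotation contains no SNPs: score undefined")
  in_set <- snp_h2$snp %in% members
  score_of <- function(keep) {
    prop_snp <- mean(in_set[keep])
    if (prop_snp == 0) return(NA_real_)
    (sum(snp_h2$h2[keep][in_set[keep]]) / sum(snp_h2$h2[keep])) / prop_snp
  }
  n_snp <- nrow(snp_h2)
  score <- score_of(rep(TRUE, n_snp))
  n_blocks <- min(n_blocks, n_snp)
  block <- ceiling(seq_len(n_snp) / (n_snp / n_blocks))
  jk <- vapply(seq_len(n_blocks), function(b) score_of(block != b), numeric(1))
  jk <- jk[is.finite(jk)]
  B <- length(jk)
  se <- if (B > 1) sqrt((B - 1) / B * sum((jk - mean(jk))^2)) else NA_real_
  tibble(
    n_snps_annotated = sum(in_set),
    proportion_of_snps = mean(in_set),
    proportion_of_h2 = sum(snp_h2$h2[in_set]) / total_h2,
    enrichment = score,
    se = se
  )
}
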