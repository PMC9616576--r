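#' Multiple-testing bookkeeping for the EV study design
#'
#' Small helpers that make the study's test accounting explicit and
#' reproducible: how many gene-level P-values the marker-prioritization step
#' yields, and the Bonferroni-corrected genome-wide significance threshold
#' for the family of EV genome scans.
#'
#' Marker prioritization scores each panel gene against a collection of
#' adiposity GWAS: one P-value per univariate trait plus one from the joint
#' multi-trait analysis.
#'
#' @param n_univariate Number of univariate trait GWAS (default 17).
#' @param n_multivariate Number of joint multi-trait analyses (default 1).
#' @return Integer: P-values per gene.
#' @examples
#' count_gene_level_tests() # 18
#' @export
count_gene_level_tests <- function(n_univariate = 17L, n_multivariate = 1L) {
  as.integer(n_univariate + n_multivariate)
}

#' @rdname count_gene_level_tests
#' @param alpha Genome-wide significance level for a single scan (default
#'   5e-8).
#' @param n_tests Number of phenotype scans in the family; default is the
#'   `marker_vs_panel` enumeration count for 12 markers in a 113-protein
#'   panel.
#' @return The Bonferroni-corrected per-test threshold `alpha / n_tests`.
#' @examples
#' signif(bonferroni_threshold(), 2) # 3.9e-11
#' @export
bonferroni_threshold <- function(alpha = 5e-8,
                                 n_tests = n_ev_gwas_phenotypes()) {
  if (n_tests < 1L) abort("n_tests must be >= 1")
  alpha / n_tests
}

#' @rdname count_gene_level_tests
#' @param n_markers Number of prioritized markers (default 12).
#' @param panel_size Panel size (default 113).
#' @return The number of pair-type EV phenotypes with at least one
#'   prioritized member: `n_markers * (panel_size - n_markers) +
#'   choose(n_markers, 2)`.
#' @export
n_ev_gwas_phenotypes <- function(n_markers = 12L, panel_size = 113L) {
  as.integer(n_markers * (panel_size - n_markers) + choose(n_markers, 2))
}
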