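#' Define a surface-protein antibody panel
#'
#' A panel is the set of surface proteins targeted by the assay's antibody
#' probes, together with the subset of markers prioritized for downstream
#' EV-phenotype construction (for adiposity work, the obesity-associated
#' markers selected from gene-level GWAS scores).
#'
#' @param proteins Character vector of unique protein identifiers (panel
#'   columns). Defaults to a synthetic 113-protein panel.
#' @param markers Character vector of prioritized marker identifiers; must be
#'   a subset of `proteins`. Defaults to the first 12 proteins.
#'
#' @return A tibble of class `ev_panel` with columns `protein` and
#'   `is_marker`.
#' @examples
#' panel <- ev_panel()
#' sum(panel$is_marker)
#' @export
ev_panel <- function(proteins = default_panel_proteins(),
                     markers = proteins[seq_len(min(12L, length(proteins)))]) {
  proteins <- as.character(proteins)
  markers <- as.character(markers)
  if (anyDuplicated(proteins) > 0L) {
    abort("panel protein ids must be unique")
  }
  if (!all(markers %in% proteins)) {
    bad <- setdiff(markers, proteins)
    abort(paste0("markers not in panel: ", paste(bad, collapse = ", ")))
  }
  out <- tibble(protein = proteins, is_marker = proteins %in% markers)
  class(out) <- c("ev_panel", class(out))
  out
}

#' @rdname ev_panel
#' @export
default_panel_proteins <- function() {
  sprintf("P%03d", seq_len(113L))
}

#' @export
print.ev_panel <- function(x, ...) {
  cat(sprintf("<ev_panel> %d proteins, %d prioritized markers\n",
              nrow(x), sum(x$is_marker)))
  NextMethod()
}

panel_proteins <- function(panel) panel$protein

panel_markers <- function(panel) panel$protein[panel$is_marker]

assert_panel <- function(panel) {
  if (!inherits(panel, "ev_panel")) {
    if (is.data.frame(panel) && all(c("protein", "is_marker") %in% names(panel))) {
      return(ev_panel(panel$protein, panel$protein[panel$is_marker]))
    }
    abort("`panel` must be an `ev_panel` (see ev_panel())")
  }
  panel
}
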