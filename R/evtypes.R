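#' Enumerate marker-specific EV phenotype definitions
#'
#' An EV phenotype (EV type) is the sub-population of vesicles carrying a
#' given set of one or two surface markers. Two enumeration schemes are
#' supported:
#'
#' * `"marker_pairs_only"`: all singletons of the prioritized markers plus
#'   all unordered pairs within them — `|M| + choose(|M|, 2)` definitions
#'   (78 for the default 12 markers: 12 singles + 66 pairs).
#' * `"marker_vs_panel"`: all unordered pairs with at least one member among
#'   the markers — `|M| * (n - |M|) + choose(|M|, 2)` definitions, the
#'   phenotype families scanned in EV genome-wide association work.
#'
#' @param markers Character vector of marker ids (subset of the panel).
#' @param panel An [ev_panel()].
#' @param scheme Enumeration scheme, see above.
#' @param match_mode How EVs qualify for a type when quantified:
#'   `"at_least"` (default; the EV carries every marker of the set, possibly
#'   among others) or `"exact"` (its nonzero support equals the set).
#' @return A tibble of class `ev_type_set` with columns `label` (canonical
#'   name, markers alphabetical joined by `" & "` and prefixed `EV_`),
#'   `marker_1`, `marker_2` (`NA` for singletons), `size` and `match_mode`,
#'   in deterministic canonical order (singletons first, then pairs, each
#'   alphabetical).
#' @examples
#' panel <- ev_panel()
#' nrow(enumerate_ev_types(panel_markers(panel), panel)) # 78
#' @export
enumerate_ev_types <- function(markers,
                               panel,
                               scheme = c("marker_pairs_only", "marker_vs_panel"),
                               match_mode = c("at_least", "exact")) {
  scheme <- match.arg(scheme)
  match_mode <- match.arg(match_mode)
  panel <- assert_panel(panel)
  markers <- sort(unique(as.character(markers)))
  if (!all(markers %in% panel_proteins(panel))) {
    abort(paste0("markers not in panel: ",
                 paste(setdiff(markers, panel_proteins(panel)), collapse = ", ")))
  }
  if (scheme == "marker_pairs_only") {
    singles <- tibble(marker_1 = markers, marker_2 = NA_character_)
    pairs <- pair_grid(markers, markers)
  } else {
    others <- sort(setdiff(panel_proteins(panel), markers))
    singles <- tibble(marker_1 = character(), marker_2 = character())
    pairs <- bind_rows(
      tidyr::expand_grid(marker_1 = markers, marker_2 = others) %>%
        mutate(lo = pmin(.data$marker_1, .data$marker_2),
               hi = pmax(.data$marker_1, .data$marker_2)) %>%
        select(marker_1 = "lo", marker_2 = "hi"),
      pair_grid(markers, markers)
    ) %>% distinct()
    inform(sprintf(
      "marker_vs_panel enumeration: %d definitions (%d x %d + %d)",
      nrow(pairs), length(markers), length(others),
      choose(length(markers), 2)
    ))
  }
  out <- bind_rows(singles, pairs) %>%
    mutate(
      size = ifelse(is.na(.data$marker_2), 1L, 2L),
      label = ifelse(
        is.na(.data$marker_2),
        paste0("EV_", .data$marker_1),
        paste0("EV_", .data$marker_1, " & ", .data$marker_2)
      ),
      match_mode = match_mode
    ) %>%
    arrange(.data$size, .data$marker_1, .data$marker_2) %>%
    select("label", "marker_1", "marker_2", "size", "match_mode")
  class(out) <- c("ev_type_set", class(out))
  out
}

pair_grid <- function(a, b) {
  if (length(a) < 2L) {
    return(tibble(marker_1 = character(), marker_2 = character()))
  }
  cmb <- utils::combn(sort(a), 2L)
  tibble(marker_1 = cmb[1L, ], marker_2 = cmb[2L, ])
}

type_marker_set <- function(type_row) {
  stats::na.omit(c(type_row$marker_1, type_row$marker_2))
}

#' Quantify one EV type in a denoised profile
#'
#' @param profile A denoised `ev_profile`.
#' @param type A one-row `ev_type_set` tibble (or a row index into one).
#' @return A one-row tibble with `sample_id`, `label`, `raw_count`
#'   (qualifying EVs), `n_evs_total` and `abundance = raw_count /
#'   n_evs_total`.
#' @export
quantify_ev_type <- function(profile, type) {
  stopifnot(inherits(profile, "ev_profile"))
  if (nrow(type) != 1L) abort("`type` must be a single EV-type definition")
  mk <- type_marker_set(type)
  if (!all(mk %in% panel_proteins(profile$panel))) {
    abort(paste0("marker not in panel: ",
                 paste(setdiff(mk, panel_proteins(profile$panel)), collapse = ", ")))
  }
  Z <- membership_matrix(profile)
  carries_all <- Matrix::rowSums(Z[, mk, drop = FALSE]) == length(mk)
  if (identical(type$match_mode, "exact")) {
    qualifies <- carries_all & (Matrix::rowSums(Z) == length(mk))
  } else {
    qualifies <- carries_all
  }
  m <- nrow(Z)
  tibble(
    sample_id = profile$sample_id,
    label = type$label,
    raw_count = sum(qualifies),
    n_evs_total = m,
    abundance = sum(qualifies) / m
  )
}

#' Total (overall) protein level in a sample
#'
#' The bulk-style readout: the protein's column read sum divided by the
#' sample's total reads, i.e. the proportion of the sample's reads carrying
#' that protein tag.
#'
#' @param profile An `ev_profile`.
#' @param protein A panel protein id, or `NULL` for all panel proteins.
#' @return A tibble with `sample_id`, `protein`, `level`.
#' @export
total_protein_level <- function(profile, protein = NULL) {
  stopifnot(inherits(profile, "ev_profile"))
  proteins <- panel_proteins(profile$panel)
  if (is.null(protein)) protein <- proteins
  if (!all(protein %in% proteins)) {
    abort(paste0("unknown protein: ",
                 paste(setdiff(protein, proteins), collapse = ", ")))
  }
  total <- sum(profile$counts)
  if (total <= 0) abort("profile holds no reads")
  lv <- Matrix::colSums(profile$counts)[protein] / total
  tibble(sample_id = profile$sample_id, protein = protein,
         level = as.numeric(lv))
}

#' Build a samples-by-EV-types abundance table
#'
#' Quantifies every EV-type definition in every sample and assembles the
#' phenotype table used for association testing: one row per sample, one
#' column per EV-type label, entries the normalized abundances (zero — not
#' missing — when no EV qualifies).
#'
#' @param profiles A list of denoised `ev_profile` objects sharing a panel.
#' @param types An `ev_type_set` from [enumerate_ev_types()].
#' @return A tibble with column `sample_id` followed by one column per type
#'   label, in the canonical type order.
#' @export
build_phenotype_table <- function(profiles, types) {
  ids <- purrr::map_chr(profiles, "sample_id")
  if (anyDuplicated(ids) > 0L) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  panels <- purrr::map(profiles, ~ panel_proteins(.x$panel))
  if (length(unique(purrr::map_chr(panels, paste, collapse = "\r"))) > 1L) {
    abort("all profiles must share the same panel")
  }
  rows <- purrr::map(profiles, function(p) {
    ab <- quantify_types_fast(p, types)
    tibble(sample_id = p$sample_id, !!!setNames(as.list(ab), types$label))
  })
  bind_rows(rows)
}

# vectorized at_least/exact quantification of a whole type set
quantify_types_fast <- function(profile, types) {
  Z <- membership_matrix(profile)
  m <- nrow(Z)
  k <- Matrix::rowSums(Z)
  vapply(seq_len(nrow(types)), function(i) {
    mk <- type_marker_set(types[i, ])
    hit <- Matrix::rowSums(Z[, mk, drop = FALSE]) == length(mk)
    if (identical(types$match_mode[i], "exact")) hit <- hit & (k == length(mk))
    sum(hit) / m
  }, numeric(1))
}
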