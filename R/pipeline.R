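#' Default pipeline configuration
#'
#' Builds the nested configuration list consumed by [run_pipeline()]. The
#' pipeline has two synthetic arms sharing one EV-type vocabulary: a
#' read-level arm (simulate PBA read tables, parse, denoise, quantify into a
#' samples-by-EV-types table) and a cohort arm (genotypes, EV abundances and
#' traits with declared effects; association testing, genome scan, SNP-set
#' extraction and heritability enrichment).
#'
#' @param out_dir Output directory for stage artifacts and the manifest.
#' @param seed Global seed; per-stage substream seeds are derived from it.
#' @param n_pba_samples Number of simulated PBA samples.
#' @param n_evs EVs per simulated PBA sample.
#' @param panel_size,n_markers Panel dimensions.
#' @param n_individuals,n_snps Cohort dimensions.
#' @param stages Character vector of stages to run (subset of the default
#'   order; later stages require their upstream outputs).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            n_pba_samples = 2L,
                            n_evs = 5000L,
                            panel_size = 113L,
                            n_markers = 12L,
                            n_individuals = 96L,
                            n_snps = 2000L,
                            stages = c("simulate", "parse", "denoise",
                                       "quantify", "associate", "gwas",
                                       "snpsets", "enrich")) {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_pba_samples = n_pba_samples, n_evs = n_evs,
         panel_size = panel_size, n_markers = n_markers,
         n_individuals = n_individuals, n_snps = n_snps,
         noise_rate = 0.02, max_proteins_per_ev = 5L, chi_quantile = 0.95,
         maf_threshold = 0.2, p_threshold = 1e-3, flank_bp = 1000L,
         beta_ev = -1.62, beta_int = 0.5, trait_noise_sd = 2.26,
         stages = stages),
    class = "pipeline_config"
  )
}

stage_seed <- function(config, idx) {
  as.integer((as.numeric(config$seed) * 97 + idx * 1013) %% (2^31 - 1))
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the enabled stages in order, writing versioned text outputs and
#' a JSON manifest (parameters, seed, per-output MD5 hashes and dimensions)
#' under `config$out_dir`. A rerun with an identical configuration
#' reproduces identical outputs. Stage inputs are validated before any
#' compute: enabling a stage without its upstream stage requires the
#' upstream output files to exist already.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a named list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  order_all <- c("simulate", "parse", "denoise", "quantify", "associate",
                 "gwas", "snpsets", "enrich")
  stages <- intersect(order_all, config$stages)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  preflight_pipeline(config, stages, order_all)
  manifest <- list(seed = config$seed, stages = list())
  panel <- ev_panel(sprintf("P%03d", seq_len(config$panel_size)))
  markers <- panel_proteins(panel)[seq_len(config$n_markers)]
  types <- enumerate_ev_types(markers, panel)
  state <- list(panel = panel, markers = markers, types = types)

  for (st in stages) {
    state <- switch(st,
      simulate = stage_simulate(config, state),
      parse = stage_parse(config, state),
      denoise = stage_denoise(config, state),
      quantify = stage_quantify(config, state),
      associate = stage_associate(config, state),
      gwas = stage_gwas(config, state),
      snpsets = stage_snpsets(config, state),
      enrich = stage_enrich(config, state)
    )
    manifest$stages[[st]] <- state$last_manifest
  }
  manifest$outputs <- manifest_hashes(config$out_dir)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

preflight_pipeline <- function(config, stages, order_all) {
  needs <- list(
    parse = "reads_s01.tsv", denoise = "reads_s01.tsv",
    quantify = "denoised_s01.mtx", associate = "cohort_phenotypes.tsv",
    gwas = "cohort_dosages.tsv", snpsets = "gwas_EV1.tsv",
    enrich = "snp_h2_truth.tsv"
  )
  for (st in stages) {
    req <- needs[[st]]
    if (is.null(req)) next
    upstream <- order_all[seq_len(match(st, order_all) - 1L)]
    if (!any(upstream %in% stages) &&
        !file.exists(file.path(config$out_dir, req))) {
      abort(sprintf(
        "stage '%s' enabled without its upstream stage and '%s' not found in %s",
        st, req, config$out_dir
      ))
    }
  }
}

manifest_hashes <- function(out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  h <- tools::md5sum(file.path(out_dir, files))
  as.list(setNames(unname(h), files))
}

sample_ids <- function(config) sprintf("s%02d", seq_len(config$n_pba_samples))

cohort_from_config <- function(config, state, seed) {
  exposures <- head(state$types$label, 3L)
  cohort_model(
    n_individuals = config$n_individuals,
    ev_phenotypes = exposures,
    ev_effects = tibble(
      exposure = exposures[1], trait = "BMI",
      beta_ev = config$beta_ev, beta_int = config$beta_int
    ),
    trait_noise_sd = config$trait_noise_sd,
    n_snps = config$n_snps,
    snp_effects_ev = tibble(
      snp = seq_len(max(2L, config$n_snps %/% 100L)),
      exposure = exposures[1],
      beta = 0.6
    ),
    snp_effects_trait = tibble(
      snp = seq_len(max(2L, config$n_snps %/% 100L)), beta = 0.3
    ),
    h2_trait = 0.5,
    seed = seed
  )
}

stage_simulate <- function(config, state) {
  ids <- sample_ids(config)
  for (i in seq_along(ids)) {
    model <- ev_population_model(
      panel = state$panel, n_evs = config$n_evs,
      noise_rate = config$noise_rate, seed = stage_seed(config, i)
    )
    sim <- simulate_ev_sample(model, ids[i])
    write_pba_reads(sim$reads, file.path(config$out_dir,
                                         paste0("reads_", ids[i], ".tsv")))
  }
  cohort <- simulate_cohort(cohort_from_config(config, state,
                                               stage_seed(config, 100L)))
  write_phenotype_table(cohort$phenotypes,
                        file.path(config$out_dir, "cohort_phenotypes.tsv"))
  write_phenotype_table(cohort$ev_abundance,
                        file.path(config$out_dir, "cohort_ev_abundance.tsv"))
  write_dosage_matrix(cohort$genotypes,
                      file.path(config$out_dir, "cohort_dosages.tsv"))
  write.table(cohort$snp_info, file.path(config$out_dir, "cohort_snps.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$snp_h2,
              file.path(config$out_dir, "snp_h2_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$cohort <- cohort
  state$last_manifest <- list(n_pba_samples = length(ids),
                              n_evs = config$n_evs,
                              n_individuals = config$n_individuals,
                              n_snps = config$n_snps)
  state
}

stage_parse <- function(config, state) {
  ids <- sample_ids(config)
  state$profiles <- purrr::map(ids, function(id) {
    reads <- read_pba_reads(file.path(config$out_dir,
                                      paste0("reads_", id, ".tsv")))
    parse_reads(reads, state$panel, id)
  })
  state$last_manifest <- list(
    evs_per_sample = purrr::map_int(state$profiles, ~ nrow(.x$counts))
  )
  state
}

stage_denoise <- function(config, state) {
  cfg <- chi_filter_config(max_proteins_per_ev = config$max_proteins_per_ev,
                           quantile = config$chi_quantile)
  state$denoised <- purrr::map(state$profiles, denoise_profile, config = cfg)
  reports <- purrr::map(state$denoised, denoise_report) %>% bind_rows()
  for (d in state$denoised) {
    write_profile_mtx(d, file.path(config$out_dir,
                                   paste0("denoised_", d$sample_id)))
  }
  write.table(reports, file.path(config$out_dir, "denoise_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$last_manifest <- as.list(setNames(reports$n_evs_after,
                                          reports$sample_id))
  state
}

stage_quantify <- function(config, state) {
  tbl <- build_phenotype_table(state$denoised, state$types)
  write_phenotype_table(tbl, file.path(config$out_dir,
                                       "ev_phenotype_table.tsv"))
  state$ev_table <- tbl
  state$last_manifest <- list(n_samples = nrow(tbl),
                              n_types = ncol(tbl) - 1L)
  state
}

stage_associate <- function(config, state) {
  cohort <- state$cohort
  d <- left_join(cohort$phenotypes, cohort$ev_abundance, by = "sample_id")
  exposures <- setdiff(names(cohort$ev_abundance), "sample_id")
  traits <- setdiff(names(cohort$phenotypes),
                    c("sample_id", "sex", "age", "complex_trait"))
  res <- associate_all(d, traits, exposures)
  write.table(res, file.path(config$out_dir, "associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$associations <- res
  state$last_manifest <- list(n_tests = nrow(res),
                              n_fdr05 = sum(res$q < 0.05))
  state
}

stage_gwas <- function(config, state) {
  cohort <- state$cohort
  flt <- maf_filter(cohort$genotypes, cohort$snp_info,
                    threshold = config$maf_threshold)
  covars <- cohort$phenotypes[, c("sex", "age")]
  exposures <- setdiff(names(cohort$ev_abundance), "sample_id")
  # scan the marker-pair phenotypes relevant to SNP-set construction
  state$gwas <- purrr::map(setNames(exposures, exposures), function(lab) {
    z <- prepare_gwas_phenotype(cohort$ev_abundance[[lab]], covars)
    linear_gwas(z, flt$genotypes, flt$snp_info)
  })
  for (i in seq_along(state$gwas)) {
    write.table(state$gwas[[i]],
                file.path(config$out_dir, sprintf("gwas_EV%d.tsv", i)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  state$snp_info_filtered <- flt$snp_info
  state$last_manifest <- list(
    n_snps_tested = nrow(flt$snp_info),
    lambda_gc = purrr::map_dbl(state$gwas, lambda_gc)
  )
  state
}

stage_snpsets <- function(config, state) {
  pair_labels <- names(state$gwas)[grepl(" & ", names(state$gwas))]
  results <- state$gwas
  sets <- extract_snp_sets(results, state$markers,
                           p_threshold = config$p_threshold)
  state$snp_sets <- sets
  for (lab in unique(sets$set_label)) {
    sub <- dplyr::filter(sets, .data$set_label == lab)
    ann <- annotate_flanks(sub, state$snp_info_filtered,
                           window_bp = config$flank_bp)
    write_bed(ann, lab, file.path(config$out_dir,
                                  paste0("snpset_", gsub("[^A-Za-z0-9]", "_", lab),
                                         ".bed")))
  }
  state$last_manifest <- list(n_sets = length(unique(sets$set_label)),
                              n_snps = nrow(sets))
  state
}

stage_enrich <- function(config, state) {
  truth <- state$cohort$truth$snp_h2
  sets <- state$snp_sets
  labs <- unique(sets$set_label)
  scores <- purrr::map(labs, function(lab) {
    sub <- dplyr::filter(sets, .data$set_label == lab)
    if (nrow(sub) == 0L) return(NULL)
    ann <- annotate_flanks(sub, state$snp_info_filtered,
                           window_bp = config$flank_bp)
    if (length(ann$members) == 0L) return(NULL)
    enrichment_score(ann, truth) %>% mutate(set_label = lab, .before = 1)
  }) %>% bind_rows()
  write.table(scores, file.path(config$out_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  state$enrichment <- scores
  state$last_manifest <- list(n_scored = nrow(scores))
  state
}
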