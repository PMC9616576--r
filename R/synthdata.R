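#' Model of a single-EV population measured by PBA
#'
#' Describes the generative model used to simulate PBA read tables with the
#' statistical structure observed in deep-sequenced plasma samples: each EV
#' carries a small number of distinct surface proteins (a majority carry
#' exactly one; among the rest the typical EV carries about five to six),
#' each true EV-protein incidence produces one or more reads, and a fraction
#' of reads is background noise landing on random (EV tag, protein tag)
#' pairs.
#'
#' @param panel An [ev_panel()] (default: 113 proteins, 12 markers).
#' @param n_evs Number of EVs in the sample.
#' @param proteins_per_ev_dist Numeric probability vector over 1..K distinct
#'   proteins per EV; must sum to 1. Default
#'   [default_proteins_per_ev_dist()].
#' @param cooccurrence Optional symmetric non-negative matrix (panel x
#'   panel) of pairwise enrichment weights; when an EV already carries
#'   proteins S, the next protein j is drawn with weight
#'   `prod(cooccurrence[S, j])`. `NULL` means uniform co-occurrence.
#' @param noise_rate Fraction of all reads that are background noise, in
#'   [0, 1).
#' @param reads_per_incidence Function `n -> integer vector of n read
#'   counts >= 1` for true incidences; default `1 + rpois(n, 2)`.
#' @param seed Integer seed; the same seed reproduces the sample exactly.
#' @return A list of class `ev_population_model`.
#' @export
ev_population_model <- function(panel = ev_panel(),
                                n_evs = 10000L,
                                proteins_per_ev_dist = default_proteins_per_ev_dist(),
                                cooccurrence = NULL,
                                noise_rate = 0.02,
                                reads_per_incidence = function(n) 1L + rpois(n, 2),
                                seed = NULL) {
  panel <- assert_panel(panel)
  p <- proteins_per_ev_dist
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    abort("proteins_per_ev_dist must be a probability vector summing to 1")
  }
  if (length(p) > nrow(panel)) {
    abort("proteins_per_ev_dist support exceeds panel size")
  }
  if (noise_rate < 0 || noise_rate >= 1) abort("noise_rate must be in [0, 1)")
  if (!is.null(cooccurrence)) {
    if (!isSymmetric(unname(cooccurrence)) || any(cooccurrence < 0)) {
      abort("cooccurrence must be a symmetric non-negative matrix")
    }
    if (nrow(cooccurrence) != nrow(panel)) {
      abort("cooccurrence dimension must match panel size")
    }
  }
  structure(
    list(panel = panel, n_evs = as.integer(n_evs),
         proteins_per_ev_dist = p / sum(p),
         cooccurrence = cooccurrence, noise_rate = noise_rate,
         reads_per_incidence = reads_per_incidence, seed = seed),
    class = "ev_population_model"
  )
}

#' Default distribution of distinct proteins per EV
#'
#' A 62% point mass on singletons plus a negative-binomial-shaped remainder
#' over 2..20 distinct proteins with its mode near 5, reproducing the
#' qualitative shape seen in deep-sequenced plasma EV populations: a
#' majority of singleton EVs, ~96% of EVs carrying 1-10 proteins, and the
#' most abundant multi-protein EVs carrying 5-6.
#'
#' @param singleton_fraction Probability of exactly one protein (default
#'   0.62).
#' @param size,mu Negative-binomial shape of the non-singleton remainder
#'   (defaults 10 and 5.5).
#' @param k_max Truncation point (default 20).
#' @return Probability vector over 1..`k_max`.
#' @export
default_proteins_per_ev_dist <- function(singleton_fraction = 0.62,
                                         size = 10, mu = 5.5, k_max = 20L) {
  tail_k <- 2:k_max
  w <- stats::dnbinom(tail_k, size = size, mu = mu)
  c(singleton_fraction, (1 - singleton_fraction) * w / sum(w))
}

#' Simulate one PBA sample
#'
#' Draws, for each EV, a distinct-protein count from the model's
#' distribution, then that many panel proteins (co-occurrence weighted,
#' without replacement), then a read count per true incidence; finally a
#' `noise_rate` fraction of reads is added uniformly over (existing EV tag,
#' random protein) pairs. The EV-level ground truth is retained for
#' evaluation.
#'
#' @param model An [ev_population_model()].
#' @param sample_id Sample identifier written into the read table.
#' @return A list of class `ev_sample_sim` with elements `reads` (tibble
#'   `sample_id`, `ev_tag`, `protein_tag`, `read_count`, aggregated and
#'   sorted), `truth` (tibble `ev_tag`, `protein_tag` of true incidences)
#'   and `panel`.
#' @export
simulate_ev_sample <- function(model, sample_id) {
  stopifnot(inherits(model, "ev_population_model"))
  if (model$n_evs == 0L) abort("n_evs is 0: nothing to simulate")
  if (!is.null(model$seed)) set.seed(model$seed)
  proteins <- panel_proteins(model$panel)
  n_prot <- length(proteins)
  n <- model$n_evs
  ev_tags <- sprintf("EV%07d", seq_len(n))
  k <- sample.int(length(model$proteins_per_ev_dist), n, replace = TRUE,
                  prob = model$proteins_per_ev_dist)
  picks <- draw_protein_sets(k, n_prot, model$cooccurrence)
  ev_idx <- rep.int(seq_len(n), k)
  reads_true <- model$reads_per_incidence(length(picks))
  if (any(reads_true < 1)) abort("reads_per_incidence must return counts >= 1")
  truth <- tibble(ev_tag = ev_tags[ev_idx], protein_tag = proteins[picks])
  reads <- tibble(
    ev_tag = truth$ev_tag,
    protein_tag = truth$protein_tag,
    read_count = as.integer(reads_true)
  )
  if (model$noise_rate > 0) {
    total_true <- sum(reads_true)
    n_noise <- round(model$noise_rate / (1 - model$noise_rate) * total_true)
    if (n_noise > 0) {
      noise <- tibble(
        ev_tag = ev_tags[sample.int(n, n_noise, replace = TRUE)],
        protein_tag = proteins[sample.int(n_prot, n_noise, replace = TRUE)],
        read_count = 1L
      )
      reads <- bind_rows(reads, noise)
    }
  }
  reads <- reads %>%
    group_by(.data$ev_tag, .data$protein_tag) %>%
    summarise(read_count = sum(.data$read_count), .groups = "drop") %>%
    mutate(sample_id = sample_id) %>%
    select("sample_id", "ev_tag", "protein_tag", "read_count") %>%
    arrange(.data$ev_tag, .data$protein_tag)
  structure(
    list(reads = reads, truth = arrange(truth, .data$ev_tag, .data$protein_tag),
         panel = model$panel),
    class = "ev_sample_sim"
  )
}

# sample k[i] distinct protein indices per EV; returns flat integer vector
# (lengths k). Uniform case is vectorized; cooccurrence weighting samples
# sequentially with weight prod(cooccurrence[S, j]) over already-picked S.
draw_protein_sets <- function(k, n_prot, cooccurrence = NULL) {
  if (is.null(cooccurrence)) {
    unlist(lapply(k, function(ki) sample.int(n_prot, ki)), use.names = FALSE)
  } else {
    unlist(lapply(k, function(ki) {
      picked <- integer(ki)
      w <- rep(1, n_prot)
      for (j in seq_len(ki)) {
        w_j <- w
        w_j[picked[seq_len(j - 1L)]] <- 0
        picked[j] <- sample.int(n_prot, 1L, prob = w_j)
        w <- w * cooccurrence[picked[j], ]
        if (all(w[-picked[seq_len(j)]] == 0)) w <- pmax(w, 1e-12)
      }
      picked
    }), use.names = FALSE)
  }
}

#' Model of a synthetic association cohort
#'
#' Describes a cohort of unrelated individuals with sex, age, EV-phenotype
#' abundances, anthropometric traits generated from declared EV effects and
#' sex interactions, and independent Hardy-Weinberg genotypes with declared
#' per-SNP effects on EV phenotypes and on a scalar complex trait of known
#' heritability.
#'
#' @param n_individuals Cohort size (default 96).
#' @param sex_ratio Proportion of males (coded 1; default 0.5).
#' @param age_range Uniform age range in years (default c(16, 100)).
#' @param ev_phenotypes Character vector of EV-phenotype labels to simulate.
#' @param ev_effects Tibble with columns `exposure`, `trait`, `beta_ev`,
#'   `beta_int`: effects of the inverse-normal transformed abundance (and
#'   its sex interaction) on each trait. Missing pairs default to zero.
#' @param traits Character vector of trait names (default the seven
#'   adiposity/lean-mass traits).
#' @param beta_sex,beta_age Shared covariate effects on every trait.
#' @param trait_noise_sd Residual standard deviation of the traits.
#' @param n_snps Number of independent biallelic SNPs (0 disables
#'   genotypes).
#' @param maf_range Uniform range for minor allele frequencies.
#' @param snp_effects_ev Tibble `snp` (index), `exposure`, `beta`: genetic
#'   effects on the latent EV abundances.
#' @param snp_effects_trait Tibble `snp`, `beta`: allelic effects on the
#'   scalar complex trait used for heritability-enrichment evaluation.
#' @param h2_trait Target heritability of the complex trait in [0, 1];
#'   residual variance is set so the realized genetic share equals this.
#' @param seed Integer seed.
#' @return A list of class `cohort_model`.
#' @export
cohort_model <- function(n_individuals = 96L,
                         sex_ratio = 0.5,
                         age_range = c(16, 100),
                         ev_phenotypes = character(),
                         ev_effects = NULL,
                         traits = c("BMI", "WC", "WHR", "total_lean",
                                    "trunk_fat", "trunk_lean", "visceral_fat"),
                         beta_sex = 0, beta_age = 0,
                         trait_noise_sd = 1,
                         n_snps = 0L,
                         maf_range = c(0.05, 0.5),
                         snp_effects_ev = NULL,
                         snp_effects_trait = NULL,
                         h2_trait = 0.5,
                         seed = NULL) {
  if (n_individuals < 3L) abort("n_individuals must be >= 3")
  if (any(maf_range <= 0) || any(maf_range > 0.5)) {
    abort("MAFs must lie in (0, 0.5]")
  }
  if (h2_trait < 0 || h2_trait > 1) abort("h2_trait must be in [0, 1]")
  if (!is.null(ev_effects)) {
    needed <- c("exposure", "trait", "beta_ev", "beta_int")
    if (!all(needed %in% names(ev_effects))) {
      abort("ev_effects needs columns exposure, trait, beta_ev, beta_int")
    }
    if (!all(ev_effects$exposure %in% ev_phenotypes)) {
      abort("ev_effects references unknown exposure labels")
    }
    if (!all(ev_effects$trait %in% traits)) {
      abort("ev_effects references unknown traits")
    }
  }
  if (!is.null(snp_effects_ev) && n_snps > 0 &&
      any(snp_effects_ev$snp > n_snps)) {
    abort("snp_effects_ev references SNP indices beyond n_snps")
  }
  if (!is.null(snp_effects_trait) && n_snps > 0 &&
      any(snp_effects_trait$snp > n_snps)) {
    abort("snp_effects_trait references SNP indices beyond n_snps")
  }
  structure(
    list(n_individuals = as.integer(n_individuals), sex_ratio = sex_ratio,
         age_range = age_range, ev_phenotypes = ev_phenotypes,
         ev_effects = ev_effects, traits = traits,
         beta_sex = beta_sex, beta_age = beta_age,
         trait_noise_sd = trait_noise_sd,
         n_snps = as.integer(n_snps), maf_range = maf_range,
         snp_effects_ev = snp_effects_ev,
         snp_effects_trait = snp_effects_trait,
         h2_trait = h2_trait, seed = seed),
    class = "cohort_model"
  )
}

#' Simulate a genotype/phenotype cohort with known truth
#'
#' Traits are generated as
#' `Y = sum_j beta_EV_j X*_j + beta_sex Sex + beta_age Age_c + sum_j
#' beta_int_j X*_j Sex + noise`, with `X*` the inverse-normal transformed EV
#' abundances and `Age_c` age centered; genotypes are independent
#' Hardy-Weinberg dosages; the complex trait is `G b + e` with residual
#' variance chosen so the realized genetic variance share equals
#' `h2_trait`. Per-SNP heritability contributions (realized
#' `b_j^2 * var(g_j)` shares) are recorded as enrichment truth.
#'
#' @param model A [cohort_model()].
#' @return A list of class `cohort_sim`: `phenotypes` (tibble `sample_id`,
#'   `sex`, `age`, traits, `complex_trait`), `ev_abundance` (tibble
#'   `sample_id` + one column per EV phenotype, proportions in (0, 1)),
#'   `genotypes` (individuals x SNPs dosage matrix or NULL), `snp_info`
#'   (tibble `snp`, `chr`, `pos`, `maf`), `truth` (list with `ev_effects`,
#'   `snp_h2` per-SNP heritability contributions summing to the realized
#'   h2, `h2_trait`).
#' @export
simulate_cohort <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  if (!is.null(model$seed)) set.seed(model$seed)
  n <- model$n_individuals
  sex <- rbinom(n, 1L, model$sex_ratio)
  age <- runif(n, model$age_range[1], model$age_range[2])
  sample_id <- sprintf("ind%03d", seq_len(n))

  # genotypes: independent HWE biallelic SNPs on one synthetic chromosome
  genotypes <- NULL
  snp_info <- NULL
  g_ev <- matrix(0, n, max(1L, length(model$ev_phenotypes)))
  complex_trait <- rep(NA_real_, n)
  snp_h2 <- NULL
  if (model$n_snps > 0L) {
    maf <- runif(model$n_snps, model$maf_range[1], model$maf_range[2])
    genotypes <- vapply(maf, function(f) rbinom(n, 2L, f), numeric(n))
    colnames(genotypes) <- sprintf("snp%05d", seq_len(model$n_snps))
    rownames(genotypes) <- sample_id
    snp_info <- tibble(
      snp = colnames(genotypes), chr = "1",
      pos = as.integer(seq_len(model$n_snps) * 5000L), maf = maf
    )
    if (!is.null(model$snp_effects_ev) && length(model$ev_phenotypes) > 0) {
      for (r in seq_len(nrow(model$snp_effects_ev))) {
        j <- match(model$snp_effects_ev$exposure[r], model$ev_phenotypes)
        g_ev[, j] <- g_ev[, j] +
          genotypes[, model$snp_effects_ev$snp[r]] * model$snp_effects_ev$beta[r]
      }
    }
    b <- rep(0, model$n_snps)
    if (!is.null(model$snp_effects_trait)) {
      b[model$snp_effects_trait$snp] <- model$snp_effects_trait$beta
    }
    g_val <- as.numeric(genotypes %*% b)
    var_g <- var(g_val)
    if (var_g > 0 && model$h2_trait > 0) {
      sigma2_e <- var_g * (1 - model$h2_trait) / model$h2_trait
      complex_trait <- g_val + rnorm(n, 0, sqrt(sigma2_e))
      contrib <- b^2 * apply(genotypes, 2, var)
      # per-SNP share of genetic variance, scaled to the realized h2
      realized_h2 <- var_g / (var_g + sigma2_e)
      snp_h2 <- tibble(
        snp = colnames(genotypes),
        h2 = contrib / sum(contrib) * realized_h2
      )
    } else {
      complex_trait <- rnorm(n)
      snp_h2 <- tibble(snp = colnames(genotypes), h2 = 0)
    }
  }

  # EV abundances: genetic value + unit noise on a latent scale, mapped to
  # a proportion scale (rank-preserving, so INT-based analysis is unaffected)
  n_ev <- length(model$ev_phenotypes)
  ev_abundance <- tibble(sample_id = sample_id)
  x_star <- NULL
  if (n_ev > 0) {
    latent <- g_ev[, seq_len(n_ev), drop = FALSE] +
      matrix(rnorm(n * n_ev), n, n_ev)
    ab <- stats::plogis(latent) * 0.2
    colnames(ab) <- model$ev_phenotypes
    ev_abundance <- bind_cols(ev_abundance, as_tibble(ab))
    x_star <- apply(ab, 2, inverse_normal_transform)
  }

  # traits with declared EV effects and sex interactions
  age_c <- age - mean(age)
  phen <- tibble(sample_id = sample_id, sex = sex, age = age)
  for (tr in model$traits) {
    y <- model$beta_sex * sex + model$beta_age * age_c +
      rnorm(n, 0, model$trait_noise_sd)
    if (!is.null(model$ev_effects) && n_ev > 0) {
      eff <- dplyr::filter(model$ev_effects, .data$trait == tr)
      for (r in seq_len(nrow(eff))) {
        j <- match(eff$exposure[r], model$ev_phenotypes)
        y <- y + eff$beta_ev[r] * x_star[, j] +
          eff$beta_int[r] * x_star[, j] * sex
      }
    }
    phen[[tr]] <- y
  }
  phen$complex_trait <- complex_trait

  structure(
    list(phenotypes = phen, ev_abundance = ev_abundance,
         genotypes = genotypes, snp_info = snp_info,
         truth = list(ev_effects = model$ev_effects, snp_h2 = snp_h2,
                      h2_trait = model$h2_trait)),
    class = "cohort_sim"
  )
}
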