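test_that("GWAS phenotype preparation residualizes then Z-scores", {
  set.seed(10)
  n <- 60
  cov <- data.frame(sex = rep(0:1, n / 2), age = runif(n, 20, 80))
  ab <- runif(n)
  z <- prepare_gwas_phenotype(ab, cov)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sd(z), 1, tolerance = 0.1) # INT sd is ~1, not exactly 1
  # covariates orthogonal to abundance: output = INT of centered abundance
  cov0 <- data.frame(c1 = rep(c(-1, 1), n / 2))
  ab_orth <- ab - mean(ab)
  ab_orth <- ab_orth - cov0$c1 * sum(ab_orth * cov0$c1) / sum(cov0$c1^2)
  expect_equal(prepare_gwas_phenotype(ab_orth, cov0),
               inverse_normal_transform(ab_orth))
  # rank-deficient covariates rejected
  expect_error(prepare_gwas_phenotype(ab, cbind(cov, sex2 = cov$sex)),
               "rank deficient")
  # abundance exactly linear in a covariate: near-constant residuals flagged
  expect_warning(prepare_gwas_phenotype(2 + 3 * cov$age, cov),
                 "near-constant")
})

test_that("MAF filter retains strictly above threshold and nests", {
  set.seed(20)
  n <- 400
  g <- cbind(
    rbinom(n, 2, 0.1), rbinom(n, 2, 0.2), rbinom(n, 2, 0.3)
  )
  # force exact empirical MAFs
  g <- rbind(matrix(rep(c(0, 0, 0), n), ncol = 3, byrow = TRUE))
  g[, 1][1:(2 * n * 0.1)] <- 1
  g[, 2][1:(2 * n * 0.2)] <- 1
  g[, 3][1:(2 * n * 0.3)] <- 1
  colnames(g) <- c("a", "b", "c")
  info <- tibble::tibble(snp = colnames(g), chr = "1", pos = c(100L, 200L, 300L))
  flt <- maf_filter(g, info, threshold = 0.2)
  expect_equal(flt$snp_info$snp, "c") # 0.2 is excluded: strict >
  # threshold 0 removes monomorphic SNPs only
  g2 <- cbind(g, mono = 0)
  info2 <- dplyr::bind_rows(info, tibble::tibble(snp = "mono", chr = "1",
                                                 pos = 400L))
  flt0 <- maf_filter(g2, info2, threshold = 0)
  expect_setequal(flt0$snp_info$snp, c("a", "b", "c"))
  # nesting: stricter threshold is a subset
  flt05 <- maf_filter(g2, info2, threshold = 0.05)
  expect_true(all(flt$snp_info$snp %in% flt05$snp_info$snp))
  expect_error(maf_filter(g, info, 0.5), "threshold")
})

test_that("per-SNP betas match the closed-form and lm oracle to 1e-10", {
  set.seed(30)
  n <- 96
  g <- hwe_genotypes(n, 50)
  z <- rnorm(n)
  res <- linear_gwas(z, g)
  for (j in seq_len(20)) {
    ref <- summary(lm(z ~ g[, j]))$coefficients
    expect_equal(res$beta[j], ref[2, 1], tolerance = 1e-10)
    expect_equal(res$se[j], ref[2, 2], tolerance = 1e-10)
    expect_equal(res$p[j], ref[2, 4], tolerance = 1e-10)
  }
  # matrix-algebra closed form (X'X)^{-1} X'y
  X <- cbind(1, g[, 1])
  expect_equal(res$beta[1], solve(crossprod(X), crossprod(X, z))[2],
               tolerance = 1e-12)
})

test_that("null genome scan is calibrated: lambda ~ 1, P uniform", {
  set.seed(40)
  n <- 96
  g <- hwe_genotypes(n, 5000)
  z <- inverse_normal_transform(rnorm(n))
  res <- linear_gwas(z, g)
  expect_lt(abs(lambda_gc(res) - 1), 0.05)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
  # permutation leaves the rejection rate at alpha
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.01)
})

test_that("a strongly causal SNP is the top hit", {
  set.seed(50)
  n <- 96
  hits <- replicate(200, {
    g <- hwe_genotypes(n, 100, maf_range = c(0.2, 0.5))
    z <- as.numeric(scale(g[, 37] * 1.5 + rnorm(n)))
    which.min(linear_gwas(z, g)$p) == 37
  })
  expect_gte(mean(hits), 0.95)
})

test_that("constant genotype columns are skipped with a warning", {
  set.seed(60)
  g <- hwe_genotypes(50, 5)
  g[, 3] <- 1
  expect_warning(res <- linear_gwas(rnorm(50), g), "constant")
  expect_true(is.na(res$beta[3]))
  expect_false(anyNA(res$beta[-3]))
})

test_that("SNP-set extraction groups by marker plus the pair set", {
  set.seed(70)
  markers <- sprintf("M%02d", 1:12)
  others <- sprintf("O%02d", 1:5)
  info <- tibble::tibble(snp = sprintf("s%03d", 1:50), chr = "1",
                         pos = as.integer(1:50 * 1000))
  fake_gwas <- function(sig_idx) {
    p <- runif(50, 0.1, 1)
    p[sig_idx] <- 1e-8
    tibble::tibble(snp = info$snp, chr = info$chr, pos = info$pos,
                   beta = 0, se = 1, p = p)
  }
  results <- list()
  for (mk in markers) {
    results[[paste0("EV_", mk, " & ", others[1])]] <- fake_gwas(match(mk, markers))
  }
  results[["EV_M01 & M02"]] <- fake_gwas(c(1, 30))
  sets <- extract_snp_sets(results, markers, p_threshold = 1e-6)
  expect_equal(length(unique(sets$set_label)), 13L)
  # marker M01's set unions across its two phenotypes, deduplicated
  m01 <- dplyr::filter(sets, set_label == "M01")
  expect_setequal(m01$snp, c("s001", "s030"))
  pair <- dplyr::filter(sets, set_label == "marker_pairs")
  expect_setequal(pair$snp, c("s001", "s030"))
  # single marker gives 2 set labels (its union set + the pair set)
  one <- suppressWarnings(extract_snp_sets(results["EV_M01 & O01"], "M01"))
  expect_equal(length(attr(one, "set_labels")), 2L)
  # threshold 1 includes every tested SNP
  all_in <- extract_snp_sets(results, markers, p_threshold = 1)
  expect_equal(nrow(dplyr::filter(all_in, set_label == "M05")), 50L)
  # nesting in the threshold; the stricter run empties every set (warned)
  loose <- extract_snp_sets(results, markers, p_threshold = 1e-4)
  expect_warning(strict <- extract_snp_sets(results, markers,
                                            p_threshold = 1e-10),
                 "empty SNP set")
  for (lab in markers) {
    expect_true(all(strict$snp[strict$set_label == lab] %in%
                      loose$snp[loose$set_label == lab]))
  }
})

test_that("flank annotation merges overlaps, clips at zero, honours window", {
  info <- tibble::tibble(
    snp = c("a", "b", "c", "d"), chr = "1",
    pos = c(0L, 500L, 5000L, 20000L)
  )
  set_snps <- info[1:3, ]
  ann <- annotate_flanks(set_snps, info, window_bp = 1000L)
  # a (pos 0, clipped) and b (pos 500) merge; c separate
  expect_equal(nrow(ann$intervals), 2L)
  expect_equal(ann$intervals$start[1], 0L)
  expect_setequal(ann$members, c("a", "b", "c"))
  expect_equal(ann$proportion_of_snps, 3 / 4)
  # window 0: membership is the member SNPs only
  ann0 <- annotate_flanks(set_snps, info, window_bp = 0L)
  expect_setequal(ann0$members, c("a", "b", "c"))
  expect_equal(nrow(ann0$intervals), 3L)
  # a nearby non-member SNP inside a window becomes annotation-positive
  info2 <- dplyr::bind_rows(info, tibble::tibble(snp = "e", chr = "1",
                                                 pos = 5600L))
  ann2 <- annotate_flanks(set_snps, info2, window_bp = 1000L)
  expect_true("e" %in% ann2$members)
})

test_that("enrichment score is exact in forced configurations", {
  h2 <- tibble::tibble(snp = sprintf("s%03d", 1:100),
                       h2 = c(rep(0.02, 25), rep(0, 75)))
  # all SNPs annotated: score exactly 1
  all_ann <- enrichment_score(h2$snp, h2)
  expect_equal(all_ann$enrichment, 1)
  # all heritability inside a 25%-of-SNPs annotation: score exactly 4
  quarter <- enrichment_score(h2$snp[1:25], h2)
  expect_equal(quarter$enrichment, 4)
  expect_equal(quarter$proportion_of_h2, 1)
  expect_error(enrichment_score(character(), h2), "no SNPs")
  expect_error(enrichment_score(h2$snp, dplyr::mutate(h2, h2 = 0)), "positive")
})

test_that("random annotations score 1 on average", {
  set.seed(80)
  h2 <- tibble::tibble(snp = sprintf("s%04d", 1:1000), h2 = runif(1000))
  scores <- replicate(100, {
    enrichment_score(sample(h2$snp, 250), h2, n_blocks = 50)$enrichment
  })
  mc_se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - 1), 3 * mc_se)
})

test_that("planted enrichment is recovered within the jackknife SE", {
  # architecture: 25% of SNPs annotated, carrying 75% of h2 -> score 3
  set.seed(90)
  cm <- cohort_model(
    n_individuals = 96L, n_snps = 1000L,
    snp_effects_trait = tibble::tibble(
      snp = c(1:250, 251:1000),
      beta = c(rep(sqrt(3) * 0.1, 250), rep(0.1 / sqrt(3), 750))
    ),
    h2_trait = 0.5, seed = 90
  )
  co <- simulate_cohort(cm)
  truth <- co$truth$snp_h2
  ann <- truth$snp[1:250]
  sc <- enrichment_score(ann, truth)
  # MAF variation perturbs realized per-SNP variance; the planted f/s = 3
  # must be inside score +/- 2*SE and inside the 2-4-fold regime
  expect_lt(abs(sc$enrichment - 3), 2 * sc$se + 0.3)
  expect_gt(sc$enrichment, 2)
  expect_lt(sc$enrichment, 4)
})
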