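test_that("marker-pair enumeration yields singles plus unordered pairs", {
  panel <- ev_panel()
  markers <- panel_markers <- panel$protein[panel$is_marker]
  types <- enumerate_ev_types(markers, panel)
  expect_equal(nrow(types), 78L) # 12 singles + 66 pairs
  expect_equal(sum(types$size == 1), 12L)
  expect_equal(sum(types$size == 2), 66L)
  expect_false(anyDuplicated(types$label) > 0)
  # canonical labels: alphabetical, " & "-joined, EV_ prefixed
  expect_true(all(grepl("^EV_", types$label)))
  pairs <- dplyr::filter(types, size == 2)
  expect_true(all(pairs$marker_1 < pairs$marker_2))

  two <- enumerate_ev_types(c("P001", "P002"), panel)
  expect_equal(nrow(two), 3L)
  expect_error(enumerate_ev_types("ZZZ", panel), "ZZZ")
})

test_that("marker-vs-panel enumeration counts |M|(n-|M|) + C(|M|,2)", {
  panel <- ev_panel()
  markers <- panel$protein[panel$is_marker]
  types <- suppressMessages(
    enumerate_ev_types(markers, panel, scheme = "marker_vs_panel")
  )
  expect_equal(nrow(types), 12L * 101L + 66L) # 1278
  expect_true(all(types$size == 2))
  # every pair touches at least one marker; brute-force cross-check
  touches <- types$marker_1 %in% markers | types$marker_2 %in% markers
  expect_true(all(touches))
  all_pairs <- utils::combn(panel$protein, 2)
  brute <- sum(all_pairs[1, ] %in% markers | all_pairs[2, ] %in% markers)
  expect_equal(nrow(types), brute)
})

test_that("enumeration counts obey the closed forms for all small panels", {
  for (n in 2:15) {
    panel <- ev_panel(sprintf("Q%02d", 1:n), markers = character())
    for (m in 1:n) {
      markers <- sprintf("Q%02d", 1:m)
      panel_m <- ev_panel(sprintf("Q%02d", 1:n), markers = markers)
      expect_equal(nrow(enumerate_ev_types(markers, panel_m)),
                   m + choose(m, 2))
      expect_equal(
        nrow(suppressMessages(enumerate_ev_types(markers, panel_m,
                                                 scheme = "marker_vs_panel"))),
        m * (n - m) + choose(m, 2)
      )
    }
  }
})

test_that("at-least and exact quantification agree with brute force", {
  prof <- profile_from_matrix(nested_support_matrix())
  types <- enumerate_ev_types(c("P1", "P2"), prof$panel)
  pair <- dplyr::filter(types, label == "EV_P1 & P2")
  at_least <- quantify_ev_type(prof, pair)
  expect_equal(at_least$raw_count, 2L)
  expect_equal(at_least$abundance, 2 / 3)
  pair_exact <- dplyr::mutate(pair, match_mode = "exact")
  expect_equal(quantify_ev_type(prof, pair_exact)$raw_count, 1L)
  # absent marker: zero, not missing
  t9 <- enumerate_ev_types("P4", prof$panel)
  expect_equal(quantify_ev_type(prof, t9[1, ])$abundance, 0)
})

test_that("exact-mode counts over size-1/2 supports partition the rows", {
  set.seed(33)
  for (rep in 1:3) {
    m <- matrix(rbinom(40 * 4, 1, 0.4), 40, 4,
                dimnames = list(NULL, sprintf("P%d", 1:4)))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    prof <- profile_from_matrix(m)
    types <- dplyr::mutate(
      enumerate_ev_types(sprintf("P%d", 1:4), prof$panel),
      match_mode = "exact"
    )
    exact_counts <- vapply(seq_len(nrow(types)), function(i) {
      quantify_ev_type(prof, types[i, ])$raw_count
    }, numeric(1))
    k <- Matrix::rowSums(prof$counts > 0)
    # exact types of size 1 and 2, plus rows with >2 proteins, tile all rows
    expect_equal(sum(exact_counts) + sum(k > 2), nrow(prof$counts))
  }
})

test_that("pair abundance never exceeds either constituent single (anti-monotone)", {
  set.seed(71)
  sim <- simulate_ev_sample(ev_population_model(
    panel = ev_panel(sprintf("P%02d", 1:15), markers = sprintf("P%02d", 1:4)),
    n_evs = 2000L, seed = 71,
    proteins_per_ev_dist = default_proteins_per_ev_dist(k_max = 10L)
  ), "s1")
  prof <- parse_reads(sim$reads, sim$panel, "s1")
  types <- enumerate_ev_types(sprintf("P%02d", 1:4), prof$panel)
  tbl <- build_phenotype_table(list(prof), types)
  for (i in which(types$size == 2)) {
    pair_ab <- tbl[[types$label[i]]]
    s1 <- tbl[[paste0("EV_", types$marker_1[i])]]
    s2 <- tbl[[paste0("EV_", types$marker_2[i])]]
    expect_lte(pair_ab, min(s1, s2))
  }
})

test_that("total protein level is the read-proportion of the column", {
  m <- rbind(c(2L, 3L, 0L), c(0L, 0L, 5L))
  colnames(m) <- c("P1", "P2", "P3")
  prof <- profile_from_matrix(m)
  lv <- total_protein_level(prof)
  expect_equal(lv$level, c(0.2, 0.3, 0.5))
  # row permutation leaves levels unchanged
  lv2 <- total_protein_level(profile_from_matrix(m[2:1, ]))
  expect_equal(lv2$level, lv$level)
  expect_error(total_protein_level(prof, "P99"), "P99")
  # single-column concentration gives level 1
  one <- profile_from_matrix(matrix(c(4L, 0L), 1, 2,
                                    dimnames = list("e1", c("P1", "P2"))))
  expect_equal(total_protein_level(one, "P1")$level, 1)
})

test_that("phenotype table has canonical shape, zeros, and replicate determinism", {
  sim1 <- simulate_ev_sample(ev_population_model(n_evs = 500L, seed = 5), "a")
  sim2 <- simulate_ev_sample(ev_population_model(n_evs = 500L, seed = 6), "b")
  p1 <- parse_reads(sim1$reads, sim1$panel, "a")
  p2 <- parse_reads(sim2$reads, sim2$panel, "b")
  types <- enumerate_ev_types(sprintf("P%03d", 1:12), p1$panel)
  tbl <- build_phenotype_table(list(p1, p2), types)
  expect_equal(dim(tbl), c(2L, 79L))
  expect_equal(names(tbl)[-1], types$label)
  expect_false(anyNA(tbl))
  # identical matrix under two ids gives identical rows
  p1b <- p1; p1b$sample_id <- "a2"
  tbl2 <- build_phenotype_table(list(p1, p1b), types)
  expect_equal(unname(unlist(tbl2[1, -1])), unname(unlist(tbl2[2, -1])))
  expect_error(build_phenotype_table(list(p1, p1), types), "duplicate")
  # disk round-trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_table(tbl, tsv)
  expect_equal(as.data.frame(read_phenotype_table(tsv)), as.data.frame(tbl))
})
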