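# shared fixture builders: everything is generated in code at test time

# build an ev_profile from a dense count matrix via the public read-table API
profile_from_matrix <- function(mat, sample_id = "s1",
                                panel = ev_panel(colnames(mat))) {
  stopifnot(!is.null(colnames(mat)))
  if (is.null(rownames(mat))) {
    rownames(mat) <- sprintf("e%03d", seq_len(nrow(mat)))
  }
  idx <- which(mat > 0, arr.ind = TRUE)
  reads <- tibble::tibble(
    sample_id = sample_id,
    ev_tag = rownames(mat)[idx[, 1]],
    protein_tag = colnames(mat)[idx[, 2]],
    read_count = as.integer(mat[idx])
  )
  parse_reads(reads, panel, sample_id)
}

# all-singleton 3-EV matrix
singleton_matrix <- function() {
  m <- diag(3L) * 2L
  dimnames(m) <- list(NULL, c("P1", "P2", "P3"))
  m
}

# tiny 3-EV matrix with supports {P1}, {P1,P2}, {P1,P2,P3}
nested_support_matrix <- function() {
  m <- matrix(0L, 3, 4, dimnames = list(c("e1", "e2", "e3"),
                                        c("P1", "P2", "P3", "P4")))
  m["e1", "P1"] <- 2L
  m["e2", c("P1", "P2")] <- c(1L, 3L)
  m["e3", c("P1", "P2", "P3")] <- c(2L, 1L, 1L)
  m
}

# independent BH step-up oracle (direct definition, no p.adjust)
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# HWE genotype matrix for null GWAS simulations
hwe_genotypes <- function(n, n_snps, maf_range = c(0.05, 0.5)) {
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  g <- vapply(maf, function(f) rbinom(n, 2L, f), numeric(n))
  colnames(g) <- sprintf("snp%05d", seq_len(n_snps))
  rownames(g) <- sprintf("ind%03d", seq_len(n))
  g
}
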