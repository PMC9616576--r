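#' Read and write PBA read tables
#'
#' The on-disk read-table format is tab-separated text with header columns
#' `sample_id`, `ev_tag`, `protein_tag`, `read_count`.
#'
#' @param path File path.
#' @return `read_pba_reads` returns a tibble in read-table form.
#' @export
read_pba_reads <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       colClasses = c("character", "character", "character",
                                      "integer")))
}

#' @rdname read_pba_reads
#' @param reads A read-table tibble.
#' @export
write_pba_reads <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export / import an EV profile as MatrixMarket
#'
#' Writes the sparse counts as `<stem>.mtx` with row (EV tag) and column
#' (protein) label files `<stem>.rows.txt` / `<stem>.cols.txt`.
#'
#' @param profile An `ev_profile`.
#' @param stem Path stem (no extension).
#' @export
write_profile_mtx <- function(profile, stem) {
  Matrix::writeMM(as(profile$counts, "CsparseMatrix"), paste0(stem, ".mtx"))
  writeLines(rownames(profile$counts), paste0(stem, ".rows.txt"))
  writeLines(colnames(profile$counts), paste0(stem, ".cols.txt"))
  invisible(stem)
}

#' @rdname write_profile_mtx
#' @param panel The [ev_panel()] the columns belong to.
#' @param sample_id Sample identifier to attach.
#' @export
read_profile_mtx <- function(stem, panel, sample_id) {
  counts <- as(Matrix::readMM(paste0(stem, ".mtx")), "CsparseMatrix")
  dimnames(counts) <- list(readLines(paste0(stem, ".rows.txt")),
                           readLines(paste0(stem, ".cols.txt")))
  new_ev_profile(sample_id, counts, assert_panel(panel))
}

#' Read and write the samples-by-EV-types phenotype table
#'
#' Tab-separated, samples in rows, EV-type labels in the header; round-trips
#' losslessly.
#'
#' @param table Phenotype tibble from [build_phenotype_table()].
#' @param path File path.
#' @export
write_phenotype_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                       stringsAsFactors = FALSE))
}

#' Write genotypes as a dosage matrix or minimal VCF
#'
#' The dosage format is tab-separated with a `sample_id` column followed by
#' one column per SNP. The VCF writer emits a minimal VCFv4.2 file with GT
#' genotypes (0/0, 0/1, 1/1) for hard-called dosages.
#'
#' @param genotypes Individuals x SNPs dosage matrix.
#' @param snp_info Tibble `snp`, `chr`, `pos` (1-based positions are written
#'   to VCF; internal positions are 0-based and converted).
#' @param path Output path.
#' @export
write_dosage_matrix <- function(genotypes, path) {
  df <- data.frame(sample_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_matrix
#' @export
read_dosage_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df$sample_id
  g
}

#' @rdname write_dosage_matrix
#' @export
write_vcf <- function(genotypes, snp_info, path) {
  gt <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(snp_info)), function(i) {
    calls <- gt[round(genotypes[, snp_info$snp[i]]) + 1L]
    paste(c(snp_info$chr[i], snp_info$pos[i] + 1L, snp_info$snp[i], "A", "G",
            ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_dosage_matrix
#' @return `read_vcf_dosages` returns a list with `genotypes` (dosage
#'   matrix) and `snp_info` (0-based positions).
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  list(
    genotypes = t(dos),
    snp_info = tibble(snp = fix$ID, chr = fix$CHROM,
                      pos = as.integer(fix$POS) - 1L)
  )
}

#' Write SNP annotations as BED
#'
#' BED is 0-based half-open, matching the internal interval convention; one
#' row per merged flanking interval, the set label in the name column.
#'
#' @param annotation A `snp_annotation` from [annotate_flanks()].
#' @param label Set label written to the name column.
#' @param path Output path.
#' @export
write_bed <- function(annotation, label, path) {
  iv <- annotation$intervals
  write.table(
    data.frame(chrom = iv$chr, chromStart = iv$start, chromEnd = iv$end,
               name = label),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' A single declarative YAML file with nested sections mirroring the
#' population-model, cohort-model and filter-configuration fields; see
#' [run_pipeline()].
#'
#' @param path Path to a YAML config.
#' @return A named list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
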