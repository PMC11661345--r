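# Plain-text interchange for the pipeline's tables. Coordinate conventions
# are centralized here: variant tables and gene models are 1-based inclusive;
# BED output is 0-based half-open.

#' Read and write summary-statistics TSV
#'
#' The dialect has columns CHR, POS, SNP, A1, A2, FREQ, BETA, SE, P, N_EFF
#' (effect allele A1, 1-based positions).
#'
#' @param stats A variant-statistics tibble (as from [simulate_sumstats()]).
#' @param path File path.
#' @param ancestry Ancestry label attached on read.
#' @return `read_sumstats()` returns the tibble; `write_sumstats()` returns
#'   `path` invisibly.
#' @export
write_sumstats <- function(stats, path) {
  out <- tibble::tibble(
    CHR = stats$chrom, POS = stats$pos, SNP = stats$snp,
    A1 = stats$a1, A2 = stats$a2, FREQ = stats$eaf,
    BETA = stats$beta, SE = stats$se, P = stats$p, N_EFF = stats$n_eff
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path, ancestry) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    chrom = raw$CHR, pos = raw$POS, snp = raw$SNP,
    a1 = raw$A1, a2 = raw$A2, eaf = raw$FREQ,
    beta = raw$BETA, se = raw$SE, p = raw$P, n_eff = raw$N_EFF,
    ancestry = ancestry
  )
}

#' Write a PLINK-style variant map (.bim dialect)
#'
#' Columns CHR, SNP, CM (always 0), POS, A1, A2, tab-separated, no header.
#'
#' @param map A variant map tibble (`chrom`, `snp`, `pos`, `a1`, `a2`).
#' @param path File path.
#' @export
write_bim <- function(map, path) {
  out <- tibble::tibble(CHR = map$chrom, SNP = map$snp, CM = 0,
                        POS = map$pos, A1 = map$a1, A2 = map$a2)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write gene models as BED
#'
#' Converts the 1-based inclusive gene table to 0-based half-open BED
#' (start - 1, end).
#'
#' @param genes Gene table (`gene`, `chrom`, `start`, `end`).
#' @param path File path.
#' @export
write_genes_bed <- function(genes, path) {
  out <- tibble::tibble(chrom = genes$chrom, start = genes$start - 1L,
                        end = genes$end, name = genes$gene)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Write / read the gene-feature matrix as TSV
#'
#' First column `gene`, one column per feature.
#'
#' @param features Numeric matrix with gene-id row names.
#' @param path File path.
#' @export
write_features <- function(features, path) {
  out <- tibble::as_tibble(features, rownames = "gene")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(raw[, -1])
  rownames(m) <- raw$gene
  m
}

#' Write the non-synonymous variant annotation (SNP, GENE) as TSV
#'
#' @param nonsyn Tibble with columns `snp`, `gene`.
#' @param path File path.
#' @export
write_nonsyn <- function(nonsyn, path) {
  readr::write_tsv(tibble::tibble(SNP = nonsyn$snp, GENE = nonsyn$gene), path)
  invisible(path)
}
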