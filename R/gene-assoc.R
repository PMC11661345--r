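# Gene-level association: SNP-wise mean statistic with its LD-determined
# mixture-of-chi-square null, computed per ancestry against that ancestry's
# own reference panel and frequencies, then meta-analyzed across ancestries
# on the z-score scale with sqrt(sample size) weights.

#' Map variants to gene bodies
#'
#' Assigns every variant with minor-allele frequency above `maf_min` to each
#' gene whose body (1-based, closed interval, no flanking window) contains
#' its position. Overlapping genes each receive the variant.
#'
#' @param stats Variant-statistics tibble.
#' @param genes Gene table (`gene`, `chrom`, `start`, `end`).
#' @param maf_min Minimum minor-allele frequency (exclusive).
#' @return A tibble with columns `gene`, `snp`.
#' @export
map_variants_to_genes <- function(stats, genes, maf_min = 0.01) {
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  common <- stats[maf > maf_min, c("chrom", "pos", "snp")]
  dplyr::inner_join(common, genes[, c("gene", "chrom", "start", "end")],
                    by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    dplyr::select("gene", "snp")
}

#' SNP-wise mean gene association test
#'
#' The statistic is the mean squared z-score over the gene's variants. Under
#' the null, `z ~ Normal(0, R)` with `R` the variants' LD correlation
#' matrix, so the statistic is distributed as `(1/m) * sum_k lambda_k
#' chisq_1` with `lambda_k` the eigenvalues of `R`; the p-value comes from
#' [pvalue_quadform()]. Eigenvalues are floored at 1e-8 before the tail
#' computation. The gene z-score is the upper-tail probit of the p-value.
#'
#' @param z Variant z-scores (at least 3).
#' @param ld Their LD correlation matrix (positive semi-definite).
#' @return A one-row tibble: `n_variants`, `stat`, `p`, `z`.
#' @export
snpwise_mean_test <- function(z, ld) {
  m <- length(z)
  if (m < 3) abort("snpwise_mean_test needs at least 3 variants")
  stopifnot(nrow(ld) == m, ncol(ld) == m)
  ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) abort("LD matrix is not positive semi-definite")
  lambda <- pmax(ev, 1e-8) / m
  stat <- mean(z^2)
  p <- pvalue_quadform(stat, lambda)
  tibble::tibble(n_variants = m, stat = stat, p = p, z = z_from_p_upper(p))
}

#' Gene-level association scores for one ancestry
#'
#' Runs [snpwise_mean_test()] for every gene with at least `min_variants`
#' mapped common variants, using the ancestry's own panel LD.
#'
#' @param stats Harmonized variant-statistics tibble for one ancestry.
#' @param panel That ancestry's `ld_panel`.
#' @param genes Gene table.
#' @param maf_min Minimum minor-allele frequency for mapping.
#' @param min_variants Genes with fewer mapped variants are not scored.
#' @return A tibble: `gene`, `ancestry`, `n_eff`, `n_variants`, `stat`,
#'   `p`, `z`.
#' @export
gene_assoc_scores <- function(stats, panel, genes, maf_min = 0.01,
                              min_variants = 3) {
  mapping <- map_variants_to_genes(stats, genes, maf_min)
  zs <- setNames(stats$beta / stats$se, stats$snp)
  n_eff <- stats$n_eff[1]
  by_gene <- split(mapping$snp, mapping$gene)
  rows <- lapply(names(by_gene), function(g) {
    snps <- by_gene[[g]]
    if (length(snps) < min_variants) return(NULL)
    R <- panel_ld(panel, snps)
    snps <- setdiff(snps, attr(R, "dropped"))
    if (length(snps) < min_variants) return(NULL)
    res <- snpwise_mean_test(zs[snps], R)
    dplyr::mutate(res, gene = g, .before = 1)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(ancestry = panel$label, n_eff = n_eff) |>
    dplyr::select("gene", "ancestry", "n_eff", "n_variants", "stat", "p", "z")
}

#' Meta-analyze gene z-scores across ancestries
#'
#' Combines per-ancestry gene z-scores with square-root-of-sample-size
#' weights: `z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))`, `w_i =
#' sqrt(n_eff_i)`. Genes scored in a single ancestry carry that z through.
#'
#' @param scores_by_ancestry List of [gene_assoc_scores()] tibbles (or one
#'   bound tibble with an `ancestry` column).
#' @return A tibble: `gene`, `n_ancestries`, `meta_z`.
#' @export
meta_gene_z <- function(scores_by_ancestry) {
  scores <- if (is.data.frame(scores_by_ancestry)) scores_by_ancestry
            else dplyr::bind_rows(scores_by_ancestry)
  scores |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_ancestries = dplyr::n(),
      meta_z = sum(sqrt(.data$n_eff) * .data$z) / sqrt(sum(.data$n_eff)),
      .groups = "drop"
    )
}
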