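# Per-locus gene prioritization: a gene is called when it is both the
# nearest gene to the credible set's PIP-weighted center and carries the
# locus's top PoPS score, or when non-synonymous credible-set variants
# mapped to it hold more than half the posterior mass. When both criteria
# fire in one locus, the non-synonymous call wins.

#' Distance from a gene body to a genomic position
#'
#' Zero when the position falls inside the (1-based, closed) gene body,
#' otherwise the distance to the nearer gene edge.
#'
#' @param gene One gene record (`chrom`, `start`, `end`), or a gene table
#'   (vectorized).
#' @param center Position in bp (may be fractional: PIP-weighted centers
#'   are real-valued).
#' @param chrom Chromosome of `center`; must equal the gene's.
#' @return Distance(s) in bp.
#' @export
gene_distance <- function(gene, center, chrom = gene$chrom[1]) {
  if (any(gene$chrom != chrom)) {
    abort("gene_distance is only defined within one chromosome")
  }
  inside <- center >= gene$start & center <= gene$end
  ifelse(inside, 0, pmin(abs(center - gene$start), abs(center - gene$end)))
}

#' Apply the prioritization rule to one locus
#'
#' Candidate genes are the locus's overlapping genes. Criterion A
#' prioritizes the gene that is simultaneously the nearest gene to the
#' credible set's PIP-weighted center and the top meta-PoPS gene in the
#' locus (genes without a PoPS score can never hold the top-PoPS flag;
#' nearest-gene ties break toward the higher meta PoPS, then lexicographic
#' gene id). Criterion B prioritizes a gene whose non-synonymous
#' credible-set variants sum to PIP above `nonsyn_pip_thresh`. When both
#' criteria fire — for the same gene or different genes — the criterion-B
#' gene is the sole prioritized gene, with basis `"nonsynonymous"`.
#'
#' @param locus A [define_locus()] object.
#' @param cs The [credible_set()] the locus was built from.
#' @param scores Gene-score tibble with columns `gene`, `meta_score`,
#'   `percentile`, `magma_meta_z` (missing genes allowed).
#' @param nonsyn Non-synonymous annotation tibble (`snp`, `gene`).
#' @param nonsyn_pip_thresh PIP-mass threshold for criterion B.
#' @return An object of class `locus_call`: list with `locus`, `candidates`
#'   (tibble: `gene`, `distance`, `meta_score`, `percentile`,
#'   `magma_meta_z`, `nearest`, `top_pops`, `nonsyn_pip`), `prioritized`
#'   (gene id or `NA`), `basis` (`"pops_nearest"`, `"nonsynonymous"`, or
#'   `NA`).
#' @export
call_locus <- function(locus, cs, scores, nonsyn, nonsyn_pip_thresh = 0.5) {
  g <- locus$genes
  if (nrow(g) == 0) {
    return(structure(list(locus = locus,
                          candidates = tibble::tibble(),
                          prioritized = NA_character_, basis = NA_character_),
                     class = "locus_call"))
  }
  cand <- g |>
    dplyr::mutate(distance = gene_distance(g, cs$weighted_center,
                                           chrom = locus$chrom)) |>
    dplyr::left_join(scores, by = "gene")

  # nearest flag: unique after tie-breaking (meta PoPS desc, then gene id)
  ord <- order(cand$distance,
               -ifelse(is.na(cand$meta_score), -Inf, cand$meta_score),
               cand$gene)
  cand$nearest <- seq_len(nrow(cand)) == 0
  cand$nearest[ord[1]] <- TRUE

  scored <- !is.na(cand$meta_score)
  cand$top_pops <- scored & cand$meta_score == suppressWarnings(max(cand$meta_score[scored]))
  if (!any(scored)) cand$top_pops <- rep(FALSE, nrow(cand))

  cs_members <- cs$variants[cs$variants$in_cs, c("snp", "pip")]
  ns <- dplyr::inner_join(nonsyn, cs_members, by = "snp") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(nonsyn_pip = sum(.data$pip), .groups = "drop")
  cand <- dplyr::left_join(cand, ns, by = "gene") |>
    dplyr::mutate(nonsyn_pip = dplyr::coalesce(.data$nonsyn_pip, 0))

  a_gene <- cand$gene[cand$nearest & cand$top_pops]
  b_idx <- which(cand$nonsyn_pip > nonsyn_pip_thresh)
  b_gene <- if (length(b_idx) > 0) cand$gene[b_idx[which.max(cand$nonsyn_pip[b_idx])]]
            else character()

  if (length(b_gene) == 1) {
    prioritized <- b_gene
    basis <- "nonsynonymous"
  } else if (length(a_gene) == 1) {
    prioritized <- a_gene
    basis <- "pops_nearest"
  } else {
    prioritized <- NA_character_
    basis <- NA_character_
  }

  structure(
    list(locus = locus,
         candidates = dplyr::select(cand, "gene", "distance", "meta_score",
                                    "percentile", "magma_meta_z", "nearest",
                                    "top_pops", "nonsyn_pip"),
         prioritized = prioritized, basis = basis),
    class = "locus_call"
  )
}

#' @export
print.locus_call <- function(x, ...) {
  cat(sprintf("<locus_call> %s chr%s:%.0f-%.0f: %s\n",
              x$locus$lead, x$locus$chrom, x$locus$start, x$locus$end,
              if (is.na(x$prioritized)) "no gene prioritized"
              else sprintf("%s (%s)", x$prioritized, x$basis)))
  invisible(x)
}

#' Rescale external per-locus causal probabilities
#'
#' Per locus: if the probabilities sum to more than 1 they are divided by
#' their sum (capping the per-locus total at 100%); otherwise they are left
#' unchanged. Idempotent. Negative probabilities are an error.
#'
#' @param preds Tibble with columns `locus`, `gene`, `prob`.
#' @return The tibble with `prob` rescaled.
#' @export
rescale_external <- function(preds) {
  if (any(preds$prob < 0)) abort("causal probabilities must be non-negative")
  preds |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(prob = .data$prob / max(1, sum(.data$prob))) |>
    dplyr::ungroup()
}

#' Evidence table for prioritized genes
#'
#' One row per prioritized gene: distance in kb from the gene to the
#' credible set's weighted center, PoPS percentile, meta gene-association
#' z-score, number of candidate genes in the locus, summed non-synonymous
#' credible-set PIP, and — where a locus mapping succeeds — external
#' per-locus causal probabilities.
#'
#' @param calls List of [call_locus()] results (one per signal).
#' @param external Optional named list of external-prediction tibbles
#'   (`locus`, `gene`, `prob`), already rescaled; `locus` must hold the
#'   signal's lead variant id.
#' @return A tibble with one row per prioritized gene.
#' @export
build_evidence_table <- function(calls, external = NULL) {
  rows <- lapply(calls, function(cl) {
    if (is.na(cl$prioritized)) return(NULL)
    cand <- cl$candidates[cl$candidates$gene == cl$prioritized, ]
    tibble::tibble(
      locus = cl$locus$lead,
      chrom = cl$locus$chrom,
      gene = cl$prioritized,
      basis = cl$basis,
      distance_kb = cand$distance / 1000,
      pops_percentile = cand$percentile,
      magma_meta_z = cand$magma_meta_z,
      n_genes_in_locus = nrow(cl$candidates),
      nonsyn_pip = cand$nonsyn_pip
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(external) && nrow(out) > 0) {
    for (nm in names(external)) {
      ext <- external[[nm]][, c("locus", "gene", "prob")]
      names(ext)[3] <- nm
      out <- dplyr::left_join(out, ext, by = c("locus", "gene"))
    }
  }
  out
}
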