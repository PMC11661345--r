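#' Greedy LD clumping of genome-wide-significant variants
#'
#' PLINK-style clumping: repeatedly take the most significant unassigned
#' variant with `p < p_thresh` as an index variant and assign to its clump
#' every unassigned variant within `window_bp` of it whose squared panel
#' correlation with the index is at least `r2_thresh`. A variant in LD with
#' two index variants therefore joins the earlier-formed (more significant)
#' clump. Each clump's physical span is then expanded by `pad` on either
#' side and overlapping spans on a chromosome are merged into one region
#' carrying all of its index variants.
#'
#' @param stats Variant-statistics tibble (typically the meta-analysis),
#'   harmonized to `panel`.
#' @param panel `ld_panel` used for LD (for meta statistics, the mixed
#'   ancestry panel).
#' @param p_thresh Genome-wide significance threshold for index variants.
#' @param r2_thresh Minimum r-squared with the index for clump membership.
#' @param window_bp Maximum distance from the index for clump membership.
#' @param pad Span expansion added to each side of a clump before merging.
#' @return A tibble of regions: `region`, `chrom`, `start`, `end` (1-based
#'   inclusive, start floored at 1), `index_variants` (list column),
#'   `n_index`. Zero rows when nothing is significant.
#' @export
clump <- function(stats, panel, p_thresh = 5e-8, r2_thresh = 0.1,
                  window_bp = 3e6, pad = 5e5) {
  stats <- dplyr::arrange(stats, .data$chrom, .data$pos)
  g_idx <- match(stats$snp, colnames(panel$genotypes))
  if (anyNA(g_idx)) abort("all variants must be present in the panel; harmonize first")

  ord <- order(stats$p, stats$chrom, stats$pos)
  sig <- ord[stats$p[ord] < p_thresh]
  if (length(sig) == 0) {
    return(tibble::tibble(region = integer(), chrom = integer(),
                          start = numeric(), end = numeric(),
                          index_variants = list(), n_index = integer()))
  }

  assigned <- rep(FALSE, nrow(stats))
  clumps <- list()
  for (i in sig) {
    if (assigned[i]) next
    near <- which(stats$chrom == stats$chrom[i] &
                    abs(stats$pos - stats$pos[i]) <= window_bp &
                    !assigned)
    g0 <- panel$genotypes[, g_idx[i]]
    r <- suppressWarnings(
      cor(g0, panel$genotypes[, g_idx[near], drop = FALSE])
    )
    members <- near[!is.na(r) & r^2 >= r2_thresh]
    members <- union(members, i)
    assigned[members] <- TRUE
    clumps[[length(clumps) + 1]] <- list(
      index = stats$snp[i], chrom = stats$chrom[i],
      start = min(stats$pos[members]), end = max(stats$pos[members])
    )
  }

  spans <- tibble::tibble(
    index = vapply(clumps, `[[`, "", "index"),
    chrom = vapply(clumps, `[[`, 1L, "chrom"),
    start = pmax(1, vapply(clumps, `[[`, 1, "start") - pad),
    end = vapply(clumps, `[[`, 1, "end") + pad
  ) |> dplyr::arrange(.data$chrom, .data$start)

  # merge overlapping padded spans per chromosome
  out <- list()
  cur <- NULL
  for (k in seq_len(nrow(spans))) {
    row <- spans[k, ]
    if (!is.null(cur) && row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$index_variants[[1]] <- c(cur$index_variants[[1]], row$index)
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- tibble::tibble(chrom = row$chrom, start = row$start,
                            end = row$end, index_variants = list(row$index))
    }
  }
  out[[length(out) + 1]] <- cur
  regions <- dplyr::bind_rows(out)
  regions$region <- seq_len(nrow(regions))
  regions$n_index <- lengths(regions$index_variants)
  dplyr::select(regions, "region", "chrom", "start", "end",
                "index_variants", "n_index")
}
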