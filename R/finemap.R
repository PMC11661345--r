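# Single-causal-variant fine-mapping with Wakefield approximate Bayes
# factors: per-variant posterior inclusion probabilities (PIPs), 95%
# credible sets, and padded locus windows around each credible set.

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2` the variance of the effect estimate and `W = prior_sd^2`
#' the prior effect-size variance, the shrinkage ratio is
#' `r = W / (W + V)` and `lABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param z Marginal (or conditional) z-score, vectorized.
#' @param se Standard error of the effect estimate, > 0.
#' @param prior_sd Prior standard deviation of the effect on the same scale
#'   as `se` (default 0.2, a conventional case-control log-odds prior).
#' @return Log approximate Bayes factor(s).
#' @export
#' @examples
#' wakefield_labf(z = 5, se = 0.1, prior_sd = 0.2)  # ~9.195
wakefield_labf <- function(z, se, prior_sd = 0.2) {
  stopifnot(all(se > 0), prior_sd > 0)
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

#' 95% credible set for one isolated signal
#'
#' PIPs are the softmax of the per-variant log approximate Bayes factors
#' over all variants in the signal's region (computed in log space, so they
#' sum to one even when the largest lABF overflows `exp`). Variants are
#' ranked by PIP and the minimal prefix whose cumulative PIP reaches
#' `coverage` forms the credible set; ties in PIP at the boundary are all
#' included. The weighted center is the PIP-weighted mean position of the
#' set's members (member PIPs renormalized).
#'
#' @param signal An `independent_signal` from [leave_one_out_condition()].
#' @param coverage Target cumulative posterior mass (default 0.95).
#' @param prior_sd Prior effect-size SD passed to [wakefield_labf()].
#' @return An object of class `credible_set`: list with `lead`, `chrom`,
#'   `variants` (tibble over all signal variants: `snp`, `pos`, `labf`,
#'   `pip`, `in_cs`), `coverage` (achieved mass), `weighted_center`.
#' @export
credible_set <- function(signal, coverage = 0.95, prior_sd = 0.2) {
  cs_tab <- signal$cond_stats
  if (is.null(cs_tab) || nrow(cs_tab) == 0) abort("signal has no variants")
  labf <- wakefield_labf(cs_tab$z, cs_tab$se, prior_sd)
  pip <- exp(labf - logsumexp(labf))

  ord <- order(pip, decreasing = TRUE)
  cum <- cumsum(pip[ord])
  k <- which(cum >= coverage)[1]
  if (is.na(k)) k <- length(ord)
  # include boundary ties deterministically
  while (k < length(ord) && pip[ord[k + 1]] == pip[ord[k]]) k <- k + 1
  in_cs <- seq_along(pip) %in% ord[seq_len(k)]

  w <- pip[in_cs] / sum(pip[in_cs])
  structure(
    list(lead = signal$lead,
         chrom = cs_tab$chrom[1],
         variants = tibble::tibble(snp = cs_tab$snp, pos = cs_tab$pos,
                                   labf = labf, pip = pip, in_cs = in_cs),
         coverage = sum(pip[in_cs]),
         weighted_center = sum(w * cs_tab$pos[in_cs])),
    class = "credible_set"
  )
}

#' @export
print.credible_set <- function(x, ...) {
  m <- x$variants[x$variants$in_cs, ]
  cat(sprintf("<credible_set> lead %s: %d/%d variants, mass %.3f, center %.0f\n",
              x$lead, nrow(m), nrow(x$variants), x$coverage,
              x$weighted_center))
  invisible(x)
}

#' Define the locus window around a credible set
#'
#' The window spans from `pad` bp below the smallest credible-set member
#' position (floored at 1) to `pad` bp above the largest. Genes whose body
#' overlaps the window (closed intervals, 1-based) are the locus's candidate
#' genes.
#'
#' @param cs A [credible_set()].
#' @param genes Gene table (`gene`, `symbol`, `chrom`, `start`, `end`).
#' @param pad Window padding in bp (default 300 kb).
#' @return An object of class `locus`: list with `lead`, `chrom`, `start`,
#'   `end`, `genes` (tibble of overlapping gene records; zero rows allowed,
#'   with a message).
#' @export
define_locus <- function(cs, genes, pad = 3e5) {
  m <- cs$variants[cs$variants$in_cs, ]
  w_start <- max(1, min(m$pos) - pad)
  w_end <- max(m$pos) + pad
  g <- dplyr::filter(genes, .data$chrom == cs$chrom,
                     .data$start <= w_end, .data$end >= w_start)
  if (nrow(g) == 0) {
    inform(sprintf("locus around %s (chr%s:%.0f-%.0f) overlaps no gene; prioritization will skip it",
                   cs$lead, cs$chrom, w_start, w_end))
  }
  structure(
    list(lead = cs$lead, chrom = cs$chrom, start = w_start, end = w_end,
         genes = g),
    class = "locus"
  )
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s chr%s:%.0f-%.0f, %d gene(s)\n",
              x$lead, x$chrom, x$start, x$end, nrow(x$genes)))
  invisible(x)
}
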