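# Study-design bookkeeping for the multi-ancestry Parkinson's disease GWAS
# setting the package emulates: two source case-control GWAS (East Asian and
# European ancestry) and LD reference panels mixed in the same ancestry
# proportions as the GWAS.

#' Source GWAS design table
#'
#' Published per-ancestry sample counts of the two Parkinson's disease GWAS
#' the pipeline's defaults are modeled on: cases, proxy cases (first-degree
#' relatives of cases), controls, the effective sample size, and the size of
#' the ancestry's LD reference panel.
#'
#' @return A tibble with one row per ancestry and columns `ancestry`,
#'   `cases`, `proxy_cases`, `controls`, `n_eff`, `panel_n`.
#' @export
#' @examples
#' pd_gwas_design()
pd_gwas_design <- function() {
  tibble::tibble(
    ancestry = c("EAS", "EUR"),
    cases = c(6724, 37688),
    proxy_cases = c(0, 18618),
    controls = c(24851, 1417791),
    n_eff = c(15886, 127626),
    panel_n = c(538, 16860)
  )
}

#' Mixed reference-panel composition matching GWAS proportions
#'
#' Computes how many reference-panel individuals of each ancestry a mixed LD
#' panel should contain so that ancestry shares match the GWAS effective
#' sample sizes, anchored on the ancestry whose full panel is smallest
#' relative to its GWAS share (every one of its samples is used and the
#' other ancestries are scaled to it).
#'
#' @param design A design table like [pd_gwas_design()] (columns `ancestry`,
#'   `n_eff`, `panel_n`).
#' @param anchor Ancestry label whose full panel is taken as given; defaults
#'   to the ancestry with the smallest `panel_n / n_eff` ratio.
#' @return A tibble with columns `ancestry`, `n_eff`, `share` (proportion of
#'   total effective sample size), `panel_n_mixed` (samples of that ancestry
#'   in the mixed panel, rounded to integers).
#' @export
#' @examples
#' panel_mix(pd_gwas_design())
panel_mix <- function(design, anchor = NULL) {
  stopifnot(all(c("ancestry", "n_eff", "panel_n") %in% names(design)))
  share <- design$n_eff / sum(design$n_eff)
  if (is.null(anchor)) {
    anchor <- design$ancestry[which.min(design$panel_n / share)]
  }
  a <- match(anchor, design$ancestry)
  if (is.na(a)) abort(sprintf("anchor ancestry '%s' not in design", anchor))
  scale <- design$panel_n[a] / share[a]
  tibble::tibble(
    ancestry = design$ancestry,
    n_eff = design$n_eff,
    share = share,
    panel_n_mixed = ifelse(seq_along(share) == a, design$panel_n[a],
                           round(share * scale))
  )
}

#' Combined cohort totals across source GWAS
#'
#' Sums cases, proxy cases and controls over the source studies.
#'
#' @param design A design table like [pd_gwas_design()].
#' @return A one-row tibble with `cases`, `proxy_cases`, `controls`, `n_eff`.
#' @export
#' @examples
#' cohort_totals(pd_gwas_design())
cohort_totals <- function(design) {
  tibble::tibble(
    cases = sum(design$cases),
    proxy_cases = sum(design$proxy_cases),
    controls = sum(design$controls),
    n_eff = sum(design$n_eff)
  )
}
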