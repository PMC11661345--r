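# Harmonization and allele-frequency QC of variant summary statistics
# against an LD reference panel.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics to a reference panel
#'
#' Matches variants to the panel by chromosome, position and allele pair.
#' When the study's effect allele is the panel's other allele the record is
#' flipped (beta negated, `eaf` replaced by `1 - eaf`, alleles swapped);
#' strand complements are resolved the same way. Strand-ambiguous (A/T, C/G)
#' variants with `eaf` in `[0.4, 0.6]` are dropped, as are variants that
#' cannot be matched to the panel.
#'
#' @param stats Variant-statistics tibble (columns as in
#'   [simulate_sumstats()]).
#' @param panel An `ld_panel`.
#' @param ambiguous_eaf_range Frequency band within which strand-ambiguous
#'   variants are considered unresolvable and dropped.
#' @return A list with `stats` (harmonized tibble, panel allele order) and
#'   `report` (one-row QC tibble: `n_input`, `n_removed_unmatched`,
#'   `n_removed_ambiguous`, `n_remaining`).
#' @export
harmonize <- function(stats, panel, ambiguous_eaf_range = c(0.4, 0.6)) {
  key <- paste(stats$chrom, stats$pos, stats$a1, stats$a2, sep = ":")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate variant row: %s", key[duplicated(key)][1]))
  }
  n_input <- nrow(stats)

  ambiguous <- is_ambiguous_pair(stats$a1, stats$a2) &
    stats$eaf >= ambiguous_eaf_range[1] & stats$eaf <= ambiguous_eaf_range[2]
  kept <- stats[!ambiguous, ]
  n_ambiguous <- sum(ambiguous)

  map <- panel$map
  pkey <- paste(map$chrom, map$pos, sep = ":")
  skey <- paste(kept$chrom, kept$pos, sep = ":")
  m <- match(skey, pkey)
  p_a1 <- map$a1[m]
  p_a2 <- map$a2[m]
  same <- !is.na(m) & kept$a1 == p_a1 & kept$a2 == p_a2
  swap <- !is.na(m) & kept$a1 == p_a2 & kept$a2 == p_a1
  c1 <- unname(.complement[kept$a1])
  c2 <- unname(.complement[kept$a2])
  comp <- !is.na(m) & !same & !swap & c1 == p_a1 & c2 == p_a2
  comp_swap <- !is.na(m) & !same & !swap & c1 == p_a2 & c2 == p_a1

  matched <- same | swap | comp | comp_swap
  flip <- swap | comp_swap
  out <- kept[matched, ]
  mf <- m[matched]
  flip_f <- flip[matched]
  out$beta[flip_f] <- -out$beta[flip_f]
  out$eaf[flip_f] <- 1 - out$eaf[flip_f]
  out$a1 <- map$a1[mf]
  out$a2 <- map$a2[mf]
  out$snp <- map$snp[mf]

  report <- tibble::tibble(
    n_input = n_input,
    n_removed_unmatched = sum(!matched),
    n_removed_ambiguous = n_ambiguous,
    n_remaining = nrow(out)
  )
  list(stats = out, report = report)
}

#' Allele-frequency QC against panel frequencies
#'
#' Two sequential filters on harmonized statistics: first remove variants
#' whose effect-allele frequency differs from the panel frequency by more
#' than `abs_thresh` in absolute value, then remove variants whose frequency
#' ratio to the panel frequency (in either direction) exceeds `fold_thresh`.
#' The two removal counts are reported separately, in that order. Variants
#' whose panel frequency is 0 or 1 fall to the fold rule.
#'
#' @param stats Harmonized variant-statistics tibble.
#' @param panel An `ld_panel`, or a named numeric vector of panel
#'   effect-allele frequencies indexed by variant id.
#' @param abs_thresh Absolute frequency-difference threshold.
#' @param fold_thresh Fold-change threshold (two-sided).
#' @return A list with `stats` (filtered tibble) and `report` (one-row
#'   tibble: `n_input`, `n_removed_absdiff`, `n_removed_foldchange`,
#'   `n_remaining`).
#' @export
af_qc <- function(stats, panel, abs_thresh = 0.1, fold_thresh = 12) {
  ref <- if (inherits(panel, "ld_panel")) panel$freq else panel
  rf <- unname(ref[stats$snp])
  if (anyNA(rf)) abort("every variant needs a panel reference frequency; harmonize first")
  n_input <- nrow(stats)

  fail_abs <- abs(stats$eaf - rf) > abs_thresh
  s1 <- stats[!fail_abs, ]
  rf1 <- rf[!fail_abs]

  degenerate <- rf1 <= 0 | rf1 >= 1
  if (any(degenerate)) {
    inform(sprintf("%d variant(s) with panel frequency 0 or 1 removed under the fold rule",
                   sum(degenerate)))
  }
  ratio <- pmax(s1$eaf / rf1, rf1 / s1$eaf)
  fail_fold <- degenerate | !is.finite(ratio) | ratio > fold_thresh
  out <- s1[!fail_fold, ]

  report <- tibble::tibble(
    n_input = n_input,
    n_removed_absdiff = sum(fail_abs),
    n_removed_foldchange = sum(fail_fold),
    n_remaining = nrow(out)
  )
  list(stats = out, report = report)
}

#' Fixed-effects inverse-variance meta-analysis of variant statistics
#'
#' Combines per-ancestry harmonized summary statistics with
#' inverse-variance weights:
#' `beta_meta = sum(beta_i / se_i^2) / sum(1 / se_i^2)`,
#' `se_meta = 1 / sqrt(sum(1 / se_i^2))`, p from the meta z-score.
#' Variants present in only one ancestry are carried through unchanged;
#' effective sample sizes are summed over contributing ancestries and the
#' reported frequency is the `n_eff`-weighted mean.
#'
#' @param stats_by_ancestry List of harmonized variant-statistics tibbles,
#'   all on the same effect-allele orientation.
#' @return A variant-statistics tibble with `ancestry = "META"`.
#' @export
meta_fixed_effects <- function(stats_by_ancestry) {
  stopifnot(length(stats_by_ancestry) >= 1)
  all_stats <- dplyr::bind_rows(stats_by_ancestry)
  alleles <- dplyr::distinct(all_stats, .data$snp, .data$a1, .data$a2)
  if (anyDuplicated(alleles$snp)) {
    bad <- alleles$snp[duplicated(alleles$snp)][1]
    abort(sprintf("conflicting alleles across ancestries for %s; harmonize to a common panel first", bad))
  }
  all_stats |>
    dplyr::group_by(.data$chrom, .data$pos, .data$snp, .data$a1, .data$a2) |>
    dplyr::summarise(
      eaf = sum(.data$eaf * .data$n_eff) / sum(.data$n_eff),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = 1 / sqrt(sum(1 / .data$se^2)),
      n_eff = sum(.data$n_eff),
      .groups = "drop"
    ) |>
    dplyr::mutate(p = p_from_z(.data$beta / .data$se), ancestry = "META") |>
    dplyr::select("chrom", "pos", "snp", "a1", "a2", "eaf", "beta", "se",
                  "p", "n_eff", "ancestry") |>
    dplyr::arrange(.data$chrom, .data$pos)
}
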