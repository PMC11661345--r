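# End-to-end orchestration: QC -> meta-analysis -> signal isolation ->
# fine-mapping -> gene association -> PoPS -> prioritization, with a run
# manifest of per-stage row counts.

#' Pipeline stage parameters
#'
#' All tunable thresholds of the pipeline in one validated list. Defaults:
#' genome-wide significance 5e-8, clumping r-squared 0.1 within a 3 Mb
#' window and 500 kb clump padding, 300 kb locus padding, 95% credible-set
#' coverage, effect-size prior SD 0.2, gene-test MAF 1% and minimum 3
#' variants per gene, feature-selection alpha 0.05, non-synonymous PIP
#' threshold 0.5, COJO collinearity cutoff 0.9.
#'
#' @param p_thresh,r2_thresh,window_bp,pad_clump Clumping parameters.
#' @param pad_locus Locus window padding (bp).
#' @param coverage,prior_sd Credible-set parameters.
#' @param maf_min,min_variants Gene-association parameters.
#' @param alpha Feature-selection threshold.
#' @param nonsyn_pip Criterion-B PIP threshold.
#' @param collinearity_r2 COJO collinearity cutoff.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(p_thresh = 5e-8, r2_thresh = 0.1,
                            window_bp = 3e6, pad_clump = 5e5,
                            pad_locus = 3e5, coverage = 0.95,
                            prior_sd = 0.2, maf_min = 0.01,
                            min_variants = 3, alpha = 0.05,
                            nonsyn_pip = 0.5, collinearity_r2 = 0.9) {
  p <- list(p_thresh = p_thresh, r2_thresh = r2_thresh,
            window_bp = window_bp, pad_clump = pad_clump,
            pad_locus = pad_locus, coverage = coverage, prior_sd = prior_sd,
            maf_min = maf_min, min_variants = min_variants, alpha = alpha,
            nonsyn_pip = nonsyn_pip, collinearity_r2 = collinearity_r2)
  stopifnot(p$p_thresh > 0, p$p_thresh < 1, p$r2_thresh >= 0,
            p$r2_thresh <= 1, p$coverage > 0, p$coverage <= 1,
            p$prior_sd > 0, p$maf_min >= 0, p$maf_min < 0.5,
            p$min_variants >= 1, p$alpha > 0, p$alpha <= 1,
            p$nonsyn_pip >= 0, p$nonsyn_pip <= 1,
            p$collinearity_r2 > 0, p$collinearity_r2 <= 1)
  structure(p, class = "pipeline_params")
}

#' Run the full prioritization pipeline on a simulated (or assembled) study
#'
#' Executes, in order: per-ancestry harmonization and allele-frequency QC
#' against the ancestry's own panel; fixed-effects meta-analysis; LD
#' clumping on the mixed panel; COJO-style signal selection and
#' leave-one-hit-out conditioning per region; credible sets and locus
#' windows per isolated signal; per-ancestry gene association and sqrt(N)
#' meta z; per-ancestry PoPS (feature selection on that ancestry's gene z,
#' LOCO ridge) and sqrt(N) meta scores with genome-wide percentiles; and
#' the per-locus prioritization rule.
#'
#' @param study A [simulate_gwas()] object, or a list with the same fields
#'   (`sumstats`, `panels`, `mixed_panel`, `genes`, `features`, `truth`
#'   optional, `config` with `ancestries`).
#' @param params A [pipeline_params()].
#' @param external Optional named list of external prediction tibbles for
#'   the evidence table (see [build_evidence_table()]).
#' @return An object of class `popsloci_run`: list with `qc_reports`,
#'   `meta_stats`, `regions`, `signals`, `credible_sets`, `loci`,
#'   `gene_scores`, `pops_fits`, `scores` (per-gene meta table), `calls`,
#'   `evidence`, `manifest`, `params`.
#' @export
run_pipeline <- function(study, params = pipeline_params(), external = NULL) {
  labels <- names(study$sumstats)
  n_eff <- vapply(labels, function(a) study$sumstats[[a]]$n_eff[1], 1)

  # stage 1: harmonize + AF QC per ancestry against its own panel
  qc_reports <- list()
  clean <- list()
  for (a in labels) {
    h <- harmonize(study$sumstats[[a]], study$panels[[a]])
    q <- af_qc(h$stats, study$panels[[a]])
    qc_reports[[a]] <- tibble::tibble(
      ancestry = a,
      n_input = h$report$n_input,
      n_removed_unmatched = h$report$n_removed_unmatched,
      n_removed_ambiguous = h$report$n_removed_ambiguous,
      n_removed_absdiff = q$report$n_removed_absdiff,
      n_removed_foldchange = q$report$n_removed_foldchange,
      n_remaining = q$report$n_remaining
    )
    clean[[a]] <- q$stats
  }

  # stage 2: fixed-effects meta-analysis
  meta_stats <- meta_fixed_effects(clean)

  # stage 3: clumping + COJO signal isolation on the mixed panel
  regions <- clump(meta_stats, study$mixed_panel, p_thresh = params$p_thresh,
                   r2_thresh = params$r2_thresh, window_bp = params$window_bp,
                   pad = params$pad_clump)
  signals <- list()
  for (k in seq_len(nrow(regions))) {
    region <- regions[k, ]
    hits <- cojo_select(region, meta_stats, study$mixed_panel,
                        p_thresh = params$p_thresh,
                        collinearity_r2 = params$collinearity_r2)
    signals <- c(signals,
                 leave_one_out_condition(region, hits, meta_stats,
                                         study$mixed_panel))
  }

  # stage 4: credible sets and loci
  credible_sets <- lapply(signals, credible_set,
                          coverage = params$coverage,
                          prior_sd = params$prior_sd)
  loci <- lapply(credible_sets, define_locus, genes = study$genes,
                 pad = params$pad_locus)

  # stage 5: gene association per ancestry + meta z
  gene_scores <- lapply(labels, function(a) {
    gene_assoc_scores(clean[[a]], study$panels[[a]], study$genes,
                      maf_min = params$maf_min,
                      min_variants = params$min_variants)
  })
  names(gene_scores) <- labels
  meta_z <- meta_gene_z(gene_scores)

  # stage 6: PoPS per ancestry on that ancestry's gene z + meta scores
  pops_fits <- lapply(labels, function(a) {
    gs <- gene_scores[[a]]
    gz <- setNames(gs$z, gs$gene)
    feats <- study$features[gs$gene, , drop = FALSE]
    sel <- select_features(gz, feats, alpha = params$alpha)
    gene_chrom <- study$genes$chrom[match(gs$gene, study$genes$gene)]
    loco_ridge(tibble::tibble(gene = gs$gene, chrom = gene_chrom, z = gs$z),
               study$features, sel, ancestry = a)
  })
  names(pops_fits) <- labels
  meta_scores <- meta_pops(lapply(pops_fits, function(f) f$scores), n_eff)
  scores <- meta_scores |>
    dplyr::mutate(percentile = pops_percentile(.data$meta_score)) |>
    dplyr::left_join(meta_z, by = "gene") |>
    dplyr::rename(magma_meta_z = "meta_z") |>
    dplyr::select("gene", "meta_score", "percentile", "magma_meta_z")

  # stage 7: prioritization
  calls <- purrr::map2(loci, credible_sets, call_locus, scores = scores,
                       nonsyn = study$truth$nonsyn %||%
                         tibble::tibble(snp = character(), gene = character()),
                       nonsyn_pip_thresh = params$nonsyn_pip)
  evidence <- build_evidence_table(calls, external)

  manifest <- tibble::tibble(
    stage = c("sumstats", "signal_isolation", "finemapping",
              "gene_assoc", "pops", "prioritization"),
    rows = c(nrow(meta_stats), length(signals), length(credible_sets),
             nrow(meta_z), nrow(scores),
             sum(vapply(calls, function(cl) !is.na(cl$prioritized), TRUE)))
  )

  structure(
    list(qc_reports = dplyr::bind_rows(qc_reports), meta_stats = meta_stats,
         regions = regions, signals = signals,
         credible_sets = credible_sets, loci = loci,
         gene_scores = gene_scores, pops_fits = pops_fits, scores = scores,
         calls = calls, evidence = evidence, manifest = manifest,
         params = params),
    class = "popsloci_run"
  )
}

#' @export
print.popsloci_run <- function(x, ...) {
  cat("<popsloci_run>\n")
  cat(sprintf("  %d region(s), %d independent signal(s), %d prioritized gene(s)\n",
              nrow(x$regions), length(x$signals), nrow(x$evidence)))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x,object A `popsloci_run`.
#' @param ... Unused.
#' @method tidy popsloci_run
#' @export
tidy.popsloci_run <- function(x, ...) x$evidence

#' @rdname run_pipeline
#' @method glance popsloci_run
#' @export
glance.popsloci_run <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$regions),
    n_signals = length(x$signals),
    n_loci = length(x$loci),
    n_prioritized = nrow(x$evidence),
    n_genes_scored = nrow(x$scores)
  )
}

#' Per-locus variant and gene report
#'
#' Tabular analogue of a LocusZoom + PoPS panel: the locus's variants with
#' their meta-analysis p-values, LD with the lead variant and credible-set
#' membership; and the locus's genes with their spans, raw meta PoPS
#' scores, percentiles, and flags for exceeding the genome-wide top-10% and
#' top-1% PoPS thresholds.
#'
#' @param run A [run_pipeline()] result.
#' @param signal_index Which isolated signal (1-based) to report.
#' @param panel The mixed `ld_panel` used in the run (for lead-variant LD).
#' @return A list with `variants` and `genes` tibbles and the two
#'   genome-wide PoPS thresholds.
#' @export
locus_report <- function(run, signal_index, panel) {
  if (signal_index < 1 || signal_index > length(run$signals)) {
    abort(sprintf("unknown signal index %s", signal_index))
  }
  sig <- run$signals[[signal_index]]
  cs <- run$credible_sets[[signal_index]]
  locus <- run$loci[[signal_index]]
  lead_g <- panel$genotypes[, sig$lead]
  r <- unname(suppressWarnings(
    drop(cor(lead_g, panel$genotypes[, sig$cond_stats$snp, drop = FALSE]))
  ))
  variants <- sig$cond_stats |>
    dplyr::transmute(snp = .data$snp, pos = .data$pos, p = .data$p,
                     r2_lead = r^2,
                     in_cs = .data$snp %in% cs$variants$snp[cs$variants$in_cs])
  thr10 <- quantile(run$scores$meta_score, 0.90, names = FALSE)
  thr1 <- quantile(run$scores$meta_score, 0.99, names = FALSE)
  genes <- locus$genes |>
    dplyr::left_join(run$scores, by = "gene") |>
    dplyr::transmute(gene = .data$gene, start = .data$start, end = .data$end,
                     meta_score = .data$meta_score,
                     percentile = .data$percentile,
                     top10 = !is.na(.data$meta_score) & .data$meta_score >= thr10,
                     top1 = !is.na(.data$meta_score) & .data$meta_score >= thr1)
  list(variants = variants, genes = genes,
       pops_top10_threshold = thr10, pops_top1_threshold = thr1)
}
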