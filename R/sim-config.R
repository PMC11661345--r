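#' Configuration for the synthetic multi-ancestry GWAS generator
#'
#' Bundles every knob of the simulator into a single validated object. The
#' defaults describe the study design the package emulates: a small
#' East-Asian-ancestry (EAS) case-control GWAS (effective sample size 15,886,
#' reference panel of 538 individuals) meta-analyzed with a much larger
#' European-ancestry (EUR) GWAS (effective sample size 127,626), with the
#' mixed reference panel holding the two ancestries in the same proportions
#' as the GWAS (11% EAS / 89% EUR, i.e. 4,322 EUR individuals alongside the
#' 538 EAS ones).
#'
#' Variants are laid out on `n_chromosomes` autosomes at a fixed physical
#' spacing and partitioned into LD blocks of `ld_block_size` consecutive
#' variants; within a block the genotype correlation between variants `i` and
#' `j` is `ld_decay^|i-j|`, across blocks it is zero. Allele frequencies are
#' drawn per block and perturbed per ancestry by a Balding-Nichols model with
#' fixation index `fst`, so the two ancestries have correlated but not
#' identical frequencies.
#'
#' @param n_variants Total number of variants across all chromosomes.
#' @param n_genes Total number of protein-coding gene models.
#' @param n_chromosomes Number of autosomes (at least 2, so that
#'   leave-one-chromosome-out fitting is well defined).
#' @param n_features Number of gene features (columns of the gene x feature
#'   matrix used by the PoPS stage).
#' @param n_causal_loci Number of causal genes; each carries one causal
#'   variant inside its body.
#' @param ancestries Data frame with columns `label`, `n_ref_samples`
#'   (reference-panel size) and `n_eff` (GWAS effective sample size), one row
#'   per ancestry.
#' @param ld_block_size Number of consecutive variants per LD block.
#' @param ld_decay Within-block correlation decay in (0,1): adjacent variants
#'   have genotype correlation `ld_decay`.
#' @param causal_effect_sd Standard deviation of the per-variant causal effect
#'   on the standardized-genotype scale; the expected marginal z-score of a
#'   causal variant is `sqrt(n_eff) * effect`.
#' @param frac_nonsyn_causal Fraction of causal variants flagged as
#'   non-synonymous coding variants.
#' @param feature_signal_strength Mean shift applied to the signature feature
#'   columns of causal genes (background features are standard normal).
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the config (including this seed).
#' @param bp_spacing Physical distance in bp between adjacent variants.
#' @param fst Balding-Nichols fixation index for cross-ancestry
#'   allele-frequency divergence.
#' @param n_signature_features Number of feature columns shifted for causal
#'   genes.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_variants = 2000, n_genes = 60, n_chromosomes = 4,
#'                   n_features = 50, n_causal_loci = 4, seed = 1)
#' cfg$ancestries
sim_config <- function(n_variants = 50000L,
                       n_genes = 1000L,
                       n_chromosomes = 22L,
                       n_features = 500L,
                       n_causal_loci = 25L,
                       ancestries = tibble::tibble(
                         label = c("EAS", "EUR"),
                         n_ref_samples = c(538L, 4322L),
                         n_eff = c(15886, 127626)
                       ),
                       ld_block_size = 50L,
                       ld_decay = 0.9,
                       causal_effect_sd = 0.03,
                       frac_nonsyn_causal = 0.25,
                       feature_signal_strength = 2,
                       seed = 1L,
                       bp_spacing = 2000L,
                       fst = 0.05,
                       n_signature_features = 10L) {
  cfg <- list(
    n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes),
    n_chromosomes = as.integer(n_chromosomes),
    n_features = as.integer(n_features),
    n_causal_loci = as.integer(n_causal_loci),
    ancestries = tibble::as_tibble(ancestries),
    ld_block_size = as.integer(ld_block_size),
    ld_decay = ld_decay,
    causal_effect_sd = causal_effect_sd,
    frac_nonsyn_causal = frac_nonsyn_causal,
    feature_signal_strength = feature_signal_strength,
    seed = as.integer(seed),
    bp_spacing = as.integer(bp_spacing),
    fst = fst,
    n_signature_features = as.integer(n_signature_features)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_variants, cfg$n_genes, cfg$n_chromosomes, cfg$n_features,
              cfg$ld_block_size, cfg$bp_spacing, cfg$n_signature_features)
  if (any(counts <= 0)) abort("all counts in a sim_config must be positive")
  if (cfg$n_causal_loci < 0) abort("n_causal_loci must be non-negative")
  if (cfg$n_chromosomes < 2) abort("n_chromosomes must be >= 2 (leave-one-chromosome-out needs a held-out fold)")
  need <- c("label", "n_ref_samples", "n_eff")
  if (!all(need %in% names(cfg$ancestries))) {
    abort("ancestries must have columns label, n_ref_samples, n_eff")
  }
  if (any(cfg$ancestries$n_ref_samples <= 0) || any(cfg$ancestries$n_eff <= 0)) {
    abort("ancestry n_ref_samples and n_eff must be positive")
  }
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1) abort("ld_decay must be in [0, 1)")
  if (cfg$frac_nonsyn_causal < 0 || cfg$frac_nonsyn_causal > 1) {
    abort("frac_nonsyn_causal must be in [0, 1]")
  }
  if (cfg$fst <= 0 || cfg$fst >= 1) abort("fst must be in (0, 1)")
  if (cfg$ld_block_size > min(split_counts(cfg$n_variants, cfg$n_chromosomes))) {
    abort("ld_block_size exceeds the number of variants on a chromosome")
  }
  if (cfg$n_causal_loci > cfg$n_genes) abort("n_causal_loci cannot exceed n_genes")
  if (cfg$n_signature_features > cfg$n_features) {
    abort("n_signature_features cannot exceed n_features")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d variants on %d chromosomes (LD blocks of %d, decay %.2f)\n",
              x$n_variants, x$n_chromosomes, x$ld_block_size, x$ld_decay))
  cat(sprintf("  %d genes, %d causal loci, %d features\n",
              x$n_genes, x$n_causal_loci, x$n_features))
  for (i in seq_len(nrow(x$ancestries))) {
    a <- x$ancestries[i, ]
    cat(sprintf("  ancestry %s: panel n = %d, N_eff = %s\n",
                a$label, a$n_ref_samples, format(a$n_eff, big.mark = ",")))
  }
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# Deterministic sub-seeds for independent generator streams. Keeps every
# op reproducible on its own while all streams derive from config$seed.
sim_seed <- function(cfg, offset) {
  (cfg$seed * 1009L + as.integer(offset)) %% 2147483647L
}
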