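#' Simulate GWAS summary statistics from an LD panel and ground truth
#'
#' Draws per-variant z-scores directly from the standard summary-statistics
#' model: within each LD block, `z ~ Normal(R s, R)` where `R` is the block's
#' empirical panel correlation and `s` is the vector of non-centralities,
#' `s_j = sqrt(n_eff) * effect_j` on the standardized-genotype scale (zero
#' for non-causal variants). Effect sizes and standard errors are recovered
#' on the allele-dosage (log-odds) scale via
#' `SE = 1 / sqrt(n_eff * 2 f (1 - f))` with `f` the panel allele frequency,
#' and `beta = z * SE`. Monomorphic panel variants (f = 0 or 1) are excluded
#' with a message.
#'
#' @param panel An [simulate_ld_panel()] panel for one ancestry.
#' @param truth A [simulate_truth()] object (its causal variants must exist
#'   in the panel).
#' @param n_eff Effective sample size of the emulated GWAS.
#' @param seed Integer seed for the z-score noise.
#' @return A tibble of variant association statistics with columns `chrom`,
#'   `pos`, `snp`, `a1`, `a2`, `eaf`, `beta`, `se`, `p`, `n_eff`, `ancestry`.
#' @export
simulate_sumstats <- function(panel, truth, n_eff, seed) {
  stopifnot(inherits(panel, "ld_panel"))
  missing_causal <- setdiff(truth$causal_variants$snp, panel$map$snp)
  if (length(missing_causal) > 0) {
    abort(sprintf("causal variant(s) absent from panel: %s",
                  paste(missing_causal, collapse = ", ")))
  }
  vmap <- panel$map
  f <- panel$freq
  mono <- f <= 0 | f >= 1
  if (any(mono)) {
    inform(sprintf("excluding %d monomorphic panel variant(s) from summary statistics",
                   sum(mono)))
  }

  s <- numeric(nrow(vmap))
  idx <- match(truth$causal_variants$snp, vmap$snp)
  s[idx] <- sqrt(n_eff) * truth$causal_variants$effect

  set.seed(seed)
  z <- numeric(nrow(vmap))
  for (b in split(seq_len(nrow(vmap)), vmap$block)) {
    b <- b[!mono[b]]
    if (length(b) == 0) next
    R <- cor(panel$genotypes[, b, drop = FALSE])
    # ridge jitter keeps the Cholesky factor defined for near-singular blocks
    L <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-6, nrow(R))))
    z[b] <- drop(crossprod(R, s[b])) + drop(crossprod(L, rnorm(length(b))))
  }

  keep <- !mono
  f <- unname(f)
  se <- 1 / sqrt(n_eff * 2 * f[keep] * (1 - f[keep]))
  zk <- z[keep]
  tibble::tibble(
    chrom = vmap$chrom[keep],
    pos = vmap$pos[keep],
    snp = vmap$snp[keep],
    a1 = vmap$a1[keep],
    a2 = vmap$a2[keep],
    eaf = f[keep],
    beta = zk * se,
    se = se,
    p = p_from_z(zk),
    n_eff = n_eff,
    ancestry = panel$label
  )
}

#' Simulate the gene x feature matrix
#'
#' Background entries are standard normal; for every causal gene the
#' designated signature feature columns are shifted upward by
#' `feature_signal_strength`, giving causal genes a shared, learnable
#' footprint across the genome.
#'
#' @param truth A [simulate_truth()] object.
#' @param config The [sim_config()] that produced it.
#' @param seed Integer seed.
#' @return A numeric matrix (`n_genes` x `n_features`) with gene ids as row
#'   names and `F0001`-style column names.
#' @export
simulate_features <- function(truth, config, seed) {
  validate_sim_config(config)
  genes <- simulate_genes(config)
  set.seed(seed)
  X <- matrix(rnorm(config$n_genes * config$n_features),
              nrow = config$n_genes,
              dimnames = list(genes$gene,
                              sprintf("F%04d", seq_len(config$n_features))))
  causal <- rownames(X) %in% truth$causal_genes
  X[causal, truth$signature_features] <-
    X[causal, truth$signature_features] + config$feature_signal_strength
  X
}

#' Simulate a complete multi-ancestry GWAS study
#'
#' Convenience wrapper tying the generator together: variant map, gene
#' models, ground truth, one LD panel per ancestry plus the mixed panel,
#' per-ancestry summary statistics, and the gene-feature matrix. Everything
#' is a deterministic function of the config.
#'
#' @param config A [sim_config()].
#' @return An object of class `gwas_sim`: list with `config`, `genes`,
#'   `truth`, `panels` (named list, one per ancestry), `mixed_panel`,
#'   `sumstats` (named list of per-ancestry tibbles), `features`.
#' @export
simulate_gwas <- function(config) {
  validate_sim_config(config)
  genes <- simulate_genes(config)
  truth <- simulate_truth(config, genes = genes)
  labels <- config$ancestries$label
  panels <- lapply(labels, function(a) simulate_ld_panel(config, a))
  names(panels) <- labels
  sumstats <- lapply(seq_along(labels), function(i) {
    simulate_sumstats(panels[[i]], truth,
                      n_eff = config$ancestries$n_eff[i],
                      seed = sim_seed(config, 2000L + i))
  })
  names(sumstats) <- labels
  structure(
    list(config = config, genes = genes, truth = truth, panels = panels,
         mixed_panel = mix_panels(panels),
         sumstats = sumstats,
         features = simulate_features(truth, config, sim_seed(config, 3000L))),
    class = "gwas_sim"
  )
}

#' @export
print.gwas_sim <- function(x, ...) {
  cat("<gwas_sim>\n")
  print(x$config)
  print(x$truth)
  invisible(x)
}
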