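#' Simulate an LD reference panel for one ancestry
#'
#' Draws `n_ref_samples` diploid genotypes with block-diagonal LD. Haplotypes
#' follow a copy-chain within each block: the allele state at variant `i` is
#' copied from variant `i-1` with probability `ld_decay`, otherwise drawn
#' fresh, which makes the haplotype (and genotype) correlation between
#' variants `i` and `j` equal to `ld_decay^|i-j|` within a block and zero
#' across blocks. Allele frequencies are ancestry-specific (Balding-Nichols
#' divergence from a shared base frequency).
#'
#' @param config A [sim_config()].
#' @param ancestry Ancestry label; must appear in `config$ancestries`.
#' @return An object of class `ld_panel`: list with `label`, `n` (panel
#'   size), `genotypes` (n x n_variants integer matrix of 0/1/2 dosages,
#'   columns named by variant id), `map` (the variant map) and `freq`
#'   (empirical effect-allele frequency per variant).
#' @export
#' @examples
#' cfg <- sim_config(n_variants = 200, n_genes = 10, n_chromosomes = 2,
#'                   n_features = 20, n_causal_loci = 2, ld_block_size = 20,
#'                   ancestries = data.frame(label = "EAS", n_ref_samples = 200,
#'                                           n_eff = 5000), seed = 7)
#' p <- simulate_ld_panel(cfg, "EAS")
#' dim(p$genotypes)
simulate_ld_panel <- function(config, ancestry) {
  validate_sim_config(config)
  a_i <- match(ancestry, config$ancestries$label)
  if (is.na(a_i)) abort(sprintf("unknown ancestry '%s'", ancestry))
  vmap <- simulate_variant_map(config)
  freqs <- variant_frequencies(config, vmap)
  f <- freqs$by_ancestry[[ancestry]]
  n <- config$ancestries$n_ref_samples[a_i]
  rho <- config$ld_decay

  set.seed(sim_seed(config, 1000L + a_i))
  n_hap <- 2L * n
  geno <- matrix(0L, nrow = n, ncol = nrow(vmap),
                 dimnames = list(NULL, vmap$snp))
  # latent uniform per haplotype, refreshed with prob 1 - rho at each step;
  # thresholding at the variant's frequency gives exact Bernoulli marginals
  u <- numeric(n_hap)
  block_prev <- -1L
  for (j in seq_len(nrow(vmap))) {
    if (vmap$block[j] != block_prev) {
      u <- runif(n_hap)
      block_prev <- vmap$block[j]
    } else {
      refresh <- runif(n_hap) >= rho
      if (any(refresh)) u[refresh] <- runif(sum(refresh))
    }
    h <- u < f[j]
    geno[, j] <- as.integer(h[1:n]) + as.integer(h[(n + 1L):n_hap])
  }

  structure(
    list(label = ancestry, n = n, genotypes = geno, map = vmap,
         freq = colMeans(geno) / 2),
    class = "ld_panel"
  )
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %s: %d samples x %d variants\n",
              x$label, x$n, ncol(x$genotypes)))
  invisible(x)
}

#' Combine ancestry panels into a mixed reference panel
#'
#' Stacks the samples of several panels into one panel, mirroring a mixed
#' (e.g. EAS+EUR) LD reference whose ancestry proportions match the GWAS
#' being meta-analyzed. The panels must share a variant map.
#'
#' @param panels A list of `ld_panel` objects.
#' @param label Label for the combined panel.
#' @return An `ld_panel` with the pooled samples.
#' @export
mix_panels <- function(panels, label = "META") {
  stopifnot(length(panels) >= 1)
  snps <- colnames(panels[[1]]$genotypes)
  for (p in panels) {
    if (!identical(colnames(p$genotypes), snps)) {
      abort("panels must share an identical variant map to be mixed")
    }
  }
  geno <- do.call(rbind, lapply(panels, function(p) p$genotypes))
  structure(
    list(label = label, n = nrow(geno), genotypes = geno,
         map = panels[[1]]$map, freq = colMeans(geno) / 2),
    class = "ld_panel"
  )
}

# Correlation matrix of a set of panel variants (by id), with monomorphic
# columns dropped. Used by clumping, COJO and the gene-level test.
panel_ld <- function(panel, snps) {
  g <- panel$genotypes[, snps, drop = FALSE]
  keep <- apply(g, 2, function(x) var(x) > 0)
  r <- cor(g[, keep, drop = FALSE])
  attr(r, "dropped") <- snps[!keep]
  r
}
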