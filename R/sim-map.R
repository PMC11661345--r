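# Variant map, allele assignment and allele-frequency model for the
# synthetic genome. All deterministic functions of the config.

# Non-ambiguous allele pairs only: strand-ambiguous (A/T, C/G) variants would
# be dropped during harmonization, so the generator avoids creating them.
.allele_pairs <- rbind(
  c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
  c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T")
)

#' Variant map for a simulated genome
#'
#' Lays `n_variants` onto `n_chromosomes` autosomes at fixed spacing and
#' partitions each chromosome into LD blocks of consecutive variants.
#' Deterministic given the config.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `chrom`, `snp`, `pos` (1-based), `a1`
#'   (effect allele), `a2`, `block` (genome-wide LD-block index).
#' @export
simulate_variant_map <- function(config) {
  validate_sim_config(config)
  per_chr <- split_counts(config$n_variants, config$n_chromosomes)
  set.seed(sim_seed(config, 11L))
  pair_idx <- sample.int(nrow(.allele_pairs), config$n_variants, replace = TRUE)
  chrom <- rep(seq_len(config$n_chromosomes), per_chr)
  idx_in_chr <- unlist(lapply(per_chr, seq_len), use.names = FALSE)
  # blocks never straddle a chromosome boundary
  block_in_chr <- (idx_in_chr - 1L) %/% config$ld_block_size
  block <- cumsum(c(0L, diff(chrom) != 0L | diff(block_in_chr) != 0L)) + 1L
  tibble::tibble(
    chrom = chrom,
    snp = sprintf("rs%06d", seq_len(config$n_variants)),
    pos = 10000L + (idx_in_chr - 1L) * config$bp_spacing,
    a1 = .allele_pairs[pair_idx, 1],
    a2 = .allele_pairs[pair_idx, 2],
    block = block
  )
}

# Allele-frequency model: one base frequency per LD block (small per-variant
# jitter keeps within-block LD essentially exact under the copy-chain
# haplotype model), Balding-Nichols perturbation per ancestry at the block
# level with fixation index fst.
variant_frequencies <- function(config, vmap = simulate_variant_map(config)) {
  n_blocks <- max(vmap$block)
  set.seed(sim_seed(config, 23L))
  base_block <- runif(n_blocks, 0.05, 0.95)
  jitter <- rnorm(nrow(vmap), 0, 0.005)
  base <- pmin(pmax(base_block[vmap$block] + jitter, 0.02), 0.98)

  anc_freqs <- lapply(seq_len(nrow(config$ancestries)), function(i) {
    set.seed(sim_seed(config, 100L + i))
    f <- base_block
    a <- f * (1 - config$fst) / config$fst
    b <- (1 - f) * (1 - config$fst) / config$fst
    f_anc_block <- rbeta(n_blocks, a, b)
    pmin(pmax(f_anc_block[vmap$block] + jitter, 0.02), 0.98)
  })
  names(anc_freqs) <- config$ancestries$label
  list(base = base, by_ancestry = anc_freqs)
}

#' Simulated protein-coding gene models
#'
#' Tiles gene bodies along each simulated chromosome (1-based, inclusive
#' start/end, autosomes only). Gene lengths are drawn uniformly between 10 kb
#' and 80 kb and genes are spaced so that the gene set spans the variant map.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene`, `symbol`, `chrom`, `start`, `end`.
#' @export
simulate_genes <- function(config) {
  validate_sim_config(config)
  per_chr_v <- split_counts(config$n_variants, config$n_chromosomes)
  per_chr_g <- split_counts(config$n_genes, config$n_chromosomes)
  set.seed(sim_seed(config, 37L))
  out <- vector("list", config$n_chromosomes)
  gene_no <- 0L
  for (c_i in seq_len(config$n_chromosomes)) {
    chr_span <- 10000L + (per_chr_v[c_i] - 1L) * config$bp_spacing
    n_g <- per_chr_g[c_i]
    spacing <- chr_span / n_g
    len <- round(runif(n_g, 10000, 80000))
    start <- pmax(1L, round((seq_len(n_g) - 1L) * spacing +
                              runif(n_g, 0, pmax(1, spacing - len))))
    end <- pmin(start + len, chr_span + config$bp_spacing)
    ids <- sprintf("G%04d", gene_no + seq_len(n_g))
    out[[c_i]] <- tibble::tibble(
      gene = ids, symbol = ids, chrom = c_i,
      start = as.integer(start), end = as.integer(end)
    )
    gene_no <- gene_no + n_g
  }
  dplyr::bind_rows(out)
}
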