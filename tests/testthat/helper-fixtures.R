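# Shared fixtures and small independent oracles used across test files.

# AR(1) correlation matrix, the generator's within-block LD target.
ar1_corr <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# Columns with an EXACT sample correlation matrix R: centered orthonormal
# basis (orthogonal to the intercept) times chol(R).
exact_cor_columns <- function(R, n) {
  m <- ncol(R)
  stopifnot(n > m + 1)
  set.seed(99)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * m), n))))[, -1, drop = FALSE]
  Q %*% chol(R)
}

# Hand-built ld_panel around arbitrary numeric "genotype" columns.
make_panel <- function(genotypes, chrom = 1L, pos = NULL,
                       a1 = "A", a2 = "G", label = "TEST") {
  m <- ncol(genotypes)
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- sprintf("v%03d", seq_len(m))
  }
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- tibble::tibble(
    chrom = rep(chrom, length.out = m), snp = colnames(genotypes),
    pos = pos, a1 = rep(a1, length.out = m), a2 = rep(a2, length.out = m),
    block = 1L
  )
  structure(list(label = label, n = nrow(genotypes), genotypes = genotypes,
                 map = map, freq = colMeans(genotypes) / 2),
            class = "ld_panel")
}

# Hand-built variant-statistics table from z-scores.
make_stats <- function(snp, z, pos = NULL, chrom = 1L, se = 0.02,
                       eaf = 0.5, n_eff = 1e5, ancestry = "META",
                       a1 = "A", a2 = "G") {
  m <- length(snp)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  se <- rep(se, length.out = m)
  tibble::tibble(
    chrom = rep(chrom, length.out = m), pos = pos, snp = snp,
    a1 = rep(a1, length.out = m), a2 = rep(a2, length.out = m),
    eaf = rep(eaf, length.out = m), beta = z * se, se = se,
    p = 2 * stats::pnorm(-abs(z)), n_eff = rep(n_eff, length.out = m),
    ancestry = ancestry
  )
}

# Isolated-signal stub feeding the fine-mapping stage directly.
# default se matches z_for_labf() so crafted lABFs survive the round trip
make_signal <- function(z, se = 0.1, pos = NULL, chrom = 1L,
                        lead = NULL) {
  m <- length(z)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  snp <- sprintf("s%03d", seq_len(m))
  se <- rep(se, length.out = m)
  structure(
    list(region = NULL, lead = lead %||% snp[which.max(abs(z))], hits = NULL,
         cond_stats = tibble::tibble(
           snp = snp, chrom = chrom, pos = pos, eaf = 0.5,
           beta = z * se, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))),
    class = "independent_signal"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# z-scores whose Wakefield lABFs equal `labf` exactly (given se, prior_sd).
z_for_labf <- function(labf, se = 0.1, prior_sd = 0.2) {
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  sqrt((2 * labf - log(1 - r)) / r)
}

# Medium synthetic study shared across files, computed once per session.
.fixture_env <- new.env(parent = emptyenv())

fixture_config <- function() {
  sim_config(
    n_variants = 6000, n_genes = 200, n_chromosomes = 6, n_features = 100,
    n_causal_loci = 10,
    ancestries = data.frame(label = c("EAS", "EUR"),
                            n_ref_samples = c(400, 800),
                            n_eff = c(15886, 127626)),
    ld_block_size = 30, causal_effect_sd = 0.035, seed = 101
  )
}

fixture_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- simulate_gwas(fixture_config())
  }
  .fixture_env$study
}

fixture_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- suppressMessages(run_pipeline(fixture_study()))
  }
  .fixture_env$run
}
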