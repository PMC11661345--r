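# Independent greedy clumping oracle: plain loops over the same rules.
clump_oracle <- function(stats, panel, p_thresh = 5e-8, r2_thresh = 0.1,
                         window_bp = 3e6, pad = 5e5) {
  stats <- stats[order(stats$chrom, stats$pos), ]
  assigned <- rep(FALSE, nrow(stats))
  spans <- NULL
  repeat {
    cand <- which(!assigned & stats$p < p_thresh)
    if (length(cand) == 0) break
    i <- cand[order(stats$p[cand], stats$chrom[cand], stats$pos[cand])][1]
    members <- i
    for (j in which(!assigned)) {
      if (j == i) next
      if (stats$chrom[j] != stats$chrom[i]) next
      if (abs(stats$pos[j] - stats$pos[i]) > window_bp) next
      r <- cor(panel$genotypes[, stats$snp[i]], panel$genotypes[, stats$snp[j]])
      if (!is.na(r) && r^2 >= r2_thresh) members <- c(members, j)
    }
    assigned[members] <- TRUE
    spans <- rbind(spans, data.frame(
      index = stats$snp[i], chrom = stats$chrom[i],
      start = max(1, min(stats$pos[members]) - pad),
      end = max(stats$pos[members]) + pad))
  }
  if (is.null(spans)) return(spans)
  spans <- spans[order(spans$chrom, spans$start), ]
  merged <- NULL
  for (k in seq_len(nrow(spans))) {
    if (!is.null(merged) && spans$chrom[k] == merged$chrom[nrow(merged)] &&
        spans$start[k] <= merged$end[nrow(merged)]) {
      merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], spans$end[k])
      merged$index[nrow(merged)] <- paste(merged$index[nrow(merged)],
                                          spans$index[k], sep = ",")
    } else {
      merged <- rbind(merged, spans[k, ])
    }
  }
  merged
}

test_that("distant uncorrelated signals form separate regions", {
  g <- exact_cor_columns(diag(2), 200)
  colnames(g) <- c("a", "b")
  panel <- make_panel(g, pos = c(1e6L, 5e6L))
  stats <- make_stats(c("a", "b"), z = c(8, 7), pos = c(1e6L, 5e6L))
  reg <- clump(stats, panel)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$n_index, c(1L, 1L))
})

test_that("correlated nearby significant variants form one clump", {
  R <- matrix(0.5, 5, 5); diag(R) <- 1
  g <- exact_cor_columns(R, 300)
  colnames(g) <- sprintf("v%d", 1:5)
  panel <- make_panel(g, pos = as.integer(seq(1e6, 2e6, length.out = 5)))
  stats <- make_stats(sprintf("v%d", 1:5), z = c(9, 8, 7, 7.5, 8.5),
                      pos = as.integer(seq(1e6, 2e6, length.out = 5)))
  reg <- clump(stats, panel)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_index, 1L)
  expect_equal(reg$index_variants[[1]], "v1")
})

test_that("clumping matches a brute-force greedy oracle on a random fixture", {
  cfg <- sim_config(
    n_variants = 200, n_genes = 10, n_chromosomes = 2, n_features = 10,
    n_causal_loci = 0,
    ancestries = data.frame(label = "A", n_ref_samples = 300, n_eff = 5e4),
    ld_block_size = 20, seed = 61
  )
  panel <- simulate_ld_panel(cfg, "A")
  set.seed(62)
  z <- rnorm(200)
  hot <- sample(200, 12)
  z[hot] <- z[hot] + sample(c(-1, 1), 12, TRUE) * runif(12, 5.5, 9)
  stats <- make_stats(panel$map$snp, z = z, pos = panel$map$pos,
                      chrom = panel$map$chrom)
  # tight pad so that not everything merges
  reg <- clump(stats, panel, pad = 2e4, window_bp = 1e5)
  oracle <- clump_oracle(stats, panel, pad = 2e4, window_bp = 1e5)
  expect_equal(nrow(reg), nrow(oracle))
  expect_equal(reg$start, oracle$start)
  expect_equal(reg$end, oracle$end)
  expect_equal(vapply(reg$index_variants, paste, "", collapse = ","),
               oracle$index)
})

test_that("no significant variant yields an empty region list", {
  g <- exact_cor_columns(diag(2), 100)
  colnames(g) <- c("a", "b")
  panel <- make_panel(g)
  stats <- make_stats(colnames(g), z = c(1, 2))
  expect_equal(nrow(clump(stats, panel)), 0L)
})

test_that("a single signal gives joint estimates equal to marginals", {
  g <- exact_cor_columns(diag(3), 200)
  colnames(g) <- c("a", "b", "c")
  panel <- make_panel(g)
  stats <- make_stats(c("a", "b", "c"), z = c(8, 1, -0.5))
  region <- tibble::tibble(region = 1L, chrom = 1L, start = 1, end = 1e6)
  hits <- cojo_select(region, stats, panel)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$snp, "a")
  expect_equal(hits$joint_beta, hits$beta, tolerance = 1e-10)
  expect_equal(hits$joint_se, hits$se, tolerance = 1e-10)
})

test_that("a perfectly collinear variant never enters the model", {
  g0 <- exact_cor_columns(diag(2), 200)
  g <- cbind(g0[, 1], g0[, 1], g0[, 2])
  colnames(g) <- c("a", "a2", "b")
  panel <- make_panel(g)
  stats <- make_stats(c("a", "a2", "b"), z = c(9, 9, 0.2))
  region <- tibble::tibble(region = 1L, chrom = 1L, start = 1, end = 1e6)
  hits <- cojo_select(region, stats, panel)
  expect_equal(hits$snp, "a")
})

test_that("joint estimates match the 2x2 linear-algebra oracle", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  g <- exact_cor_columns(R, 400)
  colnames(g) <- c("a", "b")
  panel <- make_panel(g)
  stats <- make_stats(c("a", "b"), z = c(5, 4), se = c(0.03, 0.04))
  region <- tibble::tibble(region = 1L, chrom = 1L, start = 1, end = 1e6)
  hits <- cojo_select(region, stats, panel, p_thresh = 0.1)
  expect_equal(nrow(hits), 2L)
  # R^{-1} (5,4) = (4, 2); joint z scales by 1/sqrt(diag(R^{-1}))
  Rinv <- solve(R)
  expect_equal(hits$joint_beta, stats$se * drop(Rinv %*% c(5, 4)),
               tolerance = 1e-8)
  expect_equal(hits$joint_se, stats$se * sqrt(diag(Rinv)), tolerance = 1e-8)
  expect_equal(hits$joint_beta / hits$joint_se,
               c(4, 2) / sqrt(diag(Rinv)), tolerance = 1e-8)
})

test_that("hits with non-significant joint p are removed", {
  R <- matrix(c(1, 0.7, 0.7, 1), 2)
  g <- exact_cor_columns(R, 400)
  colnames(g) <- c("a", "b")
  panel <- make_panel(g)
  # marginally strong pair, but b is mostly a shadow of a
  stats <- make_stats(c("a", "b"), z = c(12, 9), se = 0.03)
  region <- tibble::tibble(region = 1L, chrom = 1L, start = 1, end = 1e6)
  hits <- cojo_select(region, stats, panel)
  expect_true(all(hits$joint_p <= 5e-8))
})

test_that("single-hit conditioning returns the marginal statistics", {
  g <- exact_cor_columns(ar1_corr(4, 0.5), 300)
  colnames(g) <- sprintf("v%d", 1:4)
  panel <- make_panel(g)
  stats <- make_stats(sprintf("v%d", 1:4), z = c(8, 5, 2, 1))
  region <- tibble::tibble(region = 1L, chrom = 1L, start = 1, end = 1e6)
  hits <- cojo_select(region, stats, panel)
  sigs <- leave_one_out_condition(region, hits, stats, panel)
  expect_length(sigs, nrow(hits))
  expect_equal(sigs[[1]]$cond_stats$z, stats$beta / stats$se,
               tolerance = 1e-12)
  expect_equal(sigs[[1]]$cond_stats$beta, stats$beta, tolerance = 1e-12)
})

test_that("orthogonal hits leave each other's statistics untouched", {
  g <- exact_cor_columns(diag(4), 300)
  colnames(g) <- sprintf("v%d", 1:4)
  panel <- make_panel(g)
  z <- c(9, 1, 8, -1)
  stats <- make_stats(sprintf("v%d", 1:4), z = z)
  region <- tibble::tibble(region = 1L, chrom = 1L, start = 1, end = 1e6)
  hits <- cojo_select(region, stats, panel)
  expect_equal(sort(hits$snp), c("v1", "v3"))
  sigs <- leave_one_out_condition(region, hits, stats, panel)
  s1 <- sigs[[which(vapply(sigs, `[[`, "", "lead") == "v1")]]
  expect_equal(s1$cond_stats$z[1:2], z[1:2], tolerance = 1e-10)
  expect_equal(s1$cond_stats$z[3], 0)  # the conditioning hit itself
  expect_equal(s1$cond_stats$p[3], 1)
})

test_that("conditioning matches the multivariate-normal oracle", {
  R <- ar1_corr(3, 0.6)
  g <- exact_cor_columns(R, 500)
  colnames(g) <- sprintf("v%d", 1:3)
  panel <- make_panel(g)
  z <- c(8, 6.5, 3)
  stats <- make_stats(sprintf("v%d", 1:3), z = z)
  region <- tibble::tibble(region = 1L, chrom = 1L, start = 1, end = 1e6)
  hits <- tibble::tibble(snp = c("v1", "v2"))  # condition on fixed hit set
  sigs <- leave_one_out_condition(region, hits, stats, panel)
  # signal for v1 conditions everything on v2: standard MVN conditional
  s1 <- sigs[[1]]
  mvn_cond <- function(zi, zc, r) (zi - r * zc) / sqrt(1 - r^2)
  expect_equal(s1$cond_stats$z[1], mvn_cond(z[1], z[2], R[1, 2]),
               tolerance = 1e-10)
  expect_equal(s1$cond_stats$z[3], mvn_cond(z[3], z[2], R[2, 3]),
               tolerance = 1e-10)
  expect_equal(s1$cond_stats$z[2], 0)
})

test_that("stepwise selection recovers two planted independent signals", {
  cfg <- sim_config(
    n_variants = 100, n_genes = 6, n_chromosomes = 2, n_features = 10,
    n_causal_loci = 0,
    ancestries = data.frame(label = "A", n_ref_samples = 800, n_eff = 5e4),
    ld_block_size = 25, seed = 71
  )
  panel <- simulate_ld_panel(cfg, "A")
  n_eff <- 5e4
  truth <- list(causal_variants = tibble::tibble(
    snp = panel$map$snp[c(10, 40)], gene = c("G1", "G2"),
    effect = 10 / sqrt(n_eff), nonsyn = FALSE))
  stats <- simulate_sumstats(panel, truth, n_eff = n_eff, seed = 72)
  region <- tibble::tibble(region = 1L, chrom = 1L,
                           start = 1, end = max(panel$map$pos))
  hits <- cojo_select(region, stats, panel)
  expect_equal(nrow(hits), 2L)
  # each hit tags one planted block
  expect_setequal(panel$map$block[match(hits$snp, panel$map$snp)],
                  panel$map$block[c(10, 40)])
})
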