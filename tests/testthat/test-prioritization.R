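mk_genes <- function(...) {
  g <- tibble::tibble(...)
  g$symbol <- g$gene
  g$chrom <- g$chrom %||% 1L
  g
}

mk_locus <- function(genes, lead = "sLEAD", chrom = 1L,
                     start = 1, end = 2e6) {
  structure(list(lead = lead, chrom = chrom, start = start, end = end,
                 genes = genes), class = "locus")
}

mk_cs <- function(center, snps = "sLEAD", pips = 1, pos = NULL) {
  pos <- pos %||% rep(round(center), length(snps))
  structure(list(lead = snps[1], chrom = 1L,
                 variants = tibble::tibble(snp = snps, pos = pos,
                                           labf = log(pips) + 5, pip = pips,
                                           in_cs = TRUE),
                 coverage = sum(pips), weighted_center = center),
            class = "credible_set")
}

no_nonsyn <- tibble::tibble(snp = character(), gene = character())

test_that("gene distance is zero inside the body, else edge distance", {
  g <- tibble::tibble(gene = "g", chrom = 1L, start = 100, end = 200)
  expect_equal(gene_distance(g, 150), 0)
  expect_equal(gene_distance(g, 100), 0)
  expect_equal(gene_distance(g, 350), 150)
  expect_equal(gene_distance(g, 40), 60)
  expect_error(gene_distance(g, 150, chrom = 2), "one chromosome")
  # brute-force per-base scan
  for (center in c(1, 99, 100, 173, 200, 201, 500)) {
    brute <- min(abs(center - 100:200))
    expect_equal(gene_distance(g, center), brute)
  }
})

test_that("top PoPS without nearest gene yields no call", {
  # the GCH1/WDHD1 pattern: the top-PoPS gene is slightly farther from the
  # credible-set center than its neighbour
  genes <- mk_genes(gene = c("WDHD1like", "GCH1like"), chrom = 1L,
                    start = c(90000, 130000), end = c(95000, 140000))
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 100000)
  scores <- tibble::tibble(gene = c("WDHD1like", "GCH1like"),
                           meta_score = c(0.2, 1.5),
                           percentile = c(0.5, 0.99),
                           magma_meta_z = c(3, 4))
  call <- call_locus(locus, cs, scores, no_nonsyn)
  expect_true(is.na(call$prioritized))
  expect_equal(call$candidates$nearest,
               call$candidates$gene == "WDHD1like")
  expect_equal(call$candidates$top_pops,
               call$candidates$gene == "GCH1like")
})

test_that("nearest + top PoPS + non-synonymous variant gives a nonsynonymous call", {
  # the EP300 pattern
  genes <- mk_genes(gene = c("EP300like", "other"), chrom = 1L,
                    start = c(90000, 300000), end = c(150000, 350000))
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 100000, snps = c("rsns", "rs2"), pips = c(0.7, 0.3),
              pos = c(100000, 101000))
  scores <- tibble::tibble(gene = c("EP300like", "other"),
                           meta_score = c(2, 0.1),
                           percentile = c(0.99, 0.4),
                           magma_meta_z = c(8, 1))
  nonsyn <- tibble::tibble(snp = "rsns", gene = "EP300like")
  call <- call_locus(locus, cs, scores, nonsyn)
  expect_equal(call$prioritized, "EP300like")
  expect_equal(call$basis, "nonsynonymous")
  expect_equal(call$candidates$nonsyn_pip[
    call$candidates$gene == "EP300like"], 0.7)
})

test_that("a non-synonymous call beats a different pops+nearest gene", {
  genes <- mk_genes(gene = c("X", "Y"), chrom = 1L,
                    start = c(90000, 300000), end = c(150000, 350000))
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 100000, snps = c("rsy", "rs2"), pips = c(0.87, 0.13),
              pos = c(100000, 101000))
  scores <- tibble::tibble(gene = c("X", "Y"), meta_score = c(2, 0.1),
                           percentile = c(0.99, 0.4),
                           magma_meta_z = c(8, 1))
  nonsyn <- tibble::tibble(snp = "rsy", gene = "Y")
  call <- call_locus(locus, cs, scores, nonsyn)
  expect_equal(call$prioritized, "Y")
  expect_equal(call$basis, "nonsynonymous")
})

test_that("criterion A alone prioritizes the nearest top-PoPS gene", {
  genes <- mk_genes(gene = c("A", "B"), chrom = 1L,
                    start = c(90000, 300000), end = c(150000, 350000))
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 100000)
  scores <- tibble::tibble(gene = c("A", "B"), meta_score = c(2, 0.1),
                           percentile = c(0.99, 0.4),
                           magma_meta_z = c(8, 1))
  call <- call_locus(locus, cs, scores, no_nonsyn)
  expect_equal(call$prioritized, "A")
  expect_equal(call$basis, "pops_nearest")
})

test_that("sub-threshold non-synonymous mass does not fire criterion B", {
  genes <- mk_genes(gene = c("A", "B"), chrom = 1L,
                    start = c(90000, 300000), end = c(150000, 350000))
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 100000, snps = c("rsb", "rs2"), pips = c(0.5, 0.5),
              pos = c(100000, 101000))
  scores <- tibble::tibble(gene = c("A", "B"), meta_score = c(2, 0.1),
                           percentile = c(0.99, 0.4), magma_meta_z = c(8, 1))
  nonsyn <- tibble::tibble(snp = "rsb", gene = "B")
  call <- call_locus(locus, cs, scores, nonsyn)   # 0.5 is not > 0.5
  expect_equal(call$prioritized, "A")
  expect_equal(call$basis, "pops_nearest")
})

test_that("genes without PoPS scores can be nearest but never top PoPS", {
  genes <- mk_genes(gene = c("noscore", "scored"), chrom = 1L,
                    start = c(99000, 300000), end = c(101000, 350000))
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 100000)
  scores <- tibble::tibble(gene = "scored", meta_score = 1,
                           percentile = 0.9, magma_meta_z = 3)
  call <- call_locus(locus, cs, scores, no_nonsyn)
  expect_true(is.na(call$prioritized))
  cand <- call$candidates
  expect_true(cand$nearest[cand$gene == "noscore"])
  expect_false(cand$top_pops[cand$gene == "noscore"])
  expect_true(cand$top_pops[cand$gene == "scored"])
})

test_that("equidistant genes break ties toward the higher PoPS score", {
  genes <- mk_genes(gene = c("lo", "hi"), chrom = 1L,
                    start = c(80000, 110000), end = c(90000, 120000))
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 100000)   # 10 kb from both bodies
  scores <- tibble::tibble(gene = c("lo", "hi"), meta_score = c(0.1, 2),
                           percentile = c(0.3, 0.95), magma_meta_z = c(1, 5))
  call <- call_locus(locus, cs, scores, no_nonsyn)
  expect_equal(call$prioritized, "hi")
  expect_equal(call$basis, "pops_nearest")
})

test_that("an empty locus produces an empty call", {
  locus <- mk_locus(tibble::tibble(gene = character(), symbol = character(),
                                   chrom = integer(), start = integer(),
                                   end = integer()))
  call <- call_locus(locus, mk_cs(100000), tibble::tibble(), no_nonsyn)
  expect_true(is.na(call$prioritized))
  expect_equal(nrow(call$candidates), 0L)
})

test_that("external probabilities are rescaled per locus, capped at 100%", {
  preds <- tibble::tibble(locus = rep(c("L1", "L2", "L3"), c(4, 2, 2)),
                          gene = sprintf("g%d", 1:8),
                          prob = c(0.9, 0.8, 0.5, 0.3, 0.5, 0.3, 0.7, 0.3))
  r <- rescale_external(preds)
  expect_equal(r$prob[1:4], c(0.36, 0.32, 0.20, 0.12))
  expect_equal(r$prob[5:6], c(0.5, 0.3))      # sum 0.8 unchanged
  expect_equal(r$prob[7:8], c(0.7, 0.3))      # sum exactly 1 unchanged
  expect_equal(rescale_external(r), r)        # idempotent
  expect_error(rescale_external(tibble::tibble(locus = "L", gene = "g",
                                               prob = -0.1)),
               "non-negative")
})

test_that("the evidence table reports per-gene locus context", {
  genes <- mk_genes(gene = sprintf("g%d", 1:7), chrom = 1L,
                    start = 1e5 * (1:7), end = 1e5 * (1:7) + 5e4)
  locus <- mk_locus(genes)
  cs <- mk_cs(center = 98500)    # 1,500 bp from g1's start
  scores <- tibble::tibble(gene = sprintf("g%d", 1:7),
                           meta_score = c(3, 1:6 / 10),
                           percentile = seq(0.99, 0.4, length.out = 7),
                           magma_meta_z = 7:1)
  call <- call_locus(locus, cs, scores, no_nonsyn)
  ext <- list(L2G = tibble::tibble(locus = "sLEAD", gene = "g1", prob = 0.8))
  ev <- build_evidence_table(list(call), external = ext)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene, "g1")
  expect_equal(ev$n_genes_in_locus, 7L)
  expect_equal(ev$distance_kb, 1.5)
  expect_equal(ev$L2G, 0.8)
})
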