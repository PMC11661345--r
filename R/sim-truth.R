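#' Ground truth for a simulated GWAS
#'
#' Chooses `n_causal_loci` causal genes, places exactly one causal variant
#' inside each causal gene body, draws its ancestry-shared standardized
#' effect from `Normal(0, causal_effect_sd^2)`, flags a fraction of causal
#' variants as non-synonymous, and designates a common set of signature
#' feature columns that are shifted for every causal gene (so that the
#' feature matrix carries a learnable genome-wide signal). A sprinkle of
#' non-causal coding variants is added to the non-synonymous annotation so
#' that the annotation is not a causal-variant oracle.
#'
#' @param config A [sim_config()].
#' @param vmap Variant map from [simulate_variant_map()]; recomputed if omitted.
#' @param genes Gene models from [simulate_genes()]; recomputed if omitted.
#' @return An object of class `ground_truth`: a list with
#'   `causal_variants` (tibble: `snp`, `gene`, `effect`, `nonsyn`),
#'   `causal_genes` (character vector), `signature_features` (integer
#'   indices), and `nonsyn` (tibble: `snp`, `gene` — the full annotation,
#'   causal and background).
#' @export
simulate_truth <- function(config,
                           vmap = simulate_variant_map(config),
                           genes = simulate_genes(config)) {
  validate_sim_config(config)
  freqs <- variant_frequencies(config, vmap)
  set.seed(sim_seed(config, 53L))

  # candidate causal genes: need >=1 common variant strictly inside the body
  in_gene <- dplyr::inner_join(
    dplyr::select(vmap, "chrom", "snp", "pos"),
    dplyr::select(genes, "gene", "chrom", "start", "end"),
    by = "chrom", relationship = "many-to-many"
  )
  in_gene <- dplyr::filter(in_gene, .data$pos >= .data$start, .data$pos <= .data$end)
  f <- freqs$base[match(in_gene$snp, vmap$snp)]
  in_gene <- in_gene[f >= 0.1 & f <= 0.9, ]
  eligible <- unique(in_gene$gene)
  if (length(eligible) < config$n_causal_loci) {
    abort("not enough genes contain a common variant to host the causal loci")
  }
  causal_genes <- sort(sample(eligible, config$n_causal_loci))

  causal_variants <- in_gene |>
    dplyr::filter(.data$gene %in% causal_genes) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice(sample(dplyr::n(), 1L)) |>
    dplyr::ungroup() |>
    dplyr::select("snp", "gene")
  causal_variants$effect <- rnorm(nrow(causal_variants), 0, config$causal_effect_sd)
  n_ns <- round(config$frac_nonsyn_causal * nrow(causal_variants))
  nonsyn_flag <- rep(FALSE, nrow(causal_variants))
  if (n_ns > 0) nonsyn_flag[sample(nrow(causal_variants), n_ns)] <- TRUE
  causal_variants$nonsyn <- nonsyn_flag

  signature_features <- sort(sample(config$n_features, config$n_signature_features))

  # background (null) non-synonymous annotations: ~1% of in-gene variants
  bg_pool <- dplyr::anti_join(in_gene, causal_variants, by = "snp")
  n_bg <- min(nrow(bg_pool), ceiling(0.01 * nrow(bg_pool)))
  bg <- bg_pool[sample(nrow(bg_pool), n_bg), c("snp", "gene")]
  nonsyn <- dplyr::bind_rows(
    dplyr::select(causal_variants[causal_variants$nonsyn, ], "snp", "gene"),
    bg
  ) |> dplyr::distinct(.data$snp, .data$gene)

  structure(
    list(causal_variants = causal_variants,
         causal_genes = causal_genes,
         signature_features = signature_features,
         nonsyn = nonsyn),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  cat(sprintf("  %d causal genes, %d causal variants (%d non-synonymous)\n",
              length(x$causal_genes), nrow(x$causal_variants),
              sum(x$causal_variants$nonsyn)))
  cat(sprintf("  %d signature features; %d annotated non-synonymous variants\n",
              length(x$signature_features), nrow(x$nonsyn)))
  invisible(x)
}
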