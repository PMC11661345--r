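# popsloci

Gene prioritization in GWAS loci from multi-ancestry summary statistics.

A genome-wide association study (GWAS) nominates genomic *regions*, not
genes: the lead variant of a locus usually tags dozens of genes through
linkage disequilibrium (LD). `popsloci` implements a complete
summary-statistics-to-prioritized-genes pipeline of the kind used to
nominate drug-target candidates in Parkinson's disease genetics, built for
analysts who have per-ancestry GWAS summary statistics, LD reference
panels, gene models and a gene-feature matrix, and want one defensible
causal-gene call per association signal. Because the real inputs are huge
and access-controlled, the package also ships a fully synthetic
multi-ancestry study generator with known causal genes, so every stage is
testable end to end on a laptop.

## The method

For each ancestry, variant statistics (β, SE, effect-allele frequency
*f*, effective sample size *N*) are harmonized to the ancestry's LD panel
and filtered on allele-frequency agreement (|*f*−*f*_ref| > 0.1, then
fold-change > 12). Ancestries are combined by fixed-effects
inverse-variance meta-analysis,

&nbsp;&nbsp;β_meta = Σ β_i/SE_i² ⁄ Σ 1/SE_i², SE_meta = (Σ 1/SE_i²)^(−1/2).

Significant variants (*P* < 5×10⁻⁸) are clumped (r² ≥ 0.1 within 3 Mb,
spans padded ±500 kb and merged) on a mixed-ancestry panel, and each
region is decomposed into independent signals by stepwise
conditional-and-joint (COJO-style) selection on z-scores with reference
LD **R**: conditional z given a selected set *C* is

&nbsp;&nbsp;z_{i|C} = (z_i − R_{iC} R_C⁻¹ z_C) / √(1 − R_{iC} R_C⁻¹ R_{Ci}),

and joint effects for the selected set are R_S⁻¹ z rescaled by the
marginal SEs. Each signal is isolated by leave-one-hit-out conditioning
and fine-mapped with Wakefield approximate Bayes factors,
lABF = ½(log(1−r) + r z²) with r = W/(W+V), giving per-variant posterior
inclusion probabilities (PIPs), a 95% credible set, and a PIP-weighted
center position; the locus is the credible set ±300 kb.

Gene-level association uses the SNP-wise mean statistic (mean squared z
over a gene's common variants, MAF > 1%, ≥3 variants), whose null is the
LD-eigenvalue mixture (1/m)Σλ_k χ²₁, evaluated by Imhof integration with a
saddlepoint tail. Ancestry gene z-scores are meta-analyzed with √N
weights. The polygenic priority score (PoPS) regresses each ancestry's
gene z on marginally selected gene features by leave-one-chromosome-out
ridge regression (penalty by generalized cross-validation), and the
ancestry scores are √N-weighted averaged and ranked into genome-wide
percentiles.

A locus's gene is prioritized when it is simultaneously the **nearest
gene** to the credible set's PIP-weighted center and the **top PoPS**
gene in the locus — or when non-synonymous credible-set variants mapped
to it carry summed PIP > 50%, in which case the non-synonymous call wins
any conflict.

## Worked example

```r
library(popsloci)

cfg <- sim_config(n_variants = 6000, n_genes = 200, n_chromosomes = 6,
                  n_features = 100, n_causal_loci = 10,
                  ancestries = data.frame(label = c("EAS", "EUR"),
                                          n_ref_samples = c(400, 800),
                                          n_eff = c(15886, 127626)),
                  ld_block_size = 30, causal_effect_sd = 0.035, seed = 101)
study <- simulate_gwas(cfg)
run   <- run_pipeline(study)
run
#> <popsloci_run>
#>   4 region(s), 5 independent signal(s), 5 prioritized gene(s)

tidy(run)
#> # A tibble: 5 × 9
#>   locus    chrom gene  basis         distance_kb pops_percentile magma_meta_z
#> 1 rs000217     1 G0008 pops_nearest            0           0.990        15.4
#> 2 rs003681     4 G0124 pops_nearest            0           0.945         9.34
#> 3 rs004201     5 G0141 pops_nearest            0           0.980         7.46
#> 4 rs004430     5 G0149 nonsynonymous           0           0.950         5.36
#> 5 rs005139     6 G0172 pops_nearest            0           0.995         3.31
#> # plus n_genes_in_locus and nonsyn_pip columns

study$truth$causal_genes
#> "G0008" "G0034" "G0098" "G0099" "G0124" "G0141" "G0149" "G0158" "G0163" "G0172"
```

Reading the table: five statistically independent signals cleared
genome-wide significance; in each locus of ~10 candidate genes the
pipeline called one gene, every call is a planted causal gene, and
`rs004430`'s call rests on a non-synonymous credible-set variant carrying
0.985 posterior mass (`nonsyn_pip`). `distance_kb = 0` means the
PIP-weighted credible-set center falls inside the called gene's body.
`plot_locus(run, 1, study$mixed_panel)` draws the association and
gene/PoPS panels for a signal; `glance(run)` gives one-row run totals.

The study-design helpers reproduce the emulated design's bookkeeping —
the mixed LD panel that matches GWAS ancestry proportions and the
combined cohort:

```r
panel_mix(pd_gwas_design())
#>   ancestry  n_eff share panel_n_mixed
#> 1 EAS       15886 0.111           538
#> 2 EUR      127626 0.889          4322
cohort_totals(pd_gwas_design())
#>   cases proxy_cases controls  n_eff
#> 1 44412       18618  1442642 143512
```

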