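---
title: "Methods: from multi-ancestry summary statistics to prioritized genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-ancestry summary statistics to prioritized genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsloci)
```

`popsloci` turns per-ancestry GWAS summary statistics into at most one
prioritized gene per independent association signal. This vignette is the
package's account of the statistics it implements, the choices that were
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The pipeline and its model

### Harmonization and variant QC

Each ancestry's variant table is matched to that ancestry's LD reference
panel by chromosome, position and allele pair. Swapped effect/other
alleles are resolved by negating β and replacing the effect-allele
frequency *f* by 1−*f*; strand complements are resolved the same way.
Strand-ambiguous variants (A/T, C/G) with *f* ∈ [0.4, 0.6] cannot be
oriented reliably and are dropped — the standard conservatism of
fixed-effects meta-analysis tooling. Two sequential frequency filters
follow, both against the panel: an absolute rule (|*f* − *f*ref| > 0.1)
and then a two-sided fold rule (max(*f*/*f*ref, *f*ref/*f*) > 12). The
two counts are reported separately because they are applied in that
order; a variant failing both is counted under the absolute rule. The
fold rule is deliberately two-sided: nothing in the problem is
directional, and a one-sided rule would silently pass inflated rare-allele
frequencies.

### Meta-analysis

Fixed-effects inverse-variance weighting on β/SE. Effect-based (rather
than sample-size-based) weighting is the default because the downstream
stages consume β and SE directly; a variant present in one ancestry is
carried through unchanged with its own N. Under the null the meta z-score
is standard normal, which the test suite verifies by
Kolmogorov–Smirnov on 10,000 simulated null variants.

### Signal isolation

Clumping is the greedy PLINK algorithm: the most significant unassigned
variant below 5×10⁻⁸ seeds a clump and captures every unassigned variant
within 3 Mb at r² ≥ 0.1 (so a variant in LD with two index variants
belongs to the earlier, more significant clump). Clump spans are padded
by 500 kb and merged per chromosome. LD for meta-analysis statistics
comes from the mixed-ancestry panel, whose composition matches the GWAS
effective-sample-size proportions (11% EAS / 89% EUR under the default
design; `panel_mix()` computes the composition from a design table).

Within each region, stepwise conditional selection on z-scores with
reference LD **R** adds the variant with the smallest conditional
p-value while it stays below 5×10⁻⁸ and its r² with every selected
variant stays below 0.9 (the conventional collinearity cutoff). The
conditional and joint formulas are the standard summary-statistics
identities

$$z_{i|C} = \frac{z_i - R_{iC}R_C^{-1}z_C}{\sqrt{1 - R_{iC}R_C^{-1}R_{Ci}}},
\qquad
z^{joint} = \frac{(R_S^{-1}z)_i}{\sqrt{(R_S^{-1})_{ii}}},$$

with joint β and SE recovered on the allele scale through the marginal
SEs (per-variant sample sizes enter only there; this is exact when N is
constant across variants and a standard approximation otherwise). After
selection, hits with joint *P* > 5×10⁻⁸ are removed worst-first with
refitting. A singular selected-set LD matrix drops the later-entering
variant with a warning. Each hit is then isolated by conditioning the
whole region on the *other* hits; the conditioning variants themselves
get conditional z = 0 (p = 1), and with a single hit the conditional
table equals the marginal one.

### Fine-mapping

Wakefield's approximate Bayes factor uses V = SE² and prior effect
variance W: lABF = ½(log(1−r) + r·z²), r = W/(W+V). The prior SD
defaults to 0.2 on the log-odds scale — the conventional case-control
prior — and is configurable; nothing downstream is sensitive to it
within the usual 0.1–0.5 range because PIPs are rank-driven at
genome-wide-significant z. PIPs are the softmax of lABFs over all region
variants, computed in log space so that Σ PIP = 1 holds to 10⁻⁹ even
when the largest lABF exceeds 700 (beyond `exp()` overflow). The 95%
credible set is the minimal PIP-descending prefix reaching 0.95; PIP
ties at the boundary are all included, so coverage may slightly exceed
0.95 but membership is deterministic. The weighted center is the
PIP-weighted mean position over credible-set members with member PIPs
renormalized — the reading under which a two-member set with renormalized
PIPs 0.75/0.25 at 100 kb and 200 kb has center 125 kb. Locus windows are
the credible-set span ±300 kb, floored at position 1 (chromosome lengths
are not modeled); gene overlap is closed-interval in 1-based
coordinates, and BED interchange converts to 0-based half-open in the
I/O layer only.

### Gene-level association

The SNP-wise mean statistic is the mean squared z over a gene's mapped
variants (body overlap only, no flanking window; MAF > 1%; genes with
fewer than three variants are not scored). Its null distribution under
z ~ N(0, R) is the eigenvalue mixture (1/m)Σλₖχ²₁. The tail probability
is computed exactly for equal eigenvalues (scaled chi-square), by Imhof
numerical inversion in the body of the distribution, and by Kuonen's
saddlepoint approximation in the tails, where the oscillatory Imhof
integral loses all relative accuracy; the saddlepoint works on the log
scale down to the 10⁻³⁰⁰ floor. Eigenvalues are floored at 10⁻⁸ and
components below 10⁻⁷ of the largest are dropped as numerically
irrelevant. The gene z is the upper-tail probit of p. Each ancestry is
tested against its own panel and frequencies; gene z-scores are combined
as Σ wᵢzᵢ/√Σwᵢ² with wᵢ = √Nᵢ.

### PoPS scoring

Features are screened marginally against the ancestry's gene z (t-test
on the correlation, α = 0.05); screening uses each ancestry's own gene
z-scores, not the meta z, mirroring how ancestry-specific gene results
feed the similarity model. Selected features enter a ridge regression of
gene z, fit once per chromosome on all *other* chromosomes
(leave-one-chromosome-out), so a chromosome's scores are a function only
of other chromosomes' z-scores — the property that prevents a locus from
scoring itself. Features are centered and scaled with training-fold
statistics only, and the penalty is chosen per fold by generalized
cross-validation over a fixed log-spaced grid (10⁻² to 10⁵); the ridge
solver is an internal SVD implementation returning original-scale
coefficients plus intercept. With zero selected features every held-out
score is the training-fold mean. Ancestry scores are combined per gene
as a √N-weighted *mean*: PoPS values are predictions, not test
statistics, so a convex combination preserves their scale (a z-style
combination is available via `meta_pops(..., method = "zscale")`).
Percentiles are average-tie ranks scaled to [0, 1]. The marginal
screening regressions do not decorrelate gene-gene LD; this is a known
simplification relative to the full similarity-model machinery and is
recorded here as the package's standing deviation flag.

### Prioritization

Per signal: criterion A fires for the unique gene that is both nearest
to the weighted center (distance 0 if the center lies in the gene body,
else distance to the nearer edge; ties break toward higher meta PoPS,
then lexicographic gene id) *and* top meta-PoPS among the locus's
candidates (unscored genes can be nearest but never top-PoPS).
Criterion B fires for a gene whose non-synonymous credible-set variants
sum to PIP > 0.5 — the summed reading; a strictly single-variant reading
is more conservative and can be obtained by thresholding per variant
upstream. When both fire, B wins and the basis is recorded as
`nonsynonymous`, including when both name the same gene. A locus where
the top-PoPS gene is not the nearest gene gets *no* call: precision over
recall is the point of the intersection rule. Overlapping loci from
different signals are called independently per signal. External
per-locus causal probabilities are compared after capping each locus's
total at 100% (divide by the sum only when the sum exceeds 1 —
idempotent by construction).

## The synthetic study

The generator draws its defaults from the study design the package
emulates: two ancestries with effective sample sizes 15,886 (EAS) and
127,626 (EUR), reference panels of 538 and 4,322 individuals (the mixed
panel's composition at GWAS proportions), 50,000 variants on 22
autosomes, 1,000 genes, 500 features, 25 causal genes.

* **LD**: haplotypes follow a copy-chain within blocks of 50 consecutive
  variants — the latent state is kept with probability 0.9 per step —
  giving genotype correlation exactly 0.9^|i−j| within a block and zero
  across blocks. Frequencies are drawn per block (uniform 0.05–0.95)
  with small per-variant jitter, and diverge across ancestries by a
  Balding–Nichols perturbation with F = 0.05, a typical
  continental-scale divergence. The real genome's LD is not
  block-diagonal and its frequency spectrum is not uniform; tests passing
  on this generator show the estimators are correct under their stated
  model, not that the pipeline is robust to reference-panel mismatch.
* **Summary statistics** are drawn directly from the multivariate-normal
  model z ~ N(R·√N·b, R) per block, with R the empirical panel
  correlation, rather than by simulating phenotypes: every downstream
  stage consumes only summary statistics plus LD, so this is exact for
  the null and for small effects, and it keeps the full study under two
  minutes. SE = 1/√(N·2f(1−f)) and β = z·SE put effects on the log-odds
  scale. Proxy-case dilution in the larger cohort is absorbed into N and
  not modeled separately.
* **Causal architecture**: each causal gene hosts exactly one common
  causal variant (base frequency 0.1–0.9) with standardized effect drawn
  from N(0, 0.03²) — at the default meta sample size the expected |z| of
  a causal variant is ~9|N(0,1)|, so roughly half the planted loci clear
  genome-wide significance, as in a real GWAS of this size. A quarter of
  causal variants are flagged non-synonymous; the annotation also
  contains ~1% of null in-gene variants so it is not a causal-variant
  oracle. All causal genes share one set of 10 boosted feature columns
  (shift +2 SD), giving the cross-chromosome signal the LOCO regression
  is designed to learn; real feature matrices are sparser, correlated,
  and heterogeneous across genes.

Every generator output is a deterministic function of the config,
including its seed; sub-streams are derived per operation so panels,
statistics and features can be regenerated independently.

## Numerical choices and degenerate inputs

* p-values from z are computed on the log scale (smallest representable
  two-sided p ≈ 10⁻³⁰⁸); probit transforms floor p at 10⁻³⁰⁰.
* Near-singular LD blocks get a 10⁻⁶ ridge before Cholesky in the
  generator; monomorphic panel variants are excluded from simulated
  statistics with a message, and fall to the fold rule during QC.
* Duplicate variant rows at harmonization are an error naming the first
  duplicate; conflicting alleles across ancestries at meta-analysis are
  an error.
* Empty outcomes are ordinary: no significant variant gives an empty
  region list; a gene-free locus survives to prioritization and yields
  no call; a null study returns a zero-row evidence table.

## Problem sizes used in validation

The test suite runs a shared fixture study of 6,000 variants / 200 genes
/ 6 chromosomes (panels 400 + 800) once per session, plus targeted
fixtures per operation: 500-replicate credible-set coverage at
non-centrality 8, a 10⁶-draw Monte-Carlo oracle for the quadratic-form
tail, 50-replicate two-signal recovery, 20-replicate null-genome
clumping at 50,000 variants, and 10,000-variant null calibrations. The
acceptance script runs the full default study. These sizes were chosen
so each check has the statistical resolution its threshold needs.

## Known limitations

* Single-causal-variant fine-mapping per isolated signal; no multi-causal
  credible sets or colocalization with molecular QTLs.
* The gene test replaces the reference implementation's regression
  formulation with the equivalent quadratic-form statistic; gene-gene
  correlation of scores is not estimated (it is not needed downstream).
* Marginal feature screening ignores gene-gene LD correlation (flagged
  above).
* Chromosome X is out of scope; gene features are autosomal.
* The generator does not model imputation quality, phasing, or realistic
  demography, and clips locus windows at position 1 rather than at
  chromosome ends.
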