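---
title: "Models and methods behind the cernet pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cernet pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

# Scope and model

`cernet` infers candidate competing-endogenous-RNA (sponge) interactions
from a three-group expression design: control (A), an acute *elicitation*
phase (B) and a *remission* phase (C), each contrasted against control.
The working model is the standard ceRNA hypothesis: a lncRNA sharing miRNA
response elements (MREs) with an mRNA titrates the miRNA away, so in a
phase where the miRNA rises, both the lncRNA and the mRNA fall together
(and vice versa). The pipeline therefore looks for triples with

* opposite differential-expression directions between the miRNA and both
  partners, same direction between lncRNA and mRNA;
* a predicted MRE for the *same* miRNA on both the mRNA 3'UTR and the
  lncRNA;
* strong positive co-expression between lncRNA and mRNA.

No quantitative sponge mathematics (flux or occupancy modeling) is
attempted; the output is a screened, auditable candidate network.

# Normalization and detection filtering

Two normalization schemes are provided, mirroring common array practice:

* `quantile_normalize()` forces all samples onto one empirical
  distribution (rank-wise cross-sample means; ties receive the average of
  the tied ranks' means). It is idempotent and makes per-sample sorted
  vectors identical to machine precision. The computation is delegated to
  `limma::normalizeQuantiles(ties = TRUE)`, which implements exactly this
  convention.
* `median_normalize()` rescales each sample so the medians of a
  high-intensity reference set (every gene with intensity ≥ 30 in all
  samples, the usual "expressed" floor for miRNA arrays) agree at their
  grand mean. This keeps values on the original intensity scale and
  preserves within-sample ranks.

`filter_detected()` keeps genes flagged Present/Marginal in at least 3
samples (default chosen for a 12-array, 3 × 4 design).

**A caution on quantile normalization under massive asymmetric response.**
When a large fraction of genes responds in one phase (the elicitation
pattern), forcing all samples onto one distribution compresses the shifted
tails, sample by sample. We measured this on simulated studies: planted
lncRNA–mRNA pairs with true log2-scale correlation ≈ 0.999 drop to
0.91–0.99 after quantile normalization at desk scale (hundreds to a few
thousand genes), below the stringent |PCC| ≥ 0.995 co-expression screen.
This is a property of the method, not a bug: on inputs already generated
on a common intensity scale the normalization stage adds distortion
without removing any artifact, which is why `run_config(normalize =
FALSE)` exists and is used for the planted-truth recovery studies. For
real arrays (which need the correction) users should expect the 0.995
screen to be very conservative at n = 12.

# Differential expression

Fold change is the ratio of *linear-scale* group means (array convention);
down-regulation is reported both as the ratio and as "n-fold down" = 1/FC.
The test is a Welch unequal-variance t on log2 intensities with a variance
floor of 1e-8 per group, so degenerate zero-variance fixtures return
t = 0, p = 1 instead of 0/0. The test choice and the floor are exposed
because array vendors rarely document their test; Welch on log2 is the
least-assuming default. Benjamini–Hochberg q-values are always reported,
but the significance call uses the raw p (the common vendor convention);
both the p and q columns are in every table, so either policy can be
re-applied.

Class defaults: FC > 1.5 and p ≤ 0.05 for miRNAs, FC > 2.0 and p ≤ 0.05
for lncRNAs and mRNAs, strict `>` on FC. The ceRNA assembly stage reads
its own lncRNA threshold object with an *inclusive* FC ≥ 2.0 and a strict
p < 0.05, because the two filters legitimately differ between a
genome-wide DE report and a network-construction criterion; keeping two
threshold objects makes the discrepancy explicit rather than silently
reconciling it.

`hierarchical_cluster()` supports the usual two-way heatmap view:
agglomerative clustering with distance 1 − Pearson r and average linkage
(`stats::hclust`); items with zero variance are an error because their
correlation distance is undefined.

# MRE prediction

`find_seed_sites()` implements the canonical seed taxonomy. The 6mer core
is the reverse complement of miRNA positions 2–7; a match to position 8
(on the 5' side of the target site) upgrades to 7mer-m8, an adenine
opposite position 1 (3' side) to 7mer-A1, both to 8mer. Within one anchor
only the top-ranked type is kept; distinct anchors are all reported.
Coordinates are 0-based half-open on the given transcript; only the plus
strand of single-stranded RNA is considered, and T is accepted as U.

`pair_score()` is a Smith–Waterman local alignment between the full miRNA
(antiparallel) and the target window of 30 nt ending at the site's 3'
edge, scored +5 Watson–Crick, +2 G:U wobble, −3 mismatch, −8 per gap
position (linear). The constants are classical miRanda-style weights and
sit in one place in the configuration. Ties in the dynamic program are
broken deterministically (diagonal, then gap-in-target, then
gap-in-miRNA), so scores and tracebacks are reproducible.

`duplex_energy()` sums a per-base-pair stability proxy over the aligned
pairs (G:C −3, A:U −2, G:U −1 kcal/mol; aligned mismatches 0). This is an
additive stand-in for a nearest-neighbor folding energy, chosen
deliberately: it is exactly testable, dependency-free, and monotone in the
pairing content that matters for the pass/fail rule. It is *not* a
thermodynamic prediction, and no secondary-structure accessibility is
modeled.

A prediction passes when one site satisfies seed match **and** pair score
≥ 80 **and** energy ≤ −14 — an intersection-of-evidence rule emulating the
practice of keeping only sites agreed on by a seed-based and an
alignment-based predictor. lncRNA MRE prediction uses the same scanner
(optionally with its own thresholds): the assembly criterion only needs
"possesses an MRE for this miRNA", and running one auditable scanner for
both substrate classes keeps the evidence uniform.

Defaults S_min = 80 and E_max = −14 were fixed a priori against the
planted-site design: a full-complement site of a 19–24-nt miRNA scores
≥ 5·(L−1) ≥ 90 with energy ≤ −36, while a bare seed match in random flanks
scores ≈ 40–60, so the thresholds separate the two populations with a wide
margin in either direction.

# Co-expression and network assembly

`cnc_network()` computes Pearson correlation on log2 intensities (for
consistency with the DE stage) for every (lncRNA, mRNA) pair over the
shared samples, converts r to a two-sided p with the t transformation
t = r√(n−2)/√(1−r²) on n−2 df, and BH-adjusts over the *full family of
tested pairs* (the least-assuming family definition). Edges are retained
at |r| ≥ 0.995 and FDR < 0.05; the sign is kept on the edge because the
assembly stage requires positive lncRNA–mRNA co-expression specifically.
Constant genes are skipped with a warning rather than an error, so one
degenerate probe cannot abort a screen.

`assemble_cerna_triplets()` joins the evidence (five criteria listed in
the README) and de-duplicates by triple identity. The direction-
consistency rule is enforced by default but exposed as
`require_direction`, since it is an interpretation of the sponge model
rather than a property of any single measurement. "Correlated with the
miRNA's targets" is read in its strictest form — a retained positive edge
between the lncRNA and *that specific* target mRNA — so every emitted
triplet is fully auditable; `verify_triplets()` re-checks each criterion
independently from the raw tables. No miRNA–lncRNA expression
anti-correlation is required beyond MRE possession: the latent coupling
makes it hold in simulation, but it is not part of the emission rule.

# Enrichment and qPCR utilities

`hypergeometric_enrichment()` uses the upper-tail hypergeometric
probability P(X ≥ k) with BH adjustment across terms and the enrichment
score −log10 p; the universe defaults to whatever gene list the caller
passes (in the pipeline: all genes surviving detection filtering). Output
is ordered by p then term id for determinism. `ddct_fold_change()`
implements 2^−ΔΔCt with replicate Ct values averaged per condition before
differencing.

# The synthetic-data generator

`simulate_expression()` draws per-gene baselines from N(8, 1.5²) on the
log2 scale, adds planted effects and couplings, adds N(0, noise_sd²)
residual noise, and exponentiates — so planted fold changes are exact on
the linear scale at zero noise. Defaults emulate a small three-group array
study: 4 replicates per group (a 12-array design), log-normal intensities,
residual log2 SD 0.25 (typical array repeatability), detection floor 30.

Planted sponge triplets contribute two things:

* opposite DE shifts (miRNA vs lncRNA/mRNA) of magnitude `log2fc` in the
  triplet's phase, and
* one shared latent N(0,1) factor per triplet with loadings (−k, +k, +k)
  on (miRNA, lncRNA, mRNA). The factor applies to **all** samples, not
  only the triplet's phase: co-expression is screened across all 12
  arrays, so the within-group coupling has to exist everywhere for the
  planted pairs to be recoverable; within the response phase this
  reproduces the negative miRNA-vs-partners, positive lncRNA–mRNA sign
  pattern the sponge model predicts.

The loading k trades off two detectabilities: it adds co-expression signal
but inflates within-group variance for the t-test. With shift d and noise
σ, the planted lncRNA–mRNA correlation is approximately
(2d²/9 + k²)/(2d²/9 + k² + σ²) and the DE effect size is d/√(k² + σ²).
The recovery-study conditions (d = 4, k = 1, σ = 0.05) put the planted
correlation ≈ 0.9995 and the Welch t ≈ 8, so both screens pass with wide
margins; the generator default k = 0.5 with σ = 0.25 gives a correlation
≈ 0.97 — recoverable at a relaxed |PCC| ≥ 0.9, deliberately *not* at
0.995, so threshold-sensitivity tests have something to detect.

`simulate_sequences()` draws uniform RNA sequences (miRNAs 19–24 nt
starting with U, the most common 5' base) and writes, for each planted
triplet, a binding site into both the lncRNA and the mRNA 3'UTR. By
default the written block is the reverse complement of miRNA positions
2..L plus a 3' A facing position 1 ("full" extent), so the site passes the
default score thresholds; `extent = "8mer"` writes only the canonical 8-nt
seed site. `site_truth` always records the 0-based half-open span of the
8mer. One integer seed drives the whole stream, and a fixed offset
(104729) separates the sequence stream from the expression stream so the
two can be regenerated independently.

What the generator does *not* emulate: probe-level artifacts, dye bias,
batch effects, heteroscedastic intensity-dependent noise, correlated
background between RNA classes, and realistic (structured, conserved)
sequence composition. Passing tests therefore demonstrate correctness of
the algorithms under the stated generative model, not performance on real
arrays.

# Problem sizes and numerical choices

The shipped verification studies use: 50 random matrices for the quantile
invariant; 1000 random p-vectors (length ≤ 10) against the step-up
formula; 500 random (miRNA, target) pairs against the brute-force scan
oracle plus 20 planted sites; 100 random ≤ 20-nt pairs against an
exhaustive alignment oracle; 20 replicates of the 1000-gene DE study; 20
seeds of the 200 × 500 null co-expression study; 10 planted triplets among
100/30/300 genes for recovery; and two identically-seeded end-to-end runs
for determinism. These sizes give the binomial/oracle comparisons
resolving power while keeping a full check runnable in about a minute.

Numerical details worth knowing: correlations are clipped to [−1, 1]
before the t transform (|r| = 1 maps to p = 0); the BH family for CNC is
all tested pairs; expression TSVs are written with 17 significant digits
so write/read round-trips are exact; GraphML export goes through igraph
and is read back verbatim in the round-trip tests.

# Known limitations

* The energy proxy ignores stacking, loops and accessibility; scores are
  comparable within this pipeline only.
* The |PCC| ≥ 0.995 default is extremely stringent at n = 12 (see the
  normalization caution above); real studies may want to inspect the edge
  list at a relaxed cutoff before applying the default screen.
* Welch-on-log2 is an assumption standing in for undocumented vendor
  tests; moderated-variance (empirical Bayes) testing and paired designs
  are out of scope.
* Enrichment requires the user to supply gene sets (GMT); no ontology
  graph propagation or live database access is performed.
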