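---
title: "Models and methods behind bequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bequant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bequant` quantifies and predicts the outcomes of CRISPR base editing —
adenine base editors (ABE, A-to-G) and cytosine base editors (CBE, C-to-T) —
at genomic target sites, with particular attention to the endogenous
chromatin and transcriptional context of each site. This vignette explains
the models the package implements, the choices that were genuinely open and
how they were resolved, and what the synthetic-data tests do and do not
demonstrate about real sequencing data.

## Coordinates and inputs

A target site is a 20-nt protospacer (positions 1–20, 5'→3') with an NGG PAM
at positions 21–23, carried inside a 40-nt context (10 bp upstream +
protospacer + PAM + 7 bp downstream). All user-facing positions are 1-based
protospacer coordinates; the single place where the convention is defined is
the `be_sites()` constructor, and every other function maps through it. The
editing window — where deamination concentrates — defaults to positions 5–7
for ABE and 4–8 for CBE.

Quantification starts from allele-frequency tables in the CRISPResso2 column
dialect (`Aligned_Sequence`, `Reference_Sequence`, `#Reads`, …). The reference
may be the 40-nt context or a longer amplicon; the protospacer is located in
it by exact match and everything downstream works in protospacer coordinates.
Insertions are re-expressed as `(position, sequence)` annotations instead of
widening the alignment, so position numbering never shifts.

## Per-site statistics

For one site with `N` aligned reads:

* **overall efficiency** = reads carrying the intended transition (A→G or
  C→T) at any window position / `N`;
* **per-position efficiency** = reads with the intended transition at that
  position / `N`, defined only where the reference base is the target base.
  The denominator is deliberately total reads, not reads covering the
  position; an allele whose deletion spans a position counts as unedited
  there;
* **modified efficiency** = reads with any substitution or indel / `N`;
* **purity**: for each of the 12 possible base transitions, the number of
  reads containing it is counted in three scopes (whole protospacer, inside
  the window, outside the window) and normalized so the 12 proportions sum
  to 1 within each scope;
* **indels**: events are keyed by (start position, signed length); reads are
  attributed to a deaminase region (positions 1–11) or an nCas9 region
  (14–20) by the positions the event occupies. Positions 12–13 belong to
  neither region, keeping the two attributions disjoint. The cross-site positional
  profile keeps, per indel length, the sites between the 25th and 75th
  percentile of that length's frequency (linear-interpolation quantiles,
  boundaries inclusive) and divides each event's frequency by its absolute
  length — both recorded as config switches because no single convention
  is canonical for them.

Replicates under 100 aligned reads are discarded; survivors are averaged
field-wise. The editing:indel ratio is summarized across sites by the
geometric mean of per-site ratios (natural log internally), after removing
sites with zero indel reads in the region — a log-scale summary suited to
ratios spread over orders of magnitude.

## Outcome distributions

Outcome analysis is stricter than efficiency analysis. Replicates must have
a modified-read fraction (Ne/Nt) of at least 0.9, and a replicate whose mean
pairwise Kullback–Leibler divergence to the other replicates (allele
distributions smoothed with a 0.5 pseudocount) exceeds the Tukey fence
Q3 + 1.5 · IQR is discarded as discordant. The KL outlier rule is a
package decision: "extreme outlier" needed an operational definition, and
the Tukey fence is standard and parameter-free. Surviving replicates are
pooled; the wild-type allele is removed; proportions are renormalized;
alleles at or below 5% are removed; and the remainder is renormalized again.
This collapse is idempotent — run on its own output it returns the same
distribution — which the tests check.

Alleles are keyed by their **edit pattern**: a 20-character string marking
which target bases carry the intended transition. Other substitutions and
indels do not enter the pattern but are kept in a side field so such alleles
stay distinct. Paired-dataset comparisons (endogenous vs integrated copies
of the same protospacer) classify each site as Consistent / Endo-bias /
Inte-bias / Discordant by set containment of the allele sets, and
efficiency bias groups come from an OLS fit of endogenous on integrated
efficiency with a μ ± σ residual band (population σ; a zero-width band
assigns everything to Consistent, since it cannot exclude).

## Endogenous factors

Peak tracks (Pol II, CTCF, DHS, histone marks) flag a site when any peak
overlaps the protospacer interval by at least 1 bp under half-open BED
semantics. H3K27ac, a long-range mark, is queried with the interval widened
by 65 bp (150 bp total) or 500 bp (1020 bp total) per side, configurable.
Expression is log2(TPM+1); the high/low call uses a strict 1.5 threshold
*on that scale, before min-max normalization* — a min-max value can never
exceed 1, so a threshold of 1.5 is only satisfiable pre-scaling;
the threshold is a config knob. Methylation is the mean beta over covered
bases, methylated when strictly above 0.75; per-base calls consider targeted
Cs (CBE) and As inside ACG/CGA motifs (ABE) within the window. Continuous
factors are min-max normalized after a log2(x+1) transform, except beta
values, which are already in [0, 1].

When no explicit CRE track is supplied, the CRE flag is the union of the
DHS, H3K4me3, H3K27ac and CTCF flags. This is a stand-in for a proper
ENCODE-style cCRE categorization and is labeled as such in the annotation's
metadata.

Factor-vs-efficiency association uses a linear model of efficiency on the
continuous factor value, adjusting for the number of target bases in the
window (a sequence-composition confounder). The promoted-motif analysis
fixes the promoted (TAT, TAC, CAT, GAC, GAT) and inhibited (CAG, AAG, CAA,
AAA) trinucleotide lists and tests 2×2 group tables with a chi-squared test
*without* continuity correction (the plain statistic; recorded so results
are reproducible to the digit).

## Motif model

For every window target base, the 7-nt context (3 bp up, target, 3 bp down)
and its per-position efficiency form one example; examples are split 70/30
by a seeded shuffle. Efficiencies are fractions in [0, 1], not binary
outcomes, so "logistic regression" is fit as a fractional (quasi-binomial)
logit by IRLS, with responses at exactly 0 or 1 nudged by 1e-6 to keep the
logit finite. One-hot indicators encode the six flanking positions (the
constant center base is excluded, and one base level per flank is dropped to
avoid collinearity). Performance is the Pearson R between predicted and
observed held-out efficiencies; variance explained is R². Whether position
should be a covariate when pooling window positions was left open; the
package fits it as a factor covariate whenever more than one position is
present, and per-position fits are obtained by subsetting examples.

## Convolutional efficiency model

The per-position efficiency predictor maps a 40 × (4 + k) input — one-hot
sequence plus k endogenous-factor channels — to a 20-vector of efficiencies.
The architecture is inception-style: parallel 1-D convolution branches with
kernel widths 1–5 ('same' padding, ReLU), channel concatenation, one max
pool of width 2 (40 → 20), and a dense sigmoid head. The width-1 branch
joins widths 2–5 in a five-branch concatenation; branch
widths and filter counts are config-exposed rather than hard-wired, since
no particular layer sizing is canonical. Factor channels are broadcast as
constants along the 40-bp axis (annotations are per-site), except per-base
methylation, which is laid along its covered positions. The default ABE
channel set is {H3K27ac}; the default CBE set is all factors.

The loss is mean-squared error masked to target-base positions, so labels at
positions whose reference base is not the target base can never influence
gradients (verified by an exact gradient-equality test and a
finite-difference check). The optimizer is Adam (step 0.003, minibatch 128,
at most 60 epochs, early stopping on validation loss with patience 10);
these are package defaults, not claims of fidelity to any reference
implementation. Training follows a 6-shuffle protocol: each shuffle splits
sites 80/20 stratified by the presence of any endogenous-factor flag, holds
out 20% of the training split for early stopping, and reports test Pearson
R pooled and per position. The whole network is written in vectorized base R
over BLAS matrix products; at the problem sizes the package targets
(thousands of sites) training completes in minutes on one CPU, and identical
seeds reproduce metrics bit-for-bit.

## Chain proportion model

Editing at each editable position is Bernoulli with marginal `m_i` (from the
efficiency model or from observation). Dependence between positions is
reduced to adjacent pairs: the joint distribution is the chain factorization

P(X₁, …, Xₙ) = P(X₁) ∏ᵢ P(Xᵢ | Xᵢ₋₁),

with each conditional derived from the 2×2 joint of the adjacent pair. That
joint is reconstructed from the two marginals and the odds ratio
c = p₁₁p₀₀ / (p₀₁p₁₀) by solving the Plackett quadratic; with
S = 1 + (p+q)(c−1), p₁₁ is the *smaller* root
[S − √(S² − 4c(c−1)pq)] / [2(c−1)] — the only root inside the Fréchet
bounds for c ≠ 1 (the tests verify this over random draws), with c = 1
giving independence exactly. Marginals are clamped to [1e-6, 1 − 1e-6]
before conditioning so observed efficiencies of exactly 0 or 1 stay finite.
Outcome enumeration is capped at 12 editable positions (4096 outcomes);
editing windows contain far fewer target bases in practice.

The adjacent odds ratio is estimated from observed outcome distributions
that retain the wild-type allele. Because marginals differ across sites, the
odds ratio is **not collapsible**: summing 2×2 counts across heterogeneous
sites attenuates c badly (on the closure simulation below, true c = 4
pools to ĉ ≈ 1.3). The package therefore stratifies by site — each site's
adjacent pair contributes a 2×2 table (proportions × pooled reads + 0.5
pseudocount) and a log odds ratio, combined across sites by inverse-variance
(Woolf) weighting — and restricts editable positions to the editing window,
the chain model's domain. Alleles carrying side edits are excluded from
this estimation: a target base that is deleted or hit by an unintended
substitution cannot be called edited or unedited. Crude pooling remains
available (`method = "pooled"`), as does a per-position-pair c
(`pooling = "pairwise"`) instead of one global c.

A mutual-information audit quantifies the chain simplification: pairwise MI
(bits) for all position pairs, and conditional MI of the outer pair of each
consecutive triple given the middle position — exactly zero under a
first-order chain, so its magnitude on data measures what the chain misses.

The Max-form — the most frequent edited outcome — is selected with a
deterministic tie-break (fewest edited bases, then leftmost edited position,
then pattern order), a package convention chosen so that repeated runs and
platforms agree.

## Synthetic data: what it emulates, and what it does not

The generator is a first-class module: every study condition is a fixed
default, and generation is a pure function of (parameters, seed).

* Sites are random 40-nt contexts with an NGG PAM and at least one window
  target base, anchored 1 kb apart on a synthetic chromosome so interval
  tracks can be emitted and re-annotated.
* True marginals follow a logit model: intercept −1.2 (≈ 23% at a neutral
  context), 5'/3' neighbor effects mirroring the promoted/inhibited motif
  lists, a Gaussian position bump (amplitude 0.8 logits) at the window
  center, and factor effects (H3K27ac +1.0, expression +0.6, methylation
  −0.8 on the logit scale). These give window efficiencies spread over
  roughly 0.1–0.8, the range a moderate-efficiency editor shows across
  endogenous sites.
* Adjacent co-editing uses a true odds ratio of 4 — strong positive
  bystander correlation, the regime the chain model exists for.
* Reads sample the chain distribution exactly (multinomial over patterns at
  fixed depth, default 10⁴ per replicate, 2 replicates), then superimpose,
  at most one per read, a bystander substitution (1%), a 1-bp insertion
  before position 18 (1%, the nCas9 hotspot), or a 1-bp deletion at a
  window position (0.2% per position). Bystanders never emit the intended
  transition, so the generating marginals stay exact.
* Factor states are drawn per site (peak rates 0.2–0.4, log-normal TPM,
  bimodal beta) and emitted both as annotations and as raw BED /
  expression / per-base files, so the annotation module can be tested
  end-to-end against known flags.

The generator deliberately omits sequencing error, PCR chimeras,
amplification bias and multi-bp indel structure. Passing the closure tests
therefore shows that the estimators and models are correct *under their own
assumptions* — formula exactness, consistency, calibration — not that the
trained models transfer to any particular cell line or editor. Real-data
performance depends on upstream alignment quality and on how representative
the training sites are.

## Problem sizes and numerical checks

The test suite and the acceptance script use: 2000 sites × 10⁴ reads × 2
replicates for the closure experiment (marginal RMSE < 0.05, ĉ within 3
standard errors of 4, pooled efficiency-model R ≥ 0.8 against ground
truth); 10⁶ reads for the single-site sampling consistency check (total
variation < 0.01 between sampled-then-collapsed outcomes and the enumerated
chain distribution); 1000 random (p, q, c) draws for the inversion
(margins to 1e-9, odds ratio to 1e-6 relative); and 20 replicates of
n = 2000 for factor-coefficient recovery (bias < 10%). These sizes were
chosen as the smallest at which Monte-Carlo error is comfortably below each
tolerance.

## Known limitations

* The chain model ignores any dependence not mediated by adjacent
  positions; the MI audit quantifies, but does not correct, the residual.
* A single global c is the default; per-pair estimates are available but
  noisier and are not smoothed.
* The CRE flag is a union heuristic, not an ENCODE cCRE re-implementation.
* The efficiency model's capacity is intentionally small; it targets
  thousands of training sites, not millions.
* Indel modeling is limited to (position, signed length) events; no
  microhomology or multi-bp taxonomy.
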