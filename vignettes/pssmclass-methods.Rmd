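---
title: "Methods: segmented PSSM descriptors for structural class prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented PSSM descriptors for structural class prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmclass)
```

## The model

A protein domain is represented only by its PSI-BLAST profile: an
L × 20 log-odds matrix **P** whose (i, j) entry scores substitution of
residue i by amino acid type j (columns in the PSI-BLAST header order
A R N D C Q E G H I L K M F P S T W Y V). The classification target is
the four-class SCOP structural level: all-α, all-β, α/β (helices with
mostly parallel strands), α+β (helices with mostly antiparallel
strands). The premise is that substitution preferences and their local
ordering along the chain differ systematically between these classes,
so a fixed-length summary of the profile can separate them even when
sequence similarity in the dataset is low.

Every entry is first mapped through the logistic sigmoid
f(x) = 1/(1 + e^−x). The sigmoid yields the *open* interval (0, 1) for
finite scores; no clamping is applied, and the package asserts strict
inequality rather than inventing a closed-interval behaviour the
transformation cannot produce.

Three descriptor families are then fused into one 700-dimensional
vector per protein:

**Consensus-sequence composition (40 global features).** The consensus
sequence takes, at each position, the amino acid with the maximal
profile score; ties go to the lowest column index, deterministically.
Because the sigmoid is strictly increasing, the consensus is identical
on raw and normalised matrices (the package computes it on whichever it
is given and tests the equivalence). CSAAC is the 20-vector of residue
frequencies n(j)/L. CSCM weights each occurrence by its 1-based chain
position: entry i is the sum of positions of amino acid i divided by
L(L − 1). Positions are 1-based — with 0-based indexing the first
residue would be invisible to the moment — and the 20 moments always
sum to (L + 1)/(2(L − 1)), an identity used as a test oracle.

**Segmented PsePSSM (200 + 180 local features).** The profile rows are
cut into n contiguous segments of unit length L1 = round(L/n), the last
segment absorbing the remainder. `round` here is round-half-away-from-
zero (L = 5, n = 2 gives L1 = 3); the convention is pinned and tested
because banker's rounding would silently reshape segments between
implementations. Within each segment, for each amino acid type, the
λ = 0 feature is the column mean and the λ ≥ 1 features are mean
squared differences of entries λ apart. Sums never straddle a segment
boundary, each segment's denominator is its own term count, and the
per-segment means make the descriptor a *local* sequence-order summary,
unlike the classic whole-sequence PsePSSM with its single 1/(L − λ)
normaliser (that discrepancy with the unsegmented precursor is
deliberate and documented, not reconciled). n = 2 uses λ = 0..4 (200
features) and n = 3 uses λ = 0..2 (180). Larger n would leave λ ≤ 1 for
the shortest supported proteins and carry no order information, so only
n = 2, 3 are offered. The minimum profile length is 10 — the shortest
segment is then 3 rows for n = 3 and 5 for n = 2, strictly longer than
the largest lag in use.

**Segmented autocovariance (160 + 120 local features).** Within the
same segments, the lag-lg autocovariance of each column is the mean
product of mean-centred entries lg apart, with the centring mean being
the segment's own λ = 0 column mean (never the whole-sequence mean).
Constant columns therefore give exact zeros; adding a constant to a
column of a segment leaves its autocovariances unchanged, and scaling
by c multiplies them by c² — both properties are asserted as tests.
n = 2 uses lg = 1..4 (160) and n = 3 uses lg = 1..2 (120).

Feature ordering inside each block is segment-major, then amino acid in
column order, then lag ascending — the choice is arbitrary for PCA but
is fixed so that feature files are reproducible and ablations can be
named (`seg2_psep.s1.A.lam0`, `seg3_act.s2.V.lg1`, ...).

## Dimensionality reduction and classification

The 700 features are reduced by covariance PCA. Features are *not*
standardised by default: all blocks derive from the same (0, 1)
sigmoid scale, and covariance PCA keeps the blocks' natural variance
weighting; a `scale` toggle exists for correlation-PCA sensitivity
analysis, since whether the original protocol standardised is
unknowable from its description. k defaults to 224 retained components
— a value fixed upstream on one benchmark without a stated criterion,
so it is exposed as an ordinary parameter rather than hidden. Loadings
are sign-fixed (largest-magnitude entry positive) so serialized models
are deterministic; eigenvalue order ties are irrelevant at double
precision for the data sizes used.

Classification is one-vs-all: four binary RBF-SVMs (libsvm via e1071,
`scale = FALSE` so the model sees exactly the PCA scores), and the
predicted class maximises the binary real-valued decision score, ties
broken by class order (all-α, all-β, α/β, α+β). The combination rule is
not specified by the name "one against all", so argmax over decision
values — the standard choice — is pinned and tested via a
duplication-invariance property. Defaults C = 2 and γ = 2⁻⁹ are the
grid-search optimum reported for the 224D pipeline on the 1189
benchmark; γ = 0.0019531 equals 2⁻⁹ at printed precision, which
confirms the integer-power-of-2 grid reading (21 × 21 points over
C ∈ [2⁻⁵, 2¹⁵], γ ∈ [2⁻¹⁵, 2⁵]). Grid-search ties go to smaller C then
smaller γ, folds are stratified by class (unstratified folds can lose a
class entirely at these dataset sizes), and the fold shuffle seed is a
recorded configuration field (default 42).

Jackknife evaluation leaves each protein out in turn. One global
(C, γ) pair is reused across folds rather than re-tuned per fold — the
reported protocol tuned once and reused the pair "to avoid
overfitting", and per-fold re-tuning remains available through
`grid_search()` on each training split. PCA scope during the jackknife
is `"global"` by default (fit once on all proteins, matching the
apparent original protocol of selecting the reduced space once per
benchmark); `"fold-safe"` refits the PCA inside every fold so the
held-out protein cannot influence the subspace. The default reproduces
the pipeline being emulated; the option quantifies the leakage, which
for these strongly-separated synthetic datasets is not measurable in
accuracy.

Metrics follow the closed forms: Sens, Spec, Precision, F, MCC, and
AUC = (Sens + Spec)/2 — balanced accuracy, *not* a ROC integral; the
package deliberately reports the closed form everywhere the name AUC
appears. Any measure with a zero denominator is reported as 0 and
flagged in the report, a deterministic convention for degenerate
confusions.

## What the synthetic generator emulates — and what it does not

`generate_profile()` draws L uniformly from [50, 180] (typical domain
lengths; the hard minimum is 10), simulates each of the 20 columns as a
stationary AR(1) Gaussian series with lag-1 correlation ρ = 0.5 and
stationary standard deviation 2 log-odds units around a class-specific
column offset, then rounds to integers and clips to [−12, 12] to mimic
PSI-BLAST ASCII output. The default planted signal shifts five columns
per class by +2 log-odds on disjoint column sets — a strong effect,
chosen to emulate clearly distinct substitution preferences. The AR(1)
structure is there so that the lag-indexed PsePSSM and autocovariance
features carry genuine signal and the segment logic is exercised, not
just the column means; a Monte-Carlo test confirms the lag-1
autocorrelation survives integer rounding (ρ = 0.8 in, pooled estimate
within [0.6, 0.95] out over 200 profiles).

The generator does **not** emulate real homology searches: real
profiles have position-dependent score distributions tied to conserved
motifs, inter-column correlations from the substitution matrix, and
alignment-depth effects, none of which are modelled. Passing the
recovery tests therefore shows the pipeline is correct and can extract
planted class structure of realistic magnitude — it does not certify
the accuracy levels reachable on real benchmarks, which depend on
profiles this package consumes but does not create.

## Numerical and testing choices

* Every feature family is verified against an independent naive-loop
  implementation (global indices, explicit double loops) to 1e−12 on
  random profiles; PCA is verified against `eigen()` of the sample
  covariance up to per-axis sign.
* Parameter-recovery conditions: 30 proteins per class (N = 120),
  strong bias → jackknife OA ≥ 0.90 expected; zero bias → OA within 3
  standard errors of chance (0.25). These sizes keep the full test
  suite under a minute while leaving the chance band tight enough to
  detect leakage bugs (a global-PCA implementation error that leaked
  labels would show up as above-chance null accuracy).
* The worked ablation dimensionalities are 20, 40, 240, 420, 580 and
  700. The 580 deserves a note: 40 CSP + 380 segmented PsePSSM + 160
  two-segment autocovariance features sum to 580, consistent with the
  full 700 minus the 120 three-segment autocovariance block, and the
  package reports block sums as computed.
* Parser errors name the offending line; profiles shorter than 10 rows
  are rejected at parse time with the reason. The in-memory constructor
  accepts any L ≥ 1 so that the consensus and composition operations —
  well defined down to L = 2 — remain usable programmatically.

## Limitations

* No PSI-BLAST invocation: the package consumes ASCII profiles, it does
  not produce them, and checkpoint (`.asn`) profiles are not parsed.
* The classifier is fixed to the one-vs-all RBF-SVM; no probability
  calibration, no alternative kernels.
* ROC-curve AUC is intentionally absent (see above).
* Cross-covariance between different amino acid columns is out of
  scope; only per-column autocovariance is computed.
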