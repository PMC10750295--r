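---
title: "Methods: subtype-stratified drug screening, signature scoring and synergy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-stratified drug screening, signature scoring and synergy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`subtyperx` re-implements, as a tested pipeline, the statistics used to hunt
for breast-cancer subtype-specific drugs in cell-line panels and to connect
candidate hits to gene-expression programs, patient survival and drug
combinations. The package reproduces statistics, not biology: it takes IC50
z-scores, expression matrices and dose–viability grids as given and makes no
claim about molecular mechanism.

## The specificity screen

The input is a line × drug matrix of z-scores of ln IC50, standardized per
drug across the panel it came from, joined to per-line subtype labels
(typically Luminal, HER2, Basal). For each drug:

1. Missing responses are dropped; every subtype must retain at least `min_n`
   lines (default 3) or the drug is labelled `insufficient_data` — never
   silently removed.
2. Classical one-way fixed-effects ANOVA (F with k−1, N−k df) gates at raw
   p < α (default 0.05). We deliberately gate on the *raw* ANOVA p without
   multiplicity correction across drugs, matching how such screens are
   usually run as hypothesis generators; Benjamini–Hochberg across drugs is
   available behind `adjust_anova = TRUE`.
3. Drugs passing the gate get Tukey HSD post-hoc p-values from the
   studentized-range distribution with pooled within-group variance, in the
   Tukey–Kramer form for unbalanced groups.
4. A drug is called *S-specific* iff subtype S has the strictly lowest mean
   and every pairwise comparison of S against another subtype is significant
   at α. The rule is exchangeable across subtypes, at most one label can
   fire, and an exact tie at the minimum mean yields `none` (nobody is
   strictly lowest).

Classical ANOVA + Tukey was chosen over a Welch-type analysis because that is
the named procedure of the workflow being reproduced; the assumption bought is
homoscedasticity across subtypes, which holds by construction in the synthetic
world (common `noise_sd`) and approximately on z-scored panels.

## Signature scores

Per-gene z-standardization uses the sample standard deviation (n−1). The
denominator is a genuine free choice — population vs sample sd differ by a
constant factor per gene and *both* leave the sum-of-z score's ordering
unchanged — so we fixed n−1, the R default, and exposed nothing else.
Zero-variance genes map to all-zero z rather than NaN, with a log entry.

Two score families:

* **z-sum** (YAP/TAZ target score, focal-adhesion score): per-sample sum of
  per-gene z-scores over the set genes present in the matrix. Invariant under
  any per-gene positive affine transform of the input, hence insensitive to
  per-gene scale/offset normalization differences.
* **raw-sum** (CLDN score over CLDN3/CLDN4/CLDN7/CDH1; YAP1+WWTR1): per-sample
  sum of raw values. Additive over disjoint sets, sensitive to units —
  intended for within-cohort comparisons only.

Scores are computed on the matrix as supplied; a `log2(x+1)` pre-transform is
available (`log_transform = TRUE`) but off by default, since the reference
workflow sums z-scores of expression values without a stated prior transform.
Gene identifiers are matched case-insensitively after trimming; set membership
is configuration (GMT files), not constants — the shipped 22-gene YAP/TAZ list
is a labelled synthetic stand-in, since the true list is not printed anywhere
we can cite as data.

The expressed-gene filter (`filter_expressed`) defaults to "nonzero in ≥ 50%
of samples", the simplest rule that reproduces a ~420 → 408 candidate
narrowing when 12 candidates are silent; "present in matrix" is the other
policy.

## Association and survival

Correlation is Pearson r with the two-sided t-transform p and an OLS line of
y on x; pairwise-complete deletion, no imputation; zero variance on either
axis is an error, not a 0. Mutation-stratified regression fits an independent
OLS line per stratum (≥ 3 pairs each) and operationalizes "less sensitive
regardless of expression level" as the vertical offset between the stratum
lines evaluated at the pooled mean of x — a definition choice, since a drawn
pair of regression lines defines no test; we report the offset rather than
inventing a p-value for it.

Survival dichotomization defaults to a median split (high = strictly above,
ties at the cutpoint go low and are counted); a quantile override exists.
**The cutpoint is the single largest reproducibility gap** in this kind of
analysis — external plotting tools often scan for an optimal cutoff — so the
rule and cutpoint are echoed in every result. The log-rank test is the
standard two-group 1-df chi-square over pooled event times
((O−E)²/V with hypergeometric variance), with product-limit Kaplan–Meier
curves per group. The test suite cross-checks it against
`survival::survdiff` and a frozen hand-worked 6-subject table.

## Chou–Talalay synergy

Viability as percent of untreated control converts to fraction affected
`fa = 1 − pct/100`, clamped into [0.01, 0.99] before the log-odds
linearization (log-odds is undefined at the boundary; clamps are logged).
Replicates at a dose are averaged on the fa scale. The median-effect model
`fa/fu = (D/Dm)^m` is fit by least squares on
`log(fa/(1−fa)) = m·log D − m·log Dm`; `m ≤ 0` flags the fit rather than
erroring, so a flat curve is visible downstream. The combination index uses
the classic mutually-exclusive two-term form
`CI = D1/Dx1(fa) + D2/Dx2(fa)`; the non-exclusive cross-term variant is
behind `exclusive = FALSE`. Calls use an additive band of δ = 0.1 around
CI = 1 — conventional, since no threshold is canonical. Dose-scale
equivariance (rescaling one agent's units rescales its Dm and cancels in CI)
is enforced to 1e−9 in tests.

# The synthetic world

Generators are pure functions of (config, seed): randomness is routed through
an explicit seed without touching the caller's RNG, and each generator emits
a truth table sufficient to score recovery.

* **Drug response**: unplanted cells Normal(0, noise_sd) on the z scale;
  a planted (drug, subtype) effect shifts that block's mean. Defaults emulate
  the screened panel: 58 lines split 25/22/11 across Luminal/Basal/HER2, and
  unit noise (the null world of a per-drug standardized matrix). The planted
  screen used in acceptance (shift −1.0 z, noise sd 0.5, 20 lines/subtype,
  100 drugs with 10 plants) is the stated benchmark world, not a tuned one.
* **Expression**: per-gene log-mean Normal(4, 1) — median expression
  ≈ 55 with a spread typical of normalized count data — plus per-sample
  Normal(0, 0.5) residual on the log scale, exponentiated; planted set
  activity adds a constant on the log scale to set genes in a subtype. This
  mirrors count-like positivity but deliberately does not model sequencing
  depth, gene–gene correlation, or mean–variance coupling.
* **Dose response**: single agents follow the median-effect curve exactly;
  combination cells are built as sham (drug with itself; fa at the summed
  dose), Loewe-additive (solving `d1/Dx1(fa) + d2/Dx2(fa) = 1` for fa by
  bisection) or synergistic (each dose multiplied by factor f before the
  additive construction, so true CI = 1/f). Optional Gaussian fa noise is
  clamped interior and logged.
* **Survival**: exponential event times, group-2 hazard = HR × group-1 hazard
  (baseline 0.05/month ⇒ median ≈ 14 months); censoring times are independent
  Uniform(0, b) with b solved numerically so the expected censored fraction
  equals `censor_rate`.

A green test on this world establishes that the *statistics* are implemented
correctly and have the advertised operating characteristics (type-I error,
family-wise error, power at planted effect sizes, parameter recovery). It
does **not** establish that real panels satisfy the model: real IC50
z-scores have heavy tails and shared-assay structure, real expression has
correlated programs and batch effects, and real survival violates
proportional hazards. Conclusions about any specific compound require the
real data.

# Numerical choices and degenerate inputs

* ANOVA with all within-group variances zero → explicit "degenerate ANOVA"
  error; a single group or undersized groups → precondition errors.
* Duplicate gene rows on read: default error; `sum`/`mean`/`first` collapse
  rules are opt-in and recorded in provenance. Missing tokens "", "NA",
  "NaN", "null" on read; "NA" on write; round trips preserve finite values
  to full precision and missingness exactly, in input order.
* Blot arithmetic: negative activated signal (phospho > total) clamps to 0
  globally — generalizing a one-lane convention into the rule — and a
  reference whose activated value is 0 after clamping is an explicit
  "unscalable reference" error. Caliper axes are canonicalized so width is
  the smaller measurement before ½·L·W².
* Identity tolerances asserted in tests: 1e−9 for z-row normalization,
  affine invariance and CI decomposition/equivariance; 1e−3 for the frozen
  two-gene hand fixture; oracle agreement ±0.02 (permutation ANOVA),
  ≤ 0.06 family-wise error (Tukey null), 0.05 ± 0.02 (log-rank type I).

# Known limitations

* No Welch ANOVA, no Cox models, no best-cutpoint scanning, no Bliss/HSA/ZIP
  synergy scores — all out of scope by design.
* The CLI reads plain TSV/GMT and writes TSV + a JSON manifest; there is no
  YAML configuration layer.
* Scores assume samples are comparable (no normalization or batch correction
  is performed).
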