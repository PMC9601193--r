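---
title: "Metabolomic scoring of efflux-transporter inhibition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic scoring of efflux-transporter inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effluxsig)
```

## Scope and rationale

`effluxsig` turns intracellular targeted LC-MS/MS peak areas from a Caco-2
transwell assay into a per-transporter inhibition call for Pgp, BCRP and
MRP2. The premise is biological: blocking an apical efflux pump changes the
steady-state intracellular levels of its endogenous cargo, so a compact
metabolite signature measured in the routine permeability assay can flag
inhibitors without a dedicated interaction study. This vignette documents
the statistical machinery, every tunable that matters, the synthetic-data
generator used for validation, and the places where we made genuine design
choices.

## Normalization and QC

**Total-sum normalization.** Each sample's areas are divided by the sample's
total quantified area, so normalized rows sum to 1. This removes per-well
multiplicative factors (cell amount, extraction efficiency, injection
volume) that otherwise dominate between-sample variance. Consequences worth
knowing: the data become compositional, so a strong planted increase in some
metabolites depresses all others slightly. The score arithmetic tolerates
this as long as the affected metabolites are a small share of the total
area. Normalizing an already-normalized table is an error, not a no-op.

**The spiked control is QC-only.** Olomoucine is added at fixed
concentration after extraction; its raw-area CV (default acceptance limit
0.2 — the assay itself publishes no bound, and 20% is the conventional
variability cut-off used for loading controls) monitors instrument drift.
It is excluded from the total-sum denominator and from all downstream
statistics: under closure a constant spike becomes *anti*-correlated with
any treatment that raises total cellular area, and would otherwise enter
signatures as an artifact.

**Missing values** are excluded from the denominator and propagated as `NA`;
a metabolite with an undefined control mean gets an `NA` percent change
rather than being dropped. **TEER** screening is strict: a well passes only
above 1000 Ω·cm².

## The OPLS-DA model

For a two-class response coded y ∈ {−1, +1} (centered) and X the
mean-centered, unit-variance-scaled metabolite matrix, the model removes
class-orthogonal variation before fitting one predictive PLS component:

1. w ∝ Xᵀy (normalized); t = Xw; p = Xᵀt/(tᵀt);
2. orthogonal weight w_o ∝ p − (wᵀp)w; t_o = Xw_o; deflate
   X ← X − t_o p_oᵀ; repeat k times;
3. final predictive component on the filtered matrix, with y-loading
   c = yᵀt/(tᵀt).

With a single response each weight is closed-form, so the fit is exactly
deterministic — there is no iterative NIPALS convergence to tune. Requesting
more orthogonal components than the data's rank supports is an error.

Choices, with reasons:

* **Scaling: unit variance** after centering (default for peak-area
  metabolomics, where abundances span decades); Pareto and center-only are
  available.
* **One predictive component**: a binary class needs exactly one; extra
  predictive components would fit noise at n = 12.
* **Cross-validation: 7-fold, class-interleaved** ("venetian blind") fold
  assignment, deterministic given a seed. Q² = 1 − PRESS/SS with scaling
  re-estimated inside each training fold. Q² is *not* algebraically bounded
  by R²Y, but on any informative fit it should not exceed it; the test suite
  checks this as a property.
* **Orthogonal-component count**: `select_n_orthogonal()` returns the
  smallest k whose Q² is within 0.01 of the best over 0..max_k — parsimony
  first, because at 6+6 replicates every extra component is a real
  overfitting risk.
* **Permutation validation**: labels are permuted (default 99 times), the
  full pipeline refitted, and the p-value uses the add-one convention
  p = (1 + #{Q²_perm ≥ Q²_obs})/(n_perm + 1), so p is never 0 and equals
  1/(n+1) when the observed model beats every permutation.

**VIP.** With one predictive component the variable importance reduces to
VIP_j = √p·|w_j|/‖w‖, so mean(VIP²) = 1 exactly — a useful invariant the
suite asserts to 1e-8. The signature threshold VIP > 0.75 is strict.

**Outlier diagnostics.** DModX_i is the per-sample residual standard
deviation relative to the pooled model residual, with critical value
√F₀.₀₅(p−a, (n−a−1)(p−a)); T² combines predictive and orthogonal scores
with the usual a(n−1)/(n−a)·F critical form. Defaults use α = 0.05 per
sample. For *automated, iterative* elimination
(`remove_outliers_and_refit()`) note that per-sample α = 0.05 on 12 samples
carries a ~46% familywise false-flag probability; a stricter α (0.01–0.025)
is the sensible operating point there, and the removal loop never drops a
class below 3 samples regardless.

## Percent change, signatures and the score

Per metabolite, percent change = 100·(mean_T − mean_C)/mean_C on normalized
areas, with an unpaired two-sided Mann–Whitney test (exact by enumeration
when both groups have ≤ 8 tie-free observations; normal approximation with
midrank tie correction and continuity correction otherwise) and the
conventional star tiers at 0.05/0.01/0.001/0.0001. Tiers are deliberately
unadjusted for multiplicity — they describe, they do not gate; a
Benjamini–Hochberg column is emitted for completeness.

**Consensus rule.** A metabolite enters a transporter's signature when
VIP > 0.75 in *every* derivation experiment (the main-inhibitor experiments
and the knockout line) and its percent change keeps one sign across all
experiments, validation inhibitors included. We deliberately require the
VIP gate in every derivation experiment rather than in a single designated
inhibitor + KO pair: with 6+6 replicates the null distribution of VIP is
wide (the threshold 0.75 sits well inside it), and a two-experiment gate
admits spurious members at an unacceptable rate, which the
direction-consistency check alone cannot repair. Experiments marked
`validation = TRUE` are direction-checked but never VIP-gated. Direction
conflicts exclude a metabolite with a logged reason, not an error.

**Score and ranges.** The inhibition score is the signed sum of the
signature members' percent changes — decreases count negatively, which is
why the BCRP range is negative. Classification: Pgp > 600 (strict),
MRP2 ∈ [300, 600] (inclusive, matching the printed "300 to 600"),
BCRP < 0 (strict). Flags are independent; overlapping flags are reported
as-is because Pgp and MRP2 signatures genuinely share members (arginine,
threonine, pantothenate) and no precedence rule exists. Up to half of a
signature may be missing from a panel (recorded explicitly); more is an
error. The BCRP signature indicates *interaction* only: substrates and
inhibitors produce similar negative scores.

## Transport arithmetic

Papp = (dQ/dt·Vr)/(C₀·A). With the receiver concentration in µmol/L, time
in s, Vr in mL and A in cm², the units reduce to cm/s exactly (1 mL = 1 cm³).
We place Vr in the numerator — the standard transwell form and the only
placement whose units are a permeability. dQ/dt is the least-squares slope
over the sink-condition window (receiver < 10% of C₀; all points if fewer
than 3 qualify). A negative fitted slope returns Papp = 0 with a warning.
Default geometry: A = 0.11 cm², apical 0.1 mL, basolateral 0.3 mL.

## The synthetic-data generator

The generator emulates what the analysis assumes about a targeted
treated/control experiment, with these frozen defaults:

* **Design**: 6 treated + 6 control wells; 60-metabolite panel plus the
  spiked control.
* **Baselines**: per-metabolite log-normal medians; filler metabolites on a
  3.4–6.7 log₁₀ grid (> 3 decades, as in real targeted panels), the 20
  signature-eligible metabolites in the low tail (log₁₀ ~ U(3.8, 4.8)).
  Placing the signature metabolites low keeps their share of the total-sum
  denominator near 1%, so planted fold-changes survive closure — the same
  condition under which a summed percent-change score is meaningful on real
  data.
* **Effects**: multiplicative fold-changes on treated wells, 1.6 for "up"
  and 0.6 for "down" members. These are calibration choices, not measured
  values (the source effect sizes exist only as heatmaps): they are the
  smallest round effects for which the expected Pgp score (11 members)
  clears 600 with margin while the BCRP score (3 down + 1 up) is reliably
  negative and MRP2 (8 up + 1 down) sits mid-band.
* **Noise**: multiplicative log-normal replicate noise, CV 8% — the level
  of a well-controlled targeted MRM assay on replicate culture wells, where
  the spiked control shows instrument CV ≈ 1% and biology dominates. A
  per-sample log-normal size factor (CV 10%) is injected deliberately so
  total-sum normalization is demonstrably necessary, not decorative.
* **Outliers**: with probability `outlier_rate` (0 in the default
  scenarios) a sample has a random half of its panel multiplied by 5 — a
  composition-distorting failure (extraction/injection), chosen because a
  *uniform* global distortion is removed exactly by normalization and
  would be undetectable by construction.
* **Panel size 60** (realistic range 60–120): the smallest BCRP signature
  has only 4 members, and its VIP share shrinks as the panel grows, so
  larger panels both dilute true-member VIPs and multiply chance passes
  among fillers; 60 keeps exact signature recovery high without changing
  any published threshold.
* **Transport series**: receiver concentration rising at slope
  Papp·A·C₀/Vr with optional multiplicative noise; with zero noise the
  Papp round-trip is exact to machine precision.

Everything is bit-reproducible given `(scenario, n_metabolites, seed)`;
experiment sets derive sub-seeds `seed·1000 + i`.

**What passing on synthetic data does and does not show.** The generator
matches the analysis' distributional assumptions by construction: log-normal
multiplicative noise, independent metabolites given the size factor, planted
effects of one common magnitude, and no batch structure, drift, missingness
or correlated metabolite blocks. Green tests therefore demonstrate that the
pipeline is *correct* (it recovers what was planted, its identities hold,
its error contracts fire) — not that the published score ranges will
reproduce on any particular laboratory's data, where effect sizes vary per
metabolite and matrix effects are real. The problem sizes used in the suite
(25-seed recovery runs, 50-seed score-band runs, 200 permutation-calibration
nulls at a 20-metabolite panel) were chosen as the smallest giving stable
Monte-Carlo estimates of the rates being checked.

## Known limitations

* Binary designs only: one treated vs one control group per fit; no
  multi-class OPLS-DA or dose-response modelling beyond the Spearman trend
  test (exact p for small n; constant profiles are reported as ρ = 0,
  p = 1 by convention).
* The consensus rule needs at least one inhibitor and one knockout
  experiment; with a single experiment use the VIP table directly.
* Scores from replicate experiments are classified per experiment; a mean
  score across experiments is reported separately rather than folded into
  one call.
* The packaged classification ranges were established for the original
  assay format (Caco-2, 10-day culture, 2 h treatment, specific panel);
  porting them to other formats requires re-deriving signatures with
  `derive_signature()` on local inhibitor + KO data.
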