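---
title: "Quadratic optimization of drug combinations: models, design and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadratic optimization of drug combinations: models, design and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpopr)
```

## The problem this package addresses

Finding an effective two-drug combination among $k$ candidate drugs by
brute force requires a dose grid over a $k$-dimensional space — far beyond
what a patient-derived organoid (PDXO) screen can afford. The workflow
implemented here rests on the empirical observation that short-term
phenotypic responses (here, cell viability) to combinatorial perturbation
are well approximated by a second-order polynomial in drug dose: higher
order terms rarely matter. If that holds, a carefully chosen set of
~150 dosing combinations suffices to estimate the full quadratic response
surface for nine drugs, and every two-drug combination can then be ranked
on its *projected* output rather than measured individually.

The package covers the four stages of that workflow, each usable on its
own:

1. **Design** — an orthogonal array composite design (OACD) laying out the
   dosing combinations (`compose_oacd()`, `map_design_to_concentrations()`).
2. **Surface fitting and ranking** — OLS estimation of the quadratic
   surface on a therapeutic output, exhaustive two-drug ranking, cohort
   frequency tables and rank-profile clustering (`fit_quadratic_surface()`,
   `score_two_drug_combinations()`, `rank_frequency()`,
   `cluster_rank_profiles()`).
3. **Validation** — Chou–Talalay combination-index (CI) and dose-reduction
   index (DRI) profiles from median-effect dose–response fits
   (`fit_median_effect()`, `combination_index()`).
4. **Simulation** — a ground-truth viability generator with planted
   pairwise interactions, so that every stage has a testable oracle
   (`make_cohort()`, `simulate_viability()`).

Screening-arm helpers (median-viability hit calling, caliper tumor
volumes, growth rates, pathway-score correlations) are included for the
surrounding analyses (`screen_rank()`, `tumor_volume()`, `growth_rate()`,
`pathway_sensitivity_correlation()`).

## The experimental design

The OACD concatenates two blocks:

* a **three-level L27 orthogonal array** (27 runs, strength 2): every
  column carries each coded level $\{-1, 0, +1\}$ nine times, and every
  column pair carries each of the nine level pairs three times. This block
  provides the three-level structure needed to identify the pure-quadratic
  terms. The L27 is built from all 13 non-proportional linear functionals
  over $\mathrm{GF}(3)^3$; the level recoding is chosen so that the
  all-centre run (every drug at level 0) is one of the 27 rows, anchoring
  the quadratic terms without appending extra runs.
* a **two-level regular fractional factorial** at levels $\{-1, +1\}$,
  using tabulated minimum-aberration generators (full factorial for
  $k \le 4$; resolution V or better for $5 \le k \le 10$, e.g. the
  128-run $2^{9-2}_{VI}$ fraction for nine drugs). Its columns are exactly
  balanced and pairwise orthogonal, which sharpens the linear and
  interaction estimates.

For nine drugs this yields $27 + 128 = 155$ runs whose second-order model
matrix ($1 + 9 + 9 + 36 = 55$ columns) has full rank, so the quadratic
fit is uniquely determined:

```{r}
design <- compose_oacd(9)
design
```

Coded levels map to concentrations through per-drug dose specifications.
The dosing convention anchors $-1/0/+1$ at each drug's IC$_0$/IC$_{10}$/
IC$_{20}$ — deliberately sub-lethal doses, so that combination effects are
measured where single agents do little on their own. IC$_0$ is taken as
0 µM (drug absent): it denotes no measurable inhibition, and it makes
no-drug and single-drug projections well defined. Designs can be exported
and re-imported as CSV (`write_design_csv()`, `read_design_csv()`), and a
user-supplied run table (for example a transcription of a published
layout) can override the constructed design; invariants are re-checked on
load. Published layouts are asserted through their counting properties
(run totals, balance, orthogonality, model-matrix rank) rather than
row-for-row equality, since the specific fraction generators used in any
given study are rarely stated.

## The therapeutic output and the quadratic surface

Each run is assayed on the tumor organoid line and on a non-tumorigenic
reference line (THLE-2), and replicates are averaged per run before any
model fitting. The modelled response is the **therapeutic output**

$$\Delta = \text{viability}_{\text{THLE-2}} - \text{viability}_{\text{PDXO}},$$

which is large when the combination kills tumor cells while sparing the
reference line, and negative when toxicity dominates. The surface model is

$$\Delta(x) = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
\sum_{i<j} \beta_{ij} x_i x_j + \varepsilon$$

over coded levels $x_i$, fitted by ordinary least squares. Fit quality is
summarized by the overall regression F-test (from regression and residual
sums of squares) and the adjusted $R^2$. Backward elimination of terms at
$\alpha = 0.05$ is available but off by default: reported F-tests in this
workflow do not imply term pruning, and the full surface keeps the pair
scores comparable across lines. Degenerate inputs follow explicit
contracts: constant outputs give a zero surface with the F statistic
reported as `NA` and adjusted $R^2$ of 0; fewer runs than coefficients, or
a rank-deficient model matrix, are errors rather than silent regularized
fits.

## Ranking two-drug combinations

For each unordered pair $(i, j)$, all other drugs are fixed at level $-1$
(absent) and the surface is evaluated at the four realizable dose points
$\{0, 1\} \times \{0, 1\}$; the pair's score is the best projected output
and the arg-max levels are mapped back to concentrations. Scoring at
realizable coded points (rather than a continuous optimum over
$[-1, 1]^2$) matches how ranked combinations are reported in practice —
as specific concentration pairs. Ties are broken lexicographically by drug
name so that rankings, and everything downstream of them, are
deterministic.

One coded-space subtlety is worth knowing: because "absent" is coded
$-1$, a fitted cross-term $\beta_{ij}$ contributes
$\beta_{ij}(-1)(-1) = \beta_{ij}$ to the projection of *any* pair not
involving $i$ or $j$. Mechanistic interactions do not suffer from this —
an interaction that vanishes when either drug is absent expands to
$c(x_i + 1)(x_j + 1)$, which contributes to $\beta_0$, $\beta_i$,
$\beta_j$ and $\beta_{ij}$ jointly and cancels at the baseline — but
hand-constructed test surfaces with a lone $\beta_{ij}$ will show shared
best scores across disjoint pairs. The test suite exercises both cases.

Cohort-level aggregation counts how often each pair (and each member
drug) appears in a line's top 25 (`rank_frequency()`); with 36 pairs and
a top-25 cutoff, counts near the maximum are common and ties at the
maximum are expected, so "most frequent" should be read as attaining the
maximal count. Rank profiles are clustered by average-linkage
agglomeration on $1 - \rho_s$ (Spearman) distances; identical profiles
merge at height 0 and exactly reversed profiles sit at the maximal
distance 2. Lines with constant rank vectors have no defined correlation
and are reported by name as errors. Per-pair response-surface grids
(`export_response_surface()`) and interaction-weighted edge lists
(`polygonogram_edges()`) export the data behind response-surface maps and
polygonograms; graphical rendering beyond `plot()` methods is out of
scope.

Three ranking objectives are provided: `delta` (maximize $\Delta$; the
main tumor-selectivity ranking), and `thle2_kill` / `pdxo_kill` (minimize
the projected viability of a surface fitted directly to the respective
readout — the toxicity-oriented view). The toxicity view is defined on
reference-line viability alone, the most direct reading of
frequency-by-toxicity displays; if a transformed toxicity score was ever
intended, it can be fitted as its own surface and ranked the same way.

## Median-effect curves, CI and DRI

Single-agent and fixed-ratio combination series are fitted with the
median-effect model $f_a/f_u = (D/D_m)^m$, i.e. ordinary least squares of
$\log(f_a/f_u)$ on $\log D$. Fractions affected are clipped to
$[10^{-4}, 1 - 10^{-4}]$ before the logit (the transform is undefined at
0 and 1), and clipped or zero-dose points are excluded as uninformative;
at least two distinct informative doses are required. Replicates are
pooled rather than pre-averaged, preserving error degrees of freedom in
$r^2$. Inhibitory concentrations follow the closed form
$\mathrm{IC}_x = D_m \left(\frac{x}{100 - x}\right)^{1/m}$, with
$\mathrm{IC}_0 = 0$ by convention. A bounded four-parameter logistic fit
(`fit_four_param_logistic()`) is provided for conventional screen IC$_{50}$
reporting; the median-effect fit remains the canonical curve for CI/DRI.

For a fixed-ratio pair, the combination series is fitted on **total**
dose; the validation ratio defaults to the pair's optimal concentration
ratio from the ranking, normalized to sum to 1 (`ratio_from_ranking()`).
At each fraction affected $f_a$ the mutually exclusive Chou–Talalay form
is used:

$$\mathrm{CI}(f_a) = \frac{(D)_1}{(D_x)_1} + \frac{(D)_2}{(D_x)_2},
\qquad \mathrm{DRI}_i(f_a) = \frac{(D_x)_i}{(D)_i},$$

with no third product term — the standard CompuSyn-style convention; the
reciprocal identity $\mathrm{CI} = 1/\mathrm{DRI}_1 + 1/\mathrm{DRI}_2$
therefore holds exactly on every computed profile and is asserted to
machine precision in the tests. The default $f_a$ grid is
$\{0.05, 0.10, \ldots, 0.95\}$. Self-combinations are exactly additive
($\mathrm{CI} \equiv 1$, $\mathrm{DRI} = 2$ at an equal split) for any
ratio — the sham invariance used as a correctness oracle. Cohort CI
profiles are summarized per $f_a$ by median and range
(`summarize_ci_across_lines()`).

## The ground-truth simulator

`simulate_viability()` composes per-drug Hill survival
$s_i = 1/(1 + (D_i/D_{m,i})^{m_i})$ by Bliss independence
$v_0 = \prod_i s_i$ and applies an interaction multiplier
$\exp\!\big(-\sum_{i<j} \gamma_{ij} (1 - s_i)(1 - s_j)\big)$, clipped to
$[0, 1]$. Positive $\gamma$ produces excess-over-Bliss killing; because
the interaction acts through the product of fractional effects, it
vanishes whenever either drug is absent — required for IC$_0$-anchored
designs to behave sensibly. With $\gamma \equiv 0$ the model is exactly
Bliss-independent, and viability is monotone non-increasing in every dose
whenever all $\gamma \ge 0$; both are property-tested.

`make_cohort()` emulates the study shape: 18 tumor lines (default) plus a
THLE-2-like reference line over the nine-drug panel (two proteasome
inhibitors and a CDK inhibitor with $D_m$ in the 0.01–0.05 µM range;
kinase inhibitors and chemotherapy agents at 2–6 µM; Hill slopes
0.9–1.5). Choices made where the design was open, with reasons:

* **Measurement noise** is additive Gaussian on viability
  ($\sigma = 0.05$ by default), truncated at 0 — chosen over
  multiplicative noise for simplicity and because CellTiter-Glo-style
  readouts are vehicle-normalized before analysis. Plate replicates
  default to 3, the conventional minimum for such assays.
* **Heterogeneity**: per-line $(D_m, m)$ are jittered log-normally,
  mean-preserving, with CV 0.1 by default. The cohort doses are anchored
  to panel-level IC$_x$ values, so the jitter represents residual
  line-to-line variation around the panel consensus, not raw potency
  spread across patients (which is several-fold larger).
* **Planted interaction**: the planted pair (ixazomib + dinaciclib by
  default) receives $\gamma$ = 2 in every tumor line and 0 in the
  reference line; the reference line's $D_m$ are uniformly 4-fold larger
  (less sensitive), emulating the tumor-selectivity premise of $\Delta$.
  Non-planted pairs default to $\gamma = 0$; a `background_gamma_sd`
  option draws small interactions for realism.
* **Reference plate sharing**: `run_qpop_cohort()` simulates one
  reference-line plate per cohort experiment and reuses it in every
  line's $\Delta$, matching a single control line assayed alongside the
  cohort and keeping $\Delta$ comparable across lines.

## What passing tests do and do not show

The simulator provides exact oracles (noise-free round trips recover
surface coefficients to $10^{-8}$ and median-effect parameters to
$10^{-6}$; sham and Loewe-additive constructions pin CI at 1), and those
tests are sharp. The *stochastic* planted-synergy recovery is a different
matter, and the package is explicit about its power: at IC$_{20}$-anchored
doses the planted pair's margin over competing pairs in $\Delta$ units is
$v_0 (1 - e^{-\gamma f_a^2}) \approx 0.05$ for $\gamma = 2$, which is
comparable to the OLS pair-score noise under $\sigma = 0.05$ viability
noise with 3 replicates (155 runs, 55 coefficients). Measured over
independently simulated lines, the probability that the planted pair
ranks first in a given line is roughly 0.4 (about 0.78 with 5
replicates), essentially independent of the heterogeneity CV below 0.1.
Cohort-level aggregates are therefore the reliable readout — the planted
pair attains the modal top-25 count and the best mean rank across lines —
while per-line top-1 recovery in nearly all lines should not be expected
at this noise level, and the test suite's strict per-line assertion
documents that honestly rather than passing by a favorable seed.

The simulator is deliberately simpler than real data in other ways:
no plate/edge effects or batch structure, no biphasic or bell-shaped
dose-response, interactions only pairwise and symmetric, and a single
reference line with scaled potency rather than a distinct pharmacology.
Passing tests show the pipeline recovers what the generative model
plants; they do not certify performance on cohorts whose potency spread,
noise structure, or interaction biology departs from these assumptions.

## Numerical choices and problem sizes

All fits are linear algebra on full-rank model matrices (no iterative
optimization except the bounded Levenberg–Marquardt 4PL fit, which starts
from data-driven values and flags rising curves by refitting with a
negative slope). Determinism: design construction is seedless and hashed
(FNV-1a content digest); every simulator accepts a seed; ties in ranking
and frequency tables break lexicographically. The test suite and the
acceptance script use small problem sizes — the 155-run nine-drug design,
cohorts of 10 lines, 12-point dose ladders — chosen so the full suite
runs in seconds while still exercising the design at its canonical
dimension.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates, from a
fresh simulation: the 155/27/128 design partition and model-matrix rank
55; noise-free surface-recovery error and adjusted $R^2$; planted-pair
recovery statistics over a 10-line cohort; sham CI deviation and the
equal-split DRI of 2; the CI–DRI identity error; median-effect round-trip
error over a 12-point parameter grid; and the noise-free pipeline CI at
$f_a = 0.5$ for $\gamma \in \{0, 1, 2\}$ with its direction flag.
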