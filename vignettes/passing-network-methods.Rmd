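---
title: "Passing networks and the success of offensive plays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passing networks and the success of offensive plays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passnet)
```

## The question and the unit of analysis

Ball-passing networks summarise how a football team circulates the ball:
nodes are the 11 tactical positions, a directed link records that at least
one completed pass went from one position to another. Whole-match networks
mix the sequences that ended well with those that did not, so any
association between network structure and team success is confounded.
`passnet` implements the alternative: split each match into **offensive
plays**, label each play successful or not, and build *separate* networks
for successful and unsuccessful play sets within each sixth of the match.
The regression then asks whether a network's structure predicts whether it
is the successful or the unsuccessful one.

A play is a maximal same-team possession. Possession is taken to start at
the team's first completed pass (the stricter of the classical notational
criteria, which also admit two consecutive touches); it ends with a loss,
an incomplete pass, a shot, or the half-time whistle. Categories:

* **SOP** — the play contains a shot, or the team holds the ball in the
  finishing zone: a completed pass, contact or shot located in zone 4 of
  the attack-direction pitch quartering. Possession-*losing* events in
  zone 4 do not qualify: a ball given away as it arrives was never held
  there.
* **neutral** — plays started from an offensive corner or throw-in; free
  kicks whose first pass is delivered directly into the finishing zone;
  and plays truncated by the whistle with possession retained. Neutral
  plays are excluded from analysis.
* **UOP** — everything else: possession lost without meeting an SOP
  criterion.

Two conventions deserve notice. First, a free kick crossed straight into
the finishing zone would satisfy the SOP zone criterion mechanically, yet
such plays are defined as neutral; we therefore discount the delivery and
its immediate reception when testing finishing-zone entry, while a later
zone-4 action or a shot still upgrades the play to SOP. Without this
precedence rule the neutral free-kick category would be unreachable.
Second, a play is assigned to the match period containing its *first*
event, keeping plays atomic when they span a period boundary; periods are
thirds of each half measured against that half's own duration (stoppage
time included), half-open `[lower, upper)` except the final third, which
is closed at the whistle.

## Metrics

All metrics are computed on the binary link matrix with the node set fixed
at the full 11 positions — positions that never touched the ball dilute
density and clustering, which is intended: an 11-player unit that channels
play through few positions *is* less interconnected.

* **Density** Δ = L / n(n−1): realised fraction of the 110 possible
  directed links. Repeat passes on an existing link change nothing.
* **Average local clustering** C̄: for each position, the neighbourhood is
  the union of in- and out-neighbours, the coefficient the fraction of
  directed links realised among them, `k(k−1)` possible; positions with
  fewer than two neighbours contribute 0 (the 0/0 case resolved by
  convention). C̄ averages over all 11 positions.
* **Degree centralization** C_D = Σ(deg v* − deg v) / (n² − 3n + 2). The
  degree used is the count of distinct partners in the *symmetrised*
  graph, under which the normalising denominator (n−1)(n−2) = 90 is
  attained exactly by the star and the value stays in [0, 1]. A
  `directed_total` convention (in-degree + out-degree) is available as a
  switchable sensitivity check; it can exceed 1 (a hub fed by and feeding
  all ten partners scores 2), which is why it is not the default.

## The regression suite

Each of the 24 networks per match is one case: outcome 1 for SOP networks,
predictors total passes plus the three metrics. Screening follows the
standard preliminaries for logistic regression:

* **Collinearity** by Belsley condition indexes and variance-decomposition
  proportions of the unit-length-scaled design matrix (intercept included,
  no centering); a dimension is flagged when its condition index exceeds
  30 *and* two or more variables load above 0.5 on it. Exact rank
  deficiency reports an infinite condition index.
* **Linearity of the logit** by a Box–Tidwell-style model adding each
  predictor's x·ln(x) term in a single block; the assumption is tenable
  when every interaction's Wald p exceeds 0.05. Because metrics can be
  exactly 0, a predictor containing zeros is shifted by +1 inside the
  logarithm (the shift is reported; negative values are an error rather
  than silently shifted).
* **Outliers**: any predictor |z| strictly greater than 3.29; constant
  columns are skipped.
* **Zero-pass SOP removal**: successful networks with no passes carry no
  structure and are dropped; unsuccessful zero-pass networks are retained,
  mirroring the asymmetric screening used in notational practice. See
  "Limitations" for what this asymmetry implies.
* **Rescaling**: the three metrics are multiplied by 10, so reported odds
  ratios refer to a 0.1 change on the natural scale. The rescaled case
  set is flagged and a second rescaling refused.

The model itself is maximum-likelihood logistic regression via iteratively
reweighted least squares (`stats::glm`, convergence tolerance 1e-10,
at most 100 iterations), fitted in two blocks: total passes, then the
network metrics, so the metrics' effect is read *after* controlling for
pass volume. Reported per term: β, SE, Wald χ² = (β/SE)² against χ²(1),
Exp(β) and 95% CI exp(β ± 1.96·SE). Per block: G = −2(LL₀ − LL₁) against
the constant-only model, the block-2 improvement over block 1 (χ² on 3
df), Nagelkerke's r² (Cox–Snell rescaled to unit maximum), the
Hosmer–Lemeshow decile-of-risk test (type-7 quantile cutpoints, ties kept
together, df = groups − 2, zero-expected-count groups merged with a
warning — comparable to but not bit-identical with other packages'
binning), and a cutoff-0.5 classification table with per-class and
overall percentages.

Complete separation is detected as any standardized coefficient
|β·sd(x)| > 15; the fit is returned usable but flagged, with a warning,
rather than silently returning divergent estimates or refusing a fit whose
classification table is still meaningful.

## The synthetic match generator

The generator stands in for hand-notated match footage. Defaults describe
a plausible elite match; each is a single interpretable dial:

| parameter | default | meaning |
|---|---|---|
| `base_half_duration` | 2700 s | regulation half; stoppage added U(60, 300) s per half, so halves differ and the period division is exercised |
| `mean_possessions_per_period` | 22 | Poisson mean of possession starts per sixth of the match, both teams (≈ 130 per match) |
| `pass_complete_prob` | 0.82 | chance a pass reaches a teammate |
| `pass_continue_prob` | 0.78 | chance a completed pass is followed by another attempt rather than a loss (mean ≈ 2.8 completed passes per play) |
| `preference_concentration` | 1 | symmetric-Dirichlet concentration of each passer's receiver preferences, drawn once per team per match; the single dial for link diversity and hence density, independent of pass volume |
| `zone_advance_prob` | 0.35 | chance the ball advances one zone per completed pass |
| `shot_prob_in_z4` | 0.35 | shot chance per action in the finishing zone |
| `set_piece_rate` | 0.12 | fraction of possessions starting from a corner, throw-in or direct free kick (all neutral play starts) |
| `success_model` | (−0.615, 0.079, −1.32) | planted logit of network success on total passes and 10×density; magnitudes chosen to match effect sizes reported for elite match play |

Possessions alternate strictly between the teams at sorted uniform start
times (each half opens with a kickoff); receivers are drawn from the
passer's preference row; timestamps advance by U(2, 8) s per event and a
possession is truncated by the next possession's start or the whistle.
Entry into the finishing zone is made explicit as a zone-4 contact event,
so the ground-truth category and the segmenter's category coincide by
construction rather than by shared code.

**Planting.** The regression operates on network-level cases whose outcome
is structural (the SOP network of a cell *is* the successful one), so a
success model cannot simply relabel plays independently: a network's
metrics, given its pass total, carry no information about which random
play subset it holds. Success is therefore planted as a **matched-pair
assignment**: within each (team, period) cell the naturally successful and
naturally unsuccessful play groups compete for the successful label, which
stays with the natural assignment with probability
p₁(1−p₂) / [p₁(1−p₂) + p₂(1−p₁)], each group's p evaluated from the
planted logit on its own total passes and density. This is the
conditional-logistic form of the planted model: the within-cell label
contrast follows the planted slope coefficients exactly, and when both
slopes are zero the assignment is a fair coin whatever the intercept — an
exact null. A swap relabels plays by editing only zones and terminal
actions (a demoted play's zone-4 events drop to zone 3 and its shot
becomes a loss; a promoted play's final completed pass is relocated to
zone 4), leaving pass counts and link structure untouched.

What the generator does **not** emulate: spatial player tracking, tactical
formations, opponent pressure, deflections that return possession to the
attacking team, non-direct free-kick plays, rebounds after shots, and any
dependence of play quality on fatigue or score line. Passing tests on
synthetic data therefore validate the *pipeline's correctness and
calibration*, not the realism of any particular football claim.

## Numerical choices and test problem sizes

Tolerances and sizes used by the validation suite are package choices:

* The IRLS fit is checked against a derivative-free Nelder–Mead likelihood
  maximiser to 1e-5 on small designs, and against the closed-form 2×2
  log odds ratio to 1e-8.
* Planted-coefficient recovery is tested at n = 5000 cases within 3
  standard errors; the directional (one-sided, 5%) recovery of the planted
  negative density effect through the full pipeline uses 100 simulated
  matches.
* The block-2 improvement test's type-I rate is verified over 1000
  replicates of 1000 cases. At a few hundred cases the 3-df
  likelihood-ratio test is expected to be slightly liberal — a
  finite-sample property of the χ² reference, not of the implementation —
  so calibration is asserted where the reference distribution applies.
* Full-pipeline null calibration (degenerate planted model) uses 100
  replicates of 6 small matches, with zero-pass cases filtered
  symmetrically (see below).
* Hosmer–Lemeshow calibration (near-uniform p under a correct model) is
  checked by a Kolmogorov–Smirnov test at α = 0.01 over 400 replicates of
  n = 1000: the χ² reference for the statistic is itself approximate, and
  a tighter assertion would test that approximation rather than the code.
* The average-clustering implementation is compared with a brute-force
  ordered-pair enumeration oracle on 1000 random digraphs, and density
  with igraph's edge density on random digraphs.

## Limitations

* **Screening asymmetry.** Dropping zero-pass SOP cases while keeping
  zero-pass UOP cases means all-zero networks can only appear with
  outcome 0. When empty cells are common (sparse matches), this alone
  creates a spurious association between the metrics and the outcome; the
  package reproduces the rule because it is the field's practice, but
  calibration statements about the *test* are made under symmetric
  filtering. With realistically occupied cells the asymmetry affects a
  few percent of cases.
* **Attenuation.** The matched-pair planting fixes the within-cell
  contrast; an unconditional logistic fit across all cases estimates a
  somewhat attenuated coefficient, so pipeline-level recovery is asserted
  for sign and direction, not magnitude. Case-level magnitude recovery is
  asserted with the direct case generator.
* **Convention sensitivity.** Directed clustering and the degree used in
  centralization have no single canonical definition for passing data;
  both conventions are documented above and the centralization degree is
  switchable for sensitivity analysis.
* The pipeline treats an unrecorded change of possession (team changes
  without a loss event) as a lost possession; notation should resolve
  deflections explicitly.
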