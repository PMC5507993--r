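# passnet

Do the structural properties of a football team's ball-passing network
predict whether its offensive plays succeed? `passnet` is an R package for
answering that question from match event data. It is aimed at performance
analysts and researchers in team-sport network science who work with
notated pass-event logs (one record per ball event: passer, receiver,
action, pitch zone, time, restart context).

## What it computes

The pipeline mirrors a notational-analysis study design for elite football:

1. **Play segmentation.** The event stream of each match is cut into
   *offensive plays* — maximal same-team possessions starting at the first
   completed pass — and each play is categorised:
   - **SOP** (successful offensive play): contains a shot at goal, or the
     team holds the ball in the *finishing zone* (zone 4 of the four-way
     longitudinal pitch division, coded in the attack direction);
   - **neutral**: plays started from an offensive corner, a throw-in, or a
     free kick delivered directly into the finishing zone, and plays
     truncated by the half-time whistle with possession retained — these
     are excluded from analysis;
   - **UOP** (unsuccessful): possession lost without meeting an SOP
     criterion.
2. **Network construction.** Each half is split into three equal-duration
   fractions (stoppage time included), giving six match periods. Per match
   the plays aggregate into **24 directed passing networks** — period (6)
   x team (2) x outcome category (2) — over the 11 tactical positions,
   with `weight[i, j]` counting completed passes i → j.
3. **Network metrics** (binary links, n fixed at 11):
   - density Δ = L / n(n−1), the fraction of realised directed links;
   - average local clustering C̄ = (1/n) Σᵢ Cᵢ, with
     Cᵢ = |{a_jk}| / kᵢ(kᵢ−1) over the union of in- and out-neighbours;
   - Freeman degree centralization
     C_D = Σᵢ(deg v* − deg vᵢ) / (n² − 3n + 2) on the symmetrised graph.
4. **Regression suite.** Each network is one case (outcome 1 for SOP
   networks). After screening — Belsley condition-index/variance-proportion
   collinearity diagnosis, a Box–Tidwell x·ln(x) linearity-of-the-logit
   test, |z| > 3.29 outlier removal, removal of zero-pass SOP cases — and
   rescaling of the metrics to a 0–10 scale, a **two-block hierarchical
   logistic regression** is fitted: total passes first, then the three
   network metrics, reporting per-term Wald statistics, odds ratios
   Exp(β) with 95% CIs, block-improvement G statistics, Nagelkerke r²,
   the Hosmer–Lemeshow test and a classification table.
5. **Synthetic matches.** Because hand-notated match data are rarely
   shareable, `simulate_match()` / `simulate_study()` generate event logs
   with the assumed statistical structure — alternating possession chains,
   a Dirichlet passer-preference matrix whose concentration dials network
   density, zone progression, set pieces, and an optionally *planted*
   logistic dependence of network-level success on total passes and
   density — together with a ground-truth channel for end-to-end
   validation.

## Worked example

```r
library(passnet)

params <- sim_params(seed = 42)          # 12 matches, two teams each
study  <- simulate_study(params)

cases <- do.call(rbind, lapply(study$logs, function(log)
  compute_cases(build_networks(filter_plays(segment_plays(log)),
                               log$team_ids))))

sc <- screen_cases(cases)                # screening + 0-10 rescaling
print(sc$report)
hf <- hierarchical_fit(sc$cases)         # two-block logistic regression
print(hf)
```

```
Screening report
  cases: 288 initial, 268 kept (142 UOP, 126 SOP)
  max condition index: 37.631; 1 dimension(s) flagged
  linearity of the logit: met (min p = 0.366)
  outliers removed: 2; zero-pass SOP removed: 18
...
== Block 2 ==
Binary logistic regression (n = 268)
                  beta (S.E.)  Wald     p Exp(beta) CI lower CI upper
(Intercept)     0.120 (0.339) 0.126 0.723     1.128    0.580    2.193
total_passes    0.070 (0.159) 0.195 0.659     1.073    0.786    1.464
density        -1.836 (1.965) 0.874 0.350     0.159    0.003    7.497
clustering      0.184 (0.266) 0.476 0.490     1.202    0.713    2.026
centralization  0.187 (0.164) 1.297 0.255     1.205    0.874    1.662
G(4) = 6.616, p = 0.158; Nagelkerke r2 = 0.033
Hosmer-Lemeshow chi2(8) = 6.345, p = 0.609
Classification: 62.0% UOP, 44.4% SOP, 53.7% overall

Block 2 over block 1: G(3) = 3.296, p = 0.348
```

The 288 simulated cases are screened to 268 (two outliers and eighteen
pass-less successful networks removed). The block-2 table reads exactly
like an SPSS logistic-regression output: each Exp(β) is the multiplicative
change in success odds per unit of the predictor — one pass for
`total_passes`, 0.1 of raw density for the rescaled metrics. At a single
study's size the planted negative density effect is visible in the point
estimate but, as in real match samples of this size, not individually
significant; it becomes decisive as matches accumulate (see the test
suite's 100-match sign-recovery check).

A command-line wrapper is installed with the package
(`system.file("scripts", "passnet", package = "passnet")`) with
`simulate` and `analyze` subcommands over the same functions.

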