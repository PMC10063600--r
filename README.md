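# evaldiff

Tools for individual-differences studies that ask whether **deficient
emotional awareness (alexithymia)** goes along with a reduced ability to
**differentiate evaluative judgments** — to keep *dangerous*, *offensive*,
*foul* and *irrevocable loss* apart, the way one keeps fear, anger, disgust
and sadness apart. The package is aimed at researchers running (or
re-analysing) picture-rating designs: 12 affective pictures, each rated on
four 0–100 scales with either emotion or evaluation wording, plus the
TAS-20 alexithymia questionnaire and, optionally, attentional-impulsiveness
(AI) and Cognitive Reflection Test (CRT) measures.

## What it computes

**Differentiation index.** For each picture rated on *k* scales,

```
diff = (Highest Rating − Mean(Lower Ratings)) / Mean(All Ratings)
```

averaged across pictures. Normalising by mean intensity makes the score
scale-invariant: ratings of 100 vs 80 differentiate less than 40 vs 20.
The score lies in [0, k]; all-zero pictures are undefined and excluded.

**Scoring.** TAS-20 (standard key, reverse items 4/5/10/18/19; DIF, DDF and
EOT subscales), AI, CRT, Cronbach's α (= KR-20 on dichotomous items),
attention-check exclusion with a logged reason per removal, and
high/low-alexithymia group assignment with strict cutoffs
(TAS > 60 high, TAS < 52 low).

**Inference.** Lilliefors-type KS normality screen with seeded Monte-Carlo
p values; Spearman correlations (mid-ranks, t-approximation p); Mann–Whitney
U with tie-corrected z (no continuity correction) and the effect-size chain
r = |z|/√N, d = 2r/√(1−r²); OLS regression with bias-corrected (BC)
percentile bootstrap CIs, semipartial correlations and adjusted R².

**Sensitivity analyses.** Minimal detectable effect for correlation
(Fisher z), Wilcoxon–Mann–Whitney (ARE-adjusted normal approximation) and
multiple-regression f² (noncentral-F inversion) designs.

**Synthetic cohorts.** A seeded generator in which one latent trait drives
TAS responses and the blunting of rating profiles, with a tunable coupling
(`tune_trait_coupling()`) targeting any Spearman correlation between TAS and
differentiation — so the entire pipeline is testable, with recoverable
ground truth, without any participant data.

## Worked example

```r
library(evaldiff)
cfg <- cohort_config(n_participants = 200, trait_coupling = 0.3, master_seed = 42)
g   <- generate_cohort(cfg)
rep <- run_study(g$cohort, study_config("single_group", n_boot = 1000, seed = 1))
print(rep)
```

```
Study report (single_group design): 200 analysed of 200 input participants

Descriptives:
 variable      mean         sd   n
  ev_diff  1.647114  0.2679968 200
      ...
      tas 46.310000 13.4953519 200

Spearman correlations (* p < .05, ** p < .001):
        ev_diff ai       crt     dif      ddf      eot      tas
ev_diff 1.000   -0.379** 0.481** -0.529** -0.523** -0.499** -0.538**
      ...

High vs low alexithymia on ev_diff: Mann-Whitney U = 880, z = -5.90,
  p = 3.593e-09 (n1 = 36, n2 = 136), r = 0.450, d = 1.008

Bootstrapped OLS (n = 200, 1000 resamples, seed 1)
        term        B  ci_low ci_high     t        p   p_boot      sr
 (Intercept)  2.03782  1.9258 2.14057 38.48 9.52e-93 0.000999  1.8406
         CRT  0.11292  0.0879 0.13520  9.72 1.96e-18 0.000999  0.4648
      ...
R2 = 0.556, adj. R2 = 0.545
```

Read it as: in this simulated cohort the TAS–differentiation Spearman
correlation is −0.54, the high-alexithymia group differentiates evaluations
much less than the low group (z = −5.90, d ≈ 1.0), and reasoning (CRT)
makes an independent positive contribution — exactly the qualitative
structure the generating model encodes, recovered by the analysis chain.

The `analysis/` scripts run the two full study-style analyses end to end:

```sh
Rscript analysis/01_simulate_cohorts.R   # tuned Study-1/2-like cohorts + truth
Rscript analysis/02_study1_analysis.R    # two-condition analysis -> results/study1/
Rscript analysis/03_study2_analysis.R    # regression analysis    -> results/study2/
Rscript analysis/04_design_analyses.R    # printed-statistic chains & sensitivity
```

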