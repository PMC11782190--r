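# orthomorph

Clustering of postural blood-pressure morphology from beat-to-beat
active-stand recordings, with frailty association analysis.

## The problem

When an older adult stands up, systolic blood pressure (SBP) transiently
falls, stabilizes and (usually) recovers. Continuous non-invasive
beat-to-beat monitoring during the *active stand test* captures the whole
trajectory, which intermittent cuff readings miss. Rather than imposing
fixed diagnostic thresholds, this package clusters the observed
trajectories into data-driven morphologies and asks whether the
morphologies differ in frailty.

The pipeline, aimed at researchers in cardiovascular ageing and
geriatric epidemiology:

1. **Signal preparation** — read per-beat SBP/DBP/RR series (time `t = 0`
   at stand onset), screen for flatlines, spikes, gaps, calibration steps
   and short phases, and linearly interpolate SBP to a uniform 1-s grid.
   The supine baseline is the mean over 60–30 s before standing.
2. **Features** — three changes from baseline, as percentages (Δ% SBP):
   * *early phase*: nadir of trailing 2-s means within the first 15 s
     of standing,
   * *stabilization point*: 5-s mean centred on 40 s,
   * *late phase*: minimum 10-s rolling mean over 60–120 s.
3. **Clustering** — own k-means++ implementation (D² seeding, Lloyd
   iterations, restarts) with `k = 3`, silhouette, bootstrap Jaccard
   stability and centroid-geometry diagnostics. Clusters are labelled by
   their stabilization-point coordinate: **iOHYPO** (initial deficit),
   **OHYPO** (sustained deficit), **OHYPER** (persistent rise).
4. **NOR reassignment** — participants whose SBP change satisfies
   |early| ≤ 20%, |stabilization| ≤ 10% and |late| ≤ 10% form the
   normal-orthostatic-response (NOR) reference group.
5. **Frailty analysis** — dichotomized indicators (Fried phenotype,
   ADL, MoCA, gait speed, TUG, grip strength, functional reach, falls)
   compared cluster-vs-NOR via 2×2 odds ratios
   (`OR = ad/bc`, Wald CI `exp(log OR ± 1.96·SE)`,
   `SE = sqrt(1/a + 1/b + 1/c + 1/d)`) and logistic regression
   (unadjusted / age-sex / fully adjusted).

A synthetic-cohort generator (`simulate_cohort()`, `simulate_recording()`)
produces beat-to-beat recordings and linked frailty covariates with the
statistical structure the analysis assumes, so the entire pipeline runs
and is tested without access to clinical data.

## Worked example

```r
library(orthomorph)

cohort <- simulate_cohort(n = 500, seed = 42)
fit <- bp_morphology(cohort$participants, bootstrap_B = 50)
summary(fit)
```

```
Postural blood-pressure morphology model (k = 3, n = 500)
centroids (Delta% SBP: early, stabilization, late):
        early   stab   late
OHYPO  -36.05 -15.25 -14.43
OHYPER   1.60  18.85  17.63
iOHYPO -11.01   0.94   1.10
final groups:

iOHYPO    NOR OHYPER  OHYPO
    84    188    123    105

inertia 111825.07; 8 iterations to convergence
 cluster   d_c diameter early_pct stab_pct late_pct
       1 17.15    39.21      9.11     7.55     9.13
       2 15.16    37.33      7.85     6.59     8.18
       3 11.28    27.09      6.78     5.23     4.70
centroid distances (d_cc):
      1     2     3
1  0.00 60.07 33.62
2 60.07  0.00 27.44
3 33.62 27.44  0.00
silhouette 0.399, bootstrap Jaccard 0.972, 8 iterations to convergence
NOR reassignment:
  group original_n final_n reduction_pct
 iOHYPO        269      84          68.8
 OHYPER        126     123           2.4
  OHYPO        105     105           0.0
    NOR          0     188            NA
```

The centroids read directly as morphologies: the sustained-deficit
cluster stays ~36% below baseline at the early nadir and never recovers;
the persistent-rise cluster sits 17–19% above baseline from 40 s onward;
the initial-deficit cluster dips early and returns to baseline. `d_c` is
each cluster's mean distance to its centre and `diameter` the maximum;
`d_cc` the centroid separations, all in Δ% units. The NOR rule then pulls
the participants with normal responses (mostly out of the initial-deficit
cluster, whose members recover) into the reference group.

Frailty associations against that reference:

```r
merged <- merge(fit$groups, cohort$participants, by = "participant_id")
cluster_associations(merged, c("slow_gait", "fried_positive"),
                     models = "unadjusted")
```

```
       indicator cluster      model   or ci_low ci_high     p   n
1      slow_gait   OHYPO unadjusted 0.72   0.33     1.6 0.408 293
2      slow_gait  iOHYPO unadjusted 1.25   0.60     2.6 0.547 272
3      slow_gait  OHYPER unadjusted 2.11   1.16     3.8 0.014 311
4 fried_positive   OHYPO unadjusted 0.84   0.48     1.5 0.552 293
5 fried_positive  iOHYPO unadjusted 0.71   0.37     1.3 0.284 272
6 fried_positive  OHYPER unadjusted 1.79   1.10     2.9 0.020 311
```

Participants in the persistent-rise cluster have about twice the odds of
slow gait (≤ 0.6 m/s) relative to the NOR group — the generating
prevalences of the simulator (23.0% vs 13.0%, odds ratio 2.0) are
recovered. The one-command orchestrator `run_pipeline()` runs the same
stages from a YAML config or argument list and writes `features.csv`,
`clusters.json`, `groups.csv` and `assoc.csv`.

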