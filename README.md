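# dyadsync

Automated, quantitative analysis of **non-verbal coordination between two
people** — typically a clinician and a patient seated face to face in front
of a fixed camera. Instead of labour-intensive human coding of videos,
`dyadsync` reduces each recording to per-person **motion kinetic-energy
time series** and derives interpretable markers of the interaction:

- **Synchrony** `x = c(0)`: the zero-lag normalized cross-correlation of
  the two kinetic-energy series (simultaneous motion).
- **Entrainment / followership** `y`: the centre of mass of the
  cross-correlation function `c(τ)` over lags `[-T, T]` (seconds).
  Positive `y` means the subject's motion follows the actor's; `y ≈ 0`
  means mutual followership.
- **Dominance / turn-taking**: `c(τ)` recomputed in a 20-s moving window;
  runs of constant centre-of-mass sign are *dominance bouts*, and the
  ratio of mean subject-led to actor-led bout durations measures how
  balanced the turn-taking is.
- **Jitter**: the 1.5–5 Hz band power of the energy spectrum —
  high-frequency weaving of a follower's motion around the leader's,
  proposed as a kinematic marker of followership.
- A **two-feature logistic classifier** of interaction style,
  `P(B) = 1 / (1 + a·e^(b·x + c·y))`, fitted by maximum likelihood and
  characterised by bootstrap resampling (out-of-bag accuracy).

## The model in brief

Per-pixel velocities between consecutive frames are estimated with a dense
pyramidal Lucas–Kanade optical-flow estimator; the frame is split at a
vertical boundary (the middle of the desk) into subject and actor regions,
and each region's kinetic energy is `E = Σ (u² + v²)` over its pixels. The
lagged cross-correlation of the two energy series is

    c(τ) = Σₙ Ẽ_S(n + τ) Ẽ_A(n) / [(N − |τ|) · sd(E_S) · sd(E_A)]

with mean-centred series, so `c(0)` is the Pearson correlation and
positive τ means the subject moves after the actor. Group contrasts use
Mann–Whitney tests with rank-biserial effect sizes `r = 2U/(n₁n₂) − 1`.

Because study recordings are rarely shareable, the package ships a
**synthetic dyad generator** (`gen_energy_dyad()`, `gen_cohort()`,
`gen_video()`) with controllable coupling direction, lag, symmetry and
jitter content — every stage of the pipeline can be validated against
known ground truth, down to rendered image sequences.

## Worked example

Generate one "engaged" (scenario B) synthetic dyad at the study's
conditions (210 s at 25 fps) and summarise it:

```r
library(dyadsync)

de <- gen_energy_dyad(scenario_preset("B", seed = 7))
dyad_metrics(de)
#>      c0  com_s jitter_subject jitter_actor dominance_ratio ...
#> 1 0.326 -0.295          2.528        2.766           0.972
```

The dyad is strongly synchronous (`c0 = 0.33`), its entrainment centre of
mass sits near zero lag (`com_s = -0.3` s: neither person systematically
leads), and turn-taking is balanced (`dominance_ratio ≈ 0.97`).

A full cohort at the study's group sizes (21 scenario-A + 22 scenario-B
dyads), with group tests and the bootstrapped classifier:

```r
coh  <- gen_cohort(n_a = 21, n_b = 22, seed = 1)
mets <- cohort_metrics(coh)
rep  <- cohort_report(mets, n_boot = 1000, seed = 1)
rep$group_means
#>   label    c0  com_s jitter_subject jitter_actor dominance_ratio     n
#> 1 A     0.150  1.96           0.760        0.587           0.542    21
#> 2 B     0.330 -0.205          2.35         2.36            1.52     22
rep$classifier
#> <dyad_classifier> P(B) = 1 / (1 + a exp(b x + c y)); ...
#>   bootstrap (n = 1000, out-of-bag): accuracy 100.0% +/- 0.0%
```

Scenario B shows higher synchrony (0.33 vs 0.15), near-symmetric
followership (CoM −0.2 s vs +2.0 s for the one-way scenario A), more
jitter in both interlocutors and turn-taking closer to balance. The
synthetic presets separate more cleanly than real recordings do, so the
classifier saturates at 100% here; see the methods vignette for what this
does and does not say about real data.

Plot helpers: `autoplot()` on energy series, cross-correlations, spectra
and entrainment profiles; `plot_classifier()` for the feature-space view.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/dyadsync.R simulate --out-dir sim --preset B --n 5 --seed 1
Rscript inst/cli/dyadsync.R analyze  --config run.yaml
Rscript inst/cli/dyadsync.R cohort   --metrics metrics.csv --out report.json
```

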