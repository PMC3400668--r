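# swimphys

Locomotor physiology of stream fishes varies along river systems: fish
holding station in fast, steep tributaries tend to sustain higher
swimming speeds than fish from slow lowland main channels, at the cost
of higher maintenance metabolism, while escape (fast-start) performance
often shows no habitat signal at all. Testing such hypotheses requires
stitching together several quantitative methods — swim-tunnel
respirometry, swimming-cost curve fitting, high-speed kinematics,
geometric morphometrics, sequence divergence, and a multi-factor
statistics layer — that are usually scattered across ad-hoc
spreadsheets. **swimphys** packages that whole chain as tested,
reusable R functions, together with seeded synthetic-data generators
with known ground truth so every stage can be validated end to end
without field data.

## What it computes

**Respirometry and critical swimming speed.** Closed-phase oxygen
traces are regressed on time (QC: r² > 0.95, depletion only) and
converted to mass-specific oxygen consumption

$$\dot M_{O_2} = \mathrm{slope} \cdot \frac{V_{resp} - V_{fish}}{m}
\quad [\mathrm{mg\,O_2\,kg^{-1}\,h^{-1}}],$$

standardised to a 1-kg fish with mass exponent 0.75. Critical swimming
speed follows Brett's equation for an incremental-velocity trial
(increment ΔV, period T, fatigue after t min at the final step):

$$U_{crit} = V + \frac{t}{T}\,\Delta V .$$

The maximum QC-passing rate during the trial is the maximum metabolic
rate (MMR).

**Swim-cost power curve.** Metabolic rate versus speed is fitted as
$\dot M_{O_2} = \alpha e^{\beta U}$ (nonlinear least squares seeded by
the log-linear fit). α is the routine metabolic rate (RMR, the curve at
U = 0), β the steepness of the swimming cost, and the cost of transport
$COT(U) = \dot M_{O_2}/U$ is minimised at the optimal speed
$U_{opt} = 1/\beta$.

**Fast-start kinematics.** From 500 frames s⁻¹ centre-of-mass
trajectories: response latency (noise-adaptive onset threshold,
quantised to the frame grid), maximum linear velocity (5-frame central
difference on a smoothed path), and stage-1 turning radius (algebraic
least-squares circle fit).

**Morphometrics.** Generalised Procrustes superimposition of 17-landmark
configurations, thin-plate-spline partial-warp + uniform scores (an
exact orthonormal decomposition of the tangent-space residual), a
Goodall-style permutation regression of shape on any covariate, and the
classical ratios (fineness ratio, caudal-fin aspect ratio, relative
caudal peduncle depth).

**Population genetics.** Kimura 2-parameter distances with pairwise
deletion, full distance matrices, and within/between-group summaries.

**Habitat statistics.** Pearson correlations with exact t-transform
p-values, unbalanced 2-/3-way fixed-effects ANOVA that tolerates a
structurally missing cell (no upper-reach tributary site), and Duncan's
multiple range test with letter displays.

## Worked example

```r
library(swimphys)

## a fish that fatigues 15 min into its 60 cm/s step
trial <- gen_ucrit_trial(true_ucrit = 63, delta_v = 6, period = 30, start_v = 6)
compute_ucrit(trial)
#> Ucrit: 63 cm/s

## fit the swim-cost curve on a noisy synthetic speed series
pts <- gen_mo2_speed_series(alpha = 150, beta = 0.02,
                            speeds = seq(6, 66, 6), cv = 0.05, seed = 1)
fit <- fit_power_curve(pts)
#> RMR = 146.3 mg O2/kg/h, beta = 0.0210 (cm/s)^-1, Uopt = 47.6 cm/s
```

The full demo pipeline (5 sites × 6 fish, tributary and upper-reach
fish planted with higher true Ucrit) recovers the habitat contrast it
was given:

```r
res <- run_full_analysis(default_pipeline_config(seed = 7))
res$duncan_ucrit
#>   group n     mean letters
#> 1    SD 6 58.29944       a
#> 2    DG 6 55.70852      ab
#> 3    HK 6 54.61118       b
#> 4    YJ 6 45.04587       c
#> 5    SN 6 44.48177       c
as.data.frame(res$anova_ucrit)
#>           term df1 df2      F        p    ss
#> 1        reach   2  25  40.69 1.38e-08 493.8
#> 2       stream   1  25 135.17 1.41e-11 820.1
#> 3 reach:stream   1  25   4.47 4.46e-02  27.1
```

Tributary sites (SD, HK) share no letter with their main-stream
neighbours (SN, YJ): the planted stream effect separates cleanly, and
the two-way ANOVA — run on the 5 observed cells with the interaction
reduced to its single estimable contrast — flags both reach and stream
effects. A scriptable entry point wrapping the same function lives at
`inst/scripts/run_pipeline.R`.

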