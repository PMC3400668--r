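---
title: "Models and methods behind swimphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind swimphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

swimphys analyses the locomotor physiology of stream-dwelling fishes
across habitats. This vignette explains the models each stage
implements, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic-data generators do and do not
emulate, and the numerical and design choices that were genuinely open.

## Respirometry

A swim-tunnel respirometer alternates between an open (flushing) mode
and a closed mode in which the fish depletes the oxygen of a sealed
water volume. During a closed phase the dissolved-oxygen probe logs a
concentration every `interval` minutes (2 min by default, a typical
probe logging rate). `estimate_slope()` fits ordinary least squares of
oxygen (mg L⁻¹) on time and reports the depletion as a positive
magnitude in mg L⁻¹ h⁻¹; metabolic rates are conventionally expressed
per hour, so minute-sampled input is converted internally. Two quality
rules guard the conversion to metabolic rate:

* r² must *strictly* exceed the threshold (default 0.95) — a phase
  disturbed by fish transitions or probe drift is discarded, not
  patched;
* the raw regression slope must indicate depletion. An oxygen-increasing
  phase is physically impossible for a sealed respirometer with a live
  fish and is rejected as non-physical rather than folded into the mean.

`compute_mo2()` applies
MO₂ = slope · (V_resp − V_fish)/m. When the fish volume is not
measured, the generator defaults it to mass at neutral buoyancy
(1 kg ≈ 1 L), the standard field approximation. Mass standardisation
uses the per-kilogram convention MO₂_std = MO₂ · m^(1−b) with the
whole-animal exponent b = 0.75; the direction of this adjustment (per-kg
versus whole-animal) is ambiguous in parts of the literature, so the
exponent is an explicit argument rather than a buried constant. The
maximum metabolic rate (MMR) is the largest QC-passing standardised
rate of an individual's incremental-velocity test.

Routine metabolic rate is *not* measured from a resting trace: it is
defined as the swim-cost curve extrapolated to zero speed (below), so
it lives in the swim-performance stage.

## Critical swimming speed

An incremental-velocity trial raises the water speed by ΔV (default
6 cm s⁻¹) every T minutes (default 30) until fatigue; Brett's equation
U_crit = V + (t/T)·ΔV interpolates within the final, incomplete step.
The trial generator inverts this exactly: given a true U_crit it places
fatigue in the step with the largest completed speed V ≤ U_crit at
partial time t = (U_crit − V)/ΔV · T. A target lying exactly on a step
speed fatigues at t = 0 of that step, making the inversion continuous
from the right; this tie-break is what makes the round-trip identity
`compute_ucrit(gen_ucrit_trial(u)) = u` hold for every u, on or off the
grid. The absolute U_crit (cm s⁻¹) is the primary variable; the
body-length-relative form is provided but strongly size-confounded, so
group statistics use the absolute value.

## The swim-cost power curve

Metabolic rate rises approximately exponentially with sustained
swimming speed, MO₂ = α·e^{βU}. α is the routine metabolic rate (the
curve at U = 0) and β the steepness — the relative cost of each extra
cm s⁻¹. `fit_power_curve()` minimises *untransformed* squared error
(matching how nonlinear estimation is done in the field) with a
Levenberg–Marquardt optimiser started from the log-linear regression of
ln MO₂ on U; the pure log-linear fit is available as an option because
it weights proportional errors equally and is occasionally preferable
for heteroscedastic data. Which per-speed rate enters the fit is open
in principle (last closed phase of a step versus the step average); the
pipeline averages all QC-passing phases of a step, the choice that uses
all the data.

Cost of transport is COT(U) = MO₂_std/U, converted to
mg O₂ kg⁻¹ km⁻¹ (1 cm s⁻¹ = 0.036 km h⁻¹). No COT formula needs to be
fitted: under the exponential model, dCOT/dU = 0 exactly at U = 1/β,
so the optimal swimming speed is U_opt = 1/β, and the package asserts
this identity numerically (grid minimisation agrees to <0.1 cm s⁻¹).

## Fast-start kinematics

The escape response is characterised from centre-of-mass coordinates
filmed at `fps` (default 500) frames per second:

* **Latency** — the time from stimulus to the first inter-frame
  interval whose displacement exceeds a motion threshold. No onset
  criterion is standard in the literature, so the threshold adapts to
  digitising jitter: 3× the pre-stimulus frame-to-frame displacement
  SD, floored at 0.2 mm, both exposed as arguments. Latency is
  necessarily quantised to multiples of 1000/fps ms — a camera cannot
  resolve sub-frame onsets — and the generator snaps requested
  latencies to the same grid.
* **Maximum linear velocity** — the peak of a 5-frame central
  difference on a 3-frame moving-average path; both windows are
  configuration, not constants. The stencil reads speed exactly on a
  straight constant-velocity segment and to within ~2% discretisation
  error on the generator's burst profile.
* **Turning radius** — the radius of the algebraic (Kåsa) least-squares
  circle through the first 20 ms of post-onset path. The window is a
  default, not a dogma: published turning radii rarely state their fit
  or window, which is why only synthetic recovery is testable. A
  collinear path (straight escape) returns the undefined-radius flag
  `NA` rather than a huge number.

All three metrics are invariant to translation and rotation of the
coordinate frame; velocity scales linearly with spatial rescaling.

The trajectory generator is deliberately phenomenological: a
stationary pre-stimulus phase, a stage-1 turn along a circular arc at
0.3·v_max, then a straight stage-2 burst that ramps to v_max, holds it
long enough for the velocity stencil to read it exactly, and decays.
It emulates what a 500-fps centre-of-mass track *looks like* — it is
not a hydrodynamic simulation, contains no body-bend kinematics, and
its noise is isotropic Gaussian digitising jitter. Passing recovery
tests therefore validate the estimators, not any biomechanical model.

## Geometric morphometrics

`gpa_align()` performs least-squares generalised Procrustes
superimposition: configurations are centred, scaled to unit centroid
size, rotated to the evolving consensus, and iterated to convergence
(tolerance 1e-10 on the consensus). Partial Procrustes alignment is the
default — specimens keep unit centroid size — with full-Procrustes
rescaling behind a flag. Only proper rotations are used (no
reflections), and all 17 landmarks are fixed points; sliding
semilandmarks are out of scope.

`tps_partial_warps()` eigen-decomposes the bending-energy matrix of the
consensus. The k−3 non-null eigenvectors (principal warps) yield
2(k−3) partial-warp scores per specimen; the uniform (affine)
component is built on the 2-dimensional complement of the similarity
directions inside the affine subspace. Residuals are first projected
into the Procrustes tangent space, which makes the decomposition an
exact orthonormal basis: the squared scores of a specimen sum to its
squared tangent residual to machine precision, a property the test
suite asserts at 1e-8. With k = 17 landmarks this gives 28 non-uniform
plus 2 uniform dimensions.

For inference, `shape_regression()` uses a Goodall-style statistic —
explained versus residual Procrustes sums of squares across all shape
variables — with a permutation p-value (covariate labels permuted,
observed statistic included in the tail count). This was a deliberate
design choice over a parametric multivariate regression F: the
parametric degrees of freedom of legacy shape-regression software
cannot be reconstructed unambiguously, permutation inference is
distribution-free, does not require more specimens than shape
variables, and is the standard in modern geometric morphometrics. With
the default 999 permutations the smallest attainable p is ~0.001.

The 17-point template is a synthetic, stylised fish outline packaged
under `inst/extdata/` (its filename says so); it stands in for a
species-specific digitising scheme. The landmark generator deforms it
along a random mix of its three *lowest-bending* principal warps —
smooth, large-scale shape changes, which is what real ecomorphological
variation looks like — scaled by a per-specimen covariate, then adds
landmark noise and a random similarity transform so that alignment is
non-trivial. Two univariate ratio conventions coexist in the
literature for the caudal peduncle (depth relative to body length, CPH,
versus relative to body depth, CPD/BD); `morpho_ratios()` computes
both rather than adjudicating.

## Sequence divergence

`k2p_distance()` implements the Kimura 2-parameter estimator
d = −½ln(1 − 2P − Q) − ¼ln(1 − 2Q) from transition and transversion
proportions counted over sites that are unambiguous in *both*
sequences (pairwise deletion — the default of the standard distance
software, and a flag-worthy alternative to complete deletion, which
discards far more data in ragged alignments). Ambiguity codes other
than N are treated as missing; Sanger-quality mitochondrial data rarely
warrants full IUPAC handling. Saturated pairs (log arguments
non-positive) raise a typed condition; the matrix builder records them
as `NA` with a warning instead of aborting.

The generator evolves sequences on a star-of-stars genealogy under the
same K80 process with κ = 2 (a typical transition bias), with branch
lengths set so that expected within- and between-group distances equal
the targets exactly — distances are additive in expectation under the
model being estimated, which is the point: estimator and generator
share the model, so convergence failures indicate bugs, not model
mismatch. Published divergence summaries for the motivating system
require the original specimens' sequences, which were never deposited;
those numbers are documented as non-reproducible and covered by
synthetic-recovery tests instead.

## The statistics layer

`p_from_r()` exposes the exact t-transform
t = r√((n−2)/(1−r²)) ~ t(n−2) used by `pearson_with_p()`; boundary
values |r| ≥ 1 map to p = 0.

`factorial_anova()` faces a genuinely awkward design: five site cells
in a 3 (reach) × 2 (stream) layout with no upper-reach tributary. A
full-factorial fit is rank-deficient there, and Type-III machinery
built on estimable marginal means relegates entire main effects to a
"confounded" pool. The package instead tests each term by marginal
model comparison — the extra sum of squares from adding the term to
the model of all terms not containing it, referred to the
full-factorial residual mean square. On balanced designs this is
exactly the classical ANOVA decomposition; with the missing cell every
term keeps a row, the interaction is automatically reduced to its one
estimable contrast (df visible in the output), and the empty cell is
named in an attribute. The tests remain exact F tests under the null,
which the calibration suite verifies empirically. When swimming speed
enters as a factor (each fish measured at every speed it reached), the
repeated-measures structure is modelled as fixed, mirroring common
field practice; this is pseudo-replication and is flagged here as a
known limitation rather than silently accepted.

`duncan_letters()` implements Duncan's multiple range test: ranked
group means, pooled one-way MSE (harmonic-mean group size for unequal
n), and least significant ranges from the studentized range quantile at
Duncan's protection level 1−(1−α)^(p−1) for a span of p means. A
ranked span whose extreme means differ by less than its range is
homogeneous; maximal homogeneous spans receive letters, so the display
is always a contiguous staircase and two groups sharing no letter
differ at α (fixed at 0.05 throughout). Note that Duncan's test does
not control the family-wise error rate at α — that is inherent to the
procedure, not to this implementation.

Correlations across many trait–ecology pairs are reported without
multiple-testing correction, matching the descriptive use of such
tables in the field; readers should treat isolated p ≈ 0.04 entries
accordingly.

## The demo pipeline and problem sizes

`run_full_analysis()` chains every stage on synthetic cohorts: 5 sites
× 6 fish by default, each fish with its own true U_crit, RMR and β
drawn around site means in which tributary and upper-reach fish are
planted as better steady swimmers (e.g. true U_crit 58 vs 44 cm s⁻¹
between middle-reach tributary and main sites) while fast-start truth
is site-invariant — the qualitative contrast the statistics layer
should, and does, recover. All constants (ΔV = 6 cm s⁻¹, T = 30 min,
r² > 0.95, b = 0.75, fps = 500, α = 0.05) live in the single
configuration list; no stage hard-codes them. One global seed drives
every draw sequentially, so identical configurations give
byte-identical output bundles (MD5-verified in the tests).

Simulation sizes in the test and acceptance suites — 200 noisy-trace
seeds, 50 power-curve seeds, 500–1000 null replicates for calibration,
100 Duncan datasets, alignments of 10⁴ sites for convergence checks —
were chosen as the smallest sizes at which the Monte-Carlo noise of
each check is comfortably below the tolerance it asserts.

## Known limitations

* No background (microbial) respiration correction or open-phase flush
  modelling; traces are assumed to come from a clean, sealed phase.
* The fast-start generator has no stage-2 body-bend or C-start angle
  kinematics; centre-of-mass metrics only.
* Shape analysis supports fixed landmarks in 2-D only.
* The ANOVA treats repeated speed measurements as independent fixed
  effects; a mixed model would be more defensible for real data.
* Duncan's procedure is anti-conservative by construction; it is
  provided for comparability with the historical literature, not as a
  recommendation.
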