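---
title: "Margin-of-stability gait analysis: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-of-stability gait analysis: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mosgait)
```

This vignette is the package's own account of what it computes and why the
design is the way it is: the stability model and its assumptions, the
tunable parameters, what the synthetic-data generator does and does not
emulate, the numerical choices, and the known limitations.

## 1. The stability model

Dynamic stability is assessed with the anteroposterior margin of stability
(MoS) at foot touchdown. The underlying picture is an inverted pendulum:
a body of effective length $L_{ref}$ pivoting about its base of support is
recoverable only if its *extrapolated* centre of mass — position plus
velocity divided by the pendulum eigenfrequency $\omega_0 =
\sqrt{g/L_{ref}}$ — stays within the base of support. For a reduced
five-marker treadmill model (C7, both trochanters, both halluces), with
anteroposterior positions taken relative to the rearmost hallux marker:

$$
X_{CoM} = \frac{P_{TroL}+P_{TroR}}{2} - P_{HalluxP}
 + \frac{0.5\left(\frac{V_{TroL}+V_{TroR}}{2}+V_{C7}\right) + |V_{Belt}|}
        {\sqrt{g/L_{ref}}},
 \qquad MoS = BoS - X_{CoM},
$$

where $BoS$ is the anteroposterior distance between the hallux markers at
touchdown, the trochanter midpoint proxies the centre-of-mass position,
and the centre-of-mass velocity is proxied by a weighted mix of pelvis and
trunk marker velocities plus the belt speed (in the treadmill frame the
support surface moves backward under the body, which is why $|V_{Belt}|$
enters additively). `compute_xcom()` implements the equation verbatim;
`compute_step_records()` evaluates it at every touchdown.

Assumptions worth keeping in mind:

* the reduced model is a *proxy*: it tracks the true (full-body) MoS well
  during steady and perturbed treadmill walking but is not a full-body
  centre-of-mass estimate;
* MoS is evaluated at touchdown only — the instant at which foot placement
  can still correct a forward loss of balance;
* positive MoS = stable against *forward* balance loss. Mediolateral
  stability is out of scope.

$L_{ref}$ has no universally agreed measurement protocol (trochanter
height during quiet standing is the conventional choice); it is therefore
an explicit required input of `subject_params()` rather than something the
package infers.

## 2. The measurement chain and its parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `filter_cutoff` | 12 | Hz | low-pass for marker coordinates; gait signal content is < 10 Hz, optical noise above |
| `filter_order` | 2 | – | Butterworth, applied forward and backward (zero phase) |
| `force_threshold` | 50 | N | vertical-force level defining force-plate touchdown/toe-off |
| `target_mos` | 0.05 | m | the target mean MoS defining the stability-normalised speed |
| `speed_grid` | 0.4–1.8 by 0.2 | m/s | constant-speed trials for the MoS-speed curve |
| `perturbation_accel` | 3 | m/s² | belt acceleration magnitude |
| `perturbation_factor` | 1.8 | – | peak belt speed as a multiple of the base speed |
| `baseline_window` | 10 | steps | Base = mean MoS of the 11th-to-2nd-last steps before each perturbation |
| `n_post_steps` | 8 | steps | recovery steps labelled Post1–8 |
| `event_match_window` | 0.05 | s | marker/force event pairing window |
| `debounce` | 0.1 | s | velocity sign-switch chatter rejection |
| `alpha` | 0.05 | – | significance level |

**Filtering.** `lowpass_zero_phase()` applies the Butterworth filter
forward and backward, so the passband is the *squared* single-pass
magnitude, approximately $(1+(f/f_c)^{2 \cdot order})^{-1}$, and the net
phase shift is zero (event timing must not be biased by filtering). Edge
transients are controlled by reflective padding (mirroring about the end
points) of three settling lengths, $3\lceil f_s/f_c \rceil$ samples; the
padding is discarded afterwards. One numerical caveat: the digital filter
is designed by bilinear transform, so its response follows the analog
$(1+(f/f_c)^{2\,order})^{-1}$ form only where frequency warping is
negligible ($f \ll f_s/2$). At a 1000 Hz sampling rate the two-pass gain
at $2f_c$ is within 1% of the analog value $1/17$; at 100 Hz, warping
makes it visibly smaller. Tests of the attenuation law therefore run at
1000 Hz.

**Velocities.** Positions are filtered first, then differentiated
(central differences interior, one-sided at the ends). Filtering and
differentiation are both linear and shift-invariant, so the order is
mathematically immaterial away from the edges (a property the test suite
checks); filter-then-differentiate is used because it is the conventional
biomechanics order. The belt-velocity signal is a commanded, piecewise
smooth profile and is used as recorded, unfiltered.

**Events.** Marker events are the frames where the filtered hallux
anteroposterior velocity changes direction: on a treadmill the foot moves
backward with the belt during stance, forward during swing, so the
positive-to-negative switch is touchdown, the reverse toe-off. Switch
pairs closer together than the 100 ms debounce are physiologically
impossible (neither stance nor swing is that short at these speeds) and
are removed as chatter. Force-plate events are the 50 N crossings, with
linear interpolation between samples. The hybrid correction estimates the
mean force-minus-marker discrepancy — separately for touchdown and
toe-off, pooled over both limbs — over steps whose force burst appears on
exactly one belt's plate between the marker touchdown and toe-off, and
adds those constants to all marker events. Separate per-kind offsets were
chosen because the marker-velocity switch is systematically early/late in
different directions at touchdown versus toe-off; per-limb offsets were
considered and rejected (hardware latency has no reason to differ between
sides, and halving the pooled sample would double the offset variance).
Steps loading both plates are excluded from offset *estimation* but still
receive the correction. Corrected event times are continuous (not snapped
back to the 100 Hz frame clock).

**Stability-normalised walking speed.** The mean touchdown MoS of the
final 10 steps of each constant-speed trial is fitted with an unweighted
least-squares quadratic in speed (`fit_mos_speed_curve()`); weighting is
moot because every point averages the same number of steps. The
normalised speed is the real root of $mos(v) = target$ inside the speed
range (`solve_normalised_speed()`). If both roots are admissible the one
closer to the range midpoint is returned and a warning logged — with a
monotonically decreasing MoS-speed relationship over 0.4–1.8 m/s this
should not occur in practice, and it is deliberately loud when it does.
The solved speed is reported at full precision; rounding to a treadmill
command resolution is left to the protocol layer.

**Perturbations.** Each perturbation is armed at a scheduled time (30–90 s
of unperturbed walking, drawn uniformly — the bounds are part of the
protocol; uniformity is the maximum-entropy choice given only bounds) and
triggered at the first subsequent instant the to-be-perturbed hallux
passes the stance hallux (`detect_trigger()`, inclusive at the arming
sample). The belt then ramps at 3 m/s² to 180% of the base speed and
decelerates at the perturbed limb's toe-off. The deceleration slope is
set equal to the acceleration: the physical controller's braking dynamics
are unknown, and the choice only affects steps after Post2, by which time
the belt is back at base speed under every realistic timing. Only the
perturbed belt deviates; the contralateral belt holds base speed. Because
the trigger fires mid-swing of the to-be-perturbed limb ("the belt
accelerates before the foot lands"), the first touchdown after the
trigger — Post1 — is the perturbed limb's own landing on the accelerating
belt; the labeller and the generator share this convention. Consecutive
contacts of the recovery step with the still-fast perturbed belt are
possible in principle; the per-step belt attribution (below) handles them,
and the realized belt profile is recorded so they can be flagged.

**Which belt's speed enters the XCoM?** The equation has a single
$|V_{Belt}|$ but a dual-belt treadmill has two. The package uses the belt
under the *landing* limb at each touchdown: during a unilateral
perturbation this is the perturbed belt when the touchdown lands on it
and the unperturbed belt otherwise, which is the quantity that determines
that step's backward drift. Similarly, the "rearmost hallux" is resolved
per frame (whichever hallux has the smaller anteroposterior coordinate at
that instant), not per step.

**Recovery metrics.** Two reductions are deliberately different in kind.
`steps_to_positive()` is individual-level and statistics-free: the index
of the first step of the terminal run of non-negative MoS values, with a
minimum of 1 (a perturbed walker always needs at least one recovery step,
and the metric counts steps *required*, not "zero" when the first landing
already happens to be stable) and an explicit undetermined flag (K+1)
when the last analysed step is still negative. `steps_to_baseline()` is
group-level: each recovery step is compared with the pre-perturbation
baseline across subjects (paired t tests, Bonferroni-adjusted over the
family of recovery steps), and the count is the length of the *initial*
run of significant steps. Patterns with interior non-significant steps
(significant at Post1–2 and Post4 but not Post3) have no canonical
reduction; the initial-run rule is used and the full significance pattern
is returned as an attribute so the reduction is auditable.

**Repeated-measures ANOVA.** `rm_anova_two_way()` computes the standard
univariate within-subject F tests for a complete balanced subject × A × B
design (each effect against its own factor-by-subject interaction mean
square), via `stats::aov` with an `Error(subject/(A*B))` stratification;
an independent brute-force sums-of-squares implementation exists in the
test suite and the two agree to 1e-9. Sphericity corrections are *not*
applied — the reported degrees of freedom are the uncorrected ones — and
this is a documented limitation rather than an option. Post-hoc pairwise
comparisons of a factor's levels collapse the other factor to
subject-level means and use either Tukey's studentized range (with the
error stratum's mean square) or Bonferroni-adjusted paired t tests.
`normality_check()` (Shapiro–Wilk plus a Q-Q straightness coefficient) is
advisory only and gates nothing.

## 3. The synthetic-data generator

Real recordings of this kind are rarely shareable, so the package treats
synthetic data as a first-class citizen. The design principle:
**kinematics are built by construction, not forward dynamics**. The
pipeline's correctness claims concern measurement, so the generator must
*control* the ground truth exactly, not merely approximate it with a
physics model whose own truth would then be unknown.

How it works, in brief:

* Each hallux follows a two-harmonic periodic waveform of stride phase
  whose velocity has transversal zero crossings at analytically known
  phases — those crossings *are* the ground-truth touchdown (~phase 0.19)
  and toe-off (~phase 0.81, i.e. a 62% stance fraction). Being
  band-limited to twice the stride frequency, the waveform passes the
  12 Hz filter essentially unchanged.
* Trochanter midpoint and C7 sway sinusoidally at the stride frequency,
  phase-locked so their velocities vanish at touchdown instants — this
  makes the ground-truth MoS insensitive (to first order) to the few
  milliseconds of event-timing jitter any detector has. An antisymmetric
  pelvis-rotation term is added to the two trochanters; it cancels
  exactly in the midpoint and in the velocity average that the XCoM uses.
* At each touchdown, the MoS equation reduces to
  $x_{front} - p_{tm} - vel/\omega_0$ (the rearmost hallux cancels
  between BoS and XCoM), so the *foot placement* needed for any target
  MoS is known in closed form. The generator assigns each step a target —
  the model's quadratic MoS-speed curve value, plus N(0, `mos_noise_sd`)
  step-to-step noise, minus the perturbation deficit where applicable —
  and shifts each step's landing position accordingly, blending the
  offsets mid-swing with a quintic smoothstep so the event-defining
  velocity crossings are untouched.
* The perturbation response is exponential recovery: the true deficit of
  recovery step $k$ after the $j$-th perturbation of a limb is
  $drop \cdot (1-adaptation)^{j-1} \cdot recovery^k$.
* Vertical forces are smooth per-stance bursts peaking near 1.1 body
  weight with a fast (~3 ms to 50 N) onset; only their threshold
  crossings matter downstream. Marker coordinates receive 0.5 mm white
  measurement noise by default.

Default parameters and why: the true MoS-speed quadratic
$0.20 - 0.15v + 0.025v^2$ puts the normalised speed at ~1.27 m/s, inside
the 1.2–1.5 m/s range reported for healthy adults, with realistic mean
MoS values (0.14 m at 0.4 m/s, 0.01 m at 1.8 m/s); step length
$0.35 + 0.25v$ m gives cadences of 0.9–2.3 steps/s across the grid;
`mos_noise_sd` = 0.01 m and `marker_noise_sd` = 0.5 mm are typical
step-to-step and optical-capture variabilities; the perturbation response
(`drop` = 0.45 m, `recovery` = 0.5, `adaptation` = 0.1) yields Post1 MoS
around −0.18 m and 2–4 steps to consistently positive MoS, shrinking with
repetition — the qualitative signature of reactive adaptation.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: belt-foot interaction during the perturbation
(the stance foot is not dragged by the accelerating belt; the *target*
MoS is imposed instead), upper-body counter-rotation, muscle dynamics,
marker occlusion/dropout, soft-tissue artefact, and any difference
between the reduced model's MoS and a full-body MoS. Pipeline validation
against this generator demonstrates measurement fidelity — that events,
MoS values and downstream metrics are recovered from realistic signal
shapes — not biomechanical realism of the signals themselves.

## 4. Test problem sizes and statistical design of the checks

The suite validates each stage against an independent oracle: closed-form
values (filter gains, quadratic roots, hand-evaluated XCoM), generator
ground truth (event times within 2 frames, per-step MoS within 0.01 m on
noiseless settings), and a brute-force sums-of-squares ANOVA. End-to-end
parameter recovery uses 100 seeded replicates: eight 16 s constant-speed
trials per seed for the normalised speed (recovered within 0.05 m/s of
the analytic root of the true curve), and one full ten-perturbation
session per seed (~11 min of simulated walking at 30–90 s intervals) for
the recovery-step counts. Counts are compared per perturbation against
the count computed from the generator's realized (noisy) true per-step
MoS. Per-perturbation agreement is the meaningful fidelity measure: with
step-to-step MoS noise of 0.01 m, a recovery step's true MoS falls within
any measurement system's resolution of zero in a few percent of
perturbations, and no pipeline can then guarantee the same sign — exact
per-session agreement across all ten perturbations is therefore not an
attainable (or informative) bar.

A similar power consideration applies to the group-level
`steps_to_baseline()` recovery test: with drop 0.16 m, recovery fraction
0.5, noise 0.01 m and n = 18, the Post4 deficit (0.01 m) sits at only
~1.4 times the Bonferroni paired-t detectability threshold (~0.007 m), so
the expected count of 4 is recovered exactly in most but not all
replicates; the suite asserts exact recovery in the majority of seeds and
recovery within ±1 step in ≥95%.

## 5. Degenerate inputs and numerical conventions

* `solve_normalised_speed()`: curves that never reach the target report
  the curve's extremum in the error; a numerically zero quadratic
  coefficient falls back to the linear solution; two admissible roots
  warn and pick the one nearer the range midpoint.
* `steps_to_positive()`: zero MoS counts as non-negative; all-negative
  sequences return K+1 with an `undetermined` flag rather than NA.
* Belt profiles are exactly piecewise linear (`pmin`/`pmax` of affine
  pieces), so the maximum realized slope equals the configured
  acceleration to machine precision; an unreachable plateau (toe-off
  before the ramp completes) warns and peaks where the ramp was cut.
* Event correction with zero matched single-plate steps raises an error
  instructing marker-only fallback; the trial-level wrapper downgrades
  this to a warning and returns uncorrected marker events.
* Readers validate strictly (missing markers/columns, non-monotone time,
  negative belt speed) and never coerce.
* Filtering requires the cut-off below Nyquist and a signal longer than
  the padding; constants pass through with unit gain.

## 6. Known limitations

* The reduced-model MoS is a proxy; no full-body option is provided.
* Mediolateral stability, platform perturbations and overground gait are
  out of scope.
* No marker-gap filling: inputs are assumed complete.
* Sphericity corrections are not applied in the repeated-measures ANOVA.
* The group-level baseline-return metric requires a complete balanced
  cohort; it has no unbalanced-design fallback by design (the paired
  within-subject contrasts are the definition of the metric).
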