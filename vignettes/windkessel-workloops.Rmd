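---
title: "Windkessel-Laplace loading of simulated cardiac muscle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windkessel-Laplace loading of simulated cardiac muscle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wkloop)
```

## The system being simulated

Isolated ventricular trabeculae are conventionally loaded in vitro with
time-invariant afterloads: isometric clamps or constant-force (isotonic)
"flat-topped" work-loops. Real ventricular tissue instead works against the
mechanical impedance of the arterial tree, which varies within each beat.
wkloop simulates the loading system that closes this gap: a contracting
one-dimensional muscle coupled in real time to a 3-element Windkessel model
of arterial impedance through a thin-walled spherical ventricle.

Per control step (default 50 us, the 20 kHz rate of the hardware this
emulates) the causal chain is

1. muscle force F, from the active force source;
2. wall stress sigma = F / (pi d^2 / 4) and ventricular pressure
   P = 2 sigma h / r (Laplace, thin sphere);
3. aortic valve logic (ideal diode): open on strict P > Pa, closed as soon
   as the flow would reverse;
4. Windkessel update: flow Q = (P - Pp)/Zc through the characteristic
   impedance while the valve is open, with the peripheral pressure Pp
   stored on the compliance C and discharged through the peripheral
   resistance Rp;
5. diastolic refill at a prescribed volume rate, clipped at the
   end-diastolic length;
6. volume update V <- V + (inflow - Q dt) and length from the cubic map
   L = L_ref (3V / 4 pi)^{1/3} / r_ref.

During diastole no flow passes Zc, so Pa = Pp and the aortic pressure
decays exponentially with the RC time constant tau = Rp C. The valve has
zero forward drop and zero reverse leak, so Pa = P throughout ejection.

## Parameters and their defaults

Windkessel parameters are stated in the units used throughout the
work-loop literature so published sets can be copied verbatim:

| parameter | unit | normotensive | hypertensive | hypotensive | room-temp base |
|---|---|---|---|---|---|
| Rp (peripheral resistance) | GPa s m^-3 | 14.5 | 21.4 | 9.18 | 150 |
| C (arterial compliance) | pm^3 Pa^-1 | 32 | 15 | 42 | 32 |
| Zc (characteristic impedance) | GPa s m^-3 | 0.5 | 0.76 | 0.31 | 5 |

The compliance unit is interpreted as m^3 Pa^-1 scaled by 10^-12:
dimensional analysis of dV = C dP admits nothing else, and the products
Rp C then give physiologically sensible decay constants (0.32-0.48 s for
the disease triplets).

Muscle and ventricle geometry: the reference trabecula is 1.8 mm long and
0.26 mm in diameter, so a 3.5 mN twitch develops 65.9 kPa of wall stress.
The equivalent ventricle defaults to a resting radius of 5 mm with a
0.25 mm wall. The radius sets the chamber scale (about 0.52 mL at the
reference length, the scale of a rat left ventricle); the wall thickness
is the one constant of the Laplace mapping that cannot be measured from a
one-dimensional preparation, and it calibrates the pressure scale. We
chose h = 0.25 mm (h/r = 0.05, peak pressures of about 6.6 kPa from the
66 kPa reference stress) from a volume-feasibility argument: the charge
the arterial compliance absorbs per beat is approximately C times the
pulse pressure, and at the low-resistance end of the published sweeps
(Rp = 5 GPa s m^-3, where tau = 0.16 s lets the arterial pressure drain
between beats) a higher pressure scale would demand per-beat ejection
larger than the chamber itself. Both values are configuration keys, not
constants.

Initial peripheral pressure defaults to 5 kPa, just below the working
systolic pressure. Starting the Windkessel empty is not neutral: the first
beat would then see the whole systolic pressure across Zc and eject
C P_sys of volume within Zc C = 16 ms. Erring high is benign (the valve
simply stays shut while Pp decays), and ten discarded burn-in beats erase
the choice; sweeps additionally detect periodic steady state (beat-to-beat
change of peak stress and shortening both below 0.5%) before a beat is
analysed.

Diastolic refill begins when the valve is closed and the activation-level
stress has fallen below 5% of the previous beat's peak, runs at a
configurable rate (the automatic choice is two resting chamber volumes per
beat period, completing well inside diastole in every shipped protocol),
and is clipped so the muscle never overshoots its end-diastolic length.
The refill is purely kinematic; there is no atrial or mitral model.

## Force sources

**Replay mode** prescribes the force: a recorded or synthesised isometric
twitch, replayed identically every beat, invariant with shortening. The
synthetic twitch is a double exponential
a (exp(-t/t_fall) - exp(-t/t_rise)) scaled to its analytic maximum, by
default 3.5 mN. This is the validation ("dry run") mode: the muscle side
is exact and known, so every discrepancy is attributable to the load
model. Twitch kinetics must fit inside the beat: at 5 Hz pacing use time
constants near 12/35 ms; the slower 30/80 ms defaults suit 1 Hz pacing.

**The Hill fixture** closes the loop: total stress is
activation x sigma_max x fl(L) x fv(v) + passive(L), with a parabolic
force-length factor (half-width 0.35 L0), a Hill hyperbola force-velocity
factor (v_max = 3 L0/s, curvature 0.25) linearly capped at 1.1 on the
lengthening limb, an exponential passive curve (slack 0.9 L0, 0.25 kPa
scale, steepness 25, giving about 4% of developed stress at L0 — typical
for rat trabeculae and necessary for the work-afterload relation to fall
at low afterloads), and the normalised double-exponential activation
drive. Kinetics presets: body (12/35 ms, for 5 Hz), warm (30/90 ms) and
room (55/150 ms, for 1 Hz); each completes diastole before the next
stimulus at its intended rate. sigma_max defaults to 66 kPa so the
isometric twitch matches the replay reference.

The fixture is deliberately memoryless: its only "adaptation" across beats
is the one carried by the Windkessel state. Real muscle adds intrinsic
restitution and length-history effects, so transients such as the response
to an abrupt resistance step reproduce the load-borne component of the
experimental behaviour, not the myocardial component.

**The isotonic controller** reproduces flat-topped work-loops as a
four-phase machine per beat: isometric hold until the developed force
reaches the afterload; isotonic shortening with the velocity solved from
the Hill relation each step (bisection, so the recorded force tracks the
afterload to well below 0.5%); isometric relaxation once no non-negative
velocity sustains the load; constant-velocity re-lengthening back to the
end-diastolic length once activation falls below the refill trigger.
Afterloads above the peak isometric force leave the beat fully isometric
(flagged, not an error); afterloads below the passive force at
end-diastolic length are rejected.

## Numerical scheme

The engine advances on a fixed grid with no hidden state: identical
configurations give bit-identical output.

* Closed valve: Pp decays by the exact exponential integrator (one
  multiply per step; semigroup property holds to machine precision). A
  trapezoidal variant of the same decay is available for verifying the
  discretisation error of the grid.
* Open valve: Q is algebraic, and Pp advances by the trapezoidal
  (implicit-midpoint) rule with the driving pressure held constant over
  the step. In replay mode that drive is sampled at the step midpoint,
  which centres the rule and removes its leading-order bias; the valve
  logic remains causal at the step start. The bilinear-transform
  admittance filter (discretize_admittance) is the same rule in
  transfer-function form: on a pressure step its output equals the
  trapezoidal state-space flow averaged over consecutive samples to
  machine precision, and both match the circuit's DC limits exactly.
* Hill + Windkessel coupling solves the auxotonic balance
  2 h (s_iso fv(v) + passive)/r = Pp + Zc kQ v for v by bisection each
  step. An explicit previous-step-velocity coupling is unstable here: its
  discrete loop gain (L_ref/r_ref)(2h/r) sigma_max |fv'| / (Zc 4 pi r^2)
  exceeds unity for physiologic Zc, producing force collapse and valve
  chatter rather than a small lag error. The implicit solve is the same
  device the isotonic controller uses and costs ~50 function evaluations
  per open-valve step.
* Volume is the integrated state (V <- V + inflow - Q dt) and length is
  derived from it, so volume conservation and the cubic length-volume
  identity hold to round-off rather than to integration tolerance.
* Valve events are threshold crossings on the grid; refill onset gets a
  sub-step correction (linear interpolation of the trigger margin) so its
  timing is grid-independent. Ties at P = Pa keep the valve closed,
  avoiding zero-gradient chattering.
* Abrupt parameter changes are deferred to the next diastole by default
  (valve closed and activation below the refill trigger), matching how
  steps are applied between beats experimentally; immediate application is
  a flag. Preset swaps change all three parameters in the same step.

Convergence: halving dt changes every logged signal by less than 0.05% of
its peak, and a replay beat agrees with an independent adaptive
integration (deSolve lsodar with root-triggered valve events, formulated
in different state variables) to about 0.02% of each signal's peak.
Trajectory discrepancies are always measured peak-normalised —
max|x1 - x2| / max|x1| per signal — because pointwise ratios are ill-posed
for signals that are exactly zero through diastole (Q) or cross zero near
valve events.

The arterial energy audit closes the loop bookkeeping: over a periodic
beat, the integral of P Q equals the compliance storage change plus the
dissipation in Zc and Rp to within 0.5% (about 0.02% in practice at
50 us).

## Analysis conventions

Per-beat metrics integrate the logged loop: work as the absolute shoelace
area of the (L, F) path (the signed area is positive for an ejecting beat,
equalling the muscle's boundary work), the stress-length area separately
(the figure-axis convention of the experimental literature; work units in
that literature are ambiguous, so both are emitted), stroke work from the
(V, P) loop, stroke volume as the end-diastolic minus minimum volume
(cross-checked against the flow integral), and the diastolic decay
constant from a log-linear least-squares fit of aortic pressure over the
closed-valve, non-refill window. End-systole is defined as the
valve-closure sample — experimental reports rarely pin this definition down,
and valve closure is both the pressure-volume convention and unambiguous in
simulation. The work-afterload relation is summarised by a degree-2
polynomial fit constrained through the origin, per mode.

## What the tests do and do not show

The test suite and acceptance checks run the generator under the study
conditions above: closed-form circuit limits; the oracle cross-check;
sweeps of Rp (5-50 GPa s m^-3, loop narrowing with decreasing shortening
and stroke volume), C (15-80 pm^3 Pa^-1, loop-area spread under 10%) and
Zc (0.5-15 GPa s m^-3, rising peak shortening-phase force); the abrupt
Rp step 50 -> 500 GPa s m^-3 with its monotone multi-beat transient; the
disease-preset orderings (peak stress hyper > normo > hypo, shortening
reversed); and unimodal work-afterload relations in both loading modes.
Problem sizes are a few tens of beats per run (10^4-10^6 engine steps),
with sweeps capped at 300 beats per value; the whole suite runs in well
under a minute.

Passing these shows the load model and its analysis behave correctly and
reproduce the direction and structure of the experimental phenomenology.
It does not validate the Hill fixture as a model of any particular
muscle: real trabeculae have restitution, history dependence and
temperature sensitivities the fixture deliberately omits, and the
absolute magnitudes of work and shortening depend on fixture parameters
that are conditions of the virtual experiment, not fitted quantities.

## Known limitations

* Thin-wall Laplace sphere with constant wall thickness; no wall
  thinning, thick-wall or finite-element geometry, no spatial
  heterogeneity of load or sarcomere length.
* 3-element Windkessel only; no inertance (4-element) and no
  wave-propagation (complex Zc) effects.
* Kinematic refill; no atrial kick, preload protocols or valve
  regurgitation.
* Memoryless activation; no force-calcium coupling, restitution or
  energetics.
* The replay mode's prescribed force is invariant with shortening by
  design, so its loops are load-shaped only; closed-loop muscle behaviour
  requires the Hill fixture.
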