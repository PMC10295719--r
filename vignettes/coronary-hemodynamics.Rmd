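---
title: "Modelling coronary hemodynamics under aortic valve disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coronary hemodynamics under aortic valve disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

corovalve is a desk-scale simulator for the question of how aortic valve
disease reshapes blood flow in the large coronary arteries. It combines four
ingredients into one closed-loop model system: a lumped-parameter (0D)
circulation with a time-varying elastance heart, an effective-orifice-area
(EOA) parameterization of the aortic valve that expresses stenosis and
regurgitation as geometry, a three-layer model of the intramyocardial
vessels compressed by tissue pressure, and a flow-autoregulation controller
that retunes the coronary microcirculation when the myocardium's oxygen
demand changes. A distributed segment model of the proximal LAD (left
anterior descending artery) is coupled to the loop through an explicit
partitioned boundary-exchange algorithm and provides the waveforms from
which velocity-time integrals, Fourier harmonics, and wall-shear metrics
(TAWSS, OSI) are computed.

This vignette explains the model, the choices behind its defaults, what the
synthetic study conditions do and do not represent, and the numerical
decisions that make the explicit integration robust.

## The closed-loop 0D model

The circulation is a network of compartments, each characterised by a
viscous resistance R (mmHg s/mL), a compliance C (mL/mmHg) and, where blood
momentum matters, an inertance L (mmHg s²/mL). Every compliance stores a
volume `V` with pressure `V/C`, every chamber obeys the elastance relation
`P = E(t) (V - V0)`, and the governing equations are ordinary differential
equations: each stored volume changes by net inflow minus outflow, each
inertial flow accelerates under its net pressure difference. Because every
flow leaves one compartment and enters another, total blood volume is
conserved to round-off by construction — a property the test-suite checks to
below 1e-6 mL per cycle.

The topology is deliberately minimal: four chambers; an aortic root node;
upper-body and lower-body systemic branches, each artery → capillary → vein;
a pulmonary artery → capillary → vein chain; and three coronary branches
(LAD, LCX, RCA). The mitral, tricuspid and pulmonary valves are resistive
diodes; the aortic valve carries the full orifice model described below.
State integration uses the classical explicit fourth-order Runge-Kutta
method at a fixed step of 1 ms (both verified properties: empirical order at
least 3.9 on smooth problems, periodic steady state within 20 cycles at the
defaults).

### Elastance activation

Chamber contraction is driven by a normalized activation that rises from 0
to exactly 1 and back within an activation window. We use a two-limb cosine
pulse whose upstroke is `0.5 (1 - cos(pi sqrt(t/tp)))`: the square-root
argument gives a near-linear foot, so isovolumic pressure builds briskly (as
it does with the power-law foot of Hill-type activations), while the exact
floor and ceiling keep the elastance bounds `E_min <= E(t) <= E_max` sharp.
The relaxation limb is a plain raised cosine. The ventricular peak sits at
61.5% of a 0.61 s activation window (cycle length 0.8 s), which yields an
ejection time near 0.25 s and a physiological isovolumic phase; the atria
are activated late in diastole (onset 0.61 s) to provide the atrial kick.

### The aortic valve

The trans-valvular pressure drop is
`dP = R Q + B Q|Q| + L dQ/dt`, with the three coefficients computed from
geometry: `R = 8 aR pi mu l / EOA^2` (viscous), `B = (aB rho / 2) (1/EOA -
1/Ado)^2` (flow-separation loss into the outflow tract of area `Ado`), and
`L = (2 aL rho / sqrt(pi)) (1/sqrt(EOA) - 1/sqrt(Ado))` (orifice inertia);
the coefficients `aR = 0.01, aB = 1, aL = 1`. The Bernoulli term is written
sign-preserving (`Q|Q|`), so a reversed jet loses energy the same way. A
healthy valve has systolic EOA equal to the 4 cm² outflow tract — hence zero
separation loss — and seals completely in diastole. Severe stenosis (AS)
reduces the systolic EOA to 1 cm² (25% of normal); severe regurgitation (AR)
leaves a 0.3 cm² diastolic orifice.

Opening and closing are a state machine advanced once per time step: the
valve opens when ventricular pressure exceeds root pressure and the EOA
ramps up linearly over 5 ms (the growing orifice inertia makes the flow
build smoothly); a competent valve seals the instant flow reverses during
pressure decay — at that trigger the flow is essentially zero, so the drop
stays continuous — while a regurgitant valve ramps down to its diastolic
orifice and keeps conducting. In series with the orifice sit a root
characteristic impedance (0.053 mmHg s/mL) and outflow-tract blood inertance
(0.004 mmHg s²/mL); clinical aortic pressure is read proximal to that
impedance (`p_ao_root` in the traces), the standard input point of a
three-element windkessel. The coronary ostia also sit there, in the sinus
pockets, so their driving pressure carries the forward-wave component of
ejection.

### Three-layer coronary branches and the intramyocardial pump

Each branch splits into three parallel intramyocardial layers —
subepicardium, mid-wall, subendocardium — whose outer walls feel a tissue
pressure `P_im = gamma * max(P_chamber, 0)` with `gamma` increasing linearly
across the wall (defaults 0.102, 0.537, 0.972; the left ventricle drives the
LAD and LCX layers, the right ventricle the RCA). Each layer is an
arteriolar inflow resistance (the quantity the autoregulation controller
scales), a compliance referenced to `P_im`, and a venular outflow
resistance. In systole the deep layers are squeezed: stored volume is
expelled backwards and forwards, inflow collapses or reverses in the
subendocardium, and the branch inflow becomes diastolic-dominant — the
intramyocardial pump. The arteriolar share of each layer path is 39% with a
mild transmural resistance gradient (subendocardial arterioles slightly
wider), and layer compliances are a few hundredths of mL/mmHg; these values
were fixed by the reference calibration described below.

An epicardial stenosis can be added to any branch as a diameter-stenosis
element: the throat area scales as `(1 - DS)^2`, adding the Poiseuille
resistance of the narrowed throat and a separation loss of the same
`B Q|Q|` form as the valve orifice.

### Autoregulation

Resting coronary flow is regulated toward a perfusion pressure-flow (P-Q)
curve: a rising limb from (20 mmHg, 0.3) to the autoregulatory plateau at
normalized flow 1.0 between 60 and 140 mmHg, rising again above it.
Normalized flow 1.0 corresponds to each branch's reference resting flow
(1.27, 0.91, 1.14 mL/s for LAD, LCX, RCA). After each pair of cardiac cycles
the controller compares cycle-mean branch inflow with the target and updates
the arteriolar resistance multiplier by linear negative feedback,
`m <- m (1 + G (Q/Q_target - 1))` with gain `G = 0.5`, tolerance 1%, at most
50 iterations, multipliers clamped to the physiological dilation range
[0.1, 10]. On a fixed-pressure Ohmic branch this iteration contracts
monotonically to the exact fixed point `R* = P/Q_target`.

Valve disease raises myocardial oxygen demand. That long-term effect is
represented by shifting the P-Q curve's flow axis up multiplicatively by the
ratio of diseased to control pressure-volume area (PVA = stroke work plus
the end-systolic potential energy triangle), measured from the left
ventricular loop of a settled run of each scenario. A multiplicative shift
is one of two defensible readings of a "demand-proportional" shift; we use
it because it preserves the curve's shape and keeps the plateau flat. With
the defaults the demand shift is about 1.13 under severe AS and about 1.8
under severe AR (volume overload roughly doubles stroke work), raising
resting LAD flow by 13% and 31% respectively after the controller settles.

### The distributed segment and partitioned coupling

The proximal LAD segment — the region of interest that a patient-specific
3D model would occupy — is a chain of 20 compartments over 60 mm with a
1.5 mm lumen radius, each carrying its slice's Poiseuille resistance and
blood inertance. The wall is rigid; a numerical nodal capacitance of 1e-6
mL/mmHg makes the imposed flow-in / pressure-out boundary pair solvable. The
segment advances by an implicit backward-Euler step (Thomas algorithm on the
nodal pressures, Picard-linearized separation losses), because the nodal
relaxation times (~4e-8 s) are far below anything an explicit method could
resolve — exactly the position of a CFD solver inside a multi-scale model.

Coupling is partitioned and staggered: at each shared 1 ms step the closed
loop's current solution sets the segment's inlet flow and outlet pressure;
the segment is advanced; its computed inlet pressure and outlet flow come
back as boundary data for the closed loop's Runge-Kutta step to the same
time level. Two refinements keep this explicit exchange accurate and
stable. First, the segment's series inertance (0.067 mmHg s²/mL) exceeds
the proximal 0D inertance, which makes the naive exchange unconditionally
unstable (the classic added-mass instability of partitioned schemes); the
segment's fixed inertance therefore lives inside the 0D momentum equation,
and the segment feeds back the quasi-static (resistive) part of its drop.
Second, the imposed outlet pressure is extrapolated half a step forward
from its previous increment so the fast distal node does not lag the
exchange. Neither change alters which quantities are exchanged or their
ordering, and the per-step interface log still records the raw computed
inlet pressure. Convergence is declared when the cycle-to-cycle relative
errors of both sub-models' mean flows drop below 0.1%; warm-started from a
settled lumped run this takes two cycles in all three scenarios, and against
a monolithic run with the segment replaced by its lumped equivalent the
coupled inlet-pressure trace agrees to well within 1% pointwise.

## Waveform analytics

One steady-state cycle is post-processed into the indices used to compare
scenarios:

* **Velocity-time integrals.** Segment-inlet velocity is the cross-sectional
  mean `v = Q / (pi r^2)`. VTIS integrates it over mechanical systole — from
  mitral closure (the ventricular-atrial pressure crossover) to aortic valve
  closure, both exported by the simulator — and VTID over the rest of the
  cycle; their ratio is the S/D ratio. We use mechanical rather than
  ejection-only systole because stenosis lengthens ejection, and an
  ejection-only window would mechanically inflate the stenotic VTIS.
* **Fourier harmonics.** The inlet flow over exactly one period is written
  as `Q0 + sum Qn sin(n w t + psi_n)` via the FFT; moduli are phase-origin
  invariant, and at the Nyquist limit the spectrum satisfies Parseval's
  identity to 1e-9 (the even-length Nyquist bin carries full weight).
* **Wall shear.** The stand-in segment uses the Poiseuille closure
  `tau = 4 mu Q / (pi r^3)`, signed by flow direction. TAWSS is the
  time-average of `|tau|`; OSI is `0.5 (1 - |mean tau| / mean |tau|)`,
  0 for unidirectional shear and 0.5 for zero-mean reversal. Space-averaged
  values (SA-TAWSS, SA-OSI) average the per-compartment metrics along the
  segment.

## Calibration: the reference configuration and the Nelder-Mead re-fit

The package ships a *reference configuration* (`cv_config()` defaults) whose
resting control behaviour reproduces the published operating point of this
model class: cardiac output near 4.9 L/min, aortic pressure near 115/75
mmHg, mean branch flows near 1.26/0.89/1.13 mL/s, and the scenario S/D
triple near 0.26 / 0.13 / 0.46. Because the systemic and coronary
compartment constants of such models are never fully identifiable from six
resting summaries, the defaults were fixed once, during development, by a
simplex search over the model-shape parameters (activation timing,
transmural gamma gradient, layer compliances, arteriolar/venular split, root
impedance, stressed volume, systemic resistance scale) against those
published values — the same role literature-value assignment plus tuning
plays when such models are built from scratch. They are study conditions,
not per-run knobs.

`calibrate()` then re-fits a small set of multiplicative free parameters
(systemic capillary resistances, an arterial compliance scale, ventricular
contractilities, per-branch coronary resistance scales) by Nelder-Mead on
the root-mean-squared relative error of the six resting summaries against
population in vivo means (CO 5.19 L/min, 113/74 mmHg, branch flows
1.27/1.14/0.91 mL/s). The multipliers are constrained to ±15% of the
reference values: the fit is meant to *slightly tune* a physiological model,
and unconstrained simplex runs drift into degenerate contractility trades
that leave the six summaries nearly unchanged while distorting the waveform
physics. After the simplex, the flow controller trims the branch multipliers
so the coronary means track their targets within 1%. Total stressed blood
volume is deliberately not a free parameter; with preload fixed, cardiac
output saturates near 4.9-5.0 L/min even though the population target is
5.19 — the same structural residual the published model shows.

Scenario studies (`run_study()`) are run on the reference configuration.
Re-running them on a freshly re-fitted configuration moves the
waveform-sensitive indices by a few hundredths (the AS S/D ratio is the most
sensitive, since its systolic suppression sits near a flow-reversal
threshold); the reference configuration is the package's published
calibration and the basis of the reported scenario indices.

## What the three scenarios show

```r
library(corovalve)
study <- run_study(cv_config())
study$comparison
```

Under severe AS the ventricle generates a mean systolic gradient of ~13
mmHg (peak tens of mmHg), the systolic portion of the P-V loop shifts
upward, systolic coronary inflow is suppressed by the intensified squeeze
while autoregulatory dilation boosts diastolic inflow: VTIS falls by a
third, VTID rises, the S/D ratio halves to ~0.13, and the low-frequency
harmonics of the inlet waveform grow (harmonic-1 modulus roughly doubles) —
with correspondingly higher segment OSI. Under severe AR the stroke volume
roughly doubles, aortic diastolic pressure collapses toward 45-50 mmHg,
systolic coronary flow is augmented while diastolic flow is limited by the
low perfusion pressure, and the S/D ratio rises to ~0.46 with the smallest
harmonic-1 modulus of the three scenarios. Resting mean LAD flow is highest
under AR, then AS, then control, following the PVA-based demand shift.

One qualitative index departs from the published 3D study: segment OSI
under AR. In a three-dimensional artery the control-condition OSI baseline
comes from secondary flows and local geometry, and AR's flattened waveform
lowers it. The one-dimensional Poiseuille closure of the stand-in segment
has no such baseline (control OSI is ~0.005), while severe regurgitation
produces an early-systolic backflow lobe — the intramyocardial squeeze
outruns the depressed early-systolic root pressure — that raises the
segment OSI to ~0.24. The AS > control half of the OSI ordering is
reproduced; the AR < control half is a recognised limitation of a 1-D shear
closure, not of the coupling or the flow model.

## Numerical choices and degenerate inputs

* Fixed step 1 ms for both sub-models; the period must be an integer
  multiple of the step (validated to one part in 1e6).
* Valve transitions happen at step boundaries; the EOA is piecewise
  constant within a step, which keeps the Runge-Kutta stages consistent.
* An EOA evaluation floor of 0.02 cm² guards the opening ramp; a fully
  closed competent valve enforces exactly zero flow rather than evaluating
  the orifice formulas at zero area.
* The algebraic `R + B Q|Q|` elements (branch stenoses) are solved in
  closed form (sign-preserving quadratic), so no iteration is needed in the
  right-hand side.
* Divergence (any pressure beyond 1000 mmHg) and non-finite states abort
  with the offending time; the segment solver aborts with the offending
  compartment.
* Zero shear waveforms define OSI = 0 with a warning; a zero diastolic
  integral makes the S/D ratio an error rather than an infinity.
* Controller safeguards: if the flow error grows three iterations running,
  the gain is halved; multipliers clamp to [0.1, 10] with a warning.

Problem sizes used throughout the packaged tests and scripts: 800 steps per
cycle, 10-30 cycles per run, two-cycle controller iterations, 20-compartment
segment. A full three-scenario coupled study takes a few seconds on one
core; the Nelder-Mead re-fit takes a few seconds more.

## Limitations

The generator of study conditions emulates a resting adult with fixed heart
rate 75 bpm; baroreflex and other neural control, ventricular interaction,
valve leaflet dynamics, collateral flow, and patient-specific geometry are
out of scope. The segment is a straight rigid tube: spatial WSS
heterogeneity, secondary flow, and therefore absolute OSI levels are not
represented — passing waveform-level tests here says nothing about spatial
shear maps in real arteries. Severity presets are fixed (EOA 1.0 cm²
systolic for AS, 0.3 cm² diastolic for AR); mixed or graded disease is a
matter of configuration, not of validated presets.
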