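---
title: "Force balance in the metaphase spindle with a bridging fibre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force balance in the metaphase spindle with a bridging fibre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgefibre)
```

## The model

During metaphase, each kinetochore is attached to a bundle of microtubules
(a k-fibre) reaching to a spindle pole, and sister kinetochores are under
tension. A bundle of overlap (non-kinetochore) microtubules — the bridging
fibre — runs between and alongside the sister k-fibres, linking them
laterally. `bridgefibre` models one half of this system as three slender
elastic rods in a plane:

* rod **p** from the spindle pole at the origin to a junction at
  $(x_j, h_j)$, representing the merged k-fibre plus bridging-fibre bundle;
* rod **k** from the junction to the kinetochore at $(x_k, h_k)$;
* rod **b** from the junction to the spindle midplane at $(L/2, h)$, the
  central antiparallel segment of the bridging fibre.

The other half follows by reflection about the midplane. Each rod obeys the
Euler–Bernoulli relation between curvature and bending moment; in Cartesian
form, with $y(x)$ the height above the pole-to-pole axis,

$$\kappa_i \, y'' = M_i(y)\,\bigl(1 + y'^2\bigr)^{3/2}, \qquad
  i \in \{p, k, b\},$$

with affine bending moments

$$M_p = m_0 + a_0\,y, \qquad
  M_k = -a_k\,(y - h_k), \qquad
  M_b = (a_k + a_0)\,y - a_k h_k + m_0 .$$

The identity $M_b = M_p - M_k$ holds for all $y$; it expresses moment
balance at the junction and is asserted numerically in the test suite.

**Sign convention.** The package reports loads as the forces the fibre
system exerts on its anchors: `F0_pN` is the inward force at the pole and
`Fk_pN` the poleward pull felt by the kinetochore (the interkinetochore
tension). In the moment coefficients these enter as
$(a_0, a_k, m_0) = (-F_0, +F_k, -M_0)$. This is the unique sign assignment
under which the model behaves as the biology requires: rod p flattens from
its steep pole angle instead of curling vertical, a pole-force root of the
midplane-symmetry condition exists at forces of a few tens of piconewtons,
and that root increases smoothly with the number of bridging microtubules.
The statically fully consistent alternative (both forces entering with the
same sign) admits no such regime; the choice is a documented convention of
this package.

**Rigidities.** Bundle rigidity is additive over microtubules,
$\kappa_i = n_i \kappa_0$ with $\kappa_0 = 30\ \mathrm{pN\,\mu m^2}$ per
microtubule by default, and $n_p = n_k + n_b$, appropriate when
microtubules may slide within the bundle. A fully crosslinked scaling
$\kappa_i \propto n_i^2$ is available via
`fibre_architecture(..., coupling = "crosslinked")` but is not used by any
default or calibration.

## Forward problem and integrator

Given loads and a junction position, rod p is integrated from
$(0, 0)$ with slope $\tan\theta_0$; rods k and b continue from its endpoint
with continuous position and slope (the rods are clamped and tangential at
the junction). The integrator is the explicit midpoint rule (second-order
Runge–Kutta) with a fixed step $\Delta x = (x_f - x_i)/50$ per rod — 50
steps is the model's reference discretisation, configurable via `n_steps`.
The test suite checks the endpoint against an adaptive high-order solver
(`deSolve::lsoda` at tolerances of $10^{-11}$) to within 0.1%, and that
halving the step changes endpoints by well under 0.5%. A slope bound of
$\tan 89^\circ$ guards the graph parameterisation; exceeding it raises a
parameterisation-breakdown error rather than returning garbage.

## Inverse problem

The measured inputs are the spindle geometry ($\theta_0$, $L$, $x_k$,
$h_k$, $\theta_k$) and the microtubule counts; the unknowns are $F_0$,
$F_k$ and $x_j$ ($M_0$ is fixed to zero by default — it trades off against
$F_0$ and must never be freed simultaneously). Three conditions close the
system:

1. reflection symmetry at the midplane, $y_b'(L/2) = 0$;
2. the kinetochore height, $y_k(x_k) = h_k$;
3. the k-fibre angle at the kinetochore, $|\arctan y_k'(x_k)| = \theta_k$.

`solve_force_balance()` eliminates $F_0$ through condition 1 at every
evaluation — a robust one-dimensional root in $F_0$ — and runs a damped
Newton iteration on conditions 2–3 over $(F_k, x_j)$, from a fixed grid of
nine starting points. Residuals are weighted by the measurement spreads of
the constraints (0.7 µm for $h_k$, 10.1° for $\theta_k$); the weighting is
irrelevant when an exact root exists and otherwise turns the same iteration
into a least-squares fit, reported with `converged = FALSE` and the
residuals as diagnostics. Convergence requires residuals below $10^{-3}$
µm and $10^{-3}$ rad.

**Branch choice.** The angle constraint fixes only $|y'|$ at the
kinetochore. The solved branch has $y_k'(x_k) > 0$: the k-fibre is still
rising at the kinetochore and the bridging fibre passes beneath it, which
is the configuration compatible with midplane symmetry — on the descending
branch the bridge moment reverses sign above the junction and no flat
midplane exists. The branch is configurable
(`solver_control(slope_branch = -1)`).

**Identifiability.** The pole force is well determined: it is pinned by
rod p's geometry between the pole and the junction. The kinetochore
tension, and with it the junction position, are only weakly identified:
rod k is short and nearly straight, so $h_k$ and $\theta_k$ respond to
$F_k$ only through its small curvature, and solutions form a long ridge
along which $(F_k, x_j)$ co-vary with almost no observable effect.
Round-trip experiments in the test suite recover $F_0$ to a few percent
while $F_k$ can land far from its generating value at equal residuals.
Reported tensions should therefore be read as representative points on
this ridge, not as sharp estimates — consistent with treating the tension
and junction position as the least constrained quantities of the analysis.

With measured (rather than model-generated) constraints, conditions 1–3
are generally not exactly compatible: matching $h_k$ and $\theta_k$ pins
the pole force near 40 pN while a perfectly flat midplane wants a slightly
different junction state, leaving height/angle residuals of a fraction of
their measurement spreads. The solver then reports the weighted best fit
on the symmetry manifold. This is the behaviour on the package's reference
geometry; `reproduce_analysis()` records the residuals alongside the
values.

**Sweep.** `sweep_pole_force()` holds $F_k$, $x_j$ and $M_0$ fixed and
solves only condition 1 for $F_0$ at each bridging-fibre count $n_b$ —
here $\theta_k$ and $h_k$ are outputs. Multiple symmetry roots can exist;
the sweep keeps the root closest to the previous $n_b$ for continuity. The
$n_b = 0$ case is singular (a rigidity-free bridge carries no moment); its
surviving condition is that the junction height equal the zero of the
bridge moment, $h_j = a_k h_k / (a_k + a_0)$, again a one-dimensional root
in $F_0$. Continuity of the sweep across $n_b \to 0$ is a test.

## Quantification layer

The measurement procedures operate on extracted data, not images:

* **Intensity ratios.** A scan between sister kinetochores measures the
  bridging-fibre signal $I_b$; a scan across the k-fibre 1 µm from the
  kinetochore measures $I_{bk} = I_b + I_k$. After subtracting the mean
  cytoplasmic background (explicit value or profile flanks), peak areas
  are trapezoidal integrals over a window centred on the selected peak —
  the local maximum nearest the expected position with prominence at least
  twice the flank noise s.d. (the prominence rule is a package default;
  none is prescribed by the procedure itself). Default window widths are
  the typical peak base widths, 0.6 µm (bridge) and 1.0 µm (k-fibre). The
  ratio $r = I_b/I_{bk}$ converts to $I_b/I_k = r/(1-r)$ and to a count
  $n_b = \mathrm{round}(n_k\, r/(1-r))$, rounded half away from zero with
  the unrounded value attached.
* **Tracks.** Sister tilt, interkinetochore distance and its relaxation
  $d_k(t_\mathrm{cut}) - d_k(t_\mathrm{cut}+4\,\mathrm{s})$, perpendicular
  displacement (signed positive away from the spindle axis), and stub
  length are plain Euclidean geometry against an explicitly supplied
  spindle axis; all are invariant under rigid transforms applied jointly
  to track and axis (tested). Times are matched to the nearest acquired
  frame within one frame interval — acquisition intervals in the calibrated
  regime are 3.5–4.5 s, so "4 s after the cut" is the adjacent frame.
* **Contour angles** come from a total-least-squares line through three
  consecutive contour points (~250 nm apart), folded into $[0°, 90°]$.

## Synthetic data

The generator emulates the population statistics of the measured system so
the whole pipeline is testable without microscopy:

* `sample_geometry()` draws truncated-normal geometry per cell from the
  tabulated means and s.d. (HeLa and PtK1), independent across parameters
  (no covariances are reported), with $x_k = L/2 - d_k/2$.
* `generate_intensity_profile()` builds Gaussian-peak scans whose analytic
  areas satisfy the programmed ratio exactly; peak s.d. is a quarter of
  the base width, sampling step 81 nm, defaults: background 20 a.u.,
  noise s.d. 2 a.u.
* `generate_cut_response()` programmes per-cell kinematics: linear rise of
  the outward excursion to a cell-specific peak (population mean 0.32 µm
  at 11 s) followed by exponential return (time constant 15 s, matching
  the delay before poleward stub transport); linear contraction of the
  interkinetochore distance over 4 s to a relaxed value set by a logistic
  step in stub length centred at the 1 µm transition (plateaus 0.25 and
  0.05 µm, steepness 0.2 µm — the transition location is measured, the
  functional form is a package choice); and a sister tilt ramp per
  bridging-fibre class. Between-cell spreads are the reported s.e.m.
  values scaled by $\sqrt{n}$ of the cohort; positional noise is 25 nm
  per coordinate per frame (typical centroid-tracking precision); frames
  every 4 s. Default stub lengths are log-normal with median at the
  transition length, which centres the cohort mean relaxation at 0.15 µm.
* `generate_comet_events()` draws homogeneous Poisson event streams per
  direction class with Gaussian velocities (defaults 13.1 ± 1.1 µm/min).

Every generated object carries its programmed truth (as attributes or a
`truth` list) so tests can compare measurement against ground truth. What
the generator does **not** emulate: point-spread blur and pixelation,
photobleaching, z-projection effects, correlated cell-to-cell covariance,
kinetochore oscillations superimposed on the cut response, and tracking
dropouts. Passing calibration tests therefore demonstrates that the
quantification layer is correct on data with the reported population
statistics, not that it is robust to every imaging artefact.

## Numerical choices and edge cases

* Units: µm, pN, pN·µm² and degrees at the interface; radians internally.
* 50 midpoint steps per rod; tolerances $10^{-3}$ µm / $10^{-3}$ rad;
  multistart grid $F_k \in \{100, 300, 500\}$ pN,
  $x_k - x_j \in \{0.5, 1.0, 1.5\}$ µm.
* Newton steps along the nearly flat $F_k$ direction are capped at 70% of
  the current scale, and the line search demands a non-negligible decrease
  to stop flat-valley drift.
* `predict_cut_outcome()` ties (stub length exactly equal to the junction
  distance) classify as `tension_lost`: retaining the connection requires
  overlap strictly beyond the junction.
* Degenerate inputs raise typed errors: zero-rigidity rods with non-zero
  moment, near-vertical slopes, coincident contour points, missing frames
  beyond one interval.
* All stochastic generators take an explicit `seed`; equal seeds give
  byte-identical output.

## Limitations

The model is static and planar: no microtubule dynamics, no motor or
crosslinker mechanics at the junction, no viscoelastic relaxation after
severing — the cut response enters only through the calibrated generator,
and the before/after force balance through `predict_cut_outcome()`. The
kinetochore tension is structurally weakly identified from shape data (see
above), so downstream use of `Fk_pN` should propagate that caveat. The
reference problem sizes used in tests and in `reproduce_analysis()`
(cohorts of ~100 cells, sweeps over ~7 thickness values, 20 recovery
draws) are the package's default study conditions and run in minutes on a
single core.
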