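---
title: "Electro-thermal dosimetry for high-frequency nanosecond pulse bursts: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electro-thermal dosimetry for high-frequency nanosecond pulse bursts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulseheat)
```

pulseheat simulates the thermal side effects of irreversible
electroporation (IRE) protocols that deliver bursts of nanosecond pulses:
a 100 µs train of 50–500 ns rectangular pulses at 100 kHz–1 MHz intra-burst
repetition, 1–4 kV between two parallel needle electrodes inserted into a
1 cm liver tumor. The clinical question behind the model is whether such a
burst heats the tissue enough to cause thermal damage on top of the
intended (non-thermal) electroporation effect, and which corner of the
(voltage, pulse width, repetition rate) space stays below a 44 °C safety
limit.

## Model

Three coupled pieces:

1. **Quasi-static electric field.** On the time scale of a pulse the
   tissue behaves resistively, so the potential obeys
   $-\nabla\cdot(\sigma\nabla\varphi) = 0$ with $\varphi = V$ on one
   electrode–tissue interface, $\varphi = 0$ on the other, and zero normal
   current on all outer boundaries. The field magnitude
   $E = |\nabla\varphi|$, current density $J = \sigma E$ and Joule heating
   $Q = \sigma E^2$ follow pointwise.

2. **Two-state conductivity with thermal drift.** Electroporation is
   modelled as a step: wherever $E$ reaches the IRE threshold of
   800 V/cm, the conductivity switches from its baseline (liver
   0.067 S/m, tumor 0.135 S/m) to its electroporated value (0.241 and
   0.426 S/m) and stays there — poration is irreversible within a burst.
   Both states carry a linear temperature coefficient of 1.5 %/°C about
   37 °C. Because switching σ redistributes the field, the switch is
   iterated to a fixed point: solve, evaluate $E$, grow the porated set,
   re-solve, until the set is stationary (the set can only grow, so the
   iteration terminates; `porate_maxit = 1` recovers single-pass
   behaviour for sensitivity checks). At 4 kV the fixed point porates the
   whole tumor in a handful of iterations.

3. **Pennes bioheat with Arrhenius damage.** Tissue temperature follows
   $\rho c\,\partial T/\partial t = \nabla\cdot(k\nabla T)
   + \rho_b c_b \omega_b (T_b - T) + Q_m + Q_{\text{gated}}$, with the
   perfusion term written as a sink toward the arterial temperature
   $T_b = 37$ °C — the standard Pennes form. (A perfusion term with the
   opposite sign, $+\rho_b c_b \omega_b(T - T_b)$, appears in some
   transcriptions of the equation; it makes blood perfusion heat tissue
   without bound and is physically untenable. The solver flag
   `printed_perfusion_sign` restores it for sensitivity checks and the
   test suite demonstrates the runaway.) Thermal damage accumulates as
   the Arrhenius integral
   $\Omega(t) = A\int_0^t \exp(-E_a/(R\,T_K))\,\mathrm{d}t$ with
   protein-coagulation kinetics ($A = 7.39\times10^{39}$ 1/s,
   $E_a = 2.577\times10^5$ J/mol) by default; microvascular-stasis and
   cell-death kinetics ship as presets. The kill probability is
   $P(\%) = 100(1 - e^{-\Omega})$, so $\Omega = 1$ means 63 % and
   $\Omega = 4.6$ means 99 %; $\Omega = 0.53$ is used as the damage
   threshold.

The pulse train enters only through the Joule source: in `exact` mode the
source is gated pulse-by-pulse; in `averaged` mode it is scaled by the
duty cycle (pulse width × repetition rate) and applied continuously.
Because a single 500 ns pulse raises the hottest voxel by well under
0.1 °C, the two modes agree to within one single-pulse increment — a
property the test suite asserts — and sweeps default to `averaged`.

## Geometry and its one open choice

The domain is a 10 cm × 10 cm liver cylinder with a 1 cm spherical tumor
at its centre, two 1 mm needles 5.4 mm apart and a 6 mm energised
segment. A 6 mm insertion from the liver surface cannot reach a tumor at
mid-height, so the 6 mm figure is read as the *active* (bare) electrode
length, placed symmetrically about the tumor's equatorial plane, with the
needle continuing to the surface as insulated shaft. This placement is
isolated in one function (`build_grid`'s labelling block) so alternative
readings are one-line changes.

## Discretisation

COMSOL-style tetrahedra are replaced by a tensor-product voxel grid,
graded per axis: fine spacing (default 0.3 mm) in windows around the
needle cross-sections and the active segment, an intermediate 1 mm over
the tumor bounding box, growing geometrically (adjacent-cell ratio
≤ 1.5) to 3.5 mm in the far field. Mirror-symmetric window sets produce
mirror-symmetric axes, so the default grid is exactly symmetric under
y → −y. Voxels are labelled by centre containment, testing the needle
cylinders first, then the tumor sphere, then the liver cylinder.

Both the electric and the thermal problem use the same 7-point
finite-volume stencil with harmonic averaging of the cell coefficient
across faces (exact for layered 1-D profiles; the two-layer slab fixture
checks the |E₁|/|E₂| = σ₂/σ₁ relation to solver precision). Electrode
interiors are equipotential bodies excluded from the solve — Dirichlet
values act on the electrode-adjacent tissue faces through half-cell
conductances — which sidesteps the electrode's own (enormous)
conductivity. The insulating sheath, four to five orders of magnitude
less conductive than tissue, is treated as a zero-current boundary of
the electric problem; the relative error of that idealisation is of
order σ_ins/σ_tissue ≈ 10⁻⁴. Linear systems are solved by
Jacobi-preconditioned conjugate gradients (relative residual 10⁻⁸) on
fixed-offset stencil arrays.

Cell fields are reconstructed Green-Gauss style: each component of
**E** is the difference of the two face potentials across the full cell
width, with flux-consistent (conductance-weighted) interface values.
This makes the uniform and layered slab solutions exact and gives the
reconstruction an averaging support of one cell — the property that
matters most below.

## What "peak temperature" means here

The flat-tipped needle ends in a re-entrant conductor edge at which the
continuum field — and therefore the 100 µs temperature rise — diverges.
No pointwise maximum over the tumor volume can converge under grid
refinement; any finite value is set by the discretisation scale, in this
package by the fine voxel size, in a finite-element model by the local
element size. The refinement study in the test suite (and available via
`grid_convergence`) shows exactly this: the volume maximum grows
monotonically as the grid is refined, while the maximum over the tumor's
*equatorial cross-section* — the plane all the reference spatial maps are
drawn on, several needle radii away from the tip edge — changes slowly
and proportionally to the step size.

`simulate_burst` therefore reports both: `t_max_100us` / `t_max_1s` /
`omega_max_1s` are the equatorial-plane maxima and are the headline
dosimetric observables used by the sweep, the fit and the safe-envelope
extraction; `tumor_peak_100us` / `tumor_peak_1s` are the volume maxima,
reported for completeness with the explicit caveat that they are
tip-edge-limited. The default 0.3 mm fine spacing was chosen as the
package's resolution scale: it is commensurate with the 0.4 mm smallest
elements of the reference finite-element model, and the convergence
report shows the plane observable moving by about 1 °C per 0.1 mm of
refinement at the highest-energy operating point — the honest
uncertainty to attach to any peak value quoted from this class of model.

## Time integration

The burst phase uses explicit forward Euler at the reference step of
10 ns — five orders of magnitude below the diffusion stability limit at
0.3 mm cells, so stability is asserted but never binding; the point of
the small step is resolving the pulse gating in `exact` mode. The
electric field is re-solved (warm-started, with the porated mask carried
forward) whenever the temperature anywhere has drifted more than 1 °C
(`refresh_dT`) since the last solve, which bounds the σ(T) lag error at
1.5 % in σ. The cooling phase (burst end → 1 s) integrates with implicit
backward Euler at 1 ms with the Joule source off; with sources off and
insulated boundaries this scheme conserves the discrete thermal energy
exactly (to solver tolerance), which the suite checks at 10⁻¹⁰ relative
per step.

Damage is accumulated trapezoidally alongside the integration — at a 1 µs
macro-step during the burst (the temperature is smooth on that scale;
evaluating the Arrhenius exponential per 10 ns step would dominate the
run time for no accuracy gain) and at every 1 ms step during cooling.
Streaming accumulation equals batch integration to machine precision,
and halving the step on a smooth series shrinks the error fourth-fold
(second-order trapezoid), both property-tested.

## Sweep, fit and safe envelope

`run_sweep` runs one burst per lattice point over voltages {1, 2, 3,
4} kV, widths {50, 100, 250, 500} ns and rates {100, 250, 500,
1000} kHz — 64 combinations, each with duty cycle ≤ 0.5 — reusing one
grid and caching per-point rows on disk when a cache directory is given.
The responses are, to good approximation, linear in pulse width and
repetition rate and quadratic in voltage (the deposited energy per burst
is duty × V²× burst length, modulated only by the poration extent and
the σ(T) drift), so `fit_power_law` fits the single-coefficient law

  T ≈ 37 + a · p_w · f · V²   (p_w in ns, f in kHz, V in volts)

through the fixed 37 °C intercept by least squares. The fixed intercept
matches the functional form the coefficient is quoted in; a free
intercept would trade bias in `a` against the (physically pinned)
baseline. R² is computed about zero rise, the natural reference for a
through-origin fit.

Contours and the 44 °C surface interpolate the *response*, not nearest
neighbours: linearly in pulse width and rate, and in V² for voltage, so
under the law above the interpolation is exact (a product a·p_w·f·V² is
trilinear in (p_w, f, V²)). Where the response never reaches the limit
inside the sweep range the combination is reported `"unbounded"` rather
than raising an error. Multi-burst prediction multiplies the single-burst
rise by the burst count N; since each real burst starts from a partially
cooled field, that is an upper bound, trustworthy only for small N.

Problem sizes used by the shipped tests and the acceptance script, chosen
to keep a desk-scale reproduction faithful: the headline single-burst run
uses the default grid (0.3 mm fine spacing, ≈ 2.3 × 10⁵ voxels); the
64-point sweep and the envelope boundaries use a 0.35 mm sweep grid
(≈ 1.2 × 10⁵ voxels) whose highest-energy point agrees with the default
grid to about 0.2 °C; analytic fixtures run on slabs and blocks of a few
hundred voxels.

```{r example}
scn <- default_scenario(voltage = 4000, pulse_width = 500, rep_rate = 1000)
br <- simulate_burst(scn, mode = "averaged")
br
sg <- build_grid(scn$geometry,
                 grid_spec(fine_h = 3.5e-4, tumor_h = 1.2e-3,
                           coarse_h = 5e-3, fine_margin = 8e-4))
sw <- run_sweep(scn, grid = sg)   # the 64-point lattice
fit_power_law(sw, "t_max_100us")
threshold_contour(sw, free = "rep_rate",
                  fixed = list(voltage = 4000, pulse_width = 500))
```

## What the fixtures do and do not show

The analytic fixtures (`make_slab`, `make_uniform_block`,
`make_constant_T_series`, `make_synthetic_sweep`) run through the same
production solvers — the slab is a voxel grid with planar electrode
slabs, not a special-cased 1-D code — and carry their closed-form
answers: uniform field V/d, Joule density σV²/d², adiabatic rise
Q·t_on/(ρc), zero-dimensional metabolic and perfusion solutions, and the
constant-temperature Arrhenius integral. Passing them shows the
discretisation, the coupling and the integrators are implemented
correctly; it does not validate the tissue parameters, the step
conductivity model or the 800 V/cm threshold against real tissue, all of
which are inputs taken at face value. The synthetic sweep emulates only
the asserted response structure (linear in p_w and f, square in V) plus
Gaussian noise — it contains none of the poration-extent curvature the
simulated sweep has, which is why coefficient recovery on it is exact
while the simulated fit is judged by R².

## Known limitations

* Two parallel needles only; no electrode-placement optimisation, no
  arbitrary arrays.
* The dielectric response is purely resistive (no dispersion, no
  transient displacement currents) and the electroporation model is the
  two-state step — no dynamic pore-density kinetics.
* Thermal properties k, ρ, c are temperature-independent; only σ carries
  a thermal coefficient.
* One burst is simulated; multi-burst behaviour is the analytic N-fold
  extrapolation, an upper bound.
* Peak temperatures anywhere near the electrode surface carry the
  resolution-scale caveat discussed above; volumetric dose summaries
  (damage-classified voxel counts, kill-probability fields) are the
  robust quantities.
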