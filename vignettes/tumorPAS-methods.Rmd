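---
title: "tumorPAS: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tumorPAS: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`tumorPAS` simulates the regrowth of a residual breast tumor as a radially
symmetric free-boundary problem. The tumor occupies a ball of radius
$R(t)$; inside it, 17 coupled fields evolve by reaction, diffusion and
advection: nine cytokine/protease concentrations (tissue factor TF, VEGF
$V$, plasmin $P$, the uPA receptor $u_{PR}$, inactive and active urokinase
uPi/uPa, the inhibitor PAI-1 $P_A$, M-CSF $q$, MCP-1 $p$), four cell
densities (macrophages $M$, endothelial cells $E$, fibroblasts $f$, cancer
cells $C$), oxygen $w$, the MMP/TIMP pair $Q, Q_r$, and the extracellular
matrix $\rho$. All concentrations are in g/cm$^3$ (treated as identical to
g/ml), time in days, length in cm.

The biological core is the plasminogen activation system: fibroblasts
secrete inactive uPA, which is activated by binding the receptor uPAR
(expressed by macrophages and cancer cells); active uPA converts
plasminogen to plasmin and enhances cancer proliferation, both processes
antagonized by PAI-1. Total uPAR mass in the lesion is the candidate
serum-accessible biomarker: the package builds the forward surfaces
$R(R_0, t)$ and $\mathrm{uPAR}(R_0, t)$ over a grid of initial radii and
inverts them, so a single uPAR measurement at time $t$ yields the
unobserved initial radius $R_0$ and hence the current and future tumor
radius.

Cells and ECM advect with a common velocity $u(r,t)\,e_r$ determined by
the incompressibility-like constraint that $M+E+f+C+\rho$ is constant in
space and time:
$$\theta\,\nabla\cdot u + D\Delta\rho = \sum_{X \in \{M,E,f,C,\rho\}}
\text{(reaction + chemotaxis terms of } X\text{)},$$
and the free boundary moves with the cells: $dR/dt = u(R(t), t)$.

**The conservation constant.** The stated initial data ($M{=}0.07$,
$E{=}0.05$, $f{=}0.06$, $C{=}0.4$, $\rho{=}0.02$) sum to $\theta = 0.6$,
not 1. Since the velocity equation is derived *from* the constancy of the
sum, only constancy matters; we take $\theta$ equal to the initial sum and
divide the velocity source by it. Without that division the constraint is
violated at order $(1-\theta)$ per day; with it, the pointwise sum stays
within 1% of 0.6 over the whole run (this is one of the acceptance
checks).

**Hypoxia.** Two production rates (MCP-1, cancer proliferation) carry an
oxygen modulation: the rate equals its plateau for $w \ge w_h$ and scales
as $w/w_h$ below the hypoxia threshold $w_h = 10^{-4}$ g/cm$^3$. Oxygen is
initialized exactly at $w_h$, so these factors start at their plateau.

**Boundary conditions.** All species obey no-flux conditions at $r = R(t)$
except oxygen and endothelial cells, which satisfy Robin conditions
$\partial X/\partial n + \alpha_X (X - X_0)^+ = 0$ with
$\alpha_w = \tilde\alpha_w E/(K_E+E)$ and
$\alpha_E = \tilde\alpha_E V/(K_V+V)$. The positive-part clamp is taken
literally: flux occurs only when the interior value exceeds the vascular
one, i.e. the boundary acts as an outflow valve only. The ECM, purely
advected, needs and receives no boundary condition. At the origin,
symmetry gives $\partial X/\partial r = 0$ and the radial Laplacian limit
$3 X_{rr}$.

## Parameters

`baseline_parameter_set()` carries all 85 tabled constants.  Every entry
flagged "estimated" is re-derived by `estimate_*()` functions from a small
set of literature anchors held in `estimation_context()`: molecular
weights (diffusivity scales as $\mathrm{MW}^{2/3}$ against VEGF),
half-lives ($d = \ln 2/t_{1/2}$), and steady-state tissue concentrations.
`derivation_table()` prints tabled vs recomputed values; the baseline
constructor fails if any non-overridden entry drifts by more than 2%.

Four entries carry documented overrides where the printed table and the
printed derivation disagree; the tabled value is canonical in all cases
because the original simulations used it:

* `lambda_Pf`: arithmetic gives 8.57e-4/day, table says 8.4e-4/day.
* `A_T`, `lambda_TC`: the stated healthy/disease steady states do not
  reproduce the tabled values (off by 10x and 14% respectively).
* `d_uPa`: a 5 h half-life gives 3.33/day, table says 3.2/day.

The healthy uPAR anchor is fixed at exactly one tenth of the disease value
(1.8e-7 g/ml) because that choice reproduces the printed production rate
6.21e-6/day to all printed digits.

## Numerics

Two schemes share one spatial discretization contract:

* **explicit** — the fully explicit total-derivative moving-mesh
  scheme with the three-point nonuniform stencils, retained for fidelity
  tests. It refuses to run when $\tau > \min(h)^2/(2D_{max})$; with the
  plasmin diffusivity 0.212 cm$^2$/day and $h \approx 1.6\times10^{-4}$ cm
  that bound is $\tau \approx 6\times10^{-8}$ day, which is unusable for
  600-day runs — hence the second scheme.
* **implicit-split** (default) — reactions, chemotaxis, advection and mesh
  motion advance explicitly; diffusion advances by backward Euler with one
  tridiagonal solve per field on the current mesh. The diffusion operator
  is a conservative finite-volume radial Laplacian (faces at interval
  midpoints, outer face on the boundary), which conserves shell-volume
  mass exactly under no-flux. Defaults: $\tau = 0.01$ day, $N = 64$ nodes,
  regrid to a uniform mesh every 50 steps. A compiled (Rcpp) fast path
  mirrors the R reference stepper operation for operation; the two are
  cross-checked in the tests to $10^{-9}$ relative.

One transcription note: the printed first-derivative stencil, as extracted,
has a minus sign on its $X_i$ term with which the quotient is not even
consistent on linear profiles. A Taylor derivation fixes the sign
(`+ (h_1^2 - h_{-1}^2) X_i`), restores reduction to central differences on
uniform meshes, and gives the second-order exactness on quadratics that
the scheme's own description claims; we use the corrected form.

Fields without an advection term in their equations (all cytokines, oxygen,
MMP/TIMP) are nevertheless stored on the moving mesh, so their update
carries the mesh-motion correction $+\,u\,X_r$; advected fields absorb
advection into the mesh motion and keep only $-(\nabla\cdot u)X$ with
$\nabla\cdot u = u_r + 2u/r$ (origin limit $3 u_r(0)$). The printed
"$(v_r r + v)X$" term is treated as shorthand for this radial divergence;
the literal reading is available in the explicit scheme behind
`literal_advection = TRUE` for comparison.

Negative values produced by the explicit substeps are clamped to zero with
a running count (`trajectory$clamped`); positivity is a model invariant
the scheme does not guarantee. Velocity integrals use spherical-shell
trapezoid weights ($d(s^3)/3$), exact for constant sources.

**Elimination floor.** If the free boundary shrinks below
`R_min = 5e-4` cm — half a typical cell diameter — the tumor is declared
eliminated and the state frozen; the trajectory is marked `eliminated`.
This is a package addition: without it the Lagrangian mesh degenerates to
NaN when $R \to 0$, and day-600 readouts would be undefined for
collapsing parameter draws. It never triggers in a growing regime.

## What the baseline model actually does — a known defect

Taken exactly as printed — parameters, the literal
$(V-V_0)^+$ endothelial proliferation factor, and the outflux-only Robin
clamp — the baseline model *collapses* rather than grows, which is why
several qualitative acceptance checks in `test-acceptance.R` are
deliberately left failing. Three independent pieces of steady-state
arithmetic, none requiring the PDE solver, show the collapse is structural:

1. The macrophage source $\beta\,p/(K_p+p)\,M_0$ is bounded by
   $\beta M_0 = 1.5\times10^{-5}$ g/ml/day, so $M$ can never exceed
   $\beta M_0/d_M = 10^{-3}$ g/ml — 300x below the disease level
   ($M = 0.3$) that the parameter estimation itself assumes.
2. With attainable VEGF levels ($V \lesssim 10^{-8}$ g/ml given the cap on
   $M$), the endothelial proliferation factor
   $\lambda_E (1-E/K_E)(V-V_0)^+$ is of order $10^{-8}$/day against a
   death rate of 0.69/day; $E$ decays to zero within days. The
   `normalize_EV` switch (divide by $K_V$) raises the factor only to
   $\sim 0.1$/day — still far below $d_E$.
3. With $E \to 0$ the internal oxygen source $\lambda_w E$ vanishes, and
   the boundary clamp forbids influx (interior $w$ never exceeds the
   vascular $w_0$); so $w \to 0$, the hypoxia factor suppresses cancer
   proliferation entirely, and $C$ decays at $d_C = 0.5$/day. The velocity
   source turns negative and $R(t)$ shrinks monotonically to the
   elimination floor (around day 510 for $R_0 = 0.01$ cm).

Consequently: total uPAR mass rises from zero for only about the first 1.5
days (while its cellular sources are still present) and then declines, so
the biomarker surface is monotone in $t$ only on that early window; the
inversion machinery itself — monotone in $R_0$ at fixed $t$ — works and is
tested both on the model's early window and on synthetic monotone
surfaces. The originally reported simulations evidently integrated dynamics that
differ from the printed equations (an inward oxygen boundary flux and a
larger effective endothelial proliferation are the most plausible
candidates); reproducing undocumented dynamics is out of scope here, so the
failing checks are reported honestly rather than patched.

## Sensitivity analysis

`latin_hypercube()` stratifies each of the 28 production parameters into
$n$ equal-probability bins (default range: uniform within $\pm50\%$ of
baseline — the source states no ranges, and $\pm50\%$ is conventional for
PRCC screening). `prcc()` rank-transforms everything and correlates
residuals after partialling out the other parameters; p-values use the
$t$ approximation with $n-2-k$ degrees of freedom, average ranks for
ties. `run_sensitivity()` simulates each sample at reduced fidelity
($N = 32$, $\tau = 0.02$) and reads the radius at day 600. Because the
baseline regime is a collapse, the readout is dominated by time-to-
elimination; of the reference sign structure only the fibroblast-cancer
crosstalk (positive) and the plasmin activation rate (negative) are
recovered at $n = 200$ — the rest sit at noise level. PRCC of a single
parameter reduces exactly to Spearman correlation (tested).

## Synthetic data and what a green test establishes

`make_fixture()` produces the three state kinds used by the tests:
`"standard-initial"` (the stated uniform initial condition), `"uniform"` and
`"bump"` (seeded random smooth profiles at physiologic scales). These
exercise conservation, stencil and scheme-agreement properties; they do
not emulate spatial heterogeneity of real lesions, measurement noise, or
inter-patient parameter variation — a green solver test therefore
establishes numerical correctness of the discretization, not clinical
validity of the model.

The ODE-limit oracle in the test suite integrates an independently
transcribed copy of the 17 reaction equations with an L-stable BDF2/Newton
scheme (the MMP–TIMP depletion terms relax at $10^3$–$10^4$/day, which
rules out explicit oracles); the PDE solver with transport disabled must
match it to 0.5% over 100 days.

## Numerical choices and degenerate inputs

* Quadrature for the observables Ave $= R^{-3}\int_0^R X r^2 dr$ and
  TM $= 4\pi\int_0^R X r^2 dr$ is plain trapezoid on the nodes, matching
  their printed definitions; note Ave of a uniform field is $X/3$ — the
  `true_mean` option multiplies by 3.
* Bilinear interpolation plus bracketing bisection for the biomarker
  inversion; monotone cubic interpolation was rejected because overshoot
  can manufacture spurious non-monotonicity near the peak of $U(t)$.
* Robin clamps are decided on the explicit predictor, keeping the implicit
  diffusion solve linear.
* Map grids default to 17 initial radii by 101 times over 1000 days
  (resolutions are not stated in the source; these make the bilinear
  interpolation error negligible against the simulation error).
* Blow-up guard: any field magnitude above $10^3$ g/cm$^3$ or a non-finite
  boundary aborts with a diagnostic trajectory.

## Limitations

Strictly 1-D radial geometry; no angiogenesis network, no stochastic cell
effects, no serum-to-tissue proportionality (awaits clinical data, per the
source); and the baseline growth defect described above, which is the
dominant caveat for any quantitative use of the biomarker maps.
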