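---
title: "Methods: flow model, kinematics, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flow model, kinematics, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

flapwing simulates the two-dimensional unsteady incompressible flow around a
rigid insect-wing cross-section undergoing prescribed flapping kinematics,
and compares lift/drag coefficient traces across cross-section shapes. This
vignette documents the model, the numerical scheme, every tunable that
matters, and what the packaged tests do and do not demonstrate.

## The physical model

The fluid obeys the incompressible Navier-Stokes equations,

$$\nabla\cdot\mathbf{u} = 0,\qquad
\rho\left(\partial_t\mathbf{u} + \mathbf{u}\cdot\nabla\mathbf{u}\right)
 = -\nabla P + \mu\nabla^2\mathbf{u},$$

with gravity neglected. The wing section is a rigid closed polygon moving
through the fluid on a prescribed trajectory. Instead of a body-fitted
deforming mesh, the section is imposed on a *fixed* Cartesian grid by
Brinkman volume penalization: inside the solid mask $\chi\in[0,1]$ the
momentum equation acquires a relaxation term $-\chi/\eta\,(\mathbf{u} -
\mathbf{u}_b)$ driving the fluid toward the local rigid-body velocity
$\mathbf{u}_b = \mathbf{U} + \boldsymbol\omega\times\mathbf{r}$. Both
formulations converge to the same continuum problem as the grid and $\eta$
are refined; the fixed grid makes every run reproducible without a
commercial mesher, and the penalization term *is* the force integral:

$$\mathbf{F} = \rho\int \frac{\chi}{\eta}\,(\mathbf{u}-\mathbf{u}_b)\,dA
\quad\text{(force per unit span on the body).}$$

Flows here are laminar (Reynolds numbers of order $10$–$10^3$), so no
turbulence model is used.

## Kinematics

The 3D wing stroke is reduced to three components at the span station
$r_0$: pitch $\theta_3$ stays an angle; the stroke and deviation rotations
become $x$ and $y$ translations. The waveform convention is fixed by the
stroke waypoints: pitch $\theta_3(t) = \theta_{3A}\sin\omega t$ (zero
incidence at stroke reversal, $+\theta_{3A}$ at mid-upstroke) and
translations $x(t) = r_0\,\theta_{1A}[\mathrm{rad}]\cos(\omega t+\varphi_1)$,
$y(t) = r_0\,\theta_{2A}[\mathrm{rad}]\cos(\omega t+\varphi_2)$, so
translational velocity vanishes at reversal ($\tau = ft = 0,\,0.5$) and
peaks at mid-stroke ($\tau=0.25$). Both translations share the fundamental
frequency (no figure-eight harmonic). Amplitudes are entered in degrees and
converted internally; forward-flight phases default to zero.

Bee forward flight uses $f=150$ Hz, $\theta_{1A}=110^\circ$,
$\theta_{3A}=24^\circ$, $r_0=6.61$ mm, with $\theta_{2A}$ looked up from the
flight speed (10, 15, 20, 24, 26 degrees at 1–5 m/s, linearly interpolated
between integer speeds). The hovering validation case uses $f=0.25$ Hz,
$r=162.5$ mm, $\theta_{1a}=23.5^\circ$, $\theta_{3a}=45^\circ$; its
$\varphi_1=\pi/2$ is the quarter-period pitch–translation offset of normal
hovering, rendered as translation $\propto\cos\omega t$ with plate
inclination from vertical $\propto\sin\omega t$. The orientation sign is
chosen so the plate leans its upper edge into the motion on each
half-stroke, the configuration that pushes fluid downward and generates
positive lift.

The coefficient normalization speed $V_{mag}$ is the wing's maximum
translational speed over a cycle (for the validation case
$r\,\theta_{1a}[\mathrm{rad}]\,2\pi f \approx 0.105$ m/s); for static
grid-study configurations the freestream $V_\infty$ is used instead. The
reference area is the chord per unit span. Positive $C_D$ in forward flight
means net thrust; the hovering case reports the resistive convention
(force component opposing the instantaneous translation, folded per
half-stroke) so its cycle average is positive.

The Reynolds number is computed as
$\mathrm{Re}=\rho(V_{kin}+V_\infty)c/\mu$ with $V_{kin}$ the maximum
translational speed. Air properties are left open by the case
definitions; standard sea-level air ($\rho=1.204$ kg/m³,
$\mu=1.82\times10^{-5}$ Pa·s) is adopted. Under these constants the forward-flight Re evaluates to
several thousand, driven by $V_{kin}\approx12$ m/s.

## Cross-sections

Four sections share a 4 mm chord, leading edge toward $+x$, pitch axis at
mid-chord on the camber line (nothing else constrains the pitch axis;
mid-chord keeps the four sections comparable):

* **corrugated** — the synthetic bee-like stand-in. No micro-CT bee
  section is publicly deposited, so a parametric generator reproduces the
  salient structure such sections show: a thin membrane (0.0125c) whose camber line passes
  through eight vein nodes with offsets alternating ±0.02c, a circular
  thickening (radius 0.025c) at each node, and an indentation at 0.55c
  standing in for the fore/hind-wing interface. The surfaces are offset
  from the camber spline along its local normal (the physical thickness
  direction); amplitude/radius combinations that fold the offset boundary
  over itself raise an error naming the nearest vein node. Optional seeded
  jitter perturbs the node amplitudes; the default is deterministic.
* **smoothed** — the corrugated section low-pass filtered at a 0.2c
  feature scale, standing in for the manually smoothed "approximate"
  section. The smoother splits the boundary into camber (cosine basis) and
  half-thickness (sine basis, vanishing at the section tips) on a uniform
  chordwise grid and truncates both series — an exact projection, hence
  idempotent, with the chord untouched. The sine basis thins the section
  slightly near the tips (a few percent of area at typical windows).
* **ellipse** — 0.125c maximum thickness.
* **flat plate** — 0.0125c uniform thickness with semicircular end caps.

The generators emit ≥256 boundary points per loop so geometric error sits
below the flow discretization error. The default corrugated section is one
connected loop; whether the real fore and hind sections act as one body or
two bridged bodies is not derivable from the source, and one loop is the
simpler choice.

## Discretization

Staggered (MAC) finite differences on square cells: $u$ at x-faces, $v$ at
y-faces, pressure at centers. One step is a fractional step:

1. **Predictor** — explicit advection with second-order upwind-biased
   (three-point one-sided) differences plus explicit central diffusion.
2. **Penalization** — pointwise implicit:
   $u \leftarrow (u + \tfrac{\Delta t\chi}{\eta}u_b)/(1+\tfrac{\Delta t\chi}{\eta})$,
   unconditionally stable; the momentum it removes, divided by $\Delta t$,
   is recorded as the force on the wing.
3. **Projection** — a pressure Poisson solve enforces discrete
   incompressibility. The matrix depends only on the grid and boundary
   mode, so its sparse Cholesky factorization is computed once per run;
   post-projection divergence is at rounding level (~$10^{-12}$ of
   $V/\Delta X$), far below the $10^{-8}\,V_{ref}/\Delta X$ contract the
   step asserts.

Time integration is first order. The step controller uses the modified
advective CFL rule $\Delta t = \mathrm{CFL}_{max}\,\Delta X/V_{ref}$ with
$V_{ref} = \max(|V_x|+V_\infty,\ |V_y|,\ \max_\text{cells}(|u|+|v|))$,
additionally capped by the explicit diffusive limit $\Delta X^2/(4\nu)$ and
by $\eta$. Two refinements are built into the controller rather than left
to the user: the advective and diffusive restrictions are combined
harmonically ($\Delta t \le \mathrm{CFL}_{max}\,s/(V_{ref}/\Delta X +
4\nu/\Delta X^2)$), and the factor $s=0.45$ keeps the step inside the
stability region of the one-sided gradient operator, whose forward-Euler
limit is an advective Courant number of one half (its symbol reaches
magnitude $4/\Delta X$ at the grid Nyquist mode). Without that factor,
grid-scale perturbations born at the penalization interface amplify
regardless of how small the time step is subsequently driven.

**Penalization scale η.** Smaller η enforces the solid more strongly
(velocity mismatch inside the mask scales linearly with η — asserted by a
test) but, through the $\Delta t \le \eta$ cap, shortens the time step. The
default choice targets $\Delta t/\eta \approx 1$ in the developed flow:
$\eta = s\,\mathrm{CFL}_{max}/(2.5\,V_{kin}/\Delta X + 4\nu/\Delta X^2)$,
the step bound evaluated at 2.5× the kinematic reference speed (the factor
by which field speeds typically exceed the wing speed once vortices
develop). Cases may override η; the validation study uses η = 3.5×10⁻⁴ s
(see below).

**Solid mask.** The polygon is rasterized every step at the new wing
placement by signed distance: the solid fraction ramps linearly from 1 to 0
across a band of one cell centred on the boundary. The grid-summed mask
area converges to the polygon's shoelace area as the cell shrinks (tested
at two resolutions on the ellipse).

**Boundary conditions.** Forward flight: uniform inflow $u=-V_\infty$ on
the right boundary, zero-gauge pressure outflow on the left, free-slip top
and bottom, on a 22c × 11c domain. Validation: all four walls no-slip, as
in the oil-tank experiment the case replicates. A fully periodic mode
exists for the analytic verification problems. Startup is impulsive
(uniform flow or rest); statistics windows exclude early cycles.

## Verification

* **Taylor–Green vortex** (periodic, analytic Navier–Stokes solution):
  kinetic energy decays as $\exp(-4\nu k^2 t)$ within 1% at 256²; the
  observed L2 spatial convergence order between 64² and 128² exceeds 1.9
  (measured ≈ 3 on this smooth field).
* **Couette flow**: a penalized plate forming the lower wall plus a moving
  lid reaches the linear profile within 2%.
* **Penalization contract**: halving η halves the maximum in-solid velocity
  mismatch of a static plate in a freestream.
* **Galilean check**: a static plate in a freestream and the same plate
  towed through still fluid in the closed tank give matching drag at equal
  travel time within 3%.
* **Steady drag**: a circular cylinder at Re = 40 in the forward-flight
  channel. A refinement sequence of this solver (512×256 grid, 24d × 12d
  domain) gives a drag coefficient of 1.68, consistent with the classical
  unbounded value ≈1.5 plus the ~8% blockage of a 12-diameter channel; the
  test asserts a coarser run stays within 10% of that frozen refined value.

## The hovering validation study

The quantitative anchor is the hovering flat plate in mineral oil
($\rho=880$ kg/m³, $\nu=1.15\times10^{-4}$ m²/s), driven by the validation
kinematics above, for which the reference cycle averages are $C_L=0.82$
and resistive $C_D=1.33$ (2D simulation) against 0.86 and 1.34 measured in
the robotic-wing experiment. Two parameters of the setup are left open by
the case definition and are fixed here as the package's own choices: the plate thickness (0.1c, so the section spans
2–3 cells at the coarse resolution; literature plates of 0–0.03c would be
sub-grid) and the tank size (10c × 10c, leaving over two chords of wall
clearance around the 5.6c stroke; a matched-cell-size sweep over 8c, 10c
and 13c tanks moved the mean $C_L$ by roughly ±0.05, so wall placement is a
secondary effect at this scale).

The desk-scale configuration is 256² cells, four cycles from rest,
averaging over the last full cycle, with η = 3.5×10⁻⁴ s; it runs in
roughly ten to thirteen minutes on one core. At this resolution the drag
average lands about 10% above the reference (1.46 vs 1.33; bluff-body drag
is robust and, as in the cylinder check, mildly over-predicted by the
smeared interface), while the lift average converges from below: 0.55 at
192², 0.61 at 256², with halving η worth a few more points. The
phase-resolved trace shows why — the translational lift plateau of each
half-stroke is reproduced (peak C_L ≈ 1.0 at mid-stroke), but the
rotational/wake-capture lift peak near stroke reversal, which rides on the
sharp-edge circulation, is smeared away at 2–3 cells of plate thickness,
leaving the cycle mean ~25% low. Both refinement directions move the value
monotonically toward the reference. The acceptance script reports exactly
this configuration; the faithful "full" preset (512², 15 cycles,
statistics over τ∈[3,15)) tightens the band at roughly 16× the cost.

## The forward-flight sweep

The packaged sweep runs the four sections at 1–5 m/s under the bee
kinematics on the coarse preset (256×128, 4 cycles, statistics over the
last two cycles) and builds the comparison report: cycle-averaged $C_L$,
$C_D$, and the root mean square difference of each trace against the
corrugated reference resampled to a uniform τ grid,

$$\mathrm{RMSD} = \sqrt{\tfrac1n\sum_{i=1}^n (a_i - r_i)^2},$$

with $n=1600$ points on τ∈[3,15) in the faithful mode and proportionally
fewer on shorter desk-scale windows. Linear interpolation is used for the
resampling: force traces are smooth relative to the step size and nothing
in the source prescribes another rule. Averaging windows must span whole
cycles (a partial cycle biases the mean of a periodic signal); violations
warn rather than fail. Peak counting reports local maxima above a
prominence threshold of 10% of the cycle's range — the corrugated and
smoothed sections characteristically show two lift peaks per cycle where
the simple sections show one broad one.

## What the synthetic data do and do not show

The corrugated generator emulates the *qualitative* features the study
attributes to the real bee section — corrugation, discrete vein
thickenings, a fore/hind interface notch, a thin membrane — under fully
reproducible control. It is not the micro-CT geometry: vein positions are
uniform rather than anatomical, the notch is a smooth indentation rather
than a hook pair, and no planform (3D) information exists. Tests passing on
these sections therefore demonstrate that the *pipeline* (geometry →
kinematics → flow → forces → statistics) behaves correctly and that
corrugation changes vortex shedding in the expected direction; they do not
certify quantitative equality with published bee-section forces, which
come from body-fitted meshes of several hundred thousand cells. The
desk-scale presets here use 33k–66k cells; the vignette's problem sizes
are the package's definition of a reproducible desk-scale study.

## Known limitations

* First-order time accuracy; the explicit scheme's step limit makes the
  low-Reynolds validation case diffusion-limited, so runs cost tens of
  thousands of steps.
* Penalization smears the boundary over about one cell; thin sections
  (≤0.03c) are below the desk-scale grid and are simulated with thicker
  stand-ins where a single section's absolute force matters.
* Rigid sections only: no wing flexibility, passive pitch, or 3D effects.
* Single deterministic runs: no uncertainty quantification beyond the
  resolution/η sensitivity reported above.
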