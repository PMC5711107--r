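---
title: "Modeling electron dual scattering foil systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling electron dual scattering foil systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foilsim)
```

## The problem

Clinical electron beams leave the accelerator vacuum as a narrow,
near-monoenergetic pencil. To treat fields up to 25 × 25 cm² the beam
must be broadened and flattened, which most machines do with a *dual
scattering foil system*: a thin high-Z **primary foil** spreads the
pencil into an approximately Gaussian fluence at isocenter, and a
shaped low-Z **secondary foil** — thick on the axis, thin at the edge —
preferentially scatters the central electrons outward until the profile
is flat. Designing such a system by Monte Carlo alone is slow (hours
per candidate); `foilsim` reproduces the analytic approach that makes
design interactive: each full simulation takes well under a second, so
foil parameters can be swept continuously and checked against an
objective profile.

The model deliberately covers only the foil system itself: vacuum exit
window, primary foil, air gaps, secondary foil. Scatter from X-ray
jaws, applicators and inserts is out of scope, which is why designs
found here are meant to be *verified* afterwards by Monte Carlo or
measurement, with the objective-profile refinement closing the loop.

## Electron transport model

### Scattering powers

Multiple Coulomb scattering in each element is described by its
scattering power $T = d\langle\theta^2\rangle/dz$ (full-plane
mean-square angle per unit length, rad²/cm). We evaluate $T$ from the
Gaussian term of Molière theory with the *reduced-Gaussian* correction,

$$\overline{\theta^2}_{RG} = \overline{\theta^2}_{MG}\Bigl(1 - \frac{1.330}{B}\Bigr),
\qquad \overline{\theta^2}_{MG} = \chi_c^2 B,$$

where $B$ solves $B - \ln B = \ln\Omega_0$ with
$\Omega_0 = \chi_c^2 / (1.167\,\chi_a^2)$ the effective number of
scattering events (Bethe's presentation of Molière theory with the
Fano screening angle). The correction matches the width of the Gaussian
core of the full Molière distribution and repairs most of the
overestimate of the plain Gaussian term. Conventions for the constant
inside $\Omega_0$ differ between presentations at the few-percent level
in $B$; we use $e^{2C_E - 1} = 1.167$ throughout and state it in one
place. A slab is rejected as outside the Molière regime when
$\Omega_0 < e$, and the reduced-Gaussian form additionally requires
$B > 1.330$.

Scattering powers are evaluated at the **mean** energy entering each
element (not the most probable energy): energy degraders grow a
low-energy tail, and the mean tracks the extra scatter that tail
produces.

### Stopping powers and the energy schedule

Mean energies are transported with total (collision + radiative)
stopping powers:

* **Collision**: the Bethe/Berger–Seltzer closed form with the Møller
  close-collision term and the Sternheimer density effect. For water
  the density effect is evaluated *exactly* from the molecular
  oscillator model (H 1s, O 1s/2s/2p, strengths $n_i/10$, energies
  rescaled to reproduce $I$ = 75 eV); this reproduces the standard
  tabulations at 1–20 MeV to about four digits, which matters because
  the fluence-to-dose factor $K_e$ is read from this curve. For the
  metallic foils and air the generic Sternheimer fit recipe is used —
  their density effect only perturbs the thin-foil energy schedule at
  the per-mille level.
* **Radiative**: Bethe–Heitler Born cross-section, using the unscreened
  radiation logarithm bounded above by the complete-screening
  (Tsai radiation-length) limit with the Coulomb correction. This is a
  10–15% level description over 1–50 MeV, which is sufficient here:
  radiative losses only (a) nudge the energy schedule through µm-scale
  foils and (b) set the *relative* element weights of the X-ray budget,
  whose absolute scale is absorbed by the fitted central-axis
  calibration below.

Energy loss through a slab uses at least ten midpoint (second-order)
sub-steps whenever the one-step fractional loss exceeds 1%, keeping the
composition error below 10⁻⁶ without lookup tables. Transport stops
with an error if an element would absorb the beam (or drive it below
the 0.1 MeV validity floor of the formulas). The secondary foil is
handled as in the original method: the exit energy is the
fluence-weighted mean over the incident radial fluence, and its
scattering power is evaluated at the average of entrance and exit
energies. Materials are single effective elements (`Z`, `A`, density,
`I`), so compounds such as water and air are carried with effective
atomic numbers chosen to preserve `Z/A`.

### Fermi–Eyges moments and the pencil-beam convolution

The upstream stack (window, air, primary foil, air) accumulates
Fermi–Eyges moments at the secondary-foil plane $z_1$:

$$A_n(z_1) = \sum_i \int T_i\,(z_1 - z')^n\,dz' ,$$

computed with the exact per-element closed forms
($A_0 {+}{=} Tt$, $A_1 {+}{=} Ttm$, $A_2 {+}{=} Tt(m^2 + t^2/12)$,
$m$ the midpoint distance), so thin foils reduce to the familiar
point-scatterer expressions while extended air columns are integrated
exactly. Under the full-plane convention the incident fluence at $z_1$
is the unit-normalized radial Gaussian with $\sigma_r^2 = A_2$
(per-axis variance $A_2/2$).

The fluence at the calculation plane $z_2$ is the polar convolution of
that Gaussian with per-pencil kernels. Following the original geometry,
the mean direction of the pencil at radius $\rho$ on $z_1$ emanates
from the top of the primary foil, so its mean position at $z_2$ is
$(z_2/z_1)\rho$; its spread is

$$\sigma^2(z_2|\rho) = \Bigl(A_0 - \tfrac{A_1^2}{A_2}\Bigr)(z_2-z_1)^2
 + T_{sec}\bigl(t(\rho)\bigr)\,t(\rho)\,(z_2-z_1)^2
 + T_{air}\,\tfrac{(z_2-z_1)^3}{3}.$$

The first term is the *conditional* angular variance: the part of the
angular spread already spent producing the spatial spread at $z_1$ must
not drift twice. (The uncorrelated alternative, using the raw $A_0$, is
available behind `calculation$kernel = "uncorrelated"`; the default is
conditional.) The projection rule itself is an approximation — it is
exact when all upstream scatter occurs at the primary foil. For
beamlines whose exit window scatters heavily far upstream, the
fully-correlated spread differs from the projected one by a few
percent; this is a property of the method, inherited deliberately, and
is why the convolution-vs-random-walk test in the suite uses a
thin-window beamline to isolate the quadrature machinery.

The quadrature is a midpoint rule: by default 100 points in radius and
100 in angle over half the circle (doubled by symmetry), with the
profile evaluated on 60 points over a 30 cm half-range and mirrored.
The radial integration extends to the larger of the foil radius and
$4\sigma_r(z_1)$: beyond the physical foil the thickness is zero but
the incident fluence must still be transported, otherwise planar
fluence would not be conserved (the suite checks conservation to 1%).
With no secondary foil the profile is the analytic projected Gaussian —
no quadrature at all.

Relative dose equals relative fluence at shallow depths: the
fluence-to-dose factor is the water collision stopping power at
$E_d = E_{p,0} - 2d$ MeV (2 MeV/cm depth degradation), constant across
the profile under the off-axis-invariant-spectrum assumption, and is
reported rather than applied. Calculation depths beyond 2 cm trigger a
warning because the in-air profile then stops being a good proxy for
dose in water.

## X-ray contamination model

Bremsstrahlung from each element $i$ (window, primary, secondary)
contributes an off-axis fluence given by a Schiff-style multiple
scattering argument, with per-element brackets

$$\frac{\Delta E_{rad,i}}{T_i t_i}\Bigl[E_1\Bigl(\frac{\theta_r^2}{A_{0,i}+T_i t_i}\Bigr) - E_1\Bigl(\frac{\theta_r^2}{A_{0,i}}\Bigr)\Bigr],$$

where $E_1$ is the exponential integral, $\theta_r = r/z$, and the
entrance moments chain as $A_{0,i+1} = A_{0,i} + T_i t_i$ from the
empirical incident moment $A_{0,0} = 0.05\,E^{-1.6}$ (which stands in
for the forward peaking of the bremsstrahlung emission and keeps the
axis finite). On the axis the bracket has the analytic limit
$\ln(1 + T_i t_i / A_{0,i})$, which the implementation uses directly;
the suite verifies the numeric brackets reach it to 10⁻⁶. The mean
secondary thickness entering the budget is fluence-weighted over the
incident beam (a central-axis alternative is a configuration switch),
and air scatter between the three elements is not added to the X-ray
moment chain, mirroring the three-element sum of the source model.

The absolute scale comes from a semi-empirical calibration: the
statistic

$$X(E) = \frac{1}{(SAD + R_p + 2)^2}\,
 \frac{\sum_i \frac{\Delta E_{rad,i}}{T_i t_i} \ln(1 + T_i t_i/A_{0,i})}{\varphi_e(0,0,E)}$$

maps to the central-axis X-ray percent dose at depth $R_p + 2$ cm via
$\%D = aX + b(1 - e^{-cX})$ with fitted constants $a = -0.035$ %/MeV,
$b = 15.77$ %, $c = 0.016$ /MeV (user-overridable). The fit is forced
through the origin; far outside its fitted range the linear term can
drive it negative, in which case the value is clamped to zero with a
warning. Depth rescaling to the calculation depth is pure inverse
square ($R_p = E_{p,0}/2$ by the 2 MeV/cm rule); X-ray attenuation in
water (~9%) is deliberately ignored, as in the source method. The total
profile combines the components so the axis is exactly 100%:
$D_T(r) = \%D_\gamma(r) + (100 - \%D_{\gamma,CAX})\,D_e(r)/D_e(0)$.

## Design tools

`flatness_report()` scores a profile against an objective within
±14.6 cm by default (2 cm inside the half-diagonal of a 25 × 25 cm²
applicator field) with a ±3% criterion, reporting the maximum
deviations above and below separately. `refine_objective()` implements
the design loop against an external reference (measurement or Monte
Carlo): the new objective is the old one minus the
(reference − simulated) discrepancy, so that designing to the refined
objective compensates for physics the analytic model does not carry.
`sweep_parameter()` is the slider-bar workflow in batch form.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `beam$energy` | 13.99 | MeV | incident mean energy (or surface $E_{p,0}$ in backward mode) |
| `window` | Ni, 0.0125 | cm | vacuum exit window |
| `primary_foil` | Ta, 0.008 | cm | beam broadening; dominant X-ray source per µm |
| `secondary_foil` | Al, $t_0$ 0.6, $\sigma$ 1.44, 25 segments, $r_{max}$ 3.65 | cm | flattening |
| `geometry` | 3 / 15 / 85, SAD 100, depth 2 | cm | axial layout |
| `calculation` | 30 cm, 100 × 100, 60 points | — | quadrature/profile resolution |
| `xray$a,b,c` | −0.035, 15.77, 0.016 | %/MeV, %, /MeV | central-axis calibration |
| `flatness` | ±14.6 cm, 3% | — | scoring window |

The beamline distances are generic defaults, not any vendor's geometry
(machine drawings are rarely public); set them to the accelerator being
modeled before comparing to commissioning data. They were chosen once
so that the textbook 13 MeV exemplar (80 µm Ta primary, 0.6 cm/1.44 cm
aluminum Gaussian secondary) behaves the way such designs behave on
real machines: a near-flat profile over ±14.6 cm, ~3% central-axis
X-ray dose, horns growing with $t_0$ and receding as $\sigma$ widens,
and roughly +0.7% X-ray dose per doubling of either foil thickness.

The segmented secondary foil mimics manufacturing: $n$ equal-width
annuli whose step edges cross the true Gaussian at their midpoints,
anchored by the area-weighted mean over the central disc (the midpoint
rule alone only fixes differences), clamped at zero. A single segment
degenerates to a slab of the axis thickness. In transport, each
annulus scatters with its own thickness; the Molière $B$ of very thin
outer annuli is floored at the smallest positive segment thickness, and
zero-thickness radii contribute no scatter.

## Energy modes

Forward mode takes the monoenergetic incident mean energy and reports
the mean energy at the surface after all degraders. Backward mode takes
a surface energy and root-finds the incident energy on the forward
transport. The most probable surface energy $E_{p,0}$ — used for
$R_p$ and $E_d$ — is displayed as the mean surface energy plus a
configurable offset (`ep0_offset`, default 0): the mean-to-most-probable
gap depends on the spectral shape, which a monoenergetic-incident model
does not predict, so it is display-only and never enters scattering or
stopping evaluations.

## Numerical choices

* Quadrature: midpoint in both $\rho$ and $\Theta$; the suite holds the
  default 100 × 100 rule to ≤ 0.5% of the central axis against a dense
  (641²) Cartesian brute-force convolution, and an optional
  `check_convergence` run warns if doubling the point counts moves the
  axis value by more than 0.5%.
* Molière $B$: solved to 10⁻¹³ residual by bracketed root finding;
  the exact-density-effect root finds are solved to similar tolerance.
* Boundary radii of the segmented foil belong to the inner annulus;
  thickness beyond the last boundary is zero.
* Profile files round-trip at 9 significant digits; foil and
  configuration files at full double precision. All outputs are
  deterministic — there is no random number generator anywhere in the
  production path.
* Degenerate inputs fail loudly: delta beams (no upstream scatter)
  are routed to the analytic path, all-zero fluence weights, beams
  stopped in an element, non-monotone foil radii and out-of-range
  energies raise errors naming the offending quantity.

## What the tests do and do not show

The test suite validates the machinery against independent oracles:
re-coded stopping-power formulas, a series/continued-fraction
exponential integral, hand-computed budgets, a dense Cartesian
convolution, and a Gaussian random-walk Monte Carlo of the same
element stack (2–3 × 10⁵ histories, fixed seeds, widths agreeing to
1–2%). Problem sizes are kept at the method's native scale — the full
default simulation runs in a fraction of a second, the brute-force
cross-checks in seconds.

That random walk shares the model's own idealizations: Gaussian
single-element kicks, monoenergetic transport, no large-angle Molière
tail, no jaw/applicator scatter, no energy spectrum. Agreement
therefore shows the transport and quadrature are implemented correctly,
*not* that the model reproduces a real accelerator; on real machines
the known failure modes are underprediction at large off-axis
distances (missing large-angle scatter, a few percent beyond ~15 cm at
high energies) and any geometry the three-element X-ray budget does not
see. Those are exactly the gaps the objective-refinement loop is
designed to absorb.

## Worked example

```{r example}
cfg <- simulation_config()
res <- run_simulation(cfg)
res
```

```{r sweep}
sweep_parameter(cfg, "secondary.sigma", c(1.36, 1.44, 1.52))
```

The sweep reproduces the characteristic design trade-off: widening the
secondary foil's Gaussian lowers the horns while the central-axis X-ray
dose stays essentially constant.
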