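---
title: "Modeling the cavitation physics of kidney-stone dusting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cavitation physics of kidney-stone dusting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lithocav)
```

## The problem

Ho:YAG laser lithotripsy in its dusting regime (pulse energy $E_p = 0.2$ J,
70 µs FWHM, 20 Hz) erodes kidney stones even though the fiber tip is held
0.5–1 mm off the stone surface and most of the pulse energy never reaches
the stone as light. `lithocav` implements the full computational chain
needed to account for where the energy goes and what finally damages the
stone: photon transport through the dynamic vapor bubble, photothermal
crater formation, superheating-driven bubble inception, Rayleigh bubble
dynamics and acoustic-emission analysis, an axisymmetric fluid–solid wave
solver, and a Tuler–Butcher cumulative damage criterion. The central claim
the chain supports is that shock waves from the collapse of the toroidal
bubble remnant — not the liquid-jet impact and not photothermal ablation
alone — drive dusting-mode erosion.

## Synthetic inputs as study conditions

No experimental recordings ship with the package; the `synthetic_data`
generators produce every input the laboratory rig would, under documented
defaults that define the study conditions:

* **Power profile** (`make_power_profile`): the measured dusting profile is
  not tabulated, so the default is a trapezoid — 10 µs linear rise, flat
  top, 10 µs fall to a 20 % shelf that persists to the end of the 150 µs
  support — with the fall timed so the FWHM is exactly 70 µs. The integral
  is normalized to $E_p$ to 0.1 %.
* **Bubble geometry** (`make_bubble_geometry_sequence`): per 5 µs segment,
  the vapor region is the solid of revolution
  $r \le B_s\sqrt{\zeta(2 z_c(s) - \zeta)}$ ($\zeta$: depth below the fiber
  tip). The apex advances linearly and reaches the stone at segment 5 (the
  observed contact segment at SD = 0.5 mm); the width scale $B_s$ grows
  linearly with segment — slender pear early, spreading late, as in the
  recorded image sequences — and its final value is fixed by requiring the
  final clipped volume to equal $\tfrac{4}{3}\pi R_{e,\max}^3$. Masks are
  nested, so growth is monotone by construction.
* **Radius–time curves** (`make_radius_time`): Rayleigh-like growth and
  collapse limbs $R \propto (u(2-u))^{1/3}$ with labeled events; the primary
  collapse is placed at $t_1 = k_1 \cdot 2T_c$ so the analyzer's
  prolongation-factor estimate closes the loop, and the rebound radius is
  `rebound_fraction`$^{1/3} R_{e,\max}$ (volume-fraction convention).
* **Hydrophone traces** (`make_hydrophone_trace`): each shock is a one-cycle
  bipolar transient of 0.5 µs half-width, crest-aligned on the requested
  peak time, scaled by the spherical-spreading factor (1 mm / sensor
  distance), with seeded Gaussian noise.
* **Silhouettes** (`make_silhouette`): projected binary images of solids of
  revolution with optional blur and pixel noise, standing in for backlit
  shadowgraph frames. They emulate geometry only — no refraction, speckle
  or motion blur — so passing tests validate the extraction arithmetic, not
  robustness to real imaging artifacts.

Default bubble size $R_{e,\max} = 1.5$ mm at SD = 0.5 mm was chosen once so
that the potential-energy conversion $E_B/E_p \approx 0.7\,\%$ and
$\gamma = \mathrm{SD}/R_{e,\max} \approx 0.33$ sit in the reported dusting
regime.

## Photon transport

`trace_segment` launches photon packets from the fiber face (365 µm core,
NA = 0.26; directions uniform in solid angle inside the NA cone in water)
and advances them in fixed steps with continuous absorption weighting:
within each step the packet deposits $w(1 - e^{-\mu_a \Delta s})$ in the
local voxel. Because the complement is retained exactly, the bookkeeping
absorbed + transmitted + escaped = launched closes to round-off, and the
zero-scattering limit reproduces Beer–Lambert attenuation analytically.
Henyey–Greenstein scattering activates wherever $\mu_s > 0$ (zero in water
and vapor by default — no fluid scattering coefficient is reported).
Transport terminates at the stone plane: energy crossing it is booked as
delivered to the stone, and deposition inside the stone bulk is out of
scope. Water uses $\mu_a = 2.42$ mm⁻¹ and vapor $10^{-3}$ mm⁻¹ at 2080 nm;
a vacuum-bubble variant can be emulated by overriding the vapor record with
$\mu_a = 0$.

With the synthetic geometry the dynamic 30-segment run at SD = 0.5 mm
partitions roughly one fifth of $E_p$ to the interposing water and the rest
to the stone. The measured partition (about 63 % fluid / 37 % stone) relies
on the imaged bubble shapes and the measured power profile, neither of
which is published; it also counts light backscattered from the stone and
reabsorbed by the fluid, which this transport (terminating at the stone
plane) deliberately excludes. The package therefore asserts conservation,
the Moses-effect direction (more energy reaches the stone when a bubble is
present) and broad qualitative bounds, not the printed split.

## Thermal ablation

`step_heat` solves $\rho C_p \partial_t T - k\nabla^2 T = f$ on a
cell-centered axisymmetric grid in conservative finite-volume form (cell
centres at $r_i = (i - \tfrac12)\Delta r$, so the axis is a natural
zero-flux face), stepped implicitly (backward Euler by default; any step is
stable, and the 3D heat kernel is reproduced within 2 % at the resolutions
used in the tests). All boundaries are homogeneous Neumann. The ablation
rule removes a cell when its temperature has reached the phase-change
temperature and its accumulated deposited energy exceeds the volumetric
thermal resistance; removed cells never return.

For the multi-pulse crater (`run_multi_pulse`), 1 % of $E_p$ — the
calibrated absorbed fraction — is deposited per pulse into the topmost live
cell of each column inside the diverging beam footprint. Between pulses the
block relaxes exponentially toward ambient (default time constant 25 ms),
standing in for conduction into the surrounding bulk that a 0.5 × 0.5 mm
insulated block cannot represent, while the ablation dose accumulates.
BegoStone's ablation temperature and thermal resistance are not published;
they are calibration parameters. The defaults (550 K — gypsum decomposes
far below silicate melting points — and $8.5\times10^9$ J m⁻³) were fixed
once so that the 1 %-of-$E_p$ run saturates after roughly 220 pulses, the
reported saturation window; the crater then stops deepening because the
cone-divergence irradiance at the receded surface no longer reaches the
ablation temperature. The convention for comparing against threshold
irradiances is in-pulse average power over the illuminated disk;
`prf_averaged = TRUE` switches to the time-averaged alternative, since the
reported 5.79 W mm⁻² threshold does not state its averaging convention.

## Inception and bubble dynamics

The full compressible two-phase Euler/radiation solver is deliberately
replaced by two desk-scale components that carry all the printed inception
quantities. First, `absorbed_energy_to_nucleation` deposits Beer–Lambert
heating of the beam column into the conduction solver (or integrates
adiabatically) until the peak temperature reaches the assumed homogeneous
nucleation temperature $T_{vap} \in [373.15, 673.15]$ K; conduction barely
matters on these time scales (diffusion length ~3 µm at 17 µs), so the
result is essentially the time at which the cumulative face fluence reaches
$\rho c_p (T_{vap}-T_0)/\mu_a$. With the synthetic trapezoid profile
nucleation at 373.15 K occurs near 11 µs after ~15 mJ has been absorbed;
the reported 38.95 mJ at 17.4 µs depends on the measured profile's slower
rise and is treated as a plausibility scale, not a target. Second,
`integrate_rayleigh` integrates $R\ddot R + \tfrac32 \dot R^2 =
(p_{in} - p_{stat})/\rho$ with adaptive stiff integration and root finding;
for the empty cavity the collapse time is completed below the stopping
radius by the free-fall asymptote $t_{rem} = \tfrac25 R_{stop}/|\dot
R_{stop}|$, recovering the classical coefficient 0.915 to better than
$10^{-3}$.

Two interpretations of the post-flash pressure are shipped because the
equation of state behind the reported 0.15–0.22 GPa is unstated:
`saturation` (equilibrium saturation pressure, Wagner-type correlation
valid to the critical point) and `isochoric` (vapor created at nearly the
liquid parcel density, $p = \rho_{flash} R_v T$ with $\rho_{flash} =
900$ kg m⁻³ as a superheated-liquid density scale). The isochoric route
reproduces the printed band across 373–533 K; neither is asserted to be
the published model. The nucleus volume is the connected region at or
above $T_{vap}$ at nucleation time (zero in the adiabatic limit, where
only the face layer reaches threshold).

## Emission analysis

`bubble_energetics` evaluates $\gamma = \mathrm{SD}/R_{e,\max}$, $T_c =
0.915 R_{e,\max}\sqrt{\rho/(p_{stat}-p_v)}$, $k_1 = t_1/2T_c$, and $E_B =
\tfrac{4}{3}\pi (p_{stat}-p_v) R_{e,\max}^3$ (the standard bubble
potential energy; the printed rendering omits the /3 typographically,
which affects only absolute energies, not ratios). Significant acoustic
peaks are local maxima with prominence above 3× the trace noise RMS that
strictly exceed 30 % of the trace maximum; 1/r scaling refers pressures to
1 mm. The acoustic emission energy is taken as the far-field spherical-wave
form $E_s = \tfrac{4\pi r^2}{\rho c}\int p^2\,dt$ — the formula is not
printed anywhere, and this interpretation is the one consistent with the
1/r convention (it makes $E_s$ independent of sensor distance). Burst
windows for $E_{s1}$ vs $E_{s2}$ split at the rebound-maximum time. Torus
geometry uses $V = 2\pi^2 r_c r_{torus}^2$; the printed compression ratios
(~$10^5$) need the unpublished maximal cross-section radii and are not
asserted.

## Fluid–solid waves

`simulate_waves` advances an explicit velocity–stress staggered-grid
scheme in axisymmetric $(r, z)$, with the fluid as the $\mu = 0$ limit of
the same update; the harmonic averaging of $\mu$ at shear nodes vanishes
at the interface, which enforces zero shear traction while normal traction
and velocity stay continuous — no explicit coupling conditions are needed.
Sponge layers absorb outgoing waves. The monopole source is a Gaussian
blob of fixed physical radius (10 µm), clipped to the fluid, driven by the
running integral of the desired free-field waveform: a half-sine
compression lobe (default 0.5 µs) whose moment then tapers back over 20
lobe-durations, giving a compression-dominant wave with a ~3 %
rarefaction tail — the printed source waveform exists only as a figure, so
this shape is an interpretation of a collapse shock. The amplitude is
calibrated by a short free-field run at a fixed physical distance so the
peak pressure extrapolated to 1 mm by the 1/r law equals the specified
strength (30 bar at 1 mm for the SD = 0.5 mm collapse). Verified behavior
includes the 1/r law within a few percent, the water→fused-quartz
normal-incidence reflection coefficient 0.80, boundary-pressure doubling
against a near-rigid solid, capture-radius-independent radiated energy,
and a Schmidt head wave leaving the quartz surface at 24.5–26° from the
normal, extracted by a Theil–Sen line fit to the per-column crest of the
front (robust to the bipolar lobe structure) and cross-checked against
$\arcsin(c_f/c_R)$ with $c_R$ from the Rayleigh characteristic equation.

Nonlinear propagation is ignored (the shock Mach number near the source is
1.23, but the published interaction model is also linear), and the layered
BegoStone-on-photoelastic target is approximated by a homogeneous
half-space.

## Damage assessment

`stress_integral` implements the Tuler–Butcher measure $SI = \int (\sigma_T
- \sigma_0)^2 dt$ over the samples where $\sigma_T > \sigma_0$ (strict
inequality; $\sigma_T$ is read as $\sigma_1$, the maximum principal
stress, and $\sigma_0 = 7.1$ MPa for hard BegoStone).
`boundary_profiles` reduces station histories to peak tensile/compressive
profiles, sub-station extremum locations and −6 dB (half-extremum) widths.
The canonical runs reproduce the structural findings: tension peaks
off-axis where the leaky Rayleigh wave runs along the boundary, maximum
compression stays at $R = 0$, $SI$ decreases with collapse height $h_c$
over 30–110 µm, and the near-boundary collapse at SD = 0.5 mm out-damages
the SD = 1.0 mm configuration by far more than an order of magnitude.
Absolute stress and $SI$ values (57.8 MPa, −740 MPa, $1.68\times10^8$
Pa² s) require the unpublished fitted source waveform — and are
near-field-resolution dependent even then — so only shapes, monotonicities
and ratios are asserted. Source amplitudes per standoff distance follow the
measured peak-pressure trend (30 bar at 0.5 mm to 0.25 bar at 1.5 mm,
log-linear in between).

## Numerical choices and scales

Problem sizes used throughout the tests and the acceptance script were
chosen as the coarsest that keep each verified property comfortably inside
its tolerance: Monte Carlo runs use $10^3$–$10^5$ packets on ~10 µm
voxels; the conduction solver runs on 48–192 cell grids; wave runs use
6–10 µm spacing (600 × 600 cells for the head-wave configuration) at a
Courant number of 0.45, with 20-cell sponges. Peak boundary tension changes
by about 1 % between 6 µm and 3 µm spacing. All stochastic stages take
explicit seeds; `run_pipeline` fans one global seed out deterministically
per stage, and repeated runs are bit-identical.

## Known limitations

The chain is a set of decoupled single-physics stages, not the coupled
compressible solver: bubble shapes are prescribed, not computed; the
acoustic source is fitted, not emitted by a simulated collapse. Burn-mark
optics, pore micro-explosions, debris redeposition, interface
instabilities of the collapsing torus and fracture mechanics are all out
of scope, as they are in the source analyses this package re-implements.
Quartz and BegoStone elastic constants are literature values standing in
for an unavailable supplement and can be overridden via
`load_materials()`.
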