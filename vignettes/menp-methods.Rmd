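---
title: "Magnetoelectric nanoparticle forward models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Magnetoelectric nanoparticle forward models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menpsim)
```

`menpsim` models the chain by which a core–shell magnetoelectric
nanoparticle (cobalt ferrite core, barium titanate shell) transduces
neuronal extracellular electric fields into magnetization signals readable
by magnetic particle imaging. This vignette records the models, their
assumptions, and the design decisions behind them, in the order the
pipeline runs.

## Lumped particle physics

The particle is treated as zero-dimensional: one magnetization vector, one
stress tensor, one electric field. The constitutive pieces are

* **Langevin superparamagnetism.** The core magnetization follows
  `M = Ms · L(β|H_eff|) · Ĥ_eff` with `L(x) = coth x − 1/x`. The steepness
  `β = μ0 · Ms · V_core / (k_B · T)` is the thermal moment of the magnetic
  core over the thermal energy; temperature defaults to 300 K and is
  configurable (it is recorded in the particle specification). An explicit
  `beta` override admits empirically traced M–H curves. Note the tabulated
  CFO initial susceptibility (70) and the thermal-Langevin initial slope
  are independent parameterizations; both are exposed and neither is
  asserted as correct.
* **Magnetostriction.** `ε_me = (3/2)(λ_s/Ms²) · dev(M ⊗ M)` — traceless,
  quadratic in M, invariant under `M → −M`.
* **Piezoelectricity.** In Voigt form (11, 22, 33, 23, 13, 12; engineering
  shear) the shell stress is `S = S0 − eᵀE` with the tabulated 3 × 6
  coupling matrix. The tabulated 6 × 6 elasticity entries are expanded from
  the flat upper triangle (column-major); the matrix is carried as data and
  checked for symmetry, but the printed values are not positive
  semi-definite, which is recorded as an attribute rather than asserted.
* **Magnetoelastic feedback.** `H_eff = H + 3λ_s/(μ0·Ms²) · dev(S) · M`.

`solve_lumped_me()` fixes the coupled state by damped Picard iteration
(damping 0.5, relative tolerance 1e-10 on `|ΔM|/Ms`, 500-iteration cap; a
non-converged state is flagged, or raised in strict mode). Two closures for
the magnetostrictive self-stress are available:

* `"free"` (default): the particle is suspended in fluid with
  traction-free surfaces, so the core strain accommodates `ε_me` and no
  self-stress develops; only the shell-transmitted piezoelectric stress —
  scaled by a transfer factor `κ ∈ [0, 1]`, default 1 — enters `H_eff`.
  This matches the freely rotating, hysteresis-free regime relevant at
  neuronal time scales.
* `"clamped"`: zero total strain, giving back-stress `−C : ε_me` with an
  isotropic stiffness built from the core's Young's modulus and Poisson
  ratio. The feedback is then very strong (tens of MPa for moderate
  magnetization) and acts as a severe self-demagnetization; the fixed point
  converges slowly if at all. It is retained for sensitivity studies, not
  as a default.

The volume-averaged particle magnetization is `f_core · M_core` with
`f_core = (r_core/r_total)³` — the shell is magnetically inert. Field maps
around a particle use the exact uniformly-magnetized-sphere solution
(uniform `⅔ μ0 M` inside, point dipole of moment `M·V` outside) as an
analytic stand-in for finite-element maps.

## Harmonic spectroscopy

The drive is `H(t) = bias + amplitude · sin(2πft)` (sine from zero phase;
bias additive). The magnetization response is memoryless — hysteresis and
Néel/Brownian relaxation are out of scope — so `M(t) = M(H(t))` pointwise.

Harmonic amplitudes are estimated by a joint least-squares fit of an
intercept plus cosine/sine pairs at `k·f0`, `k = 1..K` (default 9), over a
whole number of drive periods. Two windowing details matter numerically:

* If the sampling step tiles an integer number of periods exactly — at the
  default 1 µs sampling of 25.25 kHz, 101 periods are exactly 4000 samples
  — the window is trimmed to that tiling. Every harmonic then sits on an
  exact discrete Fourier bin, the basis is exactly orthogonal, and the even
  harmonics of any odd M–H response vanish to machine precision (the test
  suite asserts < 1e-9 of the fundamental).
* Otherwise the window is the largest whole number of periods by time,
  half-open so the repeated phase point is not counted twice. The default
  analysis window is 4 ms rather than the historically used 80 µs, which
  spans a non-integer 2.02 cycles and would leak.

Harmonic ratios depend only on the shape of the M–H curve, not its scale.
A saturating Langevin particle under an 80 kA/m drive is close to a square
wave, whose odd harmonics fall as 1, 1/3, 1/5, 1/7; the computed ratios
(≈ 32.5%, 19.0%, 13.2% for the 30 nm, 347.1 kA/m tracer) sit slightly
below those bounds. A 120 kA/m bias pushes the operating point onto the
saturated branch and suppresses the third harmonic to below 5% of its
unbiased amplitude.

## Magnetoelectric response mapping

The forward model linearizes the particle response around the bias point:
`ΔM = slope(r_core) · (E · ĥ)` along the bias direction `ĥ` (signed
projection, the default convention — it yields the bipolar magnetization
maps seen around active neurons). An alternative magnitude convention
`slope · |E| · g(θ) · sign(E·ĥ)` uses the angular model
`g(θ) = f_min + (1 − f_min)|cos θ|` (period 180°, mirror-symmetric about
90°), with default floors taken from the ratios of the tabulated angular
extremes (35.62/539.82 for the field observable, 0.13/10.14 for flux
density). Which convention a run used is recorded in its outputs.

The slope table anchors 0.4 mA/V at a 12 nm core (0.02 A/m per 50 mV/mm)
and 0.497 mA/V at 14 nm; intermediate radii follow a power law through the
anchors (exponent ≈ 1.41), monotone and convex. The intermediate values are
a configuration default, not an asserted physical law — replace the table
to use measured slopes.

Concentration bookkeeping is first-principles: per-particle mass from
core/shell volumes and densities, number density = mass concentration /
per-particle mass. The widely quoted triple (117.5 µM, 27.495 µg/mL,
1415 particles/µm³) is mutually inconsistent with that arithmetic (27.495
µg/mL of 30 nm particles is ≈ 0.33 particles/µm³); it is available as the
labelled preset `"paper_fig4"` with `consistent = FALSE`, and conversions
never use it silently.

## Extracellular fields around neurons

Morphologies use the standard 7-column SWC format; a validated reader and
writer are provided, plus a generator of synthetic cells (ball-and-stick
and binary-branched templates carrying all three compartment types). The
membrane biophysics of real simulators is replaced by a template current:
a Gaussian-derivative waveform (biphasic, analytically zero integral) at
the soma, propagated along the tree with delay `distance/speed` (default
500 µm/ms) and exponential attenuation (default length constant 300 µm),
then balanced at every time sample by an area-weighted distributed return
current so the whole cell sums to exactly zero (a neuron is electrically
closed). Because the soma holds most of the membrane area, it also carries
most of the return current; timing comparisons between compartments should
therefore be made between neurites.

Potentials follow the standard volume-conductor kernels in an infinite
homogeneous medium: point sources `φ = I/(4πσr)` for somata, the
line-source integral for cylindrical neurites, distances clamped at the
compartment radius. The extracellular conductivity is not fixed by the
source material; the default 0.3 S/m is a typical cortical value and is a
flagged assumption. `E = −∇φ` is computed by central differences on the
recording lattice (one-sided at boundaries; exact for affine potentials),
with the single unit conversion 1 mV/µm = 1000 V/m applied there. The
lattice is inclusive of both boundary planes: `dim/spacing + 1` planes per
axis, which makes the 200 × 700 × 200 µm³ voxel at 5 µm exactly
41 × 141 × 41 = 237,021 sites.

Compartment-zone statistics label each site by the nearest compartment
within a 20 µm inclusion zone (ties broken soma > axon > dendrite) and
summarize `|ΔM|` per category at the single time of maximal spatially
integrated `|ΔM|` within the first 20 ms (mean, quartiles, Tukey fences).

## The cortical network voxel

The column is 200 × 200 µm² in cross-section and 700 µm deep: layers
II/III/IV with thicknesses 150/350/200 µm and excitatory:inhibitory counts
895:95, 988:188, 970:170. Wiring follows the reference rules — excitatory
cells project to all cells with p = 0.1 and weight `25 · y_norm`
(`y_norm` = depth of the *presynaptic* soma / 700 µm, origin at the top of
layer II; the rule does not specify which cell, and this choice is
recorded here); inhibitory cells project only to excitatory cells with
`p = 0.4·e^(−d/150 µm)` and weight 5; inhibitory–inhibitory connections
never occur. The synaptic time constants are carried as printed, in
seconds (0.8/5.3 s excitatory at 0 mV reversal, 0.6/8.5 s inhibitory at
−75 mV); because second-scale receptor kinetics are unusually slow, a
`tau_units = "ms"` flag allows the millisecond reinterpretation.

The dynamics are a leaky integrate-and-fire surrogate (τ_m = 20 ms,
threshold −50 mV, reset −65 mV, 3 ms refractory) with bi-exponential
conductances at the printed kinetics. Two additions are needed to obtain
the millisecond-scale population bursts that time-lock the downstream
Monte Carlo sampling:

* a **fast synaptic component** (3 ms excitatory / 8 ms inhibitory decay,
  same connectivity and reversal potentials, zero-able via `g_fast_e`,
  `g_fast_i`): conductances with second-scale rise cannot regenerate
  activity within a burst, so without a fast component the network has no
  millisecond positive feedback at all;
* **burst-initiation pulses**: a Poisson train (default 45 Hz) of brief
  (3 ms) population-wide depolarizing pulses in the external drive,
  standing in for the external volleys that ignite cortical bursts. Each
  pulse is amplified into an all-or-none synchronized burst by the
  recurrent fast excitation and terminated by spike-frequency adaptation
  (increment 30 mV, 15 ms decay) and refractoriness.

A 30 ms burn-in is simulated and discarded: the random membrane
initialization otherwise produces one artificially large synchronized
volley at the start. Defaults were tuned once to the bursting regime and
are part of the package's study conditions; with them, the 140 ms window
contains recurring detected bursts in the large majority of seeds. The
absolute population rates and the absolute voxel magnetization amplitudes
of conductance-based reference simulations are explicitly not reproduced —
only their structure (bursts, linear field pipeline) is.

Burst detection bins the population rate at 1 ms, smooths with a 5 ms
moving average, thresholds at mean + 2 SD, enforces ≥ 10 ms peak
separation, and localizes each peak at the raw-rate maximum within the
smoothing window. A caveat that follows from the rule itself: a mean+2·SD
threshold can only detect *narrow* rate excursions — four equal 10 ms
bursts in 140 ms raise the threshold above their own height — and on pure
Poisson noise the expected number of spurious threshold crossings per
140 ms window is of order one, so isolated false positives on featureless
rasters are expected behavior, not a defect.

For the field solver each point neuron becomes a current dipole: the
biphasic template at the soma position at each spike time, the opposite
current at a counter-pole 100 µm along +y (the distributed neurite
return), so the network's summed current is identically zero.

## Perfusion Monte Carlo

Particles start normally distributed in the x–z plane at the top of the
voxel (default SD 50 µm — a quarter of the column width, truncated to the
plane; the source material does not state this spread) and move by
`Δr = v·dt·ŷ + N(0, √(2D·dt))` per axis with D = 15 µm²/s and
v = 650 µm/ms. The transport step defaults to 10 µs: advection then moves
6.5 µm per step (safely below the 5 µm lattice via trilinear
interpolation) while the diffusion step is ≈ 0.017 µm — negligible against
advection, as the Péclet number implies. At these speeds a particle
released at y = 0 crosses the 700 µm voxel in 700/650 ≈ 1.077 ms, which is
why sampling windows of 1.0 ms centered on burst peaks capture essentially
the whole transit. Particles leaving the voxel stop contributing and are
excluded from the per-time count (washout); a reflecting boundary is
available as an option. Field values along trajectories use trilinear
spatial interpolation at the nearest 1 ms field frame (matching the
recording resolution; linear-in-time interpolation is optional).
`static_vs_perfused()` repeats the sampling with motion switched off and
reports both burst-window means and their difference, which depends on the
field geometry and is not asserted to any reference value.

## Synthetic data, test scale, and what passing tests show

The package generates all of its own inputs: morphologies, spike rasters
with injected volleys, M–H curves, and lattice fields. These emulate the
*structure* of real data — branched trees with soma/axon/dendrite types,
zero-sum membrane currents, layered rasters with burst epochs — but not
its biophysical richness: no conductance diversity, no real channel
kinetics, no tissue inhomogeneity or anisotropy, no vascular geometry.
Passing tests therefore demonstrate that the transduction chain is
implemented correctly (closed forms, conservation laws, statistical
recovery of the wiring and transport rules), not that the absolute
signal amplitudes of any particular tissue are predicted.

Problem sizes in the test suite are chosen for sub-minute runtimes: the
full 3306-cell column is built and simulated for wiring and burst
properties (the length-constant recovery uses ten reduced columns at 35%
cell count, where the distance-dependent rule is identical); lattice
tests use 3–9 planes per axis except the site-count checks, which use the
full 237,021-site lattice; Monte Carlo statistics use the full 40,000
particles, single steps. The pipeline's full-resolution field solve
(237,021 sites × all sources) is intentionally not exercised in tests —
the solver is linear and chunked, and its kernels are verified exactly at
small scale.

## Known limitations

* The lumped particle solver is a fixed point of the *lumped* constitutive
  relations; it does not resolve field gradients inside the particle, and
  the shell-to-core stress transfer factor κ summarizes interface
  mechanics that only a spatial solver could provide.
* The tabulated BTO elasticity matrix is carried verbatim but is not
  positive semi-definite as printed; it is not used mechanically under the
  default closure.
* The integrate-and-fire network is a structural surrogate: its rates and
  magnetization amplitudes track references in order of magnitude only.
* The volume conductor is infinite and homogeneous; no boundary effects.
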