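---
title: "Flow-induced membrane strain on an osteocyte process: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-induced membrane strain on an osteocyte process: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

Osteocyte processes run through nanoscale channels (canaliculi) in the
bone matrix. Load-driven interstitial fluid seeps through the pericellular
matrix (PCM) that fills the canalicular space, and tethering elements
(TEs) — perlecan-like fibers connecting the process membrane to the
canalicular wall — transmit the fluid drag to the membrane. The local
membrane strain is the mechanostimulus believed to gate channels such as
Piezo1. `canaflow` simulates this system as four coupled pieces:

1. **Fluid.** Interstitial flow obeys the Brinkman equation
   $\nabla p = -\frac{\mu}{k_p}\,\mathbf u + \mu \nabla^2 \mathbf u + \mathbf F$,
   i.e. Stokes flow with a Darcy drag representing the PCM
   (permeability $k_p = 7\ \mathrm{nm}^2$, viscosity
   $\mu = 10^{-3}\ \mathrm{Pa\,s}$). It is solved with a D3Q19 BGK
   lattice Boltzmann method (Guo forcing, halfway bounce-back walls,
   z-periodic). The axial pressure gradient
   $|\nabla p| = 1\ \mathrm{Pa/nm}$ is applied as an equivalent uniform
   body force in the pericellular voxels; the expected bulk (Darcy)
   velocity is $k_p|\nabla p|/\mu = 7\times10^{3}\ \mathrm{nm/s}$. Drag
   and drive act only in the pericellular region; the fluid enclosed by
   the process membrane is plain viscous fluid moved only through
   membrane coupling.
2. **Membrane.** The process membrane is a thin hyperelastic shell
   following Skalak's law
   $W = \tfrac{G_s}{4}\left(I_1^2 + 2I_1 - 2I_2 + C I_2^2\right)$
   with $I_1 = \lambda_1^2+\lambda_2^2-2$,
   $I_2 = \lambda_1^2\lambda_2^2-1$, discretized into constant-strain
   triangles (edge $\approx 4.7$ nm at full resolution). The surface
   shear modulus derives from the membrane Young's modulus
   $E = 4471$ Pa, thickness $t = 10$ nm and area-incompressibility
   coefficient $C = 10$ through $\nu_s = C/(C+1)$ and
   $E = 2G_s(1+\nu_s)/t$, giving $G_s \approx 1.17\times10^{-5}$ N/m.
   No bending stiffness is included. The reported strain is the largest
   eigenvalue of the in-plane Green–Lagrange tensor per element.
3. **Tethers.** Each TE is a tension-only linear spring between a
   membrane vertex $\mathbf x_m$ and a fixed wall anchor $\mathbf x_w$
   (the nearest point of the wall surface), with
   $k_{sp} = \pi r_{sp}^2 E_{sp} / l_0$ ($E_{sp} = 71$ MPa,
   $r_{sp} = 1$ nm) and natural length $l_0$ equal to the no-flow
   attachment–anchor distance, so all tensions are exactly zero before
   flow. Attachments are sampled area-uniformly at a density of
   12/37.5 per nm of axial length. The orientation angle $\theta$ is
   measured at no flow between $\mathbf x_w - \mathbf x_m$ and $+z$:
   under $+z$ flow the membrane is dragged downstream, so TEs whose
   anchors lie upstream ($\theta > \pi/2$) are the ones that stretch.
4. **Coupling.** The immersed boundary method with the 4-point cosine
   kernel spreads the total membrane restoring force
   $\mathbf q = \mathbf q_m + \mathbf q_t$ to the lattice and
   interpolates the fluid velocity back to the membrane nodes, which are
   advected with it (no-slip in the limit).

## Synthetic geometry

No nanometer-resolution canalicular reconstruction is publicly
available, so the package generates synthetic
process/canaliculus pairs that emulate the statistical character of real canaliculi. Both
tube radii are smooth random fields
$r(z,\varphi) = \bar r + \sum_{j,m} a_{jm}\cos(j\pi z/L)
[\cos,\sin](m\varphi)$ with Gaussian spectral weights. Defaults (declared
assumptions, not literature values): mean radii 52 nm (process) and
130 nm (canal), RMS roughness 10 nm, correlation length 20 nm, azimuthal
harmonics to $m = 12$. The axial basis $\cos(j\pi z/L)$ has zero slope
at both ends, so reflecting the model across the $x$–$y$ plane at
$z = L$ (the mirror-periodic extension that makes the domain z-periodic)
is smooth by construction. The pre-mirror length is snapped to an
integer number of lattice cells so the mirror plane is an exact lattice
reflection. Perturbations are rescaled if needed to keep the
wall–process gap above $2\Delta x$.

The correlation length deserves comment: it controls how strongly the
TEs incline. With very smooth walls, nearest-point anchoring produces
almost perfectly radial TEs, and — because the springs are tension-only —
radial TEs exert no first-order restoring force against axial sliding of
the process. A 20 nm correlation length at 10 nm RMS produces wall
protrusions that anchor TEs at a realistic spread of inclinations
(5–95% range of $\theta$ roughly $[1.16, 2.01]$ rad on the default
geometry), which is the regime the inclined-tether mechanism needs.

What the generator does *not* emulate: branching or curvature of the
canaliculus, sharp collagen-scale asperities, spatial correlation
between the process and wall surfaces, and any biologically organized
(non-random) TE placement. Passing tests on this geometry therefore
validate the mechanism — inclined, highly tensed TEs concentrating
strain — not the absolute strain magnitudes of any particular real
canaliculus.

## Units and scaling

All interfaces use nm, s, pN and Pa. The lattice works in lattice units
with a scaling record per run: the relaxation time is $\tau = 1$
(guarded to $(0.5, 2]$), and the velocity scale is chosen so the Darcy
plug sits at a lattice Mach of $2\times10^{-5}$ for coupled runs (the
headroom accommodates impulsive tether forces during the acceleration
described below; pure-flow validation runs use $2\times10^{-3}$).
Because the problem is in the Stokes regime, only the dimensionless
groups (e.g. $h/\sqrt{k_p}$) are preserved, not physical time.

## Reaching the steady state

The experiment of interest is the steady state under constant drive.
Relaxing the coupled system there is numerically stiff for two reasons:
tether springs ($\sim 3$ pN/nm) are orders of magnitude stiffer than the
membrane's soft modes, and the softest mode of all — rigid axial
translation of the process — is restored only by the *second-order*
engagement of mostly transverse, tension-only TEs. `run_simulation`
therefore uses pseudo-transient relaxation with accelerators that leave
the fixed point unchanged:

- **Per-node pseudo-time scaling.** Each node advances with
  $\gamma_i = \eta / (M\,k_i)$, where $k_i$ is a local stiffness
  estimate (membrane scale $8G_s(C{+}1)$, plus twice $k_{sp}$ at
  tethered vertices — the doubled margin covers mobility coupling with
  overlapping neighbour kernels) and $M$ an immersed-node mobility
  estimate combining the single-node kernel self-mobility with the
  coherent-sheet mobility of overlapping kernel footprints.
  $\eta = 0.45$ keeps every local mode below the stability limit.
- **Heavy-ball momentum** ($\beta = 0.96$; 0.88 at tethered vertices,
  whose taut/slack switching otherwise sustains local limit cycles) on
  the membrane update, accelerating the soft collective modes.
- **Secant acceleration of axial translation.** The translation
  amplitude is updated every 150 steps by a damped secant step toward
  zero mean membrane velocity, using the mean velocity averaged over the
  preceding half-interval (taut/slack switching makes instantaneous
  slopes noisy).
- **Interior damping.** The intracellular fluid, which carries no
  physical Brinkman drag, is given a numerical damping of the same
  magnitude during relaxation; the damping force is proportional to
  $\mathbf u$ and vanishes at the steady state, where the interior is at
  rest, so the converged solution is unaffected.
- **Warm starts.** Ensemble members share rigid-membrane steady flow
  fields per drive direction as initial lattice states.

**Termination.** A true fixed point (membrane speed below
$10^{-4}$ of the Darcy velocity, e.g. at zero drive) ends the run
immediately. Under drive, however, the tension-only tethers admit a
residual axial creep that never fully stops, and the taut/slack
switching of individual tethers puts a noise floor of a few percent on
any windowed stationarity detector, so adaptive stopping is both
unreliable and non-uniform across ensemble members. The production runs
therefore follow a *fixed relaxation protocol* of 6000 coupling cycles,
identical for every member and direction, which keeps members
comparable and the runtime deterministic. The budget was chosen from
convergence diagnostics: across the seeds examined, the mean membrane
drift falls below 10% of the Darcy velocity by roughly 4500-5500
cycles, and the NEAR/FAR strain medians change by only a few percent
per 1000 cycles thereafter (the residual slow settling moves the
strain-concentration ratio by under ~10% between 6000 and 12000
cycles). Each result records a `converged` flag stating whether, at the
end of the protocol, the fluid was steady, the drift bound was met and
the strain medians were stationary (8% per 1000 cycles over two
800-cycle windows, comparing window medians). The secant translation
updates switch off once the mean drift falls below 2% of the Darcy
velocity, the heavy-ball momentum anneals to $\beta = 0.85$ once the
drift bound is met, and sustained ringing episodes are quenched by
draining the momentum. A control without TEs has no steady state at all
(a freely suspended tube translates with the flow indefinitely); its
fields are reported at the same fixed budget.

## Numerical choices

- Voxel classification uses voxel centers against the analytic radius
  fields; surface-cut voxels are not sub-resolved.
- Voxel labels are fixed at the reference configuration; membrane
  displacements (sub-nm to a few nm) are small against
  $\Delta x = 5.1$ nm.
- The 4-point cosine kernel's support ($\pm 2\Delta x \approx 10$ nm) is
  wider than the Brinkman screening length $\sqrt{k_p} = 2.65$ nm, so
  the no-slip membrane is diffuse at this resolution: the quasi-steady
  state stalls a kernel-wide fluid shell rather than a sharp surface.
  This is inherent to the model's discretization scale.
- Anchor search: coarse $(z,\varphi)$ surface grid (192 x 192) with
  three 13 x 13 local refinements; grid candidates are ordered by
  ascending $z$ then azimuth so exact ties resolve deterministically.
- Degenerate triangles (reference area below $10^{-6}$ nm$^2$, or
  collapsed current elements) are rejected or flagged and excluded.
- Tie-free determinism: a fixed seed reproduces geometry, tether sets
  and results bit for bit on one platform.

## Problem sizes used in the shipped analyses

The analysis scripts and the acceptance study use a reduced
resolution: $\Delta x = 5.1$ nm, pre-mirror length 150 nm
(snapped to 147.9), membrane edge $\approx 7$ nm ($\sim$2256 vertices,
4512 elements, $\sim$119k fluid voxels), five tether seeds times two
flow directions. One coupled run relaxes in roughly 5000–9000 cycles.
Unit tests use smaller tubes (radii 20–25/48–60 nm, lengths 60–70 nm)
where closed-form oracles are exact or nearly so.

## Known limitations

- The strain measure is the per-element maximum principal
  Green–Lagrange strain; the reference is the no-flow configuration.
- Quasi-steady reporting: tensions on the residual-creep branch drift
  on timescales far beyond the stationarity windows; the reported
  medians inherit a few-percent uncertainty from the termination rule.
- No TE rupture or viscoelasticity, no wall compliance, no membrane
  bending stiffness or self-contact, no oscillatory loading, and no
  canalicular-network-scale flow coupling.
- Absolute strain/tension medians depend on the synthetic geometry's
  roughness statistics; only their orders of magnitude and the relative
  (NEAR vs FAR, tension vs angle) structure are meaningful comparisons
  against nanometer-resolution image-based results.
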