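---
title: "A multi-scale forward model of muscle EMG and MMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale forward model of muscle EMG and MMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`myomag` simulates the electric potential and the magnetic field generated
by skeletal-muscle activity, from the ion-channel kinetics of the fibre
membrane up to virtual surface sensors. This vignette describes the model,
its numerical treatment, the choices made where the design was open, and
what the simulated conditions do and do not represent.

## The model

### Electric problem

Skeletal muscle tissue is represented as a homogenised multi-domain
continuum: at every material point of the muscle region an extracellular
space coexists with $N$ intracellular spaces, one per motor unit (MU). Each
intracellular space has a potential $\phi_i^k$, the extracellular space has
$\phi_e$, and the transmembrane potential of unit $k$ is
$V_m^k = \phi_i^k - \phi_e$. In the quasi-static limit, charge conservation
plus Ohm's law yield one elliptic equation,

$$0 = \nabla\!\cdot\!\left[\sigma_e \nabla \phi_e\right]
  + \sum_{k=1}^{N} f_r^k\, \nabla\!\cdot\!\left[\sigma_i^k
  \nabla (V_m^k + \phi_e)\right],$$

and one reaction–diffusion equation per motor unit,

$$\frac{\partial V_m^k}{\partial t}
  = \frac{1}{C_m A_m}\Big( \nabla\!\cdot\!\left[\sigma_i^k \nabla (V_m^k +
  \phi_e)\right] - A_m\, I_\mathrm{ion}(\mathbf y^k, V_m^k,
  I_\mathrm{stim}^k) \Big),$$

with Hodgkin–Huxley gating dynamics $\dot{\mathbf y}^k = g(\mathbf y^k,
V_m^k)$. Here $f_r^k \in [0,1]$ is the local volume fraction of fibres
belonging to unit $k$, $C_m$ the membrane capacitance and $A_m$ the fibre
surface-to-volume ratio. The intracellular conductivity tensor is rank-one
along the fibre direction $\mathbf f$, $\sigma_i^k = \sigma_i^l\, \mathbf
f\otimes\mathbf f$, so intracellular diffusion is one-dimensional along
each fibre line. Subcutaneous fat is an electrically passive volume
conductor, $\nabla\!\cdot\!(\sigma_b \nabla\phi_b)=0$, continuous in
potential and normal current with the muscle at their interface. All outer
boundaries are insulating (zero Neumann); one outer corner node is pinned
to 0 mV to mimic a grounding electrode and fix the Neumann nullspace.

### Magnetic problem

Because tissue is non-magnetic, the magnetic field decouples and follows
from the conductive current densities. Each domain contributes its ohmic
current — extracellular $j_e=-\sigma_e\nabla\phi_e$, intracellular
$j_i^k=-\sigma_i^k\nabla(V_m^k+\phi_e)$ weighted by $f_r^k$, and body
$j_b=-\sigma_b\nabla\phi_b$ — and the contributions add linearly. In the
Coulomb gauge the vector potential solves a componentwise Poisson problem,

$$\nabla^2 \mathbf A = -\mu_0 \Big( j_e + \sum_k f_r^k j_i^k \Big)
  \quad\text{(muscle)}, \qquad \nabla^2 \mathbf A = -\mu_0\, j_b
  \quad\text{(body)}, \qquad \nabla^2 \mathbf A = 0 \quad\text{(air)},$$

with $\mathbf A \to 0$ far away and $\mathbf B = \nabla\times\mathbf A$.
Transmembrane currents are not magnetic sources: at the homogenised scale
their circular contributions around each cylindrical fibre cancel.
Macroscopic measurement components follow the tissue axes: $B_l$ along the
fibres, $B_t$ across the fibres and tangential to the surface, $B_n$ normal
to the surface.

## Parameters

| Parameter | Symbol | Default | Unit |
|---|---|---|---|
| intracellular conductivity (longitudinal / transversal) | $\sigma_i^l$, $\sigma_i^t$ | 8.93 / 0 | mS/cm |
| extracellular conductivity (longitudinal / transversal) | $\sigma_e^l$, $\sigma_e^t$ | 6.7 / 3.35 | mS/cm |
| fat conductivity | $\sigma_b$ | 0.4 | mS/cm |
| membrane capacitance | $C_m$ | 1 | uF/cm^2 |
| surface-to-volume ratio | $A_m$ | 500 | 1/cm |
| vacuum permeability | $\mu_0$ | $4\pi\times10^{-7}$ | T m/A |

The membrane model is the classic squid-axon parameter set ($g_{Na}=120$,
$g_K=36$, $g_L=0.3$ mS/cm², physiological-voltage convention with rest near
−75 mV, matching the standard CellML encoding). The working units
throughout the electric stage are cm, ms, mV, mS/cm and uA/cm²; the
magnetic stage converts to SI and reports B in picotesla.

## The reference experiments

The in-silico protocol places a 4 × 1.5 × 2 cm muscle block (fibres along
the long edge) under an optional fat layer of 0, 0.2 or 0.4 cm. Two motor
units partition the muscle: the recruited unit MU1 is a single
fibre-parallel line of nodes at cross-section $x_t = 0.75$ cm, $x_n = 2 -
d$ cm, where $d$ is the activation depth (0.3–1.1 cm); the passive unit
MU2 owns every other node; both have $f_r = 1$ on their territory. A
single current pulse (700 mA/cm² for 0.1 ms, onset 1 ms) at MU1's
neuromuscular junction ($x_l = 1$ cm) elicits two action potentials that
propagate towards the fibre ends at roughly 2.5 m/s. Virtual sensors record
$[\phi, B_l, B_t, B_n]$ at 10 kHz: a single channel at $x_l=2.5$ cm,
$x_t=0.6$ cm, and a line of channels across the fibres at $x_l = 2.5$ cm.
Signal metrics (RMS, periodogram PSD, mean frequency, inter-channel
coefficient of variation, null-to-maximum distances) are computed from
stimulus onset to the end of the run.

The stimulus amplitude, taken literally, is far above the membrane model's
threshold; it drives the junction node to non-physiological potentials for
a fraction of a millisecond before potassium currents restore it. Away from
the junction the emerging action potential is the standard suprathreshold
wave, identical for any suprathreshold amplitude.

## Numerics

* **Discretisation.** Vertex-centred regular grid, 7-point
  finite-difference stencils with harmonic face averaging of the (diagonal)
  conductivity tensors; fibres must align with a grid axis. Default spacing
  0.05 cm for production runs; the desk-scale studies in the tests and the
  acceptance script use 0.1 cm (grid 41 × 16 × 21 for the bare muscle).
* **Time stepping.** Godunov splitting with a 0.1 ms PDE step matching the
  10 kHz sampling: (i) ten 0.01 ms membrane substeps (Rush–Larsen for the
  gates, forward Euler for the potential), (ii) sparse Cholesky solve of
  the elliptic problem (factorised once, reused every step), (iii)
  backward-Euler implicit diffusion along fibre lines (block-tridiagonal,
  factorised once). Halving both steps from the default changes the surface
  EMG RMS by about 1.4%. Shrinking the time step further while keeping the
  0.1 cm grid sharpens the travelling wave towards the grid-limited profile
  and visibly changes the surface far field, so convergence studies must
  refine space and time together.
* **Magnetic solve.** The padded air box (4 cm on each side, about one
  muscle body-diagonal) imposes $\mathbf A = 0$ on its boundary; doubling
  the padding moves surface-sensor fields by under 1–2%. The uniform
  Dirichlet Laplacian is diagonalised by a type-I discrete sine transform,
  which is exactly the sparse 7-point system and costs $O(n \log n)$.
  Sensor time series use reciprocity: one adjoint solve per sensor and
  A-component gives weights whose dot product with the tissue currents is
  the sensor field — algebraically identical to the full-field solve and
  curl, and it makes the per-domain decomposition exactly additive. The
  Coulomb-gauge residual of the discrete solution is controlled by the air
  box size (it roughly vanishes cubically with padding) rather than by the
  grid spacing.
* **Degenerate inputs.** Zero spacings, non-dividing spacings, depths
  outside the muscle and non-normalised fibre fields are rejected;
  reaction substeps above 0.02 ms are refused (gate-update stability);
  non-finite states abort with the offending node.

## What the model idealises

The geometry is a box, the fibres are straight, all fibres of a unit share
one membrane state per material point, and sensors are ideal points that do
not load the fields. The recruited unit is geometrically a single grid-cell
line: its cross-section, and therefore every absolute signal amplitude,
scales with the grid spacing squared. Absolute amplitudes are consequently
reported only relative to reference runs; they sit in the tens-to-hundreds
of picotesla at desk resolution and would shrink towards realistic
single-fibre values on finer grids.

Two further consequences of this idealisation deserve emphasis. First,
signal ratios between runs are well behaved when both runs are dominated by
near-field physics, but for deep sources the magnetic components orthogonal
to the fibre become small residuals of nearly cancelling domain
contributions (the extracellular volume currents against the intracellular
ones); such residuals are sensitive to the discretisation of the wave's
along-fibre curvature and should not be over-interpreted at desk scale.
Second, the split of the field into domain contributions shows a strong
passive-fibre (non-recruited intracellular) term: the passive fibres act as
embedded conductors that carry return current against the extracellular
flow — physically expected in the multi-domain picture, and the component
of the decomposition most sensitive to resolution.

Passing the test suite therefore demonstrates that the discrete operators,
solvers and signal metrics implement the stated model faithfully (each is
checked against an independent oracle: literal 1952 rate equations, a
high-accuracy ODE integrator, the 1-D heat kernel, the anisotropic dipole
potential, Ampère's law for a straight wire, exact curl/divergence
identities and Parseval equality) — not that a 0.1 cm grid reproduces every
property of real muscle recordings or of a finer discretisation.

## Reproducing the study numbers

`scripts/acceptance.R` re-runs the full protocol — the depth sweep (0.3 and
1.1 cm), the constant-distance fat sweep (0/0.9, 0.4/0.5 cm), the
contribution analysis (0.2/0.5 cm) and the channel-line statistics — on the
0.1 cm grid and writes the resulting ratios, factors, percentages and
distances to JSON. Each run takes tens of seconds; the whole script runs in
a few minutes on one CPU.
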