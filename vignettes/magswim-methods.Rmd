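---
title: "Modelling magnetotactic swimmers in sediment-like obstacle channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling magnetotactic swimmers in sediment-like obstacle channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(magswim)
```

## The model

`magswim` simulates magnetotactic bacteria — swimmers such as
*Magnetospirillum gryphiswaldense* that carry a chain of magnetosomes and
therefore a permanent magnetic moment — as dipolar active Brownian particles
(ABPs) in two dimensions. Each particle has a position $\mathbf r$ and an
orientation angle $\varphi$ with body axis
$\hat{\mathbf e} = (\cos\varphi, \sin\varphi)$, and obeys the overdamped
Langevin equations

$$\dot{\mathbf r} = v_0 \hat{\mathbf e} + \tfrac{1}{\gamma_T}\mathbf F
  + \sqrt{2 D_T}\,\boldsymbol\xi_T, \qquad
  \dot\varphi = \tfrac{1}{\gamma_R}\tau + \sqrt{2 D_R}\,\xi_R,$$

with Stokes drags $\gamma_T = 3\pi\eta\sigma$, $\gamma_R = \pi\eta\sigma^3$
for a sphere of diameter $\sigma$ and diffusion constants fixed by
fluctuation–dissipation, $D_{T,R} = k_BT/\gamma_{T,R}$.

Three ingredients beyond free swimming:

* **Dipole alignment.** A homogeneous field $B$ along $+x$ exerts the
  restoring torque $-\mu B \sin\varphi$. The dimensionless alignment
  strength is $\kappa = \mu B / k_B T$; at the geomagnetic 50 µT and
  $\mu = 4\times10^{-16}$ J/T, $\kappa \approx 4.86$, so alignment is strong
  but far from perfect ($\langle\cos\varphi\rangle \approx 0.89$).
* **Obstacle repulsion.** Walls and circular pillars repel the swimmer
  through a WCA force evaluated against a *virtual particle* whose surface
  touches the nearest point of the solid, so that every solid behaves
  locally like a plane of particles: $\mathbf F_S = 48\epsilon
  (\mathbf r_S / r_S^2)[(\sigma/r_S)^{12} - \tfrac12 (\sigma/r_S)^6]$ for
  $r_S < 2^{1/6}\sigma$ and zero beyond, with $r_S$ the centre-to-centre
  vector and $\epsilon = 4\,k_BT$.
* **Surface torque.** Sliding along boundaries is governed by a
  phenomenological torque $\tau_S = \alpha [\hat{\mathbf e} \times
  \mathbf F_S]_z$ that rotates the body axis towards the outward normal.
  The length $\alpha$ is the model's single free parameter; the package
  calibrates it by matching simulated sliding-distance histograms
  (`calibrate_alpha()`), which recovers $\alpha = 0.2$ µm references
  cleanly on the default grid.

Default parameters (`model_params()`): $\sigma = 1$ µm, $v_0 = 50$ µm/s,
$T = 298$ K, $\eta = 8.9\times10^{-4}$ Pa·s, $\mu = 4\times10^{-16}$ J/T,
$\epsilon = 4 k_BT$, $\alpha = 0.2$ µm. These give $D_T = 0.49$ µm²/s,
$D_R = 1.47$ rad²/s, a Péclet number $v_0\sigma/D_T \approx 102$, and a time
unit $\sigma^2/D_T \approx 2.04$ s (`to_reduced()`).

## Numerical integration

The compiled engine advances all particles with the Euler–Maruyama scheme at
a base step of $dt = 10^{-4}$ s. Two refinements keep the stiff WCA force
stable without paying for it everywhere:

* an elementary step is shortened so that the deterministic displacement
  $|v_0\hat{\mathbf e} + \mathbf F/\gamma_T|\,dt$ never exceeds 0.02 µm and
  the deterministic rotation never exceeds 0.05 rad; additionally steps are
  capped at $dt/10$ whenever the surface distance $h < 0.45\sigma$. The
  sliding equilibrium sits near $h \approx 0.5\sigma$ (where the WCA
  repulsion balances $v_0$), so ordinary sliding runs at the full step and
  only genuinely stiff transients are refined.
* if a proposed move would place a particle centre inside a solid, it is
  re-proposed with fresh noise at a tenth of the step, up to four times;
  a still-failing move is rejected and counted (`n_reject` on the
  trajectory object). At the default step this path is essentially never
  taken.

Noise comes from a single xoshiro256+ stream per simulation, seeded from the
configuration seed, so every run is bitwise reproducible. By default only
the single nearest solid element exerts force and torque in a step (ties go
to the lowest obstacle index, with walls after obstacles); whether both
pillars of a wedge should push simultaneously when a swimmer sits in the
apex is a genuine modelling ambiguity, so
`run_simulation(all_contacts = TRUE)` sums the virtual-particle force over
every element within the cutoff instead — in the reference trap the two
variants give escape times that agree within sampling error. A cell list
over the pillars keeps the nearest-contact search O(1) per step in large
channels.

## Synthetic sediment channels

`generate_obstacle_channel()` emulates the measured statistics of a
silt-like freshwater sediment: pillar diameters are drawn from a Gaussian in
log diameter of the form $a\exp(-(x-\mu)^2/c^2)$ with $\mu = 3.83$,
$c = 0.5903$ (standard deviation $c/\sqrt2$; mean grain diameter
$e^{3.83} \approx 46$ µm), and pillars are added with unrestricted overlap
until the rasterised solid fraction reaches 61 %. Overlapping pillars are
essential: they create the concave wedges ("traps") that dominate transport
at strong fields.

The granulometry mirrors common practice for binarised tomography slices:
grains are separated by a diamond-shaped erosion (radius 9 px at 1.56 µm/px),
eroded components become markers, the full solid phase is partitioned among
markers by nearest-marker propagation, and each grain is summarised by an
equivalent-area circle. Radii are measured on the *uneroded* partition to
avoid systematic shrinkage. Water gaps are quantified by the 2D local
thickness of the fluid phase — the largest inscribed disc through each fluid
pixel — a two-dimensional analogue of the trabecular-separation measure used
for 3D volumes; the two are never compared numerically.

Packings at 61 % solid sit near the 2D continuum percolation threshold, so a
given realisation may or may not admit a connected fluid path.
`channel_percolates()` tests this purely geometrically (fluid connectivity
after eroding half a swimmer diameter); transit experiments precondition
their channel seed on it, the package's analogue of the experimental
practice of ensuring a perfusable channel. What the generator does *not*
emulate: irregular (non-circular) grain outlines, manual widening of
critical gaps, and any 3D structure.

## Transit, sliding, and trap analyses

Transit experiments seed particles on the fluid part of the entrance line
with uniformly random headings (the field aligns them within a fraction of a
second, far shorter than any transit time), and record per-particle arrival
times at the exit threshold; arrived particles are removed. `arrival_curves()`
reports the cumulative arrived fraction $\varphi(t)$, the first-arrival time
$t_f$, and the final fraction $\varphi_{tot}$. The OUT:IN throughput ratio
(`throughput_ratio()`) is the cumulative exit-strip count over the
cumulative entrance-strip count, with 200 µm strips by default.

Sliding events are maximal runs within 2 µm of one pillar's surface that
also touch the interaction band ($h \le 2^{1/6}\sigma - \sigma/2 \approx
0.62$ µm); the sliding distance sums the displacement components tangential
to the surface at segment midpoints. Calibration compares normalised
histograms (2 µm bins, 0–30 µm, squared-frequency objective) at $B = 0$, the
condition under which sliding is field-independent.

Traps are two-pillar wedges. For the apex (upstream circle–circle
intersection) the depth is defined as
$d = x_{apex} - \max_i(x_{c,i} - r_i)$ — the upstream excursion along the
field axis from the apex to the nearer release pole. For the symmetric
reference trap ($r = 50$ µm, $\Delta y = 100$ µm, tangent pillars) this
gives $d = 50$ µm.

**Escape criteria.** Escapes start 1.5 σ from the apex along the wedge
bisector with uniform headings. Two distinct observables both deserve the
name "escape time", and the package implements both
(`simulate_escape(criterion = ...)`), with no re-entry check in either:

* *committed* (default): the swimmer has crossed the plane $2\sigma$
  downstream of the apex while clear of both interaction bands — it has
  left the trap and proceeded downstream. This is the notion behind the
  headline mean escape time of the reference trap at 50 µT.
* *barrier*: the swimmer is farther from the apex than the farther release
  pole plus $2\sigma$ and clear of both bands — first passage over the
  barrier top of the Kramers picture.

The two agree at moderate and strong fields up to a few seconds of travel
time. At weak fields they diverge sharply: commitment requires downstream
drift that the field no longer provides, so at $B = 0$ the committed time
measures slow undirected circumnavigation of a pillar rather than the
(fast) barrier passage. Field and depth sweeps therefore default to the
barrier notion, the one comparable across field strengths and the one to
which an exponential (Kramers-like) law in $B$ or $d$ can meaningfully
refer.
Escape-time fits use the right-censored exponential MLE
$\hat\tau = \sum t_i / n_{esc}$, so deep traps with few escapes report a
finite, flagged estimate. Sweeps fit $\tau = \tau_0 e^{B/\bar B}$ (or
$e^{d/\bar d}$) by least squares in $\ln\tau$.

The field step-down release holds an ensemble in a trap at a strong field
and lowers the field in steps, reporting occupancy of a triangular region
(30 µm extent) opening upstream from the apex.

## Problem sizes and what the tests show

The test-suite simulations are scaled to run on one CPU in minutes: escape
ensembles of 30–500 swimmers, transit channels of 1500 µm × 1200 µm with
40–100 swimmers over 300–600 s, and sweeps with 30 swimmers per control
value. These reproduce, at reduced size: the closed-form free-ABP mean
squared displacement; the von-Mises stationary heading distribution
($\langle\cos\varphi\rangle = I_1(\kappa)/I_0(\kappa)$); exponential
escape-time distributions and the exponential growth of $\tau$ with $B$;
the vanishing channel throughput at 500 µT with an interior optimum at
intermediate fields; surface-torque parameter recovery; and grain-statistics
round trips at moderate packing (45 % solid — at 61 % the erosion-based
separation merges and loses too many grains for parameter recovery, a
limitation shared by the original image-analysis pipeline).

Synthetic data cannot establish that the *parameter values* describe any
particular organism, only that the implementation reproduces the model's
consequences; and a 2D disc with an effective surface torque elides
hydrodynamic wall attraction, flagellar reversals, sliding slow-down and
particle–particle interactions, all deliberately out of scope.

## A worked example

```{r example, eval = FALSE}
trap <- make_symmetric_trap(r = 50, dy = 100)
trap_depth(trap)                       # 50 um
er <- simulate_escape(trap, model_params(B = 50e-6), n = 100, seed = 1)
coef(er)                               # mean escape time, s
sw <- sweep_field(trap, c(10, 25, 50, 75, 100) * 1e-6, n = 30, seed = 2)
plot(sw)                               # ln tau grows linearly with B
```
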