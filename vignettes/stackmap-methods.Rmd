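---
title: "Modelling self-assembled hairpin stacks and their hydration with stackmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-assembled hairpin stacks and their hydration with stackmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(stackmap)
library(dplyr)
```

`stackmap` analyses the multiscale structure of a self-assembling
β-hairpin peptide in solution as seen by neutron scattering: at large
scales, hairpins stack into charged elliptical cylinders whose geometry is
read off a small-angle (SANS) curve; at atomic scales, the hydration shell
around each surface atom is characterised by site--water radial
distribution functions (RDFs) and condensed into a per-site
hydrogen-bonding index Δ. This vignette explains the models, their
assumptions, the tunable parameters, and the design decisions taken where
more than one reasonable choice existed.

## The composite small-angle model

The measured differential cross section of the peptide solution is
modelled as

$$I(Q) = \phi\,\Delta\rho^2 V_{\mathrm{block}}\, P_{EC}(Q)\, S_{ER}(Q)
 + \alpha e^{-(Q-Q_{ip})^2/2\sigma_{ip}^2}
 + \beta e^{-(Q-Q_{is})^2/2\sigma_{is}^2}
 + \gamma Q^{-n} + \mathrm{bkg},$$

with the five terms carrying distinct physics:

* **Cylinder term.** $P_{EC}$ is the orientationally averaged form factor
  of a cylinder of length $L$ with elliptical cross section (semi-axes
  $R_{minor} \le R_{major}$), describing the stacked-hairpin particle.
  $S_{ER}$ is the interparticle structure factor of charged spheres
  repelling through a screened Coulomb potential; it produces the
  characteristic low-$Q$ suppression (an inflection near
  $Q \sim 0.1\,\text{Å}^{-1}$ at the reference conditions). The particle
  charge $Z$ enters through a DLVO contact potential with the Debye length
  computed from ionic strength, temperature and dielectric constant.
* **Two Gaussians.** Mid-$Q$ peaks at $Q_{ip}$ and $Q_{is}$ encode two
  repeated internal spacings of the stack. Via the Bragg relation
  $d = 2\pi/Q$ they convert to the inter-hairpin distance
  $d_{ip} = 2\pi/Q_{ip}$ and the inter-strand distance
  $d_{is} = 2\pi/Q_{is}$; the widths are free parameters.
* **Power law.** $\gamma Q^{-n}$ captures sparse, very large aggregates
  that dominate only below $Q \sim 10^{-2}\,\text{Å}^{-1}$.
* **Background.** A constant models incoherent scattering.

The amplitude prefactor uses the standard absolute-scale convention
$\phi \Delta\rho^2 V_{\mathrm{block}}$ with
$V_{\mathrm{block}} = \pi R_{minor} R_{major} L$. Because $\phi$ and
$\Delta\rho^2 V$ are degenerate in amplitude, the fitter adjusts a single
combined scale and re-derives $\phi$ from the user-supplied contrast; the
same $\phi$ feeds the structure factor so that amplitude and interparticle
interference stay mutually consistent. The form factor and structure
factor are coupled as a plain product $P \times S$; no anisotropy
decoupling correction is applied, a known limitation for long cylinders.

The structure-factor hard core is a sphere of volume equal to the
cylinder (`equivalent_sphere_diameter()`), a conventional mapping given
that no other is singled out by the model.

```{r model-curve}
p <- paper_sans_params()
q <- exp(seq(log(0.003), log(3), length.out = 300))
autoplot(composite_intensity(q, p))
```

### Numerical engines

* **Form factor.** `elliptical_cylinder_form_factor()` averages the
  squared amplitude over the cylinder-axis polar angle and cross-section
  azimuth by fixed-order Gauss–Legendre quadrature (defaults 76 × 24,
  configurable). It is validated in the test suite against the circular
  closed form at equal radii and a $10^6$-sample Monte Carlo orientation
  average.
* **Structure factor.** `charged_structure_factor()` solves the
  Ornstein–Zernike equation with the mean-spherical-approximation closure
  (hard core plus Yukawa tail) on a sine-transform grid, with Ng-accelerated
  Picard iteration. At $Z=0$ this closure *is* Percus–Yevick, which the
  tests exploit as an independent closed-form oracle. When the plain MSA
  yields an unphysical negative contact value $g(d^+)<0$ — dilute, strongly
  charged systems — the hard core is grown at fixed density and potential
  until $g(d^{*+}) = 0$, the usual rescaled-MSA prescription. The c(r)
  discontinuity at contact is sampled with its one-sided mean, keeping the
  discretisation second-order; the default grid (128 nodes per core
  diameter, 4095 radial nodes) reproduces Percus–Yevick to better than
  $10^{-3}$ relative, and the coarser grid used inside fits (64 / 2047)
  differs from it by under 0.1%.

## The staged fit

Fitting all ~14 parameters at once is unstable because the terms dominate
disjoint $Q$ windows. `staged_fit()` therefore fits term by term
(`stage_config()` holds the windows, all configurable):

1. **Power law** on $Q <$ `pl_qmax` (default $10^{-2}\,\text{Å}^{-1}$),
   together with a local constant offset that absorbs the
   charge-suppressed cylinder plateau plus background under that window;
   only $(\gamma, n)$ are kept.
2. **Gaussians + flat baseline** on 0.5--3 Å⁻¹; the baseline becomes the
   background estimate.
3. **Cylinder** (combined scale, $L$, $R_{minor}$, $R_{major}$, $|Z|$) on
   0.02--0.5 Å⁻¹ with stages 1--2 frozen. $R_{major}$ is parameterised as
   $R_{minor}\times$ axial ratio with the ratio bounded below by 1, which
   enforces $R_{major} \ge R_{minor}$ without constrained optimisation.
4. Stages 2--3 are then **cycled once more** (default `n_cycles = 2`):
   the second pass refits the Gaussians with the now-known cylinder tail
   subtracted and vice versa. A single pass leaves a small coupling bias
   (the baseline absorbs the cylinder tail, displacing the radii by about
   half a percent); two passes reduce self-consistency error on noiseless
   data below $10^{-3}$ relative on every parameter.
5. An optional bounded **global polish** (`polish = TRUE`) refines all
   parameters jointly; it is off by default and not needed for the studies
   shipped with the package.

Residuals are weighted $1/\sigma$ where uncertainties exist, and uniformly
in $\log I$ otherwise. Optimisation uses Levenberg–Marquardt
(`minpack.lm`) with box bounds; 1-σ uncertainties come from the per-stage
covariance. The fitted object supports `tidy()`, `glance()`, `augment()`
and `autoplot()`.

`stack_metrics()` turns a fitted set into stack geometry: $d_{ip}$,
$d_{is}$ by the Bragg relation, monomers per stack as
$\mathrm{round}(L/d_{ip})$, the cross-section aspect ratio, and the total
stack charge as $n_{units}$ times a per-monomer charge. At the reference
geometry ($L = 60$ Å, $d_{ip} = 8.5$ Å, $R = 6.5/12.6$ Å, monomer charge
$-2$ e) this yields 7 hairpins per cylinder, aspect ratio 1.94 and a stack
charge of $-14$ e.

```{r metrics}
stack_metrics(p, per_monomer_charge = -2)
```

### The reference parameter set and what the recovery study shows

The amplitudes of the composite model (absolute scale, Gaussian and
power-law amplitudes, background) are not uniquely determined by the
geometry; `paper_sans_params()` fixes one realistic set: volume fraction
0.11 (a 150 mg/mL peptide solution at typical protein mass density),
contrast $3\times10^{-6}\,\text{Å}^{-2}$ (protonated peptide in D₂O),
$\gamma = 10^{-5}$, bkg = 0.05 cm⁻¹ and Gaussian amplitudes 0.05/0.04
cm⁻¹ — values that reproduce the qualitative curve anatomy: power law
dominant below $\sim$0.02 Å⁻¹, electrostatic inflection near 0.1 Å⁻¹,
twin peaks near 1 Å⁻¹ riding on a flat background.

`sans_recovery_study()` generates noisy synthetic curves (1%
multiplicative Gaussian noise, 400 log-spaced points over
0.003--3 Å⁻¹) from this set and refits each from a fixed, deliberately
wrong start (`recovery_init()`). Passing this study shows that the staged
procedure is unbiased and precise *under the model's own assumptions* —
exact model form, uncorrelated noise, single population. It does not
exercise instrument resolution smearing, polydispersity, or model
misspecification, all of which affect real beamline data.

## Total-scattering utilities

`q_from_geometry()` implements $Q = 4\pi\sin\theta/\lambda$ (with $\theta$
half the scattering angle), `d_from_q()` the Bragg relation.
`sq_from_gr()`/`gr_from_sq()` convert between site--site RDFs and partial
structure factors,

$$S_{\alpha\beta}(Q) = \rho \int 4\pi r^2\,[g_{\alpha\beta}(r)-1]\,
  \frac{\sin Qr}{Qr}\,dr,$$

by trapezoidal quadrature on uniform grids, with an optional Lorch-style
taper (off by default) to damp truncation ripple. The convention excludes
the self term, so $S_{\alpha\beta}\to 0$ at high $Q$ and the weighted sum

$$I(Q) = \sum_{\alpha\le\beta}(2-\delta_{\alpha\beta})
  c_\alpha c_\beta b_\alpha b_\beta S_{\alpha\beta}(Q)$$

is a pure interference term (`total_iq_from_partials()`). Coherent
scattering lengths are an internal table (H, D, C, N, O, Na; bound values
from the standard neutron tables, in fm); exchangeable hydrogens scatter
with the solvent-average $(1-x_D) b_H + x_D b_D$, which is what makes one
set of partials predict distinct H₂O/HDO/D₂O contrasts.

## Stack building and solvation

`build_stack_mc()` assembles `n_units` rigid monomer copies along +z by
Metropolis Monte Carlo over rigid-body poses. The score is a capped
soft-core repulsion $\sum \min((r_c/r)^{12}, 100)$, Debye-screened Coulomb
between partial charges (κ from 250 mM 1:1 electrolyte), and a harmonic
restraint pulling each consecutive center-to-center vector toward
(0, 0, spacing) — the restraint both spaces and aligns the stack. Pairs
beyond 2.5 spacings contribute nothing (screening makes them negligible).
The move set is small random rotations (σ = 4°) and translations
(σ = 0.25 Å) of one monomer, annealed geometrically; runs are
bit-reproducible for a fixed seed. This scoring function is a documented
reconstruction — a simple, physically sensible docking score — not a
transcription of any specific published protocol.

`solvate_box()` places the stacks on the box mid-plane with centers
half a box apart, then inserts rigid 3-site waters (OH 1.0 Å, HOH 109.47°,
SPC/E-like charges) and Na⁺ counterions by rejection sampling on a cell
grid: heavy atoms keep ≥ 2 Å from heavy atoms, and no atom (including
water hydrogens) comes within 0.8 Å of any other. The hydrogen check
matters: with a 2 Å oxygen--oxygen floor alone, two facing waters could
overlap their hydrogens exactly.

`synth_reference_config()` combines both at the reference composition —
two 7-mer stacks of the 172-atom toy monomer, 6944 waters, 28 Na⁺ in a
61.506 Å cube — giving 23268 atoms at 0.100 atoms/Å³ and zero net charge.
The toy monomer (`toy_hairpin_monomer()`) is a deterministic geometric
stand-in for a capped 10-residue hairpin: two antiparallel strands plus a
turn in the x--y plane, thin along z, carrying labelled chemistry probes
(a tyrosine-hydroxyl-like donor hydrogen `YHH`, glutamate-like carboxylate
oxygens `EOE1`/`EOE2`, exchangeable backbone amide hydrogens) and partial
charges summing to exactly −2 e. It is *not* a crystal structure; real
structures enter through `read_structure()` with a charge side table.

## Hydration analysis and the hydrogen-bonding index

`compute_rdf()` histograms minimum-image distances between two site labels
over an ensemble of frames, normalised per frame by
$N_\alpha\,\rho_\beta\,4\pi r^2 \Delta r$ (self pairs excluded for
same-label RDFs); the engine is tested for exact equality against a
brute-force double loop.

For each surface site X, first peaks of the X--O$_w$ and X--H$_w$ RDFs are
located by `first_shell_peak()`: the first local maximum inside a window
(default 1.0--3.5 Å) that clears an absolute height threshold (default
1.2) *and* a fraction of the window maximum (default 0.3), refined by
quadratic interpolation through three bins. The relative criterion exists
because shell-like fixtures have $g \gg 1$, where counting noise on a
steep flank would otherwise register as a spurious first maximum.

The peak offset $D = r_{X\text{-}O_w} - r_{X\text{-}H_w}$ is normalised to
the index

$$\Delta = D/R_{donor} \;(D \ge 0), \qquad
  \Delta = D/R_{acceptor} \;(D < 0),$$

with $R_{donor} = 0.96$ Å (the OH bond length as quoted in the index
definition) and $R_{acceptor} = r_{OH}\cos(\theta_{HOH}/2) = 0.577$ Å for
the 3-site reference geometry — the radial hydrogen offset when both
hydrogens point away. Two conventions deserve comment:

* **Clamping.** Δ is clamped to $[-1, 1]$. Finite-distance geometry makes
  the donor endpoint overshoot: a water at 2.8 Å with both hydrogens anti
  has its hydrogens at radial offset 0.67 Å, not 0.577 Å (curvature of the
  shell), and the quoted donor normalisation (0.96 Å OH) differs from the
  3-site model geometry (1.0 Å OH) on the acceptor side. The record keeps
  the raw offset `d` alongside Δ so either convention can be recovered.
* **Classification** is by the sign of $D$ (with $|\Delta| <$ 0.1 called
  neutral, and sites whose first-shell water-oxygen coordination is below
  0.5 called buried rather than assigned Δ = 0).

`delta_surface_map()` pools equivalent atoms across monomers and frames —
equivalent sites are assumed to share one hydration structure — and emits
one record per site label. `write_delta_pdb()` writes Δ into the B-factor
column for surface colouring in any molecular viewer.

### The synthetic shell generator

`synth_hydration_shell()` places waters at Gaussian radial distances
(default 2.8 ± 0.1 Å, a typical hydrogen-bond distance) with orientations
drawn from a mixture: with probability $|\omega|$ the ideal orientation
(one OH bond straight at the site for $\omega > 0$; dipole straight away
for $\omega < 0$), otherwise a *radially neutral* orientation with both
hydrogens at exactly the oxygen's distance from the site (dipole tilted
just past tangential, random azimuth). The neutral choice — rather than a
uniformly random rotation — is deliberate: a uniformly rotated rigid water
spreads its hydrogen density per volume $\propto 1/s$ across the whole
$[r-1, r+1]$ shell, so the first X--H$_w$ peak would sit near $r-1$ and an
unbiased shell would masquerade as a strong acceptor
($\Delta \approx +0.9$). With the neutral component, all three anchor
points $\omega = -1, 0, +1 \to \Delta = -1, 0, +1$ are realised exactly,
and the recovered Δ is a monotone, step-like function of ω (as any
first-peak statistic of a mixture must be). The generator makes no attempt
at water--water correlations; it is a test harness for the index, not a
model of liquid water.

```{r shells}
cfg <- synth_hydration_shell(2000, omega = 1, seed = 1)
gow <- compute_rdf(cfg, c("X", "Ow"), bin_width = 0.05, r_max = 8)
ghw <- compute_rdf(cfg, c("X", "Hw"), bin_width = 0.05, r_max = 8)
hbond_delta(first_shell_peak(gow), first_shell_peak(ghw))
```

## Curve reduction utilities

`stitch_curves()` rescales a wide-angle curve onto the absolute scale of a
small-angle curve with the closed-form least-squares scalar over an
overlap window (the exact rescaling protocol between two instruments'
scales is generally instrument-specific; the least-squares scalar is this
package's documented choice, and the fitted scale is recorded on the
output). `subtract_buffer()` subtracts a solvent scan point-by-point with
quadrature error propagation; the default fraction of 1 corresponds to
subtracting a pure-solvent scan in full. Duplicate $Q$ points are averaged
with sigmas combined in quadrature, keeping grids strictly increasing.

## Problem sizes and determinism

The shipped studies run at desk scale by design: recovery studies use 20
noise seeds on 400-point curves; RDF fixtures use a few thousand waters;
the reference box is a single 23268-atom configuration. Every stochastic
component (noise, shells, Monte Carlo docking, solvation) takes an
explicit integer seed and restores the caller's RNG state, so whole
analyses are reproducible end to end.

## Known limitations

* No instrument resolution smearing or polydispersity in the SANS model.
* $P \times S$ product coupling ignores anisotropy decoupling for long
  cylinders.
* The docking score is a stand-in; it produces geometrically sensible,
  clash-free stacks but is not calibrated against any force field.
* The toy monomer is a geometric object; analyses of real peptides should
  ingest a real structure via `read_structure()`.
* The Δ index summarises first-peak positions only; it does not resolve
  bimodal orientation distributions within one shell.
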