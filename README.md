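# stackmap

Multiscale neutron-scattering analysis of self-assembling β-hairpin
peptides in R.

Short β-hairpin "mini-proteins" such as the 10-residue CLN025 assemble at
high concentration into stacked, charged, roughly cylindrical particles.
Two neutron techniques see this system at complementary scales: small-angle
scattering (SANS) resolves the assembled cylinder — its length,
cross-section and interparticle electrostatic repulsion — while wide-angle
total scattering, interpreted through atomistic configurations, resolves
the hydration shell around individual surface atoms. `stackmap` implements
the analysis layer for both ends and the bookkeeping that connects them,
for structural scientists who want a scriptable, tested version of this
pipeline.

## What it computes

**The composite SANS model.** The measured intensity is fit as

    I(Q) = φ Δρ² V · P_EC(Q) · S_ER(Q)
         + α exp(−(Q−Q_ip)²/2σ_ip²) + β exp(−(Q−Q_is)²/2σ_is²)
         + γ Q⁻ⁿ + bkg

where `P_EC` is the orientationally averaged elliptical-cylinder form
factor (length `L`, semi-axes `R_minor ≤ R_major`), `S_ER` the
screened-Coulomb (rescaled-MSA) structure factor of particles with charge
`Z`, the Gaussians capture the two repeated internal spacings of the stack
(converted to distances by the Bragg relation `d = 2π/Q`), the power law
captures sparse large aggregates at the lowest `Q`, and `bkg` is the flat
incoherent background. `staged_fit()` fits the terms window by window
(power law → Gaussians → cylinder, cycled) for stability;
`stack_metrics()` converts a fitted set into hairpins-per-stack, spacings,
aspect ratio and total charge.

**Total-scattering theory utilities.** `q_from_geometry()`, `d_from_q()`,
RDF ↔ partial-structure-factor sine transforms (`sq_from_gr()`,
`gr_from_sq()`), and concentration/scattering-length weighting with
exchangeable-hydrogen H/D contrast (`total_iq_from_partials()`).

**Stack building and solvation.** `build_stack_mc()` docks rigid monomers
into a stack by Metropolis Monte Carlo (soft-core sterics, screened
electrostatics, spacing restraint); `solvate_box()` packs the stacks with
3-site waters and counterions in a periodic cube;
`synth_reference_config()` reproduces the reference simulation
composition (two 7-mer stacks, 6944 waters, 28 Na⁺, 61.506 Å box → 23268
atoms at 0.100 atoms/Å³, net charge zero).

**Hydration analysis.** `compute_rdf()` (minimum-image site–site RDFs over
frame ensembles), `first_shell_peak()`, and the per-site hydrogen-bonding
index

    Δ = (r_XOw − r_XHw) / R_donor      (acceptors, Δ ∈ [0, +1])
    Δ = (r_XOw − r_XHw) / R_acceptor   (donors,    Δ ∈ [−1, 0])

via `hbond_delta()` and `delta_surface_map()`, which pools equivalent
atoms across monomers, classifies sites as
acceptor/donor/neutral/buried, and can export Δ in the PDB B-factor
column for surface colouring.

**Synthetic data.** Every input has a generator: noisy model curves
(`synth_sans_curve()`), orientation-biased hydration shells
(`synth_hydration_shell()`), and the full solvated box — so the whole
pipeline runs and is tested at desk scale without beamline data.

## Worked example

Generate a noisy synthetic curve at the reference stacked-hairpin
geometry, refit it from a deliberately wrong start, and interpret:

```r
library(stackmap)

truth <- paper_sans_params()       # L = 60 A, R = 6.5/12.6 A, Z = −14 e, ...
q <- exp(seq(log(0.003), log(3), length.out = 400))
curve <- synth_sans_curve(truth, q, noise_fraction = 0.01, seed = 5)

fit <- staged_fit(curve, recovery_init(truth))
fit
#> <sans_fit> staged composite-model fit
#>   L = 57.83 A, R_minor = 6.53 A, R_major = 12.80 A (aspect 1.96)
#>   d_ip = 8.50 A, d_is = 4.49 A, n = 2.99, Z = -14.1 e, phi = 0.110
#>   stage power_law  chi2/dof = 0.981 (70 points)
#>   stage gaussians  chi2/dof = 1.043 (103 points)
#>   stage cylinder   chi2/dof = 1.191 (186 points)

stack_metrics(fit$params, per_monomer_charge = -2)
#> # A tibble: 1 × 5
#>   n_units  d_ip  d_is aspect_ratio total_charge
#>     <dbl> <dbl> <dbl>        <dbl>        <dbl>
#> 1       7  8.50  4.49         1.96          -14
```

The fit recovers the generating geometry within its 1% noise level: a
cylinder of 7 stacked hairpins (length ≈ 58 Å at 8.50 Å per hairpin),
elliptical cross section 6.5 × 12.8 Å, total charge ≈ −14 e, with the
inter-strand repeat at 4.49 Å and the aggregate power-law exponent at 3.
`tidy(fit)` gives estimates with 1-σ uncertainties, `autoplot(fit)` plots
data against the model and its components.

On the hydration side, the index is exact on its worked numbers: a
first-peak offset of 0.95 Å (a carboxylate-like oxygen pulling one water
hydrogen inward) gives

```r
hbond_delta(2.75, 1.80)
#> # A tibble: 1 × 5
#>   r_xow r_xhw     d delta class
#>   <dbl> <dbl> <dbl> <dbl> <chr>
#> 1  2.75   1.8  0.95 0.990 acceptor
```

See `vignette("stackmap-methods")` for the models, assumptions, parameter
defaults and design decisions.

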