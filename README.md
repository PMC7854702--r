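# phytosaxs

Solution small-angle X-ray scattering (SAXS) analysis of dimeric plant
photoreceptors, built around the phytochrome Pr/Pfr photocycle. Plant
phytochromes (~1100 residues per subunit, ~125 kDa) interconvert between a
red-light-absorbing inactive form (Pr) and a far-red-absorbing active form
(Pfr); under red light a solution reaches a *photosteady state* containing
both. phytosaxs provides the complete computational chain used to turn
scattering curves of such mixtures into pure-form structural parameters
and low-resolution shapes:

* **Photosteady-state decomposition.** The measured profile is the
  population-weighted sum
  `I_steady(S) = w_PrPr I_PrPr(S) + w_PfrPfr I_PfrPfr(S)`, `w_PrPr + w_PfrPfr = 1`.
  The weights are estimated from absorption spectra by windowed
  non-negative least squares (`estimate_populations()`), and the pure Pfr
  profile/spectrum is recovered algebraically with full error propagation
  (`decompose_steady()`, `compute_pfr_spectrum()`).
* **Guinier and dilution-series analysis.**
  `I(S) = I(0) exp[-(4π²/3) Rg² S²]` with `S = 2 sinθ/λ`
  (`guinier_fit()`), and the infinite-dilution extrapolation
  `KC/I(0,C) = 1/M_W + 2 A₂ C`, `Rg²(C) = Rg²(0) − B_if C`
  (`fit_dilution_series()`), giving the apparent molecular weight, the
  second virial coefficient and the interference-free radius of gyration.
* **Bead (dummy-residue) models.** Debye forward scattering
  `I(S) = Σᵢⱼ sinc(2πS rᵢⱼ)` with a histogram-accelerated compiled kernel,
  pair-distance histograms, Rg, χ² with the analytic optimal scale factor
  α* (`debye_intensity()`, `chi_square()`), parametric shape generators
  (`generate_shape()`), and GASBOR-style PDB I/O.
* **Ensemble shape classification.** Inertia-axis superposition with
  handedness handling, 6 Å voxel densities, PCA to the leading plane,
  k-means into groups, per-group averaged shapes, and a dummy-residue
  count optimiser over a pluggable reconstruction engine
  (`classify_ensemble()`, `optimize_dr_count()`).
* **Elastic-network normal modes.** Anisotropic Cα network with a distance
  cutoff, full eigenanalysis, B-factor prediction, cutoff calibration
  against crystallographic B-factors and force-constant scaling
  (`build_enm()`, `compute_modes()`, `calibrate_cutoff()`).
* **Smith–Waterman local alignment** with EMBOSS Water conventions
  (BLOSUM62, gap open 10 / extend 0.5) for quantifying sequence identity
  and similarity between phytochrome family members
  (`smith_waterman()`).
* **Synthetic data generators** (`make_*`) that produce every input above
  at desk scale with planted ground truth — the package is fully testable
  without beamline data.

The intended users are structural biologists and methods developers who
analyse solution scattering of photoswitchable or otherwise two-state
protein systems and want the full pipeline scriptable and reproducible in
R.

## Worked example

Estimate Pr/Pfr populations from spectra, decompose a noisy photosteady
profile, and size the recovered Pfr dimer:

```r
library(phytosaxs)

sp <- make_spectra(0.61, noise = 0.001, seed = 42)   # planted Pfr fraction 0.61
w  <- estimate_populations(sp$steady, sp$pr, sp$pfr)
w
#> <mixture_weights> PrPr = 0.3899, PfrPfr = 0.6101 (NNLS 550-800 nm, residual RMS 0.000564)

pr  <- generate_shape("two_subunit_dimer",
         list(subunit = list(kind = "bent_rod",
              params = list(length = 175, diameter = 50, bend_angle = 140)),
              crossing_angle = 60, separation = 40), n_beads = 500, seed = 1)
pfr <- generate_shape("two_subunit_dimer",
         list(subunit = list(kind = "straight_rod",
              params = list(length = 175, diameter = 50)),
              crossing_angle = 75, separation = 40), n_beads = 500, seed = 2)

s     <- seq(5e-4, 0.02, by = 2.5e-4)
i_pr  <- debye_intensity(pr, s)
i_mix <- make_steady_mixture(i_pr, debye_intensity(pfr, s),
                             w_prpr = w$w_prpr, noise_level = 0.002, seed = 7)

i_pfr <- decompose_steady(i_mix, i_pr, w)
guinier_fit(i_pfr, s2_min = 0, s2_max = 4e-6)
#> <guinier_fit> I(0) = 1e+06 +/- 23, Rg = 57.34 +/- 0.007 A (7 pts, R^2 = 1.0000)

radius_of_gyration(pfr)
#> [1] 57.3
```

The spectral unmixing recovers the planted populations (0.39/0.61) to
three decimals despite the added noise, and the Guinier fit of the
decomposed profile returns the straight-rod dimer's radius of gyration
(57.3 Å, here with I(0) = N² = 10⁶ for the 1000-bead model) to within its
standard error. The same pattern — plant a truth with a generator, run
the estimator, compare — is how the whole test suite works.

For ensemble work, `make_model_ensemble(ensemble_families(), ...)`
produces labelled three-family bead-model ensembles and
`classify_ensemble()` runs alignment → voxelisation → PCA → k-means →
group averaging in one call; `autoplot()` on the result draws the PC
plane.

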