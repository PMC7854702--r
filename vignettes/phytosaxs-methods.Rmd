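---
title: "Models and methods behind phytosaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phytosaxs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytosaxs)
```

phytosaxs reimplements, as a tested R pipeline, the computational analysis
used in solution SAXS studies of dimeric plant photoreceptors
(phytochromes): separating the scattering of a red-light photosteady state
into pure Pr and Pfr contributions, Guinier and dilution-series analysis,
classification of large ab initio bead-model ensembles into representative
molecular shapes, and elastic-network normal-mode analysis of the
photosensory module. This vignette explains each model, its assumptions,
the tunable parameters, and the choices made where the underlying protocol
left the design open.

## Scattering conventions

All scattering vectors use **S = 2 sin(θ)/λ** (units 1/Å). Consequently
every Fourier kernel in the package carries a factor 2πS: the Guinier law
is written

$$ I(S) = I(0)\,\exp\!\left[-\tfrac{4\pi^2}{3} R_g^2 S^2\right], $$

and the Debye sum over bead pairs uses sinc(2πS·r). Files recorded on the
q = 4π sin(θ)/λ convention can be ingested with
`read_profile(..., q_convention = "q")`, which halves the first column on
read (q = 2πS). The practical consequence worth remembering is that the
Guinier validity range "q·Rg ≲ 1.3" reads S·Rg ≲ 1.3/2π on this scale.

## Two-component photosteady state

Under continuous red light a phytochrome solution is a mixture of Pr–Pr
and Pfr–Pfr dimers (the heterodimer population is negligible because it
photoconverts or relaxes quickly). The measured profile is the
population-weighted sum

$$ I_{\mathrm{steady}}(S) = \omega_{\mathrm{PrPr}} I_{\mathrm{PrPr}}(S) +
   \omega_{\mathrm{PfrPfr}} I_{\mathrm{PfrPfr}}(S), \qquad
   \omega_{\mathrm{PrPr}} + \omega_{\mathrm{PfrPfr}} = 1 . $$

`decompose_steady()` inverts this algebraically; errors propagate as
σ² sums with the ω² factors. Negative decomposed intensities are **kept**,
not clipped — clipping would bias every downstream least-squares fit — and
their count is reported as a diagnostic.

How the populations were estimated from absorption spectra is not fully
specified in the experimental literature; `estimate_populations()`
implements a documented default: non-negative least squares of the
steady-state spectrum against user-supplied Pr and Pfr reference spectra
over a configurable window (default 550–800 nm, covering the red/far-red
bands), with renormalisation to unit sum. The window and the residual RMS
are recorded in the returned object's `method` string so the estimate is
auditable.

## Guinier and dilution-series analysis

`guinier_fit()` performs an error-weighted linear regression of ln I
against S², with delta-method weights (I/σ)². The default window in S²
(4–20 × 10⁻⁶ Å⁻²) matches the window used for the ~120 kDa-per-subunit
dimer this pipeline was built around; it should be overridden for other
particle sizes. There is deliberately no automatic window search. A
positive slope beyond two standard errors is rejected ("no Guinier
region"); a positive slope within errors is truncated to Rg = 0.

For a monodisperse dilution series the package fits the two linear laws

$$ \frac{KC}{I(0,C)} = \frac{1}{M_W} + 2A_2 C, \qquad
   R_g^2(C) = R_g^2(0) - B_{if} C $$

by unweighted least squares (`fit_dilution_series()`): the experimental
protocol reports no per-point errors at this level, so weighting would
invent information. A₂ (second virial coefficient) and B_if share their
sign for a given interaction mode — repulsion lowers both the apparent
mass and the apparent size with concentration — and the synthetic
round-trip tests assert exactly that.

## Bead models and the Debye simulator

Dummy-residue (DR) models represent one residue-equivalent of scattering
mass per bead (radius 3.8 Å, interpenetrating by construction). The
forward simulator treats beads as identical point scatterers:

$$ I(S) = \sum_{i}\sum_{j} \mathrm{sinc}(2\pi S\, r_{ij}), \qquad I(0)=N^2 . $$

Note the self term: for N beads the expectation of this sum for a shape
with normalised form factor f(S) is N + N(N−1)·f(S), **not** N²·f(S).
At wide angle where f ~ 10⁻³ the constant N is a percent-level
contribution for N ~ 10⁴ — the package's oracle tests compare against the
finite-N closed form for this reason. The default evaluation path bins all
N(N−1)/2 pair distances into 0.5 Å bins (compiled code, O(N²) time but
O(bins) memory) and evaluates the sum over bin midpoints; against the
exact pair sum this is accurate to ~10⁻³ relative over the small-angle
range. An optional uniform-sphere form factor of the bead radius can be
applied; it is off by default, matching the DR point-mass abstraction.

Goodness of fit uses the reduced discrepancy with an analytic optimal
scale factor:

$$ \chi^2 = \frac{1}{N-1}\sum_j
   \left[\frac{I_{e}(S_j) - \alpha I_{m}(S_j)}{\sigma(S_j)}\right]^2,
   \qquad
   \alpha^* = \frac{\sum I_e I_m/\sigma^2}{\sum I_m^2/\sigma^2} . $$

`generate_shape()` fills parametric solids (rods, bent rods, spheres,
ellipsoids, and two-subunit dimers related by an exact two-fold axis) by
rejection sampling under a fixed seed; the same seed reproduces the same
beads bitwise. A 180° bend degenerates exactly to the straight-rod
sampler.

## Ensemble classification

Ab initio reconstructions from a single SAXS curve are ambiguous, so many
independent runs are classified rather than averaged blindly. The protocol
is: (1) align each model onto its inertia-tensor principal axes (ascending
eigenvalue order, long axis → x, det +1); (2) superimpose everything onto
one common reference model, scoring all 24 proper axis-frame rotations —
and the 24 mirrored ones, since scattering-derived shapes carry no
handedness — by binary voxel overlap; (3) express each model as DR number
densities on a shared 6 Å voxel grid (half-open bins, corner-anchored,
one-voxel margin; conservation Σρ·V = N holds exactly); (4) mean-centred
covariance PCA, keeping the first two components as the classification
plane (the full variance spectrum is still reported); (5) k-means with
k = 10 and 50 restarts under a fixed seed; (6) per-group averaging.

Design points that were genuinely open:

* **Common reference pass.** Principal-axis alignment alone leaves a
  sign/handedness degeneracy of up to 8 poses per model; a point-symmetric
  dimer family then appears as several separate blobs in PCA space and
  k-means fragments it. Superimposing on one common reference collapses
  the degeneracy. The reference is simply the first model; equivariance
  tests confirm the embedding is unchanged when the whole ensemble is
  rigidly moved.
* **Near-degenerate inertia.** A cross-shaped dimer with crossing angle
  near 90° has two nearly equal inertia eigenvalues and its principal
  axes are numerically arbitrary in that plane. Cluster averaging and
  template comparison therefore follow the discrete frame search with an
  overlap-maximising rotational refinement (±40° coordinate-wise grid,
  two passes) — the package's mechanical proxy for the manual "careful
  realignment" such anisotropic groups otherwise need.
* **Occupancy masks.** Per-model masks mark every voxel whose cube lies
  within the 3.8 Å bead radius of a bead centre (beads as spheres, not
  points): a 1000-bead model cannot otherwise fill its ~1600-voxel solid
  and threshold-0.5 averaging would be meaningless. Representative
  surfaces default to occupancy ≥ 0.5, configurable.
* **Group selection is human judgement.** The tool reports group sizes and
  averaged shapes; it never auto-selects "the" shape.

`optimize_dr_count()` surveys the bead count of a pluggable reconstruction
engine (any function mapping profile × count × seed to a bead model) over
900–1200 DRs in steps of 25, averaging χ² over 14 independent seeds per
count and breaking ties toward the smaller count.

## Elastic-network normal modes

`build_enm()` assembles the anisotropic-network Hessian for the Cα trace:
every pair within the cutoff (inclusive) is joined by a spring of uniform
force constant, each pair contributing the 3×3 super-element
−k·r̂r̂ᵀ, with diagonal blocks enforcing zero block-row sums
(translation invariance). Masses are uniform — a Cα-only network has no
meaningful mass heterogeneity. A Gaussian (scalar) network variant is out
of scope. The eigendecomposition flags zero modes at a *relative*
tolerance (10⁻¹⁰ of the largest eigenvalue): a connected non-collinear
network must have exactly 6 (translations + rotations), and the tests
assert the count exactly rather than approximately, because spurious zero
modes are the symptom of a floppy (under-constrained) network.

Predicted B-factors use the standard pseudo-inverse sum
B_i ∝ Σ_m λ_m⁻¹ |v_{m,i}|² over internal modes. The contact cutoff is
calibrated by scanning a grid (default 6–15 Å in 0.5 Å steps) for the
maximum Pearson correlation with experimental B-factors, skipping
disconnected cutoffs, ties to the smaller value; 7 Å is a typical result
for Cα networks of compact domains. The force constant is then set by
equalising ΣB_pred with ΣB_exp — a pure rescaling that cannot change the
correlation. "First normal mode" always means the lowest-energy internal
mode (mode 7 of the spectrum), and `mode_displacements()` scales its
eigenvector by a magnification (default 3) for rendering.

## Sequence comparison

`smith_waterman()` is a three-state affine-gap local alignment with
EMBOSS Water conventions: BLOSUM62, gap open 10, gap extend 0.5, where a
gap of length L costs open + (L−1)·extend (the opening penalty covers the
first gap position; this is score-equivalent to Biostrings'
`gapOpening = 9.5, gapExtension = 0.5`, which charges opening plus
extension per position). Percent identity and similarity are counted over
the full alignment length including gap columns; "similar" means a
positive substitution score. Ties in the dynamic program prefer the
diagonal, then a gap in the second sequence, then in the first; among
equal maxima the smallest end coordinates win, making the traceback
deterministic. Residues outside the matrix alphabet map to X with a
warning.

The bundled FASTA pair under `inst/extdata/` is a **synthetic**
phytochrome-like pair (the file headers say so): it exercises the aligner
at realistic scale (~1100 residues) but is not the canonical UniProt
phyA/phyB pair, which cannot be redistributed here. Users wishing to
reproduce published identity/similarity figures should drop the canonical
entries in as `P15001_phyA_pea.fasta` and `P14713_phyB_arath.fasta`; the
acceptance machinery picks them up automatically.

## The synthetic-data generators

Because no experimental SAXS data are deposited for this system, the
`make_*` generators produce every pipeline input at desk scale with known
ground truth. They are pure functions of their parameters and seed.

* `make_dilution_series()` plants (M_W, A₂, Rg0, B_if) by analytic
  Guinier-level reweighting of a Debye base profile — sufficient to
  exercise the dilution laws, but *not* a structure-factor model of
  interparticle interference; real concentrated solutions are messier.
  The default concentrations are the five-point series 0.5–4.0 mg/mL.
* `make_spectra()` uses two Gaussian bands near the classical red
  (666 nm) and far-red (730 nm) absorbance maxima with a 25% mutual
  overlap — configuration defaults on the right wavelength scale, not
  measured phytochrome spectra.
* `make_model_ensemble()` emulates reconstruction ensembles: family
  templates (`ensemble_families()`: an anti-parallel pair of 175 × 50 Å
  rods at 25°, an anisotropic cross at 75°, a butterfly of bent rods at
  60°) with per-bead jitter, bead resampling, random rigid motions,
  random handedness flips, and a configurable outlier fraction of random
  blobs. Crossing angles deliberately avoid 90°, where the inertia tensor
  of a symmetric cross is degenerate by construction; reconstructed cross
  shapes are anisotropic anyway. What the generator does **not** emulate
  is the within-family variety of real annealing runs — passing the
  classification tests shows the multivariate protocol separates distinct
  morphologies under jitter and outliers, not that it resolves every
  subtlety of real reconstruction ensembles.
* `make_enm_structure()` builds Cα traces with exact 3.8 Å virtual bonds
  (regular helix, zig-zagged hairpin, or two compact-chain domains joined
  by a short helical linker) and generates B-factors from the structure's
  own network at a planted cutoff (rescaled to mean 30 Å², multiplicative
  noise). Straight or planar chain segments are avoided deliberately: in
  an anisotropic network they are mechanisms with extra zero modes. The
  generator redraws its chains (seed-derived sub-seeds) until the network
  at the planted cutoff is connected with exactly 6 zero modes — a
  validity constraint, making the cutoff-recovery experiments well-posed.

## Problem sizes and numerical choices

The test-suite and acceptance runs use: 560-model ensembles of ~1000-bead
dimers on 6 Å grids (the full multivariate protocol in about 2 minutes),
20 000-bead sphere fills for Debye oracles, 500-residue networks for the
large normal-mode check, 100-residue networks × 50 seeds for
cutoff-recovery rates, and ~1100-residue sequences for alignment. Monte
Carlo oracles near deep intensity minima average three independent fills,
since a single fill's sampling noise there is comparable to the 2%
tolerance being verified. Fixed seeds make every stochastic result
reproducible; generated shapes are bitwise seed-deterministic.

Known limitations: no hydration-shell or excluded-volume corrections in
the Debye simulator (CRYSOL territory); no indirect-transform P(r) or
D_max estimation; the population unmixing needs a trustworthy Pfr
reference spectrum; the elastic network is Cα-only with uniform springs,
so absolute B-factor scales are meaningful only after calibration; and
the ab initio reconstruction step itself is outside the package — the
DR-count optimiser treats it as a pluggable engine.
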