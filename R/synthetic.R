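#' Synthetic dilution series with planted interaction coefficients
#'
#' Builds a noise-free base profile from the Debye scattering of a bead
#' model, then modulates zero-angle intensity and radius of gyration per
#' concentration according to the dilution laws
#' `K*C/I(0,C) = 1/M_W + 2*A2*C` and `Rg(C)^2 = Rg0^2 - B_if*C`,
#' injecting the interparticle effects analytically at low angle
#' (Guinier-level reweighting) rather than through a structure-factor
#' model. Optional Gaussian noise has sigma proportional to
#' `sqrt(I)/sqrt(C)` (counting statistics improve with concentration).
#'
#' @param shape A [bead_model()] defining the particle (its point-bead Rg
#'   is the planted Rg0).
#' @param concentrations Concentrations, mg/mL (default the five-point
#'   series 0.5, 1.5, 2.0, 3.0, 4.0).
#' @param mw Planted molecular weight (kDa or any consistent unit).
#' @param a2 Planted second virial coefficient.
#' @param b_if Planted interference slope of Rg^2 vs C.
#' @param k_const Experimental constant K.
#' @param s_grid Scattering vector grid, 1/A.
#' @param noise_level Relative noise amplitude (0 = noise-free).
#' @param seed RNG seed for the noise.
#' @return List of [scattering_profile()] objects, one per concentration.
#' @export
make_dilution_series <- function(shape,
                                 concentrations = c(0.5, 1.5, 2.0, 3.0, 4.0),
                                 mw = 250, a2 = 0, b_if = 0, k_const = 1,
                                 s_grid = seq(5e-4, 0.02, by = 2.5e-4),
                                 noise_level = 0, seed = 1) {
  base <- debye_intensity(shape, s_grid, mode = "histogram")
  rg0 <- radius_of_gyration(shape)
  i_base <- base$intensity / nrow(shape)^2      # normalised to I(0) = 1
  with_local_seed(seed, {
    lapply(concentrations, function(C) {
      i0_c <- k_const * C / (1 / mw + 2 * a2 * C)
      rg2_c <- rg0^2 - b_if * C
      if (rg2_c <= 0) stop("planted B_if drives Rg^2 negative at C = ", C)
      intens <- i0_c * i_base * exp(-(4 * pi^2 / 3) * (rg2_c - rg0^2) * s_grid^2)
      sig <- pmax(1e-8, noise_level * sqrt(pmax(intens, 0)) / sqrt(C))
      if (noise_level > 0)
        intens <- intens + stats::rnorm(length(intens), 0, sig)
      scattering_profile(s_grid, intens, sig, concentration = C,
                         label = sprintf("synthetic C=%.2g", C))
    })
  })
}

#' Synthetic photosteady-state mixture of two scattering profiles
#'
#' Forward model of the two-component mixture:
#' `I = w_prpr * I_pr + (1 - w_prpr) * I_pfr` on the shared s-grid, plus
#' optional Gaussian noise of standard deviation `noise_level * sqrt(I)`.
#'
#' @param i_pr,i_pfr Pure-form [scattering_profile()] objects.
#' @param w_prpr Pr-Pr dimer population in `[0, 1]`.
#' @param noise_level Relative noise amplitude.
#' @param seed RNG seed.
#' @return A [scattering_profile()] of the mixture.
#' @export
make_steady_mixture <- function(i_pr, i_pfr, w_prpr, noise_level = 0, seed = 1) {
  stopifnot(w_prpr >= 0, w_prpr <= 1)
  g <- common_grid(i_pr, i_pfr)
  intens <- w_prpr * g$a$i + (1 - w_prpr) * g$b$i
  sig <- if (noise_level > 0) noise_level * sqrt(pmax(intens, 1e-12))
         else sqrt((w_prpr * g$a$sig)^2 + ((1 - w_prpr) * g$b$sig)^2)
  if (noise_level > 0)
    intens <- with_local_seed(seed, intens + stats::rnorm(length(intens), 0, sig))
  scattering_profile(g$s, intens, sig, label = sprintf("steady w_prpr=%.2f", w_prpr))
}

gaussian_band <- function(wl, band) {
  band[3] * exp(-((wl - band[1])^2) / (2 * band[2]^2))
}

#' Synthetic Pr/Pfr/steady-state absorption spectra
#'
#' Two Gaussian reference bands near the classical red and far-red
#' absorbance maxima (configuration defaults, adjustable), with a
#' controllable spectral overlap mixed into each reference, and a
#' photosteady-state spectrum that mixes the references with the planted
#' Pfr fraction.
#'
#' @param fraction_pfr Planted Pfr population in `[0, 1]`.
#' @param pr_band,pfr_band Numeric `(center nm, width nm, height AU)`.
#' @param overlap Fraction of the other form's band present in each
#'   reference spectrum (phytochrome Pr/Pfr spectra overlap strongly).
#' @param noise Relative Gaussian noise on the steady-state spectrum.
#' @param seed RNG seed.
#' @param wavelength Wavelength grid, nm.
#' @return List with elements `pr`, `pfr`, `steady`
#'   ([absorption_spectrum()] objects).
#' @export
make_spectra <- function(fraction_pfr, pr_band = c(666, 25, 1),
                         pfr_band = c(730, 30, 0.75), overlap = 0.25,
                         noise = 0, seed = 1,
                         wavelength = seq(500, 850, by = 1)) {
  stopifnot(fraction_pfr >= 0, fraction_pfr <= 1)
  a_pr <- gaussian_band(wavelength, pr_band) +
    overlap * gaussian_band(wavelength, pfr_band)
  a_pfr <- gaussian_band(wavelength, pfr_band) +
    overlap * gaussian_band(wavelength, pr_band)
  a_st <- (1 - fraction_pfr) * a_pr + fraction_pfr * a_pfr
  if (noise > 0)
    a_st <- with_local_seed(seed,
      pmax(0, a_st + stats::rnorm(length(a_st), 0, noise * max(a_st))))
  list(pr = absorption_spectrum(wavelength, a_pr, "synthetic Pr"),
       pfr = absorption_spectrum(wavelength, a_pfr, "synthetic Pfr"),
       steady = absorption_spectrum(wavelength, a_st,
                                    sprintf("synthetic steady f_pfr=%.2f",
                                            fraction_pfr)))
}

#' Default shape-family specifications for synthetic dimer ensembles
#'
#' Three dimer morphologies observed in phytochrome shape reconstructions,
#' as [generate_shape()] specs: a pair of rods in anti-parallel association
#' (small crossing angle), an anisotropic cross of two straight rods, and a
#' butterfly of two bent rods. Subunits are 175 x 50 A rods (about the
#' dimensions of a phytochrome subunit); crossing angles stay away from 90
#' degrees because the reconstructed cross shapes are anisotropic and an
#' exactly symmetric cross has a degenerate inertia tensor.
#'
#' @param n_beads Beads per subunit (default 500).
#' @return A named list of family specs for [make_model_ensemble()].
#' @export
ensemble_families <- function(n_beads = 500) {
  rod <- list(kind = "straight_rod", params = list(length = 175, diameter = 50))
  bent <- list(kind = "bent_rod",
               params = list(length = 175, diameter = 50, bend_angle = 120))
  list(
    twisted_tubes = list(kind = "two_subunit_dimer",
                         params = list(subunit = rod, crossing_angle = 25,
                                       separation = 45),
                         n_beads = n_beads),
    cross = list(kind = "two_subunit_dimer",
                 params = list(subunit = rod, crossing_angle = 75,
                               separation = 40),
                 n_beads = n_beads),
    butterfly = list(kind = "two_subunit_dimer",
                     params = list(subunit = bent, crossing_angle = 60,
                                   separation = 40),
                     n_beads = n_beads))
}

random_rotation_matrix <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Synthetic bead-model ensemble with planted shape families
#'
#' Emulates the output of many independent ab initio reconstructions: each
#' family has a fixed template shape; every model resamples the template's
#' beads, applies per-bead Gaussian jitter, a random rigid motion and a
#' random handedness flip (reconstructed shapes carry no handedness).
#' A fraction of models are outliers drawn from a random Gaussian blob.
#' Ground-truth labels (0 = outlier) are returned for purity scoring.
#'
#' @param families List of family specs, each a list with `kind`, `params`
#'   and optionally `n_beads` (see [generate_shape()]).
#' @param n_per_family Models per family (recycled to the family count).
#' @param jitter_sigma Per-bead Gaussian jitter, A.
#' @param outlier_fraction Fraction of models replaced by outliers.
#' @param seed RNG seed.
#' @param n_beads Default beads per model.
#' @return List with `models` (list of [bead_model()]), `labels` (integer
#'   truth labels, 0 for outliers), `templates` (list of family templates).
#' @export
make_model_ensemble <- function(families, n_per_family, jitter_sigma = 2,
                                outlier_fraction = 0.05, seed = 1,
                                n_beads = 800) {
  nf <- length(families)
  n_per_family <- rep_len(n_per_family, nf)
  templates <- lapply(seq_len(nf), function(f)
    generate_shape(families[[f]]$kind, families[[f]]$params %||% list(),
                   n_beads = families[[f]]$n_beads %||% n_beads,
                   seed = seed + 1000L * f))
  total <- sum(n_per_family)
  labels <- rep(seq_len(nf), n_per_family)
  scale_ref <- mean(vapply(templates, radius_of_gyration, 0))
  with_local_seed(seed, {
    n_out <- round(outlier_fraction * total)
    out_idx <- if (n_out > 0) sample(total, n_out) else integer(0)
    labels[out_idx] <- 0L
    models <- lapply(seq_len(total), function(i) {
      if (labels[i] == 0L) {
        coords <- matrix(stats::rnorm(3 * n_beads, 0, scale_ref / sqrt(3)),
                         ncol = 3)
      } else {
        tpl <- bead_coords(templates[[labels[i]]])
        pick <- sample(nrow(tpl), nrow(tpl), replace = TRUE)
        coords <- tpl[pick, , drop = FALSE] +
          matrix(stats::rnorm(3 * nrow(tpl), 0, jitter_sigma), ncol = 3)
      }
      if (stats::runif(1) < 0.5) coords[, 3] <- -coords[, 3]  # handedness flip
      coords <- coords %*% t(random_rotation_matrix())
      coords <- sweep(coords, 2, stats::rnorm(3, 0, 20), `+`)
      bead_model(coords, label = sprintf("model %d (family %d)", i, labels[i]))
    })
    list(models = models, labels = labels, templates = templates)
  })
}

# compact self-avoiding-ish chain with exact 3.8 A virtual bonds, confined
# to a globule of radius ~3 n^(1/3) so every residue is well connected at
# typical elastic-network cutoffs (an under-packed chain would carry floppy
# zero-energy motions)
compact_chain <- function(n, center_pull = 0.5, momentum = 0.3,
                          min_sep = 3.4, start = c(0, 0, 0)) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- start
  dir <- c(1, 0, 0)
  maxr <- 3.0 * n^(1 / 3)
  for (i in 2:n) {
    for (try_ in 1:80) {
      ctr <- colMeans(pos[1:(i - 1), , drop = FALSE])
      pull <- ctr - pos[i - 1, ]
      npull <- sqrt(sum(pull^2))
      pw <- if (npull > maxr) 2.0 else center_pull * npull / maxr
      if (npull > 0) pull <- pull / npull
      cand_dir <- momentum * dir + stats::rnorm(3) + pw * pull * (1 + try_ / 10)
      cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
      cand <- pos[i - 1, ] + 3.8 * cand_dir
      if (i <= 3) break
      d2 <- rowSums(sweep(pos[1:(i - 2), , drop = FALSE], 2, cand)^2)
      if (min(d2) >= min_sep^2) break
    }
    pos[i, ] <- cand
    dir <- cand_dir
  }
  pos
}

#' Synthetic C-alpha structure with elastic-network-consistent B-factors
#'
#' Builds a C-alpha trace with exact 3.8 A virtual bonds — a regular
#' alpha-helical trace, a two-stranded hairpin, or two compact chain
#' domains joined by a linker — and generates experimental-like B-factors
#' from the structure's own elastic network at a planted cutoff, rescaled
#' to `b_mean` and corrupted with multiplicative Gaussian noise. Used for
#' cutoff-recovery experiments with known ground truth.
#'
#' @param n_residues Residue count.
#' @param architecture `"two_domain"` (default), `"helix"` or `"hairpin"`.
#' @param planted_cutoff Cutoff, A, at which the reference B-factors are
#'   generated.
#' @param noise Relative multiplicative noise on the B-factors.
#' @param seed RNG seed.
#' @param b_mean Mean of the generated B-factors, A^2.
#' @return A [calpha_structure()] with `b_exp` set.
#' @export
make_enm_structure <- function(n_residues = 120,
                               architecture = c("two_domain", "helix", "hairpin"),
                               planted_cutoff = 9, noise = 0.05, seed = 1,
                               b_mean = 30) {
  architecture <- match.arg(architecture)
  build_coords <- function(sub_seed) with_local_seed(sub_seed, switch(architecture,
    helix = {
      rise <- 1.5; dphi <- 100 * pi / 180
      radius <- sqrt(3.8^2 - rise^2) / (2 * sin(dphi / 2))
      t <- seq_len(n_residues)
      cbind(radius * cos(t * dphi), radius * sin(t * dphi), rise * t)
    },
    hairpin = {
      # two anti-parallel strands, gently zig-zagged out of the strand
      # plane (a strictly planar anisotropic network has zero out-of-plane
      # stiffness), all virtual bonds exactly 3.8 A
      n1 <- ceiling(n_residues / 2); n2 <- n_residues - n1
      zig <- 0.4; dz <- sqrt(3.8^2 - (2 * zig)^2)
      y_up <- zig * (-1)^(seq_len(n1))
      up <- cbind(0, y_up, dz * seq_len(n1))
      y_dn <- zig * (-1)^(n1 + seq_len(n2) - 1)   # matches the turn
      sep <- sqrt(3.8^2 - 1.9^2)
      dn <- cbind(sep, y_dn, dz * n1 - 1.9 - dz * (seq_len(n2) - 1))
      rbind(up, dn)
    },
    two_domain = {
      n1 <- floor(n_residues * 0.45)
      nl <- max(3L, floor(n_residues * 0.1))
      n2 <- n_residues - n1 - nl
      d1 <- compact_chain(n1)
      # alpha-helical linker along +x: its short rise packs i+-2..i+-5
      # contacts, keeping the connector rigid (a loose chain of springs
      # would act as a ball-joint mechanism and add zero modes)
      rise <- 1.5; dphi <- 100 * pi / 180
      hrad <- sqrt(3.8^2 - rise^2) / (2 * sin(dphi / 2))
      j <- seq_len(nl + 1)
      hel <- cbind(rise * j, hrad * cos(j * dphi), hrad * sin(j * dphi))
      hel <- sweep(hel, 2, hel[1, ]) # start at origin
      lk <- sweep(hel[-1, , drop = FALSE], 2, d1[n1, ], `+`)
      d2 <- compact_chain(n2, start = lk[nl, ] + 3.8 * c(1, 0, 0))
      rbind(d1, lk, d2)
    }))
  # redraw (seed-derived sub-seeds) until the network at the planted cutoff
  # is a connected structure with exactly the 6 rigid-body zero modes
  modes <- NULL
  for (attempt in 0:24) {
    coords <- build_coords(seed + 7919L * attempt)
    st <- calpha_structure(coords)
    enm <- tryCatch(suppressWarnings(build_enm(st, cutoff = planted_cutoff)),
                    error = function(e) NULL)
    if (is.null(enm) || !enm$connected) next
    modes <- compute_modes(enm)
    if (modes$n_zero == 6L) break
    modes <- NULL
  }
  if (is.null(modes))
    stop("could not generate a mechanically regular structure at the planted cutoff")
  b_ref <- predict_bfactors(modes)
  b_exp <- b_ref * b_mean / mean(b_ref)
  if (noise > 0)
    b_exp <- with_local_seed(seed + 1L,
      pmax(1e-3, b_exp * (1 + stats::rnorm(length(b_exp), 0, noise))))
  st$b_exp <- b_exp
  st
}
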