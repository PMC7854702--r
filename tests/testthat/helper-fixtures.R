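# shared fixtures and independent oracles, built in code

# exact Guinier-law profile
guinier_profile <- function(i0 = 50, rg = 50, s = seq(1e-3, 6e-3, by = 2e-4),
                            sigma = 1, concentration = NA_real_) {
  scattering_profile(s, i0 * exp(-(4 * pi^2 / 3) * rg^2 * s^2),
                     rep(sigma, length(s)), concentration = concentration)
}

# independent three-state affine local DP (score only), plain R.
# Same penalty convention as the package: a gap of length L costs
# open + (L - 1) * ext.
oracle_sw_score <- function(a, b, subst, open = 10, ext = 0.5) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb); NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open, E[i + 1, j] - ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] - open, F[i, j + 1] - ext)
    H[i + 1, j + 1] <- max(0, H[i, j] + subst[ca[i], cb[j]],
                           E[i + 1, j + 1], F[i + 1, j + 1])
  }
  max(H)
}

blosum62_fixture <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# uniform-density sphere scattering amplitude squared, x = 2*pi*S*R
sphere_intensity <- function(s, radius, n_beads) {
  x <- 2 * pi * s * radius
  (3 * (sin(x) - x * cos(x)) / x^3)^2 * n_beads^2
}

# small rigid motion helpers
rot3 <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

transform_model <- function(model, R = diag(3), t = c(0, 0, 0)) {
  m <- cbind(model$x, model$y, model$z) %*% t(R)
  bead_model(sweep(m, 2, t, `+`), bead_radius = attr(model, "bead_radius"),
             label = attr(model, "label"))
}

# finite-difference Hessian of the explicit pairwise Hookean energy
fd_hessian <- function(coords, contacts, k = 1, h = 1e-5) {
  d0 <- sqrt(rowSums((coords[contacts[, 1], , drop = FALSE] -
                        coords[contacts[, 2], , drop = FALSE])^2))
  energy <- function(x) {
    m <- matrix(x, ncol = 3, byrow = TRUE)
    d <- sqrt(rowSums((m[contacts[, 1], , drop = FALSE] -
                         m[contacts[, 2], , drop = FALSE])^2))
    0.5 * k * sum((d - d0)^2)
  }
  x0 <- as.numeric(t(coords))
  n <- length(x0)
  H <- matrix(0, n, n)
  for (i in 1:n) for (j in i:n) {
    xpp <- x0; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
    xpm <- x0; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
    xmp <- x0; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
    xmm <- x0; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
    H[i, j] <- H[j, i] <-
      (energy(xpp) - energy(xpm) - energy(xmp) + energy(xmm)) / (4 * h^2)
  }
  H
}

skip_messages <- function(expr) suppressMessages(suppressWarnings(expr))
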