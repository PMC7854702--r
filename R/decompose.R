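#' Construct an absorption spectrum
#'
#' @param wavelength Numeric vector, nm, strictly increasing after sorting.
#' @param absorbance Numeric vector, AU.
#' @param label Free text.
#' @return A tibble of class `absorption_spectrum`.
#' @export
absorption_spectrum <- function(wavelength, absorbance, label = "") {
  wavelength <- as.numeric(wavelength); absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) stop("length mismatch")
  ord <- order(wavelength)
  if (anyDuplicated(wavelength)) stop("duplicated wavelengths")
  out <- tibble::tibble(wavelength = wavelength[ord], absorbance = absorbance[ord])
  attr(out, "label") <- label
  class(out) <- c("absorption_spectrum", class(out))
  out
}

#' Read a 2-column CSV absorption spectrum (wavelength nm, absorbance)
#' @param path File path; one header line expected.
#' @param label Label; defaults to the file name.
#' @return An [absorption_spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  df <- utils::read.csv(path)
  absorption_spectrum(df[[1]], df[[2]], label = label)
}

#' Pr/Pfr population weights
#'
#' The pair of dimer populations (omega_PrPr, omega_PfrPfr) that mixes pure
#' Pr-Pr and Pfr-Pfr signals into the red-light photosteady state. The two
#' weights sum to one.
#'
#' @param w_prpr,w_pfrpfr Fractions in `[0, 1]` summing to 1.
#' @param method Free text describing how the weights were estimated.
#' @return Object of class `mixture_weights`.
#' @export
mixture_weights <- function(w_prpr, w_pfrpfr = 1 - w_prpr, method = "manual") {
  stopifnot(is.finite(w_prpr), is.finite(w_pfrpfr))
  if (abs(w_prpr + w_pfrpfr - 1) > 1e-12)
    stop("weights must sum to 1")
  if (w_prpr < 0 || w_prpr > 1 || w_pfrpfr < 0 || w_pfrpfr > 1)
    stop("weights must lie in [0, 1]")
  structure(list(w_prpr = w_prpr, w_pfrpfr = w_pfrpfr, method = method),
            class = "mixture_weights")
}

#' @export
print.mixture_weights <- function(x, ...) {
  cat(sprintf("<mixture_weights> PrPr = %.4f, PfrPfr = %.4f (%s)\n",
              x$w_prpr, x$w_pfrpfr, x$method))
  invisible(x)
}

# Resample spectra onto the shared wavelength grid restricted to a window.
spectra_grid <- function(specs, window) {
  lo <- max(c(purrr::map_dbl(specs, ~ min(.x$wavelength)), window[1]))
  hi <- min(c(purrr::map_dbl(specs, ~ max(.x$wavelength)), window[2]))
  if (lo >= hi) stop("empty overlap range between spectra and window")
  wl <- sort(unique(unlist(purrr::map(specs, ~ {
    w <- .x$wavelength; w[w >= lo & w <= hi]
  }))))
  if (length(wl) < 2L) stop("empty overlap range between spectra and window")
  lapply(specs, function(sp) stats::approx(sp$wavelength, sp$absorbance, xout = wl)$y)
}

#' Estimate Pr/Pfr populations from absorption spectra
#'
#' Non-negative least squares of the photosteady-state spectrum against pure
#' Pr and Pfr reference spectra over a wavelength window (default
#' 550-800 nm, covering the red/far-red bands), followed by renormalisation
#' of the weights to sum to one. With only two components the active-set
#' solution is exact: if the unconstrained solution has a negative weight it
#' is clamped to zero and the other component refit.
#'
#' @param spec_steady,spec_pr,spec_pfr_ref [absorption_spectrum()] objects;
#'   resampled by linear interpolation onto their common grid.
#' @param window Wavelength window, nm.
#' @param max_condition Condition-number threshold above which the unmixing
#'   is declared ill-posed.
#' @return A [mixture_weights()] whose `method` records window and residual.
#' @export
estimate_populations <- function(spec_steady, spec_pr, spec_pfr_ref,
                                 window = c(550, 800), max_condition = 1e8) {
  g <- spectra_grid(list(spec_steady, spec_pr, spec_pfr_ref), window)
  y <- g[[1]]; X <- cbind(pr = g[[2]], pfr = g[[3]])
  sv <- svd(X)$d
  if (sv[2] <= 0 || sv[1] / sv[2] > max_condition)
    stop("unmixing ill-posed: reference spectra nearly linearly dependent")
  w <- as.numeric(qr.solve(X, y))
  for (j in 1:2) {
    if (w[j] < 0) {
      w[j] <- 0
      other <- 3 - j
      w[other] <- max(0, sum(X[, other] * y) / sum(X[, other]^2))
    }
  }
  if (sum(w) <= 0) stop("unmixing failed: zero total weight")
  res <- sqrt(mean((y - X %*% w)^2))
  w <- w / sum(w)
  mixture_weights(w[1], w[2],
                  method = sprintf("NNLS %g-%g nm, residual RMS %.3g",
                                   window[1], window[2], res))
}

#' Decompose the photosteady-state scattering into the pure Pfr profile
#'
#' Inverts the two-component mixture
#' \deqn{I_{steady}(S) = \omega_{PrPr} I_{PrPr}(S) + \omega_{PfrPfr} I_{PfrPfr}(S)}
#' to recover \eqn{I_{PfrPfr}(S) = (I_{steady} - \omega_{PrPr} I_{Pr}) /
#' \omega_{PfrPfr}}. Errors propagate as
#' \eqn{\sigma_{Pfr} = \sqrt{\sigma_{steady}^2 + \omega_{PrPr}^2
#' \sigma_{Pr}^2} / \omega_{PfrPfr}}. Negative resulting intensities are
#' kept (clipping would bias downstream fits); their count is reported in
#' the `n_negative` attribute and a message.
#'
#' @param i_steady,i_pr [scattering_profile()] objects; interpolated onto
#'   the intersection of their s-grids if they differ.
#' @param weights A [mixture_weights()] with `w_pfrpfr > 0`.
#' @return A [scattering_profile()] for the pure Pfr-Pfr dimer.
#' @export
decompose_steady <- function(i_steady, i_pr, weights) {
  if (weights$w_pfrpfr <= 0)
    stop("w_pfrpfr = 0: division by zero in decomposition")
  g <- common_grid(i_steady, i_pr)
  int <- (g$a$i - weights$w_prpr * g$b$i) / weights$w_pfrpfr
  sig <- sqrt(g$a$sig^2 + weights$w_prpr^2 * g$b$sig^2) / weights$w_pfrpfr
  nneg <- sum(int < 0)
  if (nneg > 0)
    message(sprintf("decompose_steady: %d negative intensities retained", nneg))
  out <- scattering_profile(g$s, int, sig,
                            concentration = attr(i_steady, "concentration"),
                            label = "decomposed PfrPfr")
  attr(out, "n_negative") <- nneg
  out
}

#' Compute the pure Pfr absorption spectrum from the steady-state spectrum
#'
#' Applies the same two-component inversion as [decompose_steady()] to
#' absorbance arrays: `A_pfr = (A_steady - w_prpr * A_pr) / w_pfrpfr`.
#'
#' @inheritParams estimate_populations
#' @param weights A [mixture_weights()] with `w_pfrpfr > 0`.
#' @return An [absorption_spectrum()].
#' @export
compute_pfr_spectrum <- function(spec_steady, spec_pr, weights) {
  if (weights$w_pfrpfr <= 0)
    stop("w_pfrpfr = 0: division by zero in decomposition")
  g <- spectra_grid(list(spec_steady, spec_pr), c(-Inf, Inf))
  lo <- max(min(spec_steady$wavelength), min(spec_pr$wavelength))
  hi <- min(max(spec_steady$wavelength), max(spec_pr$wavelength))
  wl <- sort(unique(c(spec_steady$wavelength, spec_pr$wavelength)))
  wl <- wl[wl >= lo & wl <= hi]
  a_st <- stats::approx(spec_steady$wavelength, spec_steady$absorbance, xout = wl)$y
  a_pr <- stats::approx(spec_pr$wavelength, spec_pr$absorbance, xout = wl)$y
  absorption_spectrum(wl, (a_st - weights$w_prpr * a_pr) / weights$w_pfrpfr,
                      label = "computed Pfr spectrum")
}
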