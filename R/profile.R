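#' Construct a scattering profile
#'
#' A scattering profile is a tibble with columns `s` (scattering vector
#' length in 1/Angstrom, using the S = 2 sin(theta)/lambda convention),
#' `intensity` (arbitrary units) and `sigma` (1-sigma errors, same units),
#' carrying the sample concentration (mg/mL) and a label as attributes.
#' All Fourier kernels in the package consequently use 2*pi*S.
#'
#' @param s Numeric vector of scattering vector lengths, 1/Angstrom.
#' @param intensity Numeric vector of intensities.
#' @param sigma Numeric vector of 1-sigma errors; if `NULL` a Poisson-like
#'   default `pmax(eps, err_scale * sqrt(pmax(intensity, 0)))` is applied.
#' @param concentration Protein concentration in mg/mL, or `NA`.
#' @param label Free-text label.
#' @param err_scale,eps Constants of the default error model (`err_scale = 1`,
#'   `eps = 1e-6`).
#' @return A tibble of class `scattering_profile`, rows sorted by `s`.
#' @export
scattering_profile <- function(s, intensity, sigma = NULL,
                               concentration = NA_real_, label = "",
                               err_scale = 1, eps = 1e-6) {
  s <- as.numeric(s); intensity <- as.numeric(intensity)
  if (length(s) < 2L) stop("a scattering profile needs at least 2 points")
  if (length(intensity) != length(s)) stop("s and intensity lengths differ")
  if (any(!is.finite(s))) stop("non-finite s values")
  if (any(s < 0)) stop("negative scattering vector length")
  if (is.null(sigma)) {
    sigma <- pmax(eps, err_scale * sqrt(pmax(intensity, 0)))
    rlang::warn("no error column: applying sqrt(I) default error model",
                class = "phytosaxs_default_sigma")
  }
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(s)) stop("sigma length differs from s")
  if (any(is.finite(sigma) & sigma <= 0)) stop("sigma must be positive")
  ord <- order(s)
  out <- tibble::tibble(s = s[ord], intensity = intensity[ord],
                        sigma = sigma[ord])
  if (anyDuplicated(out$s)) stop("duplicated s values")
  attr(out, "concentration") <- as.numeric(concentration)
  attr(out, "label") <- label
  class(out) <- c("scattering_profile", class(out))
  out
}

#' @export
print.scattering_profile <- function(x, ...) {
  conc <- attr(x, "concentration")
  cat(sprintf("<scattering_profile> %s  %d points, s in [%.4g, %.4g] 1/A%s\n",
              attr(x, "label"), nrow(x), min(x$s), max(x$s),
              if (is.finite(conc)) sprintf(", %.3g mg/mL", conc) else ""))
  NextMethod()
}

#' Read a 1-D scattering profile from an ATSAS-style .dat file
#'
#' Accepts whitespace-separated files with 2 or 3 numeric columns
#' (S, I and optionally sigma); header and footer lines that do not parse as
#' numbers are skipped. Rows are sorted by ascending S. With
#' `q_convention = "q"` the first column is interpreted as
#' q = 4 pi sin(theta)/lambda and divided by 2 pi to obtain S.
#'
#' @param path File path.
#' @param concentration Optional concentration, mg/mL.
#' @param q_convention `"s"` (default, S = 2 sin(theta)/lambda) or `"q"`.
#' @inheritParams scattering_profile
#' @return A [scattering_profile()].
#' @export
read_profile <- function(path, concentration = NA_real_,
                         q_convention = c("s", "q"),
                         err_scale = 1, eps = 1e-6) {
  q_convention <- match.arg(q_convention)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list(); ncol_seen <- NULL
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(toks) < 2L || startsWith(lines[k], "#")) next
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) next
    if (length(vals) > 3L) vals <- vals[1:3]
    if (vals[1] < 0)
      stop(sprintf("negative scattering vector on line %d of %s", k, path))
    rows[[length(rows) + 1L]] <- vals
    ncol_seen <- max(ncol_seen %||% 0L, length(vals))
  }
  if (length(rows) < 2L) stop("fewer than 2 numeric data rows in ", path)
  ncols <- min(vapply(rows, length, 1L))
  mat <- do.call(rbind, lapply(rows, function(v) v[seq_len(ncols)]))
  s <- mat[, 1]
  if (q_convention == "q") s <- s / (2 * pi)
  sigma <- if (ncols >= 3L) mat[, 3] else NULL
  scattering_profile(s, mat[, 2], sigma, concentration = concentration,
                     label = basename(path), err_scale = err_scale, eps = eps)
}

#' Write a scattering profile to a .dat file
#'
#' Three whitespace-separated columns (S, I, sigma) preceded by '#' comment
#' lines recording provenance.
#'
#' @param profile A [scattering_profile()].
#' @param path Output path.
#' @param comments Extra character lines to record in the header.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, comments = character()) {
  hdr <- c(sprintf("# phytosaxs %s", as.character(utils::packageVersion("phytosaxs"))),
           sprintf("# label: %s", attr(profile, "label")),
           sprintf("# concentration_mg_per_mL: %s", attr(profile, "concentration")),
           paste("#", comments))
  body <- sprintf("%.8e %.8e %.8e", profile$s, profile$intensity, profile$sigma)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Interpolate two profiles onto the intersection of their s-ranges (linear in
# I; extrapolation forbidden). Returns list(s, a = list(i, sig), b = ...).
common_grid <- function(a, b) {
  lo <- max(min(a$s), min(b$s)); hi <- min(max(a$s), max(b$s))
  if (lo > hi) stop("profiles have disjoint s-grids")
  s <- sort(unique(c(a$s[a$s >= lo & a$s <= hi], b$s[b$s >= lo & b$s <= hi])))
  if (length(s) < 2L) stop("fewer than 2 overlapping s points")
  interp <- function(p) list(
    i   = stats::approx(p$s, p$intensity, xout = s)$y,
    sig = stats::approx(p$s, p$sigma, xout = s)$y)
  list(s = s, a = interp(a), b = interp(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
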