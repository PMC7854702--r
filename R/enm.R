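#' Construct a C-alpha structure
#'
#' @param coords N x 3 matrix of C-alpha coordinates, A.
#' @param b_exp Optional per-residue experimental B-factors, A^2.
#' @param resid Residue identifiers (default sequence numbers).
#' @param chain Chain identifier.
#' @return A tibble of class `calpha_structure` with columns `x`, `y`, `z`,
#'   `resid`, and `b_exp` when present.
#' @export
calpha_structure <- function(coords, b_exp = NULL, resid = NULL, chain = "A") {
  m <- as.matrix(coords)
  if (nrow(m) < 2L) stop("need at least 2 residues")
  if (any(!is.finite(m))) stop("non-finite coordinates")
  if (!is.null(b_exp) && length(b_exp) != nrow(m))
    stop("b_exp length must match the residue count")
  out <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3],
                        resid = resid %||% as.character(seq_len(nrow(m))))
  if (!is.null(b_exp)) out$b_exp <- as.numeric(b_exp)
  attr(out, "chain") <- chain
  class(out) <- c("calpha_structure", class(out))
  out
}

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Keeps the first alternate location of each residue; insertion codes are
#' preserved in the residue identifiers. The B-factor column is captured as
#' `b_exp`.
#'
#' @param path PDB file path.
#' @param chain Chain identifier (default `"A"`).
#' @return A [calpha_structure()].
#' @export
read_calpha_pdb <- function(path, chain = "A") {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- at$elety == "CA" & at$chain == chain
  if (!any(keep)) stop("no CA atoms in chain ", chain, " of ", path)
  at <- at[keep, , drop = FALSE]
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  rid <- paste0(at$resno, ins)
  first <- !duplicated(rid)            # first altloc wins
  at <- at[first, , drop = FALSE]; rid <- rid[first]
  ord <- order(at$resno)               # stable: insertion order preserved
  at <- at[ord, , drop = FALSE]; rid <- rid[ord]
  calpha_structure(cbind(at$x, at$y, at$z), b_exp = at$b,
                   resid = rid, chain = chain)
}

#' Build an anisotropic elastic network and its Hessian
#'
#' Connects every pair of C-alpha atoms within the cutoff distance
#' (inclusive) by a Hookean spring of force constant `k`. The 3N x 3N
#' Hessian is assembled from per-pair super-elements
#' \eqn{-k \hat r_{ij} \hat r_{ij}^T} with diagonal blocks equal to minus
#' the sum of the off-diagonal blocks, so each block row sums to zero
#' (translation invariance). Unit masses throughout (C-alpha-only network).
#'
#' @param structure A [calpha_structure()].
#' @param cutoff Contact cutoff distance, A (7 A is a typical choice for
#'   C-alpha networks).
#' @param k Spring force constant (relative energy/A^2 units).
#' @return Object of class `enm_model`: `cutoff`, `k`, `contacts`
#'   (two-column i < j index matrix), `hessian` (3N x 3N), `n_atoms`,
#'   `connected` (single-component flag).
#' @export
build_enm <- function(structure, cutoff = 7, k = 1) {
  if (cutoff <= 0 || k <= 0) stop("cutoff and k must be positive")
  m <- unname(cbind(structure$x, structure$y, structure$z))
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  adj <- d <= cutoff & upper.tri(d)    # inclusive contact rule
  contacts <- which(adj, arr.ind = TRUE)
  if (nrow(contacts) == 0L) stop("disconnected network: no contacts at cutoff")
  colnames(contacts) <- c("i", "j")
  H <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(contacts))) {
    i <- contacts[p, 1]; j <- contacts[p, 2]
    rij <- m[j, ] - m[i, ]
    e <- rij / sqrt(sum(rij^2))
    blk <- k * tcrossprod(e)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  comp <- network_components(n, contacts)
  if (max(comp) > 1L)
    rlang::warn(sprintf("contact network has %d components", max(comp)),
                class = "phytosaxs_disconnected_enm")
  structure(list(cutoff = cutoff, k = k, contacts = contacts, hessian = H,
                 n_atoms = n, connected = max(comp) == 1L),
            class = "enm_model")
}

# connected components of the contact graph by label propagation (union-find)
network_components <- function(n, contacts) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (p in seq_len(nrow(contacts))) {
    a <- find(contacts[p, 1]); b <- find(contacts[p, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' @export
print.enm_model <- function(x, ...) {
  cat(sprintf("<enm_model> %d atoms, cutoff %.2f A, k = %g, %d springs%s\n",
              x$n_atoms, x$cutoff, x$k, nrow(x$contacts),
              if (x$connected) "" else " (DISCONNECTED)"))
  invisible(x)
}

#' Normal modes of an elastic network
#'
#' Full symmetric eigendecomposition of the Hessian with unit masses.
#' Eigenvalues come back ascending; modes with eigenvalue below
#' `tol_rel * max(eigenvalue)` are flagged as zero modes (6 for a
#' connected non-collinear 3-D network: rigid translations and rotations).
#'
#' @param x An [build_enm()] result or a symmetric 3N x 3N Hessian matrix.
#' @param tol_rel Relative zero-mode tolerance (default 1e-10).
#' @return Object of class `mode_set`: `eigenvalues` (ascending),
#'   `eigenvectors` (orthonormal columns), `n_zero`.
#' @export
compute_modes <- function(x, tol_rel = 1e-10) {
  H <- if (inherits(x, "enm_model")) x$hessian else x
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
    stop("Hessian is not symmetric")
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  vals <- ev$values[ord]; vecs <- ev$vectors[, ord, drop = FALSE]
  n_zero <- sum(vals < tol_rel * max(vals))
  structure(list(eigenvalues = vals, eigenvectors = vecs, n_zero = n_zero),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  nz <- x$n_zero
  cat(sprintf("<mode_set> %d modes, %d zero modes; lowest internal eigenvalue %.4g\n",
              length(x$eigenvalues), nz,
              if (nz < length(x$eigenvalues)) x$eigenvalues[nz + 1] else NA))
  invisible(x)
}

#' Predict relative B-factors from an elastic network's modes
#'
#' Standard pseudo-inverse estimate: per residue,
#' \eqn{B_i \propto \sum_{m > n_{zero}} \lambda_m^{-1} |v_{m,i}|^2}
#' where \eqn{|v_{m,i}|^2} collects the three Cartesian components of
#' residue i in mode m. Returned on a relative scale (unit force constant);
#' see [scale_force_constant()] for matching experimental magnitudes.
#'
#' @param modes A [compute_modes()] result.
#' @return Numeric vector of non-negative relative B-factors, length N.
#' @export
predict_bfactors <- function(modes) {
  nm <- length(modes$eigenvalues)
  if (modes$n_zero >= nm) stop("all modes are zero modes")
  idx <- (modes$n_zero + 1):nm
  V2 <- modes$eigenvectors[, idx, drop = FALSE]^2
  w <- 1 / modes$eigenvalues[idx]
  per_coord <- as.numeric(V2 %*% w)
  n <- length(per_coord) / 3
  colSums(matrix(per_coord, nrow = 3))
}

#' Calibrate the contact cutoff against experimental B-factors
#'
#' Recomputes the network and the predicted B-factors for every cutoff on
#' a grid (default 6 to 15 A in 0.5 A steps) and returns the cutoff
#' maximising the Pearson correlation with `b_exp`; ties break toward the
#' smaller cutoff, and cutoffs whose network is disconnected or degenerate
#' are skipped with a warning.
#'
#' @param structure A [calpha_structure()] with `b_exp`.
#' @param cutoff_grid Cutoffs to scan, A.
#' @return List with `best_cutoff` and `curve` (tibble of `cutoff`,
#'   `correlation`).
#' @export
calibrate_cutoff <- function(structure, cutoff_grid = seq(6, 15, by = 0.5)) {
  if (is.null(structure$b_exp)) stop("structure carries no experimental B-factors")
  if (stats::sd(structure$b_exp) == 0)
    stop("constant experimental B-factors: correlation undefined")
  cors <- vapply(cutoff_grid, function(rc) {
    out <- tryCatch({
      enm <- withCallingHandlers(
        build_enm(structure, cutoff = rc),
        warning = function(w) if (inherits(w, "phytosaxs_disconnected_enm"))
          invokeRestart("muffleWarning"))
      if (!enm$connected) return(NA_real_)
      stats::cor(predict_bfactors(compute_modes(enm)), structure$b_exp)
    }, error = function(e) NA_real_)
    out
  }, 0)
  if (all(is.na(cors))) stop("every cutoff on the grid gives a disconnected network")
  if (any(is.na(cors)))
    rlang::warn(sprintf("skipped %d disconnected cutoff(s)", sum(is.na(cors))))
  best <- cutoff_grid[which.max(cors)]  # which.max: first max = smallest cutoff
  list(best_cutoff = best,
       curve = tibble::tibble(cutoff = cutoff_grid, correlation = cors))
}

#' Scale predicted B-factors to the experimental sum
#'
#' Adjusts the (relative) predicted B-factors by the single factor
#' `sum(b_exp) / sum(b_pred)` — equivalent to adjusting the spring force
#' constant — so the theoretical and experimental sums match. Scaling
#' leaves the Pearson correlation unchanged.
#'
#' @param b_pred_relative Relative predicted B-factors.
#' @param b_exp Experimental B-factors, A^2.
#' @return Object of class `bfactor_prediction`: `b_pred` (scaled, A^2),
#'   `correlation`, `scale`.
#' @export
scale_force_constant <- function(b_pred_relative, b_exp) {
  if (length(b_pred_relative) != length(b_exp)) stop("length mismatch")
  sp <- sum(b_pred_relative)
  if (sp <= 0) stop("sum of predicted B-factors is zero")
  sc <- sum(b_exp) / sp
  structure(list(b_pred = b_pred_relative * sc,
                 correlation = stats::cor(b_pred_relative, b_exp),
                 scale = sc),
            class = "bfactor_prediction")
}

#' @export
tidy.bfactor_prediction <- function(x, ...) {
  tibble::tibble(residue = seq_along(x$b_pred), b_pred = x$b_pred)
}

#' @export
glance.bfactor_prediction <- function(x, ...) {
  tibble::tibble(correlation = x$correlation, scale = x$scale,
                 nobs = length(x$b_pred))
}

#' Displacement vectors of one internal normal mode
#'
#' Mode index 1 addresses the lowest-energy internal mode (the first mode
#' after the zero modes). Amplitudes are the unit eigenvector components
#' scaled by `magnification` (3 is a common choice for rendering).
#'
#' @param modes A [compute_modes()] result.
#' @param mode_index Internal mode number (1 = lowest energy).
#' @param magnification Scale factor applied to the displacements.
#' @return N x 3 matrix of displacement vectors.
#' @export
mode_displacements <- function(modes, mode_index = 1, magnification = 3) {
  col <- modes$n_zero + mode_index
  if (mode_index < 1 || col > length(modes$eigenvalues))
    stop("mode_index out of range")
  v <- modes$eigenvectors[, col]
  matrix(v, ncol = 3, byrow = TRUE) * magnification
}

#' Write a start/displaced two-frame PDB for mode rendering
#'
#' @param structure A [calpha_structure()].
#' @param displacements N x 3 matrix from [mode_displacements()].
#' @param path Output path; two MODEL frames are written.
#' @return `path`, invisibly.
#' @export
write_mode_pdb <- function(structure, displacements, path) {
  m <- unname(cbind(structure$x, structure$y, structure$z))
  xyz <- rbind(as.numeric(t(m)), as.numeric(t(m + displacements)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = seq_len(nrow(m)), resid = rep("GLY", nrow(m)),
                   elety = rep("CA", nrow(m)),
                   chain = rep(attr(structure, "chain") %||% "A", nrow(m)))
  invisible(path)
}
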