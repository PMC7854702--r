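#' Align a bead model onto its principal axes of inertia
#'
#' Centres the model at its centroid and rotates the inertia-tensor
#' eigenvectors onto x, y, z in ascending-eigenvalue order (the long axis of
#' an elongated particle becomes x), enforcing a proper rotation
#' (det = +1). The four-fold axis-sign degeneracy — and, with
#' `enantiomer = TRUE`, the mirror image, since scattering-derived shapes
#' carry no handedness information — is resolved by maximising binary voxel
#' overlap with `reference` when one is given; otherwise a deterministic
#' canonical rule applies: the third moments along x and y are made
#' positive and the z sign follows from det = +1.
#'
#' @param model A [bead_model()] with at least 3 non-collinear beads.
#' @param reference Optional [bead_model()] already in the target frame.
#' @param enantiomer If `TRUE` and a reference is given, the mirror image is
#'   also scored against the reference.
#' @param voxel_size Voxel edge used for the overlap score, A.
#' @param refine If `TRUE` (and a reference is given), follow the discrete
#'   frame search with a coordinate-wise rotational grid refinement that
#'   maximises voxel overlap — needed for shapes whose inertia tensor is
#'   nearly degenerate (e.g. ~90-degree crosses), where the principal-axis
#'   frame is unstable.
#' @return The aligned [bead_model()].
#' @export
align_principal_axes <- function(model, reference = NULL, enantiomer = FALSE,
                                 voxel_size = 6, refine = FALSE) {
  m <- bead_coords(model)
  if (nrow(m) < 3L) stop("need at least 3 beads to align")
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  r2 <- rowSums(mc^2)
  inertia <- diag(sum(r2), 3) - crossprod(mc)
  ev <- eigen(inertia, symmetric = TRUE)
  ord <- order(ev$values)              # ascending inertia: long axis first
  vals <- ev$values[ord]
  E <- ev$vectors[, ord, drop = FALSE]
  if (vals[3] - vals[1] < 0.02 * vals[3])
    rlang::warn("near-degenerate inertia tensor: canonical orientation is arbitrary",
                class = "phytosaxs_degenerate_inertia")
  if (qr(mc)$rank < 2L) stop("collinear bead model cannot be aligned")
  if (det(E) < 0) E[, 3] <- -E[, 3]
  rot <- mc %*% E
  if (is.null(reference)) {
    s <- c(sign3(sum(rot[, 1]^3)), sign3(sum(rot[, 2]^3)), 1)
    s[3] <- s[1] * s[2]                # keep det = +1
    rot <- sweep(rot, 2, s, `*`)
  } else {
    ref <- bead_coords(reference)
    # full proper rotation group of the axis frame (24 elements: axis
    # permutations x sign flips with det = +1), plus the 24 mirrored ones
    # when enantiomer handling is on -- shapes with near-degenerate inertia
    # eigenvalues (e.g. ~90-degree crosses) can come out axis-swapped, not
    # just sign-flipped
    cands <- axis_frame_candidates(enantiomer)
    score <- vapply(cands, function(tr)
      voxel_overlap(rot[, tr$perm, drop = FALSE] %*% diag(tr$signs), ref,
                    voxel_size), 0)
    tr <- cands[[which.max(score)]]
    rot <- rot[, tr$perm, drop = FALSE] %*% diag(tr$signs)
    if (refine) {
      best <- voxel_overlap(rot, ref, voxel_size)
      for (pass in 1:2) {
        for (axis in 1:3) {
          for (ang in setdiff(seq(-40, 40, by = 5), 0) * pi / 180) {
            R <- switch(axis, rotation_x(ang), rotation_y(ang), rotation_z(ang))
            cand <- rot %*% t(R)
            sc <- voxel_overlap(cand, ref, voxel_size)
            if (sc > best) { best <- sc; rot <- cand }
          }
        }
      }
    }
  }
  out <- bead_model(rot, bead_radius = attr(model, "bead_radius"),
                    label = attr(model, "label"))
  out
}

sign3 <- function(x) if (x < 0) -1 else 1

perm_parity <- function(p) {
  # parity of a permutation of 1:3
  if (identical(p, c(1L, 2L, 3L)) || identical(p, c(2L, 3L, 1L)) ||
      identical(p, c(3L, 1L, 2L))) 1 else -1
}

axis_frame_candidates <- local({
  cache <- list()
  function(enantiomer) {
    key <- if (enantiomer) "both" else "proper"
    if (!is.null(cache[[key]])) return(cache[[key]])
    perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                  c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
    signs <- as.matrix(expand.grid(c(1,-1), c(1,-1), c(1,-1)))
    out <- list()
    for (p in perms) for (r in seq_len(nrow(signs))) {
      det_ <- perm_parity(p) * prod(signs[r, ])
      if (det_ > 0 || enantiomer)
        out[[length(out) + 1L]] <- list(perm = p, signs = unname(signs[r, ]))
    }
    cache[[key]] <<- out
    out
  }
})

# count of occupied voxels shared by two coordinate sets on a common grid
voxel_overlap <- function(a, b, voxel_size) {
  lower <- pmin(apply(a, 2, min), apply(b, 2, min)) - voxel_size
  key <- function(m) {
    idx <- floor(sweep(m, 2, lower) / voxel_size)
    unique(idx[, 1] * 1e10 + idx[, 2] * 1e5 + idx[, 3])
  }
  length(intersect(key(a), key(b)))
}

#' Shared bounding box for an ensemble of aligned models
#'
#' Union of the models' coordinate ranges padded by one voxel on each side
#' and snapped to whole voxels, so every model of the ensemble can be
#' voxelised on one grid.
#'
#' @param models List of aligned [bead_model()] objects.
#' @param voxel_size Voxel edge, A.
#' @return List with `lower`, `upper` (corner coordinates) and `dim`.
#' @export
ensemble_extent <- function(models, voxel_size = 6) {
  lo <- Reduce(pmin, lapply(models, function(m) c(min(m$x), min(m$y), min(m$z))))
  hi <- Reduce(pmax, lapply(models, function(m) c(max(m$x), max(m$y), max(m$z))))
  lower <- floor(lo / voxel_size - 1) * voxel_size
  upper <- ceiling(hi / voxel_size + 1) * voxel_size
  list(lower = lower, upper = upper,
       dim = as.integer(round((upper - lower) / voxel_size)))
}

#' Voxelise a bead model as number densities
#'
#' Counts beads in a cubic grid with half-open voxels
#' `[edge, edge + voxel_size)` anchored at the extent corner, and divides by
#' the voxel volume. Total density times voxel volume equals the bead count
#' exactly (conservation).
#'
#' @param model An aligned [bead_model()].
#' @param voxel_size Voxel edge, A (default 6, i.e. 6 x 6 x 6 A^3 voxels).
#' @param extent Shared extent from [ensemble_extent()]; computed from the
#'   model alone when omitted.
#' @return Object of class `voxel_grid`: `origin`, `voxel_size`, `dim`,
#'   `counts` (3-D array), `density` (counts / voxel volume), `n_beads`.
#' @export
voxelize <- function(model, voxel_size = 6, extent = NULL) {
  if (is.null(extent)) extent <- ensemble_extent(list(model), voxel_size)
  m <- bead_coords(model)
  idx <- floor(sweep(m, 2, extent$lower) / voxel_size)
  if (any(idx < 0) || any(sweep(idx, 2, extent$dim, `>=`)))
    stop("bead outside extent: recompute the shared extent")
  lin <- 1L + idx[, 1] + extent$dim[1] * (idx[, 2] + extent$dim[2] * idx[, 3])
  counts <- array(tabulate(lin, nbins = prod(extent$dim)), dim = extent$dim)
  structure(list(origin = extent$lower, voxel_size = voxel_size,
                 dim = extent$dim, counts = counts,
                 density = counts / voxel_size^3, n_beads = nrow(m)),
            class = "voxel_grid")
}

#' Binary voxel occupancy mask of a bead model
#'
#' Marks every voxel whose cube lies within the bead radius of any bead
#' centre, i.e. beads are treated as spheres of their physical radius
#' rather than points. This is the mask used for cluster averaging and
#' shape comparison; [voxelize()] keeps exact per-centre counts.
#'
#' @param model A [bead_model()].
#' @param voxel_size Voxel edge, A.
#' @param extent Shared extent from [ensemble_extent()].
#' @return Logical 3-D array of dimension `extent$dim`.
#' @export
voxel_mask <- function(model, voxel_size = 6, extent = NULL) {
  if (is.null(extent)) extent <- ensemble_extent(list(model), voxel_size)
  m <- bead_coords(model)
  r <- attr(model, "bead_radius")
  rel <- sweep(m, 2, extent$lower) / voxel_size
  idx <- floor(rel)
  if (any(idx < 0) || any(sweep(idx, 2, extent$dim, `>=`)))
    stop("bead outside extent: recompute the shared extent")
  f <- (rel - idx) * voxel_size          # position within the voxel, A
  mask <- array(FALSE, dim = extent$dim)
  reach <- ceiling(r / voxel_size)
  offs <- as.matrix(expand.grid(dx = -reach:reach, dy = -reach:reach,
                                dz = -reach:reach))
  for (o in seq_len(nrow(offs))) {
    d <- offs[o, ]
    # per-axis distance from the bead centre to the neighbour voxel's box
    dist2 <- rowSums(sapply(1:3, function(k) {
      if (d[k] == 0) rep(0, nrow(m))
      else if (d[k] < 0) (f[, k] + (abs(d[k]) - 1) * voxel_size)^2
      else ((voxel_size - f[, k]) + (d[k] - 1) * voxel_size)^2
    }))
    hit <- dist2 <= r^2
    if (!any(hit)) next
    tgt <- sweep(idx[hit, , drop = FALSE], 2, d, `+`)
    ok <- rowSums(tgt < 0) == 0 & rowSums(sweep(tgt, 2, extent$dim, `>=`)) == 0
    tgt <- tgt[ok, , drop = FALSE]
    if (nrow(tgt) == 0) next
    lin <- 1L + tgt[, 1] + extent$dim[1] * (tgt[, 2] + extent$dim[2] * tgt[, 3])
    mask[lin] <- TRUE
  }
  mask
}

#' Principal component embedding of voxelised models
#'
#' Treats each voxel grid as a point in the space spanned by per-voxel
#' number densities, performs mean-centred PCA (covariance based) and
#' retains the first two components as the classification plane. Component
#' signs are fixed deterministically (largest-magnitude loading positive).
#'
#' @param grids List of at least 3 [voxelize()] outputs on one extent.
#' @return Object of class `shape_embedding`: `coords` (M x 2 scores),
#'   `explained_variance_ratio` (full spectrum), `component_axes`
#'   (voxel-space loadings, 2 columns), `mean_vector`, `grid_dim`.
#' @export
embed_pca <- function(grids) {
  if (length(grids) < 3L) stop("need at least 3 grids")
  dims <- unique(lapply(grids, function(g) g$dim))
  if (length(dims) != 1L) stop("grids must share one extent")
  X <- do.call(rbind, lapply(grids, function(g) as.numeric(g$density)))
  if (max(apply(X, 2, stats::var)) == 0) stop("zero total variance")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  axes <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    sgn <- sign3(axes[which.max(abs(axes[, j])), j])
    axes[, j] <- sgn * axes[, j]; scores[, j] <- sgn * scores[, j]
  }
  structure(list(coords = unname(scores),
                 explained_variance_ratio = evr,
                 component_axes = unname(axes),
                 mean_vector = pc$center,
                 grid_dim = grids[[1]]$dim,
                 grid_origin = grids[[1]]$origin,
                 voxel_size = grids[[1]]$voxel_size),
            class = "shape_embedding")
}

#' K-means clustering of the PCA plane
#'
#' Partitions the 2-D embedding into `k` groups with [stats::kmeans()],
#' best of `n_restarts` random starts by within-cluster sum of squares,
#' deterministic for a fixed seed. Empty clusters are reported, not
#' re-seeded.
#'
#' @param embedding A [embed_pca()] result (or an M x 2 matrix).
#' @param k Number of groups (default 10).
#' @param seed RNG seed.
#' @param n_restarts Random restarts (default 50).
#' @return Object of class `cluster_assignment`: `labels` (1..k),
#'   `centroids`, `sizes`, `inertia`, `empty_clusters`, `seed`, `coords`.
#' @export
cluster_kmeans <- function(embedding, k = 10, seed = 11, n_restarts = 50) {
  coords <- if (inherits(embedding, "shape_embedding")) embedding$coords
            else as.matrix(embedding)
  if (nrow(coords) < k) stop("fewer points than clusters")
  if (nrow(coords) == k) {
    # degenerate case: every point is its own cluster
    km <- list(cluster = seq_len(k), centers = coords, tot.withinss = 0)
  } else {
    km <- with_local_seed(seed,
      suppressWarnings(stats::kmeans(coords, centers = k, nstart = n_restarts,
                                     iter.max = 100)))
  }
  sizes <- tabulate(km$cluster, nbins = k)
  structure(list(labels = km$cluster, k = k, centroids = km$centers,
                 sizes = sizes, inertia = km$tot.withinss,
                 empty_clusters = which(sizes == 0L), seed = seed,
                 coords = coords),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, sizes: %s, inertia = %.4g\n",
              x$k, paste(x$sizes, collapse = ", "), x$inertia))
  invisible(x)
}

#' @export
tidy.cluster_assignment <- function(x, ...) {
  tibble::tibble(model = seq_along(x$labels), cluster = x$labels,
                 pc1 = x$coords[, 1], pc2 = x$coords[, 2])
}

#' Averaged molecular shape of one cluster
#'
#' Picks a reference member (nearest the cluster centroid in PC space
#' unless given), re-aligns every member onto it with enantiomer handling
#' enabled, and averages binary voxel occupancies. Voxels whose occupancy
#' reaches `threshold` form the representative surface.
#'
#' @param models The full list of aligned [bead_model()] objects.
#' @param assignment A [cluster_kmeans()] result for the same models.
#' @param cluster_id Cluster to average (1..k).
#' @param reference Optional index (into `models`) of the reference member.
#' @param voxel_size Voxel edge, A.
#' @param threshold Occupancy cut-off in `[0, 1]` (default 0.5).
#' @return Object of class `averaged_shape`: `occupancy` (3-D array in
#'   `[0, 1]`), `origin`, `voxel_size`, `threshold`, `n_members`,
#'   `reference_index`, `reference_model`.
#' @export
average_cluster <- function(models, assignment, cluster_id, reference = NULL,
                            voxel_size = 6, threshold = 0.5) {
  members <- which(assignment$labels == cluster_id)
  if (length(members) == 0L) stop("empty cluster")
  if (is.null(reference)) {
    ctr <- assignment$centroids[cluster_id, ]
    d2 <- rowSums(sweep(assignment$coords[members, , drop = FALSE], 2, ctr)^2)
    reference <- members[which.min(d2)]
  }
  ref_model <- align_principal_axes(models[[reference]])
  aligned <- lapply(models[members], align_principal_axes,
                    reference = ref_model, enantiomer = TRUE,
                    voxel_size = voxel_size, refine = TRUE)
  ext <- ensemble_extent(c(list(ref_model), aligned), voxel_size)
  occ <- Reduce(`+`, lapply(aligned, function(m)
    voxel_mask(m, voxel_size, ext) * 1)) / length(aligned)
  structure(list(occupancy = occ, origin = ext$lower,
                 voxel_size = voxel_size, threshold = threshold,
                 n_members = length(members), reference_index = reference,
                 reference_model = ref_model),
            class = "averaged_shape")
}

#' Representative bead model of an averaged shape
#'
#' Centres of voxels whose occupancy reaches the threshold.
#'
#' @param avg An [average_cluster()] result.
#' @param threshold Occupancy cut-off; defaults to the stored one.
#' @return A [bead_model()].
#' @export
averaged_shape_model <- function(avg, threshold = avg$threshold) {
  idx <- which(avg$occupancy >= threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no voxel reaches the occupancy threshold")
  ctrs <- sweep((idx - 0.5) * avg$voxel_size, 2, avg$origin, `+`)
  bead_model(ctrs, label = "averaged shape")
}

#' Jaccard index between an averaged shape and a ground-truth model
#'
#' Aligns `model` onto the averaged shape's reference frame (principal
#' axes, enantiomer handling on), builds its bead-sphere voxel mask on a
#' joint grid, and compares it against the occupancy mask
#' `occupancy >= threshold`.
#'
#' @param avg An [average_cluster()] result.
#' @param model A [bead_model()] (e.g. the planted family template).
#' @param threshold Occupancy cut-off; defaults to the stored one.
#' @return Jaccard index in `[0, 1]`.
#' @export
shape_jaccard <- function(avg, model, threshold = avg$threshold) {
  vs <- avg$voxel_size
  b <- align_principal_axes(model, reference = avg$reference_model,
                            enantiomer = TRUE, voxel_size = vs, refine = TRUE)
  # joint grid anchored on the averaged grid (whole-voxel offsets only)
  lo_b <- c(min(b$x), min(b$y), min(b$z)) - 2 * vs
  lower <- pmin(avg$origin, avg$origin +
                  floor((lo_b - avg$origin) / vs) * vs)
  hi_b <- c(max(b$x), max(b$y), max(b$z)) + 2 * vs
  upper <- pmax(avg$origin + dim(avg$occupancy) * vs,
                avg$origin + ceiling((hi_b - avg$origin) / vs) * vs)
  ext <- list(lower = lower, upper = upper,
              dim = as.integer(round((upper - lower) / vs)))
  ma <- array(FALSE, dim = ext$dim)
  off <- as.integer(round((avg$origin - lower) / vs))
  da <- dim(avg$occupancy)
  ma[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]), off[3] + seq_len(da[3])] <-
    avg$occupancy >= threshold
  mb <- voxel_mask(b, vs, ext)
  sum(ma & mb) / sum(ma | mb)
}

#' Voxel-mask Jaccard index between two bead models
#'
#' Aligns `model_b` onto `model_a` (principal axes, enantiomer handling on),
#' voxelises both on a joint grid, and returns |A & B| / |A | B| of the
#' binary occupancy masks.
#'
#' @param model_a,model_b [bead_model()] objects.
#' @param voxel_size Voxel edge, A.
#' @return Jaccard index in `[0, 1]`.
#' @export
voxel_jaccard <- function(model_a, model_b, voxel_size = 6) {
  a <- align_principal_axes(model_a)
  b <- align_principal_axes(model_b, reference = a, enantiomer = TRUE,
                            voxel_size = voxel_size)
  ext <- ensemble_extent(list(a, b), voxel_size)
  ma <- voxel_mask(a, voxel_size, ext)
  mb <- voxel_mask(b, voxel_size, ext)
  sum(ma & mb) / sum(ma | mb)
}

#' Classify an ensemble of bead models into representative shapes
#'
#' End-to-end multivariate protocol: inertia-axis alignment, voxelisation on
#' a shared 6 A grid, PCA onto the first two components, k-means into `k`
#' groups, and per-group averaged shapes.
#'
#' @param models List of [bead_model()] objects or a character vector of
#'   PDB paths.
#' @param voxel_size Voxel edge, A (default 6).
#' @param k Number of groups (default 10).
#' @param seed RNG seed for the clustering.
#' @param n_restarts K-means restarts.
#' @param threshold Occupancy threshold for representative surfaces.
#' @param average If `FALSE`, skip the per-group averaging (fast path when
#'   only the partition is needed).
#' @return Object of class `shape_classification`: `embedding`,
#'   `assignment`, `group_sizes`, `averaged` (list of [average_cluster()]
#'   results, `NULL` when `average = FALSE`), `aligned_models`.
#' @export
classify_ensemble <- function(models, voxel_size = 6, k = 10, seed = 11,
                              n_restarts = 50, threshold = 0.5,
                              average = TRUE) {
  if (is.character(models)) models <- lapply(models, read_bead_pdb)
  aligned <- lapply(models, align_principal_axes)
  # second pass: superimpose everything onto one common reference with
  # axis-flip and enantiomer scoring, collapsing the sign/handedness
  # degeneracy that would otherwise split one shape family into several
  # voxel-space blobs
  ref <- aligned[[1]]
  aligned <- lapply(aligned, align_principal_axes, reference = ref,
                    enantiomer = TRUE, voxel_size = voxel_size)
  ext <- ensemble_extent(aligned, voxel_size)
  grids <- lapply(aligned, voxelize, voxel_size = voxel_size, extent = ext)
  emb <- embed_pca(grids)
  asg <- cluster_kmeans(emb, k = k, seed = seed, n_restarts = n_restarts)
  avgs <- NULL
  if (average)
    avgs <- lapply(seq_len(k), function(g)
      if (asg$sizes[g] > 0) average_cluster(aligned, asg, g,
                                            voxel_size = voxel_size,
                                            threshold = threshold))
  structure(list(embedding = emb, assignment = asg,
                 group_sizes = asg$sizes, averaged = avgs,
                 aligned_models = aligned, voxel_size = voxel_size,
                 seed = seed),
            class = "shape_classification")
}

#' @export
print.shape_classification <- function(x, ...) {
  cat(sprintf("<shape_classification> %d models, k = %d, group sizes: %s\n",
              length(x$aligned_models), x$assignment$k,
              paste(x$group_sizes, collapse = ", ")))
  cat(sprintf("  PC1+PC2 explain %.1f%% of voxel-density variance\n",
              100 * sum(x$embedding$explained_variance_ratio[1:2])))
  invisible(x)
}

#' PC-plane scatter of a classified ensemble
#'
#' @param object A [classify_ensemble()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.shape_classification <- function(object, ...) {
  df <- tidy(object$assignment)
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2,
                                   colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = "group") +
    ggplot2::theme_minimal()
}

#' Survey the optimal dummy-residue count for a reconstruction engine
#'
#' For each DR count on a grid (default 900 to 1200 in steps of 25, per
#' subunit), runs `engine(profile, dr_count, seed)` for `n_repeats`
#' independent seeds, scores each returned model by [chi_square()] of its
#' Debye profile against the data, and averages. Returns the count with the
#' smallest mean chi-squared; ties break toward the smaller count.
#'
#' @param profile Experimental [scattering_profile()].
#' @param engine Function `(profile, dr_count, seed) -> bead_model` (any
#'   ab initio reconstruction backend, or a mock for testing).
#' @param dr_range Length-2 integer range of DR counts.
#' @param step Grid increment.
#' @param n_repeats Independent reconstructions per count (default 14).
#' @param seed Base seed; repeat r uses `seed + r - 1`.
#' @param mode Debye evaluation mode passed to [debye_intensity()].
#' @return List with `best_dr_count` and `table` (tibble of
#'   `dr_count`, `mean_chi2`).
#' @export
optimize_dr_count <- function(profile, engine, dr_range = c(900, 1200),
                              step = 25, n_repeats = 14, seed = 1,
                              mode = "histogram") {
  counts <- seq(dr_range[1], dr_range[2], by = step)
  mean_chi2 <- vapply(counts, function(dc) {
    vals <- vapply(seq_len(n_repeats), function(r) {
      mdl <- tryCatch(engine(profile, dc, seed + r - 1L),
                      error = function(e) stop(sprintf(
                        "engine failed at dr_count=%d seed=%d: %s",
                        dc, seed + r - 1L, conditionMessage(e))))
      im <- debye_intensity(mdl, profile$s, mode = mode)
      chi_square(profile, im)$chi2
    }, 0)
    mean(vals)
  }, 0)
  best <- counts[which.min(mean_chi2)]   # first minimum = smallest count
  list(best_dr_count = best,
       table = tibble::tibble(dr_count = counts, mean_chi2 = mean_chi2))
}
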