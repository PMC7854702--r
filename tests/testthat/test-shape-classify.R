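bent_fixture <- function(seed = 21)
  generate_shape("bent_rod", list(length = 120, diameter = 30, bend_angle = 130),
                 n_beads = 600, seed = seed)

test_that("principal-axis alignment is idempotent", {
  a <- align_principal_axes(bent_fixture())
  b <- align_principal_axes(a)
  expect_equal(cbind(b$x, b$y, b$z), cbind(a$x, a$y, a$z), tolerance = 1e-9)
})

test_that("alignment undoes a random rigid motion", {
  set.seed(5)
  ref <- align_principal_axes(bent_fixture())
  for (rep in 1:5) {
    R <- rot3(stats::runif(1, 0, 2 * pi), stats::runif(1, 0, 2 * pi),
              stats::runif(1, 0, 2 * pi))
    moved <- transform_model(ref, R, stats::rnorm(3, 0, 50))
    back <- align_principal_axes(moved, reference = ref)
    rmsd <- sqrt(mean(rowSums((cbind(back$x, back$y, back$z) -
                                 cbind(ref$x, ref$y, ref$z))^2)))
    expect_lt(rmsd, 3)   # half a 6 A voxel
  }
})

test_that("enantiomer handling scores the mirror image against the reference", {
  ref <- align_principal_axes(bent_fixture())
  mirrored <- bead_model(cbind(ref$x, ref$y, -ref$z))
  back <- align_principal_axes(mirrored, reference = ref, enantiomer = TRUE)
  # with the mirror allowed the truth pose must score at least as well
  ov_back <- voxel_jaccard(back, ref)
  back_no <- align_principal_axes(mirrored, reference = ref, enantiomer = FALSE)
  expect_gte(ov_back, voxel_jaccard(back_no, ref) - 1e-12)
})

test_that("collinear models are rejected and degenerate ones warned about", {
  line <- bead_model(cbind(1:10 * 2, 0, 0))
  expect_error(align_principal_axes(line), "collinear")
  sph <- generate_shape("sphere", list(radius = 20), n_beads = 30000, seed = 2)
  expect_warning(align_principal_axes(sph),
                 class = "phytosaxs_degenerate_inertia")
})

test_that("voxelisation conserves bead counts with half-open bins", {
  ext <- list(lower = c(0, 0, 0), upper = c(18, 18, 18), dim = c(3L, 3L, 3L))
  one <- bead_model(matrix(c(9, 9, 9), 1))     # centre of voxel (2,2,2)
  g <- voxelize(one, 6, ext)
  expect_equal(g$counts[2, 2, 2], 1)
  expect_equal(sum(g$counts), 1)
  expect_equal(g$density[2, 2, 2], 1 / 216)
  # a bead exactly on a shared face goes to the higher-index voxel
  face <- bead_model(matrix(c(6, 3, 3), 1))
  gf <- voxelize(face, 6, ext)
  expect_equal(gf$counts[2, 1, 1], 1)
  # conservation at scale
  m <- generate_shape("sphere", list(radius = 25), n_beads = 1000, seed = 3)
  gm <- voxelize(m, 6)
  expect_equal(sum(gm$counts), 1000)
  expect_equal(sum(gm$density) * 216, 1000, tolerance = 1e-9)
  out <- bead_model(matrix(c(100, 0, 0), 1))
  expect_error(voxelize(out, 6, ext), "outside extent")
})

test_that("PCA embedding handles rank-1 structure and rejects degenerate input", {
  base <- generate_shape("sphere", list(radius = 25), n_beads = 500, seed = 4)
  g0 <- voxelize(base, 6)
  # grids varying along exactly one synthetic voxel-space direction
  grids <- lapply(seq(0, 14, by = 2), function(t) {
    g <- g0
    g$counts[1, 1, 1] <- g$counts[1, 1, 1] + t
    g$density <- g$counts / g$voxel_size^3
    g$n_beads <- sum(g$counts)
    g
  })
  emb <- embed_pca(grids)
  expect_gt(emb$explained_variance_ratio[1], 1 - 1e-10)
  expect_true(all(diff(emb$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(emb$explained_variance_ratio), 1 + 1e-9)
  same <- replicate(4, voxelize(base, 6), simplify = FALSE)
  expect_error(embed_pca(same), "zero total variance")
  expect_error(embed_pca(same[1:2]), "at least 3")
})

test_that("k-means separates planted blobs and is seed-deterministic", {
  set.seed(8)
  pts <- rbind(matrix(stats::rnorm(60, 0, 0.3), ncol = 2),
               matrix(stats::rnorm(60, 10, 0.3), ncol = 2))
  asg <- cluster_kmeans(pts, k = 2, seed = 1, n_restarts = 10)
  expect_equal(length(unique(asg$labels[1:30])), 1)
  expect_equal(length(unique(asg$labels[31:60])), 1)
  expect_false(asg$labels[1] == asg$labels[31])
  asg2 <- cluster_kmeans(pts, k = 2, seed = 1, n_restarts = 10)
  expect_identical(asg$labels, asg2$labels)
  # k = M: every point its own cluster
  small <- pts[1:5, ]
  all_own <- cluster_kmeans(small, k = 5, seed = 2, n_restarts = 5)
  expect_equal(sort(all_own$labels), 1:5)
  expect_equal(all_own$inertia, 0, tolerance = 1e-20)
  expect_error(cluster_kmeans(small, k = 6, seed = 1), "fewer points")
})

test_that("cluster averaging reproduces members and handles singletons", {
  ref <- align_principal_axes(bent_fixture())
  models <- c(list(ref), lapply(1:4, function(i) {
    set.seed(i)
    transform_model(ref, rot3(stats::runif(1, 0, 6), stats::runif(1, 0, 6),
                              stats::runif(1, 0, 6)), stats::rnorm(3, 0, 30))
  }))
  coords <- matrix(0, 5, 2)
  asg <- structure(list(labels = rep(1L, 5), k = 1L,
                        centroids = matrix(0, 1, 2), sizes = 5L,
                        inertia = 0, empty_clusters = integer(0), seed = 1,
                        coords = coords), class = "cluster_assignment")
  avg <- average_cluster(models, asg, 1, reference = 1, voxel_size = 6)
  # identical models under rigid motions -> near-binary occupancy
  expect_gt(mean(avg$occupancy[avg$occupancy > 0] >= 0.8), 0.85)
  # singleton: occupancy equals the model's binary mask
  asg1 <- structure(list(labels = c(1L, rep(2L, 4)), k = 2L,
                         centroids = matrix(0, 2, 2), sizes = c(1L, 4L),
                         inertia = 0, empty_clusters = integer(0), seed = 1,
                         coords = coords), class = "cluster_assignment")
  avg1 <- average_cluster(models, asg1, 1, reference = 1, voxel_size = 6)
  expect_true(all(avg1$occupancy %in% c(0, 1)))
  expect_error(average_cluster(models, asg1, 3), "empty cluster")
})

test_that("two disjoint half-shapes average to occupancy 0.5", {
  a <- bead_model(cbind(stats::runif(200, -40, 40), stats::runif(200, -12, 12),
                        stats::runif(200, -9, 9)))
  # same solid, different fill: occupancy of interior voxels is 0.5 only
  # where exactly one member marks the voxel; identical solids mark both.
  # Use genuinely disjoint solids instead:
  b <- transform_model(a, t = c(0, 0, 200))
  ext <- ensemble_extent(list(a, b), 6)
  occ <- (voxel_mask(a, 6, ext) + voxel_mask(b, 6, ext)) / 2
  expect_equal(max(occ), 0.5)
  expect_equal(sum(occ >= 0.5), sum(voxel_mask(a, 6, ext)) + sum(voxel_mask(b, 6, ext)))
})

test_that("the embedding is invariant under one global rigid motion", {
  set.seed(14)
  models <- lapply(1:6, function(i) bent_fixture(seed = 30 + i))
  emb1 <- classify_ensemble(models, k = 2, seed = 3, n_restarts = 5,
                            average = FALSE)$embedding
  R <- rot3(0.4, 1.1, 2.2); t <- c(25, -40, 60)
  moved <- lapply(models, transform_model, R = R, t = t)
  emb2 <- classify_ensemble(moved, k = 2, seed = 3, n_restarts = 5,
                            average = FALSE)$embedding
  expect_equal(emb2$coords, emb1$coords, tolerance = 1e-6)
})

test_that("classification is deterministic and partitions the ensemble", {
  ens <- make_model_ensemble(ensemble_families(n_beads = 200),
                             n_per_family = 8, jitter_sigma = 1,
                             outlier_fraction = 0, seed = 2)
  cl1 <- classify_ensemble(ens$models, k = 4, seed = 5, n_restarts = 10,
                           average = FALSE)
  cl2 <- classify_ensemble(ens$models, k = 4, seed = 5, n_restarts = 10,
                           average = FALSE)
  expect_identical(cl1$assignment$labels, cl2$assignment$labels)
  expect_equal(sum(cl1$group_sizes), 24)
})

test_that("the DR-count survey finds planted optima and breaks ties downward", {
  # analytic sphere intensity as the experimental profile, so the mock
  # engine's chi^2 is a clean function of its radius error
  s <- seq(1e-3, 0.02, by = 5e-4)
  n_eng <- 400   # engine bead count; the experimental curve carries the
                 # matching self term N + N(N-1) f(S)
  iexp <- n_eng + (n_eng^2 - n_eng) * sphere_intensity(s, 30, 1)
  profile <- scattering_profile(s, iexp, pmax(iexp * 0.01, 1e-9))

  # mock engine whose chi^2 is minimised at 1000 DRs: spheres whose radius
  # error grows with |dr - 1000|
  engine <- function(prof, dr, seed)
    generate_shape("sphere",
                   list(radius = 30 + 0.02 * abs(dr - 1000)),
                   n_beads = 400, seed = seed)
  res <- optimize_dr_count(profile, engine, dr_range = c(900, 1100),
                           step = 25, n_repeats = 2, seed = 4)
  expect_equal(res$best_dr_count, 1000)
  expect_equal(nrow(res$table), 9)

  # flat engine: every count equal -> smallest count wins
  flat <- function(prof, dr, seed)
    generate_shape("sphere", list(radius = 30), n_beads = 400, seed = 17)
  res_flat <- optimize_dr_count(profile, flat, dr_range = c(900, 1000),
                                step = 50, n_repeats = 1, seed = 4)
  expect_equal(res_flat$best_dr_count, 900)

  # engine failures carry count and seed context
  bad <- function(prof, dr, seed) stop("backend exploded")
  expect_error(optimize_dr_count(profile, bad, dr_range = c(900, 925),
                                 step = 25, n_repeats = 1, seed = 9),
               "dr_count=900 seed=9")
})

test_that("a noisy mock engine still recovers the planted optimum", {
  s <- seq(1e-3, 0.02, by = 1e-3)
  n_eng <- 300
  iexp <- n_eng + (n_eng^2 - n_eng) * sphere_intensity(s, 30, 1)
  profile <- scattering_profile(s, iexp, pmax(iexp * 0.02, 1e-9))
  # radius noise varies with both count and seed; 14-repeat averaging must
  # still locate the planted minimum
  noisy_engine <- function(prof, dr, seed) {
    eps <- with_local_seed(131L * seed + dr, stats::rnorm(1, 0, 0.3))
    generate_shape("sphere",
                   list(radius = 30 + 0.02 * abs(dr - 1000) + abs(eps)),
                   n_beads = 300, seed = seed)
  }
  hits <- vapply(1:20, function(trial) {
    res <- optimize_dr_count(profile, noisy_engine, dr_range = c(950, 1050),
                             step = 25, n_repeats = 14, seed = 100 * trial)
    res$best_dr_count == 1000
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
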