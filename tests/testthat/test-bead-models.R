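test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(bead_model(matrix(c(1, 2, 3), 1))), 0)
  two <- bead_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(radius_of_gyration(two), 5)
  # Monte-Carlo sphere fill vs sqrt(3/5) R
  sp <- generate_shape("sphere", list(radius = 30), n_beads = 20000, seed = 9)
  expect_equal(radius_of_gyration(sp), sqrt(3 / 5) * 30, tolerance = 0.01)
})

test_that("pair distance histogram bins every pair once", {
  two <- bead_model(rbind(c(0, 0, 0), c(10, 0, 0)))
  h <- pair_distance_histogram(two, bin_width = 1)
  expect_equal(sum(h$counts), 1)
  expect_equal(h$counts[11], 1)   # bin [10, 11)
  tri <- bead_model(rbind(c(0, 0, 0), c(5, 0, 0), c(2.5, 5 * sqrt(3) / 2, 0)))
  h3 <- pair_distance_histogram(tri, bin_width = 1)
  expect_equal(h3$counts[6], 3)   # all three sides in bin [5, 6)
  cloud <- generate_shape("sphere", list(radius = 20), n_beads = 100, seed = 1)
  expect_equal(sum(pair_distance_histogram(cloud, 0.5)$counts), 4950)
  expect_error(pair_distance_histogram(bead_model(matrix(1:3, 1)), 1),
               "at least 2")
})

test_that("Debye intensities match closed forms", {
  s <- seq(0, 0.05, by = 0.005)
  one <- bead_model(matrix(c(0, 0, 0), 1))
  expect_equal(debye_intensity(one, s)$intensity, rep(1, length(s)))
  d <- 25
  two <- bead_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  got <- debye_intensity(two, s, mode = "exact")$intensity
  x <- 2 * pi * s * d
  want <- 2 + 2 * ifelse(x == 0, 1, sin(x) / x)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(debye_intensity(two, numeric(0)), "empty")
})

test_that("I(0) equals N^2 exactly and the histogram mode tracks exact mode", {
  m <- generate_shape("ellipsoid", list(semiaxes = c(60, 35, 25)),
                      n_beads = 1200, seed = 5)
  s <- seq(0, 0.02, by = 1e-3)
  ex <- debye_intensity(m, s, mode = "exact")$intensity
  expect_equal(ex[1], 1200^2)
  hi <- debye_intensity(m, s, mode = "histogram", bin_width = 0.5)$intensity
  expect_lt(max(abs(hi - ex) / ex), 2e-3)
})

test_that("a dense sphere fill reproduces the analytic sphere intensity", {
  sp <- generate_shape("sphere", list(radius = 30), n_beads = 20000, seed = 2)
  s <- seq(1e-3, 0.02, by = 1e-3)
  got <- debye_intensity(sp, s, mode = "histogram", bin_width = 0.5)$intensity
  # N point beads scatter as N + N(N-1) f(S): the constant self term is
  # part of the closed form, not noise
  n <- 20000
  want <- n + (n^2 - n) * sphere_intensity(s, 30, 1)
  expect_lt(max(abs(got - want) / want), 0.02)
})

test_that("chi-square scale factor is the weighted least-squares optimum", {
  p <- guinier_profile()
  self2 <- scattering_profile(p$s, 2 * p$intensity, p$sigma)
  fq <- chi_square(p, self2)
  expect_equal(fq$chi2, 0, tolerance = 1e-20)
  expect_equal(fq$alpha, 0.5, tolerance = 1e-12)
  fq1 <- chi_square(p, p)
  expect_equal(fq1$alpha, 1, tolerance = 1e-12)

  # alpha* beats a dense grid scan for random profile pairs
  set.seed(3)
  s <- seq(1e-3, 0.05, length.out = 60)
  for (rep in 1:5) {
    ie <- scattering_profile(s, stats::runif(60, 1, 50), stats::runif(60, 0.5, 2))
    im <- scattering_profile(s, stats::runif(60, 1, 50), rep(1, 60))
    fq <- chi_square(ie, im)
    chi2_at <- function(a)
      sum(((ie$intensity - a * im$intensity) / ie$sigma)^2) / (60 - 1)
    grid <- seq(0.5 * fq$alpha, 1.5 * fq$alpha, length.out = 1e4)
    expect_lte(fq$chi2, min(vapply(grid, chi2_at, 0)) + 1e-12)
  }
})

test_that("chi-square is invariant under joint model rescaling", {
  p <- guinier_profile()
  m <- scattering_profile(p$s, p$intensity * exp(-100 * p$s), p$sigma)
  c1 <- chi_square(p, m)
  c2 <- chi_square(p, scattering_profile(p$s, 37 * m$intensity, p$sigma))
  expect_equal(c1$chi2, c2$chi2, tolerance = 1e-10)
  expect_equal(c2$alpha, c1$alpha / 37, tolerance = 1e-10)
})

test_that("generated shapes have the expected geometry", {
  rod <- generate_shape("straight_rod", list(length = 175, diameter = 50),
                        n_beads = 4000, seed = 1)
  expect_equal(radius_of_gyration(rod), sqrt(175^2 / 12 + 25^2 / 2),
               tolerance = 0.03)
  # a 180-degree bend is the straight rod sampler, bitwise
  straight <- generate_shape("straight_rod", list(length = 100, diameter = 30),
                             n_beads = 500, seed = 7)
  bent180 <- generate_shape("bent_rod",
                            list(length = 100, diameter = 30, bend_angle = 180),
                            n_beads = 500, seed = 7)
  expect_identical(cbind(straight$x, straight$y, straight$z),
                   cbind(bent180$x, bent180$y, bent180$z))
})

test_that("dimers are point-symmetric about the two-fold axis", {
  dim_ <- generate_shape("two_subunit_dimer",
                         list(subunit = list(kind = "straight_rod",
                                             params = list(length = 100, diameter = 30)),
                              crossing_angle = 60, separation = 40),
                         n_beads = 400, seed = 3)
  m <- cbind(dim_$x, dim_$y, dim_$z)
  flipped <- m %*% diag(c(-1, -1, 1))    # 180 degrees about z
  # the flipped bead set equals the original set (rows permuted)
  ord1 <- m[order(m[, 1], m[, 2], m[, 3]), ]
  ord2 <- flipped[order(flipped[, 1], flipped[, 2], flipped[, 3]), ]
  expect_equal(ord1, ord2, tolerance = 1e-9)
})

test_that("generation is deterministic in the seed", {
  a <- generate_shape("bent_rod", list(bend_angle = 140), n_beads = 300, seed = 10)
  b <- generate_shape("bent_rod", list(bend_angle = 140), n_beads = 300, seed = 10)
  expect_identical(a$x, b$x); expect_identical(a$z, b$z)
  c_ <- generate_shape("bent_rod", list(bend_angle = 140), n_beads = 300, seed = 11)
  expect_false(identical(a$x, c_$x))
})

test_that("bead PDB files round trip and reject empty atom sets", {
  m <- generate_shape("sphere", list(radius = 20), n_beads = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bead_pdb(m, f)
  m2 <- read_bead_pdb(f)
  expect_equal(nrow(m2), 10)
  expect_equal(cbind(m2$x, m2$y, m2$z), cbind(m$x, m$y, m$z), tolerance = 1e-3)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f2)
  expect_error(suppressWarnings(read_bead_pdb(f2)))
})

test_that("a 1000-bead dummy-residue file reads back with N = 1000", {
  m <- generate_shape("straight_rod", list(length = 175, diameter = 50),
                      n_beads = 1000, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bead_pdb(m, f)
  expect_equal(nrow(read_bead_pdb(f)), 1000)
})

test_that("Guinier fit of a Debye profile recovers the model Rg", {
  m <- generate_shape("ellipsoid", list(semiaxes = c(50, 30, 25)),
                      n_beads = 3000, seed = 8)
  rg <- radius_of_gyration(m)
  s <- seq(5e-4, 1.0 / (2 * pi * rg), length.out = 30)  # q Rg <= 1.0
  prof <- debye_intensity(m, s, mode = "exact")
  g <- guinier_fit(prof, 0, max(s)^2)
  expect_equal(g$rg, rg, tolerance = 0.02)
})
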