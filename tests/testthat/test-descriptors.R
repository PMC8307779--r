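test_that("RMSD series matches the direct per-atom formula", {
  set.seed(5)
  top <- ca_topology(20)
  A <- matrix(rnorm(60, sd = 3), 20, 3)
  B <- A + matrix(rnorm(60, sd = 1), 20, 3)
  ens <- ens_from_frames(top, list(A, B))
  r <- rmsd_series(ens)
  expect_equal(r[1], 0, ignore_attr = TRUE)
  expect_equal(r[2], plain_rmsd(B, A), ignore_attr = TRUE)
  # uniform displacement without refit
  C <- A; C[, 1] <- C[, 1] + 2
  expect_equal(rmsd_series(ens_from_frames(top, list(A, C)))[2], 2,
               ignore_attr = TRUE)
})

test_that("RMSD is invariant to a common rigid motion after re-fitting", {
  set.seed(6)
  top <- ca_topology(12)
  A <- matrix(rnorm(36, sd = 3), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.8), 12, 3)
  base <- rmsd_series(superpose(ens_from_frames(top, list(A, B))))[2]
  Rm <- rot_z(0.6)
  moved <- superpose(ens_from_frames(top, list(A %*% Rm + 3, B %*% Rm + 3)))
  expect_equal(rmsd_series(moved)[2], base, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("RMSF recovers closed forms", {
  top <- ca_topology(5)
  X <- matrix(rnorm(15), 5, 3)
  static <- ens_from_frames(top, list(X, X, X))
  expect_true(all(rmsf_per_residue(static) == 0))
  # one atom displaced 2 A between two frames, about the mean -> 1 A
  Y <- X; Y[3, 1] <- Y[3, 1] + 2
  two <- ens_from_frames(top, list(X, Y))
  f <- rmsf_per_residue(two)
  expect_equal(unname(f[3]), 1)
  expect_equal(unname(f[1]), 0)
  expect_warning(rmsf_per_residue(ens_from_frames(top, list(X))),
                 "single-frame")
})

test_that("RMSF of isotropic Gaussian jitter approaches sigma*sqrt(3)", {
  set.seed(8)
  top <- ca_topology(4)
  X <- matrix(rnorm(12, sd = 5), 4, 3)
  sigma <- 0.7
  frames <- lapply(seq_len(10000), function(i)
    X + matrix(rnorm(12, sd = sigma), 4, 3))
  f <- rmsf_per_residue(ens_from_frames(top, frames))
  expect_equal(unname(f), rep(sigma * sqrt(3), 4), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("radius of gyration reproduces closed forms and invariances", {
  t1 <- ca_topology(1)
  expect_equal(radius_of_gyration(
    conformation_ensemble(t1, array(c(5, 1, -2), c(1, 3, 1)))), 0,
    ignore_attr = TRUE)
  t2 <- ca_topology(2)
  two <- ens_from_frames(t2, list(rbind(c(0, 0, 0), c(2, 0, 0))))
  expect_equal(radius_of_gyration(two), 1, ignore_attr = TRUE)
  t4 <- ca_topology(4)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  e4 <- ens_from_frames(t4, list(sq))
  expect_equal(radius_of_gyration(e4), sqrt(0.5), ignore_attr = TRUE)
  # rigid-motion invariance and linear scaling
  moved <- ens_from_frames(t4, list(sq %*% rot_z(0.9) + 7))
  expect_equal(radius_of_gyration(moved), sqrt(0.5), ignore_attr = TRUE)
  expect_equal(radius_of_gyration(ens_from_frames(t4, list(sq * 3))),
               3 * sqrt(0.5), ignore_attr = TRUE)
  # mass weighting: unequal masses shift the centre
  tw <- build_topology(c("CA", "O"), c("ALA", "ALA"), 1:2)
  ew <- ens_from_frames(tw, list(rbind(c(0, 0, 0), c(2, 0, 0))))
  m <- tw$mass
  com <- 2 * m[2] / sum(m)
  expected <- sqrt((m[1] * com^2 + m[2] * (2 - com)^2) / sum(m))
  expect_equal(radius_of_gyration(ew, select_atoms(ew, c("CA", "O")),
                                  mass_weighted = TRUE),
               expected, ignore_attr = TRUE)
})

test_that("SASA matches sphere closed forms", {
  t1 <- ca_topology(1)
  e1 <- conformation_ensemble(t1, array(0, c(1, 3, 1)))
  iso <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(sasa(e1), iso, tolerance = 0.01, ignore_attr = TRUE)
  t2 <- ca_topology(2)
  far <- ens_from_frames(t2, list(rbind(c(0, 0, 0), c(20, 0, 0))))
  expect_equal(sasa(far), 2 * iso, tolerance = 1e-12, ignore_attr = TRUE)
  # two equal overlapping spheres: spherical-cap closed form
  R <- 1.7 + 1.4
  for (d in c(1.5, 2.5, 4)) {
    ov <- ens_from_frames(t2, list(rbind(c(0, 0, 0), c(d, 0, 0))))
    exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
    expect_equal(sasa(ov), exact, tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("SASA decreases monotonically as two atoms approach", {
  t2 <- ca_topology(2)
  seps <- seq(6, 1, by = -0.5)
  vals <- vapply(seps, function(d)
    as.numeric(sasa(ens_from_frames(t2, list(rbind(c(0, 0, 0), c(d, 0, 0)))))),
    numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
})

test_that("compactness classes follow the printed bins", {
  expect_equal(classify_compactness(11.4), "compact")
  expect_equal(classify_compactness(11.83), "semi-compact")
  expect_equal(classify_compactness(12.5), "loose")
  expect_equal(classify_compactness(13.5), "out-of-range")
  expect_equal(classify_compactness(10.0), "out-of-range")
  # gap values go to the nearest bin by midpoint
  expect_equal(classify_compactness(c(11.62, 11.68)),
               c("compact", "semi-compact"))
})

test_that("distance geometry yields all pairwise C-alpha distances", {
  t3 <- ca_topology(3, resno = c(703, 721, 730))
  tri <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))
  dg <- distance_geometry(ens_from_frames(t3, list(tri)), c(703, 721, 730))
  expect_equal(dim(dg), c(1, 3))
  expect_equal(colnames(dg), c("703-721", "703-730", "721-730"))
  expect_equal(as.numeric(dg), c(3, 4, 5))
  t4 <- ca_topology(4, resno = c(703, 721, 730, 747))
  set.seed(2)
  e4 <- ens_from_frames(t4, lapply(1:5, function(i) matrix(rnorm(12), 4, 3)))
  expect_equal(ncol(distance_geometry(e4, c(703, 721, 730, 747))), 6)
  expect_error(distance_geometry(e4, c(703, 999)), "999")
})

test_that("a restrained terminal pair shows a constant distance series", {
  top <- ca_topology(2, resno = c(689, 768))
  frames <- lapply(1:20, function(i) {
    a <- matrix(rnorm(3), 1, 3)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rbind(a, a + 10 * u)
  })
  dg <- distance_geometry(ens_from_frames(top, frames), c(689, 768))
  expect_equal(as.numeric(dg), rep(10, 20), tolerance = 1e-10)
})

test_that("probability distributions are normalised and find their modes", {
  h <- probability_distribution(rep(4, 100), 0.5)
  expect_equal(sum(h$prob), 1, tolerance = 1e-9)
  expect_equal(max(h$prob), 1)
  h2 <- probability_distribution(c(rep(4, 50), rep(7, 50)), 0.5)
  expect_equal(sum(h2$prob), 1, tolerance = 1e-9)
  pk <- histogram_peaks(h2)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$prob), c(0.5, 0.5))
  expect_error(probability_distribution(1:5, 0), "positive")
  # Gaussian mixture: peak locations within one bin width of the means
  set.seed(9)
  x <- c(rnorm(6000, 4, 0.3), rnorm(4000, 7, 0.3))
  pk3 <- histogram_peaks(probability_distribution(x, 0.25))
  top2 <- sort(pk3$location[1:2])
  expect_lt(abs(top2[1] - 4), 0.25)
  expect_lt(abs(top2[2] - 7), 0.25)
})
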