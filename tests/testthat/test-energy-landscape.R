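test_that("kNN density matches uniform and Gaussian closed forms", {
  set.seed(2)
  pts <- cbind(runif(10000), runif(10000))
  expect_equal(mean(knn_density(pts, 100)), 1.0, tolerance = 0.05)
  # symmetry: k+1 points on a circle all see the same k-th neighbour
  ang <- 2 * pi * (0:5) / 6
  circ <- cbind(cos(ang), sin(ang))
  d <- knn_density(circ, 5)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  g <- gaussian_mixture_samples(rbind(c(0, 0)), 1, 1, 20000, seed = 3)
  d0 <- knn_density(g$points, ceiling(sqrt(20000)),
                    query = matrix(0, 1, 2))
  expect_equal(as.numeric(d0), 1 / (2 * pi), tolerance = 0.10)
  expect_error(knn_density(circ, 6), "k must be")
})

test_that("duplicate points are capped and flagged", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 2))
  d <- knn_density(pts, 1)
  expect_true(all(is.finite(d)))
  expect_equal(attr(d, "capped"), c(1, 2))
})

test_that("free-energy values follow the Boltzmann inversion closed forms", {
  set.seed(5)
  g <- gaussian_mixture_samples(rbind(c(0, 0)), 1, 1, 20000, seed = 7)
  fel <- free_energy_landscape(list(R1 = g$points[, 1], R2 = g$points[, 2]))
  dg <- fel$deltaG
  expect_equal(min(dg, na.rm = TRUE), 0)
  expect_equal(sum(dg == 0, na.rm = TRUE), 1)
  expect_true(all(dg[!is.na(dg)] >= 0))
  # a node at half the maximal density sits kB*T*ln 2 above the minimum
  expect_equal(KB_KCAL * 310 * log(2), 0.4270, tolerance = 1e-3)
  # radial profile: dG at 2 sigma minus dG at mode ~ 2 kB T
  r <- sqrt(outer(fel$zx^2, rep(1, length(fel$zy)), "*") +
            outer(rep(1, length(fel$zx)), fel$zy^2, "*"))
  band <- abs(r - 2) < 0.05 & !is.na(dg)
  mode_cell <- which(r == min(r), arr.ind = TRUE)[1, ]
  d2 <- mean(dg[band]) - dg[mode_cell[1], mode_cell[2]]
  expect_equal(d2, 2 * KB_KCAL * 310, tolerance = 0.1 / 1.232)
  expect_error(free_energy_landscape(list(a = 1:10, b = 1:10), k = 10),
               "k must be")
})

test_that("free-energy differences are invariant under affine rescaling", {
  set.seed(61)
  m <- gaussian_mixture_samples(rbind(c(0, 0), c(4, 0)), 1, c(0.7, 0.3),
                                5000, seed = 13)
  f1 <- free_energy_landscape(list(a = m$points[, 1], b = m$points[, 2]))
  f2 <- free_energy_landscape(list(a = 100 * m$points[, 1] - 7,
                                   b = 0.01 * m$points[, 2] + 3))
  expect_equal(f1$deltaG, f2$deltaG, tolerance = 1e-9)
})

test_that("wells are detected with mixture-weight energetics", {
  m <- gaussian_mixture_samples(rbind(c(0, 0), c(4, 0)), 1, c(0.7, 0.3),
                                20000, seed = 11)
  fel <- free_energy_landscape(list(R1 = m$points[, 1], R2 = m$points[, 2]))
  w <- find_wells(fel)
  expect_equal(nrow(w$wells), 2)
  expect_equal(w$wells$deltaG[1], 0)
  expect_equal(w$wells$deltaG[2], KB_KCAL * 310 * log(7 / 3),
               tolerance = 0.15 / 0.522)
  # single Gaussian -> one well; flat uniform -> one well after merging
  g <- gaussian_mixture_samples(rbind(c(0, 0)), 1, 1, 10000, seed = 17)
  w1 <- find_wells(free_energy_landscape(list(a = g$points[, 1],
                                              b = g$points[, 2])))
  expect_equal(nrow(w1$wells), 1)
  set.seed(19)
  u <- cbind(runif(10000), runif(10000))
  wu <- find_wells(free_energy_landscape(list(a = u[, 1], b = u[, 2])))
  expect_equal(nrow(wu$wells), 1)
})

test_that("basin membership recovers mixture weights and the representative", {
  # cleanly separated basins so the watershed boundary carries no mass
  m <- gaussian_mixture_samples(rbind(c(0, 0), c(8, 0)), 1, c(0.7, 0.3),
                                20000, seed = 11)
  fel <- free_energy_landscape(list(R1 = m$points[, 1], R2 = m$points[, 2]))
  w <- find_wells(fel)
  mem <- deepest_well_members(w)
  expect_equal(mem$fraction, 0.7, tolerance = 0.03 / 0.7)
  # members dominated by component 1
  expect_gt(mean(m$component[mem$frames] == 1), 0.95)
  # representative lies within one grid cell of the minimum
  zrep <- fel$points_z[mem$representative, ]
  wmin <- w$wells[1, ]
  zmin <- c((wmin$R1 - fel$center[1]) / fel$scale[1],
            (wmin$R2 - fel$center[2]) / fel$scale[2])
  cell <- c(fel$zx[2] - fel$zx[1], fel$zy[2] - fel$zy[1])
  expect_lt(abs(zrep[1] - zmin[1]), 2 * cell[1])
  expect_lt(abs(zrep[2] - zmin[2]), 2 * cell[2])
  # a one-basin landscape puts every frame in the global well
  g <- gaussian_mixture_samples(rbind(c(0, 0)), 1, 1, 5000, seed = 23)
  f1 <- free_energy_landscape(list(a = g$points[, 1], b = g$points[, 2]))
  m1 <- deepest_well_members(find_wells(f1))
  expect_gt(m1$fraction, 0.99)
})

test_that("kNN landscape agrees with a histogram-oracle estimate", {
  m <- gaussian_mixture_samples(rbind(c(0, 0), c(4, 0)), 1, c(0.7, 0.3),
                                50000, seed = 29)
  fel <- free_energy_landscape(list(a = m$points[, 1], b = m$points[, 2]),
                               grid_size = c(60, 60))
  z <- fel$points_z
  bx <- c(fel$zx - (fel$zx[2] - fel$zx[1]) / 2,
          fel$zx[60] + (fel$zx[2] - fel$zx[1]) / 2)
  by <- c(fel$zy - (fel$zy[2] - fel$zy[1]) / 2,
          fel$zy[60] + (fel$zy[2] - fel$zy[1]) / 2)
  counts <- table(factor(findInterval(z[, 1], bx, all.inside = TRUE),
                         levels = 1:60),
                  factor(findInterval(z[, 2], by, all.inside = TRUE),
                         levels = 1:60))
  counts <- matrix(as.numeric(counts), 60, 60)
  dens <- counts / sum(counts)
  dg_hist <- -KB_KCAL * 310 * log(dens / max(dens))
  well_sampled <- counts >= 100 & !is.na(fel$deltaG)
  expect_gt(sum(well_sampled), 100)
  expect_lte(max(abs(fel$deltaG[well_sampled] - dg_hist[well_sampled])),
             0.2)
})
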