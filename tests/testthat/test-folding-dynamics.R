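test_that("transition counts follow the direct enumeration", {
  # residue track H,H,H,C,C,H without smoothing
  m <- matrix(c("H", "H", "H", "C", "C", "H"), 6, 1)
  tm <- transition_matrices(ss_track(m), alpha = 0)
  P <- tm$P[[1]]
  expect_equal(P["H", "H"], 2 / 3)
  expect_equal(P["H", "C"], 1 / 3)
  expect_equal(P["C", "C"], 1 / 2)
  expect_equal(P["C", "H"], 1 / 2)
  expect_equal(unname(tm$occupancy[1, "H"]), 3)
  expect_equal(unname(tm$occupancy[1, "C"]), 2)
  # constant track: identity row for the occupied state
  tc <- transition_matrices(ss_track(matrix("T", 10, 1)), alpha = 0)
  expect_equal(tc$P[[1]]["T", "T"], 1)
  expect_error(transition_matrices(ss_track(matrix("H", 1, 1))), "at least")
  # rows always stochastic with smoothing
  fix <- kid_replica_tracks(30, seed = 3)
  ts <- transition_matrices(fix$tracks[[1]])
  for (P in ts$P) expect_equal(rowSums(P), rep(1, 8), ignore_attr = TRUE,
                               tolerance = 1e-9)
})

test_that("transition probabilities are recovered from a long simulated chain", {
  P <- ss_mixing_matrix(c(H = 0.25, G = 0.1, I = 0.05, E = 0.1, B = 0.05,
                          T = 0.15, S = 0.1, C = 0.2), rho = 0.8)
  trk <- simulate_ss_chain(P, 50000, seed = 5)
  tm <- transition_matrices(trk, alpha = 0.5)
  rows <- tm$occupancy[1, ] > 1000
  expect_true(any(rows))
  expect_lt(max(abs(tm$P[[1]][rows, ] - P[rows, ])), 0.02)
})

test_that("Fisher-Rao distance reproduces categorical closed forms", {
  P1 <- matrix(0, 8, 8); P1[, 1] <- 1
  P2 <- matrix(0, 8, 8); P2[, 2] <- 1
  P3 <- matrix(0, 8, 8); P3[, 1] <- 0.5; P3[, 2] <- 0.5
  occ <- matrix(c(1, rep(0, 7)), 1, 8)   # only the first row is occupied
  a <- tmat_set(list(P1), occ)
  b <- tmat_set(list(P2), occ)
  c3 <- tmat_set(list(P3), occ)
  expect_equal(fisher_rao_distance(a, a), 0)
  expect_equal(fisher_rao_distance(a, b), pi)
  expect_equal(fisher_rao_distance(a, c3), pi / 2)
  expect_equal(fisher_rao_distance(a, b), fisher_rao_distance(b, a))
  expect_error(fisher_rao_distance(a, tmat_set(list(P1, P1))), "mismatch")
})

test_that("Fisher-Rao distances are bounded by pi and satisfy the triangle inequality", {
  set.seed(67)
  rand_set <- function() {
    P <- matrix(rexp(64), 8, 8); P <- P / rowSums(P)
    tmat_set(list(P), matrix(rpois(8, 50) + 1, 1, 8))
  }
  for (i in 1:20) {
    x <- rand_set(); y <- rand_set(); z <- rand_set()
    dxy <- fisher_rao_distance(x, y)
    dyz <- fisher_rao_distance(y, z)
    dxz <- fisher_rao_distance(x, z)
    expect_lte(dxy, pi)
    expect_lte(dxz, dxy + dyz + 1e-12)
  }
})

test_that("replica distances grow with chain perturbation and embed correctly", {
  base <- ss_mixing_matrix(c(H = 0.5, T = 0.1, S = 0.1, C = 0.3), rho = 0.9)
  perturb <- function(eps)
    ss_mixing_matrix(c(H = 0.5 - eps, T = 0.1, S = 0.1, C = 0.3 + eps),
                     rho = 0.9)
  sets <- lapply(c(0, 0.1, 0.25, 0.4), function(eps) {
    trk <- simulate_ss_chain(rep(list(perturb(eps)), 10), 4000,
                             seed = 71 + round(100 * eps),
                             label = paste0("eps", eps))
    transition_matrices(trk)
  })
  D <- replica_distance_matrix(sets)
  expect_equal(dim(D), c(4, 4))
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
  expect_identical(D, t(D))
  expect_true(all(diff(D[1, -1]) > 0))   # monotone in the perturbation
  dup <- replica_distance_matrix(list(sets[[1]], sets[[1]]))
  expect_equal(dup[1, 2], 0)
})

test_that("classical MDS reproduces Euclidean configurations", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- D[2, 1] <- 3; D[1, 3] <- D[3, 1] <- 4; D[2, 3] <- D[3, 2] <- 5
  emb <- classical_mds(D)
  expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(emb$stress, 1e-10)
  # all-zero distances -> coincident points
  z <- classical_mds(matrix(0, 4, 4))
  expect_lt(max(dist(z$points)), 1e-10)
  # random planar point sets embed with negligible stress
  set.seed(73)
  for (i in 1:3) {
    pts <- matrix(rnorm(20), 10, 2)
    e <- classical_mds(as.matrix(dist(pts)))
    expect_lt(e$stress, 1e-10)
    # Procrustes: distances themselves are reproduced
    expect_equal(as.matrix(dist(e$points)), as.matrix(dist(pts)),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(classical_mds(asym), "symmetric")
  expect_true(all(diff(emb$eig) <= 1e-12))
})

test_that("replicas simulated from shared chains group together", {
  fix <- kid_replica_tracks(300, seed = 5)
  sets <- lapply(fix$tracks, transition_matrices)
  D <- replica_distance_matrix(sets)
  g <- fix$groups
  same <- outer(g, g, `==`) & upper.tri(D)
  diff_ <- outer(g, g, `!=`) & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff_]))
  emb <- classical_mds(D)
  expect_gt(embedding_silhouette(emb, g), 0)
})
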