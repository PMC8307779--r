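test_that("contact map reproduces the all-pairs distance oracle", {
  set.seed(19)
  nres <- 15; nf <- 100
  top <- ca_topology(nres)
  frames <- lapply(seq_len(nf), function(i) matrix(rnorm(nres * 3, sd = 5),
                                                   nres, 3))
  ens <- ens_from_frames(top, frames)
  cm <- contact_map(ens, cutoff = 10, exclude_neighbours = 2)
  oracle <- matrix(0, nres, nres)
  for (f in seq_len(nf))
    for (i in 1:nres)
      for (j in 1:nres)
        if (sqrt(sum((frames[[f]][i, ] - frames[[f]][j, ])^2)) < 10)
          oracle[i, j] <- oracle[i, j] + 1
  oracle <- oracle / nf
  comparable <- abs(row(oracle) - col(oracle)) > 2
  expect_equal(unclass(cm)[comparable], oracle[comparable])
  expect_true(all(is.na(unclass(cm)[!comparable])))
  expect_identical(unclass(cm), t(unclass(cm)))
})

test_that("contact frequencies follow the strict distance threshold", {
  top <- ca_topology(6)
  place_pair <- function(d) {
    m <- matrix(seq(0, 100, length.out = 6), 6, 3)  # spread out others
    m[1, ] <- c(0, 0, 0); m[6, ] <- c(d, 0, 0)
    m
  }
  ens8 <- ens_from_frames(top, replicate(10, place_pair(8), simplify = FALSE))
  expect_equal(unclass(contact_map(ens8))["1", "6"], 1)
  ens101 <- ens_from_frames(top, replicate(10, place_pair(10.1),
                                           simplify = FALSE))
  expect_equal(unclass(contact_map(ens101))["1", "6"], 0)
  half <- ens_from_frames(top, c(replicate(5, place_pair(8), simplify = FALSE),
                                 replicate(5, place_pair(12), simplify = FALSE)))
  expect_equal(unclass(contact_map(half))["1", "6"], 0.5)
})

test_that("contact frequency is monotone in the cutoff", {
  set.seed(23)
  top <- ca_topology(10)
  ens <- ens_from_frames(top, lapply(1:40, function(i)
    matrix(rnorm(30, sd = 4), 10, 3)))
  cuts <- c(6, 8, 10, 12)
  maps <- lapply(cuts, function(cc) unclass(contact_map(ens, cutoff = cc)))
  for (k in seq_along(cuts)[-1]) {
    d <- maps[[k]] - maps[[k - 1]]
    expect_true(all(d[!is.na(d)] >= 0))
  }
})

hb_fixture <- function(A) {
  top <- build_topology(c("N", "H", "O"), c("ALA", "ALA", "ALA"), c(1, 1, 10))
  ens_from_frames(top, list(rbind(c(0, 0, 0), c(1.01, 0, 0), A)))
}

test_that("hydrogen bonds obey the distance and angle criteria", {
  # N...O at 3.5 A, D-H...A angle 150 degrees -> detected, occurrence 1
  t <- 2.589
  good <- hb_fixture(c(1.01 + 0.866 * t, 0.5 * t, 0))
  rec <- hydrogen_bonds(good)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$occurrence, 1)
  expect_equal(rec$donor_resno, 1)
  expect_equal(rec$acceptor_resno, 10)
  # distance fail at 3.7 A
  expect_equal(nrow(hydrogen_bonds(hb_fixture(c(3.7, 0, 0)))), 0)
  # angle fail: ~100 degrees at the hydrogen, distance ~3 A
  t2 <- 2.6
  bad <- hb_fixture(c(1.01 + t2 * cos(80 * pi / 180),
                      t2 * sin(80 * pi / 180), 0))
  expect_equal(nrow(hydrogen_bonds(bad)), 0)
})

test_that("hydrogen-bond occurrence is monotone in the distance cutoff", {
  t <- 2.589
  ens <- hb_fixture(c(1.01 + 0.866 * t, 0.5 * t, 0))
  n_at <- vapply(c(3.0, 3.5, 4.0), function(dc)
    nrow(hydrogen_bonds(ens, dist_cutoff = dc)), integer(1))
  expect_true(all(diff(n_at) >= 0))
})

test_that("reconstructed amide hydrogens are used and flagged", {
  trk <- ss_track(matrix("H", 1, 20))
  helix <- build_peptide_ensemble(strrep("A", 20), trk, seed = 1)
  keep <- helix$topology$elety != "H"
  top2 <- build_topology(helix$topology$elety[keep],
                         helix$topology$resid[keep],
                         helix$topology$resno[keep])
  noH <- conformation_ensemble(top2,
                               helix$coords[keep, , , drop = FALSE])
  rec <- hydrogen_bonds(noH, exclude_intrahelix = FALSE)
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$geometry_inferred))
  # helix-internal backbone bonds are i,i+4
  expect_true(any(rec$donor_resno - rec$acceptor_resno == 4))
})

test_that("hydrophobic contacts respect the residue set and cutoff", {
  mk <- function(d, res2 = "LEU") {
    top <- build_topology(c("CA", "CB", "CA", "CB"),
                          c("LEU", "LEU", res2, res2), c(1, 1, 10, 10))
    ens_from_frames(top, list(rbind(c(0, 0, 0), c(1.5, 0, 0),
                                    c(1.5 + d + 1.5, 0, 0),
                                    c(1.5 + d, 0, 0))))
  }
  rec <- hydrophobic_contacts(mk(3.8))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$occurrence, 1)
  expect_equal(nrow(hydrophobic_contacts(mk(4.2))), 0)
  expect_equal(nrow(hydrophobic_contacts(mk(3.0, "SER"))), 0)
  expect_error(hydrophobic_contacts(mk(3), hydrophobic_set = c("LEU", "GLY")),
               "glycine")
})

test_that("segment filtering keeps high-occurrence anchored contacts", {
  rec <- data.frame(kind = "hbond",
                    donor_resno = c(700, 700, 670),
                    donor_atom = "N",
                    acceptor_resno = c(750, 750, 680),
                    acceptor_atom = "O",
                    occurrence = c(0.85, 0.79, 0.95),
                    geometry_inferred = FALSE)
  segs <- list(c(699, 709), c(754, 764), c(731, 733))
  out <- segment_contacts(rec, segs)
  expect_equal(nrow(out), 1)
  expect_equal(out$occurrence, 0.85)
  expect_error(segment_contacts(rec, list()), "empty")
  # works on a contact map too
  top <- ca_topology(3, resno = c(700, 731, 760))
  ens <- ens_from_frames(top, replicate(4, rbind(c(0, 0, 0), c(5, 0, 0),
                                                 c(50, 0, 0)),
                                        simplify = FALSE))
  cm <- contact_map(ens, exclude_neighbours = 0)
  out2 <- segment_contacts(cm, segs, min_occurrence = 0.8)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$donor_resno, 700)
  expect_equal(out2$acceptor_resno, 731)
})
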