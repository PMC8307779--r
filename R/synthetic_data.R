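# Stationary distribution of a row-stochastic matrix (power iteration).
stationary_dist <- function(P, iter = 500) {
  p <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iter)) p <- as.vector(p %*% P)
  p / sum(p)
}

#' Mixing-kernel transition matrix with a prescribed stationary law
#'
#' `P = rho * I + (1 - rho) * 1 pi'`: with probability `rho` the state
#' persists, otherwise it is redrawn from `pi`. The stationary distribution
#' is exactly `pi`, which makes generator-recovery ground truth trivial to
#' state.
#'
#' @param pi stationary probabilities over the 8 states (named or in state
#'   order `H,G,I,E,B,T,S,C`).
#' @param rho persistence probability in \[0, 1) (default 0.9).
#' @return 8 x 8 row-stochastic matrix.
#' @export
ss_mixing_matrix <- function(pi, rho = 0.9) {
  ns <- length(SS_STATES)
  p <- rep(0, ns); names(p) <- SS_STATES
  if (is.null(names(pi))) p[] <- pi else p[names(pi)] <- pi
  if (abs(sum(p) - 1) > 1e-8) stop("pi must sum to 1")
  P <- rho * diag(ns) + (1 - rho) * matrix(p, ns, ns, byrow = TRUE)
  dimnames(P) <- list(SS_STATES, SS_STATES)
  P
}

#' Simulate per-residue secondary-structure Markov chains
#'
#' Each residue evolves independently under its own 8-state transition
#' matrix; the simulation is a pure function of its arguments and seed.
#'
#' @param P a single 8 x 8 row-stochastic matrix (shared by all residues)
#'   or a list of one matrix per residue; state order `H,G,I,E,B,T,S,C`.
#' @param n_frames number of frames to simulate (>= 1).
#' @param seed RNG seed.
#' @param init initial condition: a state letter, a vector of letters (one
#'   per residue), or `NULL` (default) to draw frame 1 from each residue's
#'   stationary distribution.
#' @param resno residue numbers.
#' @param label replica identifier.
#' @return an [ss_track()] of `n_frames x n_residues` states.
#' @export
simulate_ss_chain <- function(P, n_frames, seed = 1L, init = NULL,
                              resno = NULL, label = "synthetic") {
  ns <- length(SS_STATES)
  if (is.matrix(P)) P <- list(P)
  for (m in P) {
    if (!all(dim(m) == c(ns, ns)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-8))
      stop("transition matrices must be 8 x 8 and row-stochastic")
  }
  nres <- length(P)
  resno <- resno %||% seq_len(nres)
  set.seed(seed)
  # cumulative rows stacked as ((residue-1)*8 + state) x 8 for fast lookup
  bigcum <- do.call(rbind, lapply(P, function(m) t(apply(m, 1, cumsum))))
  states <- matrix(NA_integer_, n_frames, nres)
  states[1, ] <- if (is.null(init)) {
    vapply(P, function(m)
      sample.int(ns, 1, prob = stationary_dist(m)), integer(1))
  } else {
    s <- match(rep_len(init, nres), SS_STATES)
    if (anyNA(s)) stop("invalid initial state")
    s
  }
  if (n_frames > 1) {
    base <- (seq_len(nres) - 1L) * ns
    for (f in 2:n_frames) {
      u <- runif(nres)
      rows <- bigcum[base + states[f - 1L, ], , drop = FALSE]
      states[f, ] <- 1L + rowSums(rows < u)
    }
  }
  ss_track(matrix(SS_STATES[states], n_frames, nres),
           resno = resno, label = label)
}

#' Sample a two-dimensional Gaussian mixture
#'
#' Fixture generator for landscape validation: component labels are kept
#' as ground truth.
#'
#' @param means 2-column matrix (or list of length-2 vectors) of component
#'   means.
#' @param sigmas per-component isotropic s.d. (recycled).
#' @param weights component weights, summing to 1.
#' @param n sample size.
#' @param seed RNG seed.
#' @return list with `points` (`n x 2`), `component` (integer labels).
#' @export
gaussian_mixture_samples <- function(means, sigmas, weights, n, seed = 1L) {
  if (is.list(means)) means <- do.call(rbind, means)
  means <- matrix(means, ncol = 2)
  nc <- nrow(means)
  sigmas <- rep_len(sigmas, nc)
  if (length(weights) != nc || abs(sum(weights) - 1) > 1e-8)
    stop("weights must match components and sum to 1")
  set.seed(seed)
  comp <- sample.int(nc, n, replace = TRUE, prob = weights)
  pts <- means[comp, , drop = FALSE] +
    matrix(rnorm(2 * n), n, 2) * sigmas[comp]
  list(points = pts, component = comp)
}

#' Multi-basin coordinate ensemble
#'
#' Each frame is one of the template conformations, chosen with the given
#' weights, plus isotropic Gaussian coordinate jitter: a minimal emulation
#' of an ensemble hopping between a few structurally distinct basins (the
#' bimodal RMSD structure typical of disordered-domain trajectories).
#' Basin labels are kept as ground truth in the `basin` element.
#'
#' @param topology topology shared by the templates.
#' @param templates list of `n_atoms x 3` template coordinate matrices.
#' @param weights per-template probabilities (sum 1).
#' @param sigma jitter s.d. per coordinate in Angstrom.
#' @param n_frames_total frames to generate.
#' @param seed RNG seed.
#' @param label replica identifier.
#' @return a [conformation_ensemble()] with extra element `basin`
#'   (per-frame template index).
#' @export
multi_basin_ensemble <- function(topology, templates, weights, sigma,
                                 n_frames_total, seed = 1L,
                                 label = "multibasin") {
  nb <- length(templates)
  if (length(weights) != nb || abs(sum(weights) - 1) > 1e-8)
    stop("weights must match templates and sum to 1")
  na <- nrow(templates[[1]])
  for (tp in templates)
    if (!all(dim(tp) == c(na, 3))) stop("templates differ in topology")
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  basin <- sample.int(nb, n_frames_total, replace = TRUE, prob = weights)
  coords <- array(NA_real_, c(na, 3, n_frames_total))
  for (f in seq_len(n_frames_total))
    coords[, , f] <- templates[[basin[f]]] +
      if (sigma > 0) matrix(rnorm(3 * na, sd = sigma), na, 3) else 0
  ens <- conformation_ensemble(topology, coords, label = label)
  ens$basin <- basin
  ens
}

# ---- KID-like default fixture ---------------------------------------------

#' Sequence and numbering of the 80-residue KID-like fixture
#'
#' Poly-alanine numbered 689-768 with the landmark substitutions F689,
#' Y703, Y721, Y730, Y747 and D768 (the kinase-insert-domain terminals and
#' tyrosines).
#'
#' @return list with `sequence` (1-letter string) and `resno`.
#' @export
kid_sequence <- function() {
  aa <- rep("A", 80)
  aa[1] <- "F"; aa[80] <- "D"
  aa[c(703, 721, 730, 747) - 688] <- "Y"
  list(sequence = paste(aa, collapse = ""), resno = 689:768)
}

# Helix definitions per replica group: spans (resno) and stationary helix
# probability. Targets the reported helical-content ranges: ~44-56% for
# the cleaved unconstrained group (C), 25-30% for the domain group (D),
# 30-35% for the end-restrained group (CR).
kid_group_profile <- function(group) {
  switch(group,
    C = list(spans = list(c(697, 711), c(713, 718), c(721, 727),
                          c(736, 742), c(752, 759), c(762, 766)),
             p = c(0.95, 0.80, 0.75, 0.70, 0.80, 0.65),
             alpha_only = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
             baseline = 0.02),
    D = list(spans = list(c(699, 710), c(713, 717), c(722, 726),
                          c(753, 757)),
             p = c(0.90, 0.55, 0.50, 0.55),
             alpha_only = c(TRUE, FALSE, FALSE, FALSE),
             baseline = 0.03),
    CR = list(spans = list(c(697, 712), c(713, 718), c(721, 726),
                           c(752, 758), c(763, 766)),
              p = c(0.93, 0.55, 0.50, 0.55, 0.40),
              alpha_only = c(TRUE, FALSE, FALSE, FALSE, FALSE),
              baseline = 0.03),
    stop("unknown group: ", group))
}

#' Per-residue transition matrices of a KID-like replica group
#'
#' Builds one 8 x 8 mixing-kernel matrix per residue whose stationary
#' helical probability follows the group's helix profile: a long-lived
#' all-alpha H1 region, shorter transient helices splitting their helical
#' mass between alpha (H) and 3_10 (G), and a coil/turn/bend background.
#'
#' @param group `"C"`, `"D"` or `"CR"`.
#' @param rho persistence of the mixing kernel (default 0.9).
#' @return list of 80 transition matrices (residues 689-768).
#' @export
kid_chain_matrices <- function(group, rho = 0.9) {
  prof <- kid_group_profile(group)
  resno <- 689:768
  lapply(resno, function(r) {
    ph <- prof$baseline; a_only <- FALSE
    for (s in seq_along(prof$spans)) {
      if (r >= prof$spans[[s]][1] && r <= prof$spans[[s]][2]) {
        ph <- prof$p[s]; a_only <- prof$alpha_only[s]
      }
    }
    hH <- if (a_only) ph else ph * 0.5
    hG <- if (a_only) 0 else ph * 0.5
    rest <- 1 - ph
    ss_mixing_matrix(c(H = hH, G = hG, I = 0, E = 0, B = 0,
                       T = rest * 0.2, S = rest * 0.1, C = rest * 0.7),
                     rho = rho)
  })
}

#' Synthetic KID-like replica set (4 + 2 + 2)
#'
#' Eight replicas of per-residue secondary-structure tracks mirroring the
#' study design: four replicas of group C, two of group D, two of group
#' CR, each simulated from its group's per-residue Markov chains with a
#' replica-specific seed derived from `seed`.
#'
#' @param n_frames frames per replica (default 400).
#' @param seed base RNG seed.
#' @param rho chain persistence (default 0.9).
#' @return list with `tracks` (8 [ss_track()]s), `groups` (character),
#'   `labels`, and `matrices` (per-group ground-truth chains).
#' @export
kid_replica_tracks <- function(n_frames = 400L, seed = 1L, rho = 0.9) {
  groups <- c("C", "C", "C", "C", "D", "D", "CR", "CR")
  labels <- c(paste0("C", 1:4), paste0("D", 1:2), paste0("CR", 1:2))
  mats <- list(C = kid_chain_matrices("C", rho),
               D = kid_chain_matrices("D", rho),
               CR = kid_chain_matrices("CR", rho))
  tracks <- lapply(seq_along(groups), function(i)
    simulate_ss_chain(mats[[groups[i]]], n_frames,
                      seed = seed * 100L + i,
                      resno = 689:768, label = labels[i]))
  list(tracks = tracks, groups = groups, labels = labels, matrices = mats)
}
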