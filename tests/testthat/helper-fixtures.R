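# Shared fixtures and independent oracles used across the test files.

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

ca_topology <- function(n, resid = "ALA", resno = seq_len(n)) {
  build_topology(rep("CA", n), rep(resid, n), resno)
}

# Ensemble from a list of n_atoms x 3 coordinate matrices.
ens_from_frames <- function(top, frames, label = "test") {
  coords <- array(unlist(frames), c(nrow(top), 3, length(frames)))
  conformation_ensemble(top, coords, label = label)
}

# Independent superposition oracle: quaternion (Horn) method for the
# optimal proper-rotation RMSD between two centred point sets.
quaternion_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(Pc^2) + sum(Qc^2) - 2 * lambda) / nrow(P), 0))
}

# Plain per-atom RMSD between two coordinate matrices (no fitting).
plain_rmsd <- function(A, B) {
  s <- 0
  for (i in seq_len(nrow(A))) s <- s + sum((A[i, ] - B[i, ])^2)
  sqrt(s / nrow(A))
}

# Independent replay of the reference-harvesting clustering protocol:
# uniform index draw from the remaining frames (increasing frame order),
# removal of everything within r, then nearest-reference assignment.
oracle_cluster <- function(frames, r, seed) {
  nf <- length(frames)
  set.seed(seed)
  remaining <- seq_len(nf)
  refs <- integer()
  while (length(remaining) > 0) {
    pick <- remaining[sample.int(length(remaining), 1L)]
    refs <- c(refs, pick)
    keep <- integer()
    for (f in remaining)
      if (plain_rmsd(frames[[f]], frames[[pick]]) >= r)
        keep <- c(keep, f)
    remaining <- keep
  }
  cl <- integer(nf)
  for (f in seq_len(nf)) {
    d <- vapply(refs, function(rf)
      plain_rmsd(frames[[f]], frames[[rf]]), numeric(1))
    cl[f] <- which.min(d)
  }
  list(references = refs, cluster = cl)
}

# Backbone hydrogen-bond energy oracle (independent of assign_dssp
# internals): donor residue i, acceptor residue j, explicit atom input.
ks_energy <- function(N, H, C, O) {
  0.084 * 332 * (1 / sqrt(sum((N - O)^2)) + 1 / sqrt(sum((H - C)^2)) -
                 1 / sqrt(sum((H - O)^2)) - 1 / sqrt(sum((N - C)^2)))
}

# Pull one backbone atom of one residue out of an ensemble frame.
bb_atom <- function(ens, resno, elety, frame = 1) {
  i <- which(ens$topology$resno == resno & ens$topology$elety == elety)
  ens$coords[i, , frame]
}
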