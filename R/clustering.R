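# C-alpha RMSD of every frame in `frames` to frame `ref` (no re-fitting;
# the ensemble is assumed superposed).
frames_rmsd_to <- function(coords, idx, frames, ref) {
  refm <- coords[idx, , ref]
  vapply(frames, function(f)
    sqrt(mean(rowSums((coords[idx, , f] - refm)^2))), numeric(1))
}

#' Ensemble-based conformational clustering
#'
#' Reference-harvesting clustering on C-alpha RMSD: (i) a reference frame
#' is drawn uniformly at random from the remaining conformations and every
#' conformation within RMSD `r` of it (including itself) is removed; this
#' repeats until the ensemble is exhausted, yielding references pairwise at
#' least `r` apart; (ii) every frame is assigned to the reference of
#' minimal RMSD (ties broken towards the earlier-harvested reference).
#'
#' The random protocol is fixed and reproducible: after `set.seed(seed)`,
#' each draw is `sample.int(m, 1)` on the `m` remaining frames in
#' increasing frame order, so an independent implementation sharing this
#' protocol reproduces the output exactly.
#'
#' @param ensemble a `conf_ensemble`, already superposed on a common
#'   reference.
#' @param r RMSD cutoff in Angstrom (> 0); 3-5 Angstrom is the usual range
#'   for disordered-domain ensembles.
#' @param seed integer seed for the reference draws.
#' @param stride analyse every `stride`-th frame (default 1).
#' @param selection atoms for the RMSD (default: all C-alpha).
#' @return object of class `cluster_assignment`: list with `references`
#'   (frame indices), `cluster` (per analysed frame), `frames` (analysed
#'   frame indices), `rmsd_to_reference`, `populations`, `r`, `seed`.
#' @export
cluster_ensemble <- function(ensemble, r, seed = 1L, stride = 1L,
                             selection = select_atoms(ensemble)) {
  if (r <= 0) stop("r must be positive")
  idx <- sel_indices(selection, ensemble)
  frames <- seq(1L, n_frames(ensemble), by = as.integer(stride))
  set.seed(seed)
  remaining <- frames
  refs <- integer()
  while (length(remaining) > 0) {
    pick <- remaining[sample.int(length(remaining), 1L)]
    refs <- c(refs, pick)
    d <- frames_rmsd_to(ensemble$coords, idx, remaining, pick)
    remaining <- remaining[d >= r]
  }
  dmat <- vapply(refs, function(rf)
    frames_rmsd_to(ensemble$coords, idx, frames, rf),
    numeric(length(frames)))
  dmat <- matrix(dmat, nrow = length(frames))
  cl <- max.col(-dmat, ties.method = "first")
  structure(list(references = refs, cluster = cl, frames = frames,
                 rmsd_to_reference = dmat[cbind(seq_along(frames), cl)],
                 populations = tabulate(cl, length(refs)),
                 r = r, seed = seed, label = ensemble$label),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment '%s': %d clusters over %d frames (r = %g A)\n",
              x$label, length(x$references), length(x$frames), x$r))
  invisible(x)
}

#' Compare two cluster assignments
#'
#' Reports cluster counts, the matrix of C-alpha RMSDs between the two
#' reference sets, and (when both assignments cover the same frames) the
#' pairwise agreement (Rand index, as a percentage).
#'
#' @param a,b `cluster_assignment` objects.
#' @param ensemble_a ensemble underlying `a`.
#' @param ensemble_b ensemble underlying `b` (default: `ensemble_a`).
#' @param selection atoms for the reference RMSDs.
#' @return list with `n_a`, `n_b`, `reference_rmsd` (matrix),
#'   `min_reference_rmsd`, and `agreement_pct` (or `NA`).
#' @export
compare_clusterings <- function(a, b, ensemble_a, ensemble_b = ensemble_a,
                                selection = select_atoms(ensemble_a)) {
  idx <- sel_indices(selection, ensemble_a)
  if (n_atoms(ensemble_a) != n_atoms(ensemble_b))
    stop("topology mismatch between the two ensembles")
  cross <- matrix(NA_real_, length(a$references), length(b$references))
  for (i in seq_along(a$references)) {
    refm <- ensemble_a$coords[idx, , a$references[i]]
    cross[i, ] <- vapply(b$references, function(f)
      sqrt(mean(rowSums((ensemble_b$coords[idx, , f] - refm)^2))),
      numeric(1))
  }
  agreement <- NA_real_
  if (length(a$frames) == length(b$frames) &&
      all(a$frames == b$frames) && length(a$frames) >= 2) {
    n <- length(a$frames)
    same_a <- outer(a$cluster, a$cluster, `==`)
    same_b <- outer(b$cluster, b$cluster, `==`)
    ut <- upper.tri(same_a)
    agreement <- 100 * mean(same_a[ut] == same_b[ut])
  }
  list(n_a = length(a$references), n_b = length(b$references),
       reference_rmsd = cross, min_reference_rmsd = min(cross),
       agreement_pct = agreement)
}
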