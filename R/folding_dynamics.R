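#' Per-residue transition matrices of secondary-structure dynamics
#'
#' For each residue, consecutive-frame transitions between the 8 states
#' (order `H,G,I,E,B,T,S,C`) are counted and each row normalised after
#' adding a smoothing pseudo-count `alpha` to every cell (Jeffreys
#' `alpha = 0.5` by default, so rarely-visited rows remain well-defined
#' distributions). Row occupancies (outgoing transition counts) are kept
#' for occupancy-weighted comparisons. With `alpha = 0`, unoccupied rows
#' are uniform placeholders carrying zero occupancy weight.
#'
#' @param track an [ss_track()] with at least 2 frames.
#' @param alpha pseudo-count added to every transition cell (default 0.5).
#' @param lag transition lag in frames (default 1).
#' @return object of class `tmat_set`: list with `P` (list of 8 x 8
#'   row-stochastic matrices, one per residue), `occupancy` (residues x 8
#'   matrix of row counts), `resno`, `label`, `alpha`, `lag`.
#' @export
transition_matrices <- function(track, alpha = 0.5, lag = 1L) {
  nf <- nrow(track)
  if (nf < lag + 1) stop("track needs at least lag+1 frames for transitions")
  ns <- length(SS_STATES)
  from <- matrix(match(track[seq_len(nf - lag), , drop = FALSE], SS_STATES),
                 nf - lag)
  to <- matrix(match(track[(lag + 1):nf, , drop = FALSE], SS_STATES),
               nf - lag)
  P <- vector("list", ncol(track))
  occ <- matrix(0L, ncol(track), ns, dimnames = list(NULL, SS_STATES))
  for (rsd in seq_len(ncol(track))) {
    counts <- matrix(0, ns, ns, dimnames = list(SS_STATES, SS_STATES))
    tab <- table(factor(from[, rsd], levels = seq_len(ns)),
                 factor(to[, rsd], levels = seq_len(ns)))
    counts[] <- as.numeric(tab)
    occ[rsd, ] <- rowSums(counts)
    sm <- counts + alpha
    rs <- rowSums(sm)
    if (alpha == 0) {
      empty <- rs == 0
      sm[empty, ] <- 1 / ns
      rs[empty] <- 1
    }
    P[[rsd]] <- sm / rs
  }
  structure(list(P = P, occupancy = occ,
                 resno = attr(track, "resno") %||% seq_len(ncol(track)),
                 label = attr(track, "label"), alpha = alpha, lag = lag),
            class = "tmat_set")
}

#' Construct a transition-matrix set directly
#'
#' @param P list of 8 x 8 row-stochastic matrices (state order
#'   `H,G,I,E,B,T,S,C`), one per residue.
#' @param occupancy residues x 8 matrix of row counts (weights); default
#'   1 for every row.
#' @param label replica identifier.
#' @return a `tmat_set`.
#' @export
tmat_set <- function(P, occupancy = NULL, label = "set") {
  ns <- length(SS_STATES)
  for (m in P) {
    if (!all(dim(m) == c(ns, ns))) stop("matrices must be 8 x 8")
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      stop("matrices must be row-stochastic")
  }
  if (is.null(occupancy)) occupancy <- matrix(1, length(P), ns)
  structure(list(P = P, occupancy = occupancy,
                 resno = seq_along(P), label = label,
                 alpha = NA_real_, lag = 1L),
            class = "tmat_set")
}

# Fisher-Rao geodesic between two categorical distributions:
# twice the Bhattacharyya angle.
fr_categorical <- function(p, q) {
  2 * acos(pmin(pmax(sum(sqrt(p * q)), 0), 1))
}

#' Fisher-Rao distance between two transition-matrix sets
#'
#' For each residue and each state row, the categorical Fisher-Rao
#' geodesic `d(p, q) = 2 * acos(sum_s sqrt(p_s q_s))` is computed between
#' the corresponding transition rows; rows are averaged weighted by their
#' combined occupancy (rows never visited in either replica carry no
#' information and are skipped), and residues are averaged uniformly. The
#' result is symmetric, zero for identical sets, and bounded by pi.
#'
#' @param a,b `tmat_set` objects with the same residue count.
#' @return non-negative scalar.
#' @export
fisher_rao_distance <- function(a, b) {
  if (length(a$P) != length(b$P))
    stop("residue-count mismatch between transition-matrix sets")
  per_res <- vapply(seq_along(a$P), function(rsd) {
    w <- a$occupancy[rsd, ] + b$occupancy[rsd, ]
    if (sum(w) == 0) return(0)
    d <- vapply(seq_along(w), function(s)
      fr_categorical(a$P[[rsd]][s, ], b$P[[rsd]][s, ]), numeric(1))
    sum(w * d) / sum(w)
  }, numeric(1))
  mean(per_res)
}

#' Pairwise Fisher-Rao distance matrix across replicas
#'
#' @param sets list of compatible `tmat_set` objects (>= 2).
#' @return symmetric matrix with zero diagonal, dimnames = replica labels,
#'   attribute `groups` if the list names carry them.
#' @export
replica_distance_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least two replicas")
  n <- length(sets)
  labels <- vapply(sets, function(s) s$label %||% "", character(1))
  if (any(labels == "")) labels <- paste0("rep", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- fisher_rao_distance(sets[[i]], sets[[j]])
  D
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Metric MDS by double centering `B = -1/2 * J D^2 J` and
#' eigendecomposition (via [stats::cmdscale()]): deterministic and as
#' isometric as a Euclidean embedding of the given dimension permits.
#' Negative eigenvalues are clipped to zero.
#'
#' @param d square symmetric non-negative distance matrix, zero diagonal.
#' @param dims embedding dimension (default 2).
#' @return object of class `mds_embedding`: list with `points`
#'   (n x dims), `eig` (all eigenvalues, sorted descending), `stress`
#'   (relative distance-reconstruction error,
#'   `sqrt(sum((d - dhat)^2) / sum(d^2))`).
#' @export
classical_mds <- function(d, dims = 2L) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8))
    stop("distance matrix must be square and symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  dims <- min(dims, nrow(d) - 1L)
  # degenerate (e.g. all-zero) matrices embed as coincident points;
  # cmdscale's eigenvalue-count warning is expected there
  fit <- suppressWarnings(cmdscale(d, k = dims, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < dims) {
    pts <- cbind(pts, matrix(0, nrow(d), dims - NCOL(pts)))
  }
  dhat <- as.matrix(dist(pts))
  denom <- sum(d^2)
  stress <- if (denom > 0) sqrt(sum((d - dhat)^2) / denom) else 0
  eig <- sort(pmax(fit$eig, 0), decreasing = TRUE)
  structure(list(points = pts, eig = eig, stress = stress,
                 labels = rownames(d)),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("mds_embedding: %d points in %d dims, stress %.3g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}

#' Silhouette of a grouping on embedded points
#'
#' Mean silhouette width of the given group labels under Euclidean
#' distances between embedding coordinates; positive values mean the
#' groups are separated in the embedding.
#'
#' @param embedding an `mds_embedding` (or a coordinate matrix).
#' @param groups group label per point.
#' @return mean silhouette width in \[-1, 1\].
#' @export
embedding_silhouette <- function(embedding, groups) {
  pts <- if (inherits(embedding, "mds_embedding")) embedding$points
         else as.matrix(embedding)
  groups <- as.character(groups)
  stopifnot(nrow(pts) == length(groups))
  D <- as.matrix(dist(pts))
  s <- vapply(seq_len(nrow(pts)), function(i) {
    own <- which(groups == groups[i])
    others <- setdiff(seq_len(nrow(pts)), own)
    if (length(own) <= 1) return(0)
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(unique(groups[others]), function(g)
      mean(D[i, groups == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
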