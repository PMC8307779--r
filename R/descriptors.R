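#' Per-frame RMSD series against a reference conformation
#'
#' Root-mean-square deviation of the selected atoms of every frame from the
#' same atoms in the reference frame, in Angstrom. No re-fitting is done
#' here: superpose the ensemble first so that rigid-body motion does not
#' contribute (the conventional protocol fits on the C-alpha atoms of the
#' initial conformation).
#'
#' @param ensemble a `conf_ensemble`, already superposed.
#' @param reference_frame 1-based reference frame index (default 1).
#' @param selection atoms entering the deviation (default: all C-alpha).
#' @param reference_coords optional explicit `n_sel x 3` reference matrix
#'   overriding `reference_frame`.
#' @return numeric vector of length `n_frames`, with attributes `name`
#'   ("RMSD") and `units` ("A").
#' @export
rmsd_series <- function(ensemble, reference_frame = 1L,
                        selection = select_atoms(ensemble),
                        reference_coords = NULL) {
  idx <- sel_indices(selection, ensemble)
  ref <- if (is.null(reference_coords))
    ensemble$coords[idx, , reference_frame] else reference_coords
  vals <- apply(ensemble$coords[idx, , , drop = FALSE], 3, function(m)
    sqrt(mean(rowSums((m - ref)^2))))
  structure(vals, name = "RMSD", units = "A", label = ensemble$label)
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom (one per residue for a
#' C-alpha selection), in Angstrom. `about_mean` (the standard definition)
#' measures spread about the time-averaged position; `about_reference`
#' measures it about a fixed reference frame.
#'
#' @param ensemble a `conf_ensemble`, already superposed.
#' @param selection one atom per residue (default: all C-alpha).
#' @param mode `"about_mean"` (default) or `"about_reference"`.
#' @param reference_frame reference frame for `about_reference`.
#' @return numeric vector named by residue number, attribute `units` = "A".
#'   A single-frame ensemble in `about_mean` mode returns zeros with a
#'   warning.
#' @export
rmsf_per_residue <- function(ensemble, selection = select_atoms(ensemble),
                             mode = c("about_mean", "about_reference"),
                             reference_frame = 1L) {
  mode <- match.arg(mode)
  idx <- sel_indices(selection, ensemble)
  x <- ensemble$coords[idx, , , drop = FALSE]
  if (mode == "about_mean") {
    if (dim(x)[3] == 1) {
      warning("single-frame ensemble: RMSF about the mean is identically 0")
      vals <- rep(0, length(idx))
    } else {
      xbar <- apply(x, c(1, 2), mean)
      vals <- sqrt(apply((x - as.vector(xbar))^2, 1, mean) * 3)
    }
  } else {
    ref <- x[, , reference_frame]
    vals <- sqrt(apply((x - as.vector(ref))^2, 1, mean) * 3)
  }
  structure(setNames(vals, ensemble$topology$resno[idx]), units = "A")
}

#' Per-frame radius of gyration
#'
#' Rg = sqrt( sum_i m_i r_i^2 / sum_i m_i ), where r_i is the distance of
#' atom i from the centre of mass of the selection. The unweighted mode
#' (default, matching the C-alpha-based landscape coordinate) sets all
#' m_i = 1; the mass-weighted mode uses atomic masses from the topology.
#'
#' @param ensemble a `conf_ensemble`.
#' @param selection atoms entering Rg (default: all C-alpha).
#' @param mass_weighted logical (default `FALSE`).
#' @return numeric vector of per-frame Rg in Angstrom.
#' @export
radius_of_gyration <- function(ensemble, selection = select_atoms(ensemble),
                               mass_weighted = FALSE) {
  idx <- sel_indices(selection, ensemble)
  m <- if (mass_weighted) ensemble$topology$mass[idx] else rep(1, length(idx))
  if (sum(m) <= 0) stop("zero total mass in selection")
  w <- m / sum(m)
  vals <- apply(ensemble$coords[idx, , , drop = FALSE], 3, function(xyz) {
    com <- colSums(xyz * w)
    sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
  })
  structure(vals, name = "Rg", units = "A", label = ensemble$label)
}

# Fibonacci lattice of s near-uniform points on the unit sphere.
sphere_points <- function(s) {
  i <- seq_len(s) - 0.5
  phi <- acos(1 - 2 * i / s)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-frame solvent-accessible surface area (Shrake-Rupley)
#'
#' Total SASA per frame in Angstrom^2, by sphere sampling: test points are
#' placed on each atom's solvent-expanded sphere (van der Waals radius +
#' probe radius) and the accessible fraction is the share not buried inside
#' any neighbour's expanded sphere. Van der Waals radii: C 1.7, N 1.55,
#' O 1.52, S 1.8, H 1.2 Angstrom.
#'
#' @param ensemble a `conf_ensemble`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points test points per atom (default 960).
#' @param selection atoms considered (default: all atoms).
#' @return numeric vector of per-frame total SASA (Angstrom^2); per-atom
#'   areas of the last frame available via attribute `per_atom_last`.
#' @export
sasa <- function(ensemble, probe_radius = 1.4, n_sphere_points = 960L,
                 selection = NULL) {
  idx <- if (is.null(selection)) seq_len(n_atoms(ensemble))
         else sel_indices(selection, ensemble)
  elesy <- ensemble$topology$elesy[idx]
  unknown <- !elesy %in% names(ELEMENT_RADIUS)
  if (any(unknown))
    stop("no van der Waals radius for atom(s): ",
         paste(unique(ensemble$topology$elety[idx][unknown]), collapse = ", "))
  radii <- unname(ELEMENT_RADIUS[elesy])
  sph <- sphere_points(as.integer(n_sphere_points))
  per_atom <- NULL
  vals <- vapply(seq_len(n_frames(ensemble)), function(f) {
    a <- .sasa_frame(matrix(ensemble$coords[idx, , f], ncol = 3),
                     radii, probe_radius, sph)
    per_atom <<- a
    sum(a)
  }, numeric(1))
  structure(vals, name = "SASA", units = "A^2", label = ensemble$label,
            per_atom_last = per_atom)
}

#' Classify a radius of gyration into compactness classes
#'
#' Bins follow the reported mean-value classes: compact 11.2-11.6 A,
#' semi-compact 11.7-12.2 A, loose 12.3-12.8 A. Values in the narrow gaps
#' between printed bins are assigned to the nearest bin by midpoint, so the
#' classification is total on \[11.2, 12.8\]; anything outside is
#' `out-of-range`.
#'
#' @param rg radius (or vector of radii) of gyration in Angstrom, >= 0.
#' @return character vector of labels in
#'   `{"compact","semi-compact","loose","out-of-range"}`.
#' @export
classify_compactness <- function(rg) {
  stopifnot(all(rg >= 0))
  out <- rep("out-of-range", length(rg))
  out[rg >= 11.2 & rg <= 11.65] <- "compact"
  out[rg > 11.65 & rg <= 12.25] <- "semi-compact"
  out[rg > 12.25 & rg <= 12.8] <- "loose"
  out
}

#' Per-frame distance geometry between marker residues
#'
#' Euclidean C-alpha--C-alpha distances between all pairs of the given node
#' residues (e.g. the tyrosine tetrahedron Y703, Y721, Y730, Y747, or the
#' rigid triangle Y703, V732, I756), per frame. Edge columns are ordered
#' lexicographically by residue-number pair.
#'
#' @param ensemble a `conf_ensemble`.
#' @param node_resno residue numbers of the nodes (>= 2).
#' @return matrix `n_frames x n_edges` with columns named `"703-721"` etc.
#' @export
distance_geometry <- function(ensemble, node_resno) {
  node_resno <- sort(node_resno)
  top <- ensemble$topology
  idx <- vapply(node_resno, function(r) {
    i <- which(top$resno == r & top$elety == "CA")
    if (length(i) != 1) stop("residue ", r, " has no unique C-alpha atom")
    i
  }, integer(1))
  pairs <- t(utils::combn(seq_along(idx), 2))
  out <- matrix(NA_real_, n_frames(ensemble), nrow(pairs))
  colnames(out) <- paste0(node_resno[pairs[, 1]], "-", node_resno[pairs[, 2]])
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- ensemble$coords[idx, , f]
    out[f, ] <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                              xyz[pairs[, 2], , drop = FALSE])^2))
  }
  out
}

#' Normalised histogram of a descriptor series
#'
#' @param series numeric values (e.g. an RMSD series).
#' @param bin_width positive bin width in the series' units.
#' @return a `descriptor_histogram`: list with `breaks` (bin edges),
#'   `prob` (probabilities summing to 1) and `mids`.
#' @export
probability_distribution <- function(series, bin_width) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (length(series) < 1) stop("empty series")
  lo <- floor(min(series) / bin_width) * bin_width
  hi <- ceiling(max(series) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(pmin(pmax(findInterval(series, breaks,
                                            rightmost.closed = TRUE), 1L),
                          length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, prob = counts / sum(counts),
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2),
            class = "descriptor_histogram")
}

#' Modes of a descriptor histogram
#'
#' Local maxima of the binned probability (bins strictly greater than both
#' neighbours, or plateau edges), ordered by probability mass.
#'
#' @param h a `descriptor_histogram` from [probability_distribution()].
#' @return data frame with columns `location` (bin midpoint) and `prob`,
#'   ordered by decreasing probability.
#' @export
histogram_peaks <- function(h) {
  p <- h$prob
  n <- length(p)
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  is_peak <- p > 0 & p >= left & p > right | (p > 0 & p > left & p >= right)
  out <- data.frame(location = h$mids[is_peak], prob = p[is_peak])
  out[order(-out$prob), , drop = FALSE]
}
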