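#' Construct a conformational ensemble
#'
#' A `conf_ensemble` is an ordered set of conformations (frames) of a single
#' polypeptide over a fixed topology, the in-memory surrogate of an MD
#' trajectory. Coordinates are Cartesian, in Angstrom.
#'
#' @param topology data frame with one row per atom: columns `eleno`
#'   (serial), `elety` (atom name, e.g. `"CA"`), `resid` (3-letter residue
#'   name), `resno` (author residue number, strictly increasing across
#'   residues), `chain`, `elesy` (element symbol) and `mass` (amu).
#'   [build_topology()] fills in element and mass from atom names.
#' @param coords numeric array `n_atoms x 3 x n_frames`, finite.
#' @param times optional per-frame times (ps).
#' @param label replica identifier.
#' @return object of class `conf_ensemble` with elements `topology`,
#'   `coords`, `times`, `label`.
#' @export
conformation_ensemble <- function(topology, coords, times = NULL,
                                  label = "ensemble") {
  stopifnot(is.data.frame(topology))
  needed <- c("elety", "resid", "resno", "elesy", "mass")
  missing_cols <- setdiff(needed, names(topology))
  if (length(missing_cols))
    stop("topology lacks columns: ", paste(missing_cols, collapse = ", "))
  if (any(topology$mass <= 0)) stop("atomic masses must be > 0")
  rn <- unique(topology$resno)
  if (any(diff(rn) <= 0)) stop("residue numbers must be strictly increasing")
  if (length(dim(coords)) == 2) coords <- array(coords, c(dim(coords), 1L))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology))
    stop("coords atom count (", dim(coords)[1],
         ") does not match topology (", nrow(topology), ")")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(times) && length(times) != dim(coords)[3])
    stop("times length must equal the frame count")
  structure(list(topology = topology, coords = coords, times = times,
                 label = label),
            class = "conf_ensemble")
}

#' Build an atom topology from atom names
#'
#' Element symbols are inferred from the leading letter of the atom name
#' and masses looked up from a standard table (H, C, N, O, S).
#'
#' @param elety atom names (PDB convention: `N`, `CA`, `C`, `O`, `CB`, ...).
#' @param resid 3-letter residue names, one per atom.
#' @param resno author residue numbers, one per atom.
#' @param chain chain identifier.
#' @return topology data frame suitable for [conformation_ensemble()].
#' @export
build_topology <- function(elety, resid, resno, chain = "A") {
  elesy <- sub("^[0-9]*([A-Za-z]).*", "\\1", elety)
  elesy <- toupper(elesy)
  unknown <- !elesy %in% names(ELEMENT_MASS)
  if (any(unknown))
    stop("cannot assign element/mass for atom name(s): ",
         paste(unique(elety[unknown]), collapse = ", "))
  data.frame(eleno = seq_along(elety), elety = elety, resid = resid,
             resno = resno, chain = chain, elesy = elesy,
             mass = unname(ELEMENT_MASS[elesy]),
             stringsAsFactors = FALSE)
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("conf_ensemble '%s': %d frames, %d atoms, %d residues (%d-%d)\n",
              x$label, n_frames(x), n_atoms(x),
              length(unique(x$topology$resno)),
              min(x$topology$resno), max(x$topology$resno)))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble a `conf_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[1]

#' Coordinates of one frame
#' @param ensemble a `conf_ensemble`.
#' @param frame 1-based frame index.
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(ensemble, frame) ensemble$coords[, , frame]

#' Select atoms of an ensemble
#'
#' @param ensemble a `conf_ensemble`.
#' @param elety atom names to keep (default `"CA"`).
#' @param resno optional residue numbers to restrict to.
#' @return an `atom_selection`: list with `indices` (1-based atom indices)
#'   and a human-readable `description`.
#' @export
select_atoms <- function(ensemble, elety = "CA", resno = NULL) {
  top <- ensemble$topology
  keep <- top$elety %in% elety
  if (!is.null(resno)) keep <- keep & top$resno %in% resno
  idx <- which(keep)
  if (anyDuplicated(idx)) stop("selection indices must be unique")
  desc <- paste0(paste(elety, collapse = "/"),
                 if (is.null(resno)) " of all residues" else
                   paste0(" of residues ", min(resno), "-", max(resno)))
  structure(list(indices = idx, description = desc),
            class = "atom_selection")
}

sel_indices <- function(selection, ensemble = NULL) {
  idx <- if (inherits(selection, "atom_selection")) selection$indices
         else as.integer(selection)
  if (!is.null(ensemble) &&
      (length(idx) == 0 || any(idx < 1) || any(idx > n_atoms(ensemble))))
    stop("selection indices out of range")
  idx
}

# ---- multi-model PDB I/O ---------------------------------------------------

#' Read a conformational ensemble from a multi-model PDB file
#'
#' One frame per `MODEL` record (a file without `MODEL` records is read as a
#' single-frame ensemble). The topology is taken from the first model; every
#' subsequent model must list the same atoms.
#'
#' @param path PDB file path.
#' @param stride keep every `stride`-th model (default 1 = all).
#' @param label replica identifier (default: file name).
#' @return a [conformation_ensemble()].
#' @export
read_ensemble <- function(path, stride = 1L, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  atom_line <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (!any(atom_line)) stop("no ATOM records in ", path)
  if (length(model_starts) > 1) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(i)
      sum(atom_line[bounds[i]:(bounds[i + 1] - 1L)]), integer(1))
    bad <- which(counts != counts[1])
    if (length(bad))
      stop(sprintf("model %d has %d atoms; model 1 has %d (parse error near line %d)",
                   bad[1], counts[bad[1]], counts[1], model_starts[bad[1]]))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(pdb$atom)
  top <- build_topology(pdb$atom$elety, pdb$atom$resid, pdb$atom$resno,
                        chain = pdb$atom$chain[1] %||% "A")
  keep <- seq(1L, nf, by = as.integer(stride))
  coords <- array(NA_real_, c(na, 3, length(keep)))
  for (i in seq_along(keep))
    coords[, , i] <- matrix(xyz[keep[i], ], ncol = 3, byrow = TRUE)
  conformation_ensemble(top, coords,
                        label = label %||% basename(path))
}

#' Write a conformational ensemble as a multi-model PDB file
#'
#' Models are delimited by `MODEL`/`ENDMDL`; occupancy and B-factor are
#' written as 1.00 and 0.00. Coordinates are rounded to the format's
#' 3-decimal precision.
#'
#' @param ensemble a `conf_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  top <- ensemble$topology
  nf <- n_frames(ensemble)
  xyz <- t(apply(ensemble$coords, 3, function(m) as.vector(t(m))))
  if (nf == 1) xyz <- matrix(xyz, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz, resno = top$resno,
                   resid = top$resid, eleno = top$eleno, elety = top$elety,
                   chain = top$chain %||% "A", elesy = top$elesy,
                   o = rep(1, nrow(top)), b = rep(0, nrow(top)))
  invisible(path)
}

# ---- superposition ---------------------------------------------------------

# Kabsch optimal rotation of P onto Q (both n x 3, centred), with
# determinant correction so that only proper rotations are returned.
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  s$u %*% D %*% t(s$v)
}

#' Superpose an ensemble onto a reference frame
#'
#' Each frame is rigidly transformed (optimal rotation and translation,
#' Kabsch algorithm with proper-rotation enforcement) to minimise the RMSD
#' of the selected atoms to the same atoms in the reference frame. Internal
#' geometry is untouched; only rigid-body motion is removed.
#'
#' @param ensemble a `conf_ensemble`.
#' @param reference_frame 1-based frame index of the reference (default 1,
#'   the initial conformation).
#' @param selection atoms used for the fit (default: all C-alpha atoms).
#'   Needs at least 3 non-collinear atoms.
#' @param reference_coords optional explicit `n_sel x 3` reference
#'   coordinate matrix (e.g. a frame of another replica), overriding
#'   `reference_frame`.
#' @return the superposed `conf_ensemble`.
#' @export
superpose <- function(ensemble, reference_frame = 1L,
                      selection = select_atoms(ensemble),
                      reference_coords = NULL) {
  idx <- sel_indices(selection, ensemble)
  if (length(idx) < 3) stop("degenerate fit: selection has fewer than 3 atoms")
  ref <- if (is.null(reference_coords))
    ensemble$coords[idx, , reference_frame] else reference_coords
  if (nrow(ref) != length(idx)) stop("reference/selection size mismatch")
  refc <- colMeans(ref)
  ref0 <- sweep(ref, 2, refc)
  if (svd(ref0)$d[2] < 1e-8)
    stop("degenerate fit: selected reference atoms are collinear")
  out <- ensemble$coords
  for (f in seq_len(n_frames(ensemble))) {
    mov <- ensemble$coords[idx, , f]
    movc <- colMeans(mov)
    R <- kabsch_rotation(sweep(mov, 2, movc), ref0)
    all_xyz <- sweep(ensemble$coords[, , f], 2, movc)
    out[, , f] <- sweep(all_xyz %*% R, 2, refc, `+`)
  }
  ensemble$coords <- out
  ensemble
}

#' Drop equilibration frames from the start of an ensemble
#'
#' @param ensemble a `conf_ensemble`.
#' @param n_frames_drop number of leading frames to remove
#'   (`0 <= n < n_frames(ensemble)`).
#' @return the truncated `conf_ensemble`; times and label preserved.
#' @export
drop_equilibration <- function(ensemble, n_frames_drop) {
  nf <- n_frames(ensemble)
  if (n_frames_drop < 0 || n_frames_drop >= nf)
    stop("n_frames_drop must be in [0, ", nf - 1, "]")
  if (n_frames_drop == 0) return(ensemble)
  keep <- (n_frames_drop + 1L):nf
  ensemble$coords <- ensemble$coords[, , keep, drop = FALSE]
  if (!is.null(ensemble$times)) ensemble$times <- ensemble$times[keep]
  ensemble
}

#' Concatenate replicas into one ensemble
#'
#' @param ensembles list of `conf_ensemble`s sharing an identical topology.
#' @param label label of the merged ensemble.
#' @return a single `conf_ensemble` with frames in input order.
#' @export
concatenate <- function(ensembles, label = "concatenated") {
  stopifnot(length(ensembles) >= 1)
  top <- ensembles[[1]]$topology
  for (e in ensembles[-1]) {
    if (nrow(e$topology) != nrow(top))
      stop("topology mismatch: atom counts differ (", nrow(top), " vs ",
           nrow(e$topology), ")")
    same <- e$topology$elety == top$elety & e$topology$resno == top$resno &
      e$topology$resid == top$resid
    if (!all(same)) {
      i <- which(!same)[1]
      stop(sprintf("topology mismatch at atom %d: %s %s%d vs %s %s%d",
                   i, top$elety[i], top$resid[i], top$resno[i],
                   e$topology$elety[i], e$topology$resid[i],
                   e$topology$resno[i]))
    }
  }
  coords <- array(unlist(lapply(ensembles, `[[`, "coords")),
                  c(nrow(top), 3, sum(vapply(ensembles, n_frames, 1L))))
  times <- unlist(lapply(ensembles, `[[`, "times"))
  if (length(times) != dim(coords)[3]) times <- NULL
  conformation_ensemble(top, coords, times = times, label = label)
}
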