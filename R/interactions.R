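#' Dynamic residue contact map
#'
#' A contact exists in a frame when the C-alpha--C-alpha distance is
#' strictly below `cutoff` (default 10 Angstrom); the map entry is the
#' fraction of frames with a contact. Sequence neighbours with
#' `|i - j| <= exclude_neighbours` (and the diagonal) are set to `NA` so
#' that the trivial backbone band does not dominate the statistics; set
#' `exclude_neighbours = 0` for the strict map.
#'
#' @param ensemble a `conf_ensemble` with a C-alpha atom per residue.
#' @param cutoff contact distance cutoff in Angstrom (default 10).
#' @param exclude_neighbours sequence-separation exclusion (default 2).
#' @return symmetric `n_res x n_res` matrix of frequencies in \[0,1\]
#'   (dimnames = residue numbers), class `contact_map`, attribute `cutoff`.
#' @export
contact_map <- function(ensemble, cutoff = 10, exclude_neighbours = 2L) {
  if (cutoff <= 0) stop("cutoff must be positive")
  sel <- select_atoms(ensemble, "CA")
  top <- ensemble$topology
  resno <- unique(top$resno)
  if (length(sel$indices) != length(resno))
    stop("missing C-alpha atom for residue ",
         resno[which(!resno %in% top$resno[top$elety == "CA"])[1]])
  nres <- length(resno)
  acc <- matrix(0, nres, nres)
  for (f in seq_len(n_frames(ensemble))) {
    xyz <- ensemble$coords[sel$indices, , f]
    acc <- acc + (cross_dist(xyz, xyz) < cutoff)
  }
  m <- acc / n_frames(ensemble)
  near <- abs(outer(seq_len(nres), seq_len(nres), `-`)) <= exclude_neighbours
  m[near] <- NA_real_
  dimnames(m) <- list(resno, resno)
  structure(m, cutoff = cutoff, class = c("contact_map", "matrix"))
}

# Polar heavy atoms with at least one covalently attached hydrogen in the
# given frame; returns list(donor_idx, h_idx) pairs.
find_donors <- function(top, xyz, reconstruct = TRUE) {
  polar <- which(top$elesy %in% c("N", "O", "S"))
  hyd <- which(top$elesy == "H")
  pairs <- NULL
  inferred <- NULL
  if (length(hyd)) {
    d <- cross_dist(xyz[polar, , drop = FALSE], xyz[hyd, , drop = FALSE])
    hit <- which(d < 1.25, arr.ind = TRUE)
    if (nrow(hit))
      pairs <- cbind(polar[hit[, 1]], hyd[hit[, 2]])
  }
  bonded <- if (is.null(pairs)) integer() else pairs[, 1]
  if (reconstruct) {
    # backbone N without explicit H: place the amide H geometrically
    resno <- unique(top$resno)
    for (i in seq_along(resno)[-1]) {
      ni <- which(top$resno == resno[i] & top$elety == "N")
      if (!length(ni) || ni %in% bonded) next
      if (top$resid[ni][1] == "PRO") next
      cp <- which(top$resno == resno[i - 1] & top$elety == "C")
      op <- which(top$resno == resno[i - 1] & top$elety == "O")
      if (!length(cp) || !length(op)) next
      u <- xyz[cp, ] - xyz[op, ]
      hpos <- xyz[ni, ] + 1.01 * u / sqrt(sum(u^2))
      pairs <- rbind(pairs, c(ni, NA))
      inferred <- rbind(inferred, hpos)
    }
  }
  list(pairs = pairs, inferred = inferred)
}

#' Hydrogen-bond detection with occurrence statistics
#'
#' Geometric criteria: donor--acceptor heavy-atom (N, O, S) distance
#' `<= dist_cutoff` (default 3.6 Angstrom) and donor-H...acceptor angle
#' `>= angle_cutoff` (default 120 degrees), the angle measured at the
#' hydrogen. Explicit hydrogens are used when present; missing backbone
#' amide hydrogens are reconstructed and the records flagged
#' `geometry_inferred`. Pairs within the same residue, and
#' backbone--backbone pairs of adjacent residues (covalent and 1-3
#' neighbours), are excluded. Backbone i,i+3/i+4 pairs, which stabilise
#' helices rather than tertiary structure, are excluded by default.
#'
#' @param ensemble a `conf_ensemble`.
#' @param dist_cutoff heavy-atom distance cutoff in Angstrom.
#' @param angle_cutoff D-H...A angle cutoff in degrees.
#' @param min_occurrence keep records with occurrence above this value.
#' @param exclude_intrahelix drop backbone-backbone i,i+3/i+4 bonds
#'   (default `TRUE`).
#' @return data frame of class `interaction_records`: `kind`,
#'   `donor_resno`, `donor_atom`, `acceptor_resno`, `acceptor_atom`,
#'   `occurrence`, `geometry_inferred`.
#' @export
hydrogen_bonds <- function(ensemble, dist_cutoff = 3.6, angle_cutoff = 120,
                           min_occurrence = 0, exclude_intrahelix = TRUE) {
  top <- ensemble$topology
  acceptors <- which(top$elesy %in% c("N", "O", "S"))
  if (!length(acceptors)) {
    warning("no polar heavy atoms in topology")
    return(empty_records())
  }
  nf <- n_frames(ensemble)
  counts <- list()
  inferred_flag <- logical()
  bb <- c("N", "CA", "C", "O", "H")
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[, , f]
    don <- find_donors(top, xyz)
    if (is.null(don$pairs)) next
    n_inf <- 0
    for (k in seq_len(nrow(don$pairs))) {
      di <- don$pairs[k, 1]
      hi <- don$pairs[k, 2]
      hxyz <- if (is.na(hi)) don$inferred[(n_inf <- n_inf + 1), ]
              else xyz[hi, ]
      for (ai in acceptors) {
        if (ai == di) next
        sep <- abs(top$resno[ai] - top$resno[di])
        if (sep == 0) next
        both_bb <- top$elety[ai] %in% bb && top$elety[di] %in% bb
        if (sep == 1 && both_bb) next
        if (exclude_intrahelix && both_bb && sep <= 4) next
        dv <- xyz[ai, ] - xyz[di, ]
        dda <- sqrt(sum(dv^2))
        if (dda > dist_cutoff) next
        u <- xyz[di, ] - hxyz
        v <- xyz[ai, ] - hxyz
        ang <- acos(pmin(pmax(sum(u * v) /
                                sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
        if (ang < angle_cutoff) next
        key <- paste0(di, "_", ai)
        counts[[key]] <- (counts[[key]] %||% 0) + 1
        inferred_flag[key] <- is.na(hi)
      }
    }
  }
  if (!length(counts)) return(empty_records())
  keys <- names(counts)
  di <- as.integer(sub("_.*", "", keys))
  ai <- as.integer(sub(".*_", "", keys))
  out <- data.frame(kind = "hbond",
                    donor_resno = top$resno[di], donor_atom = top$elety[di],
                    acceptor_resno = top$resno[ai],
                    acceptor_atom = top$elety[ai],
                    occurrence = unlist(counts) / nf,
                    geometry_inferred = unname(inferred_flag[keys]),
                    stringsAsFactors = FALSE)
  out <- out[out$occurrence > min_occurrence, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

empty_records <- function() {
  out <- data.frame(kind = character(), donor_resno = integer(),
                    donor_atom = character(), acceptor_resno = integer(),
                    acceptor_atom = character(), occurrence = numeric(),
                    geometry_inferred = logical(), stringsAsFactors = FALSE)
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Hydrophobic side-chain contacts
#'
#' A contact exists between two hydrophobic residues in a frame when the
#' minimum distance between their side-chain heavy atoms is at most
#' `cutoff` (default 4 Angstrom).
#'
#' @param ensemble a `conf_ensemble`.
#' @param cutoff side-chain heavy-atom distance cutoff in Angstrom.
#' @param min_occurrence keep records with occurrence above this value.
#' @param hydrophobic_set 3-letter residue names treated as hydrophobic
#'   (default A, V, L, I, P, F, M, W).
#' @return data frame of class `interaction_records` (`donor_*` /
#'   `acceptor_*` hold the residue pair; atom fields are `"sidechain"`).
#' @export
hydrophobic_contacts <- function(ensemble, cutoff = 4, min_occurrence = 0,
                                 hydrophobic_set = c("ALA", "VAL", "LEU",
                                                     "ILE", "PRO", "PHE",
                                                     "MET", "TRP")) {
  if ("GLY" %in% hydrophobic_set)
    stop("glycine has no side-chain heavy atoms")
  top <- ensemble$topology
  bb <- c("N", "CA", "C", "O", "OXT")
  sc <- top$elesy != "H" & !top$elety %in% bb
  resno <- unique(top$resno)
  hyd_res <- resno[vapply(resno, function(r)
    top$resid[top$resno == r][1] %in% hydrophobic_set, logical(1))]
  sc_idx <- lapply(hyd_res, function(r) which(sc & top$resno == r))
  missing_sc <- lengths(sc_idx) == 0
  if (any(missing_sc))
    stop("hydrophobic residue ", hyd_res[which(missing_sc)[1]],
         " has no side-chain heavy atoms")
  if (length(hyd_res) < 2) return(empty_records())
  pairs <- t(utils::combn(seq_along(hyd_res), 2))
  nf <- n_frames(ensemble)
  occ <- numeric(nrow(pairs))
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[, , f]
    for (p in seq_len(nrow(pairs))) {
      a <- sc_idx[[pairs[p, 1]]]; b <- sc_idx[[pairs[p, 2]]]
      if (min(cross_dist(xyz[a, , drop = FALSE],
                         xyz[b, , drop = FALSE])) <= cutoff)
        occ[p] <- occ[p] + 1
    }
  }
  occ <- occ / nf
  out <- data.frame(kind = "hydrophobic",
                    donor_resno = hyd_res[pairs[, 1]],
                    donor_atom = "sidechain",
                    acceptor_resno = hyd_res[pairs[, 2]],
                    acceptor_atom = "sidechain",
                    occurrence = occ, geometry_inferred = FALSE,
                    stringsAsFactors = FALSE)
  out <- out[out$occurrence > min_occurrence & out$occurrence > 0, ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Filter interactions by anchor segments and occurrence
#'
#' Keeps interactions with at least one endpoint inside one of the given
#' residue segments (e.g. the pseudo-rigid anchors E699-S709, P754-L764,
#' V731-P733) and occurrence strictly greater than `min_occurrence`
#' (default 0.80).
#'
#' @param records an `interaction_records` data frame, or a `contact_map`
#'   (converted to per-pair frequency records).
#' @param segments list of `c(first_resno, last_resno)` residue spans.
#' @param min_occurrence occurrence threshold (strict, default 0.80).
#' @return filtered `interaction_records` data frame.
#' @export
segment_contacts <- function(records, segments, min_occurrence = 0.80) {
  if (!length(segments)) stop("empty segment list")
  if (inherits(records, "contact_map")) {
    m <- unclass(records)
    resno <- as.integer(rownames(m))
    idx <- which(upper.tri(m) & !is.na(m) & m > 0, arr.ind = TRUE)
    records <- data.frame(kind = "contact",
                          donor_resno = resno[idx[, 1]], donor_atom = "CA",
                          acceptor_resno = resno[idx[, 2]],
                          acceptor_atom = "CA",
                          occurrence = m[idx], geometry_inferred = FALSE,
                          stringsAsFactors = FALSE)
  }
  in_seg <- function(r) Reduce(`|`, lapply(segments, function(s)
    r >= s[1] & r <= s[2]))
  keep <- (in_seg(records$donor_resno) | in_seg(records$acceptor_resno)) &
    records$occurrence > min_occurrence
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_records", "data.frame")
  out
}
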