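# Cross pairwise Euclidean distances between rows of A (n x 3) and B (m x 3).
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Construct a secondary-structure track
#'
#' @param states character matrix `n_frames x n_residues` over the 8-letter
#'   alphabet `H,G,I,E,B,T,S,C` (`"-"` is accepted as an alias for `C`).
#' @param resno residue numbers (columns).
#' @param label replica identifier.
#' @return object of class `ss_track` (the state matrix with attributes
#'   `resno` and `label`).
#' @export
ss_track <- function(states, resno = seq_len(ncol(states)),
                     label = "track") {
  states[states == "-"] <- "C"
  bad <- !states %in% SS_STATES
  if (any(bad))
    stop("invalid secondary-structure state(s): ",
         paste(unique(states[bad]), collapse = ", "))
  if (length(resno) != ncol(states))
    stop("resno length must match the residue dimension")
  structure(states, resno = resno, label = label, class = "ss_track")
}

#' @export
print.ss_track <- function(x, ...) {
  cat(sprintf("ss_track '%s': %d frames x %d residues\n",
              attr(x, "label"), nrow(x), ncol(x)))
  invisible(x)
}

# Backbone atom coordinates per residue for one frame; NA rows where absent.
backbone_frame <- function(top, xyz, what) {
  resno <- unique(top$resno)
  idx <- match(paste(resno, what), paste(top$resno, top$elety))
  out <- matrix(NA_real_, length(resno), 3)
  out[!is.na(idx), ] <- xyz[idx[!is.na(idx)], , drop = FALSE]
  out
}

#' Assign 8-state secondary structure from backbone geometry
#'
#' Implements the classic backbone hydrogen-bond energy assignment: for a
#' donor amide (N-H) of residue i and an acceptor carbonyl (C=O) of residue
#' j, the electrostatic energy is
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` kcal/mol and a bond
#' exists when `E < -0.5` kcal/mol. Two consecutive n-turns define helices
#' (`G`: i->i+3, `H`: i->i+4, `I`: i->i+5); bridge patterns give `E`/`B`;
#' remaining turn residues `T`; bends (C-alpha chain kink > 70 degrees) `S`;
#' otherwise coil `C`. Priority: H > E/B > G > I > T > S.
#'
#' Amide hydrogens are taken from the topology when present (atom name `H`)
#' and otherwise reconstructed 1.01 Angstrom from N along the direction of
#' the preceding carbonyl C=O bond. The first residue and prolines carry no
#' donor. A C(i)-N(i+1) distance above 2.5 Angstrom is treated as a chain
#' break (segment boundary).
#'
#' @param ensemble a `conf_ensemble` whose topology contains backbone
#'   N, CA, C, O atoms for every residue.
#' @param hbond_energy_cutoff bond threshold in kcal/mol (default -0.5).
#' @return an [ss_track()] of dimensions `n_frames x n_residues`.
#' @export
assign_dssp <- function(ensemble, hbond_energy_cutoff = -0.5) {
  top <- ensemble$topology
  resno <- unique(top$resno)
  nres <- length(resno)
  for (a in c("N", "CA", "C", "O")) {
    have <- resno %in% top$resno[top$elety == a]
    if (!all(have))
      stop("missing backbone ", a, " atom for residue ",
           resno[which(!have)[1]])
  }
  resid3 <- top$resid[match(resno, top$resno)]
  has_expl_h <- resno %in% top$resno[top$elety == "H"]
  nf <- n_frames(ensemble)
  states <- matrix("C", nf, nres)
  for (f in seq_len(nf)) {
    xyz <- ensemble$coords[, , f]
    N <- backbone_frame(top, xyz, "N")
    CA <- backbone_frame(top, xyz, "CA")
    C <- backbone_frame(top, xyz, "C")
    O <- backbone_frame(top, xyz, "O")
    H <- backbone_frame(top, xyz, "H")
    # chain segmentation by peptide-bond continuity
    brk <- sqrt(rowSums((C[-nres, , drop = FALSE] -
                         N[-1, , drop = FALSE])^2)) > 2.5
    seg <- cumsum(c(1, as.integer(brk)))
    # reconstruct missing amide H along the preceding C=O direction
    for (i in 2:nres) {
      if (!has_expl_h[i] && resid3[i] != "PRO" && !brk[i - 1]) {
        u <- C[i - 1, ] - O[i - 1, ]
        H[i, ] <- N[i, ] + 1.01 * u / sqrt(sum(u^2))
      }
    }
    donor_ok <- !is.na(H[, 1])
    # Kabsch-Sander energies, donor i (rows) x acceptor j (cols)
    E <- matrix(Inf, nres, nres)
    ca_near <- cross_dist(CA, CA) < 9
    ok <- which(donor_ok)
    if (length(ok)) {
      rON <- cross_dist(N[ok, , drop = FALSE], O)
      rCH <- cross_dist(H[ok, , drop = FALSE], C)
      rOH <- cross_dist(H[ok, , drop = FALSE], O)
      rCN <- cross_dist(N[ok, , drop = FALSE], C)
      E[ok, ] <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      E[!ca_near] <- Inf
      diag(E) <- Inf
    }
    hb <- E < hbond_energy_cutoff   # hb[d, a]: N-H(d) ... O=C(a)
    turn <- function(n) {
      t <- rep(FALSE, nres)
      i <- seq_len(nres - n)
      t[i] <- hb[cbind(i + n, i)] & seg[i] == seg[i + n]
      t
    }
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    st <- rep(NA_character_, nres)
    mark_helix <- function(tn, n, code, st) {
      for (i in which(tn[-1] & tn[-length(tn)]) + 1L) {
        span <- i:(i + n - 1L)
        st[span][is.na(st[span])] <- code
      }
      st
    }
    st <- mark_helix(t4, 4L, "H", st)
    # bridges (beta): parallel / antiparallel patterns for |i-j| >= 3
    bridge <- matrix(FALSE, nres, nres)
    if (any(hb)) {
      for (i in 2:(nres - 1)) {
        js <- which(ca_near[i, ])
        js <- js[abs(js - i) >= 3 & js > 1 & js < nres]
        for (j in js) {
          para <- (hb[j, i - 1] && hb[i + 1, j]) ||
                  (hb[i, j - 1] && hb[j + 1, i])
          anti <- (hb[j, i] && hb[i, j]) ||
                  (hb[j + 1, i - 1] && hb[i + 1, j - 1])
          if (para || anti) bridge[i, j] <- TRUE
        }
      }
    }
    in_bridge <- apply(bridge, 1, any) | apply(bridge, 2, any)
    if (any(in_bridge)) {
      ladder <- in_bridge & (c(FALSE, in_bridge[-nres]) |
                             c(in_bridge[-1], FALSE))
      st[is.na(st) & in_bridge] <- ifelse(ladder[is.na(st) & in_bridge],
                                          "E", "B")
    }
    st <- mark_helix(t3, 3L, "G", st)
    st <- mark_helix(t5, 5L, "I", st)
    # turns: residues strictly inside any n-turn
    tres <- rep(FALSE, nres)
    for (tn_n in list(list(t3, 3L), list(t4, 4L), list(t5, 5L))) {
      for (i in which(tn_n[[1]]))
        tres[(i + 1):(i + tn_n[[2]] - 1)] <- TRUE
    }
    st[is.na(st) & tres] <- "T"
    # bends: C-alpha direction kink > 70 degrees over i-2, i, i+2
    if (nres >= 5) {
      for (i in 3:(nres - 2)) {
        if (!is.na(st[i]) || seg[i - 2] != seg[i + 2]) next
        u <- CA[i, ] - CA[i - 2, ]; v <- CA[i + 2, ] - CA[i, ]
        cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
        if (cosang < cos(70 * pi / 180)) st[i] <- "S"
      }
    }
    st[is.na(st)] <- "C"
    states[f, ] <- st
  }
  ss_track(states, resno = resno, label = ensemble$label)
}

#' Per-frame helical fraction (Hfp)
#'
#' Percentage of residues per frame whose state belongs to `states`. The
#' default counts alpha- and 3_10-helices (`H`, `G`); the pi-helix state
#' `I` can be added via `states`.
#'
#' @param track an [ss_track()].
#' @param states helical state set (default `c("H","G")`).
#' @return numeric vector (length `n_frames`) of percentages, attribute
#'   `units` = "%".
#' @export
helical_fraction <- function(track, states = c("H", "G")) {
  if (length(states) == 0) stop("empty state set")
  vals <- 100 * rowMeans(matrix(track %in% states, nrow(track)))
  structure(vals, name = "Hfp", units = "%", label = attr(track, "label"))
}

#' Helix segments and their lifetimes
#'
#' Maximal per-frame runs of helical states (`H`/`G`) of at least
#' `min_length` residues are merged across frames whenever their residue
#' spans share at least one residue, and labelled `H1..Hn` from the
#' N-terminus. The lifetime of a merged segment is the fraction of frames in
#' which it appears with at least `min_length` residues.
#'
#' @param track an [ss_track()].
#' @param min_length minimum run length in residues (default 3).
#' @param min_lifetime drop segments with lifetime below this (default 0).
#' @return data frame: `label`, `first_resno`, `last_resno`, `max_length`,
#'   `lifetime`, `alpha_fraction` (share of member cells that are `H`
#'   rather than `G`).
#' @export
helix_segments <- function(track, min_length = 3L, min_lifetime = 0) {
  resno <- attr(track, "resno")
  nf <- nrow(track)
  runs <- list()
  for (f in seq_len(nf)) {
    r <- rle(track[f, ] %in% c("H", "G"))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_length))
      runs[[length(runs) + 1L]] <- c(f, starts[k], ends[k])
  }
  if (!length(runs))
    return(data.frame(label = character(), first_resno = integer(),
                      last_resno = integer(), max_length = integer(),
                      lifetime = numeric(), alpha_fraction = numeric()))
  runs <- do.call(rbind, runs)
  # union-find over runs sharing at least one residue column
  parent <- seq_len(nrow(runs))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ncol_t <- ncol(track)
  by_res <- vector("list", ncol_t)
  for (k in seq_len(nrow(runs)))
    for (c in runs[k, 2]:runs[k, 3])
      by_res[[c]] <- c(by_res[[c]], k)
  for (c in seq_len(ncol_t)) {
    ks <- by_res[[c]]
    if (length(ks) > 1)
      for (k in ks[-1]) {
        a <- find(ks[1]); b <- find(k)
        if (a != b) parent[b] <- a
      }
  }
  comp <- vapply(seq_len(nrow(runs)), find, integer(1))
  segs <- lapply(split(seq_len(nrow(runs)), comp), function(ks) {
    m <- runs[ks, , drop = FALSE]
    cells <- unlist(lapply(ks, function(k)
      track[m[which(ks == k)[1], 1], runs[k, 2]:runs[k, 3]]))
    data.frame(first_resno = resno[min(m[, 2])],
               last_resno = resno[max(m[, 3])],
               max_length = max(m[, 3] - m[, 2] + 1L),
               lifetime = length(unique(m[, 1])) / nf,
               alpha_fraction = mean(cells == "H"),
               mid = mean(resno[c(min(m[, 2]), max(m[, 3]))]))
  })
  out <- do.call(rbind, segs)
  out <- out[out$lifetime >= min_lifetime, , drop = FALSE]
  out <- out[order(out$mid), , drop = FALSE]
  out$mid <- NULL
  out <- cbind(label = paste0("H", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Read / write a secondary-structure track as TSV
#'
#' Rows are frames, columns residues (header = residue numbers), cells
#' single letters; `-` is accepted as an alias for `C` on read.
#'
#' @param track an [ss_track()].
#' @param path file path.
#' @param label replica identifier on read.
#' @return `write_ss_track`: `path` invisibly; `read_ss_track`: an
#'   [ss_track()].
#' @export
write_ss_track <- function(track, path) {
  df <- as.data.frame(unclass(track), stringsAsFactors = FALSE)
  names(df) <- attr(track, "resno")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ss_track
#' @export
read_ss_track <- function(path, label = basename(path)) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  ss_track(as.matrix(df), resno = as.integer(names(df)), label = label)
}
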