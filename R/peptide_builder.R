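# Ideal-geometry peptide builder: internal-coordinate (NeRF) chain
# extension with standard backbone bond lengths and angles.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
            Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
            L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
            S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

unitv <- function(v) v / sqrt(sum(v^2))

# Place atom D given A-B-C, bond length r (C-D), bond angle theta (B-C-D,
# degrees) and dihedral chi (A-B-C-D, degrees).
place_atom <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Backbone dihedrals characteristic of each secondary-structure state.
# Coil-like states draw from a broad coil basin.
state_phi_psi <- function(state) {
  switch(state,
         H = c(-57, -47),
         G = c(-49, -26),
         I = c(-57, -70),
         E = c(-135, 135),
         B = c(-135, 135),
         c(rnorm(1, -120, 30), rnorm(1, 130, 30)))
}

# Build one conformation: N, H, CA, CB, C, O per residue (H absent on the
# first residue and prolines; CB absent on glycine).
build_backbone_frame <- function(states, resid3) {
  n <- length(states)
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    pp <- state_phi_psi(states[i])
    phi[i] <- pp[1]; psi[i] <- pp[2]
  }
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         1.329, 116.2, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         1.525, 111.2, phi[i])
  }
  O <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    dir <- if (i < n) unitv(unitv(C[i, ] - CA[i, ]) + unitv(C[i, ] - N[i + 1, ]))
           else unitv(place_atom(N[i, ], CA[i, ], C[i, ], 1, 120.8, 0) - C[i, ])
    O[i, ] <- C[i, ] + 1.231 * dir
  }
  H <- CB <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (resid3[i] != "PRO")
      H[i, ] <- N[i, ] + 1.01 * unitv(C[i - 1, ] - O[i - 1, ])
  }
  for (i in seq_len(n)) {
    if (resid3[i] != "GLY")
      CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], 1.53, 110.5, 122.5)
  }
  list(N = N, H = H, CA = CA, CB = CB, C = C, O = O)
}

#' Build a synthetic peptide ensemble realising a secondary-structure track
#'
#' Backbones are grown frame by frame by internal-coordinate chain
#' extension with standard peptide bond lengths and angles; backbone
#' dihedrals follow the per-residue state of the track (alpha-helix
#' phi/psi = -57/-47 degrees, 3_10 -49/-26, pi -57/-70, strand -135/135,
#' coil-like states sampled from a broad coil basin). Amide hydrogens and
#' C-beta atoms are placed by ideal geometry; isotropic Gaussian jitter of
#' `jitter_sigma` per coordinate is then added. A pure function of its
#' inputs and seed.
#'
#' @param sequence 1-letter amino-acid string (length = track residues).
#' @param track an [ss_track()] prescribing per-frame, per-residue states.
#' @param jitter_sigma coordinate noise s.d. in Angstrom (default 0).
#' @param seed RNG seed (coil dihedrals and jitter).
#' @param resno residue numbers (default: the track's).
#' @param label replica identifier.
#' @return a [conformation_ensemble()] with atoms N, (H), CA, (CB), C, O
#'   per residue.
#' @export
build_peptide_ensemble <- function(sequence, track, jitter_sigma = 0,
                                   seed = 1L, resno = NULL, label = NULL) {
  aa <- strsplit(sequence, "")[[1]]
  bad <- !aa %in% names(AA1TO3)
  if (any(bad)) stop("invalid residue letter(s): ",
                     paste(unique(aa[bad]), collapse = ", "))
  if (length(aa) != ncol(track))
    stop("sequence length must equal the track residue count")
  resid3 <- unname(AA1TO3[aa])
  resno <- resno %||% attr(track, "resno") %||% seq_along(aa)
  n <- length(aa)
  atom_rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    at <- c("N",
            if (i > 1 && resid3[i] != "PRO") "H",
            "CA",
            if (resid3[i] != "GLY") "CB",
            "C", "O")
    data.frame(elety = at, resid = resid3[i], resno = resno[i],
               stringsAsFactors = FALSE)
  }))
  top <- build_topology(atom_rows$elety, atom_rows$resid, atom_rows$resno)
  nf <- nrow(track)
  coords <- array(NA_real_, c(nrow(top), 3, nf))
  set.seed(seed)
  for (f in seq_len(nf)) {
    bb <- build_backbone_frame(track[f, ], resid3)
    row <- 0L
    for (i in seq_len(n)) {
      for (at in c("N", "H", "CA", "CB", "C", "O")) {
        pos <- bb[[at]][i, ]
        if (any(is.na(pos))) next
        row <- row + 1L
        coords[row, , f] <- pos
      }
    }
    if (jitter_sigma > 0)
      coords[, , f] <- coords[, , f] +
        rnorm(3 * nrow(top), sd = jitter_sigma)
  }
  conformation_ensemble(top, coords,
                        label = label %||% attr(track, "label"))
}
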