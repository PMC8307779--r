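#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041

#' k-nearest-neighbour density estimate in the plane
#'
#' `density_i = k / (N * pi * d_ik^2)`, where `d_ik` is the distance from
#' point i to its k-th nearest neighbour among the `N` points (self
#' excluded). Coordinates are used as given: standardise incommensurate
#' axes before calling (as [free_energy_landscape()] does).
#'
#' @param points numeric `N x 2` matrix.
#' @param k neighbour order (`1 <= k <= N-1`).
#' @param query optional `M x 2` matrix of evaluation points distinct from
#'   the sample; densities are then `k / (N * pi * d_k^2)` with `d_k`
#'   measured from the query points (no self-exclusion).
#' @return numeric vector of densities (> 0). Duplicated points with zero
#'   k-th neighbour distance are capped at the largest finite estimate and
#'   flagged via attribute `capped`.
#' @export
knn_density <- function(points, k, query = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns")
  n <- nrow(points)
  if (k < 1 || k > n - 1) stop("k must be between 1 and N-1")
  self <- is.null(query)
  q <- if (self) points else as.matrix(query)
  dk <- .knn_kth_dist(q, points, as.integer(k), self)
  dens <- k / (n * pi * dk^2)
  capped <- !is.finite(dens)
  if (any(capped)) {
    dens[capped] <- max(dens[!capped], na.rm = TRUE)
    attr(dens, "capped") <- which(capped)
  }
  dens
}

#' Relative free-energy landscape over two reaction coordinates
#'
#' The relative Gibbs free energy on a regular grid over the two reaction
#' coordinates: `deltaG = -kB * T * ln(P / Pmax)`, with the probability
#' density `P` estimated by the k-nearest-neighbour scheme of
#' [knn_density()]. Each axis is standardised (z-scored) before density
#' estimation because reaction coordinates carry incommensurate units
#' (Angstrom, percent, Angstrom^2); free-energy differences are invariant
#' under this affine rescaling. Grid cells farther than `support_mult` grid
#' spacings from any sample are marked undefined (`NA`).
#'
#' @param rc list or data frame with two numeric components (the per-frame
#'   reaction-coordinate values), e.g. `list(RMSD = ..., Rg = ...)`.
#' @param temperature temperature in Kelvin (default 310, body/simulation
#'   temperature).
#' @param k neighbour order; default `ceiling(sqrt(N))`.
#' @param grid_size `c(nx, ny)` grid resolution (default 100 x 100).
#' @param pad bounding-box padding fraction (default 0.05).
#' @param support_mult support radius in grid spacings (default 2).
#' @return object of class `fel_grid`: list with `deltaG` (nx x ny matrix,
#'   kcal/mol, `NA` where unsampled), `x`, `y` (native-unit grid axes),
#'   `zx`, `zy` (standardised axes), `names`, `temperature`, `kB`, `k`,
#'   `center`, `scale`, and `points_z` (standardised sample).
#' @export
free_energy_landscape <- function(rc, temperature = 310, k = NULL,
                                  grid_size = c(100L, 100L), pad = 0.05,
                                  support_mult = 2) {
  stopifnot(length(rc) == 2)
  v1 <- rc[[1]]; v2 <- rc[[2]]
  if (length(v1) != length(v2)) stop("reaction coordinates differ in length")
  if (!all(is.finite(v1)) || !all(is.finite(v2)))
    stop("reaction coordinates must be finite")
  n <- length(v1)
  if (temperature <= 0) stop("temperature must be positive")
  if (is.null(k)) k <- ceiling(sqrt(n))
  if (k >= n) stop("k must be smaller than the number of frames")
  ctr <- c(mean(v1), mean(v2))
  scl <- c(sd(v1), sd(v2))
  scl[scl == 0] <- 1
  z <- cbind((v1 - ctr[1]) / scl[1], (v2 - ctr[2]) / scl[2])
  rng <- apply(z, 2, range)
  span <- rng[2, ] - rng[1, ]
  lo <- rng[1, ] - pad * span
  hi <- rng[2, ] + pad * span
  zx <- seq(lo[1], hi[1], length.out = grid_size[1])
  zy <- seq(lo[2], hi[2], length.out = grid_size[2])
  nodes <- cbind(rep(zx, times = length(zy)), rep(zy, each = length(zx)))
  dens <- knn_density(z, k, query = nodes)
  d1 <- .knn_kth_dist(nodes, z, 1L, FALSE)
  spacing <- max(zx[2] - zx[1], zy[2] - zy[1])
  dens[d1 > support_mult * spacing] <- NA_real_
  pmax_ <- max(dens, na.rm = TRUE)
  dg <- -KB_KCAL * temperature * log(dens / pmax_)
  structure(list(deltaG = matrix(dg, length(zx), length(zy)),
                 x = zx * scl[1] + ctr[1], y = zy * scl[2] + ctr[2],
                 zx = zx, zy = zy,
                 names = names(rc) %||% c("R1", "R2"),
                 temperature = temperature, kB = KB_KCAL, k = k,
                 center = ctr, scale = scl, points_z = z),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("fel_grid %s x %s: %d x %d nodes, T = %g K, k = %d, max deltaG %.2f kcal/mol\n",
              x$names[1], x$names[2], length(x$x), length(x$y),
              x$temperature, x$k, max(x$deltaG, na.rm = TRUE)))
  invisible(x)
}

#' Detect wells (free-energy minima) on a landscape
#'
#' Basins are grown by flooding the defined grid cells in order of
#' increasing free energy (8-neighbour connectivity). When a basin first
#' meets a deeper one, its persistence (saddle energy minus its minimum) is
#' compared with `min_depth`: shallower basins are merged, so minima that
#' are mere sampling ripples do not count as wells. Wells are ranked by the
#' free energy of their minimum (rank 1 = global minimum, depth 0).
#'
#' Because the landscape support is estimated from a finite sample, a few
#' stray frames in the tails can form small basins disconnected from the
#' populated region, where no saddle exists for the persistence rule to
#' act on. Basins holding less than `min_population` of the sample mass
#' are therefore discarded as sampling artifacts. Persistence values
#' within the density estimator's noise of `min_depth` are genuinely
#' ambiguous: wells whose true barrier sits at the threshold may resolve
#' either way from one sample to the next.
#'
#' @param fel a `fel_grid` from [free_energy_landscape()].
#' @param min_depth persistence threshold in kcal/mol (default 0.5).
#' @param min_population minimal fraction of frames a basin must hold to
#'   count as a well (default 0.01).
#' @return object of class `fel_wells`: data frame `wells` with `rank`,
#'   `R1`, `R2` (native units), `deltaG` (kcal/mol above the global
#'   minimum), `n_cells`; plus attribute `basin` (matrix of well ranks per
#'   grid cell, `NA` off-support).
#' @export
find_wells <- function(fel, min_depth = 0.5, min_population = 0.01) {
  dg <- fel$deltaG
  nx <- nrow(dg); ny <- ncol(dg)
  defined <- which(!is.na(dg))
  if (!length(defined)) stop("landscape has no defined cells")
  ord <- defined[order(dg[defined])]
  basin <- matrix(NA_integer_, nx, ny)
  basin_min <- numeric()     # deltaG at each basin's minimum
  basin_alive <- logical()   # FALSE once merged into another
  parent <- integer()
  find_root <- function(b) { while (parent[b] != b) b <- parent[b]; b }
  for (cell in ord) {
    i <- (cell - 1L) %% nx + 1L
    j <- (cell - 1L) %/% nx + 1L
    nb_i <- pmax(1L, i - 1L):pmin(nx, i + 1L)
    nb_j <- pmax(1L, j - 1L):pmin(ny, j + 1L)
    nb <- basin[nb_i, nb_j]
    nb <- unique(nb[!is.na(nb)])
    nb <- unique(vapply(nb, find_root, integer(1)))
    if (!length(nb)) {
      b <- length(basin_min) + 1L
      basin_min[b] <- dg[cell]
      parent[b] <- b
      basin_alive[b] <- TRUE
      basin[i, j] <- b
    } else if (length(nb) == 1L) {
      basin[i, j] <- nb
    } else {
      deepest <- nb[which.min(basin_min[nb])]
      for (b in setdiff(nb, deepest)) {
        if (dg[cell] - basin_min[b] < min_depth) {
          parent[b] <- deepest
          basin_alive[b] <- FALSE
        }
      }
      basin[i, j] <- deepest
    }
  }
  roots <- vapply(basin[!is.na(basin)], find_root, integer(1))
  basin[!is.na(basin)] <- roots
  alive <- sort(unique(roots))
  # basin occupancy by the underlying sample
  z <- fel$points_z
  gi <- pmin(pmax(findInterval(z[, 1], fel$zx), 1L), nx)
  gj <- pmin(pmax(findInterval(z[, 2], fel$zy), 1L), ny)
  frame_basin <- basin[cbind(gi, gj)]
  pop <- vapply(alive, function(b)
    sum(frame_basin == b, na.rm = TRUE) / nrow(z), numeric(1))
  keep <- alive[pop >= min_population]
  if (!length(keep)) keep <- alive[which.max(pop)]
  basin[!basin %in% keep] <- NA_integer_
  ranks <- keep[order(basin_min[keep])]
  wells <- do.call(rbind, lapply(seq_along(ranks), function(rk) {
    b <- ranks[rk]
    cells <- which(basin == b)
    mcell <- cells[which.min(dg[cells])]
    mi <- (mcell - 1L) %% nx + 1L
    mj <- (mcell - 1L) %/% nx + 1L
    data.frame(rank = rk, R1 = fel$x[mi], R2 = fel$y[mj],
               deltaG = dg[mcell], n_cells = length(cells),
               population = pop[match(b, alive)])
  }))
  remap <- match(basin, ranks)
  basin_rank <- matrix(remap, nx, ny)
  structure(list(wells = wells, basin = basin_rank, fel = fel),
            class = "fel_wells")
}

#' @export
print.fel_wells <- function(x, ...) {
  cat(sprintf("fel_wells: %d well(s)\n", nrow(x$wells)))
  print(x$wells)
  invisible(x)
}

#' Frames belonging to the deepest well
#'
#' Maps each frame's standardised reaction-coordinate pair to its grid cell
#' and collects the frames whose cell belongs to the basin of the global
#' minimum. The representative conformation is the frame closest to the
#' minimum in standardised coordinates.
#'
#' @param wells a `fel_wells` object from [find_wells()].
#' @param rank well rank to extract (default 1, the global minimum).
#' @return list with `frames` (indices), `representative` (frame index),
#'   `fraction` (share of all frames in the basin).
#' @export
deepest_well_members <- function(wells, rank = 1L) {
  fel <- wells$fel
  z <- fel$points_z
  gi <- pmin(pmax(findInterval(z[, 1], fel$zx), 1L), length(fel$zx))
  gj <- pmin(pmax(findInterval(z[, 2], fel$zy), 1L), length(fel$zy))
  in_basin <- !is.na(wells$basin[cbind(gi, gj)]) &
    wells$basin[cbind(gi, gj)] == rank
  frames <- which(in_basin)
  if (!length(frames)) stop("no frames fall inside the requested basin")
  w <- wells$wells[wells$wells$rank == rank, ]
  zmin <- c((w$R1 - fel$center[1]) / fel$scale[1],
            (w$R2 - fel$center[2]) / fel$scale[2])
  dz <- sqrt((z[frames, 1] - zmin[1])^2 + (z[frames, 2] - zmin[2])^2)
  list(frames = frames, representative = frames[which.min(dz)],
       fraction = length(frames) / nrow(z))
}
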