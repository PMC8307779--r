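write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full ensemble-analysis pipeline
#'
#' Executes the standard analysis sequence on a set of replica ensembles:
#' superposition on the initial conformation, equilibration removal,
#' descriptors (RMSD, RMSF, Rg, SASA), secondary-structure assignment,
#' interactions (contact map, H-bonds, hydrophobic contacts),
#' ensemble-based clustering, free-energy landscapes for the coordinate
#' pairs (RMSD, Rg), (Hfp, Rg) and (SASA, Rg) on the concatenated frames,
#' and per-residue Markov models compared across replicas by Fisher-Rao
#' distances with a 2D multidimensional-scaling embedding. All tables are
#' written as TSV under `output_dir` with a JSON manifest of parameters
#' and seeds, so a rerun with the same config reproduces every output.
#'
#' @param ensembles list of replica `conf_ensemble`s (shared topology).
#' @param config list of parameters: `equilibration_frames` (default 0),
#'   `cluster_r` (Angstrom, default 4), `cluster_seed` (default 1),
#'   `cluster_stride` (default 1), `temperature_K` (default 310), `knn_k`
#'   (default `NULL` = `ceiling(sqrt(N))`), `grid_nx`/`grid_ny` (default
#'   100), `min_well_depth` (kcal/mol, default 0.5), `contact_cutoff`
#'   (default 10), `hbond_dist`/`hbond_angle` (3.6 / 120),
#'   `hydrophobic_cutoff` (4), `segments` (pseudo-rigid anchor spans),
#'   `segment_min_occurrence` (0.80), `sasa_points` (default 240),
#'   `markov_alpha` (0.5), `markov_lag` (1).
#' @param output_dir directory for TSV outputs and the manifest.
#' @param groups optional replica group labels (for the embedding table).
#' @return (invisibly) list with the computed objects: `descriptors`,
#'   `tracks`, `contacts`, `clustering`, `fels`, `wells`,
#'   `distance_matrix`, `mds`, `manifest`.
#' @export
run_pipeline <- function(ensembles, config = list(), output_dir,
                         groups = NULL) {
  if (!length(ensembles)) stop("input stage: no replicas supplied")
  cfg <- modifyList(list(equilibration_frames = 0L, cluster_r = 4,
                         cluster_seed = 1L, cluster_stride = 1L,
                         temperature_K = 310, knn_k = NULL,
                         grid_nx = 100L, grid_ny = 100L,
                         min_well_depth = 0.5, contact_cutoff = 10,
                         hbond_dist = 3.6, hbond_angle = 120,
                         hydrophobic_cutoff = 4,
                         segments = list(c(699, 709), c(754, 764),
                                         c(731, 733)),
                         segment_min_occurrence = 0.80,
                         sasa_points = 240L, markov_alpha = 0.5,
                         markov_lag = 1L),
                    config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  labels <- vapply(seq_along(ensembles), function(i)
    ensembles[[i]]$label %||% paste0("rep", i), character(1))

  ensembles <- stage("fit", lapply(ensembles, function(e)
    drop_equilibration(superpose(e), cfg$equilibration_frames)))
  merged <- stage("concatenate", concatenate(ensembles))

  desc <- stage("descriptors", {
    per <- lapply(ensembles, function(e) {
      data.frame(replica = e$label,
                 frame = seq_len(n_frames(e)),
                 rmsd = as.numeric(rmsd_series(e)),
                 rg = as.numeric(radius_of_gyration(e)),
                 sasa = as.numeric(sasa(e, n_sphere_points = cfg$sasa_points)))
    })
    do.call(rbind, per)
  })
  write_tsv(desc, file.path(output_dir, "descriptors.tsv"))
  rmsf <- stage("rmsf", rmsf_per_residue(merged))
  write_tsv(data.frame(resno = as.integer(names(rmsf)),
                       rmsf = as.numeric(rmsf)),
            file.path(output_dir, "rmsf.tsv"))

  tracks <- stage("dssp", lapply(ensembles, assign_dssp))
  for (i in seq_along(tracks))
    write_ss_track(tracks[[i]],
                   file.path(output_dir, paste0("ss_", labels[i], ".tsv")))

  contacts <- stage("contacts", {
    cm <- contact_map(merged, cutoff = cfg$contact_cutoff)
    hb <- hydrogen_bonds(merged, dist_cutoff = cfg$hbond_dist,
                         angle_cutoff = cfg$hbond_angle)
    hp <- hydrophobic_contacts(merged, cutoff = cfg$hydrophobic_cutoff)
    seg <- segment_contacts(rbind(hb, hp), cfg$segments,
                            cfg$segment_min_occurrence)
    list(map = cm, hbonds = hb, hydrophobic = hp, segment = seg)
  })
  resno <- as.integer(rownames(contacts$map))
  idx <- which(upper.tri(contacts$map) & !is.na(contacts$map),
               arr.ind = TRUE)
  write_tsv(data.frame(res_i = resno[idx[, 1]], res_j = resno[idx[, 2]],
                       frequency = contacts$map[idx]),
            file.path(output_dir, "contact_map.tsv"))
  write_tsv(rbind(contacts$hbonds, contacts$hydrophobic),
            file.path(output_dir, "interactions.tsv"))

  clust <- stage("cluster", cluster_ensemble(merged, r = cfg$cluster_r,
                                             seed = cfg$cluster_seed,
                                             stride = cfg$cluster_stride))
  write_tsv(data.frame(frame = clust$frames, cluster = clust$cluster,
                       rmsd_to_reference = clust$rmsd_to_reference),
            file.path(output_dir, "clusters.tsv"))

  fels <- stage("fel", {
    rg <- radius_of_gyration(merged)
    rmsd <- rmsd_series(merged)
    hfp <- helical_fraction(do.call(rbind, lapply(tracks, unclass)) |>
                              ss_track(resno = attr(tracks[[1]], "resno")))
    sas <- desc$sasa
    pairs <- list(RMSD_Rg = list(RMSD = as.numeric(rmsd), Rg = as.numeric(rg)),
                  Hfp_Rg = list(Hfp = as.numeric(hfp), Rg = as.numeric(rg)),
                  SASA_Rg = list(SASA = as.numeric(sas), Rg = as.numeric(rg)))
    lapply(pairs, free_energy_landscape, temperature = cfg$temperature_K,
           k = cfg$knn_k, grid_size = c(cfg$grid_nx, cfg$grid_ny))
  })
  wells <- stage("wells", lapply(fels, find_wells,
                                 min_depth = cfg$min_well_depth))
  for (nm in names(fels)) {
    grid <- expand.grid(R1 = fels[[nm]]$x, R2 = fels[[nm]]$y)
    grid$deltaG <- as.vector(fels[[nm]]$deltaG)
    write_tsv(grid[!is.na(grid$deltaG), ],
              file.path(output_dir, paste0("fel_", nm, ".tsv")))
    write_tsv(wells[[nm]]$wells,
              file.path(output_dir, paste0("wells_", nm, ".tsv")))
  }

  tmats <- stage("markov", lapply(tracks, transition_matrices,
                                  alpha = cfg$markov_alpha,
                                  lag = cfg$markov_lag))
  D <- stage("fisher_rao", replica_distance_matrix(tmats))
  write_tsv(data.frame(replica = rownames(D), as.data.frame(D)),
            file.path(output_dir, "fisher_rao.tsv"))
  emb <- stage("mds", classical_mds(D, dims = 2))
  write_tsv(data.frame(replica = rownames(D),
                       group = groups %||% NA,
                       x = emb$points[, 1],
                       y = if (ncol(emb$points) >= 2) emb$points[, 2] else 0,
                       stress = emb$stress),
            file.path(output_dir, "mds.tsv"))

  manifest <- list(package_version = as.character(utils::packageVersion("enscape")),
                   replicas = labels, groups = groups,
                   n_frames = vapply(ensembles, n_frames, integer(1)),
                   parameters = cfg[!vapply(cfg, is.null, logical(1))],
                   fel_pairs = names(fels),
                   n_clusters = length(clust$references),
                   n_wells = vapply(wells, function(w) nrow(w$wells),
                                    integer(1)),
                   outputs = list.files(output_dir))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(descriptors = desc, tracks = tracks, contacts = contacts,
                 clustering = clust, fels = fels, wells = wells,
                 distance_matrix = D, mds = emb, manifest = manifest))
}
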