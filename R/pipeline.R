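# Condition-comparison pipeline: PBC cleanup -> RMSD -> clustering ->
# centroid extraction -> density -> RDF layouts (+ normalisation to the
# control) -> order parameters -> volumes (+ percent change vs control) ->
# pore / site / gate geometry on the centroid frame, with a comparative
# report. Stages are isolated: a failing stage is recorded and the pipeline
# continues with the independent stages.

#' Locate the leaflet planes from the phosphate density profile
#'
#' Returns the z positions of the two highest well-separated peaks of the
#' phosphate density (at least `min_separation` nm apart), sorted; the
#' default inter-leaflet bounds for the trapped-gas volume. Peak-based
#' rather than midplane-based so it tolerates the membrane sitting off
#' the box center after protein-centered PBC cleanup.
#'
#' @param traj an `md_trajectory`.
#' @param phosphate_group index group of the phosphate atoms.
#' @param n_bins density bins (default 100).
#' @param min_separation minimum peak separation (nm, default 1).
#' @export
leaflet_bounds_from_density <- function(traj, phosphate_group, n_bins = 100,
                                        min_separation = 1) {
  prof <- density_profile(traj, phosphate_group, n_bins = n_bins)
  if (max(prof$density) == 0) {
    stop("leaflet_bounds_from_density: no phosphate density")
  }
  i1 <- which.max(prof$density)
  away <- abs(prof$z - prof$z[i1]) >= min_separation
  if (!any(away) || max(prof$density[away]) == 0) {
    stop("leaflet_bounds_from_density: only one phosphate peak found")
  }
  i2 <- which(away)[which.max(prof$density[away])]
  sort(c(prof$z[i1], prof$z[i2]))
}

.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.stage <- function(state, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(ok = TRUE, value = force(expr)),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  dt <- proc.time()[["elapsed"]] - t0
  message(sprintf("[hyperbar] %-28s %s (%.1fs)", name,
                  if (res$ok) "ok" else paste("FAILED:", res$value), dt))
  state$log[[name]] <- list(stage = name, ok = res$ok,
                            error = if (res$ok) NULL else res$value)
  state$values[[name]] <- if (res$ok) res$value else NULL
  state
}

.default_params <- function() {
  list(cluster_cutoff = 0.5, window_fraction = 0.5, n_bins = 100,
       r_max = 3.4, bin_width = 0.02, stride = 5, chain = "A",
       n_windows = 4, bulk = "slab",
       probe_molecule = 0.14, probe_gas = 0.6,
       grid_molecule = 0.07, grid_gas = 0.1)
}

#' Run the full condition-comparison pipeline
#'
#' @param config list with elements:
#'   \describe{
#'     \item{conditions}{named list; each element is either a
#'       [synth_spec()] or a list with `gro` (path) and optionally `ndx`.}
#'     \item{control}{name of the control condition (required when
#'       normalisation is on; default "control" when present).}
#'     \item{normalize}{normalise layouts / volumes to the control
#'       (default TRUE when more than one condition).}
#'     \item{outdir}{output directory (created).}
#'     \item{params}{overrides of the analysis parameters; all conditions
#'       are compared on the same matched parameters.}
#'   }
#' @return (invisibly) list with per-condition results, the stage log and
#'   the output directory. Writes TSV tables, JSON metrics, centroid PDBs
#'   and `report.md` into `outdir`; outputs are deterministic given the
#'   condition seeds.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$conditions) || length(config$conditions) == 0) {
    stop("run_pipeline: config$conditions must name at least one condition")
  }
  cn <- names(config$conditions)
  if (is.null(cn) || any(!nzchar(cn))) stop("run_pipeline: conditions must be named")
  normalize <- if (!is.null(config$normalize)) config$normalize else length(cn) > 1
  control <- config$control
  if (is.null(control) && "control" %in% cn) control <- "control"
  if (normalize && (is.null(control) || !control %in% cn)) {
    stop("run_pipeline: normalisation requested but no condition named '",
         if (is.null(control)) "control" else control, "' exists")
  }
  params <- utils::modifyList(.default_params(), config$params %||% list())
  outdir <- config$outdir %||% stop("run_pipeline: config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  for (nm in cn) {
    message("[hyperbar] == condition: ", nm, " ==")
    results[[nm]] <- .run_condition(config$conditions[[nm]], nm, params, outdir)
  }
  # cross-condition tables
  if (normalize) {
    ctrl <- results[[control]]
    for (nm in setdiff(cn, control)) {
      cond <- results[[nm]]
      if (!is.null(cond$values$layout_water) && !is.null(ctrl$values$layout_water)) {
        norm <- normalize_layout(cond$values$layout_water, ctrl$values$layout_water)
        .write_tsv(norm, file.path(outdir, paste0("layout_norm_water_", nm, ".tsv")))
        results[[nm]]$values$layout_norm_water <- norm
      }
    }
  }
  vol_tab <- do.call(rbind, lapply(cn, function(nm) {
    v <- results[[nm]]$values$volumes
    if (is.null(v)) return(NULL)
    cbind(condition = nm, v)
  }))
  if (!is.null(vol_tab) && normalize) {
    ref <- vol_tab[vol_tab$condition == control, c("group", "volume")]
    refv <- ref$volume[match(vol_tab$group, ref$group)]
    ok <- !is.na(refv) & refv != 0
    vol_tab$pct_change <- NA_real_
    vol_tab$pct_change[ok] <- round_half_away(
      percent_change(vol_tab$volume[ok], refv[ok]), 2)
  }
  if (!is.null(vol_tab)) .write_tsv(vol_tab, file.path(outdir, "volumes.tsv"))
  clus_tab <- do.call(rbind, lapply(cn, function(nm) {
    s <- results[[nm]]$values$cluster$summary
    if (is.null(s)) return(NULL)
    data.frame(condition = nm, total_frames = s$total_frames,
               n_clusters = s$n_clusters,
               p_biggest = s$p_biggest_printed,
               first_ps = s$biggest_first, middle_ps = s$biggest_middle,
               last_ps = s$biggest_last)
  }))
  if (!is.null(clus_tab)) .write_tsv(clus_tab, file.path(outdir, "cluster_summary.tsv"))
  .write_report(outdir, cn, results, clus_tab, vol_tab)
  invisible(list(results = results, outdir = outdir,
                 volumes = vol_tab, clusters = clus_tab))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_condition <- function(cond, nm, params, outdir) {
  state <- list(log = list(), values = list())
  state <- .stage(state, "load", {
    if (inherits(cond, "synth_spec")) {
      build_system(cond)
    } else if (!is.null(cond$gro)) {
      traj <- read_gro(cond$gro)
      list(trajectory = traj, map = NULL, spec = NULL,
           groups = list(protein = index_group(
             "protein", traj$topology$serial[nzchar(traj$topology$chain)])))
    } else stop("condition must be a synth_spec or carry a 'gro' path")
  })
  sys <- state$values$load
  if (is.null(sys)) return(state)
  traj <- sys$trajectory
  groups <- sys$groups

  if (!is.null(sys$map)) {
    state <- .stage(state, "pbc_cleanup", pbc_cleanup(traj, sys$map))
    if (!is.null(state$values$pbc_cleanup)) traj <- state$values$pbc_cleanup
  }

  state <- .stage(state, "rmsd", {
    rs <- rmsd_series(traj, groups$protein)
    .write_tsv(rs, file.path(outdir, paste0("rmsd_", nm, ".tsv")))
    rs
  })
  state <- .stage(state, "cluster", {
    cl <- cluster_trajectory(traj, groups$protein,
                             cutoff = params$cluster_cutoff,
                             window_fraction = params$window_fraction)
    write_pdb(cl$centroid_frame, traj$topology,
              file.path(outdir, paste0("centroid_", nm, ".pdb")))
    cl
  })
  centroid <- state$values$cluster$centroid_frame %||% traj$frames[[n_frames(traj)]]

  state <- .stage(state, "density", {
    for (gn in c("gas", "lipids", "protein")) {
      if (is.null(groups[[gn]])) next
      prof <- density_profile(traj, groups[[gn]], n_bins = params$n_bins)
      .write_tsv(prof, file.path(outdir, paste0("density_", gn, "_", nm, ".tsv")))
    }
    TRUE
  })

  windows <- if (inherits(cond, "synth_spec")) synth_windows(cond, params$n_windows)
  else make_windows(min(frame_times(traj)),
                    diff(range(frame_times(traj))) / (2 * params$n_windows - 1),
                    diff(range(frame_times(traj))) / (2 * params$n_windows - 1),
                    max(frame_times(traj)))
  bulk_slab <- if (inherits(cond, "synth_spec")) cond$bulk_slab else NULL
  bulk <- if (is.null(bulk_slab)) "box" else params$bulk
  for (sp in c("water", "gas")) {
    if (is.null(groups[[sp]])) next
    state <- .stage(state, paste0("layout_", sp), {
      lay <- rdf_layout(traj, params$chain, groups[[sp]], windows,
                        r_max = params$r_max, bin_width = params$bin_width,
                        stride = params$stride, bulk = bulk,
                        bulk_slab = bulk_slab)
      .write_tsv(lay, file.path(outdir, paste0("layout_", sp, "_", nm, ".tsv")))
      lay
    })
  }

  if (!is.null(groups$lipids)) {
    state <- .stage(state, "order", {
      cd <- chain_definition(sn1 = paste0("CA", seq_len(sys$spec$n_carbons %||% 18)),
                             sn2 = paste0("CB", seq_len(sys$spec$n_carbons %||% 18)))
      op <- order_parameter(traj, cd)
      .write_tsv(op, file.path(outdir, paste0("order_", nm, ".tsv")))
      op
    })
  }

  # membrane bounds from the phosphate peaks of the (cleaned) trajectory;
  # used as the gas-bubble slab and the pore z-range
  memb_bounds <- if (!is.null(groups$phosphate)) {
    tryCatch(leaflet_bounds_from_density(traj, groups$phosphate),
             error = function(e) NULL)
  } else NULL

  state <- .stage(state, "volumes", {
    rows <- list()
    for (gn in c("lipids", "protein")) {
      if (is.null(groups[[gn]])) next
      v <- excluded_volume(centroid, groups[[gn]], traj$topology,
                           probe_radius = params$probe_molecule,
                           grid_spacing = params$grid_molecule)
      rows[[gn]] <- data.frame(group = gn, probe = v$probe_radius,
                               volume = v$volume)
    }
    if (!is.null(groups$gas) && !is.null(memb_bounds)) {
      v <- gas_phase_volume(centroid, groups$gas, traj$topology, memb_bounds,
                            probe_radius = params$probe_gas,
                            grid_spacing = params$grid_gas)
      rows$gas <- data.frame(group = "gas_bubble", probe = v$probe_radius,
                             volume = v$volume)
    }
    do.call(rbind, rows)
  })

  state <- .stage(state, "pore_site_gate", {
    top <- traj$topology
    zr <- if (!is.null(memb_bounds)) memb_bounds else {
      mid <- traj$frames[[1]]$box[3] / 2; c(mid - 2, mid + 2)
    }
    pore <- pore_profile(centroid, groups$protein, top, zr)
    if (nrow(pore$profile)) {
      .write_tsv(pore$profile, file.path(outdir, paste0("pore_", nm, ".tsv")))
    }
    site <- tryCatch(site_geometry(centroid,
                                   select_atoms(top, name = "OD1",
                                                resnum = c(606, 598)), top),
                     error = function(e) NULL)
    gate <- tryCatch(gate_distance(centroid, top), error = function(e) NULL)
    metrics <- list(
      pore_min_radius_nm = if (nrow(pore$profile)) min(pore$profile$radius) else NA,
      pore_extent_z_nm = pore$extent_z, pore_extent_x_nm = pore$extent_x,
      site_sides_A = site$sides, site_diagonals_A = site$diagonals,
      site_diagonal_ratio = site$diagonal_ratio,
      site_crossing_angle_deg = site$crossing_angle_deg,
      gate_distance_A = gate$distance, gate_state = gate$state
    )
    jsonlite::write_json(metrics, file.path(outdir, paste0("metrics_", nm, ".json")),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
    metrics
  })
  state
}

.write_report <- function(outdir, cn, results, clus_tab, vol_tab) {
  lines <- c("# Condition comparison report", "",
             paste0("Conditions: ", paste(cn, collapse = ", ")), "")
  if (!is.null(clus_tab)) {
    lines <- c(lines, "## Cluster summary", "",
               paste(utils::capture.output(print(clus_tab, row.names = FALSE)),
                     collapse = "\n"), "")
  }
  if (!is.null(vol_tab)) {
    lines <- c(lines, "## Volumes (rolling probe)", "",
               paste(utils::capture.output(print(vol_tab, row.names = FALSE)),
                     collapse = "\n"), "")
  }
  for (nm in cn) {
    bad <- Filter(function(s) !s$ok, results[[nm]]$log)
    lines <- c(lines,
               sprintf("## %s", nm),
               sprintf("- stages run: %d, failed: %d", length(results[[nm]]$log),
                       length(bad)),
               vapply(bad, function(s) sprintf("- FAILED %s: %s", s$stage, s$error),
                      character(1)),
               "")
  }
  writeLines(lines, file.path(outdir, "report.md"))
}
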