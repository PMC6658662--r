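# Z-axis mass-density profiles and per-residue RDF solvation layouts.

.AMU_PER_NM3_TO_KG_M3 <- 1.66053906660  # 1 amu/nm^3 in kg/m^3

#' Mass-density profile along the Z axis
#'
#' Histogram of group mass along z in absolute box coordinates: per frame,
#' each atom's mass accumulates into the bin containing its wrapped z; the
#' per-bin masses are averaged over frames and divided by the bin slab
#' volume, giving kg m^-3.
#'
#' @param traj an `md_trajectory` (all frames must share the box to 1e-6).
#' @param group an [index_group()] over the trajectory's topology.
#' @param n_bins number of z bins (default 100).
#' @return data.frame of class `density_profile` with columns `z` (bin
#'   centers, nm) and `density` (kg m^-3); group name and bin width attached
#'   as attributes.
#' @export
density_profile <- function(traj, group, n_bins = 100) {
  top <- traj$topology
  idx <- .resolve_group(group, top)
  if (length(idx) == 0) stop("density_profile: empty group")
  box <- traj$frames[[1]]$box
  for (f in traj$frames) {
    if (max(abs(f$box - box)) > 1e-6) {
      stop("density_profile: frames do not share a common box")
    }
  }
  if (any(box <= 0)) stop("density_profile: degenerate box")
  dz <- box[3] / n_bins
  mass <- top$mass[idx]
  acc <- numeric(n_bins)
  for (f in traj$frames) {
    z <- f$xyz[idx, 3] %% box[3]
    bin <- pmin(floor(z / dz) + 1L, n_bins)
    s <- rowsum(mass, bin)
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s[, 1]
  }
  mean_mass <- acc / n_frames(traj)
  slab_vol <- box[1] * box[2] * dz
  out <- data.frame(z = (seq_len(n_bins) - 0.5) * dz,
                    density = .AMU_PER_NM3_TO_KG_M3 * mean_mass / slab_vol)
  attr(out, "group") <- if (inherits(group, "index_group")) group$name else "custom"
  attr(out, "bin_width") <- dz
  attr(out, "box") <- box
  class(out) <- c("density_profile", "data.frame")
  out
}

#' Total mass implied by a density profile (mass-conservation check)
#' @param profile a `density_profile`.
#' @return total mass in amu.
#' @export
profile_total_mass <- function(profile) {
  box <- attr(profile, "box")
  dz <- attr(profile, "bin_width")
  sum(profile$density) * box[1] * box[2] * dz / .AMU_PER_NM3_TO_KG_M3
}

#' Radial distribution function g(r)
#'
#' Image-minimum pair histogram between a reference and a target group,
#' normalised by the ideal-gas shell expectation: g(r) = <count in
#' [r, r+dr)> / (4 pi r_mid^2 dr rho), with rho the target number density
#' N_target / V averaged over frames and r_mid the bin center. Pairs sharing
#' one atom (identical serial) are excluded.
#'
#' @param traj an `md_trajectory` (use [subset_frames()] for windows).
#' @param reference_group,target_group index groups.
#' @param r_max maximum distance (nm); must not exceed half the smallest box
#'   edge (no silent truncation).
#' @param bin_width histogram bin width (nm), default 0.02.
#' @return data.frame of class `rdf_curve` with columns `r` (bin centers)
#'   and `g`.
#' @export
rdf <- function(traj, reference_group, target_group, r_max, bin_width = 0.02) {
  top <- traj$topology
  ridx <- .resolve_group(reference_group, top)
  tidx <- .resolve_group(target_group, top)
  box <- traj$frames[[1]]$box
  if (r_max > min(box) / 2 + 1e-12) {
    stop("rdf: r_max exceeds half the smallest box edge (", min(box) / 2, " nm)")
  }
  n_bins <- ceiling(r_max / bin_width)
  counts <- numeric(n_bins)
  rho_sum <- 0
  rser <- top$serial[ridx]
  tser <- top$serial[tidx]
  for (f in traj$frames) {
    rho_sum <- rho_sum + length(tidx) / prod(f$box)
    rx <- f$xyz[ridx, , drop = FALSE]
    tx <- f$xyz[tidx, , drop = FALSE]
    for (a in seq_along(ridx)) {
      d <- sweep(tx, 2, rx[a, ])
      d <- .min_image(d, f$box)
      dist <- sqrt(rowSums(d * d))
      if (rser[a] %in% tser) dist <- dist[tser != rser[a]]
      dist <- dist[dist < r_max]
      if (length(dist)) {
        counts <- counts + tabulate(floor(dist / bin_width) + 1L, n_bins)
      }
    }
  }
  nf <- n_frames(traj)
  rho <- rho_sum / nf
  r_mid <- (seq_len(n_bins) - 0.5) * bin_width
  shell <- 4 * pi * r_mid^2 * bin_width
  g <- counts / (nf * length(ridx)) / (shell * rho)
  out <- data.frame(r = r_mid, g = g)
  attr(out, "reference") <- if (inherits(reference_group, "index_group")) reference_group$name else "custom"
  attr(out, "target") <- if (inherits(target_group, "index_group")) target_group$name else "custom"
  attr(out, "rho") <- rho
  class(out) <- c("rdf_curve", "data.frame")
  out
}

#' Sampling windows of the form (start, width, gap)
#'
#' Generates closed time intervals [s, s + width], [s + width + gap,
#' s + 2 width + gap], ... up to `t_end`, the windowing used for
#' statistically independent RDF sampling (e.g. 5 ns windows separated by
#' 10 ns gaps over the second half of a run).
#'
#' @param start first window start (ps).
#' @param width window width (ps).
#' @param gap gap between consecutive windows (ps).
#' @param t_end last admissible window end (ps).
#' @return list of length-2 numeric vectors (start, end).
#' @export
make_windows <- function(start, width, gap, t_end) {
  starts <- seq(start, t_end - width, by = width + gap)
  if (length(starts) == 0) stop("make_windows: no complete window fits")
  lapply(starts, function(s) c(s, s + width))
}

#' Per-residue RDF layout along a chain
#'
#' The layout machinery: every `stride`-th C-alpha of the chain (starting at
#' the first resolved residue) serves as a single-atom RDF reference against
#' the target species; each reference's g(r) is computed once per sampling
#' window, averaged (unweighted mean over bins) over `r` in [0, r_max], and
#' the across-window mean and standard error (n-1 denominator) are reported
#' per residue row.
#'
#' @param traj an `md_trajectory`.
#' @param chain chain identifier.
#' @param target_group index group of the target species (e.g. water
#'   oxygens or gas atoms).
#' @param windows list of (start, end) time windows, see [make_windows()];
#'   at least 2 (the standard error is undefined otherwise).
#' @param r_max averaging range upper bound (nm), default 3.4.
#' @param bin_width RDF bin width (nm), default 0.02.
#' @param stride reference stride along the chain (default 5).
#' @param ca_name C-alpha atom name (default "CA").
#' @param bulk one of "box" (target density from the whole box, default) or
#'   "slab" (density from a z sub-region given by `bulk_slab`), the latter
#'   suited to condition-to-condition comparisons because it pins the
#'   normalisation to a membrane-free reference region.
#' @param bulk_slab length-2 z range (nm) used when `bulk = "slab"`.
#' @return data.frame of class `rdf_layout` with columns `chain`, `resnum`,
#'   `mean`, `se`, `n_windows`; the per-window means are attached as the
#'   attribute `window_means` (rows = residues).
#' @export
rdf_layout <- function(traj, chain, target_group, windows, r_max = 3.4,
                       bin_width = 0.02, stride = 5, ca_name = "CA",
                       bulk = c("box", "slab"), bulk_slab = NULL) {
  bulk <- match.arg(bulk)
  if (length(windows) < 2) {
    stop("rdf_layout: need at least 2 windows (standard error undefined)")
  }
  top <- traj$topology
  refs <- select_atoms(top, name = ca_name, chain = chain, stride = stride,
                       group_name = paste0("ca_", chain))
  ref_rows <- .resolve_group(refs, top)
  resnums <- top$resnum[ref_rows]
  tidx <- .resolve_group(target_group, top)
  n_ref <- length(ref_rows)
  wm <- matrix(NA_real_, n_ref, length(windows))
  for (w in seq_along(windows)) {
    sub <- subset_frames(traj, windows[[w]][1], windows[[w]][2])
    rho_scale <- 1
    if (bulk == "slab") {
      stopifnot(length(bulk_slab) == 2)
      box <- sub$frames[[1]]$box
      v_slab <- box[1] * box[2] * (bulk_slab[2] - bulk_slab[1])
      n_slab <- mean(vapply(sub$frames, function(f) {
        z <- f$xyz[tidx, 3] %% f$box[3]
        sum(z >= bulk_slab[1] & z < bulk_slab[2])
      }, numeric(1)))
      rho_slab <- n_slab / v_slab
      rho_box <- length(tidx) / prod(box)
      if (rho_slab <= 0) stop("rdf_layout: empty bulk slab")
      rho_scale <- rho_box / rho_slab  # rescale g from box-density to slab-density norm
    }
    for (i in seq_len(n_ref)) {
      g <- rdf(sub, index_group("ref", top$serial[ref_rows[i]]), target_group,
               r_max = r_max, bin_width = bin_width)
      wm[i, w] <- mean(g$g) * rho_scale
    }
  }
  out <- data.frame(
    chain = chain, resnum = resnums,
    mean = rowMeans(wm),
    se = apply(wm, 1, stats::sd) / sqrt(length(windows)),
    n_windows = length(windows)
  )
  attr(out, "window_means") <- wm
  attr(out, "target") <- if (inherits(target_group, "index_group")) target_group$name else "custom"
  attr(out, "r_max") <- r_max
  class(out) <- c("rdf_layout", "data.frame")
  out
}

#' Normalise an RDF layout to a control condition
#'
#' Row-wise ratio of layout means (condition / control) with first-order
#' error propagation of the standard errors. Rows whose control mean falls
#' below `eps` are flagged and reported as NA rather than divided.
#'
#' @param condition,control `rdf_layout` objects with identical row indexing.
#' @param eps control-mean guard (default 1e-6).
#' @return data.frame of class `rdf_layout_norm` with columns `chain`,
#'   `resnum`, `ratio`, `se`, `flagged`.
#' @export
normalize_layout <- function(condition, control, eps = 1e-6) {
  if (nrow(condition) != nrow(control) ||
      any(condition$resnum != control$resnum) ||
      any(condition$chain != control$chain)) {
    stop("normalize_layout: row indexing of condition and control differ")
  }
  flagged <- control$mean < eps
  ratio <- ifelse(flagged, NA_real_, condition$mean / control$mean)
  se <- ifelse(flagged, NA_real_,
               abs(ratio) * sqrt((condition$se / condition$mean)^2 +
                                 (control$se / control$mean)^2))
  out <- data.frame(chain = condition$chain, resnum = condition$resnum,
                    ratio = ratio, se = se, flagged = flagged)
  class(out) <- c("rdf_layout_norm", "data.frame")
  out
}
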