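# Grid-based rolling-probe (solvent-excluded) volumes.
#
# Algorithm: (a) atoms are dilated by the probe radius (a voxel is blocked
# when its distance to some atom surface is below the probe radius),
# (b) the exterior is flood-filled from the grid boundary through unblocked
# voxels with 6-connectivity, (c) the non-exterior region is eroded by the
# probe radius, (d) the volume is the eroded voxel count times spacing^3,
# united with the vdW-occupied voxels. The erosion uses the continuous
# clearance of each near-surface exterior voxel (distance-to-atom-surface
# minus probe) to correct for lattice offsets, which keeps the systematic
# error of step (c) at O(spacing^2) instead of O(spacing).

# Signed clearance field: min over atoms of |v - x_i| - vdw_i, computed on
# the voxel lattice by local per-atom stamping out to radius
# vdw_i + reach (values beyond remain +Inf).
.clearance_field <- function(coords, vdw, origin, dims, h, reach) {
  dmin <- array(Inf, dim = dims)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ax <- origin[1] + (seq_len(nx) - 1) * h
  ay <- origin[2] + (seq_len(ny) - 1) * h
  az <- origin[3] + (seq_len(nz) - 1) * h
  for (a in seq_len(nrow(coords))) {
    r <- vdw[a] + reach
    i <- which(abs(ax - coords[a, 1]) <= r)
    j <- which(abs(ay - coords[a, 2]) <= r)
    k <- which(abs(az - coords[a, 3]) <= r)
    if (!length(i) || !length(j) || !length(k)) next
    dx2 <- (ax[i] - coords[a, 1])^2
    dy2 <- (ay[j] - coords[a, 2])^2
    dz2 <- (az[k] - coords[a, 3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - vdw[a]
    dmin[i, j, k] <- pmin(dmin[i, j, k], d)
  }
  dmin
}

# Flood-fill the exterior from the grid boundary through `free` voxels
# (6-connectivity), by repeated directional sweeps until a fixed point.
.flood_exterior <- function(free) {
  d <- dim(free)
  E <- array(FALSE, dim = d)
  E[1, , ] <- free[1, , ]; E[d[1], , ] <- free[d[1], , ]
  E[, 1, ] <- E[, 1, ] | free[, 1, ]; E[, d[2], ] <- E[, d[2], ] | free[, d[2], ]
  E[, , 1] <- E[, , 1] | free[, , 1]; E[, , d[3]] <- E[, , d[3]] | free[, , d[3]]
  repeat {
    before <- sum(E)
    for (i in 2:d[1]) E[i, , ] <- E[i, , ] | (E[i - 1, , ] & free[i, , ])
    for (i in (d[1] - 1):1) E[i, , ] <- E[i, , ] | (E[i + 1, , ] & free[i, , ])
    for (j in 2:d[2]) E[, j, ] <- E[, j, ] | (E[, j - 1, ] & free[, j, ])
    for (j in (d[2] - 1):1) E[, j, ] <- E[, j, ] | (E[, j + 1, ] & free[, j, ])
    for (k in 2:d[3]) E[, , k] <- E[, , k] | (E[, , k - 1] & free[, , k])
    for (k in (d[3] - 1):1) E[, , k] <- E[, , k] | (E[, , k + 1] & free[, , k])
    if (sum(E) == before) break
  }
  E
}

#' Rolling-probe (solvent-excluded) volume of an atom group
#'
#' Voxels count toward the volume when they cannot be reached by a probe
#' sphere rolling in from the exterior: atoms are inflated by the probe
#' radius, the exterior is flood-filled from the grid boundary, the
#' non-exterior region is eroded back by the probe radius, and the
#' vdW-occupied voxels are united in. Probe radius 0 degenerates to the
#' vdW-union volume (plus enclosed cavities).
#'
#' @param frame an `md_frame`.
#' @param group an [index_group()].
#' @param topology matching [topology()] (provides per-atom vdW radii;
#'   override with `vdw`).
#' @param probe_radius probe radius in nm (water ~ 0.14).
#' @param grid_spacing voxel edge in nm; must be <= probe_radius / 2
#'   (unrestricted when probe_radius = 0).
#' @param vdw optional per-atom vdW radii overriding the topology's.
#' @return a `volume_result`: list with `group`, `probe_radius`, `volume`
#'   (nm^3), `grid_spacing`, `n_occupied` (vdW voxels), `n_interior`
#'   (total counted voxels), `n_atoms`.
#' @export
excluded_volume <- function(frame, group, topology, probe_radius,
                            grid_spacing = 0.05, vdw = NULL) {
  idx <- .resolve_group(group, topology)
  if (length(idx) == 0) stop("excluded_volume: empty group")
  if (probe_radius > 0 && grid_spacing > probe_radius / 2 + 1e-12) {
    stop("excluded_volume: grid spacing must be <= probe_radius / 2")
  }
  coords <- frame$xyz[idx, , drop = FALSE]
  if (any(coords < -1e-9) || any(sweep(coords, 2, frame$box) > 1e-9)) {
    coords <- sweep(coords, 2, frame$box, function(x, b) x %% b)
  }
  radii <- if (is.null(vdw)) topology$vdw[idx] else rep_len(vdw, length(idx))
  h <- grid_spacing
  pad <- max(radii) + probe_radius + 3 * h
  origin <- apply(coords, 2, min) - pad
  upper <- apply(coords, 2, max) + pad
  dims <- pmax(ceiling((upper - origin) / h) + 1L, 4L)
  dmin <- .clearance_field(coords, radii, origin, dims, h,
                           reach = probe_radius + 3 * h)
  blocked <- dmin < probe_radius
  E <- .flood_exterior(!blocked)
  N <- !E
  occupied <- dmin <= 0

  removed <- array(FALSE, dim = dims)
  if (probe_radius > 0) {
    iface <- which(E & (dmin < probe_radius + 2 * h))
    if (length(iface)) {
      kmax <- ceiling((probe_radius + 2 * h) / h)
      offs <- as.matrix(expand.grid(-kmax:kmax, -kmax:kmax, -kmax:kmax))
      od <- h * sqrt(rowSums(offs^2))
      keep <- od <= probe_radius + 2 * h
      offs <- offs[keep, , drop = FALSE]
      od <- od[keep]
      oo <- order(od)
      offs <- offs[oo, , drop = FALSE]
      od <- od[oo]
      ui <- arrayInd(iface, dims)
      fvals <- dmin[iface] - probe_radius
      nx <- dims[1]; nxy <- dims[1] * dims[2]
      for (q in seq_along(iface)) {
        nmax <- findInterval(probe_radius + fvals[q] + 1e-12, od)
        if (nmax < 1) next
        nb <- offs[seq_len(nmax), , drop = FALSE]
        ii <- nb[, 1] + ui[q, 1]; jj <- nb[, 2] + ui[q, 2]; kk <- nb[, 3] + ui[q, 3]
        ok <- ii >= 1 & ii <= dims[1] & jj >= 1 & jj <= dims[2] &
          kk >= 1 & kk <= dims[3]
        removed[ii[ok] + (jj[ok] - 1L) * nx + (kk[ok] - 1L) * nxy] <- TRUE
      }
    }
  }
  interior <- (N & !removed) | occupied
  structure(list(
    group = if (inherits(group, "index_group")) group$name else "custom",
    probe_radius = probe_radius,
    volume = sum(interior) * h^3,
    grid_spacing = h,
    n_occupied = sum(occupied),
    n_interior = sum(interior),
    n_atoms = length(idx)
  ), class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("volume_result '%s': %.4g nm^3 (probe %.3g nm, grid %.3g nm, %d atoms)\n",
              x$group, x$volume, x$probe_radius, x$grid_spacing, x$n_atoms))
  invisible(x)
}

#' Volume of the continuous gas phase trapped between leaflets
#'
#' Applies [excluded_volume()] to the subset of gas atoms whose z lies
#' within the leaflet bounds, with a large probe (default 0.6 nm) so the
#' continuous pooled phase, not individual atoms, is volumised. An empty
#' slab yields a zero-volume result with a warning; a slab whose volume is
#' consistent with isolated atoms is flagged as non-continuous.
#'
#' @param frame an `md_frame`.
#' @param gas_group index group of gas atoms.
#' @param topology matching topology.
#' @param leaflet_z_bounds length-2 z range (nm) of the inter-leaflet gap.
#' @param probe_radius default 0.6 nm.
#' @param grid_spacing default 0.1 nm.
#' @param vdw gas gridding radius, default 0.14 nm (half the helium
#'   Lennard-Jones sigma of 0.256 nm, rounded up to the tabulated value).
#' @return a `volume_result` with additional fields `n_slab_atoms` and
#'   `continuous`.
#' @export
gas_phase_volume <- function(frame, gas_group, topology, leaflet_z_bounds,
                             probe_radius = 0.6, grid_spacing = 0.1,
                             vdw = 0.14) {
  idx <- .resolve_group(gas_group, topology)
  z <- frame$xyz[idx, 3] %% frame$box[3]
  inside <- z >= leaflet_z_bounds[1] & z <= leaflet_z_bounds[2]
  if (!any(inside)) {
    warning("gas_phase_volume: no gas atoms between the leaflet bounds")
    return(structure(list(group = "gas_slab", probe_radius = probe_radius,
                          volume = 0, grid_spacing = grid_spacing,
                          n_occupied = 0L, n_interior = 0L, n_atoms = 0L,
                          n_slab_atoms = 0L, continuous = FALSE),
                     class = "volume_result"))
  }
  serials <- topology$serial[idx][inside]
  res <- excluded_volume(frame, index_group("gas_slab", serials), topology,
                         probe_radius = probe_radius,
                         grid_spacing = grid_spacing, vdw = vdw)
  single <- 4 / 3 * pi * vdw^3
  res$n_slab_atoms <- sum(inside)
  res$continuous <- res$n_slab_atoms > 1 && res$volume > 3 * single
  res
}

#' Percent change of a value relative to a reference
#'
#' 100 (value - reference) / reference, full precision; reports round it
#' half away from zero to 2 decimals (see [round_half_away()]).
#'
#' @param value,reference numeric; `reference` must be nonzero.
#' @export
percent_change <- function(value, reference) {
  if (any(reference == 0)) stop("percent_change: zero reference")
  100 * (value - reference) / reference
}
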