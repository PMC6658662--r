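# Channel pore profiling and binding-site geometry.
#
# The pore profile replaces a full Voronoi/Delaunay tunnel search with
# slice-wise maximal inscribed circles along a user-given (Z) axis: after
# PBC cleanup and centering the channel is axis-aligned, and the slice
# construction is testable against closed forms.

# clearance of point p = (x, y, z_slice) against all atoms: min over atoms
# of 3D distance minus per-atom vdW radius
.pore_clearance <- function(xy, z, coords, vdw) {
  d <- sqrt((coords[, 1] - xy[1])^2 + (coords[, 2] - xy[2])^2 +
              (coords[, 3] - z)^2)
  min(d - vdw)
}

#' Pore-radius profile by slice-wise maximal inscribed circles
#'
#' For each z slice, finds the in-plane point maximising the clearance
#' r(p) = min over atoms of (3D distance to atom center - vdW radius) by a
#' coarse grid search around the previous slice's center followed by
#' Nelder-Mead refinement. The pore surface is sampled at `n_azimuth`
#' points per slice; extents along Z and X are bounding-box lengths of the
#' surface cloud. After the first slice the center may move at most
#' `max_step` per slice, which keeps the search from escaping sideways
#' through gaps between wall atoms at constrictions. Slices with no atoms
#' within 2 nm of the previous center truncate the profile with a warning.
#'
#' @param frame an `md_frame`.
#' @param group protein atoms bounding the pore.
#' @param topology matching topology (vdW radii).
#' @param z_range length-2 z interval (nm) to profile.
#' @param slice_thickness slice step (nm), default 0.1.
#' @param search_radius half-width of the coarse center search for the
#'   first slice (nm).
#' @param max_step maximum center movement between slices (nm, default 0.25).
#' @param n_azimuth surface points per slice (default 36).
#' @param init_center optional starting (x, y); default: centroid of the
#'   group atoms within the z range.
#' @return a `pore_profile`: list with `profile` (data.frame z, cx, cy,
#'   radius), `surface` (n x 3 matrix), `extent_z`, `extent_x`.
#' @export
pore_profile <- function(frame, group, topology, z_range,
                         slice_thickness = 0.1, search_radius = 0.8,
                         n_azimuth = 36, init_center = NULL, max_step = 0.25) {
  idx <- .resolve_group(group, topology)
  coords <- frame$xyz[idx, , drop = FALSE]
  vdw <- topology$vdw[idx]
  zs <- seq(z_range[1], z_range[2], by = slice_thickness)
  if (length(zs) == 0 ||
      !any(coords[, 3] >= z_range[1] - 1 & coords[, 3] <= z_range[2] + 1)) {
    warning("pore_profile: no atoms near the requested z range; empty profile")
    return(structure(list(profile = data.frame(z = numeric(0), cx = numeric(0),
                                               cy = numeric(0), radius = numeric(0)),
                          surface = matrix(numeric(0), ncol = 3),
                          extent_z = NA_real_, extent_x = NA_real_),
                     class = "pore_profile"))
  }
  in_range <- coords[, 3] >= z_range[1] & coords[, 3] <= z_range[2]
  center <- if (is.null(init_center)) {
    colMeans(coords[if (any(in_range)) in_range else TRUE, 1:2, drop = FALSE])
  } else as.numeric(init_center)
  rows <- list()
  surface <- list()
  grid_step <- min(slice_thickness / 2, max_step / 4)
  first <- TRUE
  for (z in zs) {
    near <- sqrt((coords[, 1] - center[1])^2 + (coords[, 2] - center[2])^2 +
                   (coords[, 3] - z)^2)
    if (min(near) > 2) {
      warning(sprintf("pore_profile: no atoms within 2 nm of center at z = %.3g; profile truncated", z))
      break
    }
    reach <- if (first) search_radius else max_step
    g1 <- seq(-reach, reach, by = grid_step)
    cand <- as.matrix(expand.grid(x = center[1] + g1, y = center[2] + g1))
    vals <- apply(cand, 1, .pore_clearance, z = z, coords = coords, vdw = vdw)
    best <- cand[which.max(vals), ]
    lower <- center - reach; upper <- center + reach
    opt <- stats::optim(best, function(p) -.pore_clearance(p, z, coords, vdw),
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(factr = 1e4, maxit = 200))
    if (-opt$value < max(vals)) opt <- list(par = best, value = -max(vals))
    cx <- opt$par[1]; cy <- opt$par[2]
    r <- max(-opt$value, 0)
    first <- FALSE
    rows[[length(rows) + 1L]] <- data.frame(z = z, cx = cx, cy = cy, radius = r)
    phi <- 2 * pi * (seq_len(n_azimuth) - 1) / n_azimuth
    surface[[length(surface) + 1L]] <- cbind(cx + r * cos(phi),
                                             cy + r * sin(phi),
                                             rep(z, n_azimuth))
    center <- c(cx, cy)
  }
  profile <- do.call(rbind, rows)
  surf <- do.call(rbind, surface)
  structure(list(profile = profile, surface = surf,
                 extent_z = diff(range(surf[, 3])),
                 extent_x = diff(range(surf[, 1]))),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  if (nrow(x$profile) == 0) { cat("pore_profile: empty\n"); return(invisible(x)) }
  cat(sprintf("pore_profile: %d slices, min radius %.3g nm at z = %.3g nm; extent Z %.3g / X %.3g nm\n",
              nrow(x$profile), min(x$profile$radius),
              x$profile$z[which.min(x$profile$radius)], x$extent_z, x$extent_x))
  invisible(x)
}

#' Quadrilateral geometry of a four-atom binding site (XY projection)
#'
#' Projects four selected atoms (e.g. the side-chain OD1 oxygens of the two
#' asparagine pairs lining a divalent-cation site) onto the XY plane, orders
#' the vertices by polar angle about their centroid, and reports side
#' lengths, the two diagonals, the shorter/longer diagonal ratio and the
#' diagonal crossing angle. Lengths are in Angstrom, the convention for
#' printed site distances.
#'
#' @param frame an `md_frame`.
#' @param group index group resolving to exactly four atoms.
#' @param topology matching topology.
#' @return a `site_geometry`: list with `xy` (4 x 2, Angstrom, angular
#'   order), `sides` (length 4), `diagonals` (length 2), `diagonal_ratio`
#'   (in (0, 1]), `crossing_angle_deg`, `degenerate` flag.
#' @export
site_geometry <- function(frame, group, topology) {
  idx <- .resolve_group(group, topology)
  if (length(idx) != 4) {
    stop("site_geometry: selection must resolve to exactly 4 atoms (got ",
         length(idx), ")")
  }
  xy <- frame$xyz[idx, 1:2, drop = FALSE] * 10   # nm -> Angstrom
  cen <- colMeans(xy)
  ord <- order(atan2(xy[, 2] - cen[2], xy[, 1] - cen[1]))
  xy <- xy[ord, ]
  sides <- sqrt(rowSums((xy - xy[c(2, 3, 4, 1), ])^2))
  d1 <- xy[3, ] - xy[1, ]
  d2 <- xy[4, ] - xy[2, ]
  diagonals <- c(sqrt(sum(d1^2)), sqrt(sum(d2^2)))
  degenerate <- FALSE
  for (tri in list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))) {
    a <- xy[tri[2], ] - xy[tri[1], ]; b <- xy[tri[3], ] - xy[tri[1], ]
    if (abs(a[1] * b[2] - a[2] * b[1]) < 1e-9) degenerate <- TRUE
  }
  cosang <- sum(d1 * d2) / (diagonals[1] * diagonals[2])
  ang <- acos(pmin(1, pmax(-1, abs(cosang)))) * 180 / pi
  structure(list(
    xy = xy, sides = sides, diagonals = diagonals,
    diagonal_ratio = min(diagonals) / max(diagonals),
    crossing_angle_deg = ang, degenerate = degenerate
  ), class = "site_geometry")
}

#' Gate distance between the paired C-alpha atoms of a marker residue
#'
#' Euclidean distance (Angstrom) between the C-alpha atoms of one residue
#' on the two opposite subunits, with an open/closed label: "open" when the
#' distance is >= threshold (boundary inclusive).
#'
#' @param frame an `md_frame`.
#' @param topology matching topology.
#' @param resnum marker residue number (default 299).
#' @param chains the subunit pair carrying the marker (default c("A", "C")).
#' @param threshold open/closed threshold in Angstrom; the default 28 sits
#'   between reference open (~33.6) and closed (~23.4) values.
#' @return list with `distance` (Angstrom), `state` ("open"/"closed"),
#'   `threshold`.
#' @export
gate_distance <- function(frame, topology, resnum = 299, chains = c("A", "C"),
                          threshold = 28) {
  grp <- select_atoms(topology, name = "CA", resnum = resnum, chain = chains)
  idx <- .resolve_group(grp, topology)
  if (length(idx) != 2) {
    stop("gate_distance: expected exactly 2 C-alpha atoms for residue ",
         resnum, " on chains ", paste(chains, collapse = "/"),
         " (got ", length(idx), ")")
  }
  d <- sqrt(sum((frame$xyz[idx[1], ] - frame$xyz[idx[2], ])^2)) * 10
  list(distance = d, state = if (d >= threshold) "open" else "closed",
       threshold = threshold)
}

#' Superposition RMSD between one helix in two frames
#'
#' Kabsch-superposes the helix selection of frame B onto frame A and reports
#' the residual RMSD in Angstrom (alignment only; no secondary-structure
#' assignment is attempted).
#'
#' @param frame_a,frame_b `md_frame`s sharing a topology.
#' @param helix_group index group of the helix backbone atoms.
#' @param topology matching topology.
#' @return RMSD in Angstrom.
#' @export
helix_align_rmsd <- function(frame_a, frame_b, helix_group, topology) {
  idx <- .resolve_group(helix_group, topology)
  a <- frame_a$xyz[idx, , drop = FALSE]
  b <- frame_b$xyz[idx, , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("helix_align_rmsd: selection size mismatch")
  kabsch_superpose(b, a)$rmsd * 10
}
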