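# Synthetic membrane/channel/solvent/gas system generator with analytic
# ground truth.
#
# The generator emulates the statistical structure the analyses probe, not
# dynamics: a two-leaflet bilayer slab of united-atom-like acyl chains with
# prescribed orientational order, a four-chain channel placeholder whose
# beads line an analytic pore surface and whose labelling resolves the
# standard selectors (every-5th C-alpha, the gate C-alpha pair, the four
# site OD1 atoms), bulk water beads with a prescribed dehydration factor
# inside a cylindrical shell around the transmembrane domain, and monatomic
# gas placed with a prescribed fraction in the inter-leaflet gap under a
# hard-core exclusion. Frames are independent redraws of a stationary
# ensemble — every analysis in scope is a time average of a stationary
# observable, so no time-correlation structure is generated. This is NOT
# molecular dynamics and must not be mistaken for it.

.GOLDEN <- pi * (3 - sqrt(5))
.CC_BOND <- 0.153
.CC_HALF_ANGLE <- (180 - 111) / 2 * pi / 180  # zig-zag half-angle off the chain axis
.WALL_VDW <- 0.17                             # carbon vdW of the wall beads

#' Specification of a synthetic membrane/channel system
#'
#' All lengths nm, times ps. The defaults are the package's reference study
#' conditions: a 10 x 10 x 20 nm box, 128 lipids with 18-carbon tails and a
#' C9=C10 double bond, target chain order 0.20, a four-chain channel
#' placeholder of 120 residues per chain, 5000 waters, 2000 gas atoms with
#' 90% pooled in the inter-leaflet gap, and 20 independent frames 2 ps
#' apart.
#'
#' @param box box edges (nm).
#' @param leaflet_offset phosphate planes sit at box-center +/- this (nm).
#' @param gap_halfwidth inter-leaflet gas slab half-width about the
#'   membrane center (nm).
#' @param n_lipids total lipid count (split over two leaflets).
#' @param n_carbons carbons per tail.
#' @param sp2_pair indices of the double-bond carbon pair.
#' @param s_target target order parameter, constant over carbons; must lie
#'   in (-0.5, 0.25], the range reachable by a tilted chain axis.
#' @param n_res residues per channel chain (must be < 299, the gate label).
#' @param tmd_frac fraction of residues forming the transmembrane block.
#' @param pore_radius analytic pore radius (nm).
#' @param pore_pinch optional list(z, radius, width) Gaussian constriction.
#' @param gate_sep separation of the two gate C-alpha atoms (nm).
#' @param site_half half-diagonals (x, y) of the OD1 site quadrilateral (nm).
#' @param n_water,n_gas bead counts.
#' @param dehydration water-density multiplier deficit in the TMD shell,
#'   in `[0, 1]`: local density is (1 - dehydration) x bulk.
#' @param f_gap fraction of gas placed in the inter-leaflet slab, in `[0, 1]`.
#' @param gas_sigma gas hard-core contact distance (nm); default 0.256, the
#'   Lennard-Jones sigma of helium.
#' @param n_frames,frame_dt frame count and spacing (ps).
#' @param jitter per-frame Gaussian jitter of protein beads (nm).
#' @param seed RNG seed for [build_system()].
#' @return a `synth_spec` list with derived geometry fields
#'   (`membrane_center`, `leaflet_z`, `tmd_z`, `gap_z`, `shell_radius`,
#'   `shell_z`, `bulk_slab`).
#' @export
synth_spec <- function(box = c(10, 10, 20), leaflet_offset = 1.8,
                       gap_halfwidth = 0.7, n_lipids = 128, n_carbons = 18,
                       sp2_pair = c(9, 10), s_target = 0.20, n_res = 120,
                       tmd_frac = 0.4, pore_radius = 0.8, pore_pinch = NULL,
                       gate_sep = 3.36, site_half = c(0.6, 0.45),
                       n_water = 5000, dehydration = 0, n_gas = 2000,
                       f_gap = 0.9, gas_sigma = 0.256, n_frames = 20,
                       frame_dt = 2, jitter = 0.02, seed = 42) {
  stopifnot(length(box) == 3, all(box > 0),
            f_gap >= 0, f_gap <= 1, dehydration >= 0, dehydration <= 1,
            n_water >= 0, n_gas >= 0, n_lipids >= 0, n_frames >= 1,
            s_target > -0.5, s_target <= 0.25, n_res >= 10, n_res < 299)
  mc <- box[3] / 2
  spec <- list(
    box = box, leaflet_offset = leaflet_offset, gap_halfwidth = gap_halfwidth,
    n_lipids = n_lipids, n_carbons = n_carbons, sp2_pair = sp2_pair,
    s_target = s_target, n_res = n_res, tmd_frac = tmd_frac,
    pore_radius = pore_radius, pore_pinch = pore_pinch, gate_sep = gate_sep,
    site_half = site_half, n_water = n_water, dehydration = dehydration,
    n_gas = n_gas, f_gap = f_gap, gas_sigma = gas_sigma,
    n_frames = n_frames, frame_dt = frame_dt, jitter = jitter, seed = seed,
    membrane_center = mc,
    leaflet_z = c(mc - leaflet_offset, mc + leaflet_offset),
    tmd_z = c(mc - leaflet_offset, mc + leaflet_offset),
    gap_z = c(mc - gap_halfwidth, mc + gap_halfwidth)
  )
  wall_max <- max(.pore_radius_at(spec, seq(spec$tmd_z[1], spec$tmd_z[2],
                                            length.out = 50))) + .WALL_VDW
  spec$shell_radius <- wall_max + 3.5
  spec$shell_z <- spec$tmd_z + c(-3.5, 3.5)
  spec$bulk_slab <- c(box[3] - 2.5, box[3] - 0.5)
  if (n_water > 0 && dehydration > 0 && spec$shell_radius > min(box[1:2]) / 2) {
    warning("synth_spec: dehydration shell is laterally clipped by the box; ",
            "the TMD layout-ratio truth is only approximate")
  }
  class(spec) <- "synth_spec"
  spec
}

# analytic pore radius at height z (vectorised)
.pore_radius_at <- function(spec, z) {
  r <- rep(spec$pore_radius, length(z))
  p <- spec$pore_pinch
  if (!is.null(p)) {
    w <- if (is.null(p$width)) 0.3 else p$width
    r <- r - (spec$pore_radius - p$radius) * exp(-((z - p$z) / w)^2)
  }
  r
}

# chain-axis tilt (rad, from the bilayer normal) realising a target order
# parameter: <cos^2 theta_CH> = sin^2(beta)/2 for a zig-zag chain whose
# hydrogens are perpendicular to its axis and azimuthally uniform.
.tilt_for_order <- function(s_target) {
  asin(sqrt(2 * (2 * s_target + 1) / 3))
}

# deterministic base layout of the channel placeholder
.protein_base <- function(spec) {
  axis_xy <- spec$box[1:2] / 2
  n_tmd <- round(spec$n_res * spec$tmd_frac)
  ecd_z <- c(spec$tmd_z[2] + 0.1, spec$box[3] - 0.6)
  gate_z <- spec$box[3] - 1.0
  chains <- c("A", "B", "C", "D")
  name <- resname <- chain <- character(0)
  resnum <- integer(0)
  xyz <- NULL
  bonds <- NULL
  for (k in seq_along(chains)) {
    phase <- (k - 1) * pi / 2 + 0.3
    start_atom <- length(name)
    for (i in seq_len(spec$n_res)) {
      if (i <= n_tmd) {
        z <- spec$tmd_z[1] + (i - 1) / (n_tmd - 1) * diff(spec$tmd_z)
        az <- phase + (i - 1) * .GOLDEN
        R <- .pore_radius_at(spec, z) + .WALL_VDW
      } else {
        z <- ecd_z[1] + (i - n_tmd - 1) / (spec$n_res - n_tmd - 1) * diff(ecd_z)
        az <- phase + i * 0.5
        R <- 2.0
      }
      xyz <- rbind(xyz, c(axis_xy + R * c(cos(az), sin(az)), z))
      name <- c(name, "CA"); resname <- c(resname, "GLY")
      resnum <- c(resnum, i); chain <- c(chain, chains[k])
    }
    last_reg <- length(name)
    # gate residue pair on the A/C subunits
    if (chains[k] %in% c("A", "C")) {
      sgn <- if (chains[k] == "A") -1 else 1
      xyz <- rbind(xyz, c(axis_xy[1] + sgn * spec$gate_sep / 2, axis_xy[2], gate_z))
      name <- c(name, "CA"); resname <- c(resname, "GLU")
      resnum <- c(resnum, 299L); chain <- c(chain, chains[k])
      bonds <- rbind(bonds, c(last_reg, length(name)))
    }
    # one site OD1 per chain: A/C carry residue 606, B/D residue 598
    corner <- switch(chains[k],
                     A = c(spec$site_half[1], 0), C = c(-spec$site_half[1], 0),
                     B = c(0, spec$site_half[2]), D = c(0, -spec$site_half[2]))
    xyz <- rbind(xyz, c(axis_xy + corner, spec$membrane_center))
    name <- c(name, "OD1"); resname <- c(resname, "ASN")
    resnum <- c(resnum, if (chains[k] %in% c("A", "C")) 606L else 598L)
    chain <- c(chain, chains[k])
    bonds <- rbind(bonds, c(last_reg, length(name)))
    bonds <- rbind(bonds, cbind(start_atom + seq_len(spec$n_res - 1),
                                start_atom + seq_len(spec$n_res - 1) + 1))
  }
  list(xyz = xyz, name = name, resname = resname, resnum = resnum,
       chain = chain, bonds = bonds, n_tmd = n_tmd, ecd_z = ecd_z,
       gate_z = gate_z)
}

# lipid lattice sites, avoiding the channel footprint; one row per lipid:
# x, y, leaflet (1 = lower, 2 = upper)
.lipid_sites <- function(spec) {
  if (spec$n_lipids == 0) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "leaflet"))))
  }
  n_per <- spec$n_lipids / 2
  if (n_per != round(n_per)) stop("synth: n_lipids must be even")
  wall_max <- max(.pore_radius_at(spec, seq(spec$tmd_z[1], spec$tmd_z[2],
                                            length.out = 50))) + .WALL_VDW
  n_side <- ceiling(sqrt(n_per * 1.5))
  gx <- (seq_len(n_side) - 0.5) * spec$box[1] / n_side
  gy <- (seq_len(n_side) - 0.5) * spec$box[2] / n_side
  sites <- as.matrix(expand.grid(x = gx, y = gy))
  keep <- sqrt((sites[, 1] - spec$box[1] / 2)^2 +
                 (sites[, 2] - spec$box[2] / 2)^2) > wall_max + 0.5
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) < n_per) stop("synth: packing error — not enough lattice sites for lipids")
  sites <- sites[seq_len(n_per), , drop = FALSE]
  rbind(cbind(sites, leaflet = 1), cbind(sites, leaflet = 2))
}

# grow the two zig-zag tails of one lipid for one frame; returns
# (2 * n_carbons) x 3 matrix (tail A carbons then tail B)
.grow_tails <- function(head, inward_sign, beta, n_carbons) {
  out <- matrix(NA_real_, 2 * n_carbons, 3)
  for (t in 1:2) {
    start <- head + c((2 * t - 3) * 0.08, 0, 0)
    phi <- stats::runif(1, 0, 2 * pi)
    d <- c(sin(beta) * cos(phi), sin(beta) * sin(phi), inward_sign * cos(beta))
    ref <- if (abs(d[3]) > 0.99) c(1, 0, 0) else c(0, 0, 1)
    e1 <- c(ref[2] * d[3] - ref[3] * d[2], ref[3] * d[1] - ref[1] * d[3],
            ref[1] * d[2] - ref[2] * d[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    psi <- stats::runif(1, 0, 2 * pi)
    lat <- cos(psi) * e1 + sin(psi) * e2
    b_odd <- cos(.CC_HALF_ANGLE) * d + sin(.CC_HALF_ANGLE) * lat
    b_even <- cos(.CC_HALF_ANGLE) * d - sin(.CC_HALF_ANGLE) * lat
    pos <- start
    out[(t - 1) * n_carbons + 1, ] <- pos
    for (k in seq_len(n_carbons - 1)) {
      pos <- pos + .CC_BOND * (if (k %% 2 == 1) b_odd else b_even)
      out[(t - 1) * n_carbons + k + 1, ] <- pos
    }
  }
  out
}

# draw n points from the dehydrated water density (uniform outside the TMD
# shell, (1 - d) x uniform inside) by rejection
.draw_water <- function(n, spec) {
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- max(2 * (n - nrow(out)), 64)
    p <- cbind(stats::runif(m, 0, spec$box[1]), stats::runif(m, 0, spec$box[2]),
               stats::runif(m, 0, spec$box[3]))
    inside <- (sqrt((p[, 1] - spec$box[1] / 2)^2 + (p[, 2] - spec$box[2] / 2)^2)
               <= spec$shell_radius) &
      p[, 3] >= spec$shell_z[1] & p[, 3] <= spec$shell_z[2]
    acc <- stats::runif(m) < ifelse(inside, 1 - spec$dehydration, 1)
    out <- rbind(out, p[acc, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# place n gas atoms (Bernoulli(f_gap) slab vs bulk in z) with a hard core
# enforced under image-minimum distances
.draw_gas <- function(n, spec) {
  out <- matrix(NA_real_, n, 3)
  sig2 <- spec$gas_sigma^2
  box <- spec$box
  in_slab <- stats::runif(n) < spec$f_gap
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:200) {
      z <- if (in_slab[i]) stats::runif(1, spec$gap_z[1], spec$gap_z[2])
      else stats::runif(1, 0, spec$box[3])
      p <- c(stats::runif(1, 0, spec$box[1]), stats::runif(1, 0, spec$box[2]), z)
      if (i > 1) {
        prev <- out[seq_len(i - 1), , drop = FALSE]
        dx <- prev[, 1] - p[1]; dx <- dx - box[1] * round(dx / box[1])
        dy <- prev[, 2] - p[2]; dy <- dy - box[2] * round(dy / box[2])
        dz <- prev[, 3] - p[3]; dz <- dz - box[3] * round(dz / box[3])
        d2 <- dx * dx + dy * dy + dz * dz
        if (min(d2) < sig2) next
      }
      out[i, ] <- p
      placed <- TRUE
      break
    }
    if (!placed) stop("synth: packing error — gas hard-core rejection failed after 200 tries")
  }
  attr(out, "in_slab") <- in_slab
  out
}

#' Build a synthetic system from a specification
#'
#' Deterministic given spec + seed (the global RNG is seeded from
#' `spec$seed`): identical specs produce byte-identical trajectories.
#' Frames are independent redraws of the stationary ensemble described by
#' the spec; see the package vignette for what this does and does not
#' emulate.
#'
#' @param spec a [synth_spec()].
#' @return a `synth_system`: list with `trajectory` (an [trajectory()]),
#'   `map` (a [molecule_map()]), `spec`, and `groups` (index groups
#'   `protein`, `lipids`, `water`, `gas`, `phosphate`).
#' @export
build_system <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  prot <- .protein_base(spec)
  n_prot <- nrow(prot$xyz)
  sites <- .lipid_sites(spec)
  nl <- nrow(sites)
  nc <- spec$n_carbons
  lipid_atoms_per <- 1 + 2 * nc

  # --- topology -------------------------------------------------------------
  lip_name <- c("P", paste0("CA", seq_len(nc)), paste0("CB", seq_len(nc)))
  name <- c(prot$name, rep(lip_name, nl))
  resname <- c(prot$resname, rep("DOPC", nl * lipid_atoms_per))
  resnum <- c(prot$resnum, rep(seq_len(nl), each = lipid_atoms_per))
  chain <- c(prot$chain, rep("", nl * lipid_atoms_per))

  # water count: Bernoulli thinning of the nominal count by the shell deficit
  p_shell <- pi * spec$shell_radius^2 * diff(spec$shell_z) / prod(spec$box)
  n_water_kept <- if (spec$n_water > 0) {
    cand_inside <- stats::runif(spec$n_water) < p_shell
    spec$n_water - sum(cand_inside & (stats::runif(spec$n_water) < spec$dehydration))
  } else 0L

  name <- c(name, rep("OW", n_water_kept), rep("HE", spec$n_gas))
  resname <- c(resname, rep("SOL", n_water_kept), rep("HE", spec$n_gas))
  resnum <- c(resnum, if (n_water_kept) seq_len(n_water_kept) else integer(0),
              if (spec$n_gas) seq_len(spec$n_gas) else integer(0))
  chain <- c(chain, rep("", n_water_kept + spec$n_gas))
  top <- topology(name = name, resname = resname, resnum = resnum, chain = chain)

  # --- molecule map ---------------------------------------------------------
  prot_mol <- match(prot$chain, c("A", "B", "C", "D"))
  lip_mol <- 4L + rep(seq_len(nl), each = lipid_atoms_per)
  rest_mol <- 4L + nl + seq_len(n_water_kept + spec$n_gas)
  bonds <- prot$bonds
  for (l in seq_len(nl)) {
    off <- n_prot + (l - 1) * lipid_atoms_per
    # head -> first carbon of each tail, then consecutive carbons
    bonds <- rbind(bonds,
                   cbind(off + 1L, off + 1L + c(1L, nc + 1L)),
                   cbind(off + 1L + seq_len(nc - 1), off + 2L + seq_len(nc - 1)),
                   cbind(off + 1L + nc + seq_len(nc - 1), off + 2L + nc + seq_len(nc - 1)))
  }
  map <- molecule_map(c(prot_mol, lip_mol, rest_mol), bonds)

  # --- frames ---------------------------------------------------------------
  beta <- .tilt_for_order(spec$s_target)
  frames <- vector("list", spec$n_frames)
  for (fi in seq_len(spec$n_frames)) {
    prot_xyz <- prot$xyz + matrix(stats::rnorm(3 * n_prot, sd = spec$jitter),
                                  n_prot, 3)
    lip_xyz <- matrix(NA_real_, nl * lipid_atoms_per, 3)
    for (l in seq_len(nl)) {
      lf <- sites[l, 3]
      head_z <- spec$leaflet_z[lf] + stats::rnorm(1, sd = 0.05)
      head <- c(sites[l, 1] + stats::rnorm(1, sd = 0.05),
                sites[l, 2] + stats::rnorm(1, sd = 0.05), head_z)
      inward <- if (lf == 2) -1 else 1
      off <- (l - 1) * lipid_atoms_per
      lip_xyz[off + 1, ] <- head
      lip_xyz[off + 1 + seq_len(2 * nc), ] <- .grow_tails(head, inward, beta, nc)
    }
    wat_xyz <- if (n_water_kept > 0) .draw_water(n_water_kept, spec) else matrix(NA_real_, 0, 3)
    gas_xyz <- if (spec$n_gas > 0) .draw_gas(spec$n_gas, spec) else matrix(NA_real_, 0, 3)
    frames[[fi]] <- md_frame(rbind(prot_xyz, lip_xyz, wat_xyz, gas_xyz),
                             spec$box, (fi - 1) * spec$frame_dt)
  }
  traj <- trajectory(top, frames)
  groups <- list(
    protein = index_group("protein", top$serial[nzchar(top$chain)]),
    lipids = index_group("DOPC", top$serial[top$resname == "DOPC"]),
    phosphate = index_group("P", top$serial[top$name == "P"]),
    water = if (n_water_kept > 0) index_group("water", top$serial[top$resname == "SOL"]) else NULL,
    gas = if (spec$n_gas > 0) index_group("gas", top$serial[top$resname == "HE"]) else NULL
  )
  structure(list(trajectory = traj, map = map, spec = spec, groups = groups),
            class = "synth_system")
}

#' @export
print.synth_system <- function(x, ...) {
  cat("synth_system (stationary redraws, not MD):\n  ")
  print(x$trajectory)
  invisible(x)
}

#' Analytic ground truth of a synthetic specification
#'
#' The expectations every estimator is tested against. Purely a function of
#' the spec (no randomness).
#'
#' @param spec a [synth_spec()].
#' @return list with elements `s_ch` (target order parameter), `f_gap` and
#'   `gap_z`, `gap_volume` (nm^3 of the inter-leaflet slab), `tmd_ratio`
#'   (water layout condition/control ratio in TMD rows, = 1 - dehydration
#'   under bulk-slab normalisation), `p_shell`, `tmd_refs` and
#'   `clean_bulk_refs` (residue numbers of every-5th C-alpha references
#'   whose averaging sphere lies entirely inside / outside the dehydration
#'   shell), `pore` (data.frame z, radius), `gate_distance` (Angstrom),
#'   `site` (sides, diagonals, ratio, crossing angle), `bulk_slab`.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n_tmd <- round(spec$n_res * spec$tmd_frac)
  refs <- seq(1, spec$n_res, by = 5)
  ecd_z <- c(spec$tmd_z[2] + 0.1, spec$box[3] - 0.6)
  ref_z <- ifelse(refs <= n_tmd,
                  spec$tmd_z[1] + (refs - 1) / (n_tmd - 1) * diff(spec$tmd_z),
                  ecd_z[1] + (refs - n_tmd - 1) / (spec$n_res - n_tmd - 1) * diff(ecd_z))
  zz <- seq(spec$tmd_z[1], spec$tmd_z[2], by = 0.1)
  p_shell <- pi * spec$shell_radius^2 * diff(spec$shell_z) / prod(spec$box)
  list(
    s_ch = spec$s_target,
    f_gap = spec$f_gap,
    gap_z = spec$gap_z,
    # bulk-placed gas also lands in the gap by chance, so the expected
    # fraction of atoms found inside the slab exceeds f_gap slightly
    slab_fraction_expected = spec$f_gap +
      (1 - spec$f_gap) * diff(spec$gap_z) / spec$box[3],
    gap_volume = spec$box[1] * spec$box[2] * diff(spec$gap_z),
    dehydration = spec$dehydration,
    tmd_ratio = 1 - spec$dehydration,
    p_shell = p_shell,
    tmd_refs = refs[refs <= n_tmd],
    clean_bulk_refs = refs[refs > n_tmd & ref_z >= spec$shell_z[2] + 3.5],
    ref_z = stats::setNames(ref_z, refs),
    pore = data.frame(z = zz, radius = .pore_radius_at(spec, zz)),
    gate_distance = spec$gate_sep * 10,
    site = list(
      sides = rep(sqrt(spec$site_half[1]^2 + spec$site_half[2]^2) * 10, 4),
      diagonals = sort(2 * spec$site_half * 10, decreasing = TRUE),
      diagonal_ratio = min(spec$site_half) / max(spec$site_half),
      crossing_angle_deg = 90
    ),
    bulk_slab = spec$bulk_slab
  )
}

#' Contiguous sampling windows covering a synthetic trajectory
#'
#' Splits the frames into `n` equal contiguous blocks and returns their
#' closed time ranges, the windowing used for across-window standard
#' errors on independently redrawn frames.
#'
#' @param spec a [synth_spec()] (or a trajectory).
#' @param n number of windows (default 4).
#' @export
synth_windows <- function(spec, n = 4) {
  nf <- if (inherits(spec, "synth_spec")) spec$n_frames else n_frames(spec)
  dt <- if (inherits(spec, "synth_spec")) spec$frame_dt else diff(frame_times(spec))[1]
  per <- nf %/% n
  if (per < 1) stop("synth_windows: fewer frames than windows")
  lapply(seq_len(n), function(k) {
    c((k - 1) * per, (k - 1) * per + per - 1) * dt
  })
}
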