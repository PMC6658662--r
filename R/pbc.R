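# Periodic-boundary cleanup: the three trjconv-style transforms applied, in
# order, before any structural analysis: make molecules whole, center a
# group, pack molecules compactly around the box center. All three are pure
# coordinate transforms on a single frame and preserve image-minimum
# pairwise geometry.

# Minimum-image displacement r (n x 3) under a rectangular box.
.min_image <- function(r, box) {
  for (d in 1:3) r[, d] <- r[, d] - box[d] * round(r[, d] / box[d])
  r
}

#' Minimum-image distance between two points
#' @param a,b coordinates (length 3).
#' @param box rectangular box edges (nm).
#' @export
min_image_dist <- function(a, b, box) {
  d <- .min_image(matrix(b - a, ncol = 3), box)
  sqrt(sum(d * d))
}

# adjacency list from a bond matrix, for atoms `atoms` (topology rows)
.adjacency <- function(atoms, bonds) {
  adj <- vector("list", length(atoms))
  pos <- match(seq_len(max(atoms)), atoms)
  for (k in seq_len(nrow(bonds))) {
    i <- pos[bonds[k, 1]]; j <- pos[bonds[k, 2]]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Make molecules whole across periodic boundaries
#'
#' Starting from each molecule's lowest-index atom (the anchor), traverses
#' the bond graph breadth-first and shifts every neighbour by the lattice
#' vector that minimises the bond length, so that afterwards no bond crosses
#' the boundary: every bond's direct length equals its image-minimum length.
#' Applying it to an already-whole frame is the identity.
#'
#' @param frame an `md_frame`.
#' @param map a [molecule_map()].
#' @return the repaired `md_frame`.
#' @export
make_whole <- function(frame, map) {
  xyz <- frame$xyz
  box <- frame$box
  mols <- split(seq_along(map$molecule), map$molecule)
  if (nrow(map$bonds) > 0) {
    bond_mol <- map$molecule[map$bonds[, 1]]
    bonds_by_mol <- split(seq_len(nrow(map$bonds)), bond_mol)
  } else {
    bonds_by_mol <- list()
  }
  for (mid in names(mols)) {
    atoms <- mols[[mid]]
    if (length(atoms) == 1) next
    bidx <- bonds_by_mol[[mid]]
    if (is.null(bidx)) {
      stop("make_whole: molecule ", mid, " has ", length(atoms),
           " atoms but no bonds (disconnected graph)")
    }
    b <- map$bonds[bidx, , drop = FALSE]
    adj <- .adjacency(atoms, b)
    seen <- logical(length(atoms))
    queue <- 1L            # anchor: lowest-index atom of the molecule
    seen[1L] <- TRUE
    n_seen <- 1L
    while (length(queue)) {
      i <- queue[1L]; queue <- queue[-1L]
      ai <- atoms[i]
      for (j in adj[[i]]) {
        if (seen[j]) next
        aj <- atoms[j]
        d <- .min_image(matrix(xyz[aj, ] - xyz[ai, ], ncol = 3), box)
        xyz[aj, ] <- xyz[ai, ] + d
        seen[j] <- TRUE
        n_seen <- n_seen + 1L
        queue <- c(queue, j)
      }
    }
    if (n_seen != length(atoms)) {
      stop("make_whole: molecule ", mid, " has a disconnected bond graph (",
           n_seen, " of ", length(atoms), " atoms reachable)")
    }
  }
  md_frame(xyz, box, frame$time)
}

#' Center a group in the box
#'
#' Rigidly shifts the whole frame so the unweighted mean position of the
#' group sits at box/2 in every dimension, then wraps all atoms back into
#' \code{[0, box)}. Mirrors `trjconv -center` (geometric, not mass-weighted).
#'
#' @param frame an `md_frame`.
#' @param group an [index_group()] (or integer serials).
#' @param topology topology used to resolve the group.
#' @param wrap wrap atoms into the primary cell after shifting (default TRUE).
#' @export
center_group <- function(frame, group, topology, wrap = TRUE) {
  idx <- .resolve_group(group, topology)
  if (length(idx) == 0) stop("center_group: empty group")
  box <- frame$box
  shift <- box / 2 - colMeans(frame$xyz[idx, , drop = FALSE])
  xyz <- sweep(frame$xyz, 2, shift, "+")
  if (wrap) for (d in 1:3) xyz[, d] <- xyz[, d] %% box[d]
  md_frame(xyz, box, frame$time)
}

#' Pack whole molecules compactly around the box center
#'
#' Each molecule is translated, as a rigid unit, by the lattice vector (one
#' of the 27 nearest images) that minimises the distance of its geometric
#' center to the box center. Molecules must already be whole.
#'
#' @param frame an `md_frame` with whole molecules.
#' @param map a [molecule_map()].
#' @export
compact_pack <- function(frame, map) {
  xyz <- frame$xyz
  box <- frame$box
  center <- box / 2
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  mols <- split(seq_along(map$molecule), map$molecule)
  for (atoms in mols) {
    g <- colMeans(xyz[atoms, , drop = FALSE])
    cand <- sweep(shifts, 2, box, "*")
    d2 <- rowSums((sweep(cand, 2, g - center, "+"))^2)
    best <- cand[which.min(d2), ]
    if (any(best != 0)) {
      xyz[atoms, ] <- sweep(xyz[atoms, , drop = FALSE], 2, best, "+")
    }
  }
  md_frame(xyz, box, frame$time)
}

#' Apply the full periodic-boundary cleanup to every frame
#'
#' make whole -> center group -> compact pack, the standard three-step
#' sequence, applied frame by frame.
#'
#' @param traj an `md_trajectory`.
#' @param map a [molecule_map()].
#' @param center_on group to center on (default: all protein-chain atoms,
#'   i.e. atoms with a nonempty chain id); pass an [index_group()] to
#'   override.
#' @export
pbc_cleanup <- function(traj, map, center_on = NULL) {
  top <- traj$topology
  if (is.null(center_on)) {
    idx <- which(nzchar(top$chain))
    if (length(idx) == 0) idx <- seq_len(nrow(top))
    center_on <- index_group("protein", top$serial[idx])
  }
  frames <- lapply(traj$frames, function(f) {
    f <- make_whole(f, map)
    f <- center_group(f, center_on, top, wrap = FALSE)
    compact_pack(f, map)
  })
  trajectory(top, frames)
}
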