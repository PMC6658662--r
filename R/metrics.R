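# Superposition RMSD and gromos conformational clustering.

# Apply a rigid motion x' = R x + t to an n x 3 coordinate block.
.apply_rigid <- function(xyz, rotation, translation) {
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

#' Round half away from zero
#'
#' Report-level rounding used for printed probabilities and percent changes
#' (base R's round() rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Kabsch weighted least-squares superposition
#'
#' Finds the proper rotation and translation minimising the weighted RMSD
#' between two paired point sets. The returned rotation always has
#' determinant +1 (a reflection in the raw SVD solution is corrected by
#' flipping the smallest singular direction). For degenerate (e.g. collinear)
#' point sets the SVD's own ordering breaks the tie, which keeps the result
#' deterministic.
#'
#' @param mobile,reference n x 3 matrices (n >= 3), nm.
#' @param weights non-negative weights, not all zero (default equal).
#' @return list with `rotation` (3 x 3), `translation` (length 3; the motion
#'   is x' = rotation %*% x + translation), and `rmsd` (nm).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  stopifnot(n >= 3, nrow(reference) == n, ncol(mobile) == 3, ncol(reference) == 3)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("kabsch_superpose: weights must be non-negative and not all zero")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P * w) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cr - as.vector(R %*% cm)
  moved <- .apply_rigid(mobile, R, tr)
  rmsd <- sqrt(sum(w * rowSums((moved - reference)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' RMSD time series against a reference frame
#'
#' Per frame, superposes the fit group onto the reference frame's fit group,
#' applies the fitted rigid motion to the measure group and reports its RMSD
#' from the reference measure-group coordinates, in nm. With the default
#' reference (frame 1) the first value is exactly 0.
#'
#' @param traj an `md_trajectory`.
#' @param fit_group group used for superposition.
#' @param measure_group group the RMSD is computed over (default: fit group).
#' @param reference_frame frame index (1-based) of the reference structure.
#' @param weights optional superposition/measure weights (per fit/measure atom).
#' @return data.frame of class `rmsd_series` with columns `time` (ps) and
#'   `rmsd` (nm); groups and reference recorded as attributes.
#' @export
rmsd_series <- function(traj, fit_group, measure_group = fit_group,
                        reference_frame = 1, weights = NULL) {
  top <- traj$topology
  fit_idx <- .resolve_group(fit_group, top)
  mea_idx <- .resolve_group(measure_group, top)
  if (reference_frame < 1 || reference_frame > n_frames(traj)) {
    stop("rmsd_series: reference frame out of range")
  }
  ref <- traj$frames[[reference_frame]]$xyz
  vals <- vapply(traj$frames, function(f) {
    fit <- kabsch_superpose(f$xyz[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE], weights)
    moved <- .apply_rigid(f$xyz[mea_idx, , drop = FALSE],
                          fit$rotation, fit$translation)
    sqrt(mean(rowSums((moved - ref[mea_idx, , drop = FALSE])^2)))
  }, numeric(1))
  out <- data.frame(time = frame_times(traj), rmsd = vals)
  attr(out, "fit_group") <- if (inherits(fit_group, "index_group")) fit_group$name else "custom"
  attr(out, "measure_group") <- if (inherits(measure_group, "index_group")) measure_group$name else "custom"
  attr(out, "reference_frame") <- reference_frame
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Pairwise superposition-RMSD matrix
#'
#' Distance matrix for conformational clustering: entry (i, j) is the
#' least-squares RMSD of frame j's group superposed onto frame i's.
#'
#' @param traj an `md_trajectory`.
#' @param group atoms used for both fitting and measurement.
#' @param weights optional weights.
#' @return symmetric matrix (nm) with zero diagonal.
#' @export
rmsd_matrix <- function(traj, group, weights = NULL) {
  idx <- .resolve_group(group, traj$topology)
  nf <- n_frames(traj)
  coords <- lapply(traj$frames, function(f) f$xyz[idx, , drop = FALSE])
  m <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) {
      for (j in (i + 1):nf) {
        m[i, j] <- m[j, i] <- kabsch_superpose(coords[[j]], coords[[i]],
                                               weights)$rmsd
      }
    }
  }
  m
}

#' Gromos (greedy neighbour-count) conformational clustering
#'
#' Daura-style algorithm: iteratively, the frame with the most neighbours
#' within the cutoff (counting itself) becomes a centroid; it and its
#' neighbours form a cluster and are removed; repeat until no frames remain.
#' Ties in neighbour count are broken toward the lowest frame index.
#' Clusters are reported by descending size (stable for equal sizes).
#'
#' @param dmat symmetric non-negative distance matrix with zero diagonal (nm).
#' @param cutoff neighbour cutoff (nm).
#' @return a `cluster_result`: list with `assignments` (cluster id per frame,
#'   1 = largest), `sizes`, `centroids` (frame index per cluster),
#'   `probabilities` (size / total) and `cutoff`.
#' @export
gromos_cluster <- function(dmat, cutoff) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  stopifnot(n >= 1, ncol(dmat) == n)
  if (anyNA(dmat)) stop("gromos_cluster: NaN/NA in distance matrix")
  if (any(dmat < 0)) stop("gromos_cluster: negative distances")
  if (max(abs(dmat - t(dmat))) > 1e-9) stop("gromos_cluster: matrix not symmetric")
  nb <- dmat <= cutoff
  remaining <- rep(TRUE, n)
  assign_raw <- integer(n)
  centroids_raw <- integer(0)
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    counts <- colSums(nb[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    c_idx <- which.max(counts)       # ties -> lowest frame index
    members <- which(remaining & nb[c_idx, ])
    assign_raw[members] <- k
    centroids_raw[k] <- c_idx
    remaining[members] <- FALSE
  }
  sizes_raw <- tabulate(assign_raw, k)
  ord <- order(-sizes_raw, seq_len(k))   # descending size, stable
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(
    assignments = relabel[assign_raw],
    sizes = sizes_raw[ord],
    centroids = centroids_raw[ord],
    probabilities = sizes_raw[ord] / n,
    cutoff = cutoff
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d frames in %d clusters (cutoff %.3g nm); largest p = %.3g\n",
              sum(x$sizes), length(x$sizes), x$cutoff, x$probabilities[1]))
  invisible(x)
}

#' Summarise a clustering the way comparative run tables report it
#'
#' Emits total frames, number of clusters, the probability of the biggest
#' cluster (and of the others), and the first, middle and last timestamps of
#' the biggest cluster's members, where "middle" is the member at ordinal
#' ceiling(k/2). Printed probabilities are rounded half away from zero to
#' `digits` decimals; full precision is kept alongside.
#'
#' @param result a `cluster_result`.
#' @param frame_times frame timestamps (ps), one per clustered frame.
#' @param digits printed rounding (default 2).
#' @return list with the summary fields.
#' @export
summarize_clusters <- function(result, frame_times, digits = 2) {
  n <- sum(result$sizes)
  stopifnot(length(frame_times) == length(result$assignments))
  members <- sort(frame_times[result$assignments == 1L])
  k <- length(members)
  list(
    total_frames = n,
    n_clusters = length(result$sizes),
    p_biggest = result$probabilities[1],
    p_biggest_printed = round_half_away(result$probabilities[1], digits),
    probabilities = result$probabilities,
    probabilities_printed = round_half_away(result$probabilities, digits),
    biggest_first = members[1],
    biggest_middle = members[ceiling(k / 2)],
    biggest_last = members[k]
  )
}

#' Cluster a trajectory's final window and extract the top centroid frame
#'
#' Convenience wrapper reproducing the standard workflow: restrict to the
#' final fraction of the trajectory (default last 50%), build the pairwise
#' superposition-RMSD matrix over `group`, run [gromos_cluster()], and
#' return the clustering together with the centroid frame of the most
#' probable cluster.
#'
#' @param traj an `md_trajectory` (already PBC-cleaned).
#' @param group fit/measure group for the RMSD matrix.
#' @param cutoff clustering cutoff in nm (default 0.5).
#' @param window_fraction final fraction of frames to cluster (default 0.5).
#' @return list with `result`, `summary`, `centroid_frame` (an `md_frame`),
#'   `window_times`.
#' @export
cluster_trajectory <- function(traj, group, cutoff = 0.5, window_fraction = 0.5) {
  tt <- frame_times(traj)
  t_start <- tt[1] + (1 - window_fraction) * (tt[length(tt)] - tt[1])
  sub <- subset_frames(traj, t_min = t_start)
  dmat <- rmsd_matrix(sub, group)
  res <- gromos_cluster(dmat, cutoff)
  list(
    result = res,
    summary = summarize_clusters(res, frame_times(sub)),
    centroid_frame = sub$frames[[res$centroids[1]]],
    window_times = range(frame_times(sub))
  )
}
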