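# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (explicit loops, no shared code with the package
# internals) so they stay independent of the paths they check.

# n-atom topology of identical beads
bead_topology <- function(n, name = "C", resname = "BEAD", vdw = 0.2,
                          mass = 12, chain = "") {
  topology(name = rep(name, n), resname = resname, resnum = seq_len(n),
           chain = chain, vdw = vdw, mass = mass)
}

# ideal zig-zag (all-anti) carbon chain: axis direction d, in-plane lateral
# unit vector lat, bond angle 111 degrees, bond length 0.153 nm
zigzag_chain <- function(n, d, lat, start = c(0, 0, 0),
                         bond = 0.153, half_angle = (180 - 111) / 2 * pi / 180) {
  d <- d / sqrt(sum(d^2)); lat <- lat / sqrt(sum(lat^2))
  b_odd <- cos(half_angle) * d + sin(half_angle) * lat
  b_even <- cos(half_angle) * d - sin(half_angle) * lat
  out <- matrix(NA_real_, n, 3)
  out[1, ] <- start
  for (k in seq_len(n - 1)) {
    out[k + 1, ] <- out[k, ] + bond * (if (k %% 2 == 1) b_odd else b_even)
  }
  out
}

# single-lipid trajectory whose two tails are prescribed coordinate blocks
one_lipid_traj <- function(tail_a, tail_b = tail_a + 1) {
  n <- nrow(tail_a)
  top <- topology(name = c("P", paste0("CA", 1:n), paste0("CB", 1:n)),
                  resname = "DOPC", resnum = 1, chain = "",
                  element = c("P", rep("C", 2 * n)))
  xyz <- rbind(tail_a[1, ] + c(0, 0, 0.3), tail_a, tail_b)
  trajectory(top, list(md_frame(xyz + 5, c(60, 60, 60), 0)))
}

# naive greedy neighbour-count clustering, recomputing neighbour lists from
# scratch at every iteration
naive_gromos <- function(dmat, cutoff) {
  n <- nrow(dmat)
  left <- seq_len(n)
  assign <- integer(n)
  centroids <- integer(0)
  k <- 0
  while (length(left) > 0) {
    best_i <- NA; best_count <- -1
    for (i in left) {
      count <- 0
      for (j in left) if (dmat[i, j] <= cutoff) count <- count + 1
      if (count > best_count) { best_count <- count; best_i <- i }
    }
    k <- k + 1
    members <- c()
    for (j in left) if (dmat[best_i, j] <= cutoff) members <- c(members, j)
    assign[members] <- k
    centroids[k] <- best_i
    left <- setdiff(left, members)
  }
  sizes <- as.vector(table(factor(assign, levels = seq_len(k))))
  ord <- order(-sizes, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  list(assignments = relab[assign], sizes = sizes[ord], centroids = centroids[ord])
}

# rotation-grid + refinement RMSD oracle, independent of the SVD route:
# coarse search over ZXZ Euler angles followed by Nelder-Mead refinement
grid_search_rmsd <- function(mobile, reference, step_deg = 20) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  rot <- function(ang) {
    cz1 <- cos(ang[1]); sz1 <- sin(ang[1])
    cx <- cos(ang[2]); sx <- sin(ang[2])
    cz2 <- cos(ang[3]); sz2 <- sin(ang[3])
    Rz1 <- rbind(c(cz1, -sz1, 0), c(sz1, cz1, 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Rz2 <- rbind(c(cz2, -sz2, 0), c(sz2, cz2, 0), c(0, 0, 1))
    Rz2 %*% Rx %*% Rz1
  }
  obj <- function(ang) sqrt(mean(rowSums((P %*% t(rot(ang)) - Q)^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, by = step_deg * pi / 180),
                      b = seq(0, pi, by = step_deg * pi / 180),
                      c = seq(0, 2 * pi, by = step_deg * pi / 180))
  vals <- apply(grid, 1, obj)
  best <- as.numeric(grid[which.min(vals), ])
  stats::optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))$value
}

# order parameter of a unit vector against z
p2_z <- function(v) (3 * (v[3] / sqrt(sum(v^2)))^2 - 1) / 2

# small synthetic spec variants used across test files (kept tiny; the
# heavier reference spec lives in the acceptance tests)
tiny_spec <- function(...) {
  synth_spec(n_lipids = 16, n_water = 300, n_gas = 200, n_res = 40,
             n_frames = 6, seed = 123, ...)
}
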