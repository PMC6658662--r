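# analytic cylinder of wall atoms: rings of `per_ring` atoms at radius R
cylinder_frame <- function(R = 1, z_range = c(4, 7), dz = 0.1, per_ring = 24,
                           pinch = NULL, box = c(10, 10, 11), jitter_az = TRUE) {
  zs <- seq(z_range[1], z_range[2], by = dz)
  xyz <- do.call(rbind, lapply(seq_along(zs), function(k) {
    r <- R
    if (!is.null(pinch)) r <- r - (R - pinch$r) * exp(-((zs[k] - pinch$z) / pinch$w)^2)
    phi <- 2 * pi * (seq_len(per_ring) - 1) / per_ring +
      if (jitter_az) k * 0.13 else 0
    cbind(box[1] / 2 + r * cos(phi), box[2] / 2 + r * sin(phi), zs[k])
  }))
  list(frame = md_frame(xyz, box), top = bead_topology(nrow(xyz), vdw = 0.2),
       group = index_group("wall", seq_len(nrow(xyz))))
}

test_that("a perfect cylinder profiles at R - vdW in every slice", {
  cy <- cylinder_frame(R = 1)
  pp <- pore_profile(cy$frame, cy$group, cy$top, z_range = c(4.2, 6.8))
  expect_gt(nrow(pp$profile), 20)
  expect_equal(pp$profile$radius, rep(0.8, nrow(pp$profile)), tolerance = 0.02)
  expect_equal(pp$profile$cx, rep(5, nrow(pp$profile)), tolerance = 0.02)
  # surface points sit at radius(z) from center(z)
  for (k in c(1, nrow(pp$profile))) {
    sl <- pp$surface[pp$surface[, 3] == pp$profile$z[k], ]
    rr <- sqrt((sl[, 1] - pp$profile$cx[k])^2 + (sl[, 2] - pp$profile$cy[k])^2)
    expect_equal(rr, rep(pp$profile$radius[k], nrow(sl)), tolerance = 1e-9)
  }
  # extents are bounding-box lengths of the surface cloud
  expect_equal(pp$extent_x, 2 * 0.8, tolerance = 0.05)
  expect_equal(pp$extent_z, 6.8 - 4.2, tolerance = 1e-9)
})

test_that("a pinched ring creates the profile minimum at the pinch slice", {
  cy <- cylinder_frame(R = 1, pinch = list(z = 5.5, r = 0.5, w = 0.25))
  pp <- pore_profile(cy$frame, cy$group, cy$top, z_range = c(4.2, 6.8))
  k <- which.min(pp$profile$radius)
  expect_equal(pp$profile$z[k], 5.5, tolerance = 0.1)
  expect_equal(min(pp$profile$radius), 0.3, tolerance = 0.04)
})

test_that("profiles are rotation invariant and respond linearly to vdW shrinkage", {
  cy <- cylinder_frame(R = 1)
  th <- 0.6
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- c(5, 5, 0)
  rot <- md_frame(sweep(sweep(cy$frame$xyz, 2, ctr) %*% t(Rz), 2, ctr, "+"),
                  cy$frame$box)
  p1 <- pore_profile(cy$frame, cy$group, cy$top, c(4.5, 6.5))
  p2 <- pore_profile(rot, cy$group, cy$top, c(4.5, 6.5))
  expect_equal(p2$profile$radius, p1$profile$radius, tolerance = 0.02)
  # shrinking vdW by delta grows every slice radius by exactly delta
  top_small <- cy$top
  top_small$vdw <- top_small$vdw - 0.05
  p3 <- pore_profile(cy$frame, cy$group, top_small, c(4.5, 6.5))
  expect_equal(p3$profile$radius - p1$profile$radius,
               rep(0.05, nrow(p1$profile)), tolerance = 1e-3)
})

test_that("an empty z range yields a truncation warning and empty profile", {
  cy <- cylinder_frame(R = 1)
  expect_warning(pp <- pore_profile(cy$frame, cy$group, cy$top, c(20, 21)),
                 "empty profile|truncated")
  expect_equal(nrow(pp$profile), 0)
})

test_that("site geometry reproduces square and rhombus closed forms", {
  sq <- rbind(c(0.5, 0), c(0, 0.5), c(-0.5, 0), c(0, -0.5))  # nm
  mk <- function(xy, z = 0.7) {
    top <- topology(rep("OD1", 4), "ASN", 1:4, vdw = 0.152, mass = 16)
    list(frame = md_frame(cbind(xy + 3, z + runif(4, -0.3, 0.3)), c(6, 6, 6)),
         top = top, g = index_group("site", 1:4))
  }
  set.seed(40)
  s <- mk(sq)
  geo <- site_geometry(s$frame, s$g, s$top)
  expect_equal(geo$sides, rep(sqrt(50), 4), tolerance = 1e-9)   # Angstrom
  expect_equal(geo$diagonal_ratio, 1, tolerance = 1e-9)
  expect_equal(geo$crossing_angle_deg, 90, tolerance = 1e-9)
  expect_false(geo$degenerate)

  rh <- rbind(c(1, 0), c(0, 0.5), c(-1, 0), c(0, -0.5))
  geo2 <- site_geometry(mk(rh)$frame, s$g, s$top)
  expect_equal(sort(geo2$diagonals, decreasing = TRUE), c(20, 10), tolerance = 1e-9)
  expect_equal(geo2$diagonal_ratio, 0.5, tolerance = 1e-9)
  expect_equal(geo2$crossing_angle_deg, 90, tolerance = 1e-9)
  expect_equal(geo2$sides, rep(sqrt(125), 4), tolerance = 1e-9)
})

test_that("site metrics are invariant to rotation, translation and relabeling", {
  set.seed(41)
  xy <- rbind(c(0.9, 0.1), c(0.2, 0.6), c(-0.7, 0.2), c(-0.1, -0.8))
  top <- topology(rep("OD1", 4), "ASN", 1:4, vdw = 0.152, mass = 16)
  fr <- md_frame(cbind(xy + 3, 1), c(6, 6, 6))
  base <- site_geometry(fr, index_group("s", 1:4), top)
  th <- 0.77
  Rz <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  xy2 <- xy %*% t(Rz)
  perm <- c(3, 1, 4, 2)
  fr2 <- md_frame(cbind(xy2[perm, ] + 2.2, 1.5), c(6, 6, 6))
  rot <- site_geometry(fr2, index_group("s", 1:4), top)
  expect_equal(sort(rot$sides), sort(base$sides), tolerance = 1e-9)
  expect_equal(sort(rot$diagonals), sort(base$diagonals), tolerance = 1e-9)
  expect_equal(rot$diagonal_ratio, base$diagonal_ratio, tolerance = 1e-9)
  expect_equal(rot$crossing_angle_deg, base$crossing_angle_deg, tolerance = 1e-6)
  expect_error(site_geometry(fr, index_group("s", 1:3), top), "exactly 4")
})

test_that("gate distance labels open/closed with an inclusive threshold", {
  top <- topology(rep("CA", 2), "GLU", 299, chain = c("A", "C"))
  mk <- function(d) md_frame(rbind(c(2, 2, 2), c(2 + d, 2, 2)), c(10, 10, 10))
  g <- gate_distance(mk(3.36), top)
  expect_equal(g$distance, 33.6, tolerance = 1e-9)
  expect_equal(g$state, "open")
  expect_equal(gate_distance(mk(0), top)$state, "closed")
  expect_equal(gate_distance(mk(3), top, threshold = 30)$state, "open")  # boundary: >= is open
  expect_equal(gate_distance(mk(2.343), top)$state, "closed")
  top_bad <- topology(rep("CA", 2), "GLU", 300, chain = c("A", "C"))
  expect_error(gate_distance(mk(1), top_bad), "empty selection")
})

test_that("helix alignment RMSD is zero for rigid copies and matches the grid oracle", {
  set.seed(42)
  # ideal alpha-helix backbone: rise 1.5 A, 100 degrees per residue, r 2.3 A
  n <- 12
  t <- seq_len(n) * 100 * pi / 180
  helix <- cbind(0.23 * cos(t), 0.23 * sin(t), 0.15 * seq_len(n)) + 3
  top <- topology(rep("CA", n), "ALA", seq_len(n), chain = "A")
  g <- index_group("m4", seq_len(n))
  fa <- md_frame(helix, c(8, 8, 8))
  expect_equal(helix_align_rmsd(fa, fa, g, top), 0, tolerance = 1e-9)
  th <- 1.2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  fb <- md_frame(helix %*% t(Rz) + 0.4, c(8, 8, 8))
  expect_equal(helix_align_rmsd(fa, fb, g, top), 0, tolerance = 1e-9)
  # unwind the last 4 residues by a known seeded perturbation
  bent <- helix
  bent[(n - 3):n, ] <- bent[(n - 3):n, ] + matrix(rnorm(12, sd = 0.08), 4)
  fc <- md_frame(bent %*% t(Rz) + 0.2, c(8, 8, 8))
  got <- helix_align_rmsd(fa, fc, g, top)
  want <- grid_search_rmsd(fc$xyz, fa$xyz) * 10
  expect_equal(got, want, tolerance = 1e-3)
})
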