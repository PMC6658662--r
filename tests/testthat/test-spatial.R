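test_that("density profile puts a point mass in one bin and conserves mass", {
  top <- bead_topology(10, mass = 12)
  xyz <- cbind(runif(10, 0, 4), runif(10, 0, 4), rep(2, 10))
  traj <- trajectory(top, list(md_frame(xyz, c(4, 4, 4), 0)))
  prof <- density_profile(traj, index_group("all", 1:10), n_bins = 8)
  nz <- which(prof$density > 0)
  expect_length(nz, 1)
  expect_equal(prof$z[nz], 2.25)            # bin [2, 2.5) center
  slab_vol <- 4 * 4 * 0.5
  expect_equal(prof$density[nz], 1.66053906660 * 120 / slab_vol)
  expect_equal(profile_total_mass(prof), 120, tolerance = 1e-6)
})

test_that("uniform gas gives a flat profile within binomial error bounds", {
  set.seed(10)
  n <- 4000
  top <- bead_topology(n, mass = 4)
  frames <- lapply(1:3, function(k) {
    md_frame(matrix(runif(3 * n, 0, 10), n), c(10, 10, 10), k)
  })
  traj <- trajectory(top, frames)
  prof <- density_profile(traj, index_group("all", 1:n), n_bins = 20)
  expected <- 1.66053906660 * 4 * n / 1000
  p <- 1 / 20
  se <- 1.66053906660 * 4 * sqrt(3 * n * p * (1 - p)) / 3 / (10 * 10 * 0.5)
  expect_true(all(abs(prof$density - expected) < 3.5 * se))
  expect_equal(profile_total_mass(prof), 4 * n, tolerance = 1e-6)
})

test_that("a generated gas slab integrates >= 99% of its mass inside the slab", {
  spec <- synth_spec(box = c(8, 8, 40), gap_halfwidth = 5, n_lipids = 0,
                     n_water = 0, n_gas = 1500, f_gap = 1, n_res = 20,
                     n_frames = 3, seed = 77)
  sys <- build_system(spec)
  prof <- density_profile(sys$trajectory, sys$groups$gas, n_bins = 80)
  inside <- prof$z >= spec$gap_z[1] & prof$z <= spec$gap_z[2]
  expect_gte(sum(prof$density[inside]) / sum(prof$density), 0.99)
})

test_that("rdf matches an all-pairs histogram oracle and its closed forms", {
  set.seed(11)
  n <- 60
  top <- bead_topology(n, mass = 4)
  frames <- lapply(1:3, function(k) {
    md_frame(matrix(runif(3 * n, 0, 6), n), c(6, 6, 6), k)
  })
  traj <- trajectory(top, frames)
  got <- rdf(traj, index_group("ref", 1:10), index_group("tgt", 11:n),
             r_max = 2.9, bin_width = 0.1)
  counts <- numeric(29)
  for (f in frames) for (i in 1:10) for (j in 11:n) {
    d <- f$xyz[j, ] - f$xyz[i, ]
    d <- d - 6 * round(d / 6)
    dd <- sqrt(sum(d * d))
    if (dd < 2.9) counts[floor(dd / 0.1) + 1] <- counts[floor(dd / 0.1) + 1] + 1
  }
  rmid <- (1:29 - 0.5) * 0.1
  oracle <- counts / (3 * 10) / (4 * pi * rmid^2 * 0.1 * ((n - 10) / 216))
  expect_equal(got$g, oracle, tolerance = 1e-12)
  expect_error(rdf(traj, index_group("ref", 1:10), index_group("tgt", 11:n),
                   r_max = 3.5), "half the smallest box edge")
})

test_that("ideal-gas rdf is 1 within Poisson bounds and invariant to translation/wrapping", {
  set.seed(12)
  n <- 1200
  top <- bead_topology(n, mass = 4)
  xyz <- matrix(runif(3 * n, 0, 8), n)
  traj <- trajectory(top, list(md_frame(xyz, c(8, 8, 8), 0)))
  ref <- index_group("ref", 1:20)
  tgt <- index_group("tgt", 21:n)
  g <- rdf(traj, ref, tgt, r_max = 3.5, bin_width = 0.1)
  rho <- (n - 20) / 512
  lam <- 20 * 4 * pi * g$r^2 * 0.1 * rho     # expected counts per bin
  expect_true(all(abs(g$g - 1) < 3.5 / sqrt(lam) + 0.02))
  # global translation + wrapping leaves g unchanged
  xyz2 <- sweep(xyz, 2, c(3.3, -1.7, 5.1), "+") %% 8
  traj2 <- trajectory(top, list(md_frame(xyz2, c(8, 8, 8), 0)))
  g2 <- rdf(traj2, ref, tgt, r_max = 3.5, bin_width = 0.1)
  expect_equal(g2$g, g$g, tolerance = 1e-9)
})

test_that("a single pair at fixed separation lands the closed-form spike", {
  top <- bead_topology(2, mass = 4)
  d <- 1.23
  traj <- trajectory(top, list(md_frame(rbind(c(2, 2, 2), c(2 + d, 2, 2)),
                                        c(8, 8, 8), 0)))
  g <- rdf(traj, index_group("r", 1), index_group("t", 2),
           r_max = 3, bin_width = 0.1)
  hit <- which(g$g > 0)
  expect_length(hit, 1)
  expect_equal(g$r[hit], 1.25)
  rho <- 1 / 512
  expect_equal(g$g[hit], 1 / (4 * pi * 1.25^2 * 0.1 * rho))
})

test_that("hard exclusion forces g = 0 below the contact distance", {
  spec <- synth_spec(box = c(6, 6, 6), gap_halfwidth = 3, n_lipids = 0,
                     n_water = 0, n_gas = 400, f_gap = 0, n_res = 20,
                     n_frames = 2, seed = 13, leaflet_offset = 1)
  sys <- build_system(spec)
  gas <- sys$groups$gas
  g <- rdf(sys$trajectory, gas, gas, r_max = 1, bin_width = 0.02)
  expect_true(all(g$g[g$r < spec$gas_sigma - 0.01] == 0))
  expect_gt(mean(g$g[g$r > 0.5]), 0.5)
})

test_that("layout rows are exchangeable for a species uniform around every residue", {
  spec <- synth_spec(n_lipids = 0, n_gas = 0, n_water = 2500, n_res = 60,
                     n_frames = 8, dehydration = 0, seed = 14)
  sys <- build_system(spec)
  lay <- rdf_layout(sys$trajectory, "A", sys$groups$water,
                    synth_windows(spec, 4), bulk = "slab",
                    bulk_slab = spec$bulk_slab)
  # one row per every-5th C-alpha-bearing residue of the chain (the chain
  # carries its regular residues plus the gate marker residue)
  top <- sys$trajectory$topology
  n_ca <- sum(top$name == "CA" & top$chain == "A")
  expect_equal(nrow(lay), ceiling(n_ca / 5))
  # all rows equal within ~3 SE (water is uniform; no depletion anywhere)
  pooled <- mean(lay$mean)
  expect_true(all(abs(lay$mean - pooled) < 4 * pmax(lay$se, 1e-3)))
  expect_error(rdf_layout(sys$trajectory, "A", sys$groups$water,
                          synth_windows(spec, 4)[1], bulk = "slab",
                          bulk_slab = spec$bulk_slab), "at least 2 windows")
})

test_that("gas pooled in the membrane gap elevates TMD rows over distal rows", {
  spec <- synth_spec(n_lipids = 0, n_water = 0, n_gas = 1200, f_gap = 0.95,
                     n_res = 120, n_frames = 8, seed = 15)
  sys <- build_system(spec)
  gt <- ground_truth(spec)
  lay <- rdf_layout(sys$trajectory, "A", sys$groups$gas, synth_windows(spec, 4))
  tmd <- lay$mean[lay$resnum %in% gt$tmd_refs]
  far <- lay$mean[lay$resnum %in% gt$clean_bulk_refs]
  expect_gt(min(tmd), max(far))
})

test_that("across-window standard errors shrink roughly as 1/sqrt(n_windows)", {
  # fixed window width (2 frames), 3 vs 12 windows of a stationary system:
  # the standard error of the across-window mean should halve
  ratios <- vapply(c(21, 22, 23), function(seed) {
    spec <- synth_spec(n_lipids = 0, n_gas = 0, n_water = 1200, n_res = 40,
                       n_frames = 24, seed = seed)
    sys <- build_system(spec)
    w12 <- synth_windows(spec, 12)
    se_k <- function(w) {
      lay <- rdf_layout(sys$trajectory, "A", sys$groups$water, w,
                        bulk = "slab", bulk_slab = spec$bulk_slab)
      mean(lay$se)
    }
    se_k(w12[1:3]) / se_k(w12)
  }, numeric(1))
  expect_equal(mean(ratios), 2, tolerance = 0.25)
})

test_that("layout normalisation is exact on identity and guards tiny controls", {
  spec <- tiny_spec()
  sys <- build_system(spec)
  lay <- rdf_layout(sys$trajectory, "A", sys$groups$water, synth_windows(spec, 3))
  nrm <- normalize_layout(lay, lay)
  expect_equal(nrm$ratio, rep(1, nrow(lay)))
  expect_equal(nrm$se, sqrt(2) * lay$se / lay$mean, tolerance = 1e-9)
  ctrl <- lay
  ctrl$mean[3] <- 1e-9
  nrm2 <- normalize_layout(lay, ctrl)
  expect_true(nrm2$flagged[3])
  expect_true(is.na(nrm2$ratio[3]))
  bad <- lay[-1, ]
  expect_error(normalize_layout(bad, lay), "row indexing")
})
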