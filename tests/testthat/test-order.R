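test_that("hydrogen reconstruction rejects collinear carbons", {
  expect_error(reconstruct_hydrogens(c(0, 0, -0.15), c(0, 0, 0), c(0, 0, 0.15)),
               "collinear")
})

test_that("reconstructed hydrogens obey ideal tetrahedral geometry on an all-anti backbone", {
  # zig-zag in the xz-plane, chain axis along x
  ch <- zigzag_chain(5, d = c(1, 0, 0), lat = c(0, 0, 1))
  h <- reconstruct_hydrogens(ch[1, ], ch[2, ], ch[3, ])
  vr <- (h$proR - ch[2, ]) / 0.109
  vs <- (h$proS - ch[2, ]) / 0.109
  # C-H vectors are perpendicular to the chain axis with symmetric +/- y
  expect_equal(vr[1], 0, tolerance = 1e-9)
  expect_equal(vs[1], 0, tolerance = 1e-9)
  expect_equal(vr[2], -vs[2], tolerance = 1e-9)
  expect_equal(vr[3], vs[3], tolerance = 1e-9)
  # unit length and opposite triple-product signs
  expect_equal(sqrt(sum(vr^2)), 1, tolerance = 1e-9)
  v1 <- ch[1, ] - ch[2, ]; v2 <- ch[3, ] - ch[2, ]
  trip <- function(h) det(rbind(v1, v2, h - ch[2, ]))
  expect_gt(trip(h$proR), 0)
  expect_lt(trip(h$proS), 0)
})

test_that("mirror-imaging the carbons swaps the pro-R and pro-S labels", {
  set.seed(20)
  for (rep in 1:5) {
    tri <- matrix(rnorm(9), 3)
    h <- reconstruct_hydrogens(tri[1, ], tri[2, ], tri[3, ])
    m <- tri; m[, 1] <- -m[, 1]             # reflect through the yz-plane
    hm <- reconstruct_hydrogens(m[1, ], m[2, ], m[3, ])
    flip <- function(p) { p[1] <- -p[1]; p }
    expect_equal(hm$proR, flip(h$proS), tolerance = 1e-9)
    expect_equal(hm$proS, flip(h$proR), tolerance = 1e-9)
  }
})

test_that("sp2 carbons get a single in-plane hydrogen shared by both labels", {
  tri <- rbind(c(0, 0, 0), c(0.13, 0.05, 0), c(0.26, 0, 0))
  h <- reconstruct_hydrogens(tri[1, ], tri[2, ], tri[3, ], kind = "sp2")
  expect_equal(h$proR, h$proS)
  expect_equal(h$proR[3], 0, tolerance = 1e-12)  # in the carbon plane
  expect_gt(h$proR[2], tri[2, 2])                # exterior bisector
})

test_that("order parameter hits its closed-form limits exactly", {
  # chain axis along the normal: both C-H vectors perpendicular -> S = -1/2
  tr <- one_lipid_traj(zigzag_chain(18, d = c(0, 0, 1), lat = c(1, 0, 0)),
                       zigzag_chain(18, d = c(0, 0, 1), lat = c(0, 1, 0)) + 1)
  op <- order_parameter(tr, chain_definition(sp2 = character(0)))
  expect_equal(op$proR_mean, rep(-0.5, nrow(op)), tolerance = 1e-12)
  expect_equal(op$proS_mean, rep(-0.5, nrow(op)), tolerance = 1e-12)

  # axis perpendicular to the normal, zig-zag plane containing the normal:
  # both C-H vectors sit at the magic angle -> S = 0
  tr0 <- one_lipid_traj(zigzag_chain(18, d = c(1, 0, 0), lat = c(0, 0, 1)))
  op0 <- order_parameter(tr0, chain_definition(sp2 = character(0)))
  expect_equal(op0$proR_mean, rep(0, nrow(op0)), tolerance = 1e-12)
  expect_equal(op0$proS_mean, rep(0, nrow(op0)), tolerance = 1e-12)

  # plane tilted so one geminal hydrogen is parallel to the normal -> S = 1
  lat <- c(0, sqrt(2), -1) / sqrt(3)
  tr1 <- one_lipid_traj(zigzag_chain(18, d = c(1, 0, 0), lat = lat))
  op1 <- order_parameter(tr1, chain_definition(sp2 = character(0)))
  best <- pmax(op1$proR_mean, op1$proS_mean)
  expect_equal(best, rep(1, nrow(op1)), tolerance = 1e-9)
  # and every reported value respects the hard range
  all_s <- c(op$proR_mean, op0$proR_mean, op1$proR_mean, op1$proS_mean)
  expect_true(all(all_s >= -0.5 - 1e-12 & all_s <= 1 + 1e-12))
})

test_that("isotropic chain orientations give S near zero", {
  set.seed(21)
  nlip <- 150
  tails <- lapply(seq_len(nlip), function(i) {
    z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
    d <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    ref <- if (abs(d[3]) > 0.99) c(1, 0, 0) else c(0, 0, 1)
    e1 <- ref - sum(ref * d) * d; e1 <- e1 / sqrt(sum(e1^2))
    psi <- runif(1, 0, 2 * pi)
    e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    zigzag_chain(10, d, cos(psi) * e1 + sin(psi) * e2,
                 start = runif(3, 10, 40))
  })
  n <- 10
  top_one <- function(i) topology(
    name = c("P", paste0("CA", 1:n), paste0("CB", 1:n)), resname = "DOPC",
    resnum = i, element = c("P", rep("C", 2 * n)))
  tops <- do.call(rbind, lapply(seq_len(nlip), top_one))
  tops$serial <- seq_len(nrow(tops))
  class(tops) <- c("topology", "data.frame")
  xyz <- do.call(rbind, lapply(tails, function(tl) {
    rbind(tl[1, ] + c(0, 0, 0.3), tl, tl + 0.5)
  }))
  traj <- trajectory(tops, list(md_frame(xyz, c(60, 60, 60), 0)))
  op <- order_parameter(traj, chain_definition(sn1 = paste0("CA", 1:n),
                                               sn2 = paste0("CB", 1:n),
                                               sp2 = character(0)))
  nsamp <- nlip * 2                      # independent orientations per carbon
  expect_true(all(abs(c(op$proR_mean, op$proS_mean)) < 3 / sqrt(nsamp) + 0.05))
})

test_that("the profile is invariant under rotation about the normal and mirror-swapped by reflection", {
  spec <- synth_spec(n_lipids = 32, n_water = 0, n_gas = 0, n_res = 20,
                     n_frames = 3, seed = 22)
  sys <- build_system(spec)
  cd <- chain_definition()
  op <- order_parameter(sys$trajectory, cd)
  th <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot_frames <- lapply(sys$trajectory$frames, function(f) {
    md_frame(f$xyz %*% t(Rz), f$box, f$time)
  })
  op_rot <- order_parameter(trajectory(sys$trajectory$topology, rot_frames), cd)
  expect_equal(op_rot$proR_mean, op$proR_mean, tolerance = 1e-12)
  expect_equal(op_rot$proS_mean, op$proS_mean, tolerance = 1e-12)
  # reflection through a plane containing the normal swaps the columns
  mir_frames <- lapply(sys$trajectory$frames, function(f) {
    x <- f$xyz; x[, 1] <- -x[, 1]; md_frame(x, f$box, f$time)
  })
  op_mir <- order_parameter(trajectory(sys$trajectory$topology, mir_frames), cd)
  expect_equal(op_mir$proR_mean, op$proS_mean, tolerance = 1e-12)
  expect_equal(op_mir$proS_mean, op$proR_mean, tolerance = 1e-12)
})

test_that("a missing chain atom is reported with lipid and atom name", {
  spec <- synth_spec(n_lipids = 8, n_water = 0, n_gas = 0, n_res = 20,
                     n_frames = 2, seed = 23)
  sys <- build_system(spec)
  expect_error(order_parameter(sys$trajectory,
                               chain_definition(sn1 = paste0("CA", 1:19))),
               "missing chain atom CA19")
})
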