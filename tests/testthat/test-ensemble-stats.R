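test_that("radius of gyration matches closed-form cases", {
  two <- point_atoms(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two, selection = 1:2), 1)
  same <- point_atoms(matrix(0, 4, 3))
  expect_equal(radius_of_gyration(same, selection = 1:4), 0)
  square <- point_atoms(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)))
  expect_equal(radius_of_gyration(square, selection = 1:4), sqrt(2) / 2)
  expect_error(radius_of_gyration(two, selection = integer(0)), "empty")
})

test_that("Rg is rigid-motion invariant and scales linearly", {
  conf <- hairpin20()
  rg <- radius_of_gyration(conf)
  R <- random_rotation_seeded(4)
  moved <- conformation(conf$topology, sweep(conf$xyz %*% t(R), 2, 5, "+"))
  expect_equal(radius_of_gyration(moved), rg, tolerance = 1e-12)
  doubled <- conformation(conf$topology, conf$xyz * 2)
  expect_equal(radius_of_gyration(doubled), 2 * rg, tolerance = 1e-12)
  # mass weighting: a heavy atom pulls the center of mass
  mixed <- point_atoms(rbind(c(0, 0, 0), c(1, 0, 0)), element = c("C", "S"))
  mS <- 32.06; mC <- 12.011
  cm <- mS / (mS + mC)
  expect_equal(radius_of_gyration(mixed, selection = 1:2),
               sqrt((mC * cm^2 + mS * (1 - cm)^2) / (mC + mS)))
})

test_that("free-energy surfaces follow -RT ln P", {
  # two bins with 3:1 occupancy at 310 K differ by RT ln 3
  f <- fes2d(c(0.25, 0.25, 0.25, 0.75), c(0.5, 0.5, 0.5, 0.5),
             xbreaks = c(0, 0.5, 1), ybreaks = c(0, 1),
             temperature_K = 310)
  expect_equal(max(f$G, na.rm = TRUE), 1.987e-3 * 310 * log(3),
               tolerance = 1e-9)
  expect_equal(min(f$G, na.rm = TRUE), 0)
  # uniform occupancy: all-zero shifted surface
  u <- fes2d(rep(1:4 / 4, 2), rep(c(0.2, 0.8), each = 4),
             xbreaks = seq(0, 1, 0.25), ybreaks = c(0, 0.5, 1))
  expect_true(all(abs(u$G[!is.na(u$G)]) < 1e-12))
  # all samples in one bin: that bin 0, others masked
  s <- fes2d(rep(0.1, 5), rep(0.1, 5), xbreaks = c(0, 0.5, 1),
             ybreaks = c(0, 0.5, 1))
  expect_equal(s$G[1, 1], 0)
  expect_equal(sum(is.na(s$G)), 3)
  # round-trip: re-exponentiation recovers the histogram
  withr::with_seed(6, {
    x <- stats::rnorm(500); y <- stats::rnorm(500)
  })
  g <- fes2d(x, y, bins = 8, temperature_K = 310)
  P2 <- exp(-(g$G + g$shift) / (g$R * g$temperature_K))
  P2[is.na(P2)] <- 0
  expect_equal(P2, g$P, tolerance = 1e-9)
  expect_error(fes2d(rep(1, 3), rep(2, 3)), "zero-width")
  expect_error(fes2d(numeric(0), numeric(0)), "nonempty")
})

test_that("basin detection finds planted minima and applies depth filtering", {
  # single quadratic well
  xm <- seq(-1, 1, length.out = 21)
  ym <- seq(-1, 1, length.out = 21)
  G1 <- outer(xm^2, ym^2, "+")
  mk_grid <- function(G) {
    structure(list(G = G - min(G), P = exp(-G), xbreaks = NULL,
                   ybreaks = NULL, xmid = xm, ymid = ym,
                   temperature_K = 310, R = 1.987e-3, shift = 0),
              class = "fes_grid")
  }
  b1 <- find_basins(mk_grid(G1), depth_threshold = 0.1)
  expect_equal(nrow(b1), 1)
  expect_equal(c(b1$x_center, b1$y_center), c(0, 0))
  # two Gaussian wells across a ridge
  well <- function(cx, cy, depth, w = 0.15) {
    -depth * exp(-(outer((xm - cx)^2, (ym - cy)^2, "+")) / (2 * w^2))
  }
  G2 <- 2 + well(-0.5, -0.5, 2) + well(0.5, 0.5, 1.2)
  b2 <- find_basins(mk_grid(G2), depth_threshold = 0.3)
  expect_equal(nrow(b2), 2)
  expect_lt(max(abs(b2$x_center[1] - (-0.5)), abs(b2$y_center[1] - (-0.5))), 0.11)
  expect_lt(max(abs(b2$x_center[2] - 0.5), abs(b2$y_center[2] - 0.5)), 0.11)
  expect_equal(b2$G[1], 0)
  # a threshold above the shallow well's depth suppresses it
  b3 <- find_basins(mk_grid(G2), depth_threshold = 1.5)
  expect_equal(nrow(b3), 1)
  expect_error(find_basins(mk_grid(matrix(NA_real_, 3, 3))), "masked")
})

test_that("split-half convergence distinguishes mixed from ordered ensembles", {
  sq <- rep("ALA", 8)
  mix <- generate_mixture(list(
    a = mixture_component("helix", 0.5, sequence = sq),
    b = mixture_component("strand", 0.5, sequence = sq)),
    n_frames = 200, seed = 19)
  conv <- split_half_convergence(mix$ensemble, metrics = "rg")
  expect_lt(conv$jsd, 0.1)  # both halves sample the same mixture
  # ordered halves (all helix then all strand) are maximally divergent
  helixf <- mix$ensemble$frames[mix$labels$component == "a"]
  strandf <- mix$ensemble$frames[mix$labels$component == "b"]
  k <- min(length(helixf), length(strandf))
  ordered <- ensemble(mix$ensemble$topology, c(helixf[1:k], strandf[1:k]))
  conv2 <- split_half_convergence(ordered, metrics = "helix_content")
  expect_gt(conv2$jsd, 0.9)
  # minimal input runs; too-small input errors
  four <- ensemble(mix$ensemble$topology, mix$ensemble$frames[1:4])
  expect_s3_class(split_half_convergence(four, metrics = "rg"), "tbl_df")
  three <- ensemble(mix$ensemble$topology, mix$ensemble$frames[1:3])
  expect_error(split_half_convergence(three), "at least 4")
  # unusable metric is skipped with a warning
  expect_warning(
    out <- split_half_convergence(four, metrics = list(bad = function(e)
      stop("nope"))),
    "skipped")
  expect_equal(nrow(out), 0)
})

test_that("replica traversal counts bottom-top-bottom round trips", {
  up_down <- c(0:5, 4:0)
  expect_equal(replica_traversal(list(up_down), n_replicas = 6), 1L)
  expect_equal(replica_traversal(list(rep(2L, 50)), n_replicas = 6), 0L)
  saw <- rep(c(0:5, 4:0), 4)  # four complete bottom-top-bottom cycles
  expect_equal(replica_traversal(list(saw), n_replicas = 6), 4L)
  m <- cbind(up_down, rep(0L, 11))
  expect_equal(replica_traversal(m, n_replicas = 6), c(1L, 0L))
  expect_error(replica_traversal(list(c(0, 7)), n_replicas = 6),
               "out of range")
})

test_that("temperature ladders are geometric with exact endpoints", {
  expect_equal(temperature_ladder(306, 409, 2), c(306, 409))
  lad3 <- temperature_ladder(306, 409, 3)
  expect_equal(lad3[2], sqrt(306 * 409), tolerance = 1e-9)
  lad48 <- temperature_ladder(306, 409, 48)
  expect_length(lad48, 48)
  expect_true(all(diff(lad48) > 0))
  ratios <- lad48[-1] / lad48[-48]
  expect_lt(max(ratios) - min(ratios), 1e-12)
  expect_identical(lad48[c(1, 48)], c(306, 409))
  expect_error(temperature_ladder(400, 300, 5), "t_min")
  expect_error(temperature_ladder(300, 400, 1), "at least 2")
})
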