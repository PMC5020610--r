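test_that("contact probability is the weighted frame fraction in contact", {
  top <- bead_dimer_topology(2)  # chains A, B x residues 1..2
  near <- rbind(c(0, 0, 0), c(1, 0, 0),    # A1 A2
                c(0, 0.3, 0), c(5, 5, 5))  # B1 B2
  far <- near + cbind(0, c(0, 0, 10, 10), 0)
  ens <- ensemble(top, list(near, far))
  cm <- contact_probability(ens, "MC-MC", "inter", cutoff = 0.5)
  expect_equal(cm$matrix[1, 1], 0.5)   # A1-B1 touch in frame 1 only
  expect_equal(sum(cm$matrix), 0.5)
  # all-separated ensemble gives an all-zero map
  apart <- ensemble(top, list(far))
  expect_true(all(contact_probability(apart, "MC-MC", "inter")$matrix == 0))
  expect_error(contact_probability(ens, cutoff = -1), "> 0")
  # frame weights shift the probability
  wcm <- contact_probability(ensemble(top, list(near, far),
                                      weights = c(3, 1)),
                             "MC-MC", "inter", cutoff = 0.5)
  expect_equal(wcm$matrix[1, 1], 0.75)
})

test_that("sheet dimer interface shows an antiparallel inter-chain band", {
  dm <- sheet_dimer37()
  ens <- ensemble(dm$topology, list(dm$xyz))
  cm <- contact_probability(ens, "MC-MC", "inter", cutoff = 0.5)
  hot <- which(cm$matrix > 0.4, arr.ind = TRUE)
  expect_gt(nrow(hot), 5)
  # antiparallel alignment: contacting (i, j) pairs run along an
  # anti-diagonal, i.e. i and j are negatively correlated
  expect_lt(stats::cor(hot[, 1], hot[, 2]), -0.7)
  # symmetrized homodimer map is symmetric
  expect_equal(cm$matrix, t(cm$matrix))
})

test_that("contact maps are invariant under rigid motion per frame", {
  dm <- sheet_dimer37()
  R <- random_rotation_seeded(3)
  moved <- sweep(dm$xyz %*% t(R), 2, c(1, 2, 3), "+")
  c1 <- contact_probability(ensemble(dm$topology, list(dm$xyz)), "SC-SC",
                            "intra")
  c2 <- contact_probability(ensemble(dm$topology, list(moved)), "SC-SC",
                            "intra")
  expect_equal(c1$matrix, c2$matrix, tolerance = 1e-12)
})

test_that("ring geometry fits plane, normal and planarity", {
  hexagon <- t(vapply(0:5, function(k) {
    0.14 * c(cos(pi * k / 3), sin(pi * k / 3), 0)
  }, numeric(3)))
  conf <- point_atoms(hexagon)
  g <- ring_geometry(conf, 1:6)
  expect_equal(abs(g$normal[3]), 1, tolerance = 1e-12)
  expect_lt(g$residual, 1e-12)
  expect_equal(g$centroid, c(0, 0, 0), tolerance = 1e-12)
  # equivariance under a known rotation
  R <- random_rotation_seeded(9)
  g2 <- ring_geometry(point_atoms(hexagon %*% t(R)), 1:6)
  expect_equal(abs(sum(g2$normal * (R %*% c(0, 0, 1)))), 1,
               tolerance = 1e-9)
  # puckered ring: residual agrees with a direct SVD oracle
  puck <- hexagon
  puck[2, 3] <- 0.05
  gp <- ring_geometry(point_atoms(puck), 1:6)
  sv <- svd(sweep(puck, 2, colMeans(puck)))
  expect_equal(gp$residual, sv$d[3] / sqrt(6), tolerance = 1e-12)
  line <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_error(ring_geometry(point_atoms(line), 1:5), "collinear")
  expect_error(ring_geometry(conf, 1:2), "at least 3")
})

test_that("stacking classification follows the threshold geometry", {
  mk <- function(d, ang) {
    list(res = list(centroid = c(0, 0, 0), normal = c(0, 0, 1), residual = 0),
         lig = list(centroid = c(0, 0, d),
                    normal = c(sin(ang * pi / 180), 0, cos(ang * pi / 180)),
                    residual = 0))
  }
  cases <- list(list(0.40, 0, "parallel"), list(0.55, 90, "perpendicular"),
                list(1.50, 0, "none"), list(1.50, 90, "none"),
                list(0.50, 45, "none"), list(0.70, 85, "perpendicular"))
  for (cs in cases) {
    g <- mk(cs[[1]], cs[[2]])
    expect_equal(as.character(stacking_classify(g$res, g$lig)$class), cs[[3]])
  }
  # increasing distance never turns "none" into a stacked class
  for (ang in c(0, 45, 90)) {
    cls <- vapply(seq(0.3, 1.6, by = 0.05), function(d) {
      g <- mk(d, ang)
      as.character(stacking_classify(g$res, g$lig)$class)
    }, character(1))
    stacked <- cls != "none"
    expect_false(any(diff(stacked) > 0))  # no none -> stacked transition
  }
  # folded angle never exceeds 90
  g <- mk(0.5, 170)
  expect_lte(stacking_classify(g$res, g$lig)$angle, 90)
})

test_that("stacking statistics aggregate planted geometries", {
  conf <- hiapp_hairpin()
  frames <- list(); classes <- c("parallel", "perpendicular")
  geom <- list(parallel = c(0.40, 5), perpendicular = c(0.58, 85))
  planted <- rep(classes, each = 6)
  top <- NULL
  for (i in seq_along(planted)) {
    g <- geom[[planted[i]]]
    pl <- place_with_retry(conf, "A:37:ring", g[1], g[2], seed = 100 + 50 * i)
    frames[[i]] <- pl$xyz
    top <- pl$topology
  }
  ens <- ensemble(top, frames)
  st <- stacking_statistics(ens)
  br <- st$by_ring[st$by_ring$key == "L:ring1", ]
  expect_equal(br$parallel, 0.5, tolerance = 1e-9)
  expect_equal(br$perpendicular, 0.5, tolerance = 1e-9)
  expect_equal(br$both, 1, tolerance = 1e-9)
  # parallel-only ensemble: no perpendicular events anywhere
  ens_par <- ensemble(top, frames[planted == "parallel"])
  st_par <- stacking_statistics(ens_par)
  expect_true(all(st_par$by_residue$perpendicular == 0))
  # ligand-free ensemble: empty statistics, no error
  bare <- ensemble(conf$topology, list(conf$xyz))
  st0 <- stacking_statistics(bare)
  expect_equal(nrow(st0$events), 0)
})

test_that("geometric H-bond criterion and backbone counting work", {
  d <- c(0, 0, 0)
  expect_true(hbond_geometry_ok(d, c(0.1, 0, 0), c(0.29, 0, 0)))
  expect_false(hbond_geometry_ok(d, c(0.1, 0, 0), c(0.40, 0, 0)))
  h45 <- c(cos(pi / 4), sin(pi / 4), 0) * 0.1
  expect_false(hbond_geometry_ok(d, h45, c(0.30, 0, 0)))
  # ideal helix: ladder of i -> i+4 backbone bonds
  expect_warning(n <- hbond_count(helix12()), "skipped")
  expect_gte(n, 6)
  # far-apart dimer beads: no bonds, counts are per frame
  mix <- dimer_mix()$ensemble
  counts <- suppressWarnings(hbond_count(mix))
  expect_length(counts, n_frames(mix))
  expect_true(all(counts >= 0))
})

test_that("ligand-residue contacts localize and decompose additively", {
  conf <- hiapp_hairpin()
  pl <- place_with_retry(conf, "A:37:ring", 0.40, 10, seed = 4)
  ens <- ensemble(pl$topology, list(pl$xyz))
  lc <- ligand_residue_contacts(ens, cutoff = 0.45)
  expect_true(all(lc$ring$total == lc$ring$main_chain + lc$ring$side_chain))
  touched <- lc$residue$resid[lc$residue$probability > 0]
  expect_true(37 %in% touched)
  expect_lt(length(touched), 15)  # localized: most residues untouched
  # ligand far away: all zero
  lig_idx <- select_atoms(pl$topology, class = "ligand")
  far <- pl$xyz
  far[lig_idx, ] <- far[lig_idx, ] + 50
  lc_far <- ligand_residue_contacts(ensemble(pl$topology, list(far)))
  expect_true(all(lc_far$residue$probability == 0))
  expect_true(all(lc_far$ring$total == 0))
  expect_error(ligand_residue_contacts(ensemble(conf$topology,
                                                list(conf$xyz))),
               "no ligand")
})

test_that("cation-pi distances form the declared distribution", {
  # minimal world: one cationic bead + one ligand ring at exactly 0.43 nm
  ring <- t(vapply(0:5, function(k) {
    c(0.43, 0.139 * cos(pi * k / 3), 0.139 * sin(pi * k / 3))
  }, numeric(3)))
  atoms <- rbind(
    data.frame(chain = "A", resid = 1, resname = "ARG", name = "NH1",
               element = "N", class = "side_chain", ring = NA,
               charged = "A:1:cation"),
    data.frame(chain = "L", resid = 1, resname = "EGC",
               name = paste0("C", 1:6), element = "C", class = "ligand",
               ring = "L:ring1", charged = NA))
  top <- topology(atoms)
  ens <- ensemble(top, list(rbind(c(0, 0, 0), ring)))
  pdf <- cation_pi_pdf(ens, breaks = seq(0, 1, 0.01))
  expect_lt(abs(pdf$mid[which.max(pdf$density)] - 0.43), 0.0051)
  expect_equal(sum(pdf$density) * 0.01, 1, tolerance = 1e-9)
  # uniform placements in a shell follow the r^2 geometry law
  r1 <- 0.3; r2 <- 0.6
  withr::with_seed(10, {
    frames <- replicate(4000, {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r <- (stats::runif(1) * (r2^3 - r1^3) + r1^3)^(1 / 3)
      rbind(c(0, 0, 0), sweep(ring, 2, c(0.43, 0, 0)) + rep(r * u, each = 6))
    }, simplify = FALSE)
  })
  ens2 <- ensemble(top, frames)
  pdf2 <- cation_pi_pdf(ens2, breaks = seq(r1, r2, 0.05))
  expected <- 3 * pdf2$mid^2 / (r2^3 - r1^3)
  expect_lt(max(abs(pdf2$density - expected) / expected), 0.15)
  # no rings: empty pdf
  bare <- ensemble(topology(atoms[1, ]), list(matrix(0, 1, 3)))
  expect_equal(nrow(cation_pi_pdf(bare)), 0)
})

test_that("intra-ligand ring torsions use the oriented-normal convention", {
  for (tors in list(c(0, 90), c(50, 90), c(130, 20))) {
    lig <- ligand_template(torsion12 = tors[1], torsion13 = tors[2])
    ens <- ensemble(lig$topology, list(lig$xyz))
    p12 <- ring_pair_torsion_pdf(ens, "L:ring1", "L:ring2",
                                 breaks = seq(0, 180, 1))
    expect_lt(abs(p12$mid[which.max(p12$density)] - tors[1]), 0.51)
    p13 <- ring_pair_torsion_pdf(ens, "L:ring1", "L:ring3",
                                 breaks = seq(0, 180, 1))
    expect_lt(abs(p13$mid[which.max(p13$density)] - tors[2]), 0.51)
  }
  # 180-degree flip is distinguished from coplanar (unfolded convention)
  lig <- ligand_template(torsion12 = 150, torsion13 = 0)
  ens <- ensemble(lig$topology, list(lig$xyz))
  p <- ring_pair_torsion_pdf(ens, "L:ring1", "L:ring2",
                             breaks = seq(0, 180, 1))
  expect_gt(p$mid[which.max(p$density)], 90)
  # rings of different molecules are rejected
  conf <- hiapp_hairpin()
  pl <- place_ligand_ring(conf, "A:37:ring", 0.6, 10, seed = 2)
  ens2 <- ensemble(pl$topology, list(pl$xyz))
  expect_error(ring_pair_torsion_pdf(ens2, "A:37:ring", "L:ring1"),
               "different molecules")
})
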