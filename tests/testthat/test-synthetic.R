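test_that("built backbones reproduce the requested dihedrals", {
  withr::with_seed(3, {
    phi <- stats::runif(10, -170, -50)
    psi <- stats::runif(10, -60, 170)
  })
  conf <- build_backbone(rep("ALA", 10), phi, psi)
  d <- backbone_dihedrals(conf)
  expect_lt(max(abs(d$phi[-1] - phi[-1])), 1e-3)
  expect_lt(max(abs(d$psi[-10] - psi[-10])), 1e-3)
  expect_lt(max(abs(abs(d$omega[-10]) - 180)), 1e-3)
  # rebuild from measured dihedrals is idempotent (up to rigid motion)
  conf2 <- build_backbone(rep("ALA", 10), c(phi[1], d$phi[-1]),
                          c(d$psi[-10], psi[10]))
  sel <- select_atoms(conf, class = "main_chain")
  fit <- kabsch_superpose(conf2$xyz[sel, ], conf$xyz[sel, ])
  expect_lt(fit$rmsd, 1e-6)
})

test_that("builder handles degenerate and invalid sequences", {
  expect_error(build_backbone(character(0), -57, -47), "empty")
  two <- build_backbone(rep("GLY", 2), -57, -47)
  d <- backbone_dihedrals(two)
  expect_true(is.na(d$phi[1]))   # boundary dihedrals undefined
  expect_true(is.na(d$psi[2]))
  expect_error(build_backbone(c("ALA", "XXX"), -57, -47), "unknown residue")
})

test_that("hairpin builder produces an antiparallel E ladder", {
  for (conf in list(hairpin20(), hiapp_hairpin())) {
    ranges <- if (ncol(assign_ss(conf)$classes) == 20) {
      list(s1 = 1:8, s2 = 13:20)
    } else {
      list(s1 = 8:16, s2 = 25:33)
    }
    cls <- assign_ss(conf)$classes[1, ]
    strand_cls <- cls[c(ranges$s1, ranges$s2)]
    expect_gte(mean(strand_cls %in% c("E", "B")), 0.6)
  }
  expect_error(build_hairpin(rep("ALA", 10), 1:4, 4:6, 7:10), "overlapping")
  expect_error(build_hairpin(rep("ALA", 10), 7:8, 4:6, 1:3), "ordered")
  # single-residue strands cannot ladder but still build
  tiny <- build_hairpin(rep("ALA", 6), 1, 2:5, 6)
  expect_s3_class(tiny, "conformation")
})

test_that("hairpin contact map shows the antiparallel anti-diagonal", {
  conf <- hairpin20()
  cm <- contact_probability(ensemble(conf$topology, list(conf$xyz)),
                            mode = "MC-MC", scope = "intra", cutoff = 0.5)
  hot <- which(cm$matrix >= 0.5 & abs(row(cm$matrix) - col(cm$matrix)) > 4,
               arr.ind = TRUE)
  expect_gt(nrow(hot), 3)
  # anti-diagonal: residue sums concentrate near strand1+strand2 pairing
  expect_lt(stats::sd(rowSums(hot)), 3)
  expect_lt(stats::cor(hot[, 1], hot[, 2]), -0.8)
})

test_that("dimer assembly transforms chain B rigidly and detects clashes", {
  A <- build_helix(rep("ALA", 8), chain = "A")
  B <- build_helix(rep("ALA", 8), chain = "B")
  dm <- build_dimer(A, B, translation = c(5, 0, 0))
  nb <- nrow(B$xyz)
  expect_equal(dm$xyz[seq_len(nrow(A$xyz)), ], A$xyz)
  expect_equal(dm$xyz[nrow(A$xyz) + seq_len(nb), ],
               sweep(B$xyz, 2, c(5, 0, 0), "+"))
  d2 <- dimerscope:::cross_dist2(A$xyz, sweep(B$xyz, 2, c(5, 0, 0), "+"))
  expect_gte(sqrt(min(d2)), 5 - (max(A$xyz[, 1]) - min(B$xyz[, 1])))
  expect_error(build_dimer(A, B, translation = c(0, 0, 0)), "clash")
  expect_error(build_dimer(A, B, translation = c(5, 0, 0),
                           rotation = diag(c(1, 1, -1))), "proper")
})

test_that("ligand placement realizes the requested stacking geometry exactly", {
  conf <- hiapp_hairpin()
  cases <- list(c(0.40, 0), c(0.55, 90), c(1.50, 0), c(0.62, 37.5))
  for (cs in cases) {
    pl <- place_ligand_ring(conf, "A:37:ring", cs[1], cs[2], seed = 21)
    rg <- ring_groups(pl$topology)
    g1 <- ring_geometry(pl, rg[["A:37:ring"]])
    g2 <- ring_geometry(pl, rg[["L:ring1"]])
    d <- sqrt(sum((g1$centroid - g2$centroid)^2))
    ang <- acos(min(1, abs(sum(g1$normal * g2$normal)))) * 180 / pi
    expect_lt(abs(d - cs[1]), 1e-6)
    expect_lt(abs(ang - cs[2]), 0.1)
    ev <- stacking_classify(g1, g2)
    want <- if (cs[1] <= 0.55 && cs[2] <= 30) "parallel"
            else if (cs[1] <= 0.75 && cs[2] >= 60) "perpendicular" else "none"
    expect_equal(as.character(ev$class), want)
  }
  # same seed -> identical placement; different seed -> different azimuth
  p1 <- place_ligand_ring(conf, "A:37:ring", 0.5, 20, seed = 7)
  p2 <- place_ligand_ring(conf, "A:37:ring", 0.5, 20, seed = 7)
  p3 <- place_ligand_ring(conf, "A:37:ring", 0.5, 20, seed = 8)
  expect_identical(p1$xyz, p2$xyz)
  expect_gt(max(abs(p1$xyz - p3$xyz)), 1e-3)
  expect_error(place_ligand_ring(conf, "A:37:ring", 0.2, 0, seed = 1), ">= 0.3")
  expect_error(place_ligand_ring(conf, "A:37:ring", 0.5, 120, seed = 1),
               "plane_angle")
  expect_error(place_ligand_ring(conf, "nope", 0.5, 10, seed = 1),
               "unknown target ring")
})

test_that("mixture generation is seeded, labeled and weight-consistent", {
  sq <- rep("ALA", 8)
  comps <- list(h = mixture_component("helix", 0.7, sequence = sq),
                c = mixture_component("coil", 0.3, sequence = sq))
  m1 <- generate_mixture(comps, 200, seed = 5)
  m2 <- generate_mixture(comps, 200, seed = 5)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$ensemble$frames, m2$ensemble$frames)
  fr <- mean(m1$labels$component == "h")
  expect_lt(abs(fr - 0.7), 0.07)  # ~2 binomial sd at n = 200
  only <- generate_mixture(list(h = mixture_component("helix", 1,
                                                      sequence = sq)),
                           20, seed = 1)
  expect_true(all(only$labels$component == "h"))
  expect_error(generate_mixture(list(
    h = mixture_component("helix", 0, sequence = sq)), 10, seed = 1),
    "sum to zero")
  expect_error(mixture_component("unknown_gen", 1), "unknown generator")
})

test_that("mixture label fractions obey the law of large numbers", {
  sq <- rep("GLY", 4)
  comps <- list(a = mixture_component("helix", 0.6, sequence = sq),
                b = mixture_component("strand", 0.4, sequence = sq))
  m <- generate_mixture(comps, 2000, seed = 77, jitter = 0.001)
  fr <- mean(m$labels$component == "a")
  expect_lt(abs(fr - 0.6), 3 * sqrt(0.6 * 0.4 / 2000))
  # frames follow their label's base conformer
  base_a <- m$bases$a$xyz
  i <- which(m$labels$component == "a")[1]
  expect_lt(max(abs(m$ensemble$frames[[i]] - base_a)), 0.01)
})
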