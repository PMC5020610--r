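test_that("Kabsch-Sander energy formula behaves as expected", {
  expect_equal(ks_hbond_energy(3, 3, 3, 3), 0)
  # all groups >= 10 A apart: |E| < 0.5, no bond possible
  expect_lt(abs(ks_hbond_energy(10, 11, 10.5, 10.8)), 0.5)
  # ideal helix i -> i-4 backbone bond is comfortably below the cutoff
  h <- helix12()
  e <- backbone_hbond_energy(h, donor = c("A", 6), acceptor = c("A", 2))
  expect_lt(e, -0.5)
  # excluded pairs: self and covalent neighbors
  expect_true(is.na(backbone_hbond_energy(h, c("A", 5), c("A", 5))))
  expect_true(is.na(backbone_hbond_energy(h, c("A", 5), c("A", 4))))
  # first residue has no donor
  expect_true(is.na(backbone_hbond_energy(h, c("A", 1), c("A", 5))))
  # distant pair: no bond
  e2 <- backbone_hbond_energy(h, c("A", 2), c("A", 10))
  expect_gt(e2, -0.5)
})

test_that("assignment recovers helix, strand and hairpin architectures", {
  cls_h <- assign_ss(helix12())$classes[1, ]
  expect_true(all(cls_h[3:10] %in% c("H", "G")))
  # an isolated extended chain has no strand partner, hence no E
  cls_e <- assign_ss(build_strand(rep("ALA", 10)))$classes[1, ]
  expect_false(any(cls_e %in% c("E", "B")))
  # hairpin: both strands ladder up as E
  cls_hp <- assign_ss(hairpin20())$classes[1, ]
  expect_gte(sum(cls_hp[1:8] == "E"), 4)
  expect_gte(sum(cls_hp[13:20] == "E"), 4)
  # all classes drawn from the 8-state alphabet
  expect_true(all(cls_hp %in% c("H", "G", "I", "E", "B", "T", "S", "C")))
})

test_that("inter-chain bridges are detected across a dimer interface", {
  a <- assign_ss(sheet_dimer37())
  clsB <- a$classes[1, a$residues$chain == "B"]
  expect_gte(sum(clsB == "E"), 5)
})

test_that("assignment is invariant under rigid motion", {
  conf <- hairpin20()
  base <- assign_ss(conf)$classes
  for (seed in 1:3) {
    R <- random_rotation_seeded(seed)
    moved <- conformation(conf$topology,
                          sweep(conf$xyz %*% t(R), 2, c(seed, -1, 2), "+"))
    expect_identical(assign_ss(moved)$classes, base)
  }
})

test_that("profiles collapse to six classes with unit row sums", {
  mk_assign <- function(classes_mat, weights = NULL) {
    n <- ncol(classes_mat)
    structure(list(
      classes = classes_mat,
      residues = tibble::tibble(chain = "A", resid = seq_len(n),
                                resname = "ALA"),
      weights = if (is.null(weights)) {
        rep(1 / nrow(classes_mat), nrow(classes_mat))
      } else weights),
      class = "ss_assignment")
  }
  allc <- mk_assign(matrix("C", 2, 5))
  p <- ss_profile(allc)
  expect_equal(p$summary$probability[p$summary$class == "coil"], 1)
  hc <- mk_assign(rbind(rep("H", 4), rep("C", 4)))
  p2 <- ss_profile(hc)
  res <- tidyr::pivot_wider(p2$residue, names_from = "class",
                            values_from = "probability")
  expect_true(all(res$helix == 0.5 & res$coil == 0.5))
  # real ensemble: per-residue probabilities sum to one
  ens <- dimer_mix()$ensemble
  pr <- ss_profile(assign_ss(ens))$residue
  sums <- pr |>
    dplyr::group_by(chain, resid) |>
    dplyr::summarise(s = sum(probability), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("strand run lengths are counted per frame and chain", {
  mk <- function(rows, chains) {
    structure(list(
      classes = rows,
      residues = tibble::tibble(chain = chains,
                                resid = as.integer(stats::ave(
                                  seq_along(chains), chains, FUN = seq_along)),
                                resname = "ALA"),
      weights = rep(1 / nrow(rows), nrow(rows))),
      class = "ss_assignment")
  }
  one <- mk(matrix(strsplit("CCEEEECC", "")[[1]], 1), rep("A", 8))
  pdf1 <- strand_length_pdf(one)
  expect_equal(pdf1$length, 4L)
  expect_equal(pdf1$probability, 1)
  two_runs <- mk(matrix(strsplit("CCEEECCEEEEC", "")[[1]], 1), rep("A", 12))
  pdf2 <- strand_length_pdf(two_runs)
  expect_equal(pdf2$length, c(3L, 4L))
  expect_equal(pdf2$probability, c(1, 1))  # per frame-chain normalization
  none <- mk(matrix("C", 3, 6), rep("A", 6))
  expect_equal(nrow(strand_length_pdf(none)), 0)
  # two chains: a run in one chain counts against both frame-chains
  dimer <- mk(matrix(strsplit("EEEECCCC", "")[[1]], 1), rep(c("A", "B"), each = 4))
  pdf3 <- strand_length_pdf(dimer)
  expect_equal(pdf3$length, 4L)
  expect_equal(pdf3$probability, 0.5)
})

test_that("missing backbone atoms are reported by residue", {
  conf <- helix12()
  keep <- conf$topology$atoms$name != "O" | conf$topology$atoms$resid != 5
  broken <- conformation(topology(conf$topology$atoms[keep, ]),
                         conf$xyz[keep, , drop = FALSE])
  expect_error(assign_ss(broken), "missing backbone atom O.*5")
})
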