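test_that("Kabsch superposition recovers exact transforms", {
  withr::with_seed(5, {
    pts <- matrix(stats::rnorm(30), 10, 3)
    R <- random_rotation_seeded(15)
    moved <- sweep(pts %*% t(R), 2, c(1, -2, 0.5), "+")
  })
  fit <- kabsch_superpose(moved, pts)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
  ident <- kabsch_superpose(pts, pts)
  expect_equal(ident$rotation, diag(3), tolerance = 1e-10)
  expect_lt(ident$rmsd, 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  expect_error(kabsch_superpose(pts, pts, weights = rep(0, 10)), "positive sum")
})

test_that("superposed RMSD matches a rotation-space oracle and is minimal", {
  withr::with_seed(8, {
    for (k in 1:4) {
      A <- matrix(stats::rnorm(15, sd = 0.5), 5, 3)
      B <- A + matrix(stats::rnorm(15, sd = 0.1), 5, 3)
      fit <- kabsch_superpose(A, B)
      expect_lt(abs(fit$rmsd - kabsch_oracle_rmsd(A, B)), 1e-4)
      # superposition never exceeds the unsuperposed RMSD
      expect_lte(fit$rmsd, sqrt(mean(rowSums((A - B)^2))) + 1e-12)
    }
  })
  # near-collinear case with one displaced point
  base <- cbind(seq(0, 0.9, length.out = 4), 0, 0)
  base[2, 2] <- 0.02
  mob <- base
  mob[3, 2] <- mob[3, 2] + 0.1
  fit <- kabsch_superpose(mob, base)
  expect_lt(abs(fit$rmsd - kabsch_oracle_rmsd(mob, base)), 1e-4)
})

test_that("chain-independent RMSD ignores chain labels of a homodimer", {
  mix <- dimer_mix()
  ens <- mix$ensemble
  top <- ens$topology
  idxA <- which(top$atoms$chain == "A")
  idxB <- which(top$atoms$chain == "B")
  f1 <- get_frame(ens, 1)
  swapped <- conformation(top, f1$xyz[c(idxB, idxA), ])
  expect_lt(chain_independent_rmsd(f1, swapped), 1e-10)
  expect_lt(chain_independent_rmsd(f1, f1), 1e-12)
  # asymmetric pair: equals the explicit minimum over both assignments
  f2 <- get_frame(ens, which(mix$labels$component != mix$labels$component[1])[1])
  sel <- select_atoms(top, class = "main_chain")
  selA <- sel[top$atoms$chain[sel] == "A"]
  selB <- sel[top$atoms$chain[sel] == "B"]
  direct <- kabsch_superpose(f2$xyz[c(selA, selB), ], f1$xyz[c(selA, selB), ])$rmsd
  crossed <- kabsch_superpose(f2$xyz[c(selB, selA), ], f1$xyz[c(selA, selB), ])$rmsd
  expect_equal(chain_independent_rmsd(f1, f2), min(direct, crossed),
               tolerance = 1e-12)
  expect_error(chain_independent_rmsd(helix12(), helix12()), "homodimer")
})

test_that("chain-independent RMSD is a pseudo-metric on sampled triples", {
  ens <- dimer_mix()$ensemble
  M <- rmsd_matrix(ens)
  expect_equal(unclass(M), t(unclass(M)))
  expect_true(all(diag(M) == 0))
  expect_true(all(M >= 0))
  n <- nrow(M)
  withr::with_seed(2, triples <- replicate(30, sample.int(n, 3)))
  for (k in seq_len(ncol(triples))) {
    i <- triples[1, k]; j <- triples[2, k]; l <- triples[3, k]
    expect_lte(M[i, l], M[i, j] + M[j, l] + 1e-9)
  }
})

test_that("Daura clustering matches its definition on planted structure", {
  # trivial extremes
  close_mat <- matrix(0.1, 5, 5); diag(close_mat) <- 0
  all_one <- daura_cluster(close_mat, cutoff = 0.35)
  expect_length(all_one$clusters, 1)
  expect_equal(sort(all_one$clusters[[1]]$members), 1:5)
  far <- matrix(2, 6, 6); diag(far) <- 0
  singl <- daura_cluster(far, cutoff = 0.35)
  expect_length(singl$clusters, 6)
  expect_equal(singl$populations, rep(1 / 6, 6))
  # planted 3-cluster structure equals the brute-force oracle
  withr::with_seed(31, {
    centers <- matrix(c(0, 0, 5, 5, 10, 0), 3, 2, byrow = TRUE)
    pts <- centers[rep(1:3, times = c(6, 4, 2)), ] +
      matrix(stats::rnorm(24, sd = 0.3), 12, 2)
  })
  m <- as.matrix(stats::dist(pts))
  got <- daura_cluster(m, cutoff = 2)
  expect_partition_equal(got$clusters, daura_oracle(m, 2))
  expect_length(got$clusters, 3)
  expect_equal(got$populations, c(0.5, 1 / 3, 1 / 6))
  expect_error(daura_cluster(m, cutoff = 0), "> 0")
})

test_that("Daura partitions are invariant to frame reordering", {
  withr::with_seed(13, m <- random_dist_matrix(20))
  cutoff <- stats::median(m)
  base <- daura_cluster(m, cutoff)
  withr::with_seed(14, perm <- sample.int(20))
  permuted <- daura_cluster(m[perm, perm], cutoff)
  # map permuted partition back to original frame ids and compare
  back <- lapply(permuted$clusters, function(cl) {
    list(center = perm[cl$center], members = sort(perm[cl$members]))
  })
  norm <- function(cl) {
    m2 <- lapply(cl, function(x) sort(x$members))
    m2[order(vapply(m2, min, numeric(1)))]
  }
  expect_identical(norm(back), norm(base$clusters))
})

test_that("cluster summaries report populations and write centers", {
  mix <- dimer_mix()
  M <- rmsd_matrix(mix$ensemble)
  cl <- daura_cluster(M, cutoff = 0.35)
  expect_length(cl$clusters, 2)  # two rigid components + jitter
  smry <- cluster_summary(cl, mix$ensemble, k = 2)
  expect_equal(smry$cumulative[2], 1)
  # recovered populations equal the empirical component fractions
  frac <- sort(as.numeric(table(mix$labels$component)), decreasing = TRUE) /
    n_frames(mix$ensemble)
  expect_equal(smry$population, frac, tolerance = 1e-9)
  # members of cluster 1 share one ground-truth label
  lab <- mix$labels$component[cl$clusters[[1]]$members]
  expect_length(unique(lab), 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  s1 <- cluster_summary(cl, mix$ensemble, k = 1, centers_path = f)
  expect_true(file.exists(f))
  expect_equal(n_frames(read_multi_model_pdb(f)), 1)
  expect_error(cluster_summary(cl, mix$ensemble, k = 0), "positive")
  expect_error(cluster_summary(cl, mix$ensemble, k = 99), "exceeds")
  td <- tidy(cl)
  expect_equal(nrow(td), n_frames(mix$ensemble))
  expect_equal(sum(td$is_center), 2)
  expect_equal(glance(cl)$n_clusters, 2)
})
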