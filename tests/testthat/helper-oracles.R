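# Independent oracles used by the unit and acceptance tests. Each is kept
# deliberately separate from the package code paths it checks.

# --- Reference DSSP (pydssp via MDAnalysis, 3-state H/E/-) ---------------

# Strip a built conformation to its backbone N/CA/C/O for the reference
# implementation (which reconstructs amide hydrogens itself).
backbone_only <- function(conf) {
  keep <- which(conf$topology$atoms$name %in% c("N", "CA", "C", "O") &
                  conf$topology$atoms$class == "main_chain")
  top <- topology(conf$topology$atoms[keep, ])
  conformation(top, conf$xyz[keep, , drop = FALSE])
}

# Run the reference DSSP over a list of single-chain conformations in one
# python process; returns 3-state strings ('H', 'E', '-').
reference_dssp <- function(confs) {
  td <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- vapply(seq_along(confs), function(i) {
    p <- file.path(td, sprintf("s%03d.pdb", i))
    write_multi_model_pdb(backbone_only(confs[[i]]), p)
    p
  }, character(1))
  script <- file.path(td, "ref_dssp.py")
  writeLines(c(
    "import sys, json, warnings",
    "warnings.filterwarnings('ignore')",
    "import MDAnalysis as mda",
    "from MDAnalysis.analysis.dssp import DSSP",
    "out = []",
    "for p in sys.argv[1:]:",
    "    u = mda.Universe(p)",
    "    d = DSSP(u).run()",
    "    out.append(''.join(d.results.dssp[0]))",
    "print(json.dumps(out))"), script)
  res <- system2("python", c(script, paths), stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(res[length(res)])
}

# Collapse this package's 8-state string to the reference's 3 states.
collapse3 <- function(classes) {
  out <- rep("-", length(classes))
  out[classes %in% c("H", "G", "I")] <- "H"
  out[classes %in% c("E", "B")] <- "E"
  out
}

# --- Brute-force Daura greedy clustering --------------------------------

daura_oracle <- function(m, cutoff) {
  remaining <- seq_len(nrow(m))
  clusters <- list()
  while (length(remaining)) {
    best <- NA_integer_; best_nb <- integer(0)
    for (f in remaining) {
      nb <- remaining[m[f, remaining] <= cutoff]
      if (length(nb) > length(best_nb)) {
        best <- f; best_nb <- nb
      }
    }
    clusters[[length(clusters) + 1]] <- list(center = best,
                                             members = sort(best_nb))
    remaining <- setdiff(remaining, best_nb)
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, integer(1))
  clusters[order(-sizes, centers)]
}

# --- Rotation-space minimization oracle for superposition ----------------

euler_matrix <- function(e) {
  cz <- cos(e[1]); sz <- sin(e[1])
  cy <- cos(e[2]); sy <- sin(e[2])
  cx <- cos(e[3]); sx <- sin(e[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

kabsch_oracle_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  obj <- function(e) sqrt(mean(rowSums((A %*% t(euler_matrix(e)) - B)^2)))
  starts <- expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                        b = c(-pi / 2, 0, pi / 2),
                        c = c(0, pi / 2, pi, 3 * pi / 2))
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[k, ]), obj, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-15))
    best <- min(best, o$value)
  }
  best
}

# Random symmetric "RMSD-like" matrix from points in a low-dimensional
# space (so the triangle inequality holds, as for real RMSD matrices).
random_dist_matrix <- function(n, dim = 3) {
  pts <- matrix(stats::runif(n * dim), n, dim)
  as.matrix(stats::dist(pts))
}
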