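# Kabsch superposition, chain-independent main-chain RMSD and Daura
# (GROMOS-style) greedy neighbor clustering.

#' Optimal least-squares superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' of `mobile` onto `reference`. Reflections are disallowed (determinant
#' +1), following the standard SVD sign correction.
#'
#' @param mobile,reference `n x 3` coordinate matrices (nm), equal sizes,
#'   `n >= 3`.
#' @param weights Per-atom nonnegative weights (default uniform).
#' @return List with `rotation` (3x3), `translation` (length 3) such that
#'   `mobile %*% t(rotation) + translation` superposes onto `reference`,
#'   and the minimized `rmsd` (nm).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3) {
    stop("mobile and reference must be equal-sized n x 3 matrices")
  }
  if (nrow(mobile) < 3) stop("superposition needs at least 3 atoms")
  if (is.null(weights)) weights <- rep(1, nrow(mobile))
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be nonnegative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A * w, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - B)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

# Fast minimized RMSD between two centered coordinate sets (uniform
# weights) via the singular values of the correlation matrix.
.kabsch_rmsd_centered <- function(A, B, e0) {
  H <- crossprod(A, B)
  d <- svd(H, nu = 0, nv = 0)$d
  s <- if (det(H) < 0) sum(d[1:2]) - d[3] else sum(d)
  sqrt(max(0, (e0 - 2 * s)) / nrow(A))
}

#' Chain-independent main-chain RMSD of a homodimer
#'
#' Minimum superposed RMSD over the two chain-label assignments
#' (A->A, B->B versus A->B, B->A) of a topologically identical two-chain
#' peptide - the RMSD computed as if chain identifiers were absent.
#'
#' @param frameA,frameB [conformation()]s sharing a homodimer topology.
#' @param selection Atom indices used for the fit; default the main-chain
#'   atoms (N, CA, C, O) of both peptide chains.
#' @return RMSD in nm.
#' @export
chain_independent_rmsd <- function(frameA, frameB, selection = NULL) {
  top <- frameA$topology
  if (!isTRUE(top$homodimer)) {
    stop("chain-independent RMSD requires a homodimer topology")
  }
  sel <- .ci_selection(top, selection)
  .ci_rmsd_xyz(frameA$xyz, frameB$xyz, sel)
}

# Selection bookkeeping: equal-length main-chain index vectors for the two
# peptide chains, in matching residue/atom order.
.ci_selection <- function(top, selection = NULL) {
  pc <- peptide_chains(top)
  if (is.null(selection)) selection <- select_atoms(top, class = "main_chain")
  selA <- selection[top$atoms$chain[selection] == pc[1]]
  selB <- selection[top$atoms$chain[selection] == pc[2]]
  if (length(selA) != length(selB)) {
    stop("selection is not symmetric across the two chains")
  }
  list(AB = c(selA, selB), BA = c(selB, selA))
}

# Residual-based (not the faster singular-value trace formula, which loses
# ~1e-8 nm to cancellation and would blur exact-zero cases).
.ci_rmsd_xyz <- function(xyzA, xyzB, sel) {
  ref <- xyzA[sel$AB, , drop = FALSE]
  min(kabsch_superpose(xyzB[sel$AB, , drop = FALSE], ref)$rmsd,
      kabsch_superpose(xyzB[sel$BA, , drop = FALSE], ref)$rmsd)
}

#' Pairwise RMSD matrix over an ensemble
#'
#' Full `n x n` symmetric matrix of pairwise superposed main-chain RMSD.
#' For homodimers the chain-independent RMSD (minimum over the two chain
#' assignments) is used unless disabled. Ligand atoms are never part of
#' the default selection. For large ensembles a `stride` subsamples
#' frames.
#'
#' @param ens An [ensemble()].
#' @param selection Atom indices (default main-chain atoms of the peptide
#'   chains).
#' @param chain_independent Use the two-assignment minimum? Default: yes
#'   when the topology is a homodimer.
#' @param stride Keep every `stride`-th frame (default 1 = all).
#' @return Object of class `"rmsd_matrix"`: the matrix (nm) with the used
#'   frame indices as `attr(, "frames")`.
#' @export
rmsd_matrix <- function(ens, selection = NULL, chain_independent = NULL,
                        stride = 1) {
  top <- ens$topology
  if (is.null(chain_independent)) chain_independent <- isTRUE(top$homodimer)
  frames_idx <- seq(1, n_frames(ens), by = stride)
  nf <- length(frames_idx)
  if (chain_independent) {
    sel <- .ci_selection(top, selection)
    coords <- lapply(ens$frames[frames_idx], function(x) {
      m1 <- x[sel$AB, , drop = FALSE]; m1 <- sweep(m1, 2, colMeans(m1))
      m2 <- x[sel$BA, , drop = FALSE]; m2 <- sweep(m2, 2, colMeans(m2))
      list(m1 = m1, m2 = m2, g1 = sum(m1^2), g2 = sum(m2^2))
    })
    M <- matrix(0, nf, nf)
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        a <- coords[[i]]; b <- coords[[j]]
        M[i, j] <- M[j, i] <- min(
          .kabsch_rmsd_centered(b$m1, a$m1, a$g1 + b$g1),
          .kabsch_rmsd_centered(b$m2, a$m1, a$g1 + b$g2))
      }
    }
  } else {
    if (is.null(selection)) selection <- select_atoms(top, class = "main_chain")
    coords <- lapply(ens$frames[frames_idx], function(x) {
      m <- x[selection, , drop = FALSE]
      m <- sweep(m, 2, colMeans(m))
      list(m = m, g = sum(m^2))
    })
    M <- matrix(0, nf, nf)
    for (i in seq_len(nf - 1)) {
      for (j in (i + 1):nf) {
        M[i, j] <- M[j, i] <- .kabsch_rmsd_centered(
          coords[[j]]$m, coords[[i]]$m, coords[[i]]$g + coords[[j]]$g)
      }
    }
  }
  structure(M, frames = frames_idx, class = c("rmsd_matrix", "matrix"))
}

#' Daura greedy neighbor clustering
#'
#' Iteratively takes the frame with the most neighbors within `cutoff`
#' (ties broken by lowest frame index) as a cluster center, removes the
#' center and its neighbors, and repeats until no frames remain. Clusters
#' are returned ordered by decreasing size, ties by lower center index.
#'
#' @param mat A symmetric pairwise RMSD matrix (nm), e.g. from
#'   [rmsd_matrix()].
#' @param cutoff Neighbor cutoff in nm (> 0); default 0.35, the
#'   main-chain cutoff used for peptide-dimer ensembles.
#' @param weights Optional per-frame weights for the population fractions
#'   (default uniform).
#' @return Object of class `"daura_clust"`: list with `clusters` (each a
#'   list of `center` and `members`, frame indices), `populations`,
#'   `assignment` (cluster id per frame), `cutoff`.
#' @export
daura_cluster <- function(mat, cutoff = 0.35, weights = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  mat <- unclass(mat)
  dimnames(mat) <- NULL
  n <- nrow(mat)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- weights / sum(weights)
  neigh <- mat <= cutoff
  diag(neigh) <- TRUE
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    counts <- colSums(neigh[alive, , drop = FALSE])
    counts[!alive] <- -1
    center <- which.max(counts)  # which.max takes the first (lowest) index
    members <- which(alive & neigh[, center])
    clusters[[length(clusters) + 1]] <- list(center = center, members = members)
    alive[members] <- FALSE
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  centers <- vapply(clusters, function(cl) cl$center, integer(1))
  ord <- order(-sizes, centers)
  clusters <- clusters[ord]
  assignment <- integer(n)
  for (k in seq_along(clusters)) assignment[clusters[[k]]$members] <- k
  populations <- vapply(clusters, function(cl) sum(weights[cl$members]),
                        numeric(1))
  structure(list(clusters = clusters, populations = populations,
                 assignment = assignment, cutoff = cutoff, n_frames = n),
            class = "daura_clust")
}

#' @export
print.daura_clust <- function(x, ...) {
  cat("<daura_clust> ", length(x$clusters), " clusters over ", x$n_frames,
      " frames (cutoff ", x$cutoff, " nm)\n", sep = "")
  k <- min(6, length(x$clusters))
  for (i in seq_len(k)) {
    cat(sprintf("  #%d: center %d, %d members, %.1f%%\n", i,
                x$clusters[[i]]$center, length(x$clusters[[i]]$members),
                100 * x$populations[i]))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname daura_cluster
#' @param x A `"daura_clust"` object.
#' @param ... Unused.
#' @export
tidy.daura_clust <- function(x, ...) {
  purrr::map_dfr(seq_along(x$clusters), function(k) {
    tibble::tibble(frame = x$clusters[[k]]$members, cluster = k,
                   is_center = x$clusters[[k]]$members == x$clusters[[k]]$center)
  }) |> dplyr::arrange(.data$frame)
}

#' @rdname daura_cluster
#' @export
glance.daura_clust <- function(x, ...) {
  tibble::tibble(n_clusters = length(x$clusters), n_frames = x$n_frames,
                 cutoff = x$cutoff, top_population = x$populations[1])
}

#' Summarize the top clusters of a Daura clustering
#'
#' Reports the populations and cumulative fraction of the `k`
#' most-populated clusters and (optionally) writes their center structures
#' as a multi-model PDB, mirroring the usual top-clusters figure of a
#' clustering analysis.
#'
#' @param result A `"daura_clust"`.
#' @param ens The clustered [ensemble()].
#' @param k Number of top clusters to report (`1 <= k <=` number of
#'   clusters).
#' @param centers_path Optional path: write the k center structures as a
#'   multi-model PDB.
#' @return Tibble with `cluster`, `center_frame`, `n_members`,
#'   `population`, `cumulative`.
#' @export
cluster_summary <- function(result, ens, k = 6, centers_path = NULL) {
  if (k <= 0) stop("k must be positive")
  if (k > length(result$clusters)) stop("k exceeds the number of clusters")
  frames_idx <- seq_len(result$n_frames)
  tb <- tibble::tibble(
    cluster = seq_len(k),
    center_frame = vapply(result$clusters[seq_len(k)], `[[`, integer(1), "center"),
    n_members = vapply(result$clusters[seq_len(k)], function(cl)
      length(cl$members), integer(1)),
    population = result$populations[seq_len(k)])
  tb$cumulative <- cumsum(tb$population)
  if (!is.null(centers_path)) {
    centers <- ensemble(ens$topology, ens$frames[tb$center_frame],
                        temperature_K = ens$temperature_K)
    write_multi_model_pdb(centers, centers_path)
  }
  tb
}
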