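# Residue-residue and ligand-residue contacts, geometric hydrogen-bond
# counting, aromatic-ring geometry and stacking classification, and
# cation-pi distance distributions.

#' Aromatic ring geometry: centroid, plane normal, planarity
#'
#' Least-squares plane fit: the normal is the smallest principal axis of
#' the centered ring coordinates, oriented by the declared ring-atom
#' ordering (right-hand rule), so ring flips are distinguishable where a
#' signed convention matters; the planarity residual is the RMS
#' out-of-plane distance.
#'
#' @param conf A [conformation()].
#' @param ring_atoms Integer atom indices of one ring (>= 3, non-collinear),
#'   in ring order (e.g. an entry of [ring_groups()]).
#' @return List with `centroid` (nm), `normal` (unit vector) and
#'   `residual` (nm).
#' @export
ring_geometry <- function(conf, ring_atoms) {
  if (length(ring_atoms) < 3) stop("a ring needs at least 3 atoms")
  X <- conf$xyz[ring_atoms, , drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) {
    stop("ring atoms are collinear; no plane defined")
  }
  n <- ev$vectors[, 3]
  # orient by atom ordering (Newell's method)
  ref <- c(0, 0, 0)
  k <- nrow(Xc)
  for (i in seq_len(k)) ref <- ref + cross3(Xc[i, ], Xc[i %% k + 1, ])
  if (sum(ref * n) < 0) n <- -n
  list(centroid = ctr, normal = unit(n),
       residual = sqrt(mean((Xc %*% n)^2)))
}

#' Residue-residue contact-probability map
#'
#' A residue pair is in contact in a frame when the minimum distance
#' between their selected heavy atoms is at most `cutoff`; the map holds
#' the weighted fraction of frames in contact. `mode` selects main-chain
#' (MC-MC) or side-chain (SC-SC) atoms; `scope` selects the inter-chain
#' map (chain 1 x chain 2, symmetrized over the two chain assignments for
#' a homodimer) or the intra-chain map (averaged over chains).
#'
#' @param ens An [ensemble()].
#' @param mode `"MC-MC"` or `"SC-SC"`.
#' @param scope `"inter"` or `"intra"`.
#' @param cutoff Contact cutoff in nm (> 0); default 0.5.
#' @return Object of class `"contact_map"`: probability matrix plus
#'   metadata; `tidy()` gives the long form.
#' @export
contact_probability <- function(ens, mode = c("MC-MC", "SC-SC"),
                                scope = c("inter", "intra"), cutoff = 0.5) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  if (cutoff <= 0) stop("cutoff must be > 0")
  top <- ens$topology
  cls <- if (mode == "MC-MC") "main_chain" else "side_chain"
  pc <- peptide_chains(top)
  res_tbl <- residues(top, peptide_only = TRUE)

  sel_chain <- function(ch) {
    idx <- select_atoms(top, class = cls, chain = ch, heavy = TRUE)
    res <- sort(unique(res_tbl$resid[res_tbl$chain == ch]))
    ind <- matrix(0, length(idx), length(res))
    ind[cbind(seq_along(idx), match(top$atoms$resid[idx], res))] <- 1
    list(idx = idx, ind = ind, res = res)
  }

  pair_contact <- function(xyz, s1, s2) {
    if (!length(s1$idx) || !length(s2$idx)) {
      return(matrix(0, length(s1$res), length(s2$res)))
    }
    D <- cross_dist2(xyz[s1$idx, , drop = FALSE], xyz[s2$idx, , drop = FALSE])
    (crossprod(s1$ind, (D <= cutoff^2) + 0) %*% s2$ind) > 0
  }

  w <- ens$weights
  if (scope == "inter") {
    if (length(pc) < 2) stop("inter-chain map requires two peptide chains")
    s1 <- sel_chain(pc[1]); s2 <- sel_chain(pc[2])
    P <- matrix(0, length(s1$res), length(s2$res))
    for (f in seq_along(ens$frames)) {
      P <- P + w[f] * pair_contact(ens$frames[[f]], s1, s2)
    }
    if (isTRUE(top$homodimer)) P <- (P + t(P)) / 2
    rows <- s1$res; cols <- s2$res
  } else {
    chains_use <- pc
    s <- lapply(chains_use, sel_chain)
    P <- matrix(0, length(s[[1]]$res), length(s[[1]]$res))
    for (f in seq_along(ens$frames)) {
      for (k in seq_along(s)) {
        P <- P + (w[f] / length(s)) * pair_contact(ens$frames[[f]], s[[k]], s[[k]])
      }
    }
    rows <- cols <- s[[1]]$res
  }
  structure(list(matrix = P, mode = mode, scope = scope, cutoff = cutoff,
                 row_resid = rows, col_resid = cols),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$scope, " ", x$mode, ", ", nrow(x$matrix), " x ",
      ncol(x$matrix), " residues, cutoff ", x$cutoff, " nm\n", sep = "")
  invisible(x)
}

#' @rdname contact_probability
#' @param x A `"contact_map"`.
#' @param ... Unused.
#' @export
tidy.contact_map <- function(x, ...) {
  tidyr::expand_grid(resid_i = x$row_resid, resid_j = x$col_resid) |>
    dplyr::mutate(probability = as.vector(t(x$matrix)))
}

#' Ligand-residue contact statistics
#'
#' Per peptide residue, the probability that any ligand heavy atom lies
#' within `cutoff` of any residue heavy atom; and per ligand ring, the
#' mean number of peptide heavy atoms within `cutoff` of the ring, split
#' into main-chain and side-chain counts (total = MC + SC).
#'
#' @param ens An [ensemble()] with at least one ligand.
#' @param cutoff Contact cutoff in nm, default 0.5.
#' @return List with `$residue` (chain, resid, resname, probability),
#'   `$residue_pooled` (averaged over peptide chains) and `$ring` (ring,
#'   main_chain, side_chain, total mean contact numbers).
#' @export
ligand_residue_contacts <- function(ens, cutoff = 0.5) {
  top <- ens$topology
  lig <- select_atoms(top, class = "ligand", heavy = TRUE)
  if (!length(lig)) stop("no ligand declared in the topology")
  res_tbl <- residues(top, peptide_only = TRUE)
  pep_heavy <- setdiff(select_atoms(top, heavy = TRUE), lig)
  res_key <- paste(top$atoms$chain, top$atoms$resid)[pep_heavy]
  keys <- paste(res_tbl$chain, res_tbl$resid)
  ind <- matrix(0, length(pep_heavy), nrow(res_tbl))
  ind[cbind(seq_along(pep_heavy), match(res_key, keys))] <- 1
  cls_mc <- top$atoms$class[pep_heavy] == "main_chain"

  lig_rings <- ring_groups(top, chain = ligand_chains(top))
  w <- ens$weights
  prob <- numeric(nrow(res_tbl))
  ring_mc <- ring_sc <- stats::setNames(numeric(length(lig_rings)),
                                        names(lig_rings))
  for (f in seq_along(ens$frames)) {
    xyz <- ens$frames[[f]]
    D <- cross_dist2(xyz[pep_heavy, , drop = FALSE], xyz[lig, , drop = FALSE])
    close_any <- rowSums(D <= cutoff^2) > 0
    prob <- prob + w[f] * (as.numeric(crossprod(ind, close_any)) > 0)
    for (rg in names(lig_rings)) {
      cols <- match(lig_rings[[rg]], lig)
      close_ring <- rowSums(D[, cols, drop = FALSE] <= cutoff^2) > 0
      ring_mc[rg] <- ring_mc[rg] + w[f] * sum(close_ring & cls_mc)
      ring_sc[rg] <- ring_sc[rg] + w[f] * sum(close_ring & !cls_mc)
    }
  }
  residue <- dplyr::mutate(res_tbl, probability = prob)
  pooled <- residue |>
    dplyr::group_by(.data$resid, .data$resname) |>
    dplyr::summarise(probability = mean(.data$probability), .groups = "drop")
  ring <- tibble::tibble(ring = names(lig_rings),
                         main_chain = unname(ring_mc),
                         side_chain = unname(ring_sc),
                         total = unname(ring_mc + ring_sc))
  list(residue = residue, residue_pooled = pooled, ring = ring)
}

#' Geometric hydrogen-bond criterion
#'
#' TRUE when the donor-acceptor heavy-atom distance is at most `d_cutoff`
#' and the hydrogen-donor-acceptor angle at most `angle_cutoff` - the
#' standard geometric convention of simulation analysis tools.
#'
#' @param donor,h,acceptor Length-3 coordinates (nm) of the donor heavy
#'   atom, its hydrogen, and the acceptor.
#' @param d_cutoff Distance cutoff, nm (default 0.35).
#' @param angle_cutoff H-donor-acceptor angle cutoff, degrees (default 30).
#' @return Logical.
#' @export
hbond_geometry_ok <- function(donor, h, acceptor, d_cutoff = 0.35,
                              angle_cutoff = 30) {
  vnorm(acceptor - donor) <= d_cutoff &&
    angle3(h, donor, acceptor) <= angle_cutoff
}

#' Count backbone hydrogen bonds per frame
#'
#' Counts donor-acceptor pairs satisfying [hbond_geometry_ok()] among the
#' peptide backbone amide donors (N-H; H reconstructed when not declared)
#' and carbonyl O acceptors. Same-residue and covalently adjacent
#' same-chain pairs are excluded; donors without an attachable H (chain
#' starts, prolines) are skipped with a warning the first time.
#'
#' @param ens An [ensemble()] or [conformation()].
#' @param d_cutoff,angle_cutoff See [hbond_geometry_ok()].
#' @return Integer vector, one count per frame.
#' @export
hbond_count <- function(ens, d_cutoff = 0.35, angle_cutoff = 30) {
  if (inherits(ens, "conformation")) ens <- ensemble(ens$topology, list(ens$xyz))
  bk <- .backbone_index(ens$topology)
  skipped <- which(bk$first | bk$pro)
  if (length(skipped)) {
    warning(length(skipped), " donor(s) without an attachable H skipped ",
            "(chain starts / PRO)", call. = FALSE)
  }
  cosmax <- cos(deg2rad(angle_cutoff))
  vapply(ens$frames, function(xyz) {
    H <- .donor_h(xyz, bk)
    has_h <- !is.na(H[, 1])
    Nmat <- xyz[bk$idx$N, , drop = FALSE]
    Omat <- xyz[bk$idx$O, , drop = FALSE]
    D <- sqrt(cross_dist2(Nmat[has_h, , drop = FALSE], Omat))
    cnt <- 0L
    don_ids <- which(has_h)
    for (r in seq_along(don_ids)) {
      d_id <- don_ids[r]
      cand <- which(D[r, ] <= d_cutoff)
      cand <- cand[!(bk$chain[cand] == bk$chain[d_id] & abs(cand - d_id) <= 1)]
      for (a_id in cand) {
        u <- unit(H[d_id, ] - Nmat[d_id, ])
        v <- unit(Omat[a_id, ] - Nmat[d_id, ])
        if (sum(u * v) >= cosmax) cnt <- cnt + 1L
      }
    }
    cnt
  }, integer(1))
}

#' Classify an aromatic stacking geometry
#'
#' The plane angle is `acos(|n1 . n2|)`, folded to `[0, 90]` degrees. The
#' pair is `parallel` stacking when the centroid distance is at most
#' `d_par` and the angle at most `ang_par`; `perpendicular` (T-shaped)
#' when the distance is at most `d_perp` and the angle at least
#' `ang_perp`; otherwise `none`. Defaults (0.55 nm / 30 degrees and
#' 0.75 nm / 60 degrees) bracket the basin centers reported for
#' peptide-polyphenol ring stacking, (0.4 nm, 15 deg) parallel and
#' (0.6 nm, 85 deg) perpendicular.
#'
#' @param res_ring,lig_ring Ring geometries from [ring_geometry()].
#' @param d_par,d_perp Distance caps (nm) for the two classes.
#' @param ang_par,ang_perp Angle thresholds (degrees).
#' @return Tibble row: `distance` (nm), `angle` (degrees in `[0, 90]`),
#'   `class` (factor parallel/perpendicular/none).
#' @export
stacking_classify <- function(res_ring, lig_ring, d_par = 0.55,
                              d_perp = 0.75, ang_par = 30, ang_perp = 60) {
  d <- vnorm(res_ring$centroid - lig_ring$centroid)
  ang <- rad2deg(acos(pmin(1, abs(sum(res_ring$normal * lig_ring$normal)))))
  cl <- if (d <= d_par && ang <= ang_par) {
    "parallel"
  } else if (d <= d_perp && ang >= ang_perp) {
    "perpendicular"
  } else "none"
  tibble::tibble(distance = d, angle = ang,
                 class = factor(cl, levels = c("parallel", "perpendicular",
                                               "none")))
}

#' Aromatic stacking statistics over an ensemble
#'
#' Evaluates every (peptide aromatic ring, ligand ring) pair in every
#' frame with [stacking_classify()] and aggregates formation
#' probabilities: per aromatic residue and per ligand ring, the weighted
#' probability that a frame contains at least one parallel event, at
#' least one perpendicular event, and at least one of either ("both").
#' The raw (distance, angle) samples feed [fes2d()] for the stacking
#' free-energy surface.
#'
#' @param ens An [ensemble()].
#' @inheritParams stacking_classify
#' @return List with `$events` (one row per frame x ring pair),
#'   `$by_residue`, `$by_ring` and `$samples`; all empty (zero rows) for
#'   a ligand-free ensemble.
#' @export
stacking_statistics <- function(ens, d_par = 0.55, d_perp = 0.75,
                                ang_par = 30, ang_perp = 60) {
  top <- ens$topology
  pep_rings <- ring_groups(top, chain = peptide_chains(top))
  lig_rings <- ring_groups(top, chain = ligand_chains(top))
  empty <- tibble::tibble()
  if (!length(pep_rings) || !length(lig_rings)) {
    return(list(events = empty, by_residue = empty, by_ring = empty,
                samples = empty))
  }
  w <- ens$weights
  events <- purrr::map_dfr(seq_along(ens$frames), function(f) {
    conf <- get_frame(ens, f)
    purrr::map_dfr(names(pep_rings), function(pr) {
      g1 <- ring_geometry(conf, pep_rings[[pr]])
      purrr::map_dfr(names(lig_rings), function(lr) {
        g2 <- ring_geometry(conf, lig_rings[[lr]])
        ev <- stacking_classify(g1, g2, d_par, d_perp, ang_par, ang_perp)
        dplyr::mutate(ev, frame = f, res_ring = pr, lig_ring = lr,
                      weight = w[f])
      })
    })
  })
  agg <- function(tb, key) {
    tb |>
      dplyr::group_by(.data$frame, key = .data[[key]]) |>
      dplyr::summarise(
        par = any(.data$class == "parallel"),
        perp = any(.data$class == "perpendicular"),
        weight = .data$weight[1], .groups = "drop") |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(
        parallel = sum(.data$weight * .data$par),
        perpendicular = sum(.data$weight * .data$perp),
        both = sum(.data$weight * (.data$par | .data$perp)),
        .groups = "drop")
  }
  list(events = events,
       by_residue = agg(events, "res_ring"),
       by_ring = agg(events, "lig_ring"),
       samples = events[, c("distance", "angle", "weight")])
}

#' Cation-pi distance distribution
#'
#' Probability density of the distance between each declared cationic
#' center (mean position of the charged-group atoms, e.g. the guanidinium
#' of an arginine) and the centroid of each ligand aromatic ring,
#' normalized to unit area over the binned range. A sharp peak near
#' 0.43 nm is the signature of a cation-pi contact.
#'
#' @param ens An [ensemble()].
#' @param breaks Histogram bin edges in nm (default 0 to 2 by 0.01).
#' @return Tibble with bin `mid` (nm) and `density` (1/nm); zero rows if
#'   no cation group or no ligand ring is declared.
#' @export
cation_pi_pdf <- function(ens, breaks = seq(0, 2, by = 0.01)) {
  top <- ens$topology
  cats <- charged_groups(top, chain = peptide_chains(top))
  lig_rings <- ring_groups(top, chain = ligand_chains(top))
  if (!length(cats) || !length(lig_rings)) {
    return(tibble::tibble(mid = numeric(0), density = numeric(0)))
  }
  d <- c(); wts <- c()
  for (f in seq_along(ens$frames)) {
    xyz <- ens$frames[[f]]
    for (cg in cats) {
      cc <- colMeans(xyz[cg, , drop = FALSE])
      for (rg in lig_rings) {
        d <- c(d, vnorm(cc - colMeans(xyz[rg, , drop = FALSE])))
        wts <- c(wts, ens$weights[f])
      }
    }
  }
  .weighted_pdf(d, wts, breaks)
}

.weighted_pdf <- function(x, w, breaks) {
  keep <- x >= min(breaks) & x <= max(breaks)
  x <- x[keep]; w <- w[keep]
  if (!length(x)) {
    return(tibble::tibble(mid = numeric(0), density = numeric(0)))
  }
  bin <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  mass <- vapply(seq_len(length(breaks) - 1),
                 function(b) sum(w[bin == b]), numeric(1))
  widths <- diff(breaks)
  mass <- mass / sum(mass)
  tibble::tibble(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 density = mass / widths)
}

#' Inter-ring torsion distribution within a ligand
#'
#' Angle between the oriented plane normals of two rings of the same
#' ligand molecule, in `[0, 180]` degrees: because each ring's normal
#' direction is fixed by its declared atom ordering ([ring_geometry()]),
#' the angle distinguishes a ring flipped by 180 degrees from a coplanar
#' one, unlike the folded stacking angle.
#'
#' @param ens An [ensemble()].
#' @param ringA,ringB Ring-group names (must belong to the same ligand
#'   chain).
#' @param breaks Histogram bin edges in degrees (default 0 to 180 by 2).
#' @return Tibble with bin `mid` (degrees) and `density` (1/degree).
#' @export
ring_pair_torsion_pdf <- function(ens, ringA, ringB,
                                  breaks = seq(0, 180, by = 2)) {
  top <- ens$topology
  rg <- ring_groups(top)
  for (r in c(ringA, ringB)) if (!r %in% names(rg)) stop("unknown ring: ", r)
  chA <- unique(top$atoms$chain[rg[[ringA]]])
  chB <- unique(top$atoms$chain[rg[[ringB]]])
  if (!identical(chA, chB)) stop("rings belong to different molecules")
  ang <- vapply(seq_along(ens$frames), function(f) {
    conf <- get_frame(ens, f)
    g1 <- ring_geometry(conf, rg[[ringA]])
    g2 <- ring_geometry(conf, rg[[ringB]])
    rad2deg(acos(pmin(1, pmax(-1, sum(g1$normal * g2$normal)))))
  }, numeric(1))
  .weighted_pdf(ang, ens$weights, breaks)
}
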