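# Kabsch-Sander hydrogen-bond-based secondary-structure assignment
# (8-state: H, G, I, E, B, T, S, C) and the ensemble statistics derived
# from it. Inter-chain bridges are allowed, so multi-stranded sheets that
# span a dimer interface are detected.

KS_CONST <- 27.888  # 0.084 e^2 * 332 kcal/(mol*A)
KS_CUTOFF <- -0.5   # kcal/mol

#' Kabsch-Sander electrostatic hydrogen-bond energy
#'
#' `E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with distances
#' in Angstrom, between a backbone C=O acceptor group and an N-H donor
#' group. An H-bond is registered when `E < -0.5` kcal/mol.
#'
#' @param r_on,r_ch,r_oh,r_cn O...N, C...H, O...H and C...N distances in
#'   Angstrom.
#' @return Energy in kcal/mol.
#' @export
ks_hbond_energy <- function(r_on, r_ch, r_oh, r_cn) {
  KS_CONST * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Backbone atom bookkeeping for one topology: per peptide residue the
# indices of N, CA, C, O (+ H when declared) and chain labels.
.backbone_index <- function(top) {
  a <- top$atoms
  res <- residues(top, peptide_only = TRUE)
  n <- nrow(res)
  find <- function(nm) {
    vapply(seq_len(n), function(i) {
      j <- which(a$chain == res$chain[i] & a$resid == res$resid[i] &
                   a$name == nm)
      if (length(j) == 1) j else NA_integer_
    }, integer(1))
  }
  idx <- list(N = find("N"), CA = find("CA"), C = find("C"), O = find("O"),
              H = find("H"))
  for (nm in c("N", "CA", "C", "O")) {
    if (anyNA(idx[[nm]])) {
      k <- which(is.na(idx[[nm]]))[1]
      stop("missing backbone atom ", nm, " in residue ", res$chain[k], "/",
           res$resname[k], res$resid[k])
    }
  }
  list(res = res, idx = idx, chain = res$chain, n = n,
       pro = res$resname == "PRO",
       first = !duplicated(res$chain))
}

# Donor H coordinates (nm) for every residue; NA rows where no donor
# (chain start, PRO, or H neither declared nor reconstructible).
.donor_h <- function(xyz, bk) {
  H <- matrix(NA_real_, bk$n, 3)
  for (i in seq_len(bk$n)) {
    if (bk$first[i] || bk$pro[i]) next
    if (!is.na(bk$idx$H[i])) {
      H[i, ] <- xyz[bk$idx$H[i], ]
    } else {
      cp <- xyz[bk$idx$C[i - 1], ]
      op <- xyz[bk$idx$O[i - 1], ]
      H[i, ] <- xyz[bk$idx$N[i], ] + (BOND_N_H) * unit(cp - op)
    }
  }
  H
}

# n x n logical H-bond map for one frame: hb[a, d] = TRUE when the carbonyl
# of residue a accepts a bond from the amide of residue d. Same-chain pairs
# with |a - d| <= 1 are excluded (a residue cannot bond itself or the
# neighbor it is covalently joined to).
.hbond_map <- function(xyz, bk, return_energy = FALSE) {
  A <- 10  # nm -> Angstrom
  Omat <- xyz[bk$idx$O, , drop = FALSE] * A
  Cmat <- xyz[bk$idx$C, , drop = FALSE] * A
  Nmat <- xyz[bk$idx$N, , drop = FALSE] * A
  Hmat <- .donor_h(xyz, bk) * A
  has_h <- !is.na(Hmat[, 1])
  Hsafe <- Hmat
  Hsafe[!has_h, ] <- 1e6
  E <- KS_CONST * (1 / sqrt(cross_dist2(Omat, Nmat)) +
                   1 / sqrt(cross_dist2(Cmat, Hsafe)) -
                   1 / sqrt(cross_dist2(Omat, Hsafe)) -
                   1 / sqrt(cross_dist2(Cmat, Nmat)))
  E[, !has_h] <- 0
  same_chain <- outer(bk$chain, bk$chain, "==")
  near <- abs(outer(seq_len(bk$n), seq_len(bk$n), "-")) <= 1
  E[same_chain & near] <- 0
  if (return_energy) return(E)
  E < KS_CUTOFF
}

# Shift helper: out[i, j] = M[i + k, j], FALSE where i + k leaves the
# matrix or crosses a chain boundary.
.shift_rows <- function(M, k, chain) {
  n <- nrow(M)
  out <- matrix(FALSE, n, n)
  src <- seq_len(n) + k
  ok <- src >= 1 & src <= n
  ok[ok] <- chain[src[ok]] == chain[which(ok)]
  out[ok, ] <- M[src[ok], , drop = FALSE]
  out
}
.shift_cols <- function(M, k, chain) t(.shift_rows(t(M), k, chain))

# Full 8-state assignment for one frame. Returns a character vector over
# the peptide residues in topology order.
.assign_frame <- function(xyz, bk) {
  n <- bk$n
  chain <- bk$chain
  hb <- .hbond_map(xyz, bk)
  hbT <- t(hb)

  succ_same <- function(i, k) {
    j <- i + k
    j <= n && chain[j] == chain[i]
  }

  # n-turns: CO of i accepts from NH of i+k
  turn <- list()
  for (k in 3:5) {
    tk <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (succ_same(i, k) && hb[i, i + k]) tk[i] <- TRUE
    }
    turn[[as.character(k)]] <- tk
  }

  # helices: minimal k-helix i..i+k-1 when k-turn at i-1 and at i
  helix_members <- function(tk, k) {
    mem <- rep(FALSE, n)
    for (i in 2:n) {
      if (i > n) break
      if (tk[i] && i - 1 >= 1 && chain[i - 1] == chain[i] && tk[i - 1]) {
        mem[i:min(n, i + k - 1)] <- TRUE
      }
    }
    mem
  }
  isH <- helix_members(turn[["4"]], 4)
  isG <- helix_members(turn[["3"]], 3) & !isH
  isI <- helix_members(turn[["5"]], 5) & !isH & !isG

  # turn candidates: residues strictly inside any n-turn
  isT <- rep(FALSE, n)
  for (k in 3:5) {
    for (i in which(turn[[as.character(k)]])) {
      isT[(i + 1):(i + k - 1)] <- TRUE
    }
  }

  # bridges (parallel / antiparallel), inter-chain allowed
  par <- (.shift_rows(hb, -1, chain) & .shift_rows(hbT, +1, chain)) |
         (.shift_cols(hbT, -1, chain) & .shift_cols(hb, +1, chain))
  anti <- (hb & hbT) |
          (.shift_rows(.shift_cols(hb, +1, chain), -1, chain) &
           .shift_rows(.shift_cols(hbT, -1, chain), +1, chain))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  allowed <- (!outer(chain, chain, "==")) | sep >= 3
  par <- par & allowed
  anti <- anti & allowed

  shift_both <- function(M, ki, kj) .shift_rows(.shift_cols(M, kj, chain), ki, chain)
  par_ext <- par & (shift_both(par, 1, 1) | shift_both(par, -1, -1))
  anti_ext <- anti & (shift_both(anti, 1, -1) | shift_both(anti, -1, 1))
  isE <- apply(par_ext | anti_ext, 1, any)
  isB <- apply(par | anti, 1, any) & !isE

  # bend: CA pseudo-angle kappa > 70 degrees
  isS <- rep(FALSE, n)
  CA <- xyz[bk$idx$CA, , drop = FALSE]
  for (i in seq_len(n)) {
    if (i - 2 >= 1 && i + 2 <= n && chain[i - 2] == chain[i] &&
        chain[i + 2] == chain[i]) {
      u <- CA[i, ] - CA[i - 2, ]
      v <- CA[i + 2, ] - CA[i, ]
      kappa <- rad2deg(acos(pmin(1, pmax(-1, sum(unit(u) * unit(v))))))
      isS[i] <- kappa > 70
    }
  }

  out <- rep("C", n)
  out[isS] <- "S"
  out[isT] <- "T"
  out[isI] <- "I"
  out[isG] <- "G"
  out[isB] <- "B"
  out[isE] <- "E"
  out[isH] <- "H"
  out
}

#' Backbone hydrogen-bond energy between two residues
#'
#' The Kabsch-Sander energy of the bond donated by the amide N-H of
#' `donor` to the carbonyl C=O of `acceptor` in one frame. The amide H is
#' taken from the topology if declared, otherwise reconstructed 1.0
#' Angstrom from N, anti to the preceding carbonyl C->O direction. A chain's
#' first residue and prolines have no donor; those pairs, the self pair and
#' covalently adjacent same-chain pairs return `NA` (no bond by
#' definition).
#'
#' @param conf A [conformation()].
#' @param donor,acceptor Length-2 vectors `c(chain, resid)`.
#' @return Energy in kcal/mol, or `NA` for excluded pairs.
#' @export
backbone_hbond_energy <- function(conf, donor, acceptor) {
  bk <- .backbone_index(conf$topology)
  find_res <- function(x) {
    i <- which(bk$res$chain == x[1] & bk$res$resid == as.integer(x[2]))
    if (length(i) != 1) stop("unknown residue ", x[1], "/", x[2])
    i
  }
  d <- find_res(donor); a <- find_res(acceptor)
  E <- .hbond_map(conf$xyz, bk, return_energy = TRUE)
  v <- E[a, d]
  excl <- (bk$chain[a] == bk$chain[d] && abs(a - d) <= 1) ||
    bk$first[d] || bk$pro[d]
  if (excl) NA_real_ else v
}

#' Assign per-residue secondary structure (Kabsch-Sander)
#'
#' Runs the hydrogen-bond pattern rules over every frame: 3/4/5-turns give
#' G/H/I helices by the consecutive-turn rule, parallel and antiparallel
#' bridge conditions give B with ladders extended to E (bridges between
#' chains included), isolated turns give T, CA pseudo-angle kappa > 70
#' degrees gives bend S, everything else coil C. Per residue the final
#' class follows the priority H > E > B > G > I > T > S > C.
#'
#' @param ens An [ensemble()] (or single [conformation()]).
#' @return An `"ss_assignment"`: frame x residue character matrix of
#'   8-state classes plus the residue table and frame weights.
#' @export
#' @examples
#' helix <- build_backbone(rep("ALA", 12), -57, -47)
#' assign_ss(helix)
assign_ss <- function(ens) {
  if (inherits(ens, "conformation")) ens <- ensemble(ens$topology, list(ens$xyz))
  bk <- .backbone_index(ens$topology)
  cls <- t(vapply(ens$frames, function(xyz) .assign_frame(xyz, bk),
                  character(bk$n)))
  structure(list(classes = cls, residues = bk$res, weights = ens$weights),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat("<ss_assignment> ", nrow(x$classes), " frames x ", ncol(x$classes),
      " residues\n", sep = "")
  if (nrow(x$classes) <= 5) {
    for (i in seq_len(nrow(x$classes))) {
      cat(" ", paste(x$classes[i, ], collapse = ""), "\n")
    }
  }
  invisible(x)
}

SS_COLLAPSE <- c(H = "helix", G = "helix", I = "helix", E = "sheet",
                 B = "bridge", T = "turn", S = "bend", C = "coil")
SS_CLASSES6 <- c("helix", "sheet", "bridge", "turn", "bend", "coil")

#' Secondary-structure probability profile
#'
#' Collapses the 8-state assignment to the six reported classes
#' (helix = H,G,I; sheet = E; bridge = B; turn = T; bend = S; coil = C) and
#' returns weight-averaged per-residue probabilities plus ensemble means.
#'
#' @param assign An `"ss_assignment"` from [assign_ss()].
#' @param weights Frame weights (default: the ensemble weights stored in
#'   the assignment).
#' @return An `"ss_profile"`: list with `$residue` (tibble: chain, resid,
#'   resname, class, probability; probabilities sum to 1 per residue) and
#'   `$summary` (tibble: class, probability).
#' @export
ss_profile <- function(assign, weights = NULL) {
  if (is.null(weights)) weights <- assign$weights
  weights <- weights / sum(weights)
  cls <- assign$classes
  n_res <- ncol(cls)
  prob <- vapply(SS_CLASSES6, function(cl) {
    m <- matrix(SS_COLLAPSE[cls] == cl, nrow = nrow(cls))
    as.numeric(crossprod(m, weights))
  }, numeric(n_res))
  residue <- tidyr::pivot_longer(
    dplyr::bind_cols(assign$residues,
                     tibble::as_tibble(as.data.frame(prob))),
    dplyr::all_of(SS_CLASSES6), names_to = "class", values_to = "probability")
  summary <- residue |>
    dplyr::group_by(class = factor(.data$class, levels = SS_CLASSES6)) |>
    dplyr::summarise(probability = mean(.data$probability), .groups = "drop")
  structure(list(residue = residue, summary = summary), class = "ss_profile")
}

#' @export
print.ss_profile <- function(x, ...) {
  cat("<ss_profile>\n")
  print(x$summary)
  invisible(x)
}

#' Beta-strand run-length distribution
#'
#' Counts maximal runs of consecutive E residues per frame and per chain.
#' The probability of length L is the (weight-averaged) number of runs of
#' length L divided by the number of frame-chain combinations, the
#' convention under which a single conformation contributes each of its
#' strands once; the values need not sum to 1.
#'
#' @param assign An `"ss_assignment"`.
#' @param weights Optional frame weights (default stored weights).
#' @return Tibble with `length` and `probability` (empty when no E occurs).
#' @export
strand_length_pdf <- function(assign, weights = NULL) {
  if (is.null(weights)) weights <- assign$weights
  weights <- weights / sum(weights)
  chains <- unique(assign$residues$chain)
  counts <- list()
  for (f in seq_len(nrow(assign$classes))) {
    for (ch in chains) {
      v <- assign$classes[f, assign$residues$chain == ch] == "E"
      r <- rle(v)
      lens <- r$lengths[r$values]
      for (L in lens) {
        key <- as.character(L)
        counts[[key]] <- (counts[[key]] %||% 0) + weights[f]
      }
    }
  }
  if (!length(counts)) {
    return(tibble::tibble(length = integer(0), probability = numeric(0)))
  }
  tb <- tibble::tibble(length = as.integer(names(counts)),
                       probability = unname(unlist(counts)) / length(chains))
  dplyr::arrange(tb, .data$length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
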