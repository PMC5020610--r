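# Peptide builders: internal-coordinate (NeRF) construction of backbones
# with minimal side chains. Geometry constants are ideal values in nm.

BOND_N_CA <- 0.1458
BOND_CA_C <- 0.1525
BOND_C_N  <- 0.1329
BOND_C_O  <- 0.1231
BOND_N_H  <- 0.100
BOND_CA_CB <- 0.1530
BOND_CB_CG <- 0.1510
RING_CC   <- 0.1390
ANG_C_N_CA <- 121.7
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_CA_C_O <- 120.5
ANG_N_CA_CB <- 110.4
TORS_C_N_CA_CB <- 122.55  # improper fixing the CB branch

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

#' Convert a one-letter amino-acid string to three-letter residue names
#' @param x One-letter sequence string (e.g. `"KCNTAT"`).
#' @return Character vector of 3-letter residue names.
#' @export
seq3 <- function(x) {
  s <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(s, names(AA3))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  unname(AA3[s])
}

#' The 37-residue hIAPP (amylin) sequence
#'
#' Human islet amyloid polypeptide, K1...Y37, the peptide whose dimer
#' ensembles this package is designed to analyze.
#'
#' @return Character vector of 37 three-letter residue names.
#' @export
hiapp_sequence <- function() seq3("KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY")

# Atoms emitted per residue, in build order. Minimal side chains: CB for all
# non-GLY residues, an ideal 6-ring for PHE/TYR (plus OH for TYR), and a
# single side-chain nitrogen standing in for the cationic center of ARG/LYS.
.residue_atom_plan <- function(resname, first) {
  rows <- list(c("N", "N", "main_chain"))
  if (!first && resname != "PRO") rows <- c(rows, list(c("H", "H", "hydrogen")))
  rows <- c(rows, list(c("CA", "C", "main_chain"),
                       c("C", "C", "main_chain"),
                       c("O", "O", "main_chain")))
  if (resname != "GLY") rows <- c(rows, list(c("CB", "C", "side_chain")))
  if (resname %in% c("PHE", "TYR")) {
    for (nm in c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")) {
      rows <- c(rows, list(c(nm, "C", "side_chain")))
    }
    if (resname == "TYR") rows <- c(rows, list(c("OH", "O", "side_chain")))
  }
  if (resname == "ARG") rows <- c(rows, list(c("NH1", "N", "side_chain")))
  if (resname == "LYS") rows <- c(rows, list(c("NZ", "N", "side_chain")))
  do.call(rbind, rows)
}

#' Build a peptide chain from backbone dihedral angles
#'
#' Constructs N, H, CA, C, O (and minimal side-chain) coordinates for a
#' single chain by sequential internal-to-Cartesian placement with fixed
#' ideal bond lengths and angles; the supplied phi/psi/omega angles are
#' reproduced exactly. The amide hydrogen is placed 1.0 Angstrom from N,
#' anti to the preceding carbonyl C->O direction (the Kabsch-Sander
#' reconstruction convention); the first residue and prolines carry no
#' amide H. The carbonyl O lies in the peptide plane, anti to the next
#' residue's N. Aromatic residues (PHE/TYR) get an ideal planar 6-ring
#' (C-C 1.39 Angstrom) along the CA->CB axis, registered as a ring group;
#' ARG/LYS get a single side-chain nitrogen registered as a cationic group.
#'
#' @param sequence Character vector of 3-letter residue names (or a single
#'   one-letter string).
#' @param phi,psi Backbone dihedrals in degrees; scalars are recycled.
#'   `phi[1]` and `psi[n]` do not affect the backbone trace (boundary
#'   dihedrals); `psi[n]` only orients the final carbonyl.
#' @param omega Peptide-bond dihedral, default 180 (trans).
#' @param chain Chain identifier.
#' @return A [conformation()] with its [topology()] attached.
#' @export
#' @examples
#' helix <- build_backbone(rep("ALA", 12), phi = -57, psi = -47)
build_backbone <- function(sequence, phi, psi, omega = 180, chain = "A") {
  if (length(sequence) == 1 && !sequence[1] %in% AA3) sequence <- seq3(sequence)
  n <- length(sequence)
  if (n < 1) stop("empty sequence")
  bad <- setdiff(sequence, AA3)
  if (length(bad)) stop("unknown residue name(s): ", paste(bad, collapse = ", "))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)

  bb <- .backbone_trace(n, phi, psi, omega)
  .decorate_chain(sequence, bb, psi, chain)
}

# N/CA/C trace only, as an (3n x 3) matrix in order N1,CA1,C1,N2,...
.backbone_trace <- function(n, phi, psi, omega) {
  bb <- matrix(0, 3 * n, 3)
  bb[1, ] <- c(0, 0, 0)                                   # N1
  bb[2, ] <- c(BOND_N_CA, 0, 0)                           # CA1
  th <- deg2rad(ANG_N_CA_C)
  bb[3, ] <- bb[2, ] + BOND_CA_C * c(-cos(th), sin(th), 0) # C1
  for (i in seq_len(n)[-1]) {
    r <- 3 * (i - 1)
    bb[r + 1, ] <- nerf_place(bb[r - 2, ], bb[r - 1, ], bb[r, ],
                              BOND_C_N, ANG_CA_C_N, psi[i - 1])
    bb[r + 2, ] <- nerf_place(bb[r - 1, ], bb[r, ], bb[r + 1, ],
                              BOND_N_CA, ANG_C_N_CA, omega[i - 1])
    bb[r + 3, ] <- nerf_place(bb[r, ], bb[r + 1, ], bb[r + 2, ],
                              BOND_CA_C, ANG_N_CA_C, phi[i])
  }
  bb
}

# Build full atom set + topology from an N/CA/C trace.
.decorate_chain <- function(sequence, bb, psi, chain) {
  n <- length(sequence)
  rows <- list(); coords <- list()
  Npos <- function(i) bb[3 * (i - 1) + 1, ]
  CApos <- function(i) bb[3 * (i - 1) + 2, ]
  Cpos <- function(i) bb[3 * (i - 1) + 3, ]
  for (i in seq_len(n)) {
    plan <- .residue_atom_plan(sequence[i], first = i == 1)
    O_i <- nerf_place(Npos(i), CApos(i), Cpos(i), BOND_C_O, ANG_CA_C_O,
                      psi[i] + 180)
    H_i <- if (i > 1) {
      O_prev <- nerf_place(Npos(i - 1), CApos(i - 1), Cpos(i - 1), BOND_C_O,
                           ANG_CA_C_O, psi[i - 1] + 180)
      # N-H anti to the preceding C=O (trans amide / DSSP reconstruction)
      Npos(i) + BOND_N_H * unit(Cpos(i - 1) - O_prev)
    } else NULL
    ring <- NULL
    CB <- if (sequence[i] != "GLY") {
      nerf_place(Cpos(i), Npos(i), CApos(i), BOND_CA_CB, ANG_N_CA_CB,
                 TORS_C_N_CA_CB)
    } else NULL
    if (sequence[i] %in% c("PHE", "TYR")) {
      axis <- unit(CB - CApos(i))
      CG <- CB + BOND_CB_CG * axis
      ctr <- CG + RING_CC * axis
      p <- {
        v <- Npos(i) - CApos(i)
        v <- v - sum(v * axis) * axis
        if (vnorm(v) < 1e-8) perp_vector(axis) else unit(v)
      }
      ring <- t(vapply(0:5, function(k) {
        a <- deg2rad(60 * k)
        ctr + RING_CC * (cos(a) * (-axis) + sin(a) * p)
      }, numeric(3)))
      ring_ctr <- ctr
    }
    for (j in seq_len(nrow(plan))) {
      nm <- plan[j, 1]
      xyz <- switch(nm,
        N = Npos(i), CA = CApos(i), C = Cpos(i), O = O_i, CB = CB, H = H_i,
        CG = ring[1, ], CD1 = ring[2, ], CE1 = ring[3, ], CZ = ring[4, ],
        CE2 = ring[5, ], CD2 = ring[6, ],
        OH = ring[4, ] + 0.137 * unit(ring[4, ] - ring_ctr),
        NH1 = CB + 0.30 * unit(CB - CApos(i)),
        NZ = CB + 0.25 * unit(CB - CApos(i)))
      ring_id <- if (nm %in% c("CG", "CD1", "CE1", "CZ", "CE2", "CD2") &&
                     sequence[i] %in% c("PHE", "TYR")) {
        paste0(chain, ":", i, ":ring")
      } else NA_character_
      charged_id <- if (nm %in% c("NH1", "NZ")) {
        paste0(chain, ":", i, ":cation")
      } else NA_character_
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain = chain, resid = i, resname = sequence[i], name = nm,
        element = plan[j, 2], class = plan[j, 3],
        ring = ring_id, charged = charged_id)
      coords[[length(coords) + 1]] <- xyz
    }
  }
  top <- topology(dplyr::bind_rows(rows))
  conformation(top, do.call(rbind, coords))
}

#' Measure backbone dihedrals from a built conformation
#'
#' Inverse of [build_backbone()]: back-computes per-residue (phi, psi,
#' omega) from the N/CA/C coordinates of one chain. Boundary angles that
#' need a neighboring residue are `NA`.
#'
#' @param conf A [conformation()].
#' @param chain Chain to measure (default the first peptide chain).
#' @return Tibble with `resid`, `phi`, `psi`, `omega` in degrees.
#' @export
backbone_dihedrals <- function(conf, chain = NULL) {
  top <- conf$topology
  if (is.null(chain)) chain <- peptide_chains(top)[1]
  a <- top$atoms
  sel <- function(nm, r) which(a$chain == chain & a$resid == r & a$name == nm)
  res <- sort(unique(a$resid[a$chain == chain & a$class != "ligand"]))
  out <- purrr::map_dfr(res, function(r) {
    g <- function(nm, rr) {
      i <- sel(nm, rr)
      if (length(i) != 1) return(NULL)
      conf$xyz[i, ]
    }
    phi <- psi <- omg <- NA_real_
    if (!is.null(g("C", r - 1))) {
      phi <- dihedral4(g("C", r - 1), g("N", r), g("CA", r), g("C", r))
    }
    if (!is.null(g("N", r + 1))) {
      psi <- dihedral4(g("N", r), g("CA", r), g("C", r), g("N", r + 1))
      if (!is.null(g("CA", r + 1))) {
        omg <- dihedral4(g("CA", r), g("C", r), g("N", r + 1), g("CA", r + 1))
      }
    }
    tibble::tibble(resid = r, phi = phi, psi = psi, omega = omg)
  })
  out
}

#' Canonical secondary-structure dihedral sets
#'
#' `build_helix()` uses (-57, -47) (ideal alpha helix); `build_strand()`
#' uses (-139, 135) (ideal antiparallel beta strand).
#'
#' @inheritParams build_backbone
#' @return A [conformation()].
#' @export
build_helix <- function(sequence, chain = "A") {
  build_backbone(sequence, phi = -57, psi = -47, chain = chain)
}

#' @rdname build_helix
#' @export
build_strand <- function(sequence, chain = "A") {
  build_backbone(sequence, phi = -139, psi = 135, chain = chain)
}

#' Random-coil dihedrals from broad Ramachandran-permitted regions
#'
#' Samples (phi, psi) per residue from three rectangular boxes (broad
#' beta/PPII, alpha-R, alpha-L) with weights 0.5/0.35/0.15, using the
#' current RNG stream (seed with [withr::with_seed()] or the `seed`
#' arguments of the higher-level generators). No physical force field is
#' implied; the coil generator exists to make structurally diverse,
#' assignment-poor frames.
#'
#' @param n Number of residues.
#' @return List with numeric `phi` and `psi` vectors (degrees).
#' @export
sample_coil_dihedrals <- function(n) {
  box <- matrix(c(-160, -60, 90, 175,
                  -90, -45, -60, -20,
                  45, 90, 0, 60), nrow = 3, byrow = TRUE)
  pick <- sample.int(3, n, replace = TRUE, prob = c(0.5, 0.35, 0.15))
  phi <- stats::runif(n, box[pick, 1], box[pick, 2])
  psi <- stats::runif(n, box[pick, 3], box[pick, 4])
  list(phi = phi, psi = psi)
}
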