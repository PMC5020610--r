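#' @importFrom rlang .data
NULL

ATOM_CLASSES <- c("main_chain", "side_chain", "ligand", "hydrogen")

# Average atomic masses (u) for the elements the generators emit.
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974)

#' Molecular topology for a peptide/ligand system
#'
#' A topology declares the static structure shared by every frame of an
#' ensemble: chains, residues and atoms, the main-chain/side-chain/ligand/
#' hydrogen partition used by the analyses, and named aromatic-ring and
#' cationic-group memberships. Coordinates live in [conformation()] /
#' [ensemble()] objects that reference a topology.
#'
#' @param atoms A data frame with one row per atom and columns `chain`
#'   (character), `resid` (1-based integer residue number within the chain),
#'   `resname` (3-letter residue or ligand name), `name` (atom name, unique
#'   within its residue), `element` (element symbol), `class` (one of
#'   `"main_chain"`, `"side_chain"`, `"ligand"`, `"hydrogen"`), and optional
#'   `ring` / `charged` columns holding group labels (`NA` for members of no
#'   group).
#'
#' @return An object of class `"topology"`: a list with the validated atom
#'   tibble (`$atoms`) and a `homodimer` flag set when exactly two peptide
#'   chains with identical residue and atom sequences are present.
#' @export
#' @examples
#' top <- topology(data.frame(
#'   chain = "A", resid = 1, resname = "GLY",
#'   name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
#'   class = "main_chain"
#' ))
#' n_atoms(top)
topology <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("chain", "resid", "resname", "name", "element", "class")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("topology atoms lack columns: ", paste(miss, collapse = ", "))
  if (!"ring" %in% names(atoms)) atoms$ring <- NA_character_
  if (!"charged" %in% names(atoms)) atoms$charged <- NA_character_
  atoms$resid <- as.integer(atoms$resid)
  bad <- setdiff(unique(atoms$class), ATOM_CLASSES)
  if (length(bad)) stop("unknown atom class: ", paste(bad, collapse = ", "))

  dup <- atoms |>
    dplyr::count(.data$chain, .data$resid, .data$name) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicated atom name within a residue: ",
         paste(dup$chain, dup$resid, dup$name, collapse = "; "))
  }
  ring_tbl <- atoms[!is.na(atoms$ring), ]
  if (nrow(ring_tbl)) {
    chk <- ring_tbl |>
      dplyr::group_by(.data$ring) |>
      dplyr::summarise(n = dplyr::n(),
                       nres = dplyr::n_distinct(paste(.data$chain, .data$resid)))
    if (any(chk$n < 3)) stop("ring group with fewer than 3 atoms: ",
                             paste(chk$ring[chk$n < 3], collapse = ", "))
    if (any(chk$nres > 1)) stop("ring group spanning residues: ",
                                paste(chk$ring[chk$nres > 1], collapse = ", "))
  }

  top <- structure(list(atoms = atoms), class = "topology")
  top$homodimer <- .detect_homodimer(top)
  top
}

.detect_homodimer <- function(top) {
  pc <- peptide_chains(top)
  if (length(pc) != 2) return(FALSE)
  a <- top$atoms[top$atoms$chain == pc[1] & top$atoms$class != "ligand", ]
  b <- top$atoms[top$atoms$chain == pc[2] & top$atoms$class != "ligand", ]
  nrow(a) == nrow(b) &&
    all(a$resname == b$resname) && all(a$name == b$name) &&
    all(a$resid == b$resid)
}

#' @export
print.topology <- function(x, ...) {
  res <- residues(x)
  cat("<topology> ", nrow(x$atoms), " atoms, ",
      length(unique(x$atoms$chain)), " chain(s), ",
      nrow(res), " residues",
      if (isTRUE(x$homodimer)) " [homodimer]" else "", "\n", sep = "")
  invisible(x)
}

#' Number of atoms declared by a topology
#' @param top A [topology()].
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Residue table of a topology
#' @param top A [topology()].
#' @param peptide_only Drop ligand residues?
#' @return Tibble with `chain`, `resid`, `resname`, one row per residue, in
#'   topology order.
#' @export
residues <- function(top, peptide_only = FALSE) {
  a <- top$atoms
  if (peptide_only) a <- a[a$class != "ligand", ]
  dplyr::distinct(a, .data$chain, .data$resid, .data$resname)
}

#' Chains whose atoms are peptide (non-ligand) atoms
#' @param top A [topology()].
#' @return Character vector of chain identifiers in topology order.
#' @export
peptide_chains <- function(top) {
  unique(top$atoms$chain[top$atoms$class != "ligand"])
}

#' Chains consisting of ligand atoms
#' @param top A [topology()].
#' @return Character vector of chain identifiers (may be empty).
#' @export
ligand_chains <- function(top) {
  setdiff(unique(top$atoms$chain), peptide_chains(top))
}

#' Named aromatic-ring atom groups
#' @param top A [topology()].
#' @param chain Optional chain filter.
#' @return Named list of ordered atom-index vectors, one per ring group.
#' @export
ring_groups <- function(top, chain = NULL) {
  a <- top$atoms
  idx <- which(!is.na(a$ring))
  if (!is.null(chain)) idx <- idx[a$chain[idx] %in% chain]
  split(idx, a$ring[idx])
}

#' Named cationic-group atom lists
#' @inheritParams ring_groups
#' @return Named list of atom-index vectors.
#' @export
charged_groups <- function(top, chain = NULL) {
  a <- top$atoms
  idx <- which(!is.na(a$charged))
  if (!is.null(chain)) idx <- idx[a$chain[idx] %in% chain]
  split(idx, a$charged[idx])
}

#' Select atom indices by class and chain
#'
#' Selection depends only on the topology, never on coordinates, so the
#' returned indices are valid for every frame of an ensemble sharing the
#' topology.
#'
#' @param x A [topology()], [conformation()] or [ensemble()].
#' @param class Atom classes to keep (subset of `"main_chain"`,
#'   `"side_chain"`, `"ligand"`, `"hydrogen"`); `NULL` keeps all.
#' @param chain Chains to keep; `NULL` keeps all.
#' @param heavy Drop hydrogens (class or element H)?
#' @return Integer vector of atom indices in topology order.
#' @export
select_atoms <- function(x, class = NULL, chain = NULL, heavy = FALSE) {
  top <- as_topology(x)
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(class)) {
    bad <- setdiff(class, ATOM_CLASSES)
    if (length(bad)) stop("unknown atom class: ", paste(bad, collapse = ", "))
    keep <- keep & a$class %in% class
  }
  if (!is.null(chain)) {
    bad <- setdiff(chain, unique(a$chain))
    if (length(bad)) stop("unknown chain: ", paste(bad, collapse = ", "))
    keep <- keep & a$chain %in% chain
  }
  if (heavy) keep <- keep & a$class != "hydrogen" & a$element != "H"
  which(keep)
}

as_topology <- function(x) {
  if (inherits(x, "topology")) return(x)
  if (!is.null(x$topology)) return(x$topology)
  stop("cannot extract a topology from this object")
}

#' Atomic masses for the atoms of a topology
#' @param top A [topology()].
#' @return Numeric vector of masses (u), one per atom.
#' @export
atom_masses <- function(top) {
  m <- ELEMENT_MASS[top$atoms$element]
  if (anyNA(m)) {
    stop("no mass tabulated for element(s): ",
         paste(unique(top$atoms$element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Read / write a topology declaration (JSON)
#'
#' The declaration is the JSON serialization of the atom table; it carries
#' the main-chain/side-chain partition, ring groups and charged groups that
#' coordinate files do not.
#'
#' @param path File path.
#' @return `read_topology()` returns a [topology()]; `write_topology()`
#'   returns `path` invisibly.
#' @export
read_topology <- function(path) {
  topology(jsonlite::fromJSON(path))
}

#' @rdname read_topology
#' @param top A [topology()].
#' @export
write_topology <- function(top, path) {
  jsonlite::write_json(top$atoms, path, na = "null", digits = NA)
  invisible(path)
}
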