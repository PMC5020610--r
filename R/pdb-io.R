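# Multi-MODEL PDB reader/writer. No installed R package parses PDB, so the
# fixed-width format is handled here directly. Internal unit is nm; PDB
# coordinate fields are Angstrom, converted at this boundary.

#' Read a multi-MODEL PDB file into an ensemble
#'
#' Each `MODEL ... ENDMDL` block becomes one frame; a file without MODEL
#' records is read as a single implicit model. Coordinates are converted
#' from Angstrom to nm. When a topology declaration is supplied, atom names
#' and counts are checked model by model against it; otherwise a minimal
#' topology is inferred from the records (`N`/`CA`/`C`/`O`/`OXT` ->
#' main chain, element H -> hydrogen, `HETATM` -> ligand; ring and charged
#' groups cannot be inferred and are left empty).
#'
#' @param path PDB file path.
#' @param topology_spec Optional [topology()] (or path to a JSON topology
#'   declaration) the file must conform to.
#' @return An [ensemble()] with uniform weights.
#' @export
read_multi_model_pdb <- function(path, topology_spec = NULL) {
  if (is.character(topology_spec)) topology_spec <- read_topology(topology_spec)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_id <- cumsum(trimws(rec) == "MODEL")
  if (max(model_id) == 0) model_id <- model_id + 1L
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  if (!length(atom_lines)) stop("no ATOM/HETATM records in ", path)

  parse_block <- function(ln) {
    tibble::tibble(
      het = substr(ln, 1, 6) == "HETATM",
      name = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain = trimws(substr(ln, 22, 22)),
      resid = as.integer(substr(ln, 23, 26)),
      x = as.numeric(substr(ln, 31, 38)),
      y = as.numeric(substr(ln, 39, 46)),
      z = as.numeric(substr(ln, 47, 54)),
      element = trimws(substr(ln, 77, 78))
    )
  }

  models <- split(atom_lines, atom_model)
  first <- parse_block(models[[1]])
  if (any(first$element == "")) {
    first$element <- ifelse(first$element == "",
                            substr(first$name, 1, 1), first$element)
  }

  if (is.null(topology_spec)) {
    cls <- ifelse(first$het, "ligand",
                  ifelse(first$element == "H", "hydrogen",
                         ifelse(first$name %in% c("N", "CA", "C", "O", "OXT"),
                                "main_chain", "side_chain")))
    top <- topology(tibble::tibble(
      chain = first$chain, resid = first$resid, resname = first$resname,
      name = first$name, element = first$element, class = cls
    ))
  } else {
    top <- topology_spec
  }

  n_ref <- n_atoms(top)
  frames <- vector("list", length(models))
  for (m in seq_along(models)) {
    blk <- parse_block(models[[m]])
    if (nrow(blk) != n_ref) {
      stop("model ", m, " has ", nrow(blk), " atoms; expected ", n_ref)
    }
    mism <- which(blk$name != top$atoms$name)
    if (length(mism)) {
      stop("model ", m, ": atom ", mism[1], " is '", blk$name[mism[1]],
           "' but topology declares '", top$atoms$name[mism[1]], "'")
    }
    frames[[m]] <- cbind(blk$x, blk$y, blk$z) / 10  # Angstrom -> nm
  }
  ensemble(top, frames)
}

#' Write an ensemble as a multi-MODEL PDB file
#'
#' Peptide atoms are written as `ATOM`, ligand atoms as `HETATM`, with `TER`
#' after each chain and one `MODEL`/`ENDMDL` block per frame. Coordinates
#' are converted nm to Angstrom and must fit the fixed 8.3 field.
#'
#' @param ens An [ensemble()] or [conformation()].
#' @param path Output file path.
#' @return `path`, invisibly. Round-trips through
#'   [read_multi_model_pdb()] reproduce coordinates to the 1e-3 Angstrom
#'   precision of the format.
#' @export
write_multi_model_pdb <- function(ens, path) {
  if (inherits(ens, "conformation")) ens <- ensemble(ens$topology, list(ens$xyz))
  if (!inherits(ens, "ensemble")) stop("ens must be an ensemble or conformation")
  a <- ens$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  out <- character(0)
  for (m in seq_along(ens$frames)) {
    xyz <- ens$frames[[m]] * 10  # nm -> Angstrom
    if (any(abs(xyz) >= 10000) || any(xyz <= -1000)) {
      stop("coordinates exceed the PDB 8.3 field width in frame ", m)
    }
    out <- c(out, sprintf("MODEL     %4d", m))
    serial <- 0L
    for (ch in unique(a$chain)) {
      idx <- which(a$chain == ch)
      for (i in idx) {
        serial <- serial + 1L
        nm <- a$name[i]
        nm_fmt <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
        out <- c(out, sprintf(
          "%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (a$class[i] == "ligand") "HETATM" else "ATOM",
          serial, nm_fmt, a$resname[i], ch, a$resid[i],
          xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0, a$element[i]))
      }
      if (a$class[idx[1]] != "ligand") out <- c(out, "TER")
    }
    out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, con)
  invisible(path)
}
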