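#' A single conformation (one frame)
#'
#' Couples an `n x 3` coordinate matrix (nm) to the [topology()] describing
#' its atoms.
#'
#' @param topology A [topology()].
#' @param xyz Numeric matrix, `n_atoms(topology)` rows and 3 columns, nm.
#' @param frame_index Integer frame label.
#' @param box Optional length-3 box vector (nm).
#' @return An object of class `"conformation"`.
#' @export
conformation <- function(topology, xyz, frame_index = 1L, box = NULL) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3) stop("xyz must be an n x 3 numeric matrix")
  if (nrow(xyz) != n_atoms(topology)) {
    stop("coordinate count (", nrow(xyz), ") does not match topology atom count (",
         n_atoms(topology), ")")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates in conformation")
  dimnames(xyz) <- NULL
  structure(list(topology = topology, xyz = xyz,
                 frame_index = as.integer(frame_index), box = box),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> frame", x$frame_index, "with", nrow(x$xyz), "atoms\n")
  invisible(x)
}

#' A weighted conformational ensemble
#'
#' An ordered set of frames sharing one topology, with per-frame weights
#' (uniform by default) and the temperature at which the ensemble was
#' sampled. This is the analyzed frame set of a simulation - e.g. the
#' frames collected at 310 K from a replica-exchange run.
#'
#' @param topology A [topology()].
#' @param frames List of `n x 3` coordinate matrices (nm) or of
#'   [conformation()] objects.
#' @param weights Nonnegative per-frame weights; normalized to sum to 1.
#'   Default uniform.
#' @param temperature_K Ensemble temperature in kelvin (default 310).
#' @return An object of class `"ensemble"`.
#' @export
ensemble <- function(topology, frames, weights = NULL, temperature_K = 310) {
  if (inherits(frames, "conformation")) frames <- list(frames)
  frames <- lapply(frames, function(f) if (inherits(f, "conformation")) f$xyz else as.matrix(f))
  if (length(frames) < 1) stop("an ensemble needs at least one frame")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != na || ncol(frames[[i]]) != 3) {
      stop("frame ", i, " has wrong dimensions (expected ", na, " x 3)")
    }
    if (!all(is.finite(frames[[i]]))) stop("non-finite coordinates in frame ", i)
    dimnames(frames[[i]]) <- NULL
  }
  if (is.null(weights)) weights <- rep(1, length(frames))
  if (length(weights) != length(frames)) stop("one weight per frame required")
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero")
  structure(list(topology = topology, frames = frames, weights = weights / s,
                 temperature_K = temperature_K),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble> ", n_frames(x), " frames x ", n_atoms(x$topology),
      " atoms at ", x$temperature_K, " K\n", sep = "")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens An [ensemble()].
#' @return Integer frame count.
#' @export
n_frames <- function(ens) length(ens$frames)

#' Extract one frame as a conformation
#' @param ens An [ensemble()].
#' @param i Frame index.
#' @return A [conformation()].
#' @export
get_frame <- function(ens, i) {
  conformation(ens$topology, ens$frames[[i]], frame_index = i)
}

#' Subset an ensemble by frame indices
#' @param ens An [ensemble()].
#' @param idx Frame indices to keep (order preserved, weights renormalized).
#' @return An [ensemble()].
#' @export
subset_frames <- function(ens, idx) {
  if (length(idx) < 1) stop("empty frame subset")
  ensemble(ens$topology, ens$frames[idx], weights = ens$weights[idx],
           temperature_K = ens$temperature_K)
}

#' Coordinates of an ensemble as a tidy tibble
#' @param ens An [ensemble()].
#' @return Tibble with one row per frame x atom: frame, atom index, the
#'   topology columns, and x/y/z in nm.
#' @export
coord_tbl <- function(ens) {
  a <- ens$topology$atoms
  purrr::map_dfr(seq_along(ens$frames), function(i) {
    tibble::tibble(frame = i, atom = seq_len(nrow(a)),
                   chain = a$chain, resid = a$resid, resname = a$resname,
                   name = a$name,
                   x = ens$frames[[i]][, 1], y = ens$frames[[i]][, 2],
                   z = ens$frames[[i]][, 3])
  })
}
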