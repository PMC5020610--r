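# Seeded mixture-ensemble generation with known ground truth, and the
# named presets used by the pipeline and the validation suite. Frames are
# drawn by categorical sampling over rigid component conformers plus a
# small Gaussian coordinate jitter, so component identity (the "true"
# cluster / secondary-structure label) is known for every frame.

.component_builders <- function() {
  dimer_sep <- function(A, B) {
    # translation placing B's bounding box 1 nm beyond A's along x
    c(max(A$xyz[, 1]) - min(B$xyz[, 1]) + 1.0, 0, 0)
  }
  pair <- function(build) {
    function(p) {
      A <- build(p, "A"); B <- build(p, "B")
      build_dimer(A, B, translation = dimer_sep(A, B))
    }
  }
  list(
    helix = function(p) build_helix(p$sequence),
    strand = function(p) build_strand(p$sequence),
    coil = function(p) {
      d <- sample_coil_dihedrals(length(seq3_or_id(p$sequence)))
      build_backbone(p$sequence, d$phi, d$psi)
    },
    hairpin = function(p) build_hairpin(p$sequence, p$strand1, p$turn, p$strand2),
    helix_dimer = pair(function(p, ch) build_helix(p$sequence, chain = ch)),
    strand_dimer = pair(function(p, ch) build_strand(p$sequence, chain = ch)),
    coil_dimer = pair(function(p, ch) {
      d <- sample_coil_dihedrals(length(seq3_or_id(p$sequence)))
      build_backbone(p$sequence, d$phi, d$psi, chain = ch)
    }),
    sheet_dimer = function(p) build_sheet_dimer(p$sequence, p$strand1,
                                                p$turn, p$strand2)
  )
}

seq3_or_id <- function(s) {
  if (length(s) == 1 && !s[1] %in% AA3) seq3(s) else s
}

#' Mixture-component specification
#'
#' @param generator One of `"helix"`, `"strand"`, `"coil"`, `"hairpin"`,
#'   `"helix_dimer"`, `"strand_dimer"`, `"coil_dimer"`, `"sheet_dimer"`.
#' @param weight Nonnegative mixture weight.
#' @param ... Generator parameters (`sequence`, and for hairpins
#'   `strand1`/`turn`/`strand2`).
#' @return A component spec for [generate_mixture()].
#' @export
mixture_component <- function(generator, weight, ...) {
  if (!generator %in% names(.component_builders())) {
    stop("unknown generator: ", generator)
  }
  if (weight < 0) stop("component weight must be nonnegative")
  list(generator = generator, weight = weight, params = list(...))
}

#' Generate a seeded mixture ensemble with ground-truth labels
#'
#' Builds each component's conformer once, then draws `n_frames` frames by
#' seeded categorical sampling over the components and adds isotropic
#' Gaussian coordinate jitter (`sd = jitter` nm, small relative to any
#' clustering cutoff, so each component stays one cluster). All components
#' must produce identical topologies (same sequence and chain layout).
#'
#' @param components List of [mixture_component()] specs; weights are
#'   normalized and must not sum to zero.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; the same seed reproduces the ensemble
#'   exactly.
#' @param jitter Per-coordinate Gaussian noise sd in nm (default 0.002).
#' @param temperature_K Ensemble temperature tag (default 310).
#' @return List with `$ensemble`, `$labels` (tibble: frame, component) and
#'   `$bases` (the component conformations).
#' @export
generate_mixture <- function(components, n_frames, seed, jitter = 0.002,
                             temperature_K = 310) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  w <- vapply(components, `[[`, numeric(1), "weight")
  if (any(w < 0)) stop("negative component weight")
  if (sum(w) <= 0) stop("component weights sum to zero")
  w <- w / sum(w)
  nm <- names(components)
  if (is.null(nm)) nm <- rep("", length(components))
  gen <- vapply(components, `[[`, character(1), "generator")
  nm <- ifelse(nm == "", make.unique(gen), nm)

  builders <- .component_builders()
  withr::with_seed(seed, {
    bases <- lapply(components, function(cmp) {
      builders[[cmp$generator]](cmp$params)
    })
    ref <- bases[[1]]$topology$atoms[, c("chain", "resid", "name")]
    for (b in bases[-1]) {
      if (!identical(b$topology$atoms[, c("chain", "resid", "name")], ref)) {
        stop("mixture components must share one topology")
      }
    }
    label <- sample.int(length(components), n_frames, replace = TRUE, prob = w)
    frames <- lapply(label, function(k) {
      x <- bases[[k]]$xyz
      x + matrix(stats::rnorm(length(x), sd = jitter), nrow(x), 3)
    })
  })
  list(ensemble = ensemble(bases[[1]]$topology, frames,
                           temperature_K = temperature_K),
       labels = tibble::tibble(frame = seq_len(n_frames),
                               component = nm[label]),
       bases = stats::setNames(bases, nm))
}

#' Named synthetic-ensemble presets
#'
#' Ready-made test worlds for the full pipeline:
#' * `"hairpin-dimer"`: a 37-residue homodimer mixture dominated by the
#'   three-stranded-sheet conformer (hairpin chain + paired strand chain,
#'   weight 0.5) with helix-dimer (0.25) and coil-dimer (0.25) minorities.
#' * `"hairpin-dimer+ligand"`: the same peptide world with one three-ring
#'   ligand per frame placed against the chain-A tyrosine ring at a
#'   seeded mix of parallel (0.40 nm), perpendicular (0.58 nm) and
#'   unstacked geometries.
#' * `"sheet-rich"` / `"coil-rich"`: contrasting dimer worlds (0.8/0.2 vs
#'   0.1/0.9 sheet-dimer/coil-dimer) for condition-comparison tests.
#'
#' The default hairpin ranges are strands 8-16 and 25-33 with loop 17-24,
#' the strand-loop-strand architecture reported for the amyloidogenic
#' hairpin conformer of hIAPP.
#'
#' @param name Preset name.
#' @param n_frames Frames to generate (default 40).
#' @param seed Integer seed.
#' @param sequence Peptide sequence (default [hiapp_sequence()]).
#' @return As [generate_mixture()]; for the ligand preset `$labels` gains
#'   a `stacking` column with the planted geometry class.
#' @export
synth_preset <- function(name = c("hairpin-dimer", "hairpin-dimer+ligand",
                                  "sheet-rich", "coil-rich"),
                         n_frames = 40, seed = 1,
                         sequence = hiapp_sequence()) {
  name <- match.arg(name)
  hp <- list(sequence = sequence, strand1 = 8:16, turn = 17:24,
             strand2 = 25:33)
  comp <- switch(name,
    "hairpin-dimer" = ,
    "hairpin-dimer+ligand" = list(
      sheet = do.call(mixture_component,
                      c(list("sheet_dimer", 0.5), hp)),
      helix = mixture_component("helix_dimer", 0.25, sequence = sequence),
      coil = mixture_component("coil_dimer", 0.25, sequence = sequence)),
    "sheet-rich" = list(
      sheet = do.call(mixture_component, c(list("sheet_dimer", 0.8), hp)),
      coil = mixture_component("coil_dimer", 0.2, sequence = sequence)),
    "coil-rich" = list(
      sheet = do.call(mixture_component, c(list("sheet_dimer", 0.1), hp)),
      coil = mixture_component("coil_dimer", 0.9, sequence = sequence)))
  mix <- generate_mixture(comp, n_frames, seed)
  if (name != "hairpin-dimer+ligand") return(mix)
  .add_preset_ligand(mix, seed)
}

# Attach one ligand per frame at a seeded stacking geometry against the
# first aromatic ring of chain A.
.add_preset_ligand <- function(mix, seed) {
  top <- mix$ensemble$topology
  ringsA <- ring_groups(top, chain = "A")
  if (!length(ringsA)) stop("preset sequence has no aromatic residue")
  target <- names(ringsA)[length(ringsA)]
  geoms <- list(parallel = function(u) c(0.40, 15 * u),
                perpendicular = function(u) c(0.58, 80 + 10 * u),
                none = function(u) c(1.10, 20 + 50 * u))
  withr::with_seed(seed + 1L, {
    cls <- sample(names(geoms), n_frames(mix$ensemble), replace = TRUE,
                  prob = c(0.35, 0.35, 0.3))
    us <- stats::runif(n_frames(mix$ensemble))
    sub_seeds <- sample.int(1e6, n_frames(mix$ensemble))
  })
  frames <- vector("list", n_frames(mix$ensemble))
  new_top <- NULL
  for (f in seq_along(frames)) {
    conf <- get_frame(mix$ensemble, f)
    g <- geoms[[cls[f]]](us[f])
    placed <- NULL
    for (try_k in 0:29) {
      placed <- tryCatch(
        place_ligand_ring(conf, target, centroid_distance = g[1],
                          plane_angle = g[2], seed = sub_seeds[f] + try_k,
                          side = if (try_k %% 2 == 0) 1 else -1),
        error = function(e) NULL)
      if (!is.null(placed)) break
    }
    if (is.null(placed)) stop("could not place ligand for frame ", f)
    frames[[f]] <- placed$xyz
    if (is.null(new_top)) new_top <- placed$topology
  }
  mix$ensemble <- ensemble(new_top, frames,
                           temperature_K = mix$ensemble$temperature_K)
  mix$labels$stacking <- cls
  mix
}
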