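# A rigid EGCG-like three-ring ligand template and controlled-geometry
# placement of its rings against peptide aromatic rings.

#' Rigid three-ring ligand template
#'
#' An idealized stand-in for a catechin-type polyphenol such as EGCG: three
#' planar six-membered carbon rings (ring1, ring2 and ring3, the last
#' standing in for the gallate ester group) joined by single linker atoms
#' along a common axis. The two torsions rotate ring2 and ring3 about that
#' axis, so the inter-ring plane angles are `torsion12`, `torsion13` and
#' `|torsion13 - torsion12|` exactly. No real ligand chemistry (substituents,
#' charges, conformer energetics) is modeled.
#'
#' @param torsion12,torsion13 Plane rotations of ring2 and ring3 relative to
#'   ring1, degrees.
#' @param chain Chain identifier for the ligand (default `"L"`).
#' @return A single-residue ligand [conformation()] with ring groups
#'   `<chain>:ring1`, `<chain>:ring2`, `<chain>:ring3`.
#' @export
ligand_template <- function(torsion12 = 50, torsion13 = 90, chain = "L") {
  ring_at <- function(x0, tau) {
    nrm <- c(0, -sin(deg2rad(tau)), cos(deg2rad(tau)))
    a <- c(1, 0, 0)
    b <- cross3(nrm, a)
    t(vapply(0:5, function(j) {
      th <- deg2rad(180 + 60 * j)
      c(x0, 0, 0) + RING_CC * (cos(th) * a + sin(th) * b)
    }, numeric(3)))
  }
  step <- RING_CC + 2 * 0.15 + RING_CC  # vertex-linker-vertex spacing
  r1 <- ring_at(0, 0)
  r2 <- ring_at(step, torsion12)
  r3 <- ring_at(2 * step, torsion13)
  cl1 <- c(RING_CC + 0.15, 0, 0)
  cl2 <- c(step + RING_CC + 0.15, 0, 0)

  nm <- c(paste0("C1", 1:6), "CL1", paste0("C2", 1:6), "CL2", paste0("C3", 1:6))
  ring_lab <- c(rep(paste0(chain, ":ring1"), 6), NA,
                rep(paste0(chain, ":ring2"), 6), NA,
                rep(paste0(chain, ":ring3"), 6))
  xyz <- rbind(r1, cl1, r2, cl2, r3)
  top <- topology(tibble::tibble(
    chain = chain, resid = 1L, resname = "EGC", name = nm, element = "C",
    class = "ligand", ring = ring_lab, charged = NA_character_))
  conformation(top, xyz)
}

#' Place a ligand ring at a controlled stacking geometry
#'
#' Rigidly positions a ligand so that one of its rings sits at a requested
#' centroid distance and plane angle from a target aromatic ring of the
#' peptide. The ligand-ring centroid is placed along the target ring's
#' normal; the direction in which the ligand plane tilts and the spin of the
#' ligand about its own ring normal are drawn uniformly from the seeded RNG,
#' so repeated placements sample the azimuthal degree of freedom. The
#' realized geometry reproduces the request exactly (to numerical
#' precision).
#'
#' @param conf A peptide [conformation()] containing the target ring.
#' @param target_ring Name of a ring group in `conf` (see [ring_groups()]).
#' @param centroid_distance Requested ring-centroid separation, nm
#'   (>= 0.3).
#' @param plane_angle Requested angle between ring planes, degrees in
#'   `[0, 90]`.
#' @param seed Integer seed for the azimuthal randomization.
#' @param ligand Ligand [conformation()] (default [ligand_template()]).
#' @param ligand_ring Which ligand ring to place (default its first ring
#'   group).
#' @param side Which face of the target ring to use: `+1` (along the
#'   oriented normal, default) or `-1`; distance and folded plane angle
#'   are unaffected.
#' @return A merged [conformation()] (peptide + ligand). Ring-atom overlaps
#'   closer than 0.1 nm are an error.
#' @export
place_ligand_ring <- function(conf, target_ring, centroid_distance,
                              plane_angle, seed, ligand = ligand_template(),
                              ligand_ring = NULL, side = 1) {
  if (!side %in% c(1, -1)) stop("side must be +1 or -1")
  if (centroid_distance < 0.3) stop("centroid_distance must be >= 0.3 nm")
  if (plane_angle < 0 || plane_angle > 90) stop("plane_angle must be in [0, 90]")
  rg <- ring_groups(conf$topology)
  if (!target_ring %in% names(rg)) stop("unknown target ring: ", target_ring)
  lrg <- ring_groups(ligand$topology)
  if (is.null(ligand_ring)) ligand_ring <- names(lrg)[1]
  if (!ligand_ring %in% names(lrg)) stop("unknown ligand ring: ", ligand_ring)

  tg <- ring_geometry(conf, rg[[target_ring]])
  lg <- ring_geometry(ligand, lrg[[ligand_ring]])

  withr::with_seed(seed, {
    az <- stats::runif(1, 0, 360)
    spin <- stats::runif(1, 0, 360)
  })
  e1 <- perp_vector(tg$normal)
  e2 <- cross3(tg$normal, e1)
  tilt_dir <- cos(deg2rad(az)) * e1 + sin(deg2rad(az)) * e2
  n_new <- cos(deg2rad(plane_angle)) * tg$normal +
    sin(deg2rad(plane_angle)) * tilt_dir
  p_new <- tg$centroid + side * centroid_distance * tg$normal

  # rotation taking the ligand ring normal onto n_new, then a spin about it
  v <- cross3(lg$normal, n_new)
  s <- vnorm(v)
  cth <- sum(lg$normal * n_new)
  R1 <- if (s < 1e-12) {
    if (cth > 0) diag(3) else rotation_about_axis(perp_vector(lg$normal), 180)
  } else {
    rotation_about_axis(v, rad2deg(atan2(s, cth)))
  }
  R <- rotation_about_axis(n_new, spin) %*% R1
  t3 <- p_new - as.numeric(R %*% lg$centroid)
  lig_xyz <- apply_rigid(ligand$xyz, R, t3)

  pep_heavy <- select_atoms(conf$topology, heavy = TRUE)
  d2 <- cross_dist2(conf$xyz[pep_heavy, , drop = FALSE], lig_xyz)
  if (min(d2) < 0.1^2) {
    stop(sprintf("requested geometry causes ring-atom overlap (%.3f nm < 0.1 nm)",
                 sqrt(min(d2))))
  }
  lig_chain <- unique(ligand$topology$atoms$chain)
  if (lig_chain %in% unique(conf$topology$atoms$chain)) {
    stop("ligand chain id '", lig_chain, "' already used; relabel the ligand")
  }
  top <- topology(dplyr::bind_rows(conf$topology$atoms, ligand$topology$atoms))
  conformation(top, rbind(conf$xyz, lig_xyz))
}
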