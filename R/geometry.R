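# Low-level vector geometry shared by the builders and analyses.
# All coordinates are nm unless a function says otherwise.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at vertex b of the triple a-b-c, in degrees
#' @noRd
angle3 <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(pmin(1, pmax(-1, sum(u * v)))))
}

#' Signed dihedral a-b-c-d in degrees, IUPAC convention, range (-180, 180]
#' @noRd
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place atom D given positions A, B, C, a bond length r(C-D), the angle
#' B-C-D and the torsion A-B-C-D (natural-extension reference frame step).
#' Lengths in the unit of the input coordinates; angles in degrees.
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' Rotation matrix for angle (degrees) about a unit axis (Rodrigues)
#' @noRd
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

#' Uniform random rotation matrix (unit quaternion from 4 normals).
#' Uses the current RNG stream; callers seed via withr::with_seed().
#' @noRd
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Any unit vector perpendicular to v (deterministic choice)
#' @noRd
perp_vector <- function(v) {
  v <- unit(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(cross3(v, ref))
}

#' Apply rigid transform x -> x %*% t(R) + t to an n x 3 matrix
#' @noRd
apply_rigid <- function(xyz, rot, trans = c(0, 0, 0)) {
  sweep(xyz %*% t(rot), 2, trans, "+")
}

#' All pairwise squared distances between rows of a (n x 3) and b (m x 3)
#' @noRd
cross_dist2 <- function(a, b) {
  ra <- rowSums(a * a)
  rb <- rowSums(b * b)
  d2 <- outer(ra, rb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
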