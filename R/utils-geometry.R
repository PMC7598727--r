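# Small vector-geometry helpers shared across modules. All lengths in nm.

vec_norm <- function(v) sqrt(sum(v^2))

row_norms <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) {
  n <- row_norms(m)
  if (any(n < 1e-12)) stop("zero-length vector cannot be normalized", call. = FALSE)
  m / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Row-wise cross product of an n x 3 matrix with a single 3-vector.
cross_rows <- function(m, v) {
  cbind(
    m[, 2] * v[3] - m[, 3] * v[2],
    m[, 3] * v[1] - m[, 1] * v[3],
    m[, 1] * v[2] - m[, 2] * v[1]
  )
}

#' Dihedral angle of four points
#'
#' Torsion angle about the b-c axis for points a-b-c-d, using the
#' standard atan2 formulation. Accepts either single 3-vectors or
#' n x 3 matrices (rowwise angles).
#'
#' @param a,b,c,d Points as length-3 vectors or n x 3 matrices.
#' @return Angle(s) in degrees in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  as_m <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)
  a <- as_m(a); b <- as_m(b); c <- as_m(c); d <- as_m(d)
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cbind(
    b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
    b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
    b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1]
  )
  n2 <- cbind(
    b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
    b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
    b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1]
  )
  m1 <- cbind(
    n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
    n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
    n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1]
  )
  x <- rowSums(n1 * n2)
  # (n1 x n2) . b2 = -(n1 x b2) . n2, giving the IUPAC sign convention
  y <- -rowSums(m1 * n2) / row_norms(b2)
  ang <- atan2(y, x) * 180 / pi
  drop(ang)
}

# Place a new point D from three anchors A, B, C using internal
# coordinates: |CD| = bond, angle B-C-D, torsion A-B-C-D (degrees),
# with the torsion sign matching dihedral_angle().
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / vec_norm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / vec_norm(n)
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix about arbitrary unit axis by angle (radians).
rotation_about <- function(axis, theta) {
  u <- axis / vec_norm(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Uniform random rotation matrix (Arvo's quaternion method).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Minimum-image displacement for component differences d in a periodic
# box with edge lengths L (recycled); non-periodic dims pass through.
min_image <- function(d, box, periodic = c(TRUE, TRUE, TRUE)) {
  if (is.matrix(d)) {
    for (k in seq_len(ncol(d))) {
      if (periodic[k]) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    d
  } else {
    ifelse(periodic, d - box * round(d / box), d)
  }
}

lex_less <- function(p, q) {
  for (k in seq_along(p)) {
    if (p[k] < q[k]) return(TRUE)
    if (p[k] > q[k]) return(FALSE)
  }
  FALSE
}
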