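# Internal-coordinate geometry: atom placement, dihedrals, planes.

unit <- function(v) v / sqrt(sum(v^2))

# Place atom X given three predecessors: |X-c| = bond, angle(X,c,b) = angle,
# dihedral(X, c, b, a) = torsion (degrees).  Standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), -bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Dihedral angle of four points, degrees in (-180, 180]
#' @param p1,p2,p3,p4 length-3 Cartesian points
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  a <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (a <= -180) a + 360 else a
}

# Orthogonal least-squares plane through points: list(center, normal, frame)
ls_plane <- function(x) {
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  list(center = ctr, normal = sv$v[, 3], frame = sv$v)
}

# Acute angle between two directions, degrees
acute_angle <- function(u, v) {
  cu <- abs(sum(unit(u) * unit(v)))
  acos(min(1, cu)) * 180 / pi
}

# Rotation matrix -> unit quaternion (w, x, y, z)
rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Hemisphere-aligned normalized quaternion mean of a list of rotations.
mean_rotation <- function(Rs) {
  qs <- lapply(Rs, rot_to_quat)
  ref <- qs[[1]]
  acc <- rep(0, 4)
  for (q in qs) {
    if (sum(q * ref) < 0) q <- -q
    acc <- acc + q
  }
  quat_to_rot(acc / sqrt(sum(acc^2)))
}

# Deterministic quasi-uniform sample of n rotations (super-Fibonacci spiral,
# Alexa 2022): low-discrepancy coverage of SO(3) without randomness.
quasi_uniform_rotations <- function(n) {
  phi <- sqrt(2); psi <- 1.533751168755204288118041
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- (i - 0.5) / n
    t <- (i - 0.5)
    r <- sqrt(s); R <- sqrt(1 - s)
    alpha <- 2 * pi * t / phi
    beta <- 2 * pi * t / psi
    q <- c(r * sin(alpha), r * cos(alpha), R * sin(beta), R * cos(beta))
    out[[i]] <- quat_to_rot(q)
  }
  out
}
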