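# Low-level 3D geometry: bond/angle/dihedral measurement, NeRF-style chain
# extension, axis-angle rotations, and least-squares superposition.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle defined by three points
#'
#' Returns the planar angle a-b-c in degrees.
#'
#' @param a,b,c numeric length-3 coordinate vectors (\enc{Å}{Angstrom}).
#' @return Angle in degrees in `[0, 180]`.
#' @keywords internal
angle3 <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u)
  nv <- vnorm(v)
  if (nu < 1e-9 || nv < 1e-9) stop("degenerate angle: coincident atoms")
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  rad2deg(acos(ct))
}

#' Dihedral angle defined by four points
#'
#' Signed torsion a-b-c-d in degrees, IUPAC sign convention (right-handed
#' about the b->c axis, cis = 0).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors.
#' @return Torsion in degrees in `(-180, 180]`.
#' @keywords internal
dihedral4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("degenerate dihedral: collinear atoms")
  }
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# cross product (kept local; avoids dragging a dependency in for one line)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from three predecessors (chain extension)
#'
#' Natural-extension placement: returns the coordinates of atom `d` such
#' that `|d - c| = length`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `torsion`.
#'
#' @param a,b,c coordinates of the three reference atoms.
#' @param length bond length c-d in \enc{Å}{Angstrom}.
#' @param angle planar angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return Length-3 numeric vector.
#' @keywords internal
place_atom <- function(a, b, c, length, angle, torsion) {
  # hot path: inlined cross products / normalisation (called four times per
  # residue in every coordinate refresh)
  ang <- angle * (pi / 180)
  tor <- torsion * (pi / 180)
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n * n))
  if (nn < 1e-9) stop("degenerate placement: collinear reference atoms")
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  # local displacement in the frame (bc, m, n); the n component carries the
  # torsion sign matching dihedral4's right-handed convention
  sa <- sin(ang)
  c + (-length * cos(ang)) * bc + (length * sa * cos(tor)) * m +
    (-length * sa * sin(tor)) * n
}

#' Rotation matrix about an arbitrary unit axis
#'
#' @param axis length-3 vector (normalised internally).
#' @param theta rotation angle in radians (right-handed).
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, theta) {
  k <- unit(axis)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation vector (axis * angle) from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return length-3 rotation vector, radians.
#' @keywords internal
rotmat_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) return(c(0, 0, 0))
  if (abs(pi - theta) < 1e-6) {
    # near-pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    i <- which.max(ax)
    s <- c(1, 1, 1)
    for (j in seq_len(3)) {
      if (j != i && ax[j] > 1e-8) s[j] <- sign(B[i, j] / ax[i])
    }
    return(unit(ax * s) * theta)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  ax * theta
}

#' Rotation matrix from a rotation vector
#' @param v length-3 rotation vector, radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotvec_to_rotmat <- function(v) {
  theta <- vnorm(v)
  if (theta < 1e-12) return(diag(3))
  rotation_about_axis(v / theta, theta)
}

# ---- RigidTransform ---------------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' The value of a jump: the spatial relationship between two local residue
#' frames, carrying the six rigid-body degrees of freedom (three
#' translational, three rotational).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric, \enc{Å}{Angstrom}.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(R = rotation, t = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> t = [", paste(signif(x$t, 5), collapse = ", "),
      "], |rotvec| =", signif(vnorm(rotmat_to_rotvec(x$R)), 5), "rad\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` applies `b` in the frame produced by `a`
#' (i.e. frame' = frame %*% a %*% b).
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$t + a$R %*% b$t))
}

#' Invert a rigid transform
#' @param a a `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
rt_inverse <- function(a) {
  Rt <- t(a$R)
  rigid_transform(Rt, as.numeric(-Rt %*% a$t))
}

#' Identity rigid transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform()

#' Apply a rigid transform to points
#' @param a a `rigid_transform`.
#' @param x numeric matrix (n x 3) or length-3 vector.
#' @return Transformed coordinates, same shape as `x`.
#' @export
rt_apply <- function(a, x) {
  if (is.null(dim(x))) return(as.numeric(a$R %*% x + a$t))
  t(a$R %*% t(x) + a$t)
}

# six scalar rigid-body components: rb1..rb3 translation, rb4..rb6 rotation
# vector (radians)
rt_to_rb <- function(a) c(a$t, rotmat_to_rotvec(a$R))

rb_to_rt <- function(rb) {
  rigid_transform(rotvec_to_rotmat(rb[4:6]), rb[1:3])
}

# ---- superposition ----------------------------------------------------------

#' Minimal RMSD after least-squares superposition
#'
#' Kabsch superposition of two equally sized coordinate sets; returns the
#' root-mean-square deviation after the optimal rigid-body fit.
#'
#' @param a,b numeric n x 3 coordinate matrices (n >= 3).
#' @param subset optional integer vector of row indices used for the fit and
#'   the RMSD (default: all rows).
#' @return RMSD in \enc{Å}{Angstrom}.
#' @export
superpose_rmsd <- function(a, b, subset = NULL) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!is.null(subset)) {
    a <- a[subset, , drop = FALSE]
    b <- b[subset, , drop = FALSE]
  }
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in size")
  if (nrow(a) < 3) stop("superposition needs at least 3 atoms")
  ca <- colMeans(a)
  cb <- colMeans(b)
  A <- sweep(a, 2, ca)
  B <- sweep(b, 2, cb)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  U <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Br <- A %*% t(U)
  sqrt(mean(rowSums((Br - B)^2)))
}
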