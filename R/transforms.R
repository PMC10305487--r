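#' Rigid-body transform
#'
#' A proper rigid transform (rotation + translation) acting on row-vector
#' coordinates as `x %*% t(R) + t`. The rotation must be orthonormal with
#' determinant +1.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation (Angstrom).
#' @return object of class `RigidTransform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- unname(as.numeric(translation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1")
  }
  structure(list(R = rotation, t = translation), class = "RigidTransform")
}

#' Identity transform
#' @return identity `RigidTransform`.
#' @export
rt_identity <- function() rigid_transform()

#' Rotation about an axis
#'
#' @param axis length-3 axis direction (normalized internally).
#' @param angle_deg rotation angle, degrees, right-handed about `axis`.
#' @param center point the axis passes through (default origin).
#' @return `RigidTransform`.
#' @export
rt_axis_angle <- function(axis, angle_deg, center = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  # numerical cleanup keeps long composition chains orthonormal
  s <- svd(R); R <- s$u %*% t(s$v)
  rigid_transform(R, as.numeric(center - R %*% center))
}

#' Pure translation
#' @param v length-3 translation vector.
#' @return `RigidTransform`.
#' @export
rt_translation <- function(v) rigid_transform(diag(3), v)

#' Compose two transforms
#'
#' `rt_compose(a, b)` returns the transform applying `b` first, then `a`.
#'
#' @param a,b `RigidTransform`s.
#' @return composed `RigidTransform`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a transform
#' @param tf a `RigidTransform`.
#' @return inverse `RigidTransform`.
#' @export
rt_inverse <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Apply a transform to coordinates
#' @param tf a `RigidTransform`.
#' @param xyz n x 3 matrix or length-3 vector.
#' @return transformed coordinates, same shape.
#' @export
rt_apply <- function(tf, xyz) {
  if (is.null(dim(xyz))) {
    as.numeric(tf$R %*% xyz + tf$t)
  } else {
    sweep(xyz %*% t(tf$R), 2, tf$t, "+")
  }
}

#' Apply a transform to a whole model
#' @param m a `MolecularModel`.
#' @param tf a `RigidTransform`.
#' @return transformed model.
#' @export
transform_model <- function(m, tf) set_coords(m, rt_apply(tf, coords(m)))

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimizing the RMSD of `mobile` onto
#' `reference` over paired points.
#'
#' @param mobile,reference n x 3 matrices, same n >= 3, not all collinear.
#' @return list with `transform` (`RigidTransform`) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point sets must have equal length")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  if (svd(A)$d[2] < 1e-10) stop("points are collinear; superposition is degenerate")
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tf <- rigid_transform(R, as.numeric(cr - R %*% cm))
  fit <- rt_apply(tf, mobile)
  list(transform = tf, rmsd = sqrt(mean(rowSums((fit - reference)^2))))
}

#' Pairwise RMSD without fitting
#' @param a,b n x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
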