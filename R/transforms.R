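#' Rigid-body transforms
#'
#' A rigid transform maps coordinates `x` to `R x + t`, with `R` a proper
#' rotation (orthonormal, det +1) and `t` a translation in Angstrom. These are
#' the symmetry operators relating consecutive subunits of a helical filament.
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric translation (Angstrom).
#' @return An object of class `rigid_transform`.
#' @examples
#' tf <- rigid_transform(diag(3), c(0, 0, 5.6))
#' apply_transform(tf, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    abort("`rotation` must be orthonormal with determinant +1.",
          class = "helicomb_error_transform")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- tryCatch(rotation_angle(x$rotation), error = function(e) NA_real_)
  cat(sprintf("<rigid_transform> rotation %.3f deg, |t| = %.3f A\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A [rigid_transform()].
#' @param xyz An n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(transform, xyz) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(xyz))
  m <- if (vec) matrix(xyz, 1, 3) else as.matrix(xyz)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  as.numeric(-t(transform$rotation) %*% transform$translation))
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; positive angles are right-handed about `axis`.
#'
#' @param axis length-3 direction (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) {
    abort("Rotation axis has zero length.", class = "helicomb_error_degenerate_axis")
  }
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of `source`
#' onto `target` over matched rows.
#'
#' @param source,target n x 3 matrices of matched coordinates (n >= 3).
#' @return A list with `transform` (a [rigid_transform()] mapping `source`
#'   onto `target`), `rmsd` (Angstrom), and `residuals` (per-row distances
#'   after superposition).
#' @export
kabsch <- function(source, target) {
  P <- as.matrix(source)
  Q <- as.matrix(target)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3) {
    abort("Need at least 3 matched points for superposition.",
          class = "helicomb_error_correspondence")
  }
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  tf <- rigid_transform(R, t)
  res <- sqrt(rowSums((apply_transform(tf, P) - Q)^2))
  list(transform = tf, rmsd = sqrt(mean(res^2)), residuals = res)
}
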