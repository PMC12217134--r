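#' Round half away from zero
#'
#' Table-style rounding (0.005 -> 0.01, -0.005 -> -0.01), used for report
#' tables; machine-readable outputs keep full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Rotation matrix about an axis
#'
#' Rodrigues rotation by `angle` radians about `axis` (normalized
#' internally). Handy for constructing anatomic frames and for
#' rotation-invariance checks.
#'
#' @param axis 3-vector.
#' @param angle radians.
#' @return 3x3 proper orthonormal matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# uniform random proper rotation (uses the current RNG stream)
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Write a ground-truth manifest as JSON
#'
#' @param manifest a manifest list from a phantom generator.
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
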