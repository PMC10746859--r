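#' @title Canonical orientation by PCA
#' @description
#' The "front view" lays a structure flat against the screen: the
#' principal axis of largest coordinate variance is aligned with
#' screen-x, the second with screen-y, and the smallest with the depth
#' axis, which minimizes self-occlusion.  Because eigenvectors are only
#' defined up to sign, anti-flip rules fix each axis sign
#' deterministically so that the pose does not depend on the input
#' orientation: the sign of axes 1 and 2 makes the third central moment
#' (skewness) of the projected coordinates non-negative, falling back to
#' the sign of the farthest atom's projection when the distribution is
#' symmetric; axis 3 is their cross product, guaranteeing a proper
#' rotation (det = +1).  All atoms are weighted equally.
#' @name orientation
NULL

SKEW_EPS <- 1e-9
EIG_TIE_EPS <- 1e-9

#' Principal axes of a coordinate cloud
#'
#' Eigendecomposition of the mean-centered covariance matrix
#' (population form, divisor n), eigenvalues in descending order.
#' Degenerate spectra (relative eigenvalue ties within 1e-9, including
#' coincident or collinear points) are completed deterministically by
#' preferring alignment with the world axes in x, y, z priority order.
#'
#' @param xyz numeric matrix, one row per point, columns x, y, z
#' @return list with `axes` (3x3 matrix, rows = unit axes, descending
#'   variance), `variances` (length 3, descending), `center` (centroid),
#'   and `degenerate` flag
#' @export
principal_axes <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L)
    ms_error("molshots_degenerate_geometry", "principal_axes needs at least one point")
  center <- colMeans(xyz)
  xc <- sweep(xyz, 2, center)
  C <- crossprod(xc) / nrow(xyz)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors  # columns, descending eigenvalue
  scale_ref <- max(vals, 1)
  ties <- abs(diff(vals)) <= EIG_TIE_EPS * scale_ref
  degenerate <- any(ties) || nrow(xyz) < 3L
  if (degenerate) {
    vecs <- complete_degenerate_basis(vals, vecs, scale_ref)
  }
  list(axes = t(vecs), variances = vals, center = center,
       degenerate = degenerate)
}

# Within each group of (near-)tied eigenvalues the eigenvectors span a
# subspace but are individually arbitrary; re-pick an orthonormal basis
# of that subspace that prefers the world axes in x,y,z priority order.
complete_degenerate_basis <- function(vals, vecs, scale_ref) {
  groups <- split(seq_len(3), cumsum(c(TRUE, abs(diff(vals)) > EIG_TIE_EPS * scale_ref)))
  out <- matrix(0, 3, 3)
  for (g in groups) {
    if (length(g) == 1L) {
      out[, g] <- vecs[, g]
      next
    }
    B <- vecs[, g, drop = FALSE]          # orthonormal basis of the subspace
    P <- B %*% t(B)                       # projector onto the subspace
    chosen <- matrix(0, 3, 0)
    for (w in seq_len(3)) {               # world axes in x,y,z priority
      v <- P %*% diag(3)[, w]
      if (ncol(chosen) > 0L)
        v <- v - chosen %*% crossprod(chosen, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) chosen <- cbind(chosen, v / nv)
      if (ncol(chosen) == length(g)) break
    }
    # pathological subspaces (cannot happen for real projectors, kept
    # for safety): fall back to the eigen basis
    if (ncol(chosen) < length(g)) chosen <- B
    out[, g] <- chosen
  }
  out
}

axis_sign <- function(proj) {
  sd3 <- sqrt(mean(proj^2))
  if (sd3 > 0) {
    skew <- mean(proj^3) / sd3^3
    if (abs(skew) >= SKEW_EPS) return(if (skew >= 0) 1 else -1)
  }
  # symmetric distribution: use the projection of the point farthest
  # from the centroid (proj is already centered)
  far <- which.max(abs(proj))
  if (length(far) == 0L || proj[far] == 0) 1 else sign(proj[far])
}

#' Canonical front-view rotation
#'
#' Returns the proper rotation `R` such that `R %*% (x - centroid)`
#' places the largest-variance direction along screen-x, the second
#' along screen-y and the smallest along the depth axis, with signs
#' fixed by the anti-flip rules (see [orientation]).
#'
#' @param xyz numeric matrix of coordinates (rows = points)
#' @return 3x3 rotation matrix with `det(R) = +1`
#' @export
canonical_rotation <- function(xyz) {
  xyz <- as.matrix(xyz)
  pa <- principal_axes(xyz)
  xc <- sweep(xyz, 2, pa$center)
  a1 <- pa$axes[1, ]
  a2 <- pa$axes[2, ]
  s1 <- axis_sign(as.numeric(xc %*% a1))
  a1 <- a1 * s1
  s2 <- axis_sign(as.numeric(xc %*% a2))
  a2 <- a2 * s2
  a3 <- c(a1[2] * a2[3] - a1[3] * a2[2],
          a1[3] * a2[1] - a1[1] * a2[3],
          a1[1] * a2[2] - a1[2] * a2[1])
  R <- rbind(a1, a2, a3)
  dimnames(R) <- NULL
  R
}

rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}

rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}

VIEW_KINDS <- c("front", "side", "top")

#' Rotation for a derived view
#'
#' `front` returns the input unchanged; `side` composes an additional
#' +90 degree rotation about the screen-y axis (the viewer moves to the
#' structure's right); `top` composes +90 degrees about screen-x (the
#' viewer moves above).
#'
#' @param front 3x3 canonical front rotation
#' @param view one of `"front"`, `"side"`, `"top"`
#' @return 3x3 rotation matrix
#' @export
view_rotation <- function(front, view = c("front", "side", "top")) {
  view <- match.arg(view)
  switch(view,
         front = front,
         side = rot_y(pi / 2) %*% front,
         top = rot_x(pi / 2) %*% front)
}
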