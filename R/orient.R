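#' Orient a mesh by PCA of its surface vertices
#'
#' Centres the vertices on their centroid and rotates them so that axes 1-3
#' are the eigenvectors of the vertex covariance in descending eigenvalue
#' order: axis 1 is the phytolith's ~length, axis 2 its ~width and axis 3 its
#' ~height. The sign of each axis is fixed so the third central moment of the
#' coordinates along it is non-negative (ties resolved towards the world
#' +x/+y/+z directions), and the rotation is forced to det = +1 by flipping
#' axis 3 when necessary, so orientation is deterministic.
#'
#' @param m a `tri_mesh`.
#' @param resample_surface_n optional number of uniform surface samples to
#'   use for the PCA instead of the raw vertices (off by default; raw
#'   vertices follow the original protocol, resampling guards against uneven
#'   vertex density).
#' @return an `oriented_mesh` (a `tri_mesh` with `rotation` and `centroid`).
#' @export
orient_mesh <- function(m, resample_surface_n = NULL) {
  stopifnot(inherits(m, "tri_mesh"))
  P <- m$vertices
  if (!is.null(resample_surface_n)) {
    P <- sample_surface(m, resample_surface_n)
  }
  centroid <- colMeans(P)
  X <- sweep(P, 2, centroid)
  C <- crossprod(X) / (nrow(X) - 1)
  eg <- eigen(C, symmetric = TRUE)
  ev <- eg$values
  scale2 <- max(ev)
  if (ev[3] < 1e-12 * scale2 || ev[2] < 1e-12 * scale2) {
    bad <- which(ev < 1e-12 * scale2)
    stop("degenerate orientation: vertex covariance is rank-deficient along axis ",
         paste(bad, collapse = ", "))
  }
  R <- eg$vectors # columns ordered by descending eigenvalue
  Y <- sweep(m$vertices, 2, centroid) %*% R
  for (k in 1:3) {
    sk <- mean(Y[, k]^3)
    tol <- (sd(Y[, k])^3) * 1e-9
    if (abs(sk) > tol) {
      if (sk < 0) { R[, k] <- -R[, k]; Y[, k] <- -Y[, k] }
    } else {
      # symmetric along this axis: align with the world axes
      if (R[k, k] < 0) { R[, k] <- -R[, k]; Y[, k] <- -Y[, k] }
    }
  }
  if (det(R) < 0) { R[, 3] <- -R[, 3]; Y[, 3] <- -Y[, 3] }
  out <- m
  out$vertices <- Y
  out$rotation <- R
  out$centroid <- centroid
  class(out) <- c("oriented_mesh", "tri_mesh")
  out
}

#' @export
print.oriented_mesh <- function(x, ...) {
  ext <- apply(x$vertices, 2, function(v) diff(range(v)))
  cat(sprintf("<oriented_mesh: %d vertices, %d faces; extents %.2f x %.2f x %.2f um>\n",
              nrow(x$vertices), nrow(x$faces), ext[1], ext[2], ext[3]))
  invisible(x)
}

# uniform surface sampling: faces picked proportionally to area,
# points uniform by barycentric square-root trick
sample_surface <- function(m, n) {
  ar <- face_areas(m)
  fi <- sample.int(nrow(m$faces), n, replace = TRUE, prob = ar)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  a <- m$vertices[m$faces[fi, 1], , drop = FALSE]
  b <- m$vertices[m$faces[fi, 2], , drop = FALSE]
  cc <- m$vertices[m$faces[fi, 3], , drop = FALSE]
  (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
}
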