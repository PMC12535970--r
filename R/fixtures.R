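# Analytic fixture meshes used in examples and tests.

#' Axis-aligned box mesh
#' @param lx,ly,lz edge lengths (um); centred at the origin.
#' @export
box_mesh <- function(lx, ly, lz) {
  v <- as.matrix(expand.grid(x = c(-lx, lx) / 2, y = c(-ly, ly) / 2,
                             z = c(-lz, lz) / 2))
  # 12 triangles, outward winding
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = -lz/2
             c(5, 6, 7), c(6, 8, 7),   # z = +lz/2
             c(1, 2, 5), c(2, 6, 5),   # y = -ly/2
             c(3, 7, 4), c(4, 7, 8),   # y = +ly/2
             c(1, 5, 3), c(3, 5, 7),   # x = -lx/2
             c(2, 4, 6), c(4, 8, 6))   # x = +lx/2
  tri_mesh(v, f)
}

#' Triangulated sphere (subdivided icosahedron)
#' @param radius sphere radius (um).
#' @param subdiv number of 4-to-1 subdivisions (3 gives 1280 faces).
#' @export
icosphere <- function(radius = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  tri_mesh(v, f)
}

# analytic occupancy of an elongated capsule-like core along x: elliptical
# cross-section with radii (width/2, height/2) over |x| <= a, closed by
# ellipsoidal caps of axial radius width/2
capsule_inside <- function(x, y, z, length, width, height) {
  a <- max(length / 2 - width / 2, 0)  # straight segment half-length
  u <- pmax(abs(x) - a, 0)
  (2 * u / width)^2 + (2 * y / width)^2 + (2 * z / height)^2 <= 1
}

# half-width of the capsule margin (y of the surface at height z = 0)
capsule_margin_y <- function(x, length, width) {
  a <- max(length / 2 - width / 2, 0)
  u <- pmax(abs(x) - a, 0)
  r2 <- 1 - (2 * u / width)^2
  ifelse(r2 > 0, width / 2 * sqrt(r2), 0)
}
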