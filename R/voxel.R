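#' Voxelize a mesh into a solid occupancy grid
#'
#' Surface voxels come from triangle rasterization; the interior is then
#' filled by flood-filling the exterior from the (padded) bounding box and
#' taking the complement. The grid is padded by at least `pad` voxels on all
#' sides.
#'
#' @param m a `tri_mesh` (usually an `oriented_mesh`).
#' @param pitch voxel edge length in micrometres. Must not exceed a quarter
#'   of the mesh's smallest axis extent so the thinnest axis spans >= 4
#'   voxels.
#' @param pad padding in voxels (>= 2).
#' @return a `voxel_grid`: list with `pitch`, `origin` (centre of voxel
#'   `[1,1,1]`), `occupancy` (3D logical array, solid) and `surface` (3D
#'   logical array of rasterized surface voxels).
#' @export
voxelize <- function(m, pitch, pad = 3L) {
  stopifnot(inherits(m, "tri_mesh"), pitch > 0, pad >= 2L)
  ext <- apply(m$vertices, 2, function(v) diff(range(v)))
  if (pitch > min(ext) / 4 + 1e-12)
    stop(sprintf("pitch %.3g too coarse: thinnest axis (%.3g um) must span >= 4 voxels",
                 pitch, min(ext)))
  lo <- apply(m$vertices, 2, min) - pad * pitch
  dims <- as.integer(ceiling((apply(m$vertices, 2, max) + pad * pitch - lo) / pitch) + 1L)
  occ_surf <- cpp_rasterize_tris(m$vertices, m$faces, lo, pitch, dims)
  if (is_watertight(m)) {
    # exact semantics for closed surfaces: a voxel is occupied when its
    # centre lies inside the mesh (x-ray parity count)
    solid <- cpp_parity_fill(m$vertices, m$faces, lo, pitch, dims)
  } else {
    ext_mask <- cpp_flood_exterior(occ_surf, dims)
    solid <- !ext_mask
    n_int <- sum(solid) - sum(occ_surf & solid)
    if (n_int == 0L) {
      # exterior flood leaked through an open surface: count the would-be
      # interior voxels it reached
      inner <- array(FALSE, dims)
      inner[(pad + 1):(dims[1] - pad), (pad + 1):(dims[2] - pad),
            (pad + 1):(dims[3] - pad)] <- TRUE
      leak <- sum(ext_mask & as.vector(inner) & !occ_surf)
      stop(sprintf("open surface: exterior flood fill leaked into the interior (%d voxels)",
                   leak))
    }
  }
  structure(list(pitch = pitch,
                 origin = lo,
                 dims = dims,
                 occupancy = array(solid, dims),
                 surface = array(occ_surf, dims)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid: %d x %d x %d @ %.3g um, %d occupied>\n",
              x$dims[1], x$dims[2], x$dims[3], x$pitch, sum(x$occupancy)))
  invisible(x)
}

voxel_volume <- function(grid) sum(grid$occupancy) * grid$pitch^3

# signed distance field (negative inside) sampled at voxel centres, world units
grid_sdf <- function(occ, dims, pitch) {
  d_out <- sqrt(cpp_edt_sq(as.vector(occ), dims))   # distance to nearest occupied
  d_in <- sqrt(cpp_edt_sq(!as.vector(occ), dims))   # distance to nearest background
  (d_out - d_in) * pitch
}

# surface mesh of a voxel solid via marching tetrahedra on its SDF
grid_surface <- function(occ, dims, origin, pitch) {
  sdf <- grid_sdf(occ, dims, pitch)
  res <- cpp_marching_tetra(sdf, dims, origin, pitch, 0)
  merge_vertices(tri_mesh(res$vertices, res$faces), tol = pitch * 1e-6)
}

# morphological opening (erosion then dilation) with a Euclidean ball of
# radius r voxels, via two distance transforms
open_grid <- function(occ, dims, r_vox) {
  d_bg2 <- cpp_edt_sq(!as.vector(occ), dims)       # distance to background
  eroded <- d_bg2 > r_vox^2
  d_er2 <- cpp_edt_sq(eroded, dims)                # distance to eroded set
  d_er2 <= r_vox^2
}

#' Extract the core body of a phytolith mesh
#'
#' The core body is the branch-free internal trunk: the largest connected
#' component remaining after a morphological opening (erosion then dilation
#' with a Euclidean ball of radius `r_open`) of the solid voxelization.
#' Opening removes protrusions thinner than about `2 * r_open` while
#' preserving the main body. The result is surfaced by marching tetrahedra
#' on the opened grid and returned in the same coordinate frame as `m`.
#'
#' @param m an `oriented_mesh` (any `tri_mesh` works; the frame is kept).
#' @param r_open opening ball radius in micrometres (>= 2 * pitch).
#' @param pitch voxel pitch in micrometres.
#' @param grid optional precomputed `voxel_grid` of `m` at `pitch`.
#' @return a `tri_mesh` of the core with attributes `grid` (the opened
#'   `voxel_grid`) and `r_open`.
#' @export
core_body <- function(m, r_open = 2, pitch = 0.5, grid = NULL) {
  stopifnot(r_open >= 2 * pitch)
  if (is.null(grid)) grid <- voxelize(m, pitch)
  opened <- open_grid(grid$occupancy, grid$dims, r_open / pitch)
  if (!any(opened)) stop("core vanished; decrease r_open")
  lab <- cpp_label_voxels(opened, grid$dims)
  tab <- tabulate(lab)
  keep <- as.vector(lab == which.max(tab))
  core_grid <- structure(list(pitch = pitch, origin = grid$origin,
                              dims = grid$dims,
                              occupancy = array(keep, grid$dims)),
                         class = "voxel_grid")
  core <- grid_surface(core_grid$occupancy, grid$dims, grid$origin, pitch)
  attr(core, "grid") <- core_grid
  attr(core, "r_open") <- r_open
  core
}
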