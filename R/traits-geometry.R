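geo_trait_names <- c("Volume", "ConvexHullVolume", "SurfaceArea", "Solidity",
                     "Sphericity", "MaxLength", "MaxWidth", "MaxHeight",
                     "PC1sd", "PC2sd", "PC3sd", "Elongation", "Flatness")
core_trait_names <- c("CoreVolume", "CoreConvexVolume", "CoreSurfaceArea",
                      "CoreOccupancy", "CoreSolidity", "CoreSphericity",
                      "CoremaxLength", "CoreMaxWidth", "CoreMaxHeight",
                      "CorePC1sd", "CorePC2sd", "CorePC3sd",
                      "CoreElongation", "CoreFlatness")
branching_trait_names <- c("AverageDendriticLength", "DendriticDensity",
                           "DendriticNumber", "DendriticTotalLength")
cc_trait_names <- paste0("CC_", 1:20)
ph_trait_names <- paste0("PH", 1:20)

#' Trait column names
#'
#' The 71 trait columns of the per-phytolith table, grouped as in the study
#' design: 27 geometric (whole + core body), 4 branching, 20 CC, 20 PH.
#'
#' @param set one of "all", "geometric", "branching", "cc", "ph".
#' @export
trait_columns <- function(set = c("all", "geometric", "branching", "cc", "ph")) {
  set <- match.arg(set)
  switch(set,
         geometric = c(geo_trait_names, core_trait_names),
         branching = branching_trait_names,
         cc = cc_trait_names,
         ph = ph_trait_names,
         all = c(geo_trait_names, core_trait_names, branching_trait_names,
                 cc_trait_names, ph_trait_names))
}

# geometric trait block shared by whole and core bodies; coordinates must be
# in the orientation frame in which extents are to be measured
geometry_block <- function(m, grid = NULL) {
  area <- mesh_surface_area(m)
  if (area <= 0) stop("zero surface area")
  if (is_watertight(m)) {
    vol <- abs(mesh_volume_signed(m))
  } else if (!is.null(grid)) {
    vol <- voxel_volume(grid)
  } else {
    stop("mesh is not watertight and no voxel grid supplied for volume")
  }
  hull <- tryCatch(cpp_convex_hull(m$vertices),
                   error = function(e) stop("degenerate hull: ", conditionMessage(e)))
  ext <- apply(m$vertices, 2, function(v) diff(range(v)))
  sds <- apply(m$vertices, 2, sd)
  sol <- vol / hull$volume
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  list(Volume = vol,
       ConvexHullVolume = hull$volume,
       SurfaceArea = area,
       Solidity = sol,
       Sphericity = sph,
       MaxLength = ext[[1]],
       MaxWidth = ext[[2]],
       MaxHeight = ext[[3]],
       PC1sd = sds[[1]], PC2sd = sds[[2]], PC3sd = sds[[3]],
       Elongation = 1 - ext[[2]] / ext[[1]],
       Flatness = 1 - ext[[3]] / ext[[2]])
}

#' Geometric size and shape traits of an oriented mesh
#'
#' Volume is the signed-tetrahedron sum when the mesh is watertight and the
#' voxel estimate `count * pitch^3` otherwise. Sphericity is
#' `pi^(1/3) * (6 V)^(2/3) / A` (1 for a perfect sphere), Solidity is
#' `V / V_hull`. Extents and per-axis standard deviations are measured along
#' the oriented axes (length/width/height). Elongation = 1 - width/length,
#' Flatness = 1 - height/width; both are 0 for an equant body.
#'
#' @param m an `oriented_mesh`.
#' @param grid optional matching `voxel_grid` (volume fallback for
#'   non-watertight meshes).
#' @return named list of the 13 whole-body geometric traits.
#' @export
geometric_traits <- function(m, grid = NULL) {
  stopifnot(inherits(m, "tri_mesh"))
  geometry_block(m, grid)
}

#' Geometric traits of the core body
#'
#' All whole-body traits recomputed on the core mesh, measured in the whole
#' phytolith's orientation frame (the core is deliberately not re-oriented so
#' that core extents remain comparable with whole-body extents), plus
#' CoreOccupancy = CoreVolume / Volume.
#'
#' @param core core mesh from [core_body()].
#' @param whole whole-body traits from [geometric_traits()].
#' @return named list of the 14 core traits.
#' @export
core_traits <- function(core, whole) {
  g <- geometry_block(core, attr(core, "grid"))
  occ <- g$Volume / whole$Volume
  if (occ > 1) {
    warning("CoreVolume exceeded Volume numerically; clamping CoreOccupancy to 1")
    occ <- 1
  }
  list(CoreVolume = g$Volume,
       CoreConvexVolume = g$ConvexHullVolume,
       CoreSurfaceArea = g$SurfaceArea,
       CoreOccupancy = occ,
       CoreSolidity = g$Solidity,
       CoreSphericity = g$Sphericity,
       CoremaxLength = g$MaxLength,
       CoreMaxWidth = g$MaxWidth,
       CoreMaxHeight = g$MaxHeight,
       CorePC1sd = g$PC1sd,
       CorePC2sd = g$PC2sd,
       CorePC3sd = g$PC3sd,
       CoreElongation = g$Elongation,
       CoreFlatness = g$Flatness)
}
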