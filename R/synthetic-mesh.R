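#' Parameters for the synthetic dendritic mesh generator
#'
#' Defaults emulate a typical Elongate dendritic: an elongated core body of
#' roughly 25 x 8 x 6 um carrying cone-shaped dendritic branches along both
#' long margins, with log-normally distributed branch lengths around 8 um.
#'
#' @param core_length,core_width,core_height core body dimensions (um).
#' @param branches_per_margin number of branches on each long margin.
#' @param branch_meanlog,branch_sdlog log-normal branch length parameters.
#' @param branch_base_radius,branch_tip_radius cone radii (um); the base
#'   radius must stay below core_height / 2.
#' @param spacing_jitter uniform jitter (um) on branch positions.
#' @param pitch voxel pitch of the generator grid (um).
#' @param seed RNG seed (the same seed reproduces the mesh exactly).
#' @export
phytolith_params <- function(core_length = 25, core_width = 8, core_height = 6,
                             branches_per_margin = 3,
                             branch_meanlog = log(8), branch_sdlog = 0.25,
                             branch_base_radius = 1.2, branch_tip_radius = 0.6,
                             spacing_jitter = 0.5, pitch = 0.5, seed = 1L) {
  stopifnot(core_length > 0, core_width > 0, core_height > 0,
            branches_per_margin >= 0, branch_base_radius > 0,
            branch_base_radius < core_height / 2, pitch > 0)
  structure(list(core_length = core_length, core_width = core_width,
                 core_height = core_height,
                 branches_per_margin = branches_per_margin,
                 branch_meanlog = branch_meanlog, branch_sdlog = branch_sdlog,
                 branch_base_radius = branch_base_radius,
                 branch_tip_radius = branch_tip_radius,
                 spacing_jitter = spacing_jitter, pitch = pitch,
                 seed = as.integer(seed)),
            class = "phytolith_params")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic branched phytolith mesh with ground truth
#'
#' Builds a watertight surface mesh by voxel union of an elongated capsule
#' core and cone-shaped branches placed along the two long margins, surfaced
#' by marching tetrahedra (voxel union avoids fragile boolean mesh
#' operations). The ground truth records the axial length of every planted
#' branch, measured from the core surface to the branch tip. Branches whose
#' bases overlap at the drawn spacing are merged in the ground truth, with a
#' warning.
#'
#' @param p a `phytolith_params`.
#' @return list with `mesh` (a `tri_mesh`), `ground_truth` (data.frame:
#'   side, position, length) and `params`.
#' @export
make_phytolith_mesh <- function(p) {
  stopifnot(inherits(p, "phytolith_params"))
  with_seed(p$seed, {
    nb <- p$branches_per_margin
    gt <- data.frame(side = integer(0), position = numeric(0),
                     length = numeric(0))
    if (nb > 0) {
      span <- p$core_length * 0.7
      base_x <- seq(-span / 2, span / 2, length.out = nb)
      pos <- c(base_x + runif(nb, -p$spacing_jitter, p$spacing_jitter),
               base_x + runif(nb, -p$spacing_jitter, p$spacing_jitter))
      side <- rep(c(1L, -1L), each = nb)
      len <- rlnorm(2 * nb, p$branch_meanlog, p$branch_sdlog)
      gt <- data.frame(side = side, position = pos, length = len)
      # merge branches overlapping at the base on the same margin
      merged <- merge_overlaps(gt, 2 * p$branch_base_radius)
      if (nrow(merged) < nrow(gt))
        warning("overlapping branches merged in ground truth")
      gt <- merged
    }
    max_len <- if (nrow(gt)) max(gt$length) else 0
    pad <- 4 * p$pitch
    xr <- c(-1, 1) * (p$core_length / 2 + pad)
    yr <- c(-1, 1) * (p$core_width / 2 + max_len + p$branch_base_radius + pad)
    zr <- c(-1, 1) * (p$core_height / 2 + pad)
    xs <- seq(xr[1], xr[2], by = p$pitch)
    ys <- seq(yr[1], yr[2], by = p$pitch)
    zs <- seq(zr[1], zr[2], by = p$pitch)
    dims <- c(length(xs), length(ys), length(zs))
    gx <- rep(xs, times = dims[2] * dims[3])
    gy <- rep(rep(ys, each = dims[1]), times = dims[3])
    gz <- rep(zs, each = dims[1] * dims[2])
    occ <- capsule_inside(gx, gy, gz, p$core_length, p$core_width, p$core_height)
    for (i in seq_len(nrow(gt))) {
      occ <- occ | branch_inside(gx, gy, gz, gt$side[i], gt$position[i],
                                 gt$length[i], p)
    }
    mesh <- grid_surface(occ, as.integer(dims),
                         c(xr[1], yr[1], zr[1]), p$pitch)
    list(mesh = mesh, ground_truth = gt, params = p)
  })
}

merge_overlaps <- function(gt, min_gap) {
  keep <- rep(TRUE, nrow(gt))
  for (s in unique(gt$side)) {
    idx <- which(gt$side == s)
    idx <- idx[order(gt$position[idx])]
    if (length(idx) < 2) next
    last <- idx[1]
    for (k in 2:length(idx)) {
      cur <- idx[k]
      if (abs(gt$position[cur] - gt$position[last]) < min_gap) {
        gt$length[last] <- max(gt$length[last], gt$length[cur])
        keep[cur] <- FALSE
      } else {
        last <- cur
      }
    }
  }
  gt[keep, , drop = FALSE]
}

# cone branch: axis from the core margin outward along +/- y, linear taper
branch_inside <- function(gx, gy, gz, side, x0, len, p) {
  y0 <- capsule_margin_y(x0, p$core_length, p$core_width)
  t <- side * gy - y0                     # axial coordinate, 0 at core surface
  inside_t <- t > -2 * p$pitch - p$branch_base_radius & t <= len
  r <- p$branch_base_radius +
    (p$branch_tip_radius - p$branch_base_radius) * pmax(t, 0) / len
  rho2 <- (gx - x0)^2 + gz^2
  inside_t & rho2 <= r^2
}
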