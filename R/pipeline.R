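#' Extract all single-phytolith traits from one mesh
#'
#' Runs the per-mesh stages in order: orientation, solid voxelization, core
#' body by morphological opening, geometric + core traits, geodesic field to
#' the core, persistence barcode, branching traits and the CC curve. The PH
#' coordinates are a cohort-level quantity (MDS of the pairwise bottleneck
#' matrix) and are added by [run_pipeline()] / [extract_trait_table()].
#'
#' @param mesh a `tri_mesh`.
#' @param pitch voxel pitch (um).
#' @param r_open core-body opening radius (um).
#' @param eps geodesic source tolerance (um; default = pitch).
#' @param min_persist branch persistence floor (um).
#' @return list with `traits` (named list of 51 values: geometric, branching,
#'   CC), `barcode`, `field`, `mesh` (oriented), `core`.
#' @export
extract_traits <- function(mesh, pitch = 0.5, r_open = 2, eps = NULL,
                           min_persist = 1) {
  om <- orient_mesh(mesh)
  grid <- voxelize(om, pitch)
  core <- core_body(om, r_open = r_open, pitch = pitch, grid = grid)
  gt <- geometric_traits(om, grid)
  ct <- core_traits(core, gt)
  fld <- geodesic_field(om, core, eps = eps)
  bc <- persistence_barcode(fld)
  bt <- branching_traits(bc, core_max_length = ct$CoremaxLength,
                         min_persist = min_persist)
  cc <- as.list(cc_curve(fld))
  list(traits = c(gt, ct, bt, cc), barcode = bc, field = fld,
       mesh = om, core = core)
}

#' Trait table for a set of meshes, including PH coordinates
#'
#' @param meshes named list of `tri_mesh` objects.
#' @param pitch,r_open,eps,min_persist forwarded to [extract_traits()].
#' @param ph_k number of MDS coordinates.
#' @return list: `traits` (data.frame, one row per mesh, 71 trait columns),
#'   `barcodes`, `distance_matrix`, `mds`.
#' @export
extract_trait_table <- function(meshes, pitch = 0.5, r_open = 2, eps = NULL,
                                min_persist = 1, ph_k = 20) {
  if (is.null(names(meshes)))
    names(meshes) <- sprintf("phy%04d", seq_along(meshes))
  res <- lapply(meshes, extract_traits, pitch = pitch, r_open = r_open,
                eps = eps, min_persist = min_persist)
  rows <- lapply(res, function(r) as.data.frame(r$traits))
  tab <- do.call(rbind, rows)
  tab <- cbind(phytolith_id = names(meshes), tab)
  rownames(tab) <- NULL
  barcodes <- lapply(res, `[[`, "barcode")
  D <- bottleneck_matrix(barcodes)
  emb <- mds_embed(D, k = ph_k)
  ph <- as.data.frame(emb$coordinates)
  names(ph) <- paste0("PH", seq_len(ph_k))
  tab <- cbind(tab, ph)
  list(traits = tab, barcodes = barcodes, distance_matrix = D, mds = emb)
}

#' Pipeline run configuration
#'
#' Validates every numeric field before any computation; all randomness is
#' funnelled through the named seeds.
#'
#' @param input either a character vector of mesh file paths or a list with
#'   `n_meshes` (synthetic meshes are generated).
#' @param out_dir output directory for the run.
#' @param pitch,r_open,eps,min_persist per-mesh trait parameters.
#' @param corr_threshold correlation filter threshold.
#' @param n_components "auto" or an integer.
#' @param level classification level.
#' @param trait_sets predictor sets for the Random Forest.
#' @param trim_cap samples-per-class cap for the splits.
#' @param seeds named list of stage seeds (mesh, split, forest).
#' @param units_scale scale applied to input mesh coordinates.
#' @export
run_config <- function(input, out_dir,
                       pitch = 0.5, r_open = 2, eps = NULL, min_persist = 1,
                       corr_threshold = 0.90, n_components = "auto",
                       level = "lineage",
                       trait_sets = c("geometric", "branching", "cc"),
                       trim_cap = Inf,
                       seeds = list(mesh = 1L, split = 1L, forest = 1L),
                       units_scale = 1) {
  if (pitch <= 0) stop("invalid config: pitch must be > 0")
  if (r_open <= 0) stop("invalid config: r_open must be > 0")
  if (r_open < 2 * pitch) stop("invalid config: r_open must be >= 2 * pitch")
  if (!is.null(eps) && eps <= 0) stop("invalid config: eps must be > 0")
  if (min_persist < 0) stop("invalid config: min_persist must be >= 0")
  if (corr_threshold <= 0 || corr_threshold > 1)
    stop("invalid config: corr_threshold in (0, 1]")
  if (!identical(n_components, "auto") &&
      (!is.numeric(n_components) || n_components < 1))
    stop("invalid config: n_components must be 'auto' or a positive integer")
  if (units_scale <= 0) stop("invalid config: units_scale must be > 0")
  if (!all(trait_sets %in% c("geometric", "branching", "cc", "ph")))
    stop("invalid config: unknown trait set")
  structure(list(input = input, out_dir = out_dir, pitch = pitch,
                 r_open = r_open, eps = eps, min_persist = min_persist,
                 corr_threshold = corr_threshold,
                 n_components = n_components, level = level,
                 trait_sets = trait_sets, trim_cap = trim_cap,
                 seeds = seeds, units_scale = units_scale),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the workflow stages in order: mesh input (files or synthetic),
#' per-phytolith trait extraction, barcode export, bottleneck distances, MDS
#' embedding and the trait CSV. A manifest (config, seeds, file list, stage
#' status) is written last; a stage failure aborts with the stage name and
#' leaves prior outputs intact. Unreadable input files are skipped and
#' listed in the manifest.
#'
#' @param cfg a [run_config()].
#' @return the run directory, invisibly; side effects: `traits.csv`,
#'   `barcodes.csv`, `bottleneck_distances.csv`, `manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("dendriform")),
                   config = cfg[setdiff(names(cfg), "input")],
                   seeds = cfg$seeds, skipped = character(0),
                   stages = character(0))
  note_skip <- function(p) manifest$skipped <<- c(manifest$skipped, p)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    res
  }
  meshes <- stage("input", {
    if (is.character(cfg$input)) {
      ms <- list()
      for (p in cfg$input) {
        m <- tryCatch(load_mesh(p, units_scale = cfg$units_scale),
                      error = function(e) NULL)
        if (is.null(m)) {
          note_skip(p)
        } else {
          ms[[tools::file_path_sans_ext(basename(p))]] <- m
        }
      }
      ms
    } else {
      n <- cfg$input$n_meshes
      ms <- lapply(seq_len(n), function(i)
        make_phytolith_mesh(phytolith_params(seed = cfg$seeds$mesh + i - 1L))$mesh)
      names(ms) <- sprintf("synthetic%03d", seq_len(n))
      ms
    }
  })
  if (!length(meshes)) stop("pipeline stage 'input' failed: no readable meshes")
  ett <- stage("traits", extract_trait_table(
    meshes, pitch = cfg$pitch, r_open = cfg$r_open, eps = cfg$eps,
    min_persist = cfg$min_persist))
  stage("export", {
    write.csv(ett$traits, file.path(cfg$out_dir, "traits.csv"),
              row.names = FALSE)
    bc <- do.call(rbind, lapply(names(ett$barcodes), function(id) {
      b <- ett$barcodes[[id]]
      data.frame(phytolith_id = id, birth = b$birth, death = b$death,
                 essential = as.integer(b$essential))
    }))
    write.csv(bc, file.path(cfg$out_dir, "barcodes.csv"), row.names = FALSE)
    D <- as.data.frame(ett$distance_matrix)
    write.csv(cbind(phytolith_id = rownames(ett$distance_matrix), D),
              file.path(cfg$out_dir, "bottleneck_distances.csv"),
              row.names = FALSE)
  })
  manifest$n_meshes <- length(meshes)
  manifest$mds_stress <- ett$mds$stress
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(cfg$out_dir)
}
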