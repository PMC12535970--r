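#' Geodesic distance field to the core body
#'
#' Multi-source Dijkstra on the whole-mesh vertex graph (edge weight =
#' Euclidean edge length). Sources are all whole-mesh vertices lying inside
#' the core or within `eps` of its surface; their distance is 0 and every
#' other vertex carries its shortest-path distance to the source set, so
#' branch tips have the largest values.
#'
#' @param m the whole `oriented_mesh`.
#' @param core core mesh from [core_body()] (its voxel grid, when attached,
#'   is used to measure vertex-to-core distances; otherwise distances to the
#'   core vertices are used).
#' @param eps source tolerance in micrometres (default: the core grid pitch).
#' @return a `scalar_field`: list with `f` (per-vertex distance, um),
#'   `sources` (vertex indices), `edges`, `lengths`, `kept` (vertex indices
#'   of the component analysed) and `mesh`.
#' @export
geodesic_field <- function(m, core, eps = NULL) {
  stopifnot(inherits(m, "tri_mesh"))
  ed <- mesh_edges(m)
  g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
  if (igraph::vcount(g) < nrow(m$vertices))
    g <- igraph::add_vertices(g, nrow(m$vertices) - igraph::vcount(g))
  comp <- igraph::components(g)
  kept <- seq_len(nrow(m$vertices))
  if (comp$no > 1L) {
    warning("mesh edge graph is disconnected; using its largest component")
    main <- which.max(comp$csize)
    kept <- which(comp$membership == main)
  }
  cg <- attr(core, "grid")
  if (!is.null(cg)) {
    if (is.null(eps)) eps <- cg$pitch
    d2 <- cpp_edt_sq(as.vector(cg$occupancy), cg$dims)
    idx <- vertex_voxel_index(m$vertices, cg)
    dist_core <- rep(Inf, nrow(m$vertices))
    ok <- !is.na(idx)
    dist_core[ok] <- sqrt(d2[idx[ok]]) * cg$pitch
  } else {
    if (is.null(eps)) stop("eps is required when the core carries no voxel grid")
    dist_core <- min_dist_to_points(m$vertices, core$vertices)
  }
  src <- intersect(which(dist_core <= eps), kept)
  if (!length(src)) stop("core does not touch mesh: empty source set")
  # virtual source vertex joined to all sources with zero-weight edges
  n <- nrow(m$vertices)
  gsub <- igraph::graph_from_edgelist(rbind(ed$edges, cbind(n + 1L, src)),
                                      directed = FALSE)
  igraph::E(gsub)$weight <- c(ed$lengths, rep(0, length(src)))
  f <- as.vector(igraph::distances(gsub, v = n + 1L,
                                   to = seq_len(n), algorithm = "dijkstra"))
  f[setdiff(seq_len(n), kept)] <- NA_real_
  keep_e <- ed$edges[, 1] %in% kept & ed$edges[, 2] %in% kept
  structure(list(f = f, sources = src,
                 edges = ed$edges[keep_e, , drop = FALSE],
                 lengths = ed$lengths[keep_e],
                 kept = kept, mesh = m),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field: %d vertices, %d sources, max %.2f um>\n",
              length(x$kept), length(x$sources), max(x$f, na.rm = TRUE)))
  invisible(x)
}

vertex_voxel_index <- function(V, grid) {
  i <- floor((V[, 1] - grid$origin[1]) / grid$pitch + 0.5)
  j <- floor((V[, 2] - grid$origin[2]) / grid$pitch + 0.5)
  k <- floor((V[, 3] - grid$origin[3]) / grid$pitch + 0.5)
  ok <- i >= 0 & j >= 0 & k >= 0 &
    i < grid$dims[1] & j < grid$dims[2] & k < grid$dims[3]
  out <- rep(NA_integer_, nrow(V))
  out[ok] <- as.integer(i[ok] + grid$dims[1] * (j[ok] + grid$dims[2] * k[ok]) + 1)
  out
}

min_dist_to_points <- function(A, B, chunk = 2000L) {
  out <- numeric(nrow(A))
  for (s in seq(1L, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    d2 <- outer(rowSums(A[s:e, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * A[s:e, , drop = FALSE] %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Superlevel-set persistence barcode of a geodesic field
#'
#' Zero-dimensional persistence of the superlevel sets `{f >= t}` as the
#' threshold t sweeps down from the maximum of f to zero: a component (a
#' dendritic branch) is born at its highest vertex, and on a merge the
#' component with the smaller birth value dies (elder rule; ties are broken
#' so the lower-index birth vertex survives). The component born at the
#' global maximum never dies and is recorded as the essential bar with
#' death 0.
#'
#' @param field a `scalar_field`.
#' @return a `barcode`: data.frame with columns `birth`, `death`,
#'   `essential`, `vertex`, sorted by decreasing persistence.
#' @export
persistence_barcode <- function(field) {
  stopifnot(inherits(field, "scalar_field"))
  kept <- field$kept
  remap <- integer(length(field$f))
  remap[kept] <- seq_along(kept)
  e <- cbind(remap[field$edges[, 1]], remap[field$edges[, 2]])
  bars <- cpp_persistence(field$f[kept], e)
  out <- data.frame(birth = bars[, 1], death = bars[, 2],
                    essential = bars[, 3] == 1,
                    vertex = kept[bars[, 4]])
  out <- out[out$essential | (out$birth - out$death) > 0, , drop = FALSE]
  out <- out[order(-(out$birth - out$death)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("barcode", "data.frame")
  out
}

#' Branching traits from a barcode
#'
#' A branch is a bar: its length is the bar's persistence. The branch set is
#' every non-essential bar with persistence >= `min_persist` plus the
#' essential bar (the longest process of the phytolith).
#' DendriticDensity is branches per micrometre of core length.
#'
#' @param b a `barcode`.
#' @param core_max_length CoremaxLength of the same phytolith (um).
#' @param min_persist minimum persistence (um) for a bar to count as a
#'   branch; the default 1 um suppresses voxel-scale noise bars and matches
#'   the 1 um floor of the CC curve.
#' @param include_essential count the essential bar as a branch.
#' @return named list: DendriticNumber, AverageDendriticLength,
#'   DendriticTotalLength, DendriticDensity.
#' @export
branching_traits <- function(b, core_max_length, min_persist = 1,
                             include_essential = TRUE) {
  stopifnot(min_persist >= 0)
  if (core_max_length <= 0) stop("CoremaxLength must be positive")
  pers <- b$birth - b$death
  sel <- (!b$essential & pers >= min_persist)
  if (include_essential) {
    ess <- which(b$essential)
    if (length(ess)) sel[ess[which.max(pers[ess])]] <- TRUE
  }
  len <- pers[sel]
  n <- length(len)
  list(DendriticNumber = n,
       AverageDendriticLength = if (n) mean(len) else 0,
       DendriticTotalLength = sum(len),
       DendriticDensity = n / core_max_length)
}

#' Connected-component (CC) curve
#'
#' CC_k is the number of connected components of the vertex-induced subgraph
#' `{f > d_k}` with d_k = 21 - k micrometres: CC_1 counts branches longer
#' than 20 um, CC_20 branches longer than 1 um. The inequality is strict so
#' "longer than" excludes exact ties. Each threshold is counted directly by
#' component labelling of the thresholded graph.
#'
#' @param field a `scalar_field`.
#' @return named integer vector CC_1..CC_20 (monotone non-decreasing).
#' @export
cc_curve <- function(field) {
  stopifnot(inherits(field, "scalar_field"))
  kept <- field$kept
  f <- field$f
  out <- integer(20)
  for (k in 1:20) {
    d <- 21 - k
    act <- kept[f[kept] > d]
    if (!length(act)) { out[k] <- 0L; next }
    sel <- field$edges[, 1] %in% act & field$edges[, 2] %in% act
    remap <- integer(length(f))
    remap[act] <- seq_along(act)
    e <- field$edges[sel, , drop = FALSE]
    g <- igraph::graph_from_edgelist(cbind(remap[e[, 1]], remap[e[, 2]]),
                                     directed = FALSE)
    if (igraph::vcount(g) < length(act))
      g <- igraph::add_vertices(g, length(act) - igraph::vcount(g))
    out[k] <- igraph::components(g)$no
  }
  names(out) <- cc_trait_names
  out
}

barcode_points <- function(b) {
  if (is.null(b) || nrow(b) == 0) return(matrix(numeric(0), 0, 2))
  cbind(b$birth, b$death)
}

#' Bottleneck distance between two barcodes
#'
#' Exact bottleneck distance between persistence diagrams in the L-infinity
#' plane, with matching to the diagonal allowed (a bar may be erased at cost
#' persistence/2). The answer is found by binary search over the finite set
#' of candidate radii (all point-point and point-diagonal costs), testing
#' feasibility at each radius with a maximum bipartite matching on the
#' standard augmented graph (points of one diagram + diagonal copies of the
#' other).
#'
#' @param a,b `barcode` objects (essential bars enter as points (birth, 0)).
#' @return bottleneck distance in micrometres.
#' @export
bottleneck_distance <- function(a, b) {
  A <- barcode_points(a)
  B <- barcode_points(b)
  na <- nrow(A); nb <- nrow(B)
  if (na == 0 && nb == 0) return(0)
  diag_a <- if (na) (A[, 1] - A[, 2]) / 2 else numeric(0)
  diag_b <- if (nb) (B[, 1] - B[, 2]) / 2 else numeric(0)
  if (na == 0) return(max(diag_b))
  if (nb == 0) return(max(diag_a))
  cost <- matrix(0, na, nb)
  for (i in seq_len(na))
    cost[i, ] <- pmax(abs(A[i, 1] - B[, 1]), abs(A[i, 2] - B[, 2]))
  cand <- sort(unique(c(0, as.vector(cost), diag_a, diag_b)))
  # can every "required" point of one diagram (persistence/2 > r, so the
  # diagonal is out of reach) be matched into the other diagram within r?
  saturates <- function(req_idx, costs_to_other, n_other) {
    k <- length(req_idx)
    if (k == 0) return(TRUE)
    el <- which(costs_to_other <= r_cur, arr.ind = TRUE)
    el <- el[el[, 1] %in% req_idx, , drop = FALSE]
    if (nrow(el) == 0) return(FALSE)
    left <- match(el[, 1], req_idx)
    g <- igraph::graph_from_edgelist(cbind(left, k + el[, 2]),
                                     directed = FALSE)
    if (igraph::vcount(g) < k + n_other)
      g <- igraph::add_vertices(g, k + n_other - igraph::vcount(g))
    igraph::V(g)$type <- c(rep(FALSE, k), rep(TRUE, n_other))
    igraph::max_bipartite_match(g)$matching_size == k
  }
  r_cur <- NA_real_
  feasible <- function(r) {
    # by Mendelsohn-Dulmage, a matching saturating the required points of
    # both diagrams exists iff each side's required set can be saturated
    # on its own; everything optional is erased via the diagonal
    r_cur <<- r
    saturates(which(diag_a > r), cost, nb) &&
      saturates(which(diag_b > r), t(cost), na)
  }
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (feasible(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  cand[lo]
}

#' Pairwise bottleneck distance matrix
#'
#' @param barcodes named list of `barcode` objects.
#' @return symmetric matrix of bottleneck distances with zero diagonal.
#' @export
bottleneck_matrix <- function(barcodes) {
  n <- length(barcodes)
  D <- matrix(0, n, n, dimnames = list(names(barcodes), names(barcodes)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- bottleneck_distance(barcodes[[i]], barcodes[[j]])
  D
}

#' Classical MDS embedding of a distance matrix
#'
#' Double-centres the squared distances and eigendecomposes; coordinates come
#' from the top-k eigenpairs with positive eigenvalues (zero-padded when
#' fewer exist), axes ordered by eigenvalue and each coordinate column's sign
#' fixed so its skewness is non-negative. The first 20 coordinates of the
#' bottleneck matrix are the PH traits (PH1..PH20).
#'
#' @param D symmetric non-negative distance matrix with zero diagonal.
#' @param k number of coordinates to retain.
#' @return list with `coordinates` (n x k, columns PH1..PHk), `eigenvalues`,
#'   and `stress` (relative error of the embedded distances).
#' @export
mds_embed <- function(D, k = 20) {
  D <- as.matrix(D)
  if (any(is.na(D))) {
    bad <- which(is.na(D), arr.ind = TRUE)[1, ]
    stop(sprintf("NaN in distance matrix at pair (%d, %d)", bad[1], bad[2]))
  }
  stopifnot(isSymmetric(unname(D), tol = 1e-8), all(D >= 0))
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  Bm <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((Bm + t(Bm)) / 2, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values, 0) * 1e-12 & eg$values > 0)
  kk <- min(k, length(pos))
  X <- matrix(0, n, k)
  if (kk > 0) {
    X[, seq_len(kk)] <- eg$vectors[, pos[seq_len(kk)], drop = FALSE] %*%
      diag(sqrt(eg$values[pos[seq_len(kk)]]), kk)
    for (j in seq_len(kk)) {
      s <- mean((X[, j] - mean(X[, j]))^3)
      if (s < 0) X[, j] <- -X[, j]
    }
  }
  colnames(X) <- paste0("PH", seq_len(k))
  rownames(X) <- rownames(D)
  Dhat <- as.matrix(dist(X))
  stress <- if (sum(D^2) > 0) sqrt(sum((Dhat - D)^2) / sum(D^2)) else 0
  list(coordinates = X, eigenvalues = eg$values, stress = stress)
}
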