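# shared fixtures and independent oracles

make_barcode <- function(birth, death, essential = NULL) {
  if (is.null(essential))
    essential <- c(TRUE, rep(FALSE, length(birth) - 1))[seq_along(birth)]
  structure(data.frame(birth = birth, death = death, essential = essential,
                       vertex = seq_along(birth)),
            class = c("barcode", "data.frame"))
}

empty_barcode <- function() {
  structure(data.frame(birth = numeric(0), death = numeric(0),
                       essential = logical(0), vertex = integer(0)),
            class = c("barcode", "data.frame"))
}

# random connected toy graph with a scalar field, as a scalar_field object
random_toy_field <- function(n = 40, seed = 1) {
  set.seed(seed)
  # random spanning tree plus extra edges guarantees connectivity
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  edges <- cbind(2:n, parent[2:n])
  extra <- cbind(sample.int(n, n %/% 2, replace = TRUE),
                 sample.int(n, n %/% 2, replace = TRUE))
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  edges <- unique(rbind(cbind(pmin(edges[, 1], edges[, 2]),
                              pmax(edges[, 1], edges[, 2])),
                        cbind(pmin(extra[, 1], extra[, 2]),
                              pmax(extra[, 1], extra[, 2]))))
  f <- round(runif(n, 0, 20), 2)
  f[sample.int(n, 3)] <- 0 # some true sources
  structure(list(f = f, sources = which(f == 0), edges = edges,
                 lengths = rep(1, nrow(edges)), kept = seq_len(n),
                 mesh = NULL),
            class = "scalar_field")
}

# independent component count of the superlevel subgraph {f > t}
oracle_components_above <- function(field, t) {
  act <- which(field$f > t)
  if (!length(act)) return(0L)
  sel <- field$edges[, 1] %in% act & field$edges[, 2] %in% act
  remap <- integer(length(field$f))
  remap[act] <- seq_along(act)
  e <- field$edges[sel, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(remap[e[, 1]], remap[e[, 2]]),
                                   directed = FALSE)
  if (igraph::vcount(g) < length(act))
    g <- igraph::add_vertices(g, length(act) - igraph::vcount(g))
  igraph::components(g)$no
}

# bars alive at threshold t (superlevel sets; merge vertex excluded at its
# own level, so a bar is alive when birth > t >= death)
bars_alive_at <- function(b, t) sum(b$birth > t & b$death <= t)

# exhaustive bottleneck distance for diagrams with <= 4 points each:
# enumerate every subset of A matched to the diagonal and every injective
# assignment of the rest into B
oracle_bottleneck <- function(a, b) {
  A <- cbind(a$birth, a$death)
  B <- cbind(b$birth, b$death)
  na <- nrow(A); nb <- nrow(B)
  diag_a <- if (na) (A[, 1] - A[, 2]) / 2 else numeric(0)
  diag_b <- if (nb) (B[, 1] - B[, 2]) / 2 else numeric(0)
  if (na == 0 && nb == 0) return(0)
  if (na == 0) return(max(diag_b))
  if (nb == 0) return(max(diag_a))
  cost <- matrix(0, na, nb)
  for (i in seq_len(na))
    cost[i, ] <- pmax(abs(A[i, 1] - B[, 1]), abs(A[i, 2] - B[, 2]))
  best <- Inf
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), na))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  for (s in seq_len(nrow(subsets))) {
    to_diag <- which(unlist(subsets[s, ]))
    keep <- setdiff(seq_len(na), to_diag)
    if (length(keep) > nb) next
    base <- if (length(to_diag)) max(diag_a[to_diag]) else 0
    if (length(keep) == 0) {
      best <- min(best, max(base, if (nb) max(diag_b) else 0))
      next
    }
    for (tgt in perms(seq_len(nb))) {
      assign_to <- tgt[seq_along(keep)]
      mcost <- max(cost[cbind(keep, assign_to)])
      rest <- setdiff(seq_len(nb), assign_to)
      dcost <- if (length(rest)) max(diag_b[rest]) else 0
      best <- min(best, max(base, mcost, dcost))
    }
  }
  best
}

# random rigid motion
random_rotation <- function(seed = 1) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(m, R, t = c(0, 0, 0)) {
  m$vertices <- sweep(m$vertices %*% t(R), 2, t, "+")
  m
}

# capsule + cone branches fixture with known geometry (deterministic)
capsule_fixture <- function(n_branches = 8, branch_len = 10, seed = 1) {
  p <- phytolith_params(core_length = 26, core_width = 8, core_height = 8,
                        branches_per_margin = n_branches / 2,
                        branch_meanlog = log(branch_len), branch_sdlog = 0,
                        spacing_jitter = 0, seed = seed)
  make_phytolith_mesh(p)
}

# midpoint subdivision of every face (no smoothing)
subdivide_mesh <- function(m) {
  V <- m$vertices
  F <- m$faces
  newF <- matrix(0L, 0, 3)
  env <- new.env(hash = TRUE)
  mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (!is.null(env[[key]])) return(env[[key]])
    V <<- rbind(V, (V[a, ] + V[b, ]) / 2)
    env[[key]] <- nrow(V)
    nrow(V)
  }
  for (i in seq_len(nrow(F))) {
    a <- F[i, 1]; b <- F[i, 2]; cc <- F[i, 3]
    ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
    newF <- rbind(newF, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
  }
  tri_mesh(V, newF)
}

# brute-force convex hull volume for small generic point clouds: enumerate
# supporting planes from point triples and fan the facets from the centroid
oracle_hull_volume <- function(P) {
  n <- nrow(P)
  cen <- colMeans(P)
  vol <- 0
  eps <- 1e-9 * max(abs(P))
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    u <- P[j, ] - P[i, ]; w <- P[k, ] - P[i, ]
    nn <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    if (sum(nn^2) < 1e-18) next
    d <- as.vector(P %*% nn) - sum(nn * P[i, ])
    if (all(d <= eps) || all(d >= -eps)) {
      vol <- vol + abs(det(rbind(P[i, ] - cen, P[j, ] - cen, P[k, ] - cen))) / 6
    }
  }
  vol
}
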