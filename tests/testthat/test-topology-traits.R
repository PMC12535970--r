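# straight triangulated tube along x with an open disk of sources at x = 0
tube_mesh <- function(len = 30, radius = 2, nseg = 60, nring = 16) {
  th <- seq(0, 2 * pi, length.out = nring + 1)[-(nring + 1)]
  xs <- seq(0, len, length.out = nseg + 1)
  V <- do.call(rbind, lapply(xs, function(x)
    cbind(x, radius * cos(th), radius * sin(th))))
  F <- matrix(0L, 0, 3)
  for (i in seq_len(nseg)) {
    a <- (i - 1) * nring + seq_len(nring)
    b <- i * nring + seq_len(nring)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    F <- rbind(F, cbind(a, b, b2), cbind(a, b2, a2))
  }
  tri_mesh(V, F)
}

test_that("geodesic field measures arc length along a tube", {
  m <- tube_mesh(30, 2)
  src <- which(m$vertices[, 1] == 0)
  core <- tri_mesh(m$vertices[c(src, src[1:2]), , drop = FALSE],
                   matrix(c(1, 2, 3), 1, 3), validate = FALSE)
  fld <- geodesic_field(m, core, eps = 1e-6)
  expect_true(all(fld$f[src] == 0))
  far <- which(m$vertices[, 1] == 30)
  edge_len <- 30 / 60
  expect_lt(max(abs(fld$f[far] - 30)), edge_len + 1e-9)
})

test_that("all-source field is identically zero", {
  m <- tube_mesh(10, 2, nseg = 10, nring = 8)
  core <- m
  fld <- geodesic_field(m, core, eps = 10)
  expect_true(all(fld$f == 0))
})

test_that("geodesic distances equal a brute-force shortest-path oracle", {
  m <- tube_mesh(12, 2, nseg = 10, nring = 8) # 88 vertices
  src <- which(m$vertices[, 1] == 0)
  core <- tri_mesh(m$vertices[c(src, src[1:2]), , drop = FALSE],
                   matrix(c(1, 2, 3), 1, 3), validate = FALSE)
  fld <- geodesic_field(m, core, eps = 1e-6)
  # Floyd-Warshall on the dense weight matrix
  n <- nrow(m$vertices)
  W <- matrix(Inf, n, n); diag(W) <- 0
  ed <- dendriform:::mesh_edges(m)
  W[ed$edges] <- ed$lengths; W[ed$edges[, c(2, 1)]] <- ed$lengths
  for (k in seq_len(n)) {
    Wk <- outer(W[, k], W[k, ], "+")
    W <- pmin(W, Wk)
  }
  oracle <- apply(W[, src, drop = FALSE], 1, min)
  expect_equal(fld$f, oracle, tolerance = 1e-12)
})

test_that("geodesic field requires sources and warns on disconnection", {
  m <- tube_mesh(10, 2, nseg = 6, nring = 8)
  core <- tri_mesh(m$vertices[1:4, , drop = FALSE] + 1000,
                   matrix(1:3, 1, 3), validate = FALSE)
  expect_error(geodesic_field(m, core, eps = 0.5), "core does not touch")
  # disjoint union of two tubes: largest component used, with a warning
  m2 <- tube_mesh(10, 2, nseg = 8, nring = 8)
  m2$vertices[, 1] <- m2$vertices[, 1] + 100
  both <- tri_mesh(rbind(m$vertices, m2$vertices),
                   rbind(m$faces, m2$faces + nrow(m$vertices)))
  src <- which(both$vertices[, 1] == 100)
  core <- tri_mesh(both$vertices[src[1:4], , drop = FALSE],
                   matrix(1:3, 1, 3), validate = FALSE)
  expect_warning(fld <- geodesic_field(both, core, eps = 1e-6),
                 "largest component")
  expect_true(all(is.na(fld$f[seq_len(nrow(m$vertices))])))
})

test_that("persistence barcode matches hand-traced merges on a toy graph", {
  # path graph: core (f=0) - saddle - branch A tip (12) - saddle - B tip (8)
  f <- c(0, 12, 0.5, 8)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4))
  bars <- dendriform:::cpp_persistence(f, edges)
  b <- data.frame(birth = bars[, 1], death = bars[, 2], ess = bars[, 3])
  b <- b[b$ess == 1 | b$birth - b$death > 0, ] # drop zero-persistence merges
  expect_equal(b$birth[b$ess == 1], 12)
  expect_equal(b$death[b$ess == 1], 0)
  nb <- b[b$ess == 0, ]
  expect_equal(nrow(nb), 1)
  expect_equal(nb$birth, 8)
  expect_equal(nb$death, 0.5)
})

test_that("constant zero field yields only the degenerate essential bar", {
  m <- tube_mesh(10, 2, nseg = 6, nring = 8)
  fld <- geodesic_field(m, m, eps = 10)
  b <- persistence_barcode(fld)
  expect_equal(sum(b$essential), 1)
  expect_equal(nrow(b[!b$essential, ]), 0)
  expect_equal(b$birth[b$essential], 0)
  expect_true(all(cc_curve(fld) == 0))
})

test_that("bar counts equal brute-force component counts at every level", {
  for (seed in 1:50) {
    fld <- random_toy_field(n = 35, seed = seed)
    bars <- persistence_barcode(fld)
    for (t in seq(0, 20, by = 2.5)) {
      expect_equal(bars_alive_at(bars, t),
                       oracle_components_above(fld, t),
                       label = sprintf("seed %d, t = %.1f", seed, t))
    }
  }
})

test_that("branching traits follow the bar arithmetic", {
  b <- make_barcode(birth = c(12, 8, 0.4), death = c(0, 0, 0),
                    essential = c(TRUE, FALSE, FALSE))
  bt <- branching_traits(b, core_max_length = 20, min_persist = 1)
  expect_equal(bt$DendriticNumber, 2)
  expect_equal(bt$AverageDendriticLength, 10)
  expect_equal(bt$DendriticTotalLength, 20)
  expect_equal(bt$DendriticDensity, 2 / 20)
  expect_equal(bt$DendriticTotalLength,
               bt$DendriticNumber * bt$AverageDendriticLength,
               tolerance = 1e-9)

  only_ess <- make_barcode(5, 0, TRUE)
  bt2 <- branching_traits(only_ess, core_max_length = 10)
  expect_equal(bt2$DendriticNumber, 1)
  expect_equal(bt2$AverageDendriticLength, 5)
  expect_error(branching_traits(b, core_max_length = 0), "positive")
})

test_that("CC curve uses strict superlevel thresholds", {
  # three branches with tip distances 25, 10 and 0.5 off a core vertex
  f <- c(0, 25, 10, 0.5)
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4))
  fld <- structure(list(f = f, sources = 1L, edges = edges,
                        lengths = rep(1, nrow(edges)), kept = 1:4,
                        mesh = NULL), class = "scalar_field")
  cc <- cc_curve(fld)
  expect_equal(unname(cc["CC_1"]), 1)   # d = 20
  expect_equal(unname(cc["CC_11"]), 1)  # d = 10, strict: tip 10 excluded
  expect_equal(unname(cc["CC_12"]), 2)  # d = 9
  expect_equal(unname(cc["CC_20"]), 2)  # d = 1
})

test_that("CC curves agree with bar counts on arbitrary fields", {
  for (seed in 1:20) {
    fld <- random_toy_field(n = 30, seed = 100 + seed)
    cc <- cc_curve(fld)
    bars <- persistence_barcode(fld)
    for (k in 1:20) {
      expect_equal(unname(cc[k]), bars_alive_at(bars, 21 - k))
    }
  }
})

test_that("CC curves are monotone on geodesic-to-core fields", {
  # branches of an Elongate dendritic merge next to the core (below the 1 um
  # CC floor), so the branch count can only grow as the threshold drops
  for (seed in c(3, 17)) {
    fx <- capsule_fixture(n_branches = 6, branch_len = 9, seed = seed)
    et <- extract_traits(fx$mesh)
    cc <- cc_curve(et$field)
    expect_true(all(diff(cc) >= 0))
    # true branch bars (above the persistence floor) merge next to the core;
    # sub-floor voxel-noise bumps may die anywhere and are ignored
    real <- !et$barcode$essential & (et$barcode$birth - et$barcode$death) >= 1
    expect_true(all(et$barcode$death[real] < 1))
  }
})

test_that("bottleneck distance matches closed forms and the oracle", {
  b1 <- make_barcode(12, 0)
  expect_equal(bottleneck_distance(b1, b1), 0)
  expect_equal(bottleneck_distance(b1, empty_barcode()), 6)
  expect_equal(bottleneck_distance(make_barcode(10, 0), make_barcode(8, 0)), 2)
  expect_equal(bottleneck_distance(empty_barcode(), empty_barcode()), 0)

  set.seed(8)
  rand_bc <- function() {
    n <- sample.int(4, 1)
    d <- round(runif(n, 0, 3), 2)
    make_barcode(birth = d + round(runif(n, 0.1, 10), 2), death = d)
  }
  for (i in 1:20) {
    a <- rand_bc(); b <- rand_bc()
    expect_equal(bottleneck_distance(a, b), oracle_bottleneck(a, b),
                 tolerance = 1e-12, label = sprintf("pair %d", i))
  }
})

test_that("bottleneck distance is a pseudometric", {
  set.seed(15)
  bcs <- lapply(1:6, function(i) {
    n <- sample.int(5, 1)
    d <- round(runif(n, 0, 2), 2)
    make_barcode(birth = d + round(runif(n, 0.5, 8), 2), death = d)
  })
  for (rep in 1:20) {
    tri <- sample(6, 3)
    a <- bcs[[tri[1]]]; b <- bcs[[tri[2]]]; cc <- bcs[[tri[3]]]
    dab <- bottleneck_distance(a, b)
    dba <- bottleneck_distance(b, a)
    expect_equal(dab, dba, tolerance = 1e-12)
    expect_lte(dab, bottleneck_distance(a, cc) +
                 bottleneck_distance(cc, b) + 1e-12)
    expect_equal(bottleneck_distance(a, a), 0)
  }
})

test_that("persistence is stable under field perturbation", {
  delta <- 0.25
  for (seed in 1:10) {
    fld <- random_toy_field(n = 40, seed = 200 + seed)
    b1 <- persistence_barcode(fld)
    fld2 <- fld
    set.seed(seed)
    fld2$f <- pmax(0, fld$f + runif(length(fld$f), -delta, delta))
    b2 <- persistence_barcode(fld2)
    expect_lte(bottleneck_distance(b1, b2), delta + 1e-12)
  }
})

test_that("classical MDS reproduces Euclidean configurations", {
  pts <- seq(0, 18, by = 2)
  D <- abs(outer(pts, pts, "-"))
  emb <- mds_embed(D, 20)
  expect_lt(max(abs(as.matrix(dist(emb$coordinates)) - D)), 1e-8)
  expect_true(all(abs(emb$coordinates[, 2:20]) < 1e-8))

  z <- matrix(0, 4, 4)
  embz <- mds_embed(z, 20)
  expect_true(all(embz$coordinates == 0))

  Dna <- D; Dna[2, 3] <- NA
  expect_error(mds_embed(Dna), "NaN")
})

test_that("MDS of a bottleneck matrix respects the eigenvalue error bound", {
  set.seed(30)
  bcs <- lapply(1:5, function(i) {
    d <- round(runif(3, 0, 2), 2)
    make_barcode(birth = d + round(runif(3, 1, 9), 2), death = d)
  })
  names(bcs) <- paste0("b", 1:5)
  D <- bottleneck_matrix(bcs)
  expect_true(isSymmetric(unname(D)))
  expect_true(all(diag(D) == 0))
  emb <- mds_embed(D, 20)
  neg <- sum(abs(emb$eigenvalues[emb$eigenvalues < 0]))
  Dhat <- as.matrix(dist(emb$coordinates))
  # additive error induced by the discarded negative spectrum
  bound <- sqrt(2 * neg) + 1e-8
  expect_lt(max(abs(Dhat - D)), max(bound, 1e-8))
})
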