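test_that("voxel volumes match closed forms and converge with pitch", {
  cube <- orient_mesh(box_mesh(10, 10, 10))
  g1 <- voxelize(cube, 1)
  expect_lt(abs(sum(g1$occupancy) - 1000) / 1000, 0.10)
  g05 <- voxelize(cube, 0.5)
  expect_lt(abs(voxel_volume(g05) - voxel_volume(g1)) / voxel_volume(g1), 0.03)

  sph <- orient_mesh(icosphere(5, 3))
  gs <- voxelize(sph, 0.5)
  expect_lt(abs(voxel_volume(gs) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)

  # voxel and tetrahedron volume agree on a watertight fixture
  expect_lt(abs(voxel_volume(gs) - abs(dendriform:::mesh_volume_signed(sph))) /
              voxel_volume(gs), 0.03)

  expect_error(voxelize(cube, 4), "pitch")
})

test_that("voxelize reports open surfaces", {
  s <- icosphere(5, 2)
  s$faces <- s$faces[-seq_len(60), ] # rip a large hole
  s <- tri_mesh(s$vertices, s$faces)
  o <- s; class(o) <- c("oriented_mesh", "tri_mesh")
  expect_error(voxelize(o, 0.5), "open surface.*[0-9]+ voxels")
})

test_that("geometric traits match closed forms", {
  sph <- orient_mesh(icosphere(6, 3))
  gt <- geometric_traits(sph, voxelize(sph, 0.5))
  expect_equal(gt$Sphericity, 1, tolerance = 0.02)
  expect_gte(gt$Solidity, 0.98)

  box <- orient_mesh(box_mesh(20, 6, 3))
  gb <- geometric_traits(box, voxelize(box, 0.5))
  expect_equal(gb$Volume, 360, tolerance = 0.01)
  expect_equal(gb$Solidity, 1, tolerance = 1e-6)
  expect_equal(gb$Elongation, 0.7, tolerance = 1e-9)
  expect_equal(gb$Flatness, 0.5, tolerance = 1e-9)
  expect_equal(gb$SurfaceArea, 2 * (20 * 6 + 20 * 3 + 6 * 3), tolerance = 1e-9)
})

test_that("scaling behaves dimensionally", {
  fx <- capsule_fixture(n_branches = 4, seed = 11)
  m1 <- orient_mesh(fx$mesh)
  m2 <- m1; m2$vertices <- m2$vertices * 2
  t1 <- geometric_traits(m1)
  t2 <- geometric_traits(m2)
  expect_equal(t2$Volume / t1$Volume, 8, tolerance = 1e-6)
  expect_equal(t2$SurfaceArea / t1$SurfaceArea, 4, tolerance = 1e-6)
  for (tr in c("Solidity", "Sphericity", "Elongation", "Flatness"))
    expect_equal(t2[[tr]], t1[[tr]], tolerance = 1e-6)
})

test_that("quickhull volume matches a brute-force oracle", {
  set.seed(4)
  for (i in 1:5) {
    P <- matrix(rnorm(3 * 15), 15, 3)
    h <- dendriform:::cpp_convex_hull(P)
    expect_equal(h$volume, oracle_hull_volume(P), tolerance = 1e-9)
  }
  expect_error(dendriform:::cpp_convex_hull(cbind(1:9, (1:9) * 2, (1:9) * 3)),
               "collinear")
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(dendriform:::cpp_convex_hull(flat), "coplanar")
})

test_that("core body removes branches and keeps the trunk", {
  fx <- capsule_fixture(n_branches = 8, branch_len = 10, seed = 5)
  bare <- capsule_fixture(n_branches = 0, seed = 5)
  om <- orient_mesh(fx$mesh)
  grid <- voxelize(om, 0.5)
  core <- core_body(om, r_open = 2, pitch = 0.5, grid = grid)
  vol_core <- abs(dendriform:::mesh_volume_signed(core))
  vol_bare <- abs(dendriform:::mesh_volume_signed(bare$mesh))
  expect_lt(abs(vol_core - vol_bare) / vol_bare, 0.10)

  # no branches survive the opening: geodesic field on the core-only mesh
  # has no bar of branch scale
  et <- extract_traits(fx$mesh, pitch = 0.5)
  bars <- et$barcode
  expect_equal(sum(!bars$essential & (bars$birth - bars$death) >= 3), 7)

  # CoreOccupancy reproduces the known volume ratio
  gt <- geometric_traits(om, grid)
  ct <- core_traits(core, gt)
  expect_equal(ct$CoreOccupancy, vol_bare / gt$Volume, tolerance = 0.05)
})

test_that("core of a branchless convex body is the body itself", {
  bare <- capsule_fixture(n_branches = 0, seed = 2)
  et <- extract_traits(bare$mesh, pitch = 0.5)
  expect_gt(et$traits$CoreOccupancy, 0.9)

  sph <- orient_mesh(icosphere(6, 3))
  core <- core_body(sph, r_open = 1, pitch = 0.5)
  vol <- abs(dendriform:::mesh_volume_signed(core))
  expect_lt(abs(vol - 4 / 3 * pi * 216) / (4 / 3 * pi * 216), 0.10)

  expect_error(core_body(sph, r_open = 20, pitch = 0.5), "core vanished")
})

test_that("re-opening the core changes it little (idempotence)", {
  fx <- capsule_fixture(n_branches = 6, seed = 9)
  om <- orient_mesh(fx$mesh)
  core1 <- core_body(om, r_open = 2, pitch = 0.5)
  core2 <- core_body(core1, r_open = 2, pitch = 0.5,
                     grid = attr(core1, "grid"))
  v1 <- abs(dendriform:::mesh_volume_signed(core1))
  v2 <- abs(dendriform:::mesh_volume_signed(core2))
  expect_lt(abs(v2 - v1) / v1, 0.05)
})

test_that("traits are robust to one mesh subdivision", {
  fx <- capsule_fixture(n_branches = 4, seed = 13)
  m <- fx$mesh
  ms <- subdivide_mesh(m)
  t1 <- geometric_traits(orient_mesh(m))
  t2 <- geometric_traits(orient_mesh(ms))
  for (tr in c("Volume", "ConvexHullVolume", "SurfaceArea", "Solidity",
               "Sphericity", "MaxLength", "MaxWidth", "MaxHeight")) {
    expect_lt(abs(t2[[tr]] - t1[[tr]]) / abs(t1[[tr]]), 0.02)
  }
})
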