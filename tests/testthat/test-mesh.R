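test_that("a single voxel yields a closed genus-0 surface of unit volume", {
  m <- array(FALSE, c(3, 3, 3))
  m[2, 2, 2] <- TRUE
  mesh <- extract_isosurface(binary_mask(m, spacing = c(1, 1, 2)))
  expect_true(mesh_is_watertight(mesh))
  expect_equal(mesh_euler(mesh), 2)
  vol <- mesh_volume(mesh)
  voxvol <- 1 * 1 * 2
  expect_gt(vol, 0.5 * voxvol)
  expect_lt(vol, 1.5 * voxvol)
  expect_equal(vol, voxvol) # boundary surface encloses the voxel exactly

  expect_error(extract_isosurface(binary_mask(array(FALSE, c(3, 3, 3)))),
    "empty surface"
  )
})

test_that("the enclosed volume of a digital ball matches the analytic sphere", {
  m <- digital_ball(12)
  mesh <- extract_isosurface(m)
  expect_true(mesh_is_watertight(mesh))
  expect_equal(mesh_euler(mesh), 2)
  analytic <- 4 / 3 * pi * 12^3
  expect_lt(abs(mesh_volume(mesh) - analytic) / analytic, 0.10)
  # surface volume equals the voxel count exactly (voxel-boundary surface)
  expect_equal(mesh_volume(mesh), sum(m$voxels))
})

test_that("disjoint blocks produce separate surface components", {
  m <- array(FALSE, c(10, 6, 6))
  m[2:3, 2:3, 2:3] <- TRUE
  m[7:8, 3:4, 3:4] <- TRUE
  mesh <- extract_isosurface(binary_mask(m))
  expect_equal(mesh_component_count(mesh), 2)
  expect_equal(mesh_volume(mesh), 16)
})

test_that("mesh vertices respect the mask's physical frame", {
  m <- rand_mask(c(8, 7, 6), p = 0.4, seed = 12, spacing = c(0.7, 0.8, 2.0))
  m$origin <- c(5, -3, 10)
  mesh <- extract_isosurface(m)
  lo <- m$origin - 1.5 * m$spacing
  hi <- m$origin + (m$size - 1 + 1.5) * m$spacing
  expect_true(all(t(mesh$vertices) >= lo - 1e-9))
  expect_true(all(t(t(mesh$vertices) - hi) <= 1e-9))
})

test_that("decimation halves the face count and preserves topology and volume", {
  mesh <- extract_isosurface(digital_ball(12))

  same <- decimate_mesh(mesh, 0)
  expect_equal(nrow(same$faces), nrow(mesh$faces))

  dec <- decimate_mesh(mesh, 0.5)
  expect_lte(nrow(dec$faces), ceiling(0.5 * nrow(mesh$faces)))
  expect_equal(mesh_euler(dec), 2)
  expect_equal(mesh_component_count(dec), 1)
  expect_true(mesh_is_watertight(dec))
  expect_lt(abs(mesh_volume(dec) - mesh_volume(mesh)) / mesh_volume(mesh), 0.05)

  # two components stay two components
  m <- array(FALSE, c(16, 10, 10))
  m[2:7, 2:7, 2:7] <- TRUE
  m[10:15, 3:8, 3:8] <- TRUE
  two <- extract_isosurface(binary_mask(m))
  dec2 <- decimate_mesh(two, 0.5)
  expect_equal(mesh_component_count(dec2), 2)
  expect_equal(mesh_euler(dec2), 4) # 2 per closed genus-0 component
})

test_that("smoothing follows the mean-of-neighbors update exactly", {
  # symmetric star: the centroid of the neighbors is the vertex itself
  v <- rbind(
    c(0, 0, 0),
    c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)
  )
  f <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2))
  sm <- laplacian_smooth(triangle_mesh(v, f), iterations = 1, relaxation = 1)
  expect_equal(sm$vertices[1, ], c(0, 0, 0), tolerance = 1e-15)

  # two neighbors at (2,0,0) and (0,2,0): full relaxation lands on (1,1,0)
  v2 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  f2 <- rbind(c(1, 2, 3))
  sm2 <- laplacian_smooth(triangle_mesh(v2, f2), iterations = 1, relaxation = 1)
  expect_equal(sm2$vertices[1, ], c(1, 1, 0), tolerance = 1e-15)

  # connectivity is unchanged
  expect_identical(sm2$faces, matrix(c(1L, 2L, 3L), 1))
})

test_that("smoothing shrinks a closed convex surface monotonically", {
  mesh <- extract_isosurface(digital_ball(8))
  vols <- numeric(6)
  cur <- mesh
  vols[1] <- mesh_volume(cur)
  for (i in 2:6) {
    cur <- laplacian_smooth(cur, iterations = 2, relaxation = 0.5)
    vols[i] <- mesh_volume(cur)
  }
  expect_true(all(diff(vols) < 0))
})

test_that("OBJ export writes v/f records that round-trip exactly", {
  tet <- triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  )
  dir <- withr_tempdir()
  p <- file.path(dir, "tet.obj")
  export_mesh(tet, p)
  lines <- readLines(p)
  expect_equal(sum(startsWith(lines, "v ")), 4)
  expect_equal(sum(startsWith(lines, "f ")), 4)
  back <- read_mesh(p)
  expect_identical(back$faces, tet$faces)
  expect_lt(max(abs(back$vertices - tet$vertices)), 1e-4)
})

test_that("mesh export/import round-trips a phantom-scale surface", {
  mesh <- laplacian_smooth(extract_isosurface(digital_ball(8)), 5, 0.2)
  dir <- withr_tempdir()

  obj <- file.path(dir, "ball.obj")
  export_mesh(mesh, obj)
  back <- read_mesh(obj)
  expect_equal(nrow(back$faces), nrow(mesh$faces))
  expect_identical(back$faces, mesh$faces)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-4)

  stl <- file.path(dir, "ball.stl")
  export_mesh(mesh, stl)
  # facet count equals face count
  con <- file(stl, "rb")
  seek(con, 80)
  nfacet <- readBin(con, "integer", size = 4, endian = "little")
  close(con)
  expect_equal(nfacet, nrow(mesh$faces))
  backs <- read_mesh(stl)
  expect_equal(nrow(backs$faces), nrow(mesh$faces))
  expect_lt(max(abs(sort(backs$vertices[, 1]) - sort(mesh$vertices[, 1]))), 1e-4)
  expect_equal(mesh_volume(backs), mesh_volume(mesh), tolerance = 1e-6)
})

test_that("degenerate meshes are rejected", {
  expect_error(
    triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(1, 2, 2))),
    "degenerate"
  )
  expect_error(
    triangle_mesh(rbind(c(0, 0, 0)), rbind(c(1, 1, 2))),
    "out of range"
  )
})
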