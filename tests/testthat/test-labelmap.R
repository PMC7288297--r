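test_that("labeling partitions foreground with deterministic numbering", {
  m <- array(FALSE, c(8, 8, 8))
  m[2:3, 2:3, 2:3] <- TRUE
  m[6:7, 6:7, 6:7] <- TRUE
  lm <- label_components(binary_mask(m))
  expect_equal(nrow(lm$components), 2)
  expect_equal(lm$components$voxel_count, c(8, 8))
  # first-encountered component (scan order) gets label 1
  expect_equal(lm$labels[2, 2, 2], 1L)
  expect_equal(lm$labels[6, 6, 6], 2L)
  # 0-based bounding boxes and extents
  expect_equal(
    unlist(lm$components[1, c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")]),
    c(xmin = 1, xmax = 2, ymin = 1, ymax = 2, zmin = 1, zmax = 2)
  )
  expect_equal(lm$components$extent_x, c(2L, 2L))

  empty <- label_components(binary_mask(array(FALSE, c(4, 4, 4))))
  expect_equal(nrow(empty$components), 0)
})

test_that("labeling agrees with flood fill at both connectivities", {
  for (seed in 1:5) {
    m <- rand_mask(c(15, 13, 11), p = 0.35, seed = seed)
    for (conn in c(6, 26)) {
      lm <- label_components(m, connectivity = conn)
      expect_identical(as.vector(lm$labels), as.vector(oracle_label(m, conn)),
        info = sprintf("seed=%d conn=%d", seed, conn)
      )
      expect_equal(sum(lm$components$voxel_count), sum(m$voxels))
    }
  }
})

test_that("small-component removal keeps exactly the large groups", {
  m <- array(FALSE, c(20, 10, 10))
  m[1:2, 1:2, 1] <- TRUE # 4 voxels (with one removed below: 3)
  m[1, 1, 1] <- FALSE
  m[5:14, 3:9, 2:9] <- TRUE # 560 voxels
  lm <- label_components(binary_mask(m))
  expect_equal(sort(lm$components$voxel_count), c(3, 560))
  out <- remove_small_components(lm, min_voxels = 10)
  expect_equal(sum(out$voxels), 560)

  ident <- remove_small_components(lm, min_voxels = 1)
  expect_identical(ident$voxels, m)

  for (seed in 1:3) {
    rm <- rand_mask(c(12, 12, 8), p = 0.3, seed = seed)
    lm <- label_components(rm)
    out <- remove_small_components(lm, min_voxels = 5)
    keep <- lm$components$voxel_count[lm$components$voxel_count >= 5]
    expect_equal(sum(out$voxels), sum(keep))
    # anti-extensive and idempotent
    expect_true(all(rm$voxels[out$voxels]))
    lm2 <- label_components(out)
    expect_identical(
      remove_small_components(lm2, min_voxels = 5)$voxels,
      out$voxels
    )
  }
})

test_that("border-spanning removal uses strict equality of extents", {
  m <- array(FALSE, c(16, 12, 6))
  m[1:16, 2:3, 2:3] <- TRUE # slab spanning the full x width
  m[5:7, 6:8, 4:5] <- TRUE # interior blob
  lm <- label_components(binary_mask(m))
  out <- remove_border_spanning(lm)
  expect_equal(sum(out$voxels), 3 * 3 * 2)
  expect_true(all(out$voxels[5:7, 6:8, 4:5]))

  m2 <- array(FALSE, c(16, 12, 6))
  m2[1:15, 2:3, 2:3] <- TRUE # extent_x = nx - 1: kept
  lm2 <- label_components(binary_mask(m2))
  expect_equal(sum(remove_border_spanning(lm2)$voxels), sum(m2))

  # never removes a component fully interior in x and y
  for (seed in 1:3) {
    blob <- array(FALSE, c(14, 14, 8))
    blob[3:7, 4:9, 2:6] <- TRUE
    lm3 <- label_components(binary_mask(blob))
    expect_identical(remove_border_spanning(lm3)$voxels, blob)
  }
})

test_that("phantom scene reduces to exactly the two lungs", {
  ph <- generate_phantom(phantom_spec(seed = 2, noise_sigma = 0))
  th <- hu_threshold(ph$volume)
  lm <- label_components(th)
  survivors <- remove_border_spanning(
    label_components(remove_small_components(lm, 1000))
  )
  # exterior air and the full-width stretcher laminae are eliminated;
  # what remains is the lung air (parenchyma minus vessels), exactly
  expect_identical(survivors$voxels, ph$truth_lung_air$voxels)
  expect_equal(nrow(label_components(survivors)$components), 2)
})

test_that("first-slice rule removes laminated thin arcs and keeps blocks", {
  fx <- laminated_arc_and_block()
  out <- remove_stretcher_first_slice(fx$mask,
    fill_radius = 2,
    fill_iterations = 700
  )
  expect_equal(sum(out$voxels & fx$arc), 0)
  expect_identical(out$voxels & fx$block, fx$block)

  # empty first slice passes through unchanged
  m <- array(FALSE, c(10, 10, 3))
  m[3:6, 3:6, 2] <- TRUE
  msk <- binary_mask(m)
  expect_identical(remove_stretcher_first_slice(msk)$voxels, m)

  # only slice 0 is touched
  m2 <- array(FALSE, c(64, 48, 2))
  m2[, , 1] <- fx$mask$voxels[, , 1]
  m2[, , 2] <- fx$mask$voxels[, , 1]
  out2 <- remove_stretcher_first_slice(binary_mask(m2))
  expect_identical(out2$voxels[, , 2], m2[, , 2])
  expect_equal(sum(out2$voxels[, , 1] & fx$arc[, , 1]), 0)

  # idempotent
  expect_identical(remove_stretcher_first_slice(out)$voxels, out$voxels)
})

test_that("phantom first-slice stretcher is removed without touching the air", {
  ph <- generate_phantom(phantom_spec(
    seed = 4,
    stretcher_first_slice_only = TRUE
  ))
  th <- hu_threshold(ph$volume)
  out <- remove_stretcher_first_slice(th)
  expect_equal(sum(out$voxels & ph$truth_stretcher$voxels), 0)
  # the bulky exterior-air region of slice 0 survives (almost) untouched
  air0 <- phantom_exterior_air(ph)[, , 1] & th$voxels[, , 1]
  # a little creep where the fill bridges the pad's jagged end caps is
  # tolerated; the air region as a whole must stay
  kept <- sum(out$voxels[, , 1] & air0) / sum(air0)
  expect_gt(kept, 0.98)
})
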