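test_that("thresholding keeps exactly the voxels inside the inclusive range", {
  v <- ct_volume(array(c(-1000, -500, 0, -400), c(4, 1, 1)))
  m <- hu_threshold(v, c(-4000, -400))
  expect_equal(as.vector(m$voxels), c(TRUE, TRUE, FALSE, TRUE))

  const <- ct_volume(array(-123, c(3, 3, 3)))
  expect_true(all(hu_threshold(const, c(-123, -123))$voxels))

  vol <- rand_volume(c(10, 10, 10), seed = 42)
  m <- hu_threshold(vol, c(-900, -350))
  brute <- array(FALSE, dim(vol$voxels))
  for (i in seq_along(vol$voxels)) {
    brute[i] <- vol$voxels[i] >= -900 && vol$voxels[i] <= -350
  }
  expect_identical(m$voxels, brute)
})

test_that("ball erosion strips one boundary layer from a solid cube", {
  m <- array(FALSE, c(7, 7, 7))
  m[2:6, 2:6, 2:6] <- TRUE
  out <- erode(binary_mask(m), se_ball(1))
  expect_equal(sum(out$voxels), 27)
  expect_true(all(out$voxels[3:5, 3:5, 3:5]))

  empty <- mask_like(binary_mask(m))
  expect_equal(sum(erode(empty, se_ball(3))$voxels), 0)
})

test_that("erosion and dilation match the set-inclusion definition", {
  for (seed in 1:6) {
    m <- rand_mask(c(16, 14, 12), p = 0.6, seed = seed)
    for (se in list(se_ball(1), se_ball(2), se_box(1))) {
      expect_identical(erode(m, se)$voxels, oracle_erode(m, se)$voxels,
        info = sprintf("erode seed=%d %s r=%d", seed, se$shape, se$radius)
      )
      expect_identical(dilate(m, se)$voxels, oracle_dilate(m, se)$voxels,
        info = sprintf("dilate seed=%d %s r=%d", seed, se$shape, se$radius)
      )
    }
  }
})

test_that("dilating a single voxel with a unit ball gives the 7-voxel cross", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  out <- dilate(binary_mask(m), se_ball(1))
  expect_equal(sum(out$voxels), 7)
  expect_true(all(out$voxels[3, 3, 2:4]))
  expect_true(all(out$voxels[2:4, 3, 3]))

  full <- binary_mask(array(TRUE, c(4, 4, 4)))
  expect_identical(dilate(full, se_ball(1))$voxels, full$voxels)
})

test_that("erosion/dilation duality under complement holds away from borders", {
  # embed with a margin wider than the element so the border convention
  # of the two operators mirrors exactly
  for (seed in 1:4) {
    inner <- rand_mask(c(8, 8, 8), p = 0.5, seed = seed)
    m <- array(FALSE, c(14, 14, 14))
    m[4:11, 4:11, 4:11] <- inner$voxels
    m <- binary_mask(m)
    se <- se_ball(2)
    dual <- mask_complement(erode(mask_complement(m), se))
    # compare away from the frame, where the complement's border handling
    # (out-of-bounds reads) cannot differ between the two routes
    inner <- 3:12
    expect_identical(
      dilate(m, se)$voxels[inner, inner, inner],
      dual$voxels[inner, inner, inner]
    )
  }
})

test_that("opening is anti-extensive, closing extensive, both idempotent", {
  se <- se_ball(1)

  single <- array(FALSE, c(5, 5, 5))
  single[3, 3, 3] <- TRUE
  expect_equal(sum(open_mask(binary_mask(single), se)$voxels), 0)

  holed <- array(TRUE, c(5, 5, 5))
  holed[3, 3, 3] <- FALSE
  closed <- close_mask(binary_mask(holed), se)
  expect_true(all(closed$voxels))

  for (seed in 1:4) {
    m <- rand_mask(c(12, 12, 10), p = 0.55, seed = seed)
    op <- open_mask(m, se)
    cl <- close_mask(m, se)
    expect_true(all(m$voxels[op$voxels])) # open(m) subset of m
    expect_true(all(cl$voxels[m$voxels])) # m subset of close(m)
    expect_identical(open_mask(op, se)$voxels, op$voxels)
    expect_identical(close_mask(cl, se)$voxels, cl$voxels)
  }
})

test_that("voting fill flips a fully enclosed voxel in one iteration", {
  m <- array(TRUE, c(5, 5, 5))
  m[3, 3, 3] <- FALSE
  out <- voting_hole_fill(binary_mask(m), radius = 1, max_iterations = 10,
                          majority = 1)
  expect_true(all(out$voxels))
  expect_equal(attr(out, "iterations"), 2) # one flip pass + one to converge

  empty <- binary_mask(array(FALSE, c(6, 6, 6)))
  expect_equal(sum(voting_hole_fill(empty, 2, 5)$voxels), 0)
})

test_that("voting fill is monotone and matches the counting rule", {
  for (seed in 1:4) {
    m <- rand_mask(c(10, 9, 8), p = 0.55, seed = seed)
    out <- voting_hole_fill(m, radius = 1, max_iterations = 4, majority = 1)
    expect_true(all(out$voxels[m$voxels])) # never removes foreground
    want <- oracle_voting(m, radius = 1, max_iterations = 4, majority = 1)
    expect_identical(out$voxels, want$voxels)
  }
  # converged output is a fixed point
  m <- rand_mask(c(10, 10, 6), p = 0.6, seed = 9)
  conv <- voting_hole_fill(m, radius = 1, max_iterations = 100)
  again <- voting_hole_fill(conv, radius = 1, max_iterations = 100)
  expect_identical(conv$voxels, again$voxels)
})

test_that("a single-slice mask is filled with the 2D neighborhood rule", {
  # 24-neighbor 2D rule: a 1-gap between 2-thick plates fills, and the
  # 3D threshold (62 of 124) would not behave this way
  m <- array(FALSE, c(9, 7, 1))
  m[2:8, 2:3, 1] <- TRUE
  m[2:8, 5:6, 1] <- TRUE
  out <- voting_hole_fill(binary_mask(m), radius = 2, max_iterations = 10)
  expect_true(all(out$voxels[2:8, 4, 1]))
  want <- oracle_voting(binary_mask(m), 2, 10)
  expect_identical(out$voxels, want$voxels)
})

test_that("mask algebra matches its truth table and mask_apply selects voxels", {
  a <- binary_mask(array(c(FALSE, FALSE, TRUE, TRUE), c(4, 1, 1)))
  b <- binary_mask(array(c(FALSE, TRUE, FALSE, TRUE), c(4, 1, 1)))
  expect_equal(as.vector(mask_and(a, b)$voxels), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(as.vector(mask_or(a, b)$voxels), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(as.vector(mask_xor(a, b)$voxels), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(
    as.vector(mask_subtract(a, b)$voxels),
    c(FALSE, FALSE, TRUE, FALSE)
  )
  expect_equal(sum(mask_xor(a, a)$voxels), 0)
  full <- binary_mask(array(TRUE, c(4, 1, 1)))
  expect_identical(mask_subtract(full, b)$voxels, mask_complement(b)$voxels)

  vol <- rand_volume(c(8, 8, 8), seed = 5)
  m <- rand_mask(c(8, 8, 8), p = 0.5, seed = 6)
  res <- mask_apply(vol, m, outside_value = -4096)
  want <- vol$voxels
  for (i in seq_along(want)) if (!m$voxels[i]) want[i] <- -4096
  expect_identical(res$voxels, want)
  expect_identical(
    mask_apply(vol, mask_like(vol, TRUE))$voxels,
    vol$voxels
  )
  expect_true(all(mask_apply(vol, mask_like(vol, FALSE))$voxels == -4096))

  small <- binary_mask(array(TRUE, c(2, 2, 2)))
  expect_error(mask_and(a, small), "geometry mismatch")
  expect_error(mask_apply(vol, small), "geometry mismatch")
})

test_that("structuring elements contain the center and are symmetric", {
  for (se in list(se_ball(0), se_ball(1), se_ball(3), se_box(2))) {
    off <- se$offsets
    expect_true(any(rowSums(abs(off)) == 0))
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    expect_setequal(key(off), key(-off))
  }
  expect_equal(nrow(se_ball(1)$offsets), 7)
  expect_equal(nrow(se_box(1)$offsets), 27)
  expect_error(se_ball(-1), "radius")
  expect_error(hu_range(10, -10), "lower")
})
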