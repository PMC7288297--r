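test_that("NRRD round-trip is bit-exact for integer HU volumes and masks", {
  dir <- withr_tempdir()
  vol <- rand_volume(c(9, 7, 5), seed = 11, lo = -4000, hi = 3000)
  vol$origin <- c(-200.5, -180.0, -50.0)
  vol <- ct_volume(vol$voxels, spacing = c(0.7, 0.7, 2.5),
                   origin = c(-200.5, -180.0, -50.0))
  p <- file.path(dir, "v.nrrd")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-9)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)

  m <- rand_mask(c(6, 5, 4), p = 0.4, seed = 3)
  pm <- file.path(dir, "m.nrrd")
  write_volume(m, pm)
  backm <- read_mask(pm)
  expect_identical(backm$voxels, m$voxels)

  empty <- mask_like(m, FALSE)
  pe <- file.path(dir, "e.nrrd")
  write_volume(empty, pe)
  expect_equal(sum(read_volume(pe)$voxels), 0)
})

test_that("MHA round-trip preserves voxels and header metadata", {
  dir <- withr_tempdir()
  vol <- ct_volume(array(round(stats::rnorm(4 * 5 * 6, -500, 400)), c(4, 5, 6)),
    spacing = c(0.7, 0.7, 2.5), origin = c(1.25, -2.5, 10)
  )
  p <- file.path(dir, "v.mha")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, c(0.7, 0.7, 2.5), tolerance = 1e-9)
  expect_equal(back$origin, vol$origin, tolerance = 1e-9)
})

test_that("non-3D volumes are rejected", {
  dir <- withr_tempdir()
  p <- file.path(dir, "bad.nrrd")
  writeLines(c(
    "NRRD0004", "type: int16", "dimension: 4", "sizes: 2 2 2 2",
    "encoding: raw", ""
  ), p)
  expect_error(read_volume(p), "unsupported dimensionality")
})

test_that("axis-aligned direction flips are normalized on read", {
  dir <- withr_tempdir()
  # write a NRRD with a negative z direction by hand
  vox <- array(as.integer(1:24), c(2, 3, 4))
  p <- file.path(dir, "flip.nrrd")
  con <- file(p, "wb")
  writeLines(c(
    "NRRD0004", "type: int16", "dimension: 3", "sizes: 2 3 4",
    "space directions: (1,0,0) (0,1,0) (0,0,-2)",
    "space origin: (0,0,6)", "endian: little", "encoding: raw", ""
  ), con)
  writeBin(as.integer(vox), con, size = 2, endian = "little")
  close(con)
  v <- read_volume(p)
  expect_equal(v$spacing, c(1, 1, 2))
  expect_equal(v$origin, c(0, 0, 0)) # 6 + (-2) * 3
  expect_identical(v$voxels[, , 1], matrix(as.double(19:24), 2, 3))

  # oblique orientations are refused
  p2 <- file.path(dir, "obl.nrrd")
  con <- file(p2, "wb")
  writeLines(c(
    "NRRD0004", "type: int16", "dimension: 3", "sizes: 2 2 2",
    "space directions: (1,0.2,0) (0,1,0) (0,0,1)", "encoding: raw", ""
  ), con)
  writeBin(as.integer(1:8), con, size = 2, endian = "little")
  close(con)
  expect_error(read_volume(p2), "oblique")
})

test_that("DICOM series round-trips a phantom bit-exactly", {
  dir <- withr_tempdir()
  ph <- generate_phantom(phantom_spec(size = c(32, 32, 32), seed = 5))
  paths <- write_phantom_dicom(ph, dir)
  expect_length(paths, 32)
  v <- read_dicom_series(dir)
  expect_identical(v$voxels, ph$volume$voxels)
  expect_equal(v$spacing, ph$volume$spacing, tolerance = 1e-9)
  expect_equal(v$origin, ph$volume$origin, tolerance = 1e-9)
})

test_that("slice order is a function of position, not filename", {
  dir <- withr_tempdir()
  ph <- generate_phantom(phantom_spec(size = c(32, 32, 32), seed = 6))
  src <- file.path(dir, "orig")
  write_phantom_dicom(ph, src)
  shuf <- file.path(dir, "shuffled")
  dir.create(shuf)
  files <- list.files(src, full.names = TRUE)
  set.seed(1)
  for (i in seq_along(files)) {
    file.copy(files[i], file.path(shuf, sprintf("%04d.dcm", sample(1e6, 1))))
  }
  v <- read_dicom_series(shuf)
  expect_identical(v$voxels, ph$volume$voxels)
  expect_equal(v$origin, ph$volume$origin, tolerance = 1e-9)
})

test_that("HU calibration applies each file's rescale slope and intercept", {
  dir <- withr_tempdir()
  px <- matrix(500L, 8, 8)
  for (k in 1:2) {
    ctlungseg:::dicom_write_slice(
      file.path(dir, sprintf("s%d.dcm", k)),
      pixels = px, slope = 2, intercept = -1000,
      position = c(0, 0, (k - 1) * 2.5), pixel_spacing = c(1, 1),
      series_uid = "1.2.3.4", sop_uid = paste0("1.2.3.4.", k),
      instance_number = k
    )
  }
  v <- read_dicom_series(dir)
  # by-hand oracle: 2 * 500 - 1000 = 0 HU in every voxel
  expect_true(all(v$voxels == 0))
  expect_equal(v$spacing[3], 2.5)

  dir2 <- withr_tempdir()
  for (k in 1:3) {
    ctlungseg:::dicom_write_slice(
      file.path(dir2, sprintf("s%d.dcm", k)),
      pixels = matrix(1024L, 4, 4), slope = 1, intercept = -1024,
      position = c(0, 0, k - 1), pixel_spacing = c(1, 1),
      series_uid = "1.2.3.5", sop_uid = paste0("1.2.3.5.", k),
      instance_number = k
    )
  }
  v2 <- read_dicom_series(dir2)
  expect_true(all(v2$voxels == 0))
  expect_equal(v2$spacing[3], 1)
})

test_that("mixed series and unreadable inputs are rejected", {
  dir <- withr_tempdir()
  expect_error(read_dicom_series(dir), "no readable slices")

  writeLines("not dicom", file.path(dir, "junk.txt"))
  expect_error(
    suppressWarnings(read_dicom_series(dir)),
    "no readable slices"
  )

  for (k in 1:2) {
    ctlungseg:::dicom_write_slice(
      file.path(dir, sprintf("s%d.dcm", k)),
      pixels = matrix(0L, 4, 4), slope = 1, intercept = 0,
      position = c(0, 0, k), pixel_spacing = c(1, 1),
      series_uid = paste0("1.2.9.", k), # different series per file
      sop_uid = paste0("1.2.9.9.", k), instance_number = k
    )
  }
  expect_warning(
    expect_error(read_dicom_series(dir), "mixed series"),
    "unreadable"
  )
})

test_that("non-uniform slice gaps warn and fall back to the median", {
  dir <- withr_tempdir()
  zs <- c(0, 2, 4, 6.8) # one irregular gap
  for (k in seq_along(zs)) {
    ctlungseg:::dicom_write_slice(
      file.path(dir, sprintf("s%d.dcm", k)),
      pixels = matrix(100L, 4, 4), slope = 1, intercept = 0,
      position = c(0, 0, zs[k]), pixel_spacing = c(1, 1),
      series_uid = "1.2.10", sop_uid = paste0("1.2.10.", k),
      instance_number = k
    )
  }
  expect_warning(v <- read_dicom_series(dir), "non-uniform")
  expect_equal(v$spacing[3], 2)
})

test_that("the DICOM writer is readable by an independent implementation", {
  dir <- withr_tempdir()
  px <- matrix(seq_len(64) + 100L, 8, 8)
  f <- file.path(dir, "x.dcm")
  ctlungseg:::dicom_write_slice(
    f,
    pixels = px, slope = 1, intercept = -1024,
    position = c(-10.5, 20.25, 3.5), pixel_spacing = c(0.7, 0.9),
    series_uid = "1.2.3.77", sop_uid = "1.2.3.77.1", instance_number = 1
  )
  script <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(int(ds.Rows), int(ds.Columns))",
    "print(float(ds.RescaleSlope), float(ds.RescaleIntercept))",
    "print(','.join(str(float(v)) for v in ds.ImagePositionPatient))",
    "print(','.join(str(float(v)) for v in ds.PixelSpacing))",
    "arr = ds.pixel_array",
    "print(int(arr[0,0]), int(arr[7,0]), int(arr.sum()))",
    sep = "\n"
  )
  out <- suppressWarnings(system2("python", c("-", f),
    input = script,
    stdout = TRUE, stderr = FALSE
  ))
  expect_equal(out[1], "8 8")
  expect_equal(out[2], "1.0 -1024.0")
  expect_equal(out[3], "-10.5,20.25,3.5")
  expect_equal(out[4], "0.9,0.7") # row spacing (y), column spacing (x)
  # pixel_array is row-major [row, col]: [0,0] = px[1,1]; [7,0] = px[1,8]
  expect_equal(
    out[5],
    paste(px[1, 1], px[1, 8], sum(px))
  )
})
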