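# Shared fixtures built in code at test time.

withr_tempdir <- function() {
  d <- tempfile("ctlungseg-test-")
  dir.create(d)
  d
}

# A laminated thin arc (three 2-voxel plates with 2-voxel gaps) next to a
# solid block, in a single-slice mask: the canonical stretcher-vs-anatomy
# scene for the first-slice removal rule.
laminated_arc_and_block <- function(nx = 64, ny = 48) {
  m <- array(FALSE, c(nx, ny, 1))
  for (p in 0:2) {
    rows <- 10 + p * 4 + 0:1
    m[5:55, rows, 1] <- TRUE
  }
  m[10:29, 26:45, 1] <- TRUE # 20 x 20 solid block
  list(
    mask = binary_mask(m),
    arc = {
      a <- array(FALSE, c(nx, ny, 1))
      for (p in 0:2) a[5:55, 10 + p * 4 + 0:1, 1] <- TRUE
      a
    },
    block = {
      b <- array(FALSE, c(nx, ny, 1))
      b[10:29, 26:45, 1] <- TRUE
      b
    }
  )
}

# digital ball mask of radius r voxels on an isotropic grid
digital_ball <- function(r = 12, spacing = c(1, 1, 1)) {
  n <- 2 * r + 7
  ctr <- (n - 1) / 2
  g <- seq_len(n) - 1
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  binary_mask((X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2 <= r^2,
    spacing = spacing
  )
}

default_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}

# exterior air of a phantom: below-threshold voxels that are neither lung
# air nor stretcher foam
phantom_exterior_air <- function(ph) {
  ph$volume$voxels < -400 & !ph$truth_lung$voxels & !ph$truth_stretcher$voxels
}
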