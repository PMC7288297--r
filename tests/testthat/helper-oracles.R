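# Brute-force reference implementations of the voxel operators, written
# directly from their defining formulas and kept independent of the package
# internals. Used to freeze expected values and for operator-equivalence
# property tests.

rand_mask <- function(d, p = 0.5, seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  binary_mask(array(stats::runif(prod(d)) < p, d), spacing = spacing)
}

rand_volume <- function(d, seed = 1, lo = -1200, hi = 200) {
  set.seed(seed)
  ct_volume(array(round(stats::runif(prod(d), lo, hi)), d))
}

# out[z] = a[z + off], out-of-bounds reads give FALSE
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, d)
  rng <- vector("list", 3)
  src <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    dst <- max(1, 1 - o):min(d[ax], d[ax] - o)
    if (length(dst) == 0 || dst[1] > dst[length(dst)]) {
      return(out)
    }
    rng[[ax]] <- dst
    src[[ax]] <- dst + o
  }
  out[rng[[1]], rng[[2]], rng[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

# Erosion by literal set inclusion: z kept iff every translated offset of
# the structuring element lands on foreground (OOB = background).
oracle_erode <- function(mask, se) {
  out <- array(TRUE, dim(mask$voxels))
  for (r in seq_len(nrow(se$offsets))) {
    out <- out & shift_array(mask$voxels, se$offsets[r, ])
  }
  binary_mask(out, spacing = mask$spacing, origin = mask$origin)
}

oracle_dilate <- function(mask, se) {
  out <- array(FALSE, dim(mask$voxels))
  for (r in seq_len(nrow(se$offsets))) {
    out <- out | shift_array(mask$voxels, se$offsets[r, ])
  }
  binary_mask(out, spacing = mask$spacing, origin = mask$origin)
}

# One voting iteration by direct neighborhood counting.
oracle_voting_step <- function(m, radius, majority) {
  d <- dim(m)
  nb <- 1
  for (ax in 1:3) if (d[ax] > 1) nb <- nb * (2 * radius + 1)
  thr <- (nb - 1) / 2 + majority
  out <- m
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        if (m[i, j, k]) next
        xs <- max(1, i - radius):min(d[1], i + radius)
        ys <- max(1, j - radius):min(d[2], j + radius)
        zs <- max(1, k - radius):min(d[3], k + radius)
        if (sum(m[xs, ys, zs]) >= thr) out[i, j, k] <- TRUE
      }
    }
  }
  out
}

oracle_voting <- function(mask, radius, max_iterations, majority = 1) {
  m <- mask$voxels
  for (it in seq_len(max_iterations)) {
    nxt <- oracle_voting_step(m, radius, majority)
    if (identical(nxt, m)) break
    m <- nxt
  }
  binary_mask(m, spacing = mask$spacing, origin = mask$origin)
}

# Flood-fill labeling in scan order (x fastest, then y, then z), matching
# the package's deterministic numbering contract.
oracle_label <- function(mask, connectivity) {
  m <- mask$voxels
  d <- dim(m)
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) {
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  }
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(m)) {
    if (lab[s] > 0) next
    nxt <- nxt + 1L
    stack <- s
    lab[s] <- nxt
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        p <- cc + offs[r, ]
        if (any(p < 1) || any(p > d)) next
        lin <- p[1] + d[1] * (p[2] - 1 + d[2] * (p[3] - 1))
        if (m[lin] && lab[lin] == 0L) {
          lab[lin] <- nxt
          stack <- c(stack, lin)
        }
      }
    }
  }
  lab
}
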