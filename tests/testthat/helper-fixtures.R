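# Shared fixtures: tiny volumes, reference implementations used as
# independent oracles, and a cached miniature dataset.

rand_zstack <- function(dims = c(4L, 8L, 8L), channels = 3L, seed = 1L,
                        range = "raw") {
  set.seed(seed)
  zstack(array(runif(prod(dims) * channels), c(dims, channels)), range)
}

# Plain-R "same"-padded strided 3D convolution, looping over every output
# voxel and kernel tap; the oracle for the BLAS-backed engine path.
r_conv3d_oracle <- function(x, W5, bias, stride) {
  ind <- dim(x)
  k <- dim(W5)[1:3]
  cin <- dim(W5)[4]
  cout <- dim(W5)[5]
  od <- ceiling(ind[1:3] / stride)
  pad_tot <- pmax((od - 1) * stride + k - ind[1:3], 0)
  pad_beg <- pad_tot %/% 2
  out <- array(0, c(od, cout))
  for (co in seq_len(cout)) for (oz in seq_len(od[1]))
    for (oy in seq_len(od[2])) for (ox in seq_len(od[3])) {
      acc <- bias[co]
      for (kz in seq_len(k[1])) for (ky in seq_len(k[2]))
        for (kx in seq_len(k[3])) {
          iz <- (oz - 1) * stride[1] - pad_beg[1] + kz
          iy <- (oy - 1) * stride[2] - pad_beg[2] + ky
          ix <- (ox - 1) * stride[3] - pad_beg[3] + kx
          if (iz >= 1 && iz <= ind[1] && iy >= 1 && iy <= ind[2] &&
              ix >= 1 && ix <= ind[3]) {
            for (ci in seq_len(cin))
              acc <- acc + x[iz, iy, ix, ci] * W5[kz, ky, kx, ci, co]
          }
        }
      out[oz, oy, ox, co] <- acc
    }
  out
}

# Plain-R flood fill with 26-connectivity; the oracle for the C++
# component labelling used by extract_events.
r_flood_fill_oracle <- function(mask3d) {
  d <- dim(mask3d)
  labels <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask3d)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    labels[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      co <- arrayInd(cur, d)
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        nz <- co[1] + dz; ny <- co[2] + dy; nx <- co[3] + dx
        if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] ||
            nx < 1 || nx > d[3]) next
        ni <- nz + d[1] * ((ny - 1) + d[2] * (nx - 1))
        if (mask3d[ni] && labels[ni] == 0L) {
          labels[ni] <- nxt
          stack <- c(stack, ni)
        }
      }
    }
  }
  labels
}

# Miniature on-disk dataset shared by manifest/training tests (built once
# per test run).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "mitovox-tiny-ds")
      params <- simulation_params(dims = c(8L, 16L, 16L), n_structures = 2L,
                                  event_rate = 1, seed = 7L)
      cache <<- simulate_dataset(8, params, clean_fraction = 0.5, dir,
                                 seed = 70)
    }
    cache
  }
})

have_python_tifffile <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- nzchar(Sys.which("python")) &&
        suppressWarnings(system2("python",
                                 c("-c", shQuote("import tifffile")),
                                 stdout = FALSE, stderr = FALSE)) == 0
    }
    cache
  }
})
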