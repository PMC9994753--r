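# Synthetic fluorescence z-stack simulator.  Emulates what the upstream
# event localiser produces for training: an intensity volume of tubular
# mitochondria-like structures on a dark background (with optional
# low-intensity bridges between nearby structures — the imaging confound
# that misleads threshold-based localisation), a target volume of small
# bright event kernels colour-coded by event type, a binary event mask,
# and the ground-truth event list.  Events carry learnable morphological
# cues: fission/fusion kernels sit on structure endpoints or interior
# points, depolarisation kernels sit where the input intensity is locally
# attenuated.  This is a stand-in for real training data, not a
# biological claim.

EVENT_TYPES <- c("fission", "fusion", "depolarisation")

#' Simulation parameters
#'
#' Defaults describe one 8x128x128 volume (the published per-sample
#' geometry) with a handful of tubular structures and on average
#' `event_rate` events per type.
#'
#' @param dims `(z, y, x)` volume dimensions; each axis must be >= 4.
#' @param n_structures number of tubular structures.
#' @param tube_radius_vox Gaussian cross-section sigma of tubes, voxels.
#' @param event_rate Poisson mean of events per type per volume.
#' @param event_kernel_sigma_vox sigma of the isotropic Gaussian event
#'   kernels (thresholded at half maximum, giving compact bright balls of
#'   radius ~2 voxels at the default).
#' @param bridge_probability chance that a pair of structures in close
#'   proximity (< 6 voxels) is joined by a low-intensity bridge.
#' @param bridge_intensity_fraction bridge peak intensity as a fraction of
#'   the tube peak, strictly in (0, 1).
#' @param noise_sigma additive Gaussian background noise sd (input volume
#'   peak is 1).
#' @param target_mode `"events_only"` (kernels on a black background) or
#'   `"events_on_structure"` (kernels superimposed on the structures).
#' @param seed integer seed; the sample is a deterministic function of the
#'   parameters including the seed.
#' @param structures optional list of `(n x 3)` point matrices (z, y, x,
#'   0-based continuous coordinates) overriding random structure
#'   generation; used for controlled experiments.
#' @export
simulation_params <- function(dims = c(8L, 128L, 128L), n_structures = 8L,
                              tube_radius_vox = 1.4, event_rate = 2,
                              event_kernel_sigma_vox = 1.5,
                              bridge_probability = 0.3,
                              bridge_intensity_fraction = 0.35,
                              noise_sigma = 0.05,
                              target_mode = c("events_only",
                                              "events_on_structure"),
                              seed = 1L, structures = NULL) {
  target_mode <- match.arg(target_mode)
  if (any(dims < 4)) stop("dims too small to fit a tube (< 4 voxels)")
  if (tube_radius_vox < 0 || event_rate < 0 || event_kernel_sigma_vox < 0 ||
      noise_sigma < 0)
    stop("rates and sigmas must be non-negative")
  if (bridge_intensity_fraction <= 0 || bridge_intensity_fraction >= 1)
    stop("bridge_intensity_fraction must be strictly between 0 and 1")
  structure(list(dims = as.integer(dims), n_structures = n_structures,
                 tube_radius_vox = tube_radius_vox, event_rate = event_rate,
                 event_kernel_sigma_vox = event_kernel_sigma_vox,
                 bridge_probability = bridge_probability,
                 bridge_intensity_fraction = bridge_intensity_fraction,
                 noise_sigma = noise_sigma, target_mode = target_mode,
                 seed = seed, structures = structures),
            class = "simulation_params")
}

# Splat a Gaussian of peak `intensity` around continuous centre (z, y, x)
# (0-based) into vol (max blend), with sd `sigma`; values below
# `floor_frac` of the peak are not written.
splat_gaussian <- function(vol, centre, sigma, intensity = 1,
                           floor_frac = 0.01) {
  d <- dim(vol)
  r <- ceiling(sigma * sqrt(-2 * log(floor_frac))) + 1L
  zr <- max(0L, floor(centre[1] - r)):min(d[1] - 1L, ceiling(centre[1] + r))
  yr <- max(0L, floor(centre[2] - r)):min(d[2] - 1L, ceiling(centre[2] + r))
  xr <- max(0L, floor(centre[3] - r)):min(d[3] - 1L, ceiling(centre[3] + r))
  if (length(zr) == 0 || length(yr) == 0 || length(xr) == 0) return(vol)
  dz <- (zr - centre[1])^2
  dy <- (yr - centre[2])^2
  dx <- (xr - centre[3])^2
  g <- intensity * exp(-(outer(outer(dz, dy, "+"), dx, "+")) /
                         (2 * sigma^2))
  g[g < intensity * floor_frac] <- 0
  sub <- vol[zr + 1L, yr + 1L, xr + 1L, drop = FALSE]
  vol[zr + 1L, yr + 1L, xr + 1L] <- pmax(sub, g)
  vol
}

# Rasterise a polyline of continuous (z, y, x) points as a tube.
rasterize_tube <- function(vol, points, sigma, intensity = 1) {
  for (i in seq_len(nrow(points)))
    vol <- splat_gaussian(vol, points[i, ], sigma, intensity)
  vol
}

# Smooth random 3D curve: a lateral random walk with slowly varying
# heading and drifting depth, clamped to the volume.
random_curve <- function(dims, step = 0.75) {
  margin <- 3
  n_steps <- max(10L, as.integer(stats::runif(1, 30, 90) / step))
  pos <- c(stats::runif(1, margin, dims[1] - 1 - margin * 0.5),
           stats::runif(1, margin, dims[2] - 1 - margin),
           stats::runif(1, margin, dims[3] - 1 - margin))
  theta <- stats::runif(1, 0, 2 * pi)
  zvel <- stats::rnorm(1, 0, 0.05)
  pts <- matrix(0, n_steps, 3)
  for (i in seq_len(n_steps)) {
    pts[i, ] <- pos
    theta <- theta + stats::rnorm(1, 0, 0.25)
    zvel <- 0.9 * zvel + stats::rnorm(1, 0, 0.03)
    delta <- c(zvel, sin(theta) * step, cos(theta) * step)
    pos <- pos + delta
    lo <- c(1, 1, 1)
    hi <- dims - 2
    ref <- pos < lo | pos > hi
    if (any(ref)) {
      pos <- pmin(pmax(pos, lo), hi)
      if (ref[1]) zvel <- -zvel
      if (ref[2] || ref[3]) theta <- theta + pi / 2
    }
  }
  pts
}

# Half-maximum support radius of an event kernel.
kernel_halfmax_radius <- function(sigma) sigma * sqrt(2 * log(2))

place_events <- function(n, params, curves, existing_centres) {
  dims <- params$dims
  r_k <- kernel_halfmax_radius(params$event_kernel_sigma_vox)
  margin <- ceiling(r_k)
  min_sep <- 2 * r_k + 3
  centres <- list()
  for (e in seq_len(n)) {
    placed <- FALSE
    for (try in 1:50) {
      ci <- sample.int(length(curves), 1)
      pts <- curves[[ci]]
      at_end <- stats::runif(1) < 0.5
      p <- if (at_end) pts[if (stats::runif(1) < 0.5) 1 else nrow(pts), ]
           else pts[sample.int(nrow(pts), 1), ]
      if (any(p < margin) || any(p > dims - 1 - margin)) next
      all_c <- c(existing_centres, centres)
      if (length(all_c) > 0) {
        dists <- vapply(all_c, function(q) sqrt(sum((q - p)^2)), numeric(1))
        if (min(dists) < min_sep) next
      }
      centres[[length(centres) + 1L]] <- p
      placed <- TRUE
      break
    }
    if (!placed) break  # volume too crowded; drop remaining events
  }
  centres
}

#' Simulate one paired training sample
#'
#' Deterministic given the seed in `params`.  Returns the input intensity
#' volume (structures + optional bridges + noise, 3 equal channels), the
#' target event volume (colour-coded kernels, red = fission, green =
#' fusion, blue = depolarisation), the binary event mask, and the planted
#' event records (0-based voxel centroids).
#'
#' @param params a [simulation_params()] object.
#' @return a `simulated_sample`: list with `input_volume`, `target_volume`,
#'   `mask_volume` ([zstack]s / array) and `events` (data.frame with
#'   columns `event_type`, `z`, `y`, `x`, `n_voxels`, `peak_value`).
#' @export
simulate_sample <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  dims <- params$dims
  curves <- params$structures
  if (is.null(curves))
    curves <- lapply(seq_len(params$n_structures), function(i)
      random_curve(dims))
  struct <- array(0, dims)
  for (pts in curves)
    struct <- rasterize_tube(struct, pts, params$tube_radius_vox)
  # low-intensity bridges between structures in close proximity
  if (params$bridge_probability > 0 && length(curves) >= 2) {
    for (i in seq_len(length(curves) - 1L)) {
      for (j in (i + 1L):length(curves)) {
        a <- curves[[i]]
        b <- curves[[j]]
        sub_a <- a[seq(1, nrow(a), by = 3), , drop = FALSE]
        sub_b <- b[seq(1, nrow(b), by = 3), , drop = FALSE]
        dmat <- outer(seq_len(nrow(sub_a)), seq_len(nrow(sub_b)),
                      Vectorize(function(u, v)
                        sqrt(sum((sub_a[u, ] - sub_b[v, ])^2))))
        if (min(dmat) < 6 && min(dmat) > 0.5 &&
            stats::runif(1) < params$bridge_probability) {
          hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
          pa <- sub_a[hit[1], ]
          pb <- sub_b[hit[2], ]
          n_pts <- max(2L, ceiling(min(dmat) / 0.5))
          seg <- sapply(seq(0, 1, length.out = n_pts), function(t)
            pa + t * (pb - pa))
          struct <- rasterize_tube(struct, t(seg), params$tube_radius_vox,
                                   params$bridge_intensity_fraction)
        }
      }
    }
  }
  # events
  n_per_type <- stats::rpois(3, params$event_rate)
  names(n_per_type) <- EVENT_TYPES
  centres_by_type <- list()
  existing <- list()
  for (et in EVENT_TYPES) {
    cs <- place_events(n_per_type[[et]], params, curves, existing)
    centres_by_type[[et]] <- cs
    existing <- c(existing, cs)
  }
  # depolarisation cue: locally attenuate the input structure intensity
  for (p in centres_by_type$depolarisation) {
    att <- array(0, dims)
    att <- splat_gaussian(att, p, 2 * max(params$tube_radius_vox, 1), 0.7)
    struct <- struct * (1 - att)
  }
  # render kernels (half-maximum thresholded Gaussians), one channel/type
  events_vol <- array(0, c(dims, 3L))
  records <- list()
  for (ch in seq_along(EVENT_TYPES)) {
    et <- EVENT_TYPES[ch]
    plane <- array(0, dims)
    for (p in centres_by_type[[et]]) {
      kern <- array(0, dims)
      kern <- splat_gaussian(kern, p, params$event_kernel_sigma_vox)
      kern[kern < 0.5] <- 0
      plane <- pmax(plane, kern)
      records[[length(records) + 1L]] <- data.frame(
        event_type = et, z = p[1], y = p[2], x = p[3],
        n_voxels = sum(kern > 0), peak_value = max(kern))
    }
    events_vol[, , , ch] <- plane
  }
  mask <- binarize_events(events_vol)
  target <- if (params$target_mode == "events_only") events_vol
            else pmax(array(struct, c(dims, 3L)), events_vol)
  input <- struct
  if (params$noise_sigma > 0)
    input <- input + stats::rnorm(length(input), 0, params$noise_sigma)
  input[input < 0] <- 0
  input_vol <- zstack(array(input, c(dims, 3L)), "raw")
  events <- if (length(records)) do.call(rbind, records) else
    data.frame(event_type = character(), z = numeric(), y = numeric(),
               x = numeric(), n_voxels = integer(), peak_value = numeric())
  structure(list(input_volume = input_vol,
                 target_volume = zstack(target, "unit"),
                 mask_volume = mask, events = events,
                 params = params),
            class = "simulated_sample")
}

#' Simulate a dataset on disk
#'
#' Writes TIFF triplets (input, target, mask) plus a per-sample planted
#' events CSV and a manifest.  A `clean_fraction` of the samples is
#' generated under low-noise, bridge-free parameters and tagged
#' `clean_*`; every sample (clean or not) belongs to the `complete_*`
#' split, so the clean entries are a subset of the complete entries.
#' Roughly 10% (at least one) of each split is tagged as validation.
#'
#' @param n_samples number of samples (>= 0).
#' @param params a [simulation_params()]; per-sample seeds are derived
#'   from `seed`.
#' @param clean_fraction fraction of samples generated clean.
#' @param out_dir output directory (created if needed).
#' @param seed base seed.
#' @return the `dataset_manifest` (also written as `manifest.csv`).
#' @export
simulate_dataset <- function(n_samples, params = simulation_params(),
                             clean_fraction = 0.25, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  n_clean <- round(n_samples * clean_fraction)
  clean_idx <- seq_len(n_clean)
  clean_params <- params
  clean_params$noise_sigma <- min(params$noise_sigma, 0.01)
  clean_params$bridge_probability <- 0
  val_pick <- function(n) {
    if (n == 0) return(integer(0))
    n_val <- max(1L, round(0.1 * n))
    seq(n - n_val + 1L, n)
  }
  complete_val <- val_pick(n_samples)
  clean_val <- val_pick(n_clean)
  # a clean validation sample must never be trained on in any phase, so it
  # is tagged as complete validation too
  complete_val <- sort(union(complete_val, clean_idx[clean_val]))
  for (i in seq_len(n_samples)) {
    p <- if (i %in% clean_idx) clean_params else params
    p$seed <- (seed + i) %% .Machine$integer.max
    smp <- simulate_sample(p)
    stem <- sprintf("sample_%04d", i)
    paths <- file.path(out_dir, paste0(stem, c("_input.tif", "_target.tif",
                                               "_mask.tif", "_events.csv")))
    write_zstack(smp$input_volume, paths[1])
    write_zstack(smp$target_volume, paths[2])
    write_zstack(zstack(smp$mask_volume, "raw"), paths[3])
    utils::write.csv(smp$events, paths[4], row.names = FALSE)
    tag_c <- if (i %in% complete_val) "complete_val" else "complete_train"
    entries[[length(entries) + 1L]] <- data.frame(
      input_path = paths[1], target_path = paths[2], mask_path = paths[3],
      split_tag = tag_c)
    if (i %in% clean_idx) {
      tag_cl <- if (match(i, clean_idx) %in% clean_val) "clean_val"
                else "clean_train"
      entries[[length(entries) + 1L]] <- data.frame(
        input_path = paths[1], target_path = paths[2],
        mask_path = paths[3], split_tag = tag_cl)
    }
  }
  df <- if (length(entries)) do.call(rbind, entries) else
    data.frame(input_path = character(), target_path = character(),
               mask_path = character(), split_tag = character())
  manifest <- dataset_manifest(df, check_files = n_samples > 0)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
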