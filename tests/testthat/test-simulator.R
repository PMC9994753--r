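test_that("simulation is deterministic given the seed", {
  p <- simulation_params(dims = c(8L, 32L, 32L), n_structures = 3L,
                         seed = 99L)
  a <- simulate_sample(p)
  b <- simulate_sample(p)
  expect_identical(a$input_volume$data, b$input_volume$data)
  expect_identical(a$target_volume$data, b$target_volume$data)
  expect_identical(a$mask_volume, b$mask_volume)
  expect_identical(a$events, b$events)
  c_ <- simulate_sample(simulation_params(dims = c(8L, 32L, 32L),
                                          n_structures = 3L, seed = 100L))
  expect_false(identical(a$input_volume$data, c_$input_volume$data))
})

test_that("event_rate 0 yields an empty, background-only target", {
  p <- simulation_params(dims = c(8L, 32L, 32L), event_rate = 0, seed = 5L)
  s <- simulate_sample(p)
  expect_equal(nrow(s$events), 0)
  expect_true(all(s$mask_volume == 0))
  expect_true(all(s$target_volume$data == 0))
  expect_gt(max(s$input_volume$data), 0)  # structures still present
})

test_that("dims below the minimum are rejected", {
  expect_error(simulation_params(dims = c(2L, 32L, 32L)), "too small")
})

test_that("planted events round-trip through extraction (many seeds)", {
  cfg <- matching_config(channel_threshold = 0.5, min_component_voxels = 1)
  for (seed in 1:25) {
    p <- simulation_params(dims = c(8L, 64L, 64L), n_structures = 4L,
                           seed = seed)
    s <- simulate_sample(p)
    got <- extract_events(zstack(s$mask_volume, "raw"),
                          modifyList(cfg, list(channel_threshold = 0.5)))
    expect_equal(nrow(got), nrow(s$events))
    for (et in unique(s$events$event_type)) {
      expect_equal(sum(got$event_type == et),
                   sum(s$events$event_type == et))
    }
    m <- match_events(got, s$events, matching_config(match_radius_vox = 1))
    expect_equal(nrow(m), nrow(s$events))  # centroids within 1 voxel
    # every centroid lies inside a nonzero voxel of its channel
    for (i in seq_len(nrow(s$events))) {
      ch <- matching_config()$channel_map[[s$events$event_type[i]]]
      vox <- round(c(s$events$z[i], s$events$y[i], s$events$x[i])) + 1
      expect_gt(s$mask_volume[vox[1], vox[2], vox[3], ch], 0)
    }
  }
})

test_that("low-intensity bridges join structures in close proximity", {
  # two straight parallel tubes 5 voxels apart (within bridging range)
  t1 <- cbind(4, 14, 5:26)
  t2 <- cbind(4, 19, 5:26)
  p <- simulation_params(dims = c(8L, 32L, 32L), bridge_probability = 1,
                         event_rate = 0, noise_sigma = 0, seed = 1L,
                         tube_radius_vox = 0.8, structures = list(t1, t2))
  s <- simulate_sample(p)
  peak <- max(s$input_volume$data)
  # the bridge raises the midline (y ~ 16.5) strictly between the
  # tube-overlap background and the tube peak
  mid_max <- max(s$input_volume$data[5, 17:18, , 1])
  expect_lt(mid_max, peak)
  p0 <- modifyList(p, list(bridge_probability = 0))
  class(p0) <- "simulation_params"
  s0 <- simulate_sample(p0)
  mid_without <- max(s0$input_volume$data[5, 17:18, , 1])
  expect_gt(mid_max, mid_without)
})

test_that("structures contrast against background at default noise", {
  p <- simulation_params(dims = c(8L, 64L, 64L), n_structures = 4L,
                         event_rate = 0, seed = 11L)
  s <- simulate_sample(p)
  p_clean <- modifyList(p, list(noise_sigma = 0))
  class(p_clean) <- "simulation_params"
  sc <- simulate_sample(p_clean)
  on_structure <- sc$input_volume$data > 0.3
  expect_gt(mean(s$input_volume$data[on_structure]),
            mean(s$input_volume$data[!on_structure]))
})

test_that("events_on_structure mode superimposes kernels on structures", {
  p <- simulation_params(dims = c(8L, 48L, 48L), n_structures = 3L,
                         event_rate = 2, seed = 21L,
                         target_mode = "events_on_structure")
  s <- simulate_sample(p)
  skip_if(nrow(s$events) == 0)
  # the target contains the structures (all channels) plus the kernels
  expect_gt(sum(s$target_volume$data > 0), sum(s$mask_volume > 0))
  # mask still binarises the kernels only
  p2 <- modifyList(p, list(target_mode = "events_only"))
  class(p2) <- "simulation_params"
  s2 <- simulate_sample(p2)
  expect_identical(s$mask_volume, s2$mask_volume)
})

test_that("simulate_dataset writes a coherent split structure", {
  man <- tiny_dataset()
  tags <- table(man$split_tag)
  expect_equal(sum(tags[c("complete_train", "complete_val")]), 8)
  expect_equal(sum(tags[c("clean_train", "clean_val")]), 4)
  expect_gte(tags[["complete_val"]], 1)
  expect_gte(tags[["clean_val"]], 1)
  # same seed reproduces identical files
  dir2 <- file.path(tempdir(), "mitovox-tiny-ds2")
  params <- simulation_params(dims = c(8L, 16L, 16L), n_structures = 2L,
                              event_rate = 1, seed = 7L)
  man2 <- simulate_dataset(8, params, clean_fraction = 0.5, dir2, seed = 70)
  h1 <- tools::md5sum(sort(man$input_path[man$split_tag == "complete_train"]))
  h2 <- tools::md5sum(sort(man2$input_path[man2$split_tag == "complete_train"]))
  expect_equal(unname(h1), unname(h2))
  # n = 0: empty manifest, no files
  dir3 <- file.path(tempdir(), "mitovox-empty-ds")
  man0 <- simulate_dataset(0, params, 0.5, dir3, seed = 1)
  expect_equal(nrow(man0), 0)
  expect_equal(length(list.files(dir3, pattern = "[.]tif$")), 0)
})
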