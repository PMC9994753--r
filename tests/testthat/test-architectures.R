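test_that("closed-form parameter count matches hand-enumerated blocks", {
  # single 1x1x1 conv, 1 -> 1 channels, bias, no norm: 2 parameters
  b <- conv_block_spec("solo", 1, kernel = c(1, 1, 1), has_norm = FALSE,
                       activation = "none")
  spec <- structure(list(encoder = list(b), in_channels = 1L,
                         width_multiplier = 1),
                    class = "discriminator_spec")
  expect_equal(count_spec_parameters(spec), 2)
  # first encoder block alone: 4^3 * 3 * 64 weights + 64 biases
  e1 <- conv_block_spec("E1", 64, stride = c(1, 2, 2), has_norm = FALSE)
  spec1 <- structure(list(encoder = list(e1), in_channels = 3L,
                          width_multiplier = 1),
                     class = "discriminator_spec")
  expect_equal(count_spec_parameters(spec1), 4^3 * 3 * 64 + 64)
})

test_that("published-scale generator counts are exact", {
  p2p <- generator_spec("pix2pix3d")
  expect_equal(count_spec_parameters(p2p), 129546755)
  # the ledger decomposition: conv weights + biases + norm affines
  rows <- mitovox:::spec_channel_ledger(p2p)
  w <- sum(vapply(rows, function(r)
    prod(r$block$kernel) * r$cin * r$block$n_filters, numeric(1)))
  b <- sum(vapply(rows, function(r) r$block$n_filters, numeric(1)))
  n <- sum(vapply(rows, function(r)
    if (r$block$has_norm) 2 * r$block$n_filters else 0, numeric(1)))
  expect_equal(w, 129536000)
  expect_equal(b, 3971)
  expect_equal(n, 6784)
})

test_that("built networks allocate exactly the counted parameters", {
  for (wm in c(1 / 8, 1 / 4)) {
    for (variant in c("pix2pix3d", "vox2vox")) {
      spec <- generator_spec(variant, wm)
      net <- if (variant == "pix2pix3d") build_pix2pix_generator(spec, 1)
             else build_vox2vox_generator(spec, 1)
      expect_equal(count_trainable_parameters(net),
                   count_spec_parameters(spec))
    }
    dspec <- discriminator_spec(wm)
    expect_equal(count_trainable_parameters(
      build_patch_discriminator(dspec, 1)), count_spec_parameters(dspec))
  }
})

test_that("receptive-field recursion reproduces the published extents", {
  enc <- discriminator_spec()$encoder
  expect_equal(analytic_receptive_field(enc, "x", 128), 94)
  expect_equal(analytic_receptive_field(enc, "y", 128), 94)
  # along z the unclipped recursion exceeds the stack depth and is clipped
  expect_equal(analytic_receptive_field(enc, "z", 8), 8)
  expect_equal(analytic_receptive_field(enc, "z", 1000), 70)
  # single layer: one kernel footprint
  one <- list(conv_block_spec("c", 8, stride = c(2, 2, 2)))
  expect_equal(analytic_receptive_field(one, "x", 100), 4)
  expect_error(analytic_receptive_field(
    list(conv_block_spec("u", 8, upsample = c(2, 2, 2))), "x", 10),
    "strided stacks")
})

test_that("encoder stride ledger reaches the published bottleneck dims", {
  p2p <- generator_spec("pix2pix3d")
  led <- mitovox:::encoder_dims_ledger(
    c(p2p$encoder, p2p$bottleneck), c(8L, 128L, 128L))
  expect_equal(vapply(led, `[`, integer(1), 1),
               c(8L, 8L, 8L, 4L, 2L, 1L, 1L))
  expect_equal(led[[7]], c(1L, 1L, 1L))
  v2v <- generator_spec("vox2vox")
  led2 <- mitovox:::encoder_dims_ledger(v2v$encoder, c(8L, 128L, 128L))
  expect_equal(led2[[4]], c(1L, 8L, 8L))
  dled <- mitovox:::encoder_dims_ledger(discriminator_spec()$encoder,
                                        c(8L, 128L, 128L))
  expect_equal(dled[[5]], c(1L, 8L, 8L))
})

test_that("forward shape contracts hold across width multipliers", {
  x <- array(rnorm(8 * 32 * 32 * 3, 0, 0.3), c(8, 32, 32, 3))
  for (wm in c(1 / 8, 1 / 4)) {
    g <- build_pix2pix_generator(generator_spec("pix2pix3d", wm), seed = 1)
    out <- mitovox:::forward_network(g, x)$out
    expect_equal(dim(out), dim(x))
    expect_true(all(out >= -1 & out <= 1))  # tanh codomain
    v <- build_vox2vox_generator(generator_spec("vox2vox", wm), seed = 2)
    outv <- mitovox:::forward_network(v, x)$out
    expect_equal(dim(outv), dim(x))
    expect_true(all(outv >= -1 & outv <= 1))
    d <- build_patch_discriminator(discriminator_spec(wm), seed = 3)
    xd <- array(rnorm(8 * 32 * 32 * 6, 0, 0.3), c(8, 32, 32, 6))
    outd <- mitovox:::forward_network(d, xd)$out
    expect_equal(dim(outd), c(1, 2, 2, 1))
    expect_true(all(outd >= 0 & outd <= 1))  # sigmoid codomain
  }
})

test_that("discriminator rejects wrong channel counts; generator names the
           indivisible axis", {
  d <- build_patch_discriminator(discriminator_spec(1 / 8), seed = 1)
  x3 <- array(0, c(8, 32, 32, 3))
  expect_error(mitovox:::forward_network(d, x3), "channels")
  g <- build_pix2pix_generator(generator_spec("pix2pix3d", 1 / 8), seed = 1)
  bad <- array(0, c(8, 48, 48, 3))
  expect_error(mitovox:::forward_network(g, bad), "axis")
})

test_that("vox2vox head restores 3 output channels after the 128-filter
           final decoder", {
  spec <- generator_spec("vox2vox")
  expect_equal(spec$decoder[[5]]$n_filters, 128L)
  expect_equal(spec$head$n_filters, 3L)
  expect_equal(spec$head$activation, "tanh")
  expect_false(spec$head$has_norm)
})

test_that("inspect_model reports blocks, parameters and receptive field", {
  info <- inspect_model("discriminator")
  expect_equal(info$receptive_field[["x"]], 94)
  expect_equal(info$receptive_field[["z"]], 8)
  info2 <- inspect_model("pix2pix3d")
  expect_equal(info2$trainable_parameters, 129546755)
  expect_equal(nrow(info2$blocks), 14)  # 6 enc + bottleneck + 7 dec
})
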