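# Engine-level properties: the BLAS-backed convolution against a plain-R
# oracle, backpropagation against finite differences, adjoint identities,
# inference determinism, and the empirical receptive-field probe.

test_that("fused conv3d matches the plain-R oracle", {
  set.seed(31)
  for (case in list(list(ind = c(5, 6, 7, 2), k = c(3, 3, 3),
                         s = c(1, 2, 2), cout = 3),
                    list(ind = c(4, 4, 4, 3), k = c(4, 4, 4),
                         s = c(2, 2, 2), cout = 2),
                    list(ind = c(2, 5, 5, 1), k = c(4, 4, 4),
                         s = c(1, 1, 1), cout = 4))) {
    x <- array(rnorm(prod(case$ind)), case$ind)
    cin <- case$ind[4]
    W5 <- array(rnorm(prod(case$k) * cin * case$cout),
                c(case$k, cin, case$cout))
    bias <- rnorm(case$cout)
    od <- as.integer(ceiling(case$ind[1:3] / case$s))
    pad_tot <- pmax((od - 1L) * case$s + case$k - case$ind[1:3], 0L)
    Wmat <- matrix(W5, prod(case$k) * cin, case$cout)
    got <- mitovox:::cpp_conv3d_forward(
      x, as.integer(case$ind), Wmat, bias, as.integer(case$k),
      as.integer(case$s), as.integer(pad_tot %/% 2L), od)
    expect_equal(array(got, c(od, case$cout)),
                 r_conv3d_oracle(x, W5, bias, case$s), tolerance = 1e-12)
  }
})

test_that("network gradients match finite differences", {
  fwd <- mitovox:::forward_network
  bwd <- mitovox:::backward_network
  set.seed(32)
  nets <- list(
    p2p = build_pix2pix_generator(generator_spec("pix2pix3d", 1 / 16), 41),
    v2v = build_vox2vox_generator(generator_spec("vox2vox", 1 / 16), 42))
  x <- array(rnorm(8 * 16 * 16 * 3, 0, 0.5), c(8, 16, 16, 3))
  for (net in nets) {
    f0 <- fwd(net, x)
    wts <- array(rnorm(length(f0$out)), dim(f0$out))
    loss_of <- function(n) sum(fwd(n, x)$out * wts)
    f <- fwd(net, x, retain = TRUE)
    bb <- bwd(net, f, wts)
    eps <- 1e-6
    for (bi in sample(seq_along(net$blocks), 5)) {
      i <- sample(length(net$blocks[[bi]]$W), 1)
      n2 <- net; n2$blocks[[bi]]$W[i] <- n2$blocks[[bi]]$W[i] + eps
      n3 <- net; n3$blocks[[bi]]$W[i] <- n3$blocks[[bi]]$W[i] - eps
      num <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
      expect_equal(bb$grads[[bi]]$dW[i], num, tolerance = 1e-4)
      if (!is.null(net$blocks[[bi]]$gamma)) {
        j <- sample(length(net$blocks[[bi]]$gamma), 1)
        n4 <- net
        n4$blocks[[bi]]$gamma[j] <- n4$blocks[[bi]]$gamma[j] + eps
        n5 <- net
        n5$blocks[[bi]]$gamma[j] <- n5$blocks[[bi]]$gamma[j] - eps
        num_g <- (loss_of(n4) - loss_of(n5)) / (2 * eps)
        expect_equal(bb$grads[[bi]]$dgamma[j], num_g, tolerance = 1e-4)
      }
    }
    # gradient with respect to the input volume
    for (i in sample(length(x), 3)) {
      x2 <- x; x2[i] <- x2[i] + eps
      x3 <- x; x3[i] <- x3[i] - eps
      num <- (sum(fwd(net, x2)$out * wts) - sum(fwd(net, x3)$out * wts)) /
        (2 * eps)
      expect_equal(bb$dx[i], num, tolerance = 1e-4)
    }
  }
})

test_that("discriminator from-logits gradient matches finite differences", {
  fwd <- mitovox:::forward_network
  bwd <- mitovox:::backward_network
  set.seed(33)
  d <- build_patch_discriminator(discriminator_spec(1 / 16), 43)
  x <- array(rnorm(8 * 32 * 32 * 6, 0, 0.5), c(8, 32, 32, 6))
  f <- fwd(d, x, retain = TRUE)
  # BCE against the "real" label, folded with the sigmoid
  m <- length(f$out)
  p <- as.numeric(f$out)
  dlog <- array((p - 1) / m, dim(f$out))
  bb <- bwd(d, f, dlog, from_logits = TRUE)
  loss_of <- function(net) {
    pr <- pmin(pmax(as.numeric(fwd(net, x)$out), 1e-12), 1 - 1e-12)
    -mean(log(pr))
  }
  eps <- 1e-6
  for (bi in seq_along(d$blocks)) {
    i <- sample(length(d$blocks[[bi]]$W), 1)
    n2 <- d; n2$blocks[[bi]]$W[i] <- n2$blocks[[bi]]$W[i] + eps
    n3 <- d; n3$blocks[[bi]]$W[i] <- n3$blocks[[bi]]$W[i] - eps
    num <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
    expect_equal(bb$grads[[bi]]$dW[i], num, tolerance = 1e-4)
  }
})

test_that("upsampling and its backward are adjoint", {
  set.seed(34)
  x <- array(rnorm(3 * 4 * 5 * 2), c(3, 4, 5, 2))
  sc <- c(2L, 2L, 3L)
  y <- mitovox:::cpp_upsample_nn(x, dim(x), sc)
  expect_equal(dim(y), c(6, 8, 15, 2))
  # every value replicated over its block
  expect_equal(y[2, 3, 4, 1], x[1, 2, 2, 1])
  # adjoint identity: <U x, w> == <x, U^T w>
  w <- array(rnorm(length(y)), dim(y))
  wt <- mitovox:::cpp_upsample_nn_backward(w, dim(y), sc)
  expect_equal(sum(y * w), sum(x * wt), tolerance = 1e-10)
})

test_that("inference is deterministic; train-mode dropout is not a no-op", {
  fwd <- mitovox:::forward_network
  g <- build_pix2pix_generator(generator_spec("pix2pix3d", 1 / 16), 44)
  x <- array(rnorm(8 * 16 * 16 * 3), c(8, 16, 16, 3))
  a <- fwd(g, x, mode = "inference")$out
  b <- fwd(g, x, mode = "inference")$out
  expect_identical(a, b)
  set.seed(1)
  tr1 <- fwd(g, x, mode = "train")$out
  set.seed(2)
  tr2 <- fwd(g, x, mode = "train")$out
  expect_false(identical(tr1, tr2))
  set.seed(3)
  tr3 <- fwd(g, x, mode = "train")$out
  set.seed(3)
  tr4 <- fwd(g, x, mode = "train")$out
  expect_identical(tr3, tr4)
})

test_that("analytic receptive field agrees with a perturbation probe", {
  fwd <- mitovox:::forward_network
  # strided stack without normalisation so no probe signal is rescaled
  # away; leaky ReLU keeps every unit responsive
  blocks <- list(
    conv_block_spec("E1", 4, stride = c(1, 2, 2), has_norm = FALSE,
                    kernel = c(3, 4, 4)),
    conv_block_spec("E2", 1, stride = c(2, 2, 2), has_norm = FALSE,
                    kernel = c(3, 4, 4)))
  spec <- structure(list(encoder = blocks, in_channels = 1L,
                         width_multiplier = 1),
                    class = "discriminator_spec")
  net <- mitovox:::build_network(spec, "discriminator", "probe", seed = 45)
  dims <- c(16L, 32L, 32L)
  x <- array(rnorm(prod(dims)), c(dims, 1L))
  f <- fwd(net, x, retain = TRUE)
  od <- dim(f$out)
  # central output unit; gradient support = receptive field
  centre <- ceiling(od[1:3] / 2)
  dout <- array(0, od)
  dout[centre[1], centre[2], centre[3], 1] <- 1
  dx <- mitovox:::backward_network(net, f, dout)$dx
  support <- which(abs(dx) > 0, arr.ind = TRUE)
  for (ax in 1:3) {
    axis_name <- c("z", "y", "x")[ax]
    extent <- max(support[, ax]) - min(support[, ax]) + 1
    expect_equal(extent,
                 analytic_receptive_field(blocks, axis_name, dims[ax]))
  }
})
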