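# Declarative network specifications.  Strides, upsampling scales and
# kernels are stored internally in axis order (z, y, x) to match the
# package's volume layout; all published blocks are laterally symmetric,
# so the (z, x, y) order used in the architecture tables reads the same.

#' Specification of one convolutional block
#'
#' A block is: optional nearest-neighbour upsampling, a 3D convolution
#' (always with bias), optional instance normalisation with trainable
#' per-channel scale and offset, an activation, and optional dropout.
#'
#' @param name label used in block tables.
#' @param n_filters output channels of the convolution.
#' @param stride length-3 integer `(z, y, x)` stride; "same" padding.
#' @param upsample `NULL`, or length-3 integer nearest-neighbour scale
#'   applied before the convolution (decoder blocks; stride must be 1).
#' @param kernel length-3 integer kernel size, default `c(4, 4, 4)`.
#' @param has_norm apply instance normalisation after the convolution.
#' @param activation one of `"leaky_relu"`, `"relu"`, `"tanh"`,
#'   `"sigmoid"`, `"none"`.
#' @param slope negative slope of leaky ReLU.
#' @param dropout_rate dropout rate in `[0, 1]` applied after activation.
#' @param residual add the block input to its output (ResNet-style short
#'   skip; requires equal input/output channels, stride 1, no upsampling).
#' @return a `conv_block_spec`.
#' @export
conv_block_spec <- function(name, n_filters, stride = c(1L, 1L, 1L),
                            upsample = NULL, kernel = c(4L, 4L, 4L),
                            has_norm = TRUE,
                            activation = c("leaky_relu", "relu", "tanh",
                                           "sigmoid", "none"),
                            slope = 0.2, dropout_rate = 0,
                            residual = FALSE) {
  activation <- match.arg(activation)
  if (n_filters < 1) stop("n_filters must be >= 1")
  if (any(stride < 1) || (!is.null(upsample) && any(upsample < 1)))
    stop("strides and upsampling scales must be >= 1")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must be in [0, 1]")
  if (residual && (!is.null(upsample) || any(stride != 1)))
    stop("residual blocks require stride 1 and no upsampling")
  structure(list(name = name, n_filters = as.integer(n_filters),
                 stride = as.integer(stride), upsample = upsample,
                 kernel = as.integer(kernel), has_norm = has_norm,
                 activation = activation, slope = slope,
                 dropout_rate = dropout_rate, residual = residual),
            class = "conv_block_spec")
}

scale_filters <- function(f, wm) max(1L, as.integer(round(f * wm)))

#' Generator architecture specification
#'
#' `"pix2pix3d"` is a 3D U-Net-style generator: six strided encoder blocks
#' (leaky ReLU 0.2; no normalisation in E1), a single-conv bottleneck
#' (ReLU, no normalisation) that reduces an 8x128x128 input to a 1x1x1
#' latent, and seven decoder blocks (upsample + stride-1 conv, ReLU,
#' normalisation except in the last, 50% dropout in D1-D4, tanh output).
#' Each decoder output is concatenated along the channel axis with its
#' equal-size encoder partner (D1 with E6 ... D6 with E1).
#'
#' `"vox2vox"` is shallower: four encoder blocks, then four 512-filter
#' stride-1 bottleneck blocks with additive ResNet-style short skips
#' (leaky ReLU 0.2, 20% dropout), five decoder blocks (D1 with E4 ... D4
#' with E1), and a final 3-filter tanh projection head appended because
#' the last listed decoder block carries 128 filters while the target has
#' 3 channels.  The bottleneck operates on a 1x8x8 latent volume rather
#' than a single latent vector.
#'
#' @param variant `"pix2pix3d"` or `"vox2vox"`.
#' @param width_multiplier scales every filter count (1 = published
#'   scale); output channels are never scaled.
#' @param in_channels,out_channels volume channels (3 and 3).
#' @return a `generator_spec` with fields `encoder`, `bottleneck`,
#'   `decoder`, `head`, and `skip_after` (for decoder block i, the index
#'   of the encoder block whose output is concatenated after it, or NA).
#' @export
generator_spec <- function(variant = c("pix2pix3d", "vox2vox"),
                           width_multiplier = 1,
                           in_channels = 3L, out_channels = 3L) {
  variant <- match.arg(variant)
  wm <- width_multiplier
  if (wm <= 0) stop("width_multiplier must be positive")
  if (variant == "pix2pix3d") {
    enc_f <- vapply(c(64, 128, 256, 256, 512, 512), scale_filters, 1L, wm)
    enc_s <- list(c(1, 2, 2), c(1, 2, 2), c(1, 2, 2),
                  c(2, 2, 2), c(2, 2, 2), c(2, 2, 2))
    encoder <- lapply(seq_along(enc_f), function(i)
      conv_block_spec(paste0("E", i), enc_f[i], stride = enc_s[[i]],
                      has_norm = i > 1, activation = "leaky_relu"))
    bottleneck <- list(conv_block_spec("bottleneck", scale_filters(512, wm),
                                       stride = c(1, 2, 2), has_norm = FALSE,
                                       activation = "relu"))
    dec_f <- c(vapply(c(512, 512, 256, 256, 128, 64), scale_filters, 1L, wm),
               as.integer(out_channels))
    dec_u <- list(c(1, 2, 2), c(2, 2, 2), c(2, 2, 2), c(2, 2, 2),
                  c(1, 2, 2), c(1, 2, 2), c(1, 2, 2))
    decoder <- lapply(seq_along(dec_f), function(i)
      conv_block_spec(paste0("D", i), dec_f[i], upsample = dec_u[[i]],
                      has_norm = i < 7,
                      activation = if (i < 7) "relu" else "tanh",
                      dropout_rate = if (i <= 4) 0.5 else 0))
    head <- NULL
    skip_after <- c(6L, 5L, 4L, 3L, 2L, 1L, NA)
  } else {
    enc_f <- vapply(c(64, 128, 256, 512), scale_filters, 1L, wm)
    enc_s <- list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2), c(1, 2, 2))
    encoder <- lapply(seq_along(enc_f), function(i)
      conv_block_spec(paste0("E", i), enc_f[i], stride = enc_s[[i]],
                      has_norm = i > 1, activation = "leaky_relu"))
    bottleneck <- lapply(1:4, function(i)
      conv_block_spec(paste0("B", i), scale_filters(512, wm),
                      stride = c(1, 1, 1), has_norm = TRUE,
                      activation = "leaky_relu", dropout_rate = 0.2,
                      residual = TRUE))
    dec_f <- vapply(c(512, 512, 256, 256, 128), scale_filters, 1L, wm)
    dec_u <- list(c(1, 1, 1), c(1, 2, 2), c(2, 2, 2), c(2, 2, 2), c(2, 2, 2))
    decoder <- lapply(seq_along(dec_f), function(i)
      conv_block_spec(paste0("D", i), dec_f[i], upsample = dec_u[[i]],
                      has_norm = TRUE, activation = "relu"))
    head <- conv_block_spec("out", as.integer(out_channels),
                            has_norm = FALSE, activation = "tanh")
    skip_after <- c(4L, 3L, 2L, 1L, NA)
  }
  structure(list(variant = variant, width_multiplier = wm,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 encoder = encoder, bottleneck = bottleneck,
                 decoder = decoder, head = head, skip_after = skip_after),
            class = "generator_spec")
}

#' PatchGAN discriminator specification
#'
#' Five strided encoder blocks (kernel 4; no normalisation in E1; leaky
#' ReLU 0.2; sigmoid on the single-filter final block) that reduce a
#' 6-channel 8x128x128 input — the input frame concatenated with the
#' target or generated volume — to a 1x8x8x1 patch of probabilities.
#' Each patch voxel judges an 8x94x94 receptive-field cube of the input.
#'
#' @param width_multiplier scales filter counts of E1-E4; the final
#'   single-filter block is never scaled.
#' @param in_channels 6 = 3 (input frame) + 3 (target/generated).
#' @return a `discriminator_spec` with field `encoder`.
#' @export
discriminator_spec <- function(width_multiplier = 1, in_channels = 6L) {
  wm <- width_multiplier
  f <- c(vapply(c(64, 128, 256, 512), scale_filters, 1L, wm), 1L)
  s <- list(c(2, 2, 2), c(2, 2, 2), c(2, 2, 2), c(1, 2, 2), c(1, 1, 1))
  blocks <- lapply(seq_along(f), function(i)
    conv_block_spec(paste0("E", i), f[i], stride = s[[i]],
                    has_norm = i %in% 2:4,
                    activation = if (i == 5) "sigmoid" else "leaky_relu"))
  structure(list(encoder = blocks, width_multiplier = wm,
                 in_channels = as.integer(in_channels)),
            class = "discriminator_spec")
}

# Channel ledger: input channels of every convolution in build order,
# accounting for the channel concatenations after decoder blocks.
spec_channel_ledger <- function(spec) {
  if (inherits(spec, "discriminator_spec")) {
    cin <- spec$in_channels
    rows <- list()
    for (b in spec$encoder) {
      rows[[length(rows) + 1L]] <- list(block = b, cin = cin)
      cin <- b$n_filters
    }
    return(rows)
  }
  rows <- list()
  cin <- spec$in_channels
  enc_out <- integer(length(spec$encoder))
  for (i in seq_along(spec$encoder)) {
    rows[[length(rows) + 1L]] <- list(block = spec$encoder[[i]], cin = cin)
    cin <- spec$encoder[[i]]$n_filters
    enc_out[i] <- cin
  }
  for (b in spec$bottleneck) {
    rows[[length(rows) + 1L]] <- list(block = b, cin = cin)
    cin <- b$n_filters
  }
  for (i in seq_along(spec$decoder)) {
    rows[[length(rows) + 1L]] <- list(block = spec$decoder[[i]], cin = cin)
    cin <- spec$decoder[[i]]$n_filters
    if (!is.na(spec$skip_after[i])) cin <- cin + enc_out[spec$skip_after[i]]
  }
  if (!is.null(spec$head))
    rows[[length(rows) + 1L]] <- list(block = spec$head, cin = cin)
  rows
}

#' Closed-form trainable-parameter count of a specification
#'
#' Sums, over every convolution in the spec, `prod(kernel) * cin * cout`
#' weights plus `cout` biases plus `2 * cout` instance-norm scale/offset
#' parameters where normalisation is present.  At published scale the 3D
#' Pix2Pix generator totals 129,546,755 (129,536,000 weights + 3,971
#' biases + 6,784 normalisation parameters).
#'
#' @param spec a `generator_spec` or `discriminator_spec`.
#' @return integer-valued numeric count.
#' @export
count_spec_parameters <- function(spec) {
  total <- 0
  for (row in spec_channel_ledger(spec)) {
    b <- row$block
    total <- total + prod(b$kernel) * row$cin * b$n_filters + b$n_filters
    if (b$has_norm) total <- total + 2 * b$n_filters
  }
  total
}

#' Analytic receptive field of a strided convolution stack
#'
#' Backward recursion from a single output unit: starting at `RF = 1`,
#' apply `RF <- stride * RF + (kernel - stride)` over the blocks in
#' reverse.  The result is clipped to the input extent, since a footprint
#' cannot exceed the volume.
#'
#' @param blocks ordered list of `conv_block_spec` (no upsampling blocks).
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param input_extent input size along the axis, in voxels.
#' @return receptive-field extent in input voxels.
#' @export
analytic_receptive_field <- function(blocks, axis = c("x", "y", "z"),
                                     input_extent) {
  axis <- match.arg(axis)
  ai <- c(z = 1L, y = 2L, x = 3L)[[axis]]
  rf <- 1
  for (b in rev(blocks)) {
    if (!is.null(b$upsample))
      stop("receptive field recursion is defined for strided stacks only")
    rf <- b$stride[ai] * rf + (b$kernel[ai] - b$stride[ai])
  }
  min(input_extent, rf)
}

# Output extent of a "same"-padded strided convolution.
conv_out_extent <- function(extent, stride) as.integer(ceiling(extent / stride))

# Spatial dims ledger of an encoder stack for a given input (z, y, x).
encoder_dims_ledger <- function(blocks, dims) {
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    dims <- conv_out_extent(dims, blocks[[i]]$stride)
    out[[i]] <- dims
  }
  out
}
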