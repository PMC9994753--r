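# CPU engine for the 3D conditional GANs.  Convolutions are im2col +
# BLAS matrix multiplies (src/engine.cpp); every layer has a hand-derived
# backward pass.  Activations flow as R arrays of dim (z, y, x, c).
#
# Spatial geometry is resolved at forward time: encoder extents follow
# ceil(extent / stride) ("same" padding), and each decoder's upsampling
# scale is derived as the ratio between its skip partner's extent and the
# incoming extent.  At the published 8x128x128 geometry the derived
# scales equal the architecture tables exactly; smaller inputs whose
# ledger stays integral (e.g. 8x64x64) reuse the same weights.

INSTANCE_NORM_EPS <- 1e-5

init_block_params <- function(spec, cin) {
  k3 <- prod(spec$kernel)
  cout <- spec$n_filters
  W <- matrix(stats::rnorm(k3 * cin * cout, 0, 0.02), k3 * cin, cout)
  b <- numeric(cout)
  if (spec$has_norm) {
    gamma <- stats::rnorm(cout, 1, 0.02)
    beta <- numeric(cout)
  } else {
    gamma <- NULL
    beta <- NULL
  }
  list(spec = spec, cin = as.integer(cin), cout = as.integer(cout),
       W = W, b = b, gamma = gamma, beta = beta)
}

build_network <- function(spec, kind, variant, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  ledger <- spec_channel_ledger(spec)
  blocks <- lapply(ledger, function(row) init_block_params(row$block, row$cin))
  roles <- if (kind == "generator") {
    n_enc <- length(spec$encoder)
    n_bot <- length(spec$bottleneck)
    n_dec <- length(spec$decoder)
    list(enc = seq_len(n_enc), bot = n_enc + seq_len(n_bot),
         dec = n_enc + n_bot + seq_len(n_dec),
         head = if (is.null(spec$head)) integer(0)
                else n_enc + n_bot + n_dec + 1L)
  } else {
    list(enc = seq_along(spec$encoder), bot = integer(0),
         dec = integer(0), head = integer(0))
  }
  structure(list(kind = kind, variant = variant, spec = spec,
                 blocks = blocks, roles = roles, mode = "inference"),
            class = "mito_network")
}

#' Build the 3D Pix2Pix generator
#'
#' @param spec a `generator_spec` with variant `"pix2pix3d"` (default:
#'   published scale).
#' @param seed optional integer; weights are drawn N(0, 0.02) (norm scales
#'   N(1, 0.02), offsets and biases zero) under this seed.
#' @return a `mito_network` handle (mode `"inference"`).
#' @export
build_pix2pix_generator <- function(spec = generator_spec("pix2pix3d"),
                                    seed = NULL) {
  if (spec$variant != "pix2pix3d") stop("spec variant must be pix2pix3d")
  build_network(spec, "generator", "pix2pix3d", seed)
}

#' Build the Vox2Vox generator
#'
#' @param spec a `generator_spec` with variant `"vox2vox"`.
#' @param seed optional integer seed for weight initialisation.
#' @return a `mito_network` handle.
#' @export
build_vox2vox_generator <- function(spec = generator_spec("vox2vox"),
                                    seed = NULL) {
  if (spec$variant != "vox2vox") stop("spec variant must be vox2vox")
  build_network(spec, "generator", "vox2vox", seed)
}

#' Build the 3D PatchGAN discriminator
#'
#' @param spec a `discriminator_spec`.
#' @param seed optional integer seed for weight initialisation.
#' @return a `mito_network` handle.
#' @export
build_patch_discriminator <- function(spec = discriminator_spec(),
                                      seed = NULL) {
  if (!inherits(spec, "discriminator_spec"))
    stop("spec must be a discriminator_spec")
  build_network(spec, "discriminator", "patchgan", seed)
}

#' Count trainable parameters of a built network
#'
#' Sums the lengths of all weight, bias and normalisation scale/offset
#' arrays actually allocated in the network; equals
#' [count_spec_parameters()] of the originating spec.
#'
#' @param network a `mito_network`.
#' @return numeric count.
#' @export
count_trainable_parameters <- function(network) {
  stopifnot(inherits(network, "mito_network"))
  sum(vapply(network$blocks, function(b)
    length(b$W) + length(b$b) + length(b$gamma) + length(b$beta), numeric(1)))
}

#' Set train/inference mode
#'
#' Dropout is active only in `"train"` mode; inference is deterministic.
#'
#' @param network a `mito_network`.
#' @param mode `"train"` or `"inference"`.
#' @export
set_mode <- function(network, mode = c("inference", "train")) {
  network$mode <- match.arg(mode)
  network
}

#' @export
print.mito_network <- function(x, ...) {
  cat(sprintf("<mito_network> %s (%s), %d blocks, %s trainable parameters\n",
              x$kind, x$variant, length(x$blocks),
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

# --- forward -------------------------------------------------------------

block_forward <- function(bb, x, mode, retain, upscale = NULL) {
  cache <- list(upscale = NULL)
  if (!is.null(upscale) && any(upscale > 1)) {
    cache$upscale <- as.integer(upscale)
    x <- cpp_upsample_nn(x, dim(x), cache$upscale)
  }
  ind <- dim(x)
  sp <- bb$spec
  od <- as.integer(ceiling(ind[1:3] / sp$stride))
  pad_tot <- pmax((od - 1L) * sp$stride + sp$kernel - ind[1:3], 0L)
  pad_beg <- as.integer(pad_tot %/% 2L)
  M <- cpp_conv3d_forward(x, as.integer(ind), bb$W, bb$b, sp$kernel,
                          sp$stride, pad_beg, od)
  n <- prod(od)
  dim(M) <- c(n, bb$cout)
  if (retain) {
    cache$x_in <- x
    cache$in_dim <- as.integer(ind)
    cache$pad_beg <- pad_beg
    cache$out_sp <- od
  }
  if (sp$has_norm) {
    mu <- .colMeans(M, n, bb$cout)
    xc <- M - rep(mu, each = n)
    sd_ <- sqrt(.colMeans(xc * xc, n, bb$cout) + INSTANCE_NORM_EPS)
    xhat <- xc / rep(sd_, each = n)
    M <- xhat * rep(bb$gamma, each = n) + rep(bb$beta, each = n)
    if (retain) {
      cache$xhat <- xhat
      cache$sd <- sd_
    }
  }
  if (retain) cache$preact <- M
  M <- switch(sp$activation,
              leaky_relu = { neg <- M < 0; M[neg] <- sp$slope * M[neg]; M },
              relu = { M[M < 0] <- 0; M },
              tanh = tanh(M),
              sigmoid = stats::plogis(M),
              none = M)
  if (retain && sp$activation %in% c("tanh", "sigmoid")) cache$act_out <- M
  if (sp$dropout_rate > 0 && mode == "train") {
    keep <- (stats::runif(length(M)) >= sp$dropout_rate) /
      (1 - sp$dropout_rate)
    M <- M * keep
    if (retain) cache$drop <- keep
  }
  out <- M
  dim(out) <- c(od, bb$cout)
  list(out = out, cache = cache)
}

block_backward <- function(bb, cache, dy, from_logits = FALSE) {
  sp <- bb$spec
  n <- prod(dim(dy)[1:3])
  dM <- matrix(dy, n, bb$cout)
  if (!is.null(cache$drop)) dM <- dM * cache$drop
  if (!from_logits) {
    dM <- switch(sp$activation,
                 leaky_relu = { neg <- cache$preact < 0
                                dM[neg] <- sp$slope * dM[neg]; dM },
                 relu = { dM[cache$preact < 0] <- 0; dM },
                 tanh = dM * (1 - cache$act_out^2),
                 sigmoid = dM * cache$act_out * (1 - cache$act_out),
                 none = dM)
  }
  dgamma <- NULL
  dbeta <- NULL
  if (sp$has_norm) {
    xhat <- cache$xhat
    dgamma <- colSums(dM * xhat)
    dbeta <- colSums(dM)
    dxhat <- dM * rep(bb$gamma, each = n)
    m1 <- .colMeans(dxhat, n, bb$cout)
    m2 <- .colMeans(dxhat * xhat, n, bb$cout)
    dM <- (dxhat - rep(m1, each = n) - xhat * rep(m2, each = n)) /
      rep(cache$sd, each = n)
  }
  conv_bw <- cpp_conv3d_backward(cache$x_in, cache$in_dim, bb$W, dM,
                                 sp$kernel, sp$stride, cache$pad_beg,
                                 cache$out_sp)
  dx <- conv_bw$dx
  if (!is.null(cache$upscale)) {
    dx <- cpp_upsample_nn_backward(dx, dim(dx), cache$upscale)
  }
  list(dx = dx, dW = conv_bw$dW, db = conv_bw$db, dgamma = dgamma,
       dbeta = dbeta)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

derive_upscale <- function(prev, target) {
  ratio <- target / prev
  if (any(ratio != as.integer(ratio)))
    stop("input dims are indivisible for this architecture along axis ",
         paste(c("z", "y", "x")[ratio != as.integer(ratio)], collapse = ","),
         " (cannot upsample ", paste(prev, collapse = "x"), " to ",
         paste(target, collapse = "x"), ")")
  as.integer(ratio)
}

# Forward pass.  x: array (z, y, x, c).  With retain=TRUE all per-block
# caches needed by backward_network are kept.
forward_network <- function(net, x, mode = net$mode, retain = FALSE) {
  if (dim(x)[4] != net$blocks[[1]]$cin)
    stop("input has ", dim(x)[4], " channels; network expects ",
         net$blocks[[1]]$cin)
  caches <- vector("list", length(net$blocks))
  if (net$kind == "discriminator") {
    h <- x
    for (i in seq_along(net$blocks)) {
      res <- block_forward(net$blocks[[i]], h, mode, retain)
      caches[[i]] <- res$cache
      h <- res$out
    }
    logits <- caches[[length(net$blocks)]]$preact
    return(list(out = h, logits = logits, caches = caches))
  }
  roles <- net$roles
  spec <- net$spec
  in_sp <- dim(x)[1:3]
  enc_out <- vector("list", length(roles$enc))
  h <- x
  for (j in seq_along(roles$enc)) {
    i <- roles$enc[j]
    res <- block_forward(net$blocks[[i]], h, mode, retain)
    caches[[i]] <- res$cache
    h <- res$out
    enc_out[[j]] <- h
  }
  for (i in roles$bot) {
    res <- block_forward(net$blocks[[i]], h, mode, retain)
    caches[[i]] <- res$cache
    h <- if (net$blocks[[i]]$spec$residual) h + res$out else res$out
  }
  for (j in seq_along(roles$dec)) {
    i <- roles$dec[j]
    partner <- spec$skip_after[j]
    target <- if (!is.na(partner)) dim(enc_out[[partner]])[1:3] else in_sp
    up <- derive_upscale(dim(h)[1:3], target)
    res <- block_forward(net$blocks[[i]], h, mode, retain, upscale = up)
    caches[[i]] <- res$cache
    h <- if (!is.na(partner)) concat_channels(res$out, enc_out[[partner]])
         else res$out
  }
  for (i in roles$head) {
    res <- block_forward(net$blocks[[i]], h, mode, retain)
    caches[[i]] <- res$cache
    h <- res$out
  }
  list(out = h, caches = caches, enc_out = if (retain) enc_out else NULL)
}

# Backward pass: returns per-block parameter gradients and the gradient
# with respect to the network input.  `dout` is the gradient w.r.t. the
# network output; with from_logits=TRUE (discriminator only) it is taken
# w.r.t. the final pre-activation instead, which folds the sigmoid into
# the loss for numerical stability.
backward_network <- function(net, fw, dout, from_logits = FALSE) {
  grads <- vector("list", length(net$blocks))
  if (net$kind == "discriminator") {
    dh <- dout
    for (i in rev(seq_along(net$blocks))) {
      res <- block_backward(net$blocks[[i]], fw$caches[[i]], dh,
                            from_logits = from_logits &&
                              i == length(net$blocks))
      grads[[i]] <- res[c("dW", "db", "dgamma", "dbeta")]
      dh <- res$dx
    }
    return(list(grads = grads, dx = dh))
  }
  roles <- net$roles
  spec <- net$spec
  d_enc <- vector("list", length(roles$enc))
  dh <- dout
  for (i in rev(roles$head)) {
    res <- block_backward(net$blocks[[i]], fw$caches[[i]], dh)
    grads[[i]] <- res[c("dW", "db", "dgamma", "dbeta")]
    dh <- res$dx
  }
  for (j in rev(seq_along(roles$dec))) {
    i <- roles$dec[j]
    partner <- spec$skip_after[j]
    if (!is.na(partner)) {
      cout <- net$blocks[[i]]$cout
      d4 <- dim(dh)[4]
      d_block <- array(dh[, , , seq_len(cout)], c(dim(dh)[1:3], cout))
      d_skip <- array(dh[, , , (cout + 1L):d4], c(dim(dh)[1:3], d4 - cout))
      d_enc[[partner]] <- if (is.null(d_enc[[partner]])) d_skip
                          else d_enc[[partner]] + d_skip
      dh <- d_block
    }
    res <- block_backward(net$blocks[[i]], fw$caches[[i]], dh)
    grads[[i]] <- res[c("dW", "db", "dgamma", "dbeta")]
    dh <- res$dx
  }
  for (i in rev(roles$bot)) {
    res <- block_backward(net$blocks[[i]], fw$caches[[i]], dh)
    grads[[i]] <- res[c("dW", "db", "dgamma", "dbeta")]
    dh <- if (net$blocks[[i]]$spec$residual) dh + res$dx else res$dx
  }
  for (j in rev(seq_along(roles$enc))) {
    i <- roles$enc[j]
    if (!is.null(d_enc[[j]])) dh <- dh + d_enc[[j]]
    res <- block_backward(net$blocks[[i]], fw$caches[[i]], dh)
    grads[[i]] <- res[c("dW", "db", "dgamma", "dbeta")]
    dh <- res$dx
  }
  list(grads = grads, dx = dh)
}

#' Predict event locations from a single z-stack
#'
#' Normalises the input to `[-1, 1]` if needed, triplicates a
#' single-channel volume, and runs the generator in inference mode
#' (dropout off; deterministic).
#'
#' @param generator a generator `mito_network`.
#' @param input_volume a [zstack].
#' @return a [zstack] with 3 channels, values in `[-1, 1]`.
#' @export
predict_volume <- function(generator, input_volume) {
  stopifnot(inherits(generator, "mito_network"),
            generator$kind == "generator")
  v <- normalize_to_signed_unit(input_volume)
  if (dim(v$data)[4] == 1L) v <- replicate_channels(v)
  fw <- forward_network(generator, v$data, mode = "inference",
                        retain = FALSE)
  zstack(fw$out, "unit_signed", input_volume$voxel_size)
}
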