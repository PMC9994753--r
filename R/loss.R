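# Event-location-penalised mean absolute error (ELP-MAE).
#
# Plain MAE treats the handful of event voxels and the vast dark background
# equally, so a generator minimising it simply paints background.  ELP-MAE
# multiplies the absolute error at voxels inside the binary event mask by
# (penalty + 1) and leaves the rest at weight 1:
#
#   ELP-MAE = mean( |y_true - y_pred| * (penalty * mask + 1) )
#
# The "+ 1" keeps every background voxel contributing to the gradient; with
# a weight of penalty * mask alone, an event-free sample would have zero
# loss and zero gradient everywhere — an untrainable model.  The
# ground-truth volume and the mask travel together in a "stacked" array
# with a leading axis of size 2, mirroring two-argument loss interfaces
# that only accept (y_true, y_pred).

#' Binarise an event volume into a {0, 1} mask
#'
#' Any voxel strictly above `threshold` becomes 1, all others 0.  The
#' default threshold 0 matches event kernels drawn at full intensity on a
#' zero background (raw/unit scale); raise it for noisy masks.
#'
#' @param events_volume a [zstack] or a bare numeric array.
#' @param threshold scalar; voxels `> threshold` are events.
#' @return numeric array of 0/1 with the input's dimensions.
#' @export
binarize_events <- function(events_volume, threshold = 0) {
  data <- if (inherits(events_volume, "zstack")) events_volume$data
          else events_volume
  if (!all(is.finite(data))) stop("events volume contains non-finite values")
  out <- array(0, dim(data))
  out[data > threshold] <- 1
  out
}

#' Pack a ground-truth volume and event mask into a stacked target
#'
#' The two volumes are stacked along a new leading axis of size 2, slot 1
#' holding the ground truth and slot 2 the binary mask, so that both reach
#' the loss through a single `y_true` argument.  [split_stacked_target()]
#' is the exact inverse.  A single-channel mask is expanded to the ground
#' truth's channel count at packing time.
#'
#' @param ground_truth a [zstack] (the training target volume).
#' @param mask binary array (same `(z,y,x)` dims; 1 or matching channels).
#' @return a `stacked_target`: 5D array `(2, z, y, x, c)` with attributes.
#' @export
pack_stacked_target <- function(ground_truth, mask) {
  validate_zstack(ground_truth)
  gt <- ground_truth$data
  d <- dim(gt)
  md <- dim(mask)
  if (length(md) == 4L && md[4] == 1L && d[4] == 3L)
    mask <- array(mask, c(md[1:3], 3L))
  if (!identical(dim(mask), d))
    stop("ground truth and mask dimensions differ: (",
         paste(d, collapse = ","), ") vs (", paste(md, collapse = ","), ")")
  if (!all(mask %in% c(0, 1))) stop("mask must contain only 0 and 1")
  out <- array(0, c(2L, d))
  out[1, , , , ] <- gt
  out[2, , , , ] <- mask
  structure(out, class = "stacked_target",
            value_range = ground_truth$value_range)
}

#' Split a stacked target back into ground truth and mask
#'
#' Exact inverse of [pack_stacked_target()].
#'
#' @param stacked a `stacked_target` (5D array, leading axis of size 2).
#' @return list with `ground_truth` ([zstack]) and `mask` (array).
#' @export
split_stacked_target <- function(stacked) {
  d <- dim(stacked)
  if (length(d) != 5L || d[1] != 2L)
    stop("stacked target must be a 5D array with leading axis of size 2")
  vr <- attr(stacked, "value_range")
  if (is.null(vr)) vr <- "raw"
  gt <- array(stacked[1, , , , ], d[-1])
  mask <- array(stacked[2, , , , ], d[-1])
  list(ground_truth = zstack(gt, vr), mask = mask)
}

#' Event-location-penalised mean absolute error
#'
#' `mean(|gt - pred| * (penalty * mask + 1))` over all voxels and channels.
#' Deterministic, non-negative, equal to plain MAE at `penalty = 0`, and
#' linear in the penalty:
#' `elp_mae(p) = MAE + p * mean(mask * |gt - pred|)`.
#'
#' @param stacked a `stacked_target` from [pack_stacked_target()], or a
#'   list of them (a batch; the mean over the batch is returned).
#' @param prediction a [zstack] or numeric array with the per-slot dims, or
#'   a list of them for a batch.
#' @param penalty non-negative finite scalar weight on masked voxels.
#' @param add_one keep the `+ 1` term (default). Disabling it exists only
#'   to demonstrate the untrainable-model ablation.
#' @return non-negative scalar.
#' @export
elp_mae <- function(stacked, prediction, penalty = 100, add_one = TRUE) {
  if (is.list(stacked) && !inherits(stacked, "stacked_target")) {
    vals <- mapply(function(s, p) elp_mae(s, p, penalty, add_one),
                   stacked, prediction)
    return(mean(vals))
  }
  if (!is.numeric(penalty) || length(penalty) != 1 || !is.finite(penalty) ||
      penalty < 0)
    stop("penalty must be a non-negative finite scalar")
  parts <- split_stacked_target(stacked)
  pred <- if (inherits(prediction, "zstack")) prediction$data else prediction
  gt <- parts$ground_truth$data
  if (!identical(dim(pred), dim(gt)))
    stop("prediction dims differ from stacked target per-slot dims")
  w <- penalty * parts$mask + as.numeric(add_one)
  mean(abs(gt - pred) * w)
}

# Gradient of ELP-MAE with respect to the prediction (used by training).
# d/dpred mean(w |gt - pred|) = -w * sign(gt - pred) / N.
elp_mae_grad <- function(stacked, prediction, penalty = 100, add_one = TRUE) {
  parts <- split_stacked_target(stacked)
  pred <- if (inherits(prediction, "zstack")) prediction$data else prediction
  gt <- parts$ground_truth$data
  w <- penalty * parts$mask + as.numeric(add_one)
  -w * sign(gt - pred) / length(gt)
}
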