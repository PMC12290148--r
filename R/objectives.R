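# ---------------------------------------------------------------------------
# Objectives: Dice-based segmentation loss averaged over the deeply
# supervised heads, the multi-scale L1 adversarial losses of generator and
# critic (which sum to 1 by construction), and the DSC/precision/recall
# evaluation metrics.
# ---------------------------------------------------------------------------

#' Loss weighting configuration
#'
#' @param alpha weight of the segmentation loss.
#' @param beta weight of the adversarial loss.
#' @param head_weights nonnegative weights of the (up to) 4 decoder heads;
#'   normalized to sum to 1, so equal weights reproduce the plain mean over
#'   heads.
#' @param seg_loss_kind `"dice"`, `"bce"` or `"dice_plus_bce"`.
#' @return a list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 1, head_weights = rep(1, 4),
                         seg_loss_kind = c("dice", "bce", "dice_plus_bce")) {
  seg_loss_kind <- match.arg(seg_loss_kind)
  if (alpha < 0 || beta < 0 || (alpha == 0 && beta == 0))
    stop("alpha and beta must be nonnegative and not both zero")
  if (any(head_weights < 0) || all(head_weights == 0))
    stop("head_weights must be nonnegative and not all zero")
  structure(list(alpha = alpha, beta = beta, head_weights = head_weights,
                 seg_loss_kind = seg_loss_kind),
            class = "loss_weights")
}

as_mask_array <- function(m) {
  if (inherits(m, "lesion_mask")) m <- m$pixels
  as_nchw(m)
}

#' Soft Dice coefficient
#'
#' `(2 * sum(pred * gt) + smooth) / (sum(pred) + sum(gt) + smooth)`.
#' On binarized inputs this equals `2TP / (2TP + FP + FN)`, the harmonic
#' combination of precision and recall. For batched arrays the coefficient
#' is computed per image and averaged.
#'
#' @param pred probability map (values in `[0, 1]`), matrix or
#'   `(H, W, 1, N)` array.
#' @param gt binary ground-truth mask of the same shape, or [lesion_mask()].
#' @param smooth smoothing constant added to numerator and denominator;
#'   1 by default, which makes two empty masks score 1.
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, gt, smooth = 1) {
  pred <- as_nchw(pred)
  gt <- as_mask_array(gt)
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ")
  N <- dim(pred)[4]
  vals <- vapply(seq_len(N), function(n) {
    p <- pred[, , , n]; g <- gt[, , , n]
    (2 * sum(p * g) + smooth) / (sum(p) + sum(g) + smooth)
  }, numeric(1))
  mean(vals)
}

# d(mean-over-batch soft Dice)/d(pred), elementwise
dice_grad <- function(pred, gt, smooth = 1) {
  N <- dim(pred)[4]
  g_out <- array(0, dim = dim(pred))
  for (n in seq_len(N)) {
    p <- pred[, , , n, drop = FALSE]; g <- gt[, , , n, drop = FALSE]
    num <- 2 * sum(p * g) + smooth
    den <- sum(p) + sum(g) + smooth
    g_out[, , , n] <- (2 * g * den - num) / den^2 / N
  }
  g_out
}

bce_value <- function(pred, gt, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(gt * log(p) + (1 - gt) * log(1 - p))
}

bce_grad <- function(pred, gt, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  (-(gt / p) + (1 - gt) / (1 - p)) / length(pred)
}

check_binary <- function(gt) {
  if (!all(gt %in% c(0, 1))) stop("ground truth must be binary (0/1)")
}

seg_loss_with_grad <- function(outputs, gt, w, smooth = 1,
                               want_grad = TRUE) {
  gt <- as_mask_array(gt)
  check_binary(gt)
  hw <- w$head_weights[seq_along(outputs)]
  hw <- hw / sum(hw)
  loss <- 0
  grads <- if (want_grad) vector("list", length(outputs)) else NULL
  for (i in seq_along(outputs)) {
    y <- as_nchw(outputs[[i]])
    if (!all(dim(y) == dim(gt))) stop("head ", i, " shape differs from gt")
    li <- 0; gi <- 0
    if (w$seg_loss_kind %in% c("dice", "dice_plus_bce")) {
      li <- li + (1 - dice_coefficient(y, gt, smooth))
      if (want_grad) gi <- gi - dice_grad(y, gt, smooth)
    }
    if (w$seg_loss_kind %in% c("bce", "dice_plus_bce")) {
      li <- li + bce_value(y, gt)
      if (want_grad) gi <- gi + bce_grad(y, gt)
    }
    loss <- loss + hw[i] * li
    if (want_grad) grads[[i]] <- hw[i] * gi
  }
  list(loss = loss, grads = grads)
}

#' Segmentation loss over the supervised heads
#'
#' The head-weight-normalized mean of per-head losses. With the default
#' Dice kind, equal weights and four heads this is the deep-supervision
#' loss `1/4 * sum_i (1 - Dice(y_i, gt))`.
#'
#' @param outputs list of head probability maps (from
#'   [generator_forward()]).
#' @param gt binary ground-truth mask.
#' @param w a [loss_weights()].
#' @param smooth Dice smoothing constant.
#' @return scalar loss.
#' @export
seg_loss <- function(outputs, gt, w = loss_weights(), smooth = 1) {
  seg_loss_with_grad(outputs, gt, w, smooth, want_grad = FALSE)$loss
}

adv_loss_with_grad <- function(outputs, gt, image, critic,
                               want_grad = TRUE, training = TRUE) {
  gt <- as_mask_array(gt)
  image <- as_nchw(image)
  mode <- critic$cfg$input_mode
  n_heads <- length(outputs)
  xg <- critic_input(image, gt, mode)
  fwd_gt <- critic_forward(critic, xg, training)
  nl <- critic$cfg$layers
  loss <- 0
  grads <- if (want_grad) vector("list", n_heads) else NULL
  for (i in seq_len(n_heads)) {
    y <- as_nchw(outputs[[i]])
    xp <- critic_input(image, y, mode)
    fwd_p <- critic_forward(critic, xp, training)
    diff <- fwd_p$sig - fwd_gt$sig
    loss <- loss + sum(abs(diff)) / nl / n_heads
    if (want_grad) {
      gsig <- sign(diff) / (nl * n_heads)
      gx <- critic_backward(critic, fwd_p, gsig, want_gw = FALSE)
      grads[[i]] <- switch(mode,
                           product = gx * image,
                           concat = split_ch(gx, 1L)[[2]],
                           sum = gx,
                           mask_only = gx)
    }
  }
  list(loss = loss, grads = grads)
}

#' Adversarial loss of the generator
#'
#' The mean over heads of the multi-scale L1 distance between the critic
#' signatures of the predicted-mask and ground-truth-mask image products:
#' `1/4 * sum_i | D(y_i x image) - D(gt x image) |`.
#'
#' @inheritParams seg_loss
#' @param image normalized input image (matrix or `(H, W, 1, N)` array).
#' @param critic an `ss_critic` from [build_critic()].
#' @param training logical; critic batch-norm mode.
#' @return scalar loss (0 when every head equals the ground truth).
#' @export
adv_loss_G <- function(outputs, gt, image, critic, training = TRUE) {
  adv_loss_with_grad(outputs, gt, image, critic, want_grad = FALSE,
                     training = training)$loss
}

#' Critic loss
#'
#' `1 - adv_loss_G` computed on critic-detached generator outputs; the two
#' losses sum to 1 on any fixed inputs.
#'
#' @inheritParams adv_loss_G
#' @return scalar loss (1 when every head equals the ground truth).
#' @export
disc_loss <- function(outputs, gt, image, critic, training = TRUE) {
  1 - adv_loss_G(outputs, gt, image, critic, training = training)
}

#' Total generator objective
#'
#' `alpha * seg_loss + beta * adv_loss_G`.
#'
#' @inheritParams adv_loss_G
#' @param w a [loss_weights()].
#' @param smooth Dice smoothing constant.
#' @return scalar loss.
#' @export
total_gen_loss <- function(outputs, gt, image, critic, w = loss_weights(),
                           smooth = 1) {
  l <- w$alpha * seg_loss(outputs, gt, w, smooth)
  if (w$beta > 0) l <- l + w$beta * adv_loss_G(outputs, gt, image, critic)
  l
}

#' Pixel confusion counts between a predicted and a reference mask
#'
#' @param pred,gt binary masks (matrices or [lesion_mask()]s).
#' @return list with fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, gt) {
  p <- if (inherits(pred, "lesion_mask")) pred$pixels else pred
  g <- if (inherits(gt, "lesion_mask")) gt$pixels else gt
  if (!all(dim(p) == dim(g))) stop("mask shapes differ")
  list(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
       fn = sum(p == 0 & g == 1), tn = sum(p == 0 & g == 0))
}

metrics_from_counts <- function(cc, empty_value = 1) {
  pos_pred <- cc$tp + cc$fp
  pos_gt <- cc$tp + cc$fn
  if (pos_pred == 0 && pos_gt == 0)
    return(list(dsc = empty_value, precision = empty_value,
                recall = empty_value))
  precision <- if (pos_pred == 0) 0 else cc$tp / pos_pred
  recall <- if (pos_gt == 0) 0 else cc$tp / pos_gt
  dsc <- 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
  list(dsc = dsc, precision = precision, recall = recall)
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-image confusion counts, derives per-image DSC, precision
#' and recall, and macro-averages them over the image list. An image whose
#' ground truth and prediction are both empty scores `empty_value`
#' (1 by default: correct rejection).
#'
#' @param pred_masks,gt_masks equal-length lists of binary masks.
#' @param empty_value score assigned when both masks are empty.
#' @return an object of class `metrics_report` with a per-image data frame
#'   and macro-averaged `dsc`, `precision`, `recall`.
#' @export
evaluate <- function(pred_masks, gt_masks, empty_value = 1) {
  if (length(pred_masks) != length(gt_masks))
    stop("pred_masks and gt_masks must have the same length")
  rows <- lapply(seq_along(pred_masks), function(i) {
    cc <- confusion_counts(pred_masks[[i]], gt_masks[[i]])
    m <- metrics_from_counts(cc, empty_value)
    data.frame(image = i, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
               dsc = m$dsc, precision = m$precision, recall = m$recall)
  })
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 dsc = mean(per_image$dsc),
                 precision = mean(per_image$precision),
                 recall = mean(per_image$recall)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics over %d images: DSC %.4f  precision %.4f  recall %.4f\n",
              nrow(x$per_image), x$dsc, x$precision, x$recall))
  invisible(x)
}

#' Aggregate metrics reports across repeated runs
#'
#' @param reports list of `metrics_report` objects (one per run).
#' @return data frame with per-run rows and a `mean +/- sd` summary.
#' @export
aggregate_runs <- function(reports) {
  per_run <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(run = i, dsc = r$dsc, precision = r$precision,
               recall = r$recall)
  }))
  summary <- data.frame(run = NA_integer_,
                        dsc = mean(per_run$dsc),
                        precision = mean(per_run$precision),
                        recall = mean(per_run$recall),
                        dsc_sd = if (nrow(per_run) > 1) sd(per_run$dsc) else 0,
                        precision_sd = if (nrow(per_run) > 1)
                          sd(per_run$precision) else 0,
                        recall_sd = if (nrow(per_run) > 1)
                          sd(per_run$recall) else 0)
  list(per_run = per_run, summary = summary)
}

#' Write a metrics report to CSV and JSON
#'
#' @param agg result of [aggregate_runs()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_metrics_report <- function(agg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "metrics_per_run.csv")
  js <- file.path(dir, "metrics_summary.json")
  utils::write.csv(agg$per_run, csv, row.names = FALSE)
  jsonlite::write_json(as.list(agg$summary), js, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
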