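# Weighted segmentation losses: an entry-weighted Dice loss over the
# flattened one-hot expansion, the Lovasz extension of the per-class
# Jaccard loss combined by normalised class weights, and their convex
# combination L = alpha * L_Dice + beta * L_Lovasz.

check_pred_truth <- function(pred, truth, weights) {
  pred <- unclass(pred); truth <- unclass(truth)
  dp <- dim(pred); dt <- dim(truth)
  if (is.null(dp) || length(dp) != 3L || !identical(dp, dt))
    stop("pred and truth must be C x H x W arrays of identical shape")
  if (length(weights) != dp[1L])
    stop("weights length must equal the number of channels")
  list(pred = pred, truth = truth, w = as.numeric(weights))
}

#' Weighted Dice loss
#'
#' The default (`mode = "entry"`) evaluates the Dice ratio over all
#' `C * H * W` one-hot entries at once, each entry weighted by its class's
#' weight:
#' `L = 1 - 2 * sum(y * p * w) / sum((y + p) * w)`,
#' with `epsilon` added to numerator and denominator for stability. With
#' uniform weights this reduces to the standard soft Dice loss.
#' `mode = "per_class"` instead computes one Dice loss per class and
#' returns their weight-normalised average.
#'
#' @param pred C x H x W array of predicted class probabilities.
#' @param truth C x H x W one-hot ground-truth mask.
#' @param weights Length-C class weights.
#' @param epsilon Smoothing constant (default 1e-6).
#' @param mode `"entry"` (weight each flattened entry) or `"per_class"`
#'   (weighted average of per-class Dice losses).
#' @return Scalar loss in `[0, 1]`; 0 at a perfect hard prediction.
#' @export
weighted_dice_loss <- function(pred, truth, weights, epsilon = 1e-6,
                               mode = c("entry", "per_class")) {
  mode <- match.arg(mode)
  z <- check_pred_truth(pred, truth, weights)
  C <- dim(z$pred)[1L]
  if (mode == "entry") {
    wfull <- array(z$w, dim = dim(z$pred))   # class weight broadcast over H, W
    num <- 2 * sum(z$truth * z$pred * wfull)
    den <- sum((z$truth + z$pred) * wfull)
    1 - (num + epsilon) / (den + epsilon)
  } else {
    pf <- matrix(z$pred, nrow = C)
    tf <- matrix(z$truth, nrow = C)
    num <- 2 * rowSums(tf * pf)
    den <- rowSums(tf + pf)
    dice <- (num + epsilon) / (den + epsilon)
    sum(z$w * (1 - dice)) / sum(z$w)
  }
}

# Gradient of the Jaccard loss along the sorted-error path (the discrete
# derivative of 1 - IoU as pixels are flipped in error order).
lovasz_grad <- function(gt_sorted) {
  p <- length(gt_sorted)
  gts <- sum(gt_sorted)
  intersection <- gts - cumsum(gt_sorted)
  union <- gts + cumsum(1 - gt_sorted)
  jaccard <- 1 - intersection / union
  if (p > 1L) jaccard[2:p] <- jaccard[2:p] - jaccard[1:(p - 1L)]
  jaccard
}

# One class's Lovasz term on flattened foreground indicator / probability.
lovasz_class_term <- function(fg, prob) {
  errors <- abs(fg - prob)
  perm <- order(errors, decreasing = TRUE)
  sum(errors[perm] * lovasz_grad(fg[perm]))
}

#' Weighted Lovasz loss
#'
#' For each class the Lovasz extension of the Jaccard (1 - IoU) loss is
#' evaluated on the class's error vector (errors sorted in decreasing
#' order, inner product with the discrete Jaccard gradient); class terms
#' are combined as `sum(w_c * l_c) / sum(w_c)`. At hard binary
#' predictions each class term equals exactly `1 - IoU` for that class.
#' A class absent from the truth contributes, under the same formula, its
#' maximum predicted probability (a false-positive penalty that preserves
#' the vertex property); set `absent_classes = "skip"` to drop such
#' classes from the average instead.
#'
#' @inheritParams weighted_dice_loss
#' @param absent_classes `"penalty"` (default, evaluate the extension as
#'   is) or `"skip"` (average over classes present in the truth only).
#' @return Scalar loss in `[0, 1]`; 0 at a perfect hard prediction.
#' @export
weighted_lovasz_loss <- function(pred, truth, weights,
                                 absent_classes = c("penalty", "skip")) {
  absent_classes <- match.arg(absent_classes)
  z <- check_pred_truth(pred, truth, weights)
  C <- dim(z$pred)[1L]
  pf <- matrix(z$pred, nrow = C)
  tf <- matrix(z$truth, nrow = C)
  keep <- if (absent_classes == "skip") rowSums(tf) > 0 else rep(TRUE, C)
  if (!any(keep)) return(0)
  terms <- vapply(which(keep), function(c)
    lovasz_class_term(tf[c, ], pf[c, ]), numeric(1))
  sum(z$w[keep] * terms) / sum(z$w[keep])
}

#' Loss configuration
#'
#' @param class_weights Length-C class weights (see [compute_weights()]).
#' @param alpha,beta Mixing coefficients of the Dice and Lovasz terms
#'   (both 0.5 by default, the equal-contribution setting).
#' @param epsilon Dice smoothing constant.
#' @param dice_mode Passed to [weighted_dice_loss()].
#' @param absent_classes Passed to [weighted_lovasz_loss()].
#' @return A list of class `"loss_config"`.
#' @export
loss_config <- function(class_weights = rep(0.25, 4), alpha = 0.5, beta = 0.5,
                        epsilon = 1e-6, dice_mode = "entry",
                        absent_classes = "penalty") {
  stopifnot(alpha >= 0, beta >= 0, epsilon > 0)
  structure(list(class_weights = as.numeric(class_weights), alpha = alpha,
                 beta = beta, epsilon = epsilon, dice_mode = dice_mode,
                 absent_classes = absent_classes),
            class = "loss_config")
}

#' Combined weighted Dice + Lovasz loss
#'
#' `total = alpha * dice_term + beta * lovasz_term`.
#'
#' @inheritParams weighted_dice_loss
#' @param config A [loss_config()].
#' @return A list of class `"loss_value"` with `total`, `dice_term` and
#'   `lovasz_term`.
#' @export
combined_loss <- function(pred, truth, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  d <- weighted_dice_loss(pred, truth, config$class_weights,
                          epsilon = config$epsilon, mode = config$dice_mode)
  l <- weighted_lovasz_loss(pred, truth, config$class_weights,
                            absent_classes = config$absent_classes)
  structure(list(total = config$alpha * d + config$beta * l,
                 dice_term = d, lovasz_term = l),
            class = "loss_value")
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> total %.5f (dice %.5f, lovasz %.5f)\n",
              x$total, x$dice_term, x$lovasz_term))
  invisible(x)
}
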