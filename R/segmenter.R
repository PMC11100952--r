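# Pluggable segmenter interface. A segmenter takes a grayscale image plus
# per-class prompt boxes and returns a C x H x W probability map. The
# package ships a CPU-scale surrogate — a per-pixel multinomial-logistic
# model over intensity and box-indicator features — so the loss /
# optimizer / early-stopping machinery is exercisable without a GPU
# foundation model, and two oracle segmenters used by the prompt-offset
# ablation.

#' Predict a probability map from an image and prompt boxes
#'
#' @param model A segmenter object.
#' @param image Numeric H x W matrix in `[0, 1]`.
#' @param boxes A `"prompt_boxes"` list (one box per class).
#' @param truth Optional ground-truth [label_map()]; consumed by oracle
#'   segmenters only.
#' @return C x H x W probability array (channels sum to 1 per pixel).
#' @export
predict_segmenter <- function(model, image, boxes, truth = NULL) {
  UseMethod("predict_segmenter")
}

# F x N per-pixel design matrix: bias, intensity, intensity^2, one box
# indicator per non-background class.
surrogate_features <- function(image, boxes) {
  h <- nrow(image); w <- ncol(image)
  C <- length(boxes)
  ch <- boxes_to_channels(boxes, h, w)
  X <- rbind(1, as.vector(image), as.vector(image)^2,
             matrix(ch[-1L, , ], nrow = C - 1L))
  X
}

#' CPU-scale surrogate segmenter
#'
#' A per-pixel multinomial-logistic (softmax) classifier over six
#' features: bias, intensity, squared intensity, and one binary
#' box-membership channel per non-background class (the prompt boxes
#' rendered as indicator images). Linear in its parameter matrix, so the
#' combined weighted Dice + Lovasz loss has a closed-form gradient and
#' the harness trains it with AdamW on one CPU.
#'
#' @param n_classes Number of classes (default 4).
#' @param init_sd Standard deviation of the Gaussian weight
#'   initialisation (0 gives an exactly uniform initial softmax).
#' @param seed Seed for the initialisation.
#' @return An object of class `"surrogate_segmenter"` with weight matrix
#'   `W` (C x F).
#' @export
surrogate_segmenter <- function(n_classes = 4L, init_sd = 0.01, seed = 1L) {
  FF <- 3L + n_classes - 1L
  W <- if (init_sd > 0) {
    with_seed(child_seed(seed, "init"),
              matrix(stats::rnorm(n_classes * FF, 0, init_sd), n_classes, FF))
  } else matrix(0, n_classes, FF)
  structure(list(W = W, n_classes = as.integer(n_classes)),
            class = "surrogate_segmenter")
}

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

#' @export
predict_segmenter.surrogate_segmenter <- function(model, image, boxes,
                                                  truth = NULL) {
  X <- surrogate_features(image, boxes)
  P <- softmax_cols(model$W %*% X)
  array(P, dim = c(model$n_classes, nrow(image), ncol(image)))
}

#' Oracle segmenters for the prompt-offset ablation
#'
#' `mode = "truth_in_box"` reproduces the ground truth inside each
#' class's box and background outside it — a best-case prompted
#' segmenter. `mode = "box_fill"` predicts each class over its entire
#' box (later classes take precedence), so growing the box offset
#' directly inflates false positives and mean DSC degrades
#' monotonically, the direction seen when prompt offsets are widened.
#'
#' @param mode Oracle behaviour.
#' @return An object of class `"oracle_segmenter"`.
#' @export
oracle_segmenter <- function(mode = c("truth_in_box", "box_fill")) {
  structure(list(mode = match.arg(mode)), class = "oracle_segmenter")
}

#' @export
predict_segmenter.oracle_segmenter <- function(model, image, boxes,
                                               truth = NULL) {
  if (is.null(truth)) stop("oracle segmenters need the ground-truth label map")
  h <- nrow(image); w <- ncol(image)
  C <- length(boxes)
  ch <- boxes_to_channels(boxes, h, w)
  lab <- matrix(0L, h, w)
  if (model$mode == "truth_in_box") {
    tv <- unclass(truth)
    for (ci in seq_len(C - 1L)) {          # non-background classes
      inbox <- ch[ci + 1L, , ] > 0
      lab[tv == ci & inbox] <- ci
    }
  } else {
    for (ci in seq_len(C - 1L)) {
      b <- boxes[[ci + 1L]]
      if (all(b == 0L)) next
      lab[(b[2L] + 1L):(b[4L] + 1L), (b[1L] + 1L):(b[3L] + 1L)] <- ci
    }
  }
  unclass(encode_one_hot(label_map(lab, C), C))
}
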