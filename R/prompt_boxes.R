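# Per-class prompt bounding boxes from one-hot masks: for every class the
# tight [x_min, y_min, x_max, y_max] extent of pixels whose activation
# exceeds a threshold, expanded symmetrically by an offset and clamped to
# the image; classes with no activated pixels get the sentinel
# [0, 0, 0, 0]. Coordinates are 0-based and inclusive.

#' Prompt box configuration
#'
#' @param threshold Activation cutoff in `[0, 1)`; for binary one-hot
#'   channels any value in (0, 1) is equivalent and 0.5 is the default.
#' @param offset Non-negative symmetric outward expansion in pixels.
#'   Offsets 0/10/20 are the prompt-size ablation settings.
#' @return A list of class `"prompt_config"`.
#' @export
prompt_config <- function(threshold = 0.5, offset = 0L) {
  stopifnot(threshold >= 0, threshold < 1, offset >= 0)
  structure(list(threshold = threshold, offset = as.integer(offset)),
            class = "prompt_config")
}

#' Derive per-class prompt bounding boxes from a one-hot mask
#'
#' @param mask C x H x W one-hot (or soft) mask.
#' @param config A [prompt_config()].
#' @param n_classes Number of classes expected in the result; every index
#'   `0..n_classes-1` is present, absent classes filled with the sentinel
#'   `[0, 0, 0, 0]`.
#' @return Named list (class `"prompt_boxes"`) mapping class index (as
#'   character) to integer `c(x_min, y_min, x_max, y_max)`.
#' @export
derive_boxes <- function(mask, config = prompt_config(), n_classes = NULL) {
  mask <- unclass(mask)
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stop("mask must be a C x H x W array")
  if (is.null(n_classes)) n_classes <- d[1L]
  h <- d[2L]; w <- d[3L]
  boxes <- stats::setNames(vector("list", n_classes),
                           as.character(seq_len(n_classes) - 1L))
  for (i in seq_len(min(n_classes, d[1L]))) {
    act <- which(mask[i, , ] > config$threshold, arr.ind = TRUE)
    if (nrow(act) == 0L) next
    y <- act[, 1L] - 1L; x <- act[, 2L] - 1L
    off <- config$offset
    boxes[[i]] <- as.integer(c(max(min(x) - off, 0L), max(min(y) - off, 0L),
                               min(max(x) + off, w - 1L), min(max(y) + off, h - 1L)))
  }
  for (i in seq_len(n_classes))
    if (is.null(boxes[[i]])) boxes[[i]] <- c(0L, 0L, 0L, 0L)
  structure(boxes, class = "prompt_boxes")
}

#' Derive prompt boxes directly from a label map
#'
#' Convenience composition of [encode_one_hot()] and [derive_boxes()].
#'
#' @param label_map A [label_map()].
#' @param config A [prompt_config()].
#' @param n_classes Number of classes.
#' @return A `"prompt_boxes"` list, one box per class.
#' @export
boxes_from_label_map <- function(label_map, config = prompt_config(),
                                 n_classes = NULL) {
  if (is.null(n_classes))
    n_classes <- attr(label_map, "n_classes") %||% (max(label_map) + 1L)
  derive_boxes(encode_one_hot(label_map, n_classes), config, n_classes)
}

#' @export
print.prompt_boxes <- function(x, ...) {
  for (k in names(x))
    cat(sprintf("class %s: [%s]\n", k, paste(x[[k]], collapse = ", ")))
  invisible(x)
}

#' Render prompt boxes as binary indicator channels
#'
#' One H x W channel per class, 1 inside the class's box. The sentinel
#' box of an absent class renders as a single corner pixel; callers that
#' want truly empty channels should test for the sentinel first. Used to
#' feed box prompts to segmenters that take image-like input.
#'
#' @param boxes A `"prompt_boxes"` list.
#' @param h,w Image size.
#' @return C x H x W binary array.
#' @export
boxes_to_channels <- function(boxes, h, w) {
  C <- length(boxes)
  out <- array(0, dim = c(C, h, w))
  for (i in seq_len(C)) {
    b <- boxes[[i]]
    if (all(b == 0L) && i > 1L) next   # sentinel for absent non-background class
    out[i, (b[2L] + 1L):(b[4L] + 1L), (b[1L] + 1L):(b[3L] + 1L)] <- 1
  }
  out
}

#' Write prompt boxes for a set of masks to JSON
#'
#' Schema: `{stem: {class_index: [x_min, y_min, x_max, y_max]}}`.
#'
#' @param box_sets Named list (stem -> `"prompt_boxes"`).
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_boxes_json <- function(box_sets, path) {
  jsonlite::write_json(lapply(box_sets, function(b) lapply(b, as.integer)),
                       path, auto_unbox = FALSE)
  invisible(path)
}
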