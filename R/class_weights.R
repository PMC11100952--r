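# Inverse-frequency class weighting: count pixels per class over a mask
# collection, replace zero counts by one, take inverse frequencies
# normalised by their sum, then min-max rescale into [min_weight,
# max_weight]. The rarest class receives max_weight and the most frequent
# min_weight whenever counts differ.

#' Count class occurrences over a collection of masks
#'
#' Accepts label maps and/or one-hot masks (one-hot input is collapsed by
#' argmax first). Any class absent from the whole collection gets a count
#' of 1 so downstream inverse frequencies stay finite.
#'
#' @param masks List of [label_map()] matrices or C x H x W one-hot
#'   arrays; a single mask may be passed directly.
#' @param n_classes Number of classes.
#' @return Integer vector of length `n_classes` with class
#'   `"class_counts"`; every entry >= 1.
#' @export
count_classes <- function(masks, n_classes = 4L) {
  if (is.matrix(masks) || (is.array(masks) && length(dim(masks)) == 3L))
    masks <- list(masks)
  if (length(masks) == 0L) stop("empty mask collection")
  counts <- numeric(n_classes)
  for (m in masks) {
    if (is.array(m) && length(dim(m)) == 3L) m <- decode_argmax(m)
    v <- as.vector(unclass(m))
    if (any(v < 0 | v >= n_classes)) stop("mask contains labels outside the schema")
    tab <- tabulate(v + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  counts[counts == 0] <- 1
  structure(as.integer(counts), class = "class_counts")
}

#' Inverse-frequency class weights smoothed into a range
#'
#' Raw weights are the inverse class frequencies `total / counts`
#' normalised by their sum, then min-max rescaled so the most frequent
#' class maps to `min_weight` and the rarest to `max_weight`. If all
#' normalised weights are equal (the min-max denominator degenerates)
#' every class receives the midpoint of the range.
#'
#' @param counts Positive integer vector of per-class pixel counts (see
#'   [count_classes()]).
#' @param min_weight,max_weight Bounds of the smoothing range. The
#'   defaults 0.1 / 0.9 bracket weight vectors of the shape
#'   `[0.1, 0.1, 0.9, 0.7]` that arise on imbalanced fetal-head data.
#' @return Numeric vector of weights in `[min_weight, max_weight]` with
#'   class `"class_weights"` and attributes `min_weight`, `max_weight`.
#' @examples
#' compute_weights(c(1000, 1000, 10, 100))
#' @export
compute_weights <- function(counts, min_weight = 0.1, max_weight = 0.9) {
  counts <- as.numeric(unclass(counts))
  if (any(counts <= 0))
    stop("non-positive class count: apply zero-count handling first")
  if (min_weight >= max_weight) stop("min_weight must be < max_weight")
  raw <- sum(counts) / counts
  raw <- raw / sum(raw)
  rng <- max(raw) - min(raw)
  w <- if (rng < .Machine$double.eps) {
    rep((min_weight + max_weight) / 2, length(counts))
  } else {
    (raw - min(raw)) / rng * (max_weight - min_weight) + min_weight
  }
  structure(w, class = "class_weights",
            min_weight = min_weight, max_weight = max_weight)
}

#' @export
print.class_weights <- function(x, ...) {
  cat("<class_weights> [", paste(sprintf("%.5f", unclass(x)), collapse = ", "),
      "] in [", attr(x, "min_weight"), ",", attr(x, "max_weight"), "]\n")
  invisible(x)
}

#' Write / read class weights as YAML
#'
#' The interchange format between the weight calculation and the loss /
#' training configuration: a mapping from class name to weight.
#'
#' @param weights A [compute_weights()] result.
#' @param path Output YAML file.
#' @param schema A [label_schema()] naming the classes.
#' @return `path` invisibly (`write_weights`); a `class_weights` vector
#'   (`read_weights`).
#' @export
write_weights <- function(weights, path, schema = label_schema()) {
  stopifnot(length(weights) == schema$n_classes)
  yaml::write_yaml(as.list(stats::setNames(as.numeric(weights), schema$class_names)),
                   path)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  v <- unlist(yaml::read_yaml(path))
  structure(as.numeric(v), class = "class_weights", names = names(v))
}
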