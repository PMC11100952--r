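#' One-hot encode a label map
#'
#' Expands an H x W label map into a C x H x W binary array with channel
#' `c + 1` set to 1 exactly where the map equals class `c`. Every pixel is
#' hot in exactly one channel.
#'
#' @param label_map Integer H x W matrix of 0-based class indices.
#' @param schema A [label_schema()] (or the number of classes).
#' @return Numeric array of dimension `c(C, H, W)` with class
#'   `"one_hot_mask"`.
#' @examples
#' m <- label_map(matrix(c(0L, 1L, 2L, 3L), 2, 2), 4)
#' oh <- encode_one_hot(m)
#' sum(oh)  # one hot entry per pixel
#' @export
encode_one_hot <- function(label_map, schema = label_schema()) {
  C <- if (inherits(schema, "label_schema")) schema$n_classes else as.integer(schema)
  v <- unclass(label_map)
  if (!is.matrix(v)) stop("label_map must be a matrix")
  if (any(v < 0L | v >= C)) {
    off <- v[which(v < 0L | v >= C)[1L]]
    stop(sprintf("invalid label %d for a %d-class schema", off, C))
  }
  h <- nrow(v); w <- ncol(v)
  oh <- array(0, dim = c(C, h, w))
  # index into C x H x W: channel = value + 1
  idx <- cbind(as.vector(v) + 1L,
               rep.int(seq_len(h), w),
               rep(seq_len(w), each = h))
  oh[idx] <- 1
  structure(oh, class = "one_hot_mask")
}

#' Collapse a probability map (or one-hot mask) to a label map by argmax
#'
#' Each pixel takes the 0-based index of its maximal channel; ties are
#' broken toward the lowest class index, so the result is deterministic.
#'
#' @param prob Numeric C x H x W array of per-class scores or
#'   probabilities.
#' @return A [label_map()] of dimension H x W.
#' @export
decode_argmax <- function(prob) {
  prob <- unclass(prob)
  d <- dim(prob)
  if (is.null(d) || length(d) != 3L || any(d == 0L))
    stop("expected a non-empty C x H x W array")
  if (d[1L] < 2L) stop("argmax needs at least 2 channels")
  flat <- matrix(prob, nrow = d[1L])           # C x (H*W)
  lab <- max.col(t(flat), ties.method = "first") - 1L
  label_map(matrix(lab, d[2L], d[3L]), n_classes = d[1L])
}

#' Validate the exactly-one-hot invariant
#'
#' @param mask A C x H x W array.
#' @return `TRUE` if every pixel has channel sum exactly 1 and all entries
#'   are 0/1.
#' @export
is_one_hot <- function(mask) {
  mask <- unclass(mask)
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) return(FALSE)
  all(mask %in% c(0, 1)) &&
    all(abs(apply(mask, c(2, 3), sum) - 1) < 1e-12)
}
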