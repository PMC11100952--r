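#' Label schema for multi-class segmentation
#'
#' Defines the ordered class vocabulary shared by every other component.
#' Index 0 is always the background class; the default schema is the
#' four-class fetal head anatomy: background, fetal brain, cavum septum
#' pellucidum (CSP) and lateral ventricles (LV).
#'
#' @param class_names Character vector of unique class names, background
#'   first. Class `i` (0-based) is `class_names[i + 1]`.
#' @return An object of class `"label_schema"` with elements `class_names`
#'   and `n_classes`.
#' @examples
#' s <- label_schema()
#' s$n_classes
#' @export
label_schema <- function(class_names = c("background", "brain", "CSP", "LV")) {
  stopifnot(is.character(class_names))
  if (anyDuplicated(class_names))
    stop("class names must be unique")
  if (length(class_names) < 2L)
    stop("a schema needs at least 2 classes (background + one structure)")
  structure(
    list(class_names = class_names, n_classes = length(class_names)),
    class = "label_schema"
  )
}

#' @export
print.label_schema <- function(x, ...) {
  cat("<label_schema> ", x$n_classes, " classes: ",
      paste(x$class_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a label map
#'
#' A label map is an H x W integer matrix whose entries are 0-based class
#' indices. Row index is y (downward), column index is x (rightward), the
#' coordinate convention shared by all modules.
#'
#' @param values Integer matrix, entries in `[0, n_classes)`.
#' @param n_classes Number of classes the map may reference.
#' @return The validated integer matrix with class `"label_map"` and an
#'   `n_classes` attribute.
#' @export
label_map <- function(values, n_classes = 4L) {
  if (!is.matrix(values) || nrow(values) < 1L || ncol(values) < 1L)
    stop("label map must be a non-empty matrix")
  storage.mode(values) <- "integer"
  bad <- values < 0L | values >= n_classes
  if (any(bad)) {
    off <- values[which(bad)[1L]]
    stop(sprintf("invalid label %d: labels must lie in [0, %d)", off, n_classes))
  }
  structure(values, class = c("label_map", "matrix"),
            n_classes = as.integer(n_classes))
}

#' Bundle an image with its label map
#'
#' @param image Numeric H x W matrix of grayscale intensities in `[0, 1]`.
#' @param label_map A [label_map()] of the same H x W.
#' @param id Sample identifier (filename stem).
#' @return A list of class `"image_sample"`.
#' @export
image_sample <- function(image, label_map, id = "sample") {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (!identical(dim(image), dim(unclass(label_map))))
    stop("image and label map dimensions differ")
  structure(list(image = image, label_map = label_map, id = id),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample '%s'> %dx%d, labels {%s}\n", x$id,
              nrow(x$image), ncol(x$image),
              paste(sort(unique(as.vector(x$label_map))), collapse = ",")))
  invisible(x)
}

#' Display an image sample with its label map
#'
#' Draws the grayscale image and the label map side by side using base
#' graphics (labels colour-coded by class index).
#'
#' @param x An [image_sample()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.image_sample <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  ras <- function(m) t(m)[, nrow(m):1, drop = FALSE]  # matrix -> image() orientation
  graphics::image(ras(x$image), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, main = x$id, ...)
  n <- attr(x$label_map, "n_classes") %||% (max(x$label_map) + 1L)
  graphics::image(ras(unclass(x$label_map)),
                  col = grDevices::hcl.colors(max(n, 2L), "viridis"),
                  zlim = c(0, n - 1L), axes = FALSE, main = "labels", ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
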