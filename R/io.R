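# Paired-PNG dataset layout: <dir>/images/<stem>.png (8-bit grayscale) and
# <dir>/masks/<stem>.png (8-bit grayscale, pixel value = class index).

#' Write an image sample to the paired-PNG dataset layout
#'
#' @param sample An [image_sample()].
#' @param dir Dataset directory; `images/` and `masks/` are created.
#' @return The sample, invisibly.
#' @export
write_sample <- function(sample, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  img <- pmin(pmax(sample$image, 0), 1)
  png::writePNG(img, file.path(dir, "images", paste0(sample$id, ".png")))
  png::writePNG(unclass(sample$label_map) / 255,
                file.path(dir, "masks", paste0(sample$id, ".png")))
  invisible(sample)
}

#' Read an image sample from the paired-PNG dataset layout
#'
#' @param dir Dataset directory.
#' @param stem Filename stem.
#' @param n_classes Number of classes for label validation.
#' @return An [image_sample()].
#' @export
read_sample <- function(dir, stem, n_classes = 4L) {
  img <- png::readPNG(file.path(dir, "images", paste0(stem, ".png")))
  if (length(dim(img)) == 3L) img <- img[, , 1L]    # tolerate gray written as RGB
  msk <- png::readPNG(file.path(dir, "masks", paste0(stem, ".png")))
  if (length(dim(msk)) == 3L) msk <- msk[, , 1L]
  lab <- label_map(matrix(as.integer(round(msk * 255)), nrow(msk), ncol(msk)),
                   n_classes = n_classes)
  image_sample(img, lab, id = stem)
}

#' List the sample stems present in a dataset directory
#'
#' @param dir Dataset directory.
#' @return Sorted character vector of stems present in both `images/` and
#'   `masks/`.
#' @export
list_stems <- function(dir) {
  s1 <- sub("\\.png$", "", list.files(file.path(dir, "images"), "\\.png$"))
  s2 <- sub("\\.png$", "", list.files(file.path(dir, "masks"), "\\.png$"))
  sort(intersect(s1, s2))
}

#' Read every sample in a dataset directory
#'
#' @inheritParams read_sample
#' @return List of [image_sample()] objects, ordered by stem.
#' @export
read_dataset <- function(dir, n_classes = 4L) {
  lapply(list_stems(dir), read_sample, dir = dir, n_classes = n_classes)
}

#' Write a list of samples to a dataset directory
#'
#' @param samples List of [image_sample()] objects.
#' @param dir Dataset directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  for (s in samples) write_sample(s, dir)
  invisible(dir)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a parent seed and one or more tags
# (integers or strings); keeps results independent across pipeline stages.
child_seed <- function(seed, ...) {
  tags <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (t in tags) {
    bytes <- if (is.character(t)) utf8ToInt(t) else as.integer(t)
    for (b in bytes) h <- (h * 131 + (b %% 65536) + 17) %% 2147483563
  }
  as.integer(h %% 2147483563) + 1L
}
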