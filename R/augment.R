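# Nine augmentation strategies applied jointly to image and label map.
# Geometric transforms use bilinear resampling for images and
# nearest-neighbour for labels (border fill = background); intensity
# transforms (brightness/contrast, noise, blur) touch the image only.

# ---- resampling helpers ----------------------------------------------------

resize_mat <- function(m, h, w, nearest = FALSE) {
  # EBImage images are (x, y); our matrices are (row = y, col = x) H x W, so
  # dim1 maps to EBImage's w argument.
  out <- EBImage::resize(EBImage::as.Image(m), w = h, h = w,
                         filter = if (nearest) "none" else "bilinear")
  matrix(EBImage::imageData(out), h, w)
}

resize_pair <- function(img, lab, h, w) {
  list(image = resize_mat(img, h, w),
       lab = matrix(as.integer(round(resize_mat(lab, h, w, nearest = TRUE))), h, w))
}

rotate_mat <- function(m, angle, nearest = FALSE) {
  out <- EBImage::rotate(EBImage::as.Image(m), angle,
                         filter = if (nearest) "none" else "bilinear",
                         output.dim = dim(m), bg.col = 0)
  matrix(EBImage::imageData(out), nrow(m), ncol(m))
}

crop_at <- function(m, y0, x0, ch, cw) m[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), drop = FALSE]

reflect_pad <- function(m, p) {
  h <- nrow(m); w <- ncol(m)
  if (p >= h || p >= w) stop("pad exceeds image size")
  yi <- c((p + 1L):2L, 1L:h, (h - 1L):(h - p))
  xi <- c((p + 1L):2L, 1L:w, (w - 1L):(w - p))
  m[yi, xi, drop = FALSE]
}

# Separable Gaussian smoothing with edge-replication padding.
gauss_smooth <- function(m, sigma) {
  r <- max(1L, min(as.integer(ceiling(3 * sigma)), nrow(m) - 1L, ncol(m) - 1L))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(x) {
    n <- nrow(x)
    xp <- x[c(rep(1L, r), 1L:n, rep(n, r)), , drop = FALSE]
    f <- stats::filter(xp, k, sides = 2)
    matrix(f[(r + 1L):(r + n), ], n, ncol(x))
  }
  t(smooth1(t(smooth1(m))))
}

# Remap (y,x) -> (y + dy, x + dx) sampling the source bilinearly (images)
# or by nearest neighbour (labels); coordinates clamped to the grid.
remap <- function(m, dy, dx, nearest = FALSE) {
  h <- nrow(m); w <- ncol(m)
  ys <- matrix(seq_len(h), h, w) + dy
  xs <- matrix(seq_len(w), h, w, byrow = TRUE) + dx
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  if (nearest) {
    out <- m[cbind(as.vector(round(ys)), as.vector(round(xs)))]
  } else {
    y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
    fy <- ys - y0; fx <- xs - x0
    g <- function(yy, xx) m[cbind(as.vector(yy), as.vector(xx))]
    out <- (1 - fy) * (1 - fx) * g(y0, x0) + (1 - fy) * fx * g(y0, x0 + 1L) +
      fy * (1 - fx) * g(y0 + 1L, x0) + fy * fx * g(y0 + 1L, x0 + 1L)
  }
  matrix(out, h, w)
}

# ---- the nine strategies ---------------------------------------------------

#' Build the nine augmentation strategies
#'
#' Returns, in order, the nine named strategies with their constants:
#' plain resize (Rz); random crop of half the target size then resize
#' (RC+Rz); vertical / horizontal flip with probability 0.3 (VF+Rz,
#' HF+Rz); rotation within 30 degrees with probability 0.3 (ROT+Rz); the
#' chained combination of crop, both flips and rotation (CMB); random
#' resized crop at scale 1.2-1.4 (RRC+Rz); reflection padding followed by
#' a random crop back to the target (PAD+RC+Rz); and the advanced
#' intensity/elastic set RB+ET+GN+GB, each member applied with
#' probability 0.5 (brightness/contrast, elastic transform with alpha 1
#' and sigma 50, Gaussian noise with variance 10-50 on the 8-bit scale,
#' Gaussian blur with kernel limit 3-7).
#'
#' @param size Output image side in pixels (default 256). Crop size is
#'   `size/2` and the reflection pad `size/8`, scaling the 256-pixel
#'   constants to reduced working resolutions.
#' @param pad Reflection pad per side for PAD+RC+Rz.
#' @return List of 9 `"aug_strategy"` objects.
#' @export
build_strategies <- function(size = 256L, pad = size %/% 8L) {
  size <- as.integer(size)
  st <- function(name, ...) structure(list(name = name, size = size, ...),
                                      class = "aug_strategy")
  list(
    st("Rz"),
    st("RC+Rz", crop = size %/% 2L),
    st("VF+Rz", p = 0.3),
    st("HF+Rz", p = 0.3),
    st("ROT+Rz", p = 0.3, limit = 30),
    st("CMB", crop = size %/% 2L, p = 0.3, limit = 30),
    st("RRC+Rz", scale = c(1.2, 1.4)),
    st("PAD+RC+Rz", pad = as.integer(pad)),
    st("RB+ET+GN+GB", p = 0.5, bc_limit = 0.2, et_alpha = 1, et_sigma = 50,
       noise_var = c(10, 50), blur_limit = c(3L, 7L))
  )
}

#' @export
print.aug_strategy <- function(x, ...) {
  cat("<aug_strategy>", x$name, "size", x$size, "\n")
  invisible(x)
}

rand_crop_pair <- function(img, lab, ch, cw) {
  y0 <- sample.int(nrow(img) - ch + 1L, 1L)
  x0 <- sample.int(ncol(img) - cw + 1L, 1L)
  list(image = crop_at(img, y0, x0, ch, cw), lab = crop_at(lab, y0, x0, ch, cw))
}

#' Apply one augmentation strategy to a sample
#'
#' Deterministic given `(seed, sample id, strategy name)`. Geometric
#' operations transform image and label map identically; intensity
#' operations leave the labels untouched. Output is always
#' `size x size`.
#'
#' @param sample An [image_sample()].
#' @param strategy One element of [build_strategies()].
#' @param seed Integer seed.
#' @return The augmented [image_sample()], id suffixed with the strategy
#'   name.
#' @export
apply_strategy <- function(sample, strategy, seed = 1L) {
  stopifnot(inherits(strategy, "aug_strategy"))
  S <- strategy$size
  if (!is.null(strategy$crop) && strategy$crop > S)
    stop("crop size exceeds the resized image")
  with_seed(child_seed(seed, sample$id, strategy$name), {
    p <- resize_pair(sample$image, unclass(sample$label_map), S, S)
    img <- p$image; lab <- p$lab
    switch(strategy$name,
      "Rz" = NULL,
      "RC+Rz" = {
        rc <- rand_crop_pair(img, lab, strategy$crop, strategy$crop)
        rp <- resize_pair(rc$image, rc$lab, S, S)
        img <- rp$image; lab <- rp$lab
      },
      "VF+Rz" = if (stats::runif(1) < strategy$p) {
        img <- img[S:1L, , drop = FALSE]; lab <- lab[S:1L, , drop = FALSE]
      },
      "HF+Rz" = if (stats::runif(1) < strategy$p) {
        img <- img[, S:1L, drop = FALSE]; lab <- lab[, S:1L, drop = FALSE]
      },
      "ROT+Rz" = if (stats::runif(1) < strategy$p) {
        ang <- stats::runif(1, -strategy$limit, strategy$limit)
        img <- rotate_mat(img, ang)
        lab <- matrix(as.integer(round(rotate_mat(lab, ang, nearest = TRUE))), S, S)
      },
      "CMB" = {
        rc <- rand_crop_pair(img, lab, strategy$crop, strategy$crop)
        rp <- resize_pair(rc$image, rc$lab, S, S)
        img <- rp$image; lab <- rp$lab
        if (stats::runif(1) < strategy$p) {
          img <- img[S:1L, , drop = FALSE]; lab <- lab[S:1L, , drop = FALSE]
        }
        if (stats::runif(1) < strategy$p) {
          img <- img[, S:1L, drop = FALSE]; lab <- lab[, S:1L, drop = FALSE]
        }
        if (stats::runif(1) < strategy$p) {
          ang <- stats::runif(1, -strategy$limit, strategy$limit)
          img <- rotate_mat(img, ang)
          lab <- matrix(as.integer(round(rotate_mat(lab, ang, nearest = TRUE))), S, S)
        }
      },
      "RRC+Rz" = {
        sc <- stats::runif(1, strategy$scale[1], strategy$scale[2])
        hs <- as.integer(round(S * sc))
        rp <- resize_pair(img, lab, hs, hs)
        rc <- rand_crop_pair(rp$image, rp$lab, S, S)
        img <- rc$image; lab <- rc$lab
      },
      "PAD+RC+Rz" = {
        pi_ <- reflect_pad(img, strategy$pad)
        pl <- reflect_pad(lab, strategy$pad)
        rc <- rand_crop_pair(pi_, pl, S, S)
        img <- rc$image; lab <- rc$lab
      },
      "RB+ET+GN+GB" = {
        if (stats::runif(1) < strategy$p) {              # brightness/contrast
          alpha <- 1 + stats::runif(1, -strategy$bc_limit, strategy$bc_limit)
          beta <- stats::runif(1, -strategy$bc_limit, strategy$bc_limit)
          img <- img * alpha + beta
        }
        if (stats::runif(1) < strategy$p) {              # elastic transform
          dy <- gauss_smooth(matrix(stats::runif(S * S, -1, 1), S, S),
                             strategy$et_sigma) * strategy$et_alpha
          dx <- gauss_smooth(matrix(stats::runif(S * S, -1, 1), S, S),
                             strategy$et_sigma) * strategy$et_alpha
          img <- remap(img, dy, dx)
          lab <- matrix(as.integer(remap(lab, dy, dx, nearest = TRUE)), S, S)
        }
        if (stats::runif(1) < strategy$p) {              # Gaussian noise
          v <- stats::runif(1, strategy$noise_var[1], strategy$noise_var[2])
          img <- img + matrix(stats::rnorm(S * S, 0, sqrt(v) / 255), S, S)
        }
        if (stats::runif(1) < strategy$p) {              # Gaussian blur
          k <- sample(seq(strategy$blur_limit[1], strategy$blur_limit[2], by = 2L), 1L)
          img <- gauss_smooth(img, 0.3 * ((k - 1) * 0.5 - 1) + 0.8)
        }
      },
      stop("unknown strategy: ", strategy$name)
    )
    img <- pmin(pmax(img, 0), 1)
    image_sample(img, label_map(lab, attr(sample$label_map, "n_classes") %||% 4L),
                 id = paste0(sample$id, "__", strategy$name))
  })
}

#' Augment a dataset with all nine strategies
#'
#' Each strategy emits exactly one output per input, so the result has
#' `9 * length(samples)` samples (2,299 training images expand to 20,691).
#' Validation data should never be routed through this function; the
#' pipeline enforces that.
#'
#' @param samples List of [image_sample()] objects.
#' @param seed Integer seed; the whole augmented set is deterministic
#'   given it.
#' @param strategies Strategy list; defaults to [build_strategies()] at
#'   the first sample's height.
#' @return List of augmented samples, grouped by source sample.
#' @export
augment_dataset <- function(samples, seed = 1L, strategies = NULL) {
  if (length(samples) == 0L) return(list())
  if (is.null(strategies)) strategies <- build_strategies(nrow(samples[[1L]]$image))
  out <- vector("list", length(samples) * length(strategies))
  k <- 0L
  for (s in samples) {
    for (st in strategies) {
      k <- k + 1L
      out[[k]] <- apply_strategy(s, st, seed = seed)
    }
  }
  out
}
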