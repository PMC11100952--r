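#' Parameters of the fetal-head phantom generator
#'
#' The phantom emulates the structure of a trans-thalamic/trans-ventricular
#' fetal head ultrasound plane: a dark background, one dominant bright
#' elliptical "brain" region, and two small darker (fluid-filled)
#' rectangles for the CSP (near the midline) and the LV (lateral), both
#' strictly inside the ellipse, the whole image degraded by multiplicative
#' speckle noise. Class pixel counts are guaranteed to satisfy
#' background > brain > each of CSP/LV, reproducing the class imbalance
#' that motivates inverse-frequency weighting.
#'
#' Size-dependent defaults (semi-axes, rectangle sizes) are derived from
#' `min(height, width)` so phantoms remain well-formed at reduced
#' resolutions.
#'
#' @param height,width Image size in pixels (default 256 x 256, the
#'   working resolution of the study conditions).
#' @param brain_axes_range Length-2 integer range for the ellipse
#'   semi-axes (pixels). The upper end keeps the ellipse under half the
#'   image area so background always dominates.
#' @param csp_size_range,lv_size_range Length-2 integer ranges for the
#'   rectangle side lengths (pixels).
#' @param include_csp,include_lv Whether the CSP / LV structures are
#'   present (both absent emulates a first-trimester plane, where these
#'   structures are not yet visible).
#' @param speckle_variance Variance of the multiplicative Gaussian speckle
#'   field (intensity units squared).
#' @param seed Integer seed; together with the sample index it fully
#'   determines each phantom.
#' @return A list of class `"phantom_params"`.
#' @export
phantom_params <- function(height = 256L, width = 256L,
                           brain_axes_range = NULL,
                           csp_size_range = NULL,
                           lv_size_range = NULL,
                           include_csp = TRUE, include_lv = TRUE,
                           speckle_variance = 0.02,
                           seed = 1L) {
  m <- min(height, width)
  if (m < 16L) stop("phantom images must be at least 16 pixels")
  if (is.null(brain_axes_range)) brain_axes_range <- round(m * c(0.27, 0.38))
  if (is.null(csp_size_range))   csp_size_range <- pmax(1L, round(m * c(0.030, 0.055)))
  if (is.null(lv_size_range))    lv_size_range <- pmax(1L, round(m * c(0.040, 0.070)))
  stopifnot(speckle_variance >= 0, length(brain_axes_range) == 2L)
  if (max(brain_axes_range)^2 * pi >= 0.5 * height * width)
    stop("brain_axes_range too large: ellipse could cover half the image")
  structure(list(height = as.integer(height), width = as.integer(width),
                 brain_axes_range = brain_axes_range,
                 csp_size_range = csp_size_range,
                 lv_size_range = lv_size_range,
                 include_csp = isTRUE(include_csp),
                 include_lv = isTRUE(include_lv),
                 speckle_variance = speckle_variance,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Try to place an axis-aligned wxh rectangle with centre (cy,cx) offset from
# the ellipse centre so that all corners lie inside the shrunken ellipse.
place_rect <- function(cy0, cx0, a, b, w, h, x_shift_frac, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    dx <- round(a * stats::runif(1, x_shift_frac[1], x_shift_frac[2])) *
      sample(c(-1L, 1L), 1L)
    dy <- round(b * stats::runif(1, -0.25, 0.25))
    cy <- cy0 + dy; cx <- cx0 + dx
    ys <- c(cy - h %/% 2, cy - h %/% 2 + h - 1L)
    xs <- c(cx - w %/% 2, cx - w %/% 2 + w - 1L)
    corners_in <- all(outer(ys - cy0, xs - cx0,
                            function(y, x) (x / a)^2 + (y / b)^2) < 0.8^2)
    if (corners_in) return(list(y = ys[1L]:ys[2L], x = xs[1L]:xs[2L]))
  }
  stop("could not place structure rectangle inside the brain ellipse")
}

#' Generate one phantom sample
#'
#' Deterministic given `(params$seed, index)`.
#'
#' @param params A [phantom_params()].
#' @param index Non-negative sample index.
#' @return An [image_sample()] whose label map uses classes 0 (background),
#'   1 (brain), and when enabled 2 (CSP) and 3 (LV).
#' @export
generate_phantom <- function(params, index = 0L) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(child_seed(params$seed, "phantom", index), {
    h <- params$height; w <- params$width
    ar <- params$brain_axes_range
    a <- round(stats::runif(1, ar[1], ar[2]))   # x semi-axis
    b <- round(stats::runif(1, ar[1], ar[2]))   # y semi-axis
    jit <- round(0.04 * min(h, w))
    cy <- h %/% 2 + sample(-jit:jit, 1L)
    cx <- w %/% 2 + sample(-jit:jit, 1L)

    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    inside <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1

    lab <- matrix(0L, h, w)
    lab[inside] <- 1L
    img <- matrix(0.15, h, w)
    img[inside] <- 0.65

    if (params$include_csp) {
      sz <- params$csp_size_range
      rw <- round(stats::runif(1, sz[1], sz[2]))
      rh <- round(stats::runif(1, sz[1], sz[2]))
      r <- place_rect(cy, cx, a, b, rw, rh, x_shift_frac = c(0, 0.10))
      lab[r$y, r$x] <- 2L
      img[r$y, r$x] <- 0.35
    }
    if (params$include_lv) {
      sz <- params$lv_size_range
      rw <- round(stats::runif(1, sz[1], sz[2]))
      rh <- round(stats::runif(1, sz[1], sz[2]))
      r <- place_rect(cy, cx, a, b, rw, rh, x_shift_frac = c(0.35, 0.60))
      lab[r$y, r$x] <- 3L
      img[r$y, r$x] <- 0.30
    }

    if (params$speckle_variance > 0) {
      speckle <- matrix(stats::rnorm(h * w, 0, sqrt(params$speckle_variance)), h, w)
      img <- img * (1 + speckle)
    }
    img <- pmin(pmax(img, 0), 1)

    image_sample(img, label_map(lab, 4L),
                 id = sprintf("phantom_%05d", as.integer(index)))
  })
}

#' Generate a phantom dataset
#'
#' A configurable fraction of the samples (default 20%) is generated with
#' CSP and LV absent, emulating first-trimester planes where those
#' structures are not yet visible. Which samples lack them is a
#' deterministic function of the seed.
#'
#' @param n Number of samples (>= 0).
#' @param params A [phantom_params()].
#' @param absent_frac Fraction of samples generated without CSP/LV.
#' @return List of `n` [image_sample()] objects with indices `0..n-1`.
#' @export
generate_dataset <- function(n, params = phantom_params(), absent_frac = 0.2) {
  if (n < 0) stop("n must be non-negative")
  n <- as.integer(n)
  if (n == 0L) return(list())
  n_absent <- floor(n * absent_frac)
  absent_idx <- with_seed(child_seed(params$seed, "absent"),
                          sample(seq_len(n), n_absent))
  lapply(seq_len(n), function(i) {
    p <- params
    if (i %in% absent_idx) {
      p$include_csp <- FALSE
      p$include_lv <- FALSE
    }
    generate_phantom(p, index = i - 1L)
  })
}

#' Train/validation/test split fractions
#'
#' @param train,val,test Fractions in (0, 1) summing to 1. The default
#'   0.6/0.2/0.2 is the study's split.
#' @return A list of class `"split_fractions"`.
#' @export
split_fractions <- function(train = 0.6, val = 0.2, test = 0.2) {
  f <- c(train = train, val = val, test = test)
  if (any(f <= 0) || any(f >= 1))
    stop("each split fraction must lie in (0, 1)")
  if (abs(sum(f) - 1) > 1e-8)
    stop("split fractions must sum to 1")
  structure(as.list(f), class = "split_fractions")
}

#' Split a dataset into train/validation/test
#'
#' Counts follow the floor-then-remainder rule: `train = floor(n * f_train)`,
#' `val = floor(n * f_val)`, and the test set absorbs the remainder. At
#' n = 3832 with 0.6/0.2/0.2 this yields 2299/766/767 — the one odd image
#' lands in the test split. Assignment of individual items is a
#' deterministic shuffle under `seed`; with `seed = NULL` items are
#' assigned in order.
#'
#' @param n Number of items (>= 0).
#' @param fractions A [split_fractions()].
#' @param seed Optional integer seed for the shuffle.
#' @return A list with `counts` (named integer vector train/val/test) and
#'   `assignment` (character vector of length `n` in item order).
#' @export
split_dataset <- function(n, fractions = split_fractions(), seed = NULL) {
  if (!inherits(fractions, "split_fractions"))
    stop("fractions must be a split_fractions() object")
  if (n < 0) stop("n must be non-negative")
  n <- as.integer(n)
  n_train <- as.integer(floor(n * fractions$train))
  n_val <- as.integer(floor(n * fractions$val))
  n_test <- n - n_train - n_val
  counts <- c(train = n_train, val = n_val, test = n_test)
  ord <- if (is.null(seed)) seq_len(n) else
    with_seed(child_seed(seed, "split"), sample.int(n))
  assignment <- character(n)
  assignment[ord] <- rep(c("train", "val", "test"), times = counts)
  list(counts = counts, assignment = assignment)
}
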