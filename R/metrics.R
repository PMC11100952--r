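# DSC / Hausdorff / average surface distance evaluation. Distances are
# Euclidean in pixel units. Border points of a class region are its pixels
# with at least one 4-neighbour outside the region or lying on the image
# edge. Empty-set conventions (both class regions empty -> DSC 1, HD 0,
# ASD 0; exactly one empty -> DSC 0, HD and ASD equal to the image
# diagonal) keep every metric finite and monotone.

class_pixels <- function(map, class_index) {
  which(unclass(map) == class_index, arr.ind = TRUE)
}

#' Border points of a class region
#'
#' @param map A [label_map()].
#' @param class_index 0-based class index.
#' @return Integer matrix of (row, col) border pixel coordinates
#'   (1-based), possibly with zero rows.
#' @export
boundary_points <- function(map, class_index) {
  m <- unclass(map)
  h <- nrow(m); w <- ncol(m)
  inside <- m == class_index
  if (!any(inside)) return(matrix(integer(0), 0, 2))
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- inside
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  nb_all <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(core & !nb_all, arr.ind = TRUE)
}

cross_dist <- function(a, b) {
  # all pairwise Euclidean distances between two (n x 2) point matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

check_maps <- function(pred, truth) {
  if (!identical(dim(unclass(pred)), dim(unclass(truth))))
    stop("pred and truth label maps must share dimensions")
}

diag_len <- function(map) {
  d <- dim(unclass(map)); sqrt((d[1] - 1)^2 + (d[2] - 1)^2)
}

#' Dice similarity coefficient for one class
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)` on the class's pixel
#' sets; 1 when both sets are empty.
#'
#' @param pred,truth [label_map()]s of identical size.
#' @param class_index 0-based class index.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(pred, truth, class_index) {
  check_maps(pred, truth)
  a <- unclass(pred) == class_index
  b <- unclass(truth) == class_index
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Hausdorff distance between two class boundaries
#'
#' The maximum of the two directed Hausdorff distances between the border
#' point sets, in Euclidean pixel units.
#'
#' @inheritParams dsc
#' @return Non-negative distance; 0 when both regions are empty, the
#'   image diagonal when exactly one is.
#' @export
hausdorff <- function(pred, truth, class_index) {
  check_maps(pred, truth)
  a <- boundary_points(pred, class_index)
  b <- boundary_points(truth, class_index)
  if (nrow(a) == 0L && nrow(b) == 0L) return(0)
  if (nrow(a) == 0L || nrow(b) == 0L) return(diag_len(pred))
  d <- cross_dist(a, b)
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

#' Average surface distance between two class boundaries
#'
#' Directed by default: the mean distance from each predicted border
#' point to its nearest truth border point. `symmetric = TRUE` averages
#' the two directed means.
#'
#' @inheritParams dsc
#' @param symmetric Average both directions instead of prediction ->
#'   truth only.
#' @return Non-negative distance; conventions as in [hausdorff()].
#' @export
asd <- function(pred, truth, class_index, symmetric = FALSE) {
  check_maps(pred, truth)
  a <- boundary_points(pred, class_index)
  b <- boundary_points(truth, class_index)
  if (nrow(a) == 0L && nrow(b) == 0L) return(0)
  if (nrow(a) == 0L || nrow(b) == 0L) return(diag_len(pred))
  d <- cross_dist(a, b)
  fwd <- mean(apply(d, 1, min))
  if (!symmetric) return(fwd)
  (fwd + mean(apply(d, 2, min))) / 2
}

#' Evaluate a predicted label map against ground truth
#'
#' Computes DSC, HD and ASD separately for every class (background
#' included) and their unweighted arithmetic means — the aggregation
#' under which the four per-class FetSAM scores average to the headline
#' 0.90117 / 1.86484 / 0.46645 triple.
#'
#' @param pred,truth [label_map()]s of identical size.
#' @param schema A [label_schema()].
#' @param symmetric_asd Use the symmetric ASD variant.
#' @return An object of class `"eval_report"`: a data frame with columns
#'   `class`, `dsc`, `hd`, `asd`, one row per class plus a final `mean`
#'   row.
#' @export
evaluate <- function(pred, truth, schema = label_schema(),
                     symmetric_asd = FALSE) {
  check_maps(pred, truth)
  C <- schema$n_classes
  rows <- lapply(seq_len(C) - 1L, function(ci) {
    data.frame(class = schema$class_names[ci + 1L],
               dsc = dsc(pred, truth, ci),
               hd = hausdorff(pred, truth, ci),
               asd = asd(pred, truth, ci, symmetric = symmetric_asd))
  })
  aggregate_mean(do.call(rbind, rows))
}

#' Append the unweighted mean row to per-class metrics
#'
#' The aggregation convention of the comparison tables: the `mean` row is
#' the unweighted arithmetic average of the per-class values, background
#' included.
#'
#' @param per_class Data frame with columns `class`, `dsc`, `hd`, `asd`,
#'   one row per class.
#' @return An `"eval_report"`: `per_class` plus a final `mean` row.
#' @export
aggregate_mean <- function(per_class) {
  stopifnot(all(c("class", "dsc", "hd", "asd") %in% names(per_class)),
            !"mean" %in% per_class$class)
  out <- rbind(per_class,
               data.frame(class = "mean", dsc = mean(per_class$dsc),
                          hd = mean(per_class$hd), asd = mean(per_class$asd)))
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Average several evaluation reports
#'
#' Unweighted elementwise mean over reports sharing a schema — the
#' convention used to aggregate per-sample reports into a dataset-level
#' table row.
#'
#' @param reports List of `"eval_report"` objects.
#' @return One `"eval_report"`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) > 0)
  out <- reports[[1L]]
  for (col in c("dsc", "hd", "asd"))
    out[[col]] <- rowMeans(sapply(reports, function(r) r[[col]]))
  out
}

#' Lay out evaluation reports as a wide comparison table
#'
#' One row per model; for every class (and the mean) three columns
#' `<class>_DSC`, `<class>_HD`, `<class>_ASD`, rounded half-even to five
#' decimals — the layout of the model-comparison tables.
#'
#' @param reports Named list (model name -> `"eval_report"`).
#' @param digits Rounding digits (default 5).
#' @return A data frame with a `model` column and 3 x (C + 1) numeric
#'   columns.
#' @export
report_table <- function(reports, digits = 5L) {
  stopifnot(length(reports) > 0, !is.null(names(reports)))
  classes <- reports[[1L]]$class
  for (r in reports)
    if (!identical(r$class, classes)) stop("reports use inconsistent schemas")
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    vals <- as.vector(t(as.matrix(r[, c("dsc", "hd", "asd")])))
    df <- as.data.frame(as.list(round(vals, digits)))
    names(df) <- paste0(rep(r$class, each = 3L), "_", c("DSC", "HD", "ASD"))
    cbind(data.frame(model = nm), df)
  })
  do.call(rbind, rows)
}

#' Write / read a comparison table as CSV
#'
#' `read_report_csv(write_report_csv(x))` round-trips the rounded table.
#'
#' @param table A [report_table()] data frame.
#' @param path CSV file path.
#' @return `path` invisibly; the parsed data frame for the reader.
#' @export
write_report_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
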