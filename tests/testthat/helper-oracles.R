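# Independent brute-force oracles: coded from the set-level definitions
# with explicit loops / set operations, deliberately sharing no code with
# the implementation they check.

# random small label map
rand_map <- function(h, w, C = 4L) {
  label_map(matrix(sample(0:(C - 1L), h * w, replace = TRUE), h, w), C)
}

# random probability map (softmax of Gaussian logits)
rand_prob <- function(C, h, w) {
  z <- array(rnorm(C * h * w), dim = c(C, h, w))
  e <- exp(z)
  s <- apply(e, c(2, 3), sum)
  for (ci in seq_len(C)) e[ci, , ] <- e[ci, , ] / s
  e
}

oracle_dsc <- function(pred, truth, ci) {
  A <- which(unclass(pred) == ci)
  B <- which(unclass(truth) == ci)
  if (length(A) + length(B) == 0L) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

# border points by per-pixel 4-neighbour scan
oracle_border <- function(map, ci) {
  m <- unclass(map)
  h <- nrow(m); w <- ncol(m)
  pts <- NULL
  for (y in seq_len(h)) for (x in seq_len(w)) {
    if (m[y, x] != ci) next
    edge <- y == 1L || y == h || x == 1L || x == w
    nb_out <- (y > 1L && m[y - 1L, x] != ci) || (y < h && m[y + 1L, x] != ci) ||
      (x > 1L && m[y, x - 1L] != ci) || (x < w && m[y, x + 1L] != ci)
    if (edge || nb_out) pts <- rbind(pts, c(y, x))
  }
  if (is.null(pts)) matrix(integer(0), 0, 2) else pts
}

oracle_min_dists <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    min(vapply(seq_len(nrow(b)), function(j)
      sqrt(sum((a[i, ] - b[j, ])^2)), numeric(1)))
  }, numeric(1))
}

oracle_hd <- function(pred, truth, ci) {
  a <- oracle_border(pred, ci); b <- oracle_border(truth, ci)
  if (nrow(a) == 0L && nrow(b) == 0L) return(0)
  dg <- sqrt((nrow(unclass(pred)) - 1)^2 + (ncol(unclass(pred)) - 1)^2)
  if (nrow(a) == 0L || nrow(b) == 0L) return(dg)
  max(max(oracle_min_dists(a, b)), max(oracle_min_dists(b, a)))
}

oracle_asd <- function(pred, truth, ci) {
  a <- oracle_border(pred, ci); b <- oracle_border(truth, ci)
  if (nrow(a) == 0L && nrow(b) == 0L) return(0)
  dg <- sqrt((nrow(unclass(pred)) - 1)^2 + (ncol(unclass(pred)) - 1)^2)
  if (nrow(a) == 0L || nrow(b) == 0L) return(dg)
  mean(oracle_min_dists(a, b))
}

# Lovasz extension via its prefix-set definition: sort errors descending,
# L = sum_k e_k (F(S_k) - F(S_{k-1})) where S_k is the top-k pixel set and
# F(S) = 1 - |G \ S| / |G union S| is the Jaccard loss set function.
oracle_lovasz_ext <- function(fg, prob) {
  e <- abs(fg - prob)
  ord <- order(e, decreasing = TRUE)
  G <- which(fg == 1)
  Fset <- function(S) {
    if (length(union(G, S)) == 0L) return(0)
    1 - length(setdiff(G, S)) / length(union(G, S))
  }
  tot <- 0
  prev <- Fset(integer(0))
  for (k in seq_along(ord)) {
    cur <- Fset(ord[seq_len(k)])
    tot <- tot + e[ord[k]] * (cur - prev)
    prev <- cur
  }
  tot
}

# per-class 1 - IoU at a binary vertex; empty union -> 0
oracle_jaccard_loss <- function(pred_lab, truth_lab, ci) {
  P <- which(unclass(pred_lab) == ci)
  G <- which(unclass(truth_lab) == ci)
  if (length(union(P, G)) == 0L) return(0)
  1 - length(intersect(P, G)) / length(union(P, G))
}

# step-by-step transcription of the class-weight procedure
oracle_weights <- function(counts, min_w = 0.1, max_w = 0.9) {
  counts <- as.numeric(counts)
  total <- sum(counts)
  cw <- total / counts
  cw <- cw / sum(cw)
  if (max(cw) == min(cw)) return(rep((min_w + max_w) / 2, length(counts)))
  (cw - min(cw)) / (max(cw) - min(cw)) * (max_w - min_w) + min_w
}

# exhaustive pixel scan for prompt-box tightness at offset 0
oracle_box <- function(oh_channel, threshold = 0.5) {
  act <- which(oh_channel > threshold, arr.ind = TRUE)
  if (nrow(act) == 0L) return(c(0L, 0L, 0L, 0L))
  c(min(act[, 2]) - 1L, min(act[, 1]) - 1L, max(act[, 2]) - 1L, max(act[, 1]) - 1L)
}

# bare integer matrix of a label map (class/attrs stripped)
lab_mat <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

box_contains <- function(outer, inner) {
  all(outer[1:2] <= inner[1:2]) && all(outer[3:4] >= inner[3:4])
}

small_phantoms <- function(n, seed = 42, size = 48) {
  generate_dataset(n, phantom_params(size, size, seed = seed))
}
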