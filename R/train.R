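# Training harness: AdamW (decoupled weight decay) with a MultiStepLR
# schedule and early stopping on validation combined loss, around the
# surrogate segmenter. Prompts are derived from the ground-truth masks,
# as in prompted-segmentation fine-tuning.

#' Training configuration
#'
#' Defaults follow the study's optimiser setup: AdamW with learning rate
#' and weight decay both 1e-4, MultiStepLR milestones at epochs 10/20/30
#' with gamma 0.7, and early stopping with a patience of 5 epochs on the
#' validation combined loss.
#'
#' @param learning_rate Base learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param lr_milestones Strictly increasing epochs at which the rate
#'   drops.
#' @param lr_gamma Multiplicative decay per milestone.
#' @param early_stop_patience Epochs without validation improvement
#'   before stopping.
#' @param min_delta Minimum decrease of validation loss that counts as an
#'   improvement.
#' @param max_epochs Maximum training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Seed for shuffling and initialisation.
#' @param loss A [loss_config()].
#' @param prompt A [prompt_config()] used to derive training prompts.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                         lr_milestones = c(10L, 20L, 30L), lr_gamma = 0.7,
                         early_stop_patience = 5L, min_delta = 0,
                         max_epochs = 40L, batch_size = 8L, seed = 1L,
                         loss = loss_config(), prompt = prompt_config()) {
  stopifnot(learning_rate > 0, weight_decay >= 0, lr_gamma > 0,
            early_stop_patience >= 1, max_epochs >= 1, batch_size >= 1)
  if (is.unsorted(lr_milestones, strictly = TRUE))
    stop("lr_milestones must be strictly increasing")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_milestones = as.integer(lr_milestones),
                 lr_gamma = lr_gamma,
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss, prompt = prompt),
            class = "train_config")
}

#' Learning rate at a given epoch under the multi-step schedule
#'
#' `base_lr * gamma^k` where `k` is the number of milestones `<= epoch`.
#'
#' @param epoch 0-based epoch index.
#' @param config A [train_config()].
#' @return The learning rate.
#' @examples
#' lr_schedule(0, train_config())   # 1e-4
#' lr_schedule(10, train_config())  # 0.7e-4
#' @export
lr_schedule <- function(epoch, config = train_config()) {
  stopifnot(epoch >= 0)
  config$learning_rate * config$lr_gamma^sum(config$lr_milestones <= epoch)
}

# Gradient of the combined loss w.r.t. the softmax probabilities (C x N).
combined_loss_grad_p <- function(P, Y, cfg) {
  w <- cfg$class_weights
  C <- nrow(P)
  G <- matrix(0, C, ncol(P))
  if (cfg$alpha > 0) {                     # entry-weighted Dice term
    S1 <- sum(Y * P * w)
    S2 <- sum((Y + P) * w)
    eps <- cfg$epsilon
    Gd <- -((2 * Y * (S2 + eps) - (2 * S1 + eps)) * w) / (S2 + eps)^2
    G <- G + cfg$alpha * Gd
  }
  if (cfg$beta > 0) {                      # Lovasz term (fixed permutation)
    sw <- sum(w)
    for (ci in seq_len(C)) {
      y <- Y[ci, ]; p <- P[ci, ]
      e <- abs(y - p)
      ord <- order(e, decreasing = TRUE)
      g <- lovasz_grad(y[ord])
      gp <- numeric(length(e))
      gp[ord] <- g
      G[ci, ] <- G[ci, ] + cfg$beta * w[ci] * (1 - 2 * y) * gp / sw
    }
  }
  G
}

# Loss and weight gradient of the surrogate on one sample.
surrogate_loss_grad <- function(model, sample, cfg, prompt_cfg) {
  boxes <- boxes_from_label_map(sample$label_map, prompt_cfg, model$n_classes)
  X <- surrogate_features(sample$image, boxes)
  P <- softmax_cols(model$W %*% X)
  Y <- matrix(unclass(encode_one_hot(sample$label_map, model$n_classes)),
              nrow = model$n_classes)
  d <- c(model$n_classes, dim(sample$image))
  lv <- combined_loss(array(P, d), array(Y, d), cfg)
  G <- combined_loss_grad_p(P, Y, cfg)
  s <- colSums(P * G)
  dZ <- P * sweep(G, 2, s)                 # softmax backward
  list(loss = lv$total, grad = dZ %*% t(X))
}

surrogate_val_loss <- function(model, samples, cfg, prompt_cfg) {
  mean(vapply(samples, function(s) {
    boxes <- boxes_from_label_map(s$label_map, prompt_cfg, model$n_classes)
    pred <- predict_segmenter(model, s$image, boxes)
    combined_loss(pred, unclass(encode_one_hot(s$label_map, model$n_classes)),
                  cfg)$total
  }, numeric(1)))
}

#' Train the surrogate segmenter
#'
#' Mini-batch AdamW on the combined weighted Dice + Lovasz loss with the
#' multi-step learning-rate schedule; training halts once the validation
#' combined loss has not improved for `early_stop_patience` consecutive
#' epochs, and the returned model is the state from the best validation
#' epoch. Fully deterministic given the config seed.
#'
#' @param model A [surrogate_segmenter()].
#' @param train_set,val_set Disjoint lists of [image_sample()]s; the
#'   validation set must never be augmented.
#' @param config A [train_config()].
#' @return A list of class `"train_result"`: `model` (best state), `log`
#'   (data frame epoch/lr/train_loss/val_loss; epoch 0 is the untrained
#'   baseline), `best_epoch`, `best_val_loss`, `stopped_early`.
#' @export
train <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "surrogate_segmenter"),
            inherits(config, "train_config"))
  if (length(train_set) == 0L || length(val_set) == 0L)
    stop("train and validation sets must be non-empty")
  cfg <- config$loss
  pc <- config$prompt

  mW <- model$W * 0; vW <- mW; tstep <- 0
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  log_rows <- list()
  val0 <- surrogate_val_loss(model, val_set, cfg, pc)
  log_rows[[1L]] <- data.frame(epoch = 0L, lr = NA_real_,
                               train_loss = NA_real_, val_loss = val0)
  best <- list(model = model, val = val0, epoch = 0L)
  bad_epochs <- 0L
  stopped_early <- FALSE

  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_schedule(epoch - 1L, config)
    ord <- with_seed(child_seed(config$seed, "shuffle", epoch),
                     sample.int(length(train_set)))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      gsum <- model$W * 0; lsum <- 0
      for (i in b) {
        lg <- surrogate_loss_grad(model, train_set[[i]], cfg, pc)
        gsum <- gsum + lg$grad
        lsum <- lsum + lg$loss
      }
      grad <- gsum / length(b)
      tstep <- tstep + 1
      mW <- beta1 * mW + (1 - beta1) * grad
      vW <- beta2 * vW + (1 - beta2) * grad^2
      mhat <- mW / (1 - beta1^tstep)
      vhat <- vW / (1 - beta2^tstep)
      model$W <- model$W - lr * (mhat / (sqrt(vhat) + adam_eps) +
                                   config$weight_decay * model$W)
      ep_loss <- ep_loss + lsum
    }
    if (!is.finite(ep_loss)) stop("non-finite training loss at epoch ", epoch)
    val <- surrogate_val_loss(model, val_set, cfg, pc)
    log_rows[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                         train_loss = ep_loss / length(train_set),
                                         val_loss = val)
    if (val < best$val - config$min_delta) {
      best <- list(model = model, val = val, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$early_stop_patience) {
        stopped_early <- TRUE
        break
      }
    }
  }

  structure(list(model = best$model, log = do.call(rbind, log_rows),
                 best_epoch = best$epoch, best_val_loss = best$val,
                 stopped_early = stopped_early),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs run, best val loss %.5f at epoch %d%s\n",
              max(x$log$epoch), x$best_val_loss, x$best_epoch,
              if (x$stopped_early) " (early stop)" else ""))
  invisible(x)
}

#' Evaluate a segmenter over a dataset
#'
#' Derives prompt boxes from each sample's ground truth, predicts,
#' argmax-decodes and evaluates; per-sample reports are averaged
#' elementwise.
#'
#' @param model A segmenter.
#' @param samples List of [image_sample()]s.
#' @param config A [prompt_config()].
#' @param schema A [label_schema()].
#' @return An `"eval_report"` averaged over the dataset.
#' @export
evaluate_segmenter <- function(model, samples, config = prompt_config(),
                               schema = label_schema()) {
  reports <- lapply(samples, function(s) {
    boxes <- boxes_from_label_map(s$label_map, config, schema$n_classes)
    pred <- predict_segmenter(model, s$image, boxes, truth = s$label_map)
    evaluate(decode_argmax(pred), s$label_map, schema)
  })
  aggregate_reports(reports)
}

#' Prompt-offset ablation
#'
#' Re-derives the prompt boxes at each offset and evaluates the same
#' (fixed) segmenter, mirroring the prompt-size sensitivity study at
#' offsets 0, 10 and 20.
#'
#' @param model A segmenter (trained surrogate or oracle).
#' @param samples Evaluation samples.
#' @param offsets Integer vector of box offsets.
#' @param schema A [label_schema()].
#' @return Named list (offset -> `"eval_report"`).
#' @export
ablate_prompts <- function(model, samples, offsets = c(0L, 10L, 20L),
                           schema = label_schema()) {
  stats::setNames(lapply(offsets, function(off)
    evaluate_segmenter(model, samples, prompt_config(offset = off), schema)),
    as.character(offsets))
}

#' Loss-function ablation
#'
#' Trains one fresh surrogate per loss variant — Dice only (alpha 1,
#' beta 0), Lovasz only (alpha 0, beta 1) and the combined loss (both
#' 0.5) — under a shared seed and evaluates each on the same validation
#' set.
#'
#' @param train_set,val_set Sample lists.
#' @param config Base [train_config()]; its `loss` supplies the class
#'   weights.
#' @param variants Subset of `c("dice", "lovasz", "combined")`.
#' @param schema A [label_schema()].
#' @return Named list (variant -> `"eval_report"`).
#' @export
ablate_losses <- function(train_set, val_set, config = train_config(),
                          variants = c("dice", "lovasz", "combined"),
                          schema = label_schema()) {
  mix <- list(dice = c(1, 0), lovasz = c(0, 1), combined = c(0.5, 0.5))
  out <- list()
  for (v in match.arg(variants, several.ok = TRUE)) {
    cfg <- config
    cfg$loss$alpha <- mix[[v]][1L]
    cfg$loss$beta <- mix[[v]][2L]
    model <- surrogate_segmenter(schema$n_classes, seed = config$seed)
    fit <- train(model, train_set, val_set, cfg)
    out[[v]] <- evaluate_segmenter(fit$model, val_set, config$prompt, schema)
  }
  out
}
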