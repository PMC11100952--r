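# End-to-end pipeline: phantom generation -> split -> augmentation of the
# training split (validation is never augmented) -> class weights ->
# surrogate training -> evaluation and prompt ablation, with one seed
# governing every stochastic stage and the resolved configuration
# serialized into the run directory.

#' Pipeline run configuration
#'
#' @param seed Global seed; every stage derives its own child seed from
#'   it.
#' @param n_phantoms Number of phantom samples to generate.
#' @param size Image side in pixels.
#' @param absent_frac Fraction of phantoms without CSP/LV.
#' @param fractions A [split_fractions()].
#' @param val_augment Must be `FALSE`: the validation split is left
#'   unaugmented by design, and a config requesting otherwise is
#'   rejected.
#' @param min_weight,max_weight Class-weight smoothing range.
#' @param max_epochs,batch_size Training-stage settings.
#' @param offsets Prompt-offset ablation settings.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 7L, n_phantoms = 50L, size = 64L,
                       absent_frac = 0.2, fractions = split_fractions(),
                       val_augment = FALSE, min_weight = 0.1, max_weight = 0.9,
                       max_epochs = 10L, batch_size = 8L,
                       offsets = c(0L, 10L, 20L)) {
  if (isTRUE(val_augment))
    stop("val_augment = TRUE is rejected: validation data is never augmented")
  structure(list(seed = as.integer(seed), n_phantoms = as.integer(n_phantoms),
                 size = as.integer(size), absent_frac = absent_frac,
                 fractions = fractions, val_augment = FALSE,
                 min_weight = min_weight, max_weight = max_weight,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 offsets = as.integer(offsets)),
            class = "run_config")
}

#' Run the full pipeline into a run directory
#'
#' Executes, in order: phantom generation, the 60/20/20 split (written to
#' `split.yaml`), 9-strategy augmentation of the training split only,
#' inverse-frequency class weights over the training masks
#' (`weights.yaml`), surrogate training with AdamW / MultiStepLR / early
#' stopping (`epochs.csv`), evaluation of the trained surrogate on the
#' validation split and the prompt-offset ablation (`report.csv`,
#' `ablation.csv`). The resolved configuration is written to
#' `config.yaml`; reruns from the same config are identical.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("fetseg_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schema <- label_schema()
  yaml::write_yaml(unclass(config)[setdiff(names(unclass(config)), "fractions")],
                  file.path(out_dir, "config.yaml"))

  params <- phantom_params(config$size, config$size, seed = config$seed)
  samples <- generate_dataset(config$n_phantoms, params,
                              absent_frac = config$absent_frac)
  write_dataset(samples, file.path(out_dir, "data"))

  sp <- split_dataset(length(samples), config$fractions, seed = config$seed)
  stems <- vapply(samples, `[[`, "", "id")
  split_lists <- split(stems, factor(sp$assignment, c("train", "val", "test")))
  yaml::write_yaml(lapply(split_lists, as.list), file.path(out_dir, "split.yaml"))

  train_set <- samples[sp$assignment == "train"]
  val_set <- samples[sp$assignment == "val"]

  aug <- augment_dataset(train_set, seed = child_seed(config$seed, "augment"))
  write_dataset(aug, file.path(out_dir, "train_aug"))

  counts <- count_classes(lapply(aug, `[[`, "label_map"), schema$n_classes)
  weights <- compute_weights(counts, config$min_weight, config$max_weight)
  write_weights(weights, file.path(out_dir, "weights.yaml"), schema)

  tcfg <- train_config(max_epochs = config$max_epochs,
                       batch_size = config$batch_size,
                       seed = child_seed(config$seed, "train"),
                       loss = loss_config(class_weights = as.numeric(weights)))
  fit <- train(surrogate_segmenter(schema$n_classes, seed = tcfg$seed),
               aug, val_set, tcfg)
  utils::write.csv(fit$log, file.path(out_dir, "epochs.csv"), row.names = FALSE)

  report <- evaluate_segmenter(fit$model, val_set, prompt_config(), schema)
  write_report_csv(report_table(list(surrogate = report)),
                   file.path(out_dir, "report.csv"))

  ab <- ablate_prompts(fit$model, val_set, config$offsets, schema)
  write_report_csv(report_table(stats::setNames(ab, paste0("offset_", names(ab)))),
                   file.path(out_dir, "ablation.csv"))

  invisible(out_dir)
}
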