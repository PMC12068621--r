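#' Experiment recipes
#'
#' The study's eight model configurations. `baseline` is a plain beta-VAE
#' on the balanced dataset. `E1M1` and `E1M2` are plain beta-VAEs on the
#' 10x-unbalanced datasets (lower corridor left, and corridors aligned,
#' respectively). `E2M1`-`E2M4` are hybrid models trained jointly with one
#' classifier on tasks T1-T4 (all linear heads except the nonlinear
#' 1500-unit head of E2M4, whose 25-class binning task is not linearly
#' separable in the latent). `E2M5` trains all four heads simultaneously.
#'
#' @param experiment_id One of `"baseline"`, `"E1M1"`, `"E1M2"`,
#'   `"E2M1"`..`"E2M5"`.
#' @param c_max Capacity target in nats.
#' @param n_images Dataset size for the recipe's dataset spec.
#' @param data_seed Seed of the recipe's dataset spec.
#' @param ... Passed to [train_config()] (e.g. `seed`, `epochs`,
#'   `profile`).
#' @return An object of class `experiment_recipe` with elements
#'   `experiment_id`, `dataset_spec`, `model_spec`, `train_config`.
#' @export
experiment_recipe <- function(experiment_id, c_max = 0.3, n_images = 20000L,
                              data_seed = 20L, ...) {
  experiment_id <- match.arg(experiment_id,
    c("baseline", "E1M1", "E1M2", "E2M1", "E2M2", "E2M3", "E2M4", "E2M5"))
  weighting <- switch(experiment_id, E1M1 = "lower_left_10x",
                      E1M2 = "aligned_10x", "balanced")
  tasks <- switch(experiment_id,
                  E2M1 = "T1", E2M2 = "T2", E2M3 = "T3", E2M4 = "T4",
                  E2M5 = c("T1", "T2", "T3", "T4"), character(0))
  heads <- lapply(tasks, function(tk)
    classifier_spec(if (tk == "T4") "nonlinear" else "linear",
                    n_classes = task_n_classes(tk)))
  regime <- if (experiment_id == "E2M5") "multitask"
            else if (length(tasks)) "joint" else "baseline"
  structure(list(
    experiment_id = experiment_id,
    dataset_spec = dataset_spec(n_images, weighting, seed = data_seed),
    model_spec = vae_spec(heads = heads),
    train_config = train_config(regime = regime, tasks = tasks,
                                c_max = c_max, ...)),
    class = "experiment_recipe")
}

#' Run a recipe end-to-end into a run directory
#'
#' Generates (or reuses) the recipe's dataset, trains the model, and
#' writes a self-describing run directory: `manifest.yaml` (all specs and
#' seeds), `log.csv` (per-epoch metrics), `model.rds` (weights),
#' `kl_per_dim.csv` and `channel_maps.csv`. Regenerating CSVs from the
#' same recipe is bit-stable.
#'
#' @param recipe An [experiment_recipe()].
#' @param out_dir Output directory; refuses to overwrite an existing run
#'   unless `overwrite = TRUE`.
#' @param dataset Optional pre-generated `corridors_dataset` matching the
#'   recipe's spec (saves regeneration in sweeps).
#' @param overwrite Allow writing into an existing run directory.
#' @return The trained model, invisibly; side effect is the run directory.
#' @export
run_recipe <- function(recipe, out_dir, dataset = NULL, overwrite = FALSE) {
  stopifnot(inherits(recipe, "experiment_recipe"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("run directory ", out_dir, " already exists; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(dataset)) dataset <- generate_dataset(recipe$dataset_spec)
  model <- train_vae(dataset, recipe$model_spec, recipe$train_config)

  cfg <- recipe$train_config
  yaml::write_yaml(list(
    experiment_id = recipe$experiment_id,
    dataset = list(n_images = recipe$dataset_spec$n_images,
                   weighting = recipe$dataset_spec$weighting,
                   seed = recipe$dataset_spec$seed),
    model = list(latent_dim = recipe$model_spec$latent_dim,
                 hidden = recipe$model_spec$hidden,
                 heads = lapply(recipe$model_spec$heads, unclass)),
    training = list(regime = cfg$regime, tasks = cfg$tasks, c_max = cfg$c_max,
                    lr = cfg$lr, batch_size = cfg$batch_size,
                    epochs = cfg$epochs, gamma = cfg$gamma, seed = cfg$seed)),
    file.path(out_dir, "manifest.yaml"))
  data.table::fwrite(model$log, file.path(out_dir, "log.csv"))
  saveRDS(model, file.path(out_dir, "model.rds"))

  ev <- evaluate(model, dataset, tasks = cfg$tasks)
  data.table::fwrite(data.frame(channel = seq_along(ev$kl_per_dim),
                                kl_nats = ev$kl_per_dim),
                     file.path(out_dir, "kl_per_dim.csv"))
  cm <- channel_activation_maps(model, dataset)
  long <- do.call(rbind, lapply(seq_along(cm$maps), function(k) {
    g <- nrow(cm$maps[[k]])
    data.frame(channel = k, x_uc = rep(0:(g - 1L), each = g),
               x_lc = rep(0:(g - 1L), times = g),
               activation = as.vector(t(cm$maps[[k]])))
  }))
  data.table::fwrite(long, file.path(out_dir, "channel_maps.csv"))
  invisible(model)
}

#' Compare the latent geometry of two models
#'
#' Embeds the same evaluation dataset with both models, computes the
#' pairwise distortion ratios of model B relative to reference model A,
#' and aggregates them into the item-level (position-label) matrix and,
#' when a class scheme is given, a class-level matrix.
#'
#' @param model_a Reference model (distances in the denominator).
#' @param model_b Comparison model (distances in the numerator).
#' @param dataset Shared evaluation `corridors_dataset`.
#' @param class_labels Optional per-image 0-based class labels (aligned
#'   with the evaluation split) for the class matrix, e.g. a task labeling
#'   or a frequency class.
#' @param split Evaluation split.
#' @param max_per_label Stratified subsample cap per position label (the
#'   full pair set is quadratic in the split size).
#' @param seed Subsampling seed.
#' @return A list with `rho` (a `distortion_ratios`), `item`
#'   (`distortion_matrix` over 169 position labels), `class` (or `NULL`),
#'   and `indices` (rows of the split used).
#' @export
compare_models <- function(model_a, model_b, dataset, class_labels = NULL,
                           split = c("test", "train", "all"),
                           max_per_label = 20L, seed = 1L) {
  split <- match.arg(split)
  emb_a <- embed_dataset(model_a, dataset, split)
  emb_b <- embed_dataset(model_b, dataset, split)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(emb_a)), emb_a$label), function(i)
    if (length(i) > max_per_label) sample(i, max_per_label) else i),
    use.names = FALSE)
  keep <- sort(keep)
  emb_a <- emb_a[keep, ]; class(emb_a) <- c("embedding_table", "data.frame")
  emb_b <- emb_b[keep, ]; class(emb_b) <- c("embedding_table", "data.frame")
  rho <- distortion_ratios(emb_a, emb_b)
  item <- item_distortion_matrix(rho, emb_a$label)
  cls <- NULL
  if (!is.null(class_labels)) {
    cl <- class_labels[keep]
    cls <- class_distortion_matrix(rho, cl)
  }
  list(rho = rho, item = item, class = cls, indices = emb_a$index)
}

#' Mean within- and between-class distortion
#'
#' Convenience summary of a class distortion comparison: the mean rho over
#' pairs whose images share a class, and over pairs that do not.
#'
#' @param rho A `distortion_ratios`.
#' @param class_labels Per-image class labels aligned with the embeddings.
#' @return Named vector `c(within = ..., between = ...)`.
#' @export
within_between_distortion <- function(rho, class_labels) {
  same <- class_labels[rho$i] == class_labels[rho$j]
  c(within = mean(rho$rho[same]), between = mean(rho$rho[!same]))
}
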