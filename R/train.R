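#' Capacity annealing schedule
#'
#' The capacity target C ramps linearly from 0 to `c_max` over
#' `anneal_steps` optimizer steps and stays at `c_max` thereafter.
#'
#' @param c_max Final capacity target (nats).
#' @param gamma Capacity-constraint weight.
#' @param anneal_steps Steps over which C ramps up.
#' @param total_steps Total optimizer steps of the run.
#' @return An object of class `capacity_schedule`.
#' @export
capacity_schedule <- function(c_max, gamma, anneal_steps, total_steps) {
  stopifnot(c_max >= 0, gamma >= 0, anneal_steps >= 0,
            total_steps >= anneal_steps)
  structure(list(c_max = c_max, gamma = gamma,
                 anneal_steps = as.integer(anneal_steps),
                 total_steps = as.integer(total_steps)),
            class = "capacity_schedule")
}

#' @rdname capacity_schedule
#' @param step Optimizer step (0..total_steps).
#' @param schedule A `capacity_schedule`.
#' @return `capacity_at_step`: the capacity target C (nats) at `step`.
#' @export
capacity_at_step <- function(step, schedule) {
  stopifnot(inherits(schedule, "capacity_schedule"),
            all(step >= 0), all(step <= schedule$total_steps))
  if (schedule$anneal_steps == 0) return(rep(schedule$c_max, length(step)))
  schedule$c_max * pmin(1, step / schedule$anneal_steps)
}

#' Training configuration
#'
#' Defaults follow the desk-scale study profile: 20,000 images are trained
#' for 30 epochs in batches of 64 with Adam at learning rate 5e-5 and a
#' capacity weight gamma of 100, annealing C over the first half of
#' training. The full-scale profile (`profile = "full"`) uses gamma 1000,
#' intended for 200,000-image datasets.
#'
#' @param regime Training regime: `"baseline"` (no heads), `"joint"`
#'   (heads and VAE trained together), `"frozen_then_classifier"` (train
#'   heads on a frozen pretrained VAE), `"transfer"` (same, but the frozen
#'   VAE came from a different task) or `"multitask"` (joint with all four
#'   tasks).
#' @param tasks Character vector of task ids (`"T1"`..`"T4"`) matched
#'   one-to-one with the model's classifier heads.
#' @param c_max Capacity target Cmax in nats (the study sweeps
#'   0.3, 1, 3, 6, 10).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Number of passes over the training split.
#' @param gamma Capacity-constraint weight.
#' @param anneal_frac Fraction of total steps over which C is annealed.
#' @param seed Seed for minibatch order, reparameterization noise and
#'   weight initialization.
#' @param profile Convenience switch for `"desk"` or `"full"` defaults.
#' @return An object of class `train_config`.
#' @export
train_config <- function(regime = c("baseline", "joint", "frozen_then_classifier",
                                    "transfer", "multitask"),
                         tasks = character(0), c_max = 0.3, lr = 5e-5,
                         batch_size = 64L, epochs = NULL, gamma = NULL,
                         anneal_frac = 0.5, seed = 1L,
                         profile = c("desk", "full")) {
  regime <- match.arg(regime)
  profile <- match.arg(profile)
  if (is.null(epochs)) epochs <- 30L
  if (is.null(gamma)) gamma <- if (profile == "desk") 100 else 1000
  if (regime == "baseline" && length(tasks))
    stop("baseline regime takes no tasks")
  if (regime == "multitask" && !setequal(tasks, c("T1", "T2", "T3", "T4")))
    stop("multitask regime requires all four tasks")
  if (regime %in% c("joint", "frozen_then_classifier", "transfer") &&
      !length(tasks))
    stop(regime, " regime requires at least one task")
  stopifnot(c_max >= 0, lr > 0, batch_size >= 1, epochs >= 1, gamma >= 0)
  structure(list(regime = regime, tasks = tasks, c_max = c_max, lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 gamma = gamma, anneal_frac = anneal_frac,
                 seed = as.integer(seed), profile = profile),
            class = "train_config")
}

#' Train a model
#'
#' Minibatch Adam on the capacity-constrained objective. In the frozen
#' regimes (`"frozen_then_classifier"`, `"transfer"`) the pretrained
#' encoder/decoder weights are carried over untouched and only the
#' classifier heads receive updates; heads are (re-)initialized fresh.
#'
#' @param dataset A `corridors_dataset` carrying labels for all configured
#'   tasks.
#' @param spec A [vae_spec()] whose heads match `config$tasks`.
#' @param config A [train_config()].
#' @param pretrained A trained `corridor_vae` whose encoder/decoder are
#'   reused (required for the frozen regimes).
#' @param log_every Record evaluation metrics every this many epochs.
#' @return A trained `corridor_vae` with the training `config` and a
#'   per-epoch `log` data.frame (epoch, step, capacity C, held-out
#'   reconstruction loss as per-pixel mean squared error and per-pixel
#'   Bernoulli cross-entropy, KL in nats, per-task F1).
#' @export
train_vae <- function(dataset, spec, config, pretrained = NULL, log_every = 1L) {
  stopifnot(inherits(dataset, "corridors_dataset"), inherits(spec, "vae_spec"),
            inherits(config, "train_config"))
  if (length(spec$heads) != length(config$tasks))
    stop("spec has ", length(spec$heads), " heads but config lists ",
         length(config$tasks), " tasks")
  frozen <- config$regime %in% c("frozen_then_classifier", "transfer")
  if (frozen && is.null(pretrained))
    stop("regime ", config$regime, " requires a pretrained model")
  if (!all(config$tasks %in% colnames(dataset$tasks)))
    stop("dataset lacks labels for some configured tasks")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  model <- init_vae(spec, seed = config$seed)
  if (frozen) {
    for (nm in c("enc1", "enc2", "mu", "lv", "dec1", "dec2", "out"))
      model$params[[nm]] <- pretrained$params[[nm]]
  }
  params <- model$params
  state <- adam_state(params)

  tr <- dataset$train
  task_cols <- match(config$tasks, colnames(dataset$tasks))
  steps_per_epoch <- max(1L, length(tr) %/% config$batch_size)
  total_steps <- steps_per_epoch * config$epochs
  sched <- capacity_schedule(config$c_max, config$gamma,
                             max(1L, floor(config$anneal_frac * total_steps)),
                             total_steps)
  X <- dataset$images
  storage.mode(X) <- "double"

  log <- list()
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    for (b in seq_len(steps_per_epoch)) {
      ix <- ord[((b - 1L) * config$batch_size + 1L):(b * config$batch_size)]
      step <- step + 1L
      C <- capacity_at_step(step, sched)
      ylist <- lapply(task_cols, function(k) dataset$tasks[ix, k])
      eps <- matrix(stats::rnorm(length(ix) * spec$latent_dim), length(ix))
      r <- vae_batch_loss(params, X[ix, , drop = FALSE], eps, C, config$gamma,
                          ylist)
      if (!is.finite(r$total))
        stop("training diverged (non-finite loss) at step ", step)
      g <- r$grads
      if (frozen)
        for (nm in c("enc1", "enc2", "mu", "lv", "dec1", "dec2", "out"))
          g[[nm]] <- NULL
      upd <- adam_step(params, state, g, config$lr, step)
      params <- upd$p
      state <- upd$s
    }
    if (ep %% log_every == 0L || ep == config$epochs) {
      model$params <- params
      ev <- evaluate(model, dataset, tasks = config$tasks)
      log[[length(log) + 1L]] <- data.frame(
        epoch = ep, step = step, capacity = C,
        recon_mse = ev$recon_mse, recon_bce = ev$recon_bce, kl = ev$kl,
        f1 = if (length(ev$f1)) paste(signif(ev$f1, 6), collapse = ";") else "")
    }
  }
  model$params <- params
  model$config <- config
  model$log <- do.call(rbind, log)
  model$trained_on <- dataset$spec
  model
}

#' Evaluate a model on the held-out split
#'
#' Embeddings use the posterior mean (no sampling), so evaluation is
#' deterministic. The reported reconstruction loss is the per-pixel mean
#' squared error between the input pixels and the decoded probabilities
#' (with the per-pixel Bernoulli cross-entropy alongside); F1 is the
#' positive-class F1 for binary tasks and the macro average over classes
#' for the 25-class task.
#'
#' @param model A trained `corridor_vae`.
#' @param dataset A `corridors_dataset`.
#' @param split `"test"`, `"train"` or `"all"`.
#' @param tasks Task ids matched to the model's heads (defaults to the
#'   training configuration's tasks).
#' @return A list with `recon_mse`, `recon_bce`, `kl` (nats), `kl_per_dim`
#'   (mean per-channel KL), and `f1` (named per task).
#' @export
evaluate <- function(model, dataset, split = c("test", "train", "all"),
                     tasks = NULL) {
  stopifnot(inherits(model, "corridor_vae"), inherits(dataset, "corridors_dataset"))
  split <- match.arg(split)
  if (is.null(tasks)) tasks <- if (!is.null(model$config)) model$config$tasks
                               else character(0)
  idx <- switch(split, test = dataset$test, train = dataset$train,
                all = seq_len(nrow(dataset$images)))
  X <- dataset$images[idx, , drop = FALSE]
  storage.mode(X) <- "double"
  post <- encode(model, X)
  probs <- decode(model, post$mu)
  kpd <- kl_divergence(post, per_dim = TRUE)
  f1 <- numeric(0)
  for (i in seq_along(tasks)) {
    y <- dataset$tasks[idx, tasks[i]]
    yhat <- max.col(classify(model, post$mu, head = i)) - 1L
    f1 <- c(f1, if (task_n_classes(tasks[i]) == 2L) f1_binary(y, yhat)
                else f1_macro(y, yhat, task_n_classes(tasks[i])))
  }
  names(f1) <- tasks
  list(recon_mse = mean((X - probs)^2),
       recon_bce = reconstruction_loss(X, probs, "mean"),
       kl = mean(rowSums(kpd)), kl_per_dim = colMeans(kpd), f1 = f1)
}

#' F1 scores
#'
#' `f1_binary` is the standard positive-class F1 (`2TP / (2TP + FP + FN)`)
#' for 0/1 labels; `f1_macro` averages the one-vs-rest F1 over all
#' `n_classes` classes.
#'
#' @param y True 0-based labels.
#' @param yhat Predicted 0-based labels.
#' @param n_classes Number of classes for the macro average.
#' @return A number in \[0, 1\].
#' @export
f1_binary <- function(y, yhat) {
  tp <- sum(y == 1 & yhat == 1)
  fp <- sum(y == 0 & yhat == 1)
  fn <- sum(y == 1 & yhat == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' @rdname f1_binary
#' @export
f1_macro <- function(y, yhat, n_classes) {
  mean(vapply(seq_len(n_classes) - 1L, function(k)
    f1_binary(as.integer(y == k), as.integer(yhat == k)), numeric(1)))
}

#' Train one experiment across a sweep of capacities
#'
#' @param experiment_id One of `"baseline"`, `"E1M1"`, `"E1M2"`,
#'   `"E2M1"`..`"E2M5"`; see [experiment_recipe()].
#' @param dataset A `corridors_dataset` with the experiment's weighting.
#' @param c_max_list Capacities to sweep (nats).
#' @param ... Further arguments passed to [train_config()].
#' @return A named list of trained models, one per capacity
#'   (names `"C<value>"`).
#' @export
run_capacity_sweep <- function(experiment_id, dataset,
                               c_max_list = c(0.3, 1, 3, 6, 10), ...) {
  out <- lapply(c_max_list, function(cm) {
    rec <- experiment_recipe(experiment_id, c_max = cm, ...)
    train_vae(dataset, rec$model_spec, rec$train_config)
  })
  names(out) <- paste0("C", c_max_list)
  out
}
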