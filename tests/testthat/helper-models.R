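# Shared desk-scale datasets and trained models, built lazily and memoized
# so that every test file reuses the same runs. Training conditions follow
# the desk profile: 20,000 images, Adam lr 5e-5, latent dim 5.

.test_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .test_cache, inherits = FALSE))
    assign(key, force(expr), envir = .test_cache)
  get(key, envir = .test_cache, inherits = FALSE)
}

test_dataset <- function(weighting = "balanced") {
  memo(paste0("ds_", weighting),
       generate_dataset(20000, weighting = weighting, seed = 20))
}

# A small balanced probe set covering all 169 position pairs, for geometry.
probe_dataset <- function() {
  memo("ds_probe", generate_dataset(3380, weighting = "balanced", seed = 99))
}

test_model <- function(experiment_id, c_max, seed = 1) {
  key <- sprintf("m_%s_%g_%d", experiment_id, c_max, seed)
  memo(key, {
    rec <- experiment_recipe(experiment_id, c_max = c_max, seed = seed)
    ds <- test_dataset(rec$dataset_spec$weighting)
    train_vae(ds, rec$model_spec, rec$train_config)
  })
}

# Independent brute-force enumeration of the four task labelings, written
# directly from the task definitions as scalar rules.
oracle_task_table <- function() {
  out <- NULL
  for (u in 0:12) for (l in 0:12) {
    t1 <- if (u <= l) 1L else 0L
    t2 <- if (u < 6) 1L else if (u >= 6 && l >= 6) 1L else 0L
    t3 <- if (u == l) 1L else 0L
    bin <- function(p) {
      if (p <= 1) 0L else if (p <= 4) 1L else if (p <= 7) 2L
      else if (p <= 10) 3L else 4L
    }
    out <- rbind(out, data.frame(x_uc = u, x_lc = l, T1 = t1, T2 = t2,
                                 T3 = t3, T4 = bin(u) * 5L + bin(l)))
  }
  out
}

# Wrap a plain matrix of latent coordinates as an embedding table.
as_embedding <- function(z, label = seq_len(nrow(z)) - 1L, index = seq_len(nrow(z))) {
  colnames(z) <- paste0("z", seq_len(ncol(z)))
  out <- data.frame(z, x_uc = 0L, x_lc = 0L, label = label,
                    T1 = 0L, T2 = 0L, T3 = 0L, T4 = 0L, index = index)
  class(out) <- c("embedding_table", "data.frame")
  out
}

random_orthogonal <- function(d) {
  qr.Q(qr(matrix(rnorm(d * d), d)))
}
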