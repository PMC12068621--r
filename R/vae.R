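#' Specify a classifier head
#'
#' Classifier heads consume the 5-D latent vector. The linear head is a
#' feed-forward network with a single 1024-unit hidden layer and no
#' activation functions, so it composes to an affine map of the latent.
#' The nonlinear head has a single 1500-unit hidden layer with a leaky-ReLU
#' activation.
#'
#' @param kind `"linear"` or `"nonlinear"`.
#' @param n_classes Number of output classes (logits).
#' @param hidden_units Hidden-layer width; defaults to 1024 (linear) or
#'   1500 (nonlinear).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("linear", "nonlinear"), n_classes,
                            hidden_units = NULL) {
  kind <- match.arg(kind)
  if (is.null(hidden_units)) hidden_units <- if (kind == "linear") 1024L else 1500L
  stopifnot(n_classes >= 2, hidden_units >= 1)
  structure(list(kind = kind, n_classes = as.integer(n_classes),
                 hidden_units = as.integer(hidden_units)),
            class = "classifier_spec")
}

#' Specify the beta-VAE architecture
#'
#' A fully connected encoder (pixels -> hidden\[1\] -> hidden\[2\] ->
#' posterior mean and log-variance) and mirrored decoder, with leaky-ReLU
#' activations and a sigmoid output layer producing per-pixel Bernoulli
#' probabilities. The latent dimension defaults to 5: the data have two
#' generative factors and the three extra dimensions let the model show
#' whether it recruits them.
#'
#' @param latent_dim Latent dimensionality.
#' @param hidden Widths of the two hidden layers (encoder order).
#' @param n_pixels Number of input pixels (`grid_size^2`).
#' @param heads List of [classifier_spec()]s for jointly trained heads
#'   (empty for a plain beta-VAE).
#' @return An object of class `vae_spec`.
#' @export
vae_spec <- function(latent_dim = 5L, hidden = c(256L, 128L), n_pixels = 169L,
                     heads = list()) {
  stopifnot(latent_dim >= 1, length(hidden) == 2, n_pixels >= 4)
  if (inherits(heads, "classifier_spec")) heads <- list(heads)
  stopifnot(all(vapply(heads, inherits, TRUE, "classifier_spec")))
  structure(list(latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden), n_pixels = as.integer(n_pixels),
                 heads = heads),
            class = "vae_spec")
}

#' Initialize an untrained model
#'
#' He-style initialization for leaky-ReLU layers; the posterior layers use
#' a smaller fan-in scale so training starts close to the prior.
#'
#' @param spec A [vae_spec()].
#' @param seed Integer seed for the weight draws.
#' @return An object of class `corridor_vae` holding `spec` and `params`.
#' @export
init_vae <- function(spec = vae_spec(), seed = 1L) {
  stopifnot(inherits(spec, "vae_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  h <- spec$hidden
  params <- list(
    enc1 = dense_init(spec$n_pixels, h[1]),
    enc2 = dense_init(h[1], h[2]),
    mu = dense_init(h[2], spec$latent_dim, scale = sqrt(1 / h[2])),
    lv = dense_init(h[2], spec$latent_dim, scale = sqrt(1 / h[2])),
    dec1 = dense_init(spec$latent_dim, h[2]),
    dec2 = dense_init(h[2], h[1]),
    out = dense_init(h[1], spec$n_pixels),
    heads = lapply(spec$heads, function(hs) {
      list(kind = hs$kind,
           h1 = dense_init(spec$latent_dim, hs$hidden_units),
           h2 = dense_init(hs$hidden_units, hs$n_classes))
    }))
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "corridor_vae")
}

#' @export
print.corridor_vae <- function(x, ...) {
  cat(sprintf("beta-VAE: %d pixels -> (%s) -> %d latent dims, %d classifier head(s)%s\n",
              x$spec$n_pixels, paste(x$spec$hidden, collapse = ", "),
              x$spec$latent_dim, length(x$spec$heads),
              if (is.null(x$config)) " (untrained)" else ""))
  if (!is.null(x$config))
    cat(sprintf("  trained: regime %s, Cmax %g nats, %d epochs\n",
                x$config$regime, x$config$c_max, x$config$epochs))
  invisible(x)
}

# Coerce images to a batch matrix (n x n_pixels).
as_image_batch <- function(x, n_pixels) {
  if (inherits(x, "corridors_dataset")) x <- x$images
  if (inherits(x, "corridor_image") || (is.matrix(x) && ncol(x) != n_pixels &&
                                        nrow(x) * ncol(x) == n_pixels))
    x <- matrix(image_to_vec(x), 1)
  if (is.vector(x) && length(x) == n_pixels) x <- matrix(x, 1)
  if (!is.matrix(x) || ncol(x) != n_pixels)
    stop("expected images with ", n_pixels, " pixels per row")
  storage.mode(x) <- "double"
  x
}

#' Encode images to posterior parameters
#'
#' @param model A `corridor_vae`.
#' @param images A `corridors_dataset`, an `n x n_pixels` matrix of
#'   row-major pixel vectors, or a single image matrix.
#' @return A list of class `posterior_params` with `mu` and `logvar`
#'   (`n x latent_dim` matrices).
#' @export
encode <- function(model, images) {
  stopifnot(inherits(model, "corridor_vae"))
  X <- as_image_batch(images, model$spec$n_pixels)
  enc <- encoder_forward(model$params, X)
  structure(list(mu = enc$mu, logvar = enc$logvar), class = "posterior_params")
}

#' Sample latent vectors by reparameterization
#'
#' `z = mu + exp(logvar / 2) * eps` with standard-normal `eps`.
#'
#' @param params A `posterior_params` object from [encode()].
#' @param eps Optional noise matrix (same shape as `params$mu`); drawn from
#'   the R RNG when omitted.
#' @return An `n x latent_dim` matrix of latent samples.
#' @export
sample_latent <- function(params, eps = NULL) {
  stopifnot(inherits(params, "posterior_params"))
  if (is.null(eps))
    eps <- matrix(stats::rnorm(length(params$mu)), nrow(params$mu))
  stopifnot(identical(dim(eps), dim(params$mu)))
  params$mu + exp(params$logvar / 2) * eps
}

#' Decode latent vectors to pixel probabilities
#'
#' @param model A `corridor_vae`.
#' @param z An `n x latent_dim` matrix (or a single latent vector).
#' @return An `n x n_pixels` matrix of Bernoulli probabilities in (0, 1).
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "corridor_vae"))
  if (is.vector(z)) z <- matrix(z, 1)
  stopifnot(ncol(z) == model$spec$latent_dim)
  decoder_forward(model$params, z)$probs
}

#' Classifier logits for latent vectors
#'
#' @param model A `corridor_vae` with at least one classifier head.
#' @param z An `n x latent_dim` matrix (or single latent vector).
#' @param head Head index.
#' @return An `n x n_classes` matrix of logits.
#' @export
classify <- function(model, z, head = 1L) {
  stopifnot(inherits(model, "corridor_vae"))
  if (length(model$params$heads) < head) stop("model has no head ", head)
  if (is.vector(z)) z <- matrix(z, 1)
  head_forward(model$params$heads[[head]], z)$logits
}

#' Kullback-Leibler divergence of the posterior from the prior
#'
#' Closed form for a diagonal Gaussian against the standard normal,
#' summed over latent dimensions:
#' `0.5 * sum(mu^2 + exp(logvar) - 1 - logvar)` (nats).
#'
#' @param params A `posterior_params` object.
#' @param per_dim If `TRUE`, return the `n x latent_dim` matrix of
#'   per-dimension contributions instead of row sums.
#' @return Numeric vector of per-sample KL divergences (or a matrix).
#' @export
kl_divergence <- function(params, per_dim = FALSE) {
  stopifnot(inherits(params, "posterior_params"))
  k <- 0.5 * (params$mu^2 + exp(params$logvar) - 1 - params$logvar)
  if (per_dim) k else rowSums(k)
}

#' Bernoulli reconstruction loss
#'
#' Negative Bernoulli log-likelihood of binary pixels under predicted
#' probabilities, averaged over images. `reduction = "sum"` (the training
#' form) sums over pixels first; `reduction = "mean"` reports the per-pixel
#' mean. Probabilities are clamped to \[1e-7, 1 - 1e-7\] before the log.
#'
#' @param x Binary pixel matrix (`n x n_pixels`).
#' @param x_hat Predicted probability matrix of the same shape.
#' @param reduction `"sum"` (nats per image) or `"mean"` (nats per pixel).
#' @return A single number.
#' @export
reconstruction_loss <- function(x, x_hat, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (is.vector(x)) x <- matrix(x, 1)
  if (is.vector(x_hat)) x_hat <- matrix(x_hat, 1)
  stopifnot(identical(dim(x), dim(x_hat)), all(x %in% c(0, 1)))
  p <- pmin(pmax(x_hat, 1e-7), 1 - 1e-7)
  bce <- -x * log(p) - (1 - x) * log(1 - p)
  if (reduction == "sum") mean(rowSums(bce)) else mean(bce)
}

#' Full training objective for one batch
#'
#' `total = recon + gamma * |KL - C| + sum_i xent_i`, all terms averaged
#' over the batch; the reconstruction term is the summed Bernoulli loss.
#'
#' @param model A `corridor_vae`.
#' @param x Pixel batch (`n x n_pixels`).
#' @param c_target Current capacity target C (nats), >= 0.
#' @param gamma Capacity-constraint weight, > 0.
#' @param task_labels List of 0-based label vectors, one per classifier
#'   head (empty for a plain beta-VAE).
#' @param eps Optional reparameterization noise (drawn if omitted).
#' @return A list of class `loss_breakdown` with components `recon`,
#'   `kl`, `capacity`, `classifier` and `total`.
#' @export
total_loss <- function(model, x, c_target, gamma, task_labels = list(),
                       eps = NULL) {
  stopifnot(inherits(model, "corridor_vae"), c_target >= 0, gamma >= 0)
  X <- as_image_batch(x, model$spec$n_pixels)
  if (length(task_labels) != length(model$params$heads))
    stop("need one label vector per classifier head")
  if (is.null(eps))
    eps <- matrix(stats::rnorm(nrow(X) * model$spec$latent_dim), nrow(X))
  r <- vae_batch_loss(model$params, X, eps, c_target, gamma, task_labels,
                      want_grads = FALSE)
  structure(r, class = "loss_breakdown")
}
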