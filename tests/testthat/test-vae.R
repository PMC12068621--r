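test_that("KL closed form matches examples and numerical quadrature", {
  p0 <- structure(list(mu = matrix(0, 1, 5), logvar = matrix(0, 1, 5)),
                  class = "posterior_params")
  expect_equal(kl_divergence(p0), 0)
  p1 <- structure(list(mu = matrix(c(1, 0, 0, 0, 0), 1), logvar = matrix(0, 1, 5)),
                  class = "posterior_params")
  expect_equal(kl_divergence(p1), 0.5)

  # quadrature oracle: KL factorizes over dimensions for diagonal Gaussians
  kl_quad_1d <- function(mu, lv) {
    s <- exp(lv / 2)
    f <- function(z) {
      q <- stats::dnorm(z, mu, s)
      q * (stats::dnorm(z, mu, s, log = TRUE) - stats::dnorm(z, log = TRUE))
    }
    stats::integrate(f, mu - 12 * s, mu + 12 * s, rel.tol = 1e-10)$value
  }
  set.seed(31)
  for (i in 1:10) {
    mu <- matrix(rnorm(3), 1)
    lv <- matrix(rnorm(3, 0, 0.7), 1)
    p <- structure(list(mu = mu, logvar = lv), class = "posterior_params")
    oracle <- sum(mapply(kl_quad_1d, mu, lv))
    expect_equal(kl_divergence(p), oracle, tolerance = 1e-6)
    expect_gte(kl_divergence(p), 0)
  }
})

test_that("reconstruction loss matches Bernoulli closed forms", {
  set.seed(4)
  x <- matrix(rbinom(169, 1, 0.5), 1)
  # perfect reconstruction (clamped)
  expect_equal(reconstruction_loss(x, x), 1e-7 * 169, tolerance = 1e-2)
  # maximal uncertainty: 169 * ln 2 summed, ln 2 per pixel
  half <- matrix(0.5, 1, 169)
  expect_equal(reconstruction_loss(x, half, "sum"), 169 * log(2))
  expect_equal(reconstruction_loss(x, half, "mean"), log(2))
})

test_that("reparameterized sampling has the right limits and moments", {
  mu <- matrix(rnorm(10), 2)
  p <- structure(list(mu = mu, logvar = matrix(-30, 2, 5)),
                 class = "posterior_params")
  expect_equal(sample_latent(p), mu, tolerance = 1e-6)

  eps <- matrix(rnorm(10), 2)
  p2 <- structure(list(mu = matrix(0, 2, 5), logvar = matrix(0, 2, 5)),
                  class = "posterior_params")
  expect_equal(sample_latent(p2, eps), eps)

  # Monte-Carlo mean within 3 standard errors
  set.seed(12)
  p3 <- structure(list(mu = matrix(1.5, 1, 5), logvar = matrix(log(0.25), 1, 5)),
                  class = "posterior_params")
  n <- 1e5
  zs <- vapply(seq_len(n %/% 1000), function(i) {
    colMeans(do.call(rbind, lapply(1:1000, function(j) sample_latent(p3)[1, ])))
  }, numeric(5))
  expect_equal(mean(zs), 1.5, tolerance = 3 * 0.5 / sqrt(n))
})

test_that("encoder and decoder are deterministic with valid output ranges", {
  m <- init_vae(vae_spec(), seed = 2)
  set.seed(1)
  X <- matrix(rbinom(5 * 169, 1, 0.3), 5)
  p1 <- encode(m, X); p2 <- encode(m, X)
  expect_identical(p1, p2)
  expect_equal(dim(p1$mu), c(5L, 5L))
  probs <- decode(m, p1$mu)
  expect_true(all(probs > 0 & probs < 1))
  expect_equal(dim(probs), c(5L, 169L))
  # single image input is accepted
  img <- vec_to_image(X[1, ])
  expect_equal(encode(m, img)$mu, p1$mu[1, , drop = FALSE])
})

test_that("the linear head composes to an affine map of the latent", {
  spec <- vae_spec(heads = classifier_spec("linear", 2))
  m <- init_vae(spec, seed = 3)
  # algebraic check: two stacked affine layers equal one affine map
  hd <- m$params$heads[[1]]
  W_eff <- hd$h1$W %*% hd$h2$W
  b_eff <- as.vector(hd$h1$b %*% hd$h2$W) + hd$h2$b
  z <- matrix(rnorm(10), 2)
  expect_equal(classify(m, z), z %*% W_eff + rep(b_eff, each = 2))
  # with zero biases the map is exactly linear
  m$params$heads[[1]]$h1$b[] <- 0
  m$params$heads[[1]]$h2$b[] <- 0
  z1 <- matrix(rnorm(5), 1); z2 <- matrix(rnorm(5), 1)
  expect_equal(classify(m, 2 * z1 + 3 * z2),
               2 * classify(m, z1) + 3 * classify(m, z2))
})

test_that("nonlinear head solves XOR latents that defeat the linear head", {
  # classic separability oracle on 2-D XOR points
  z <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, byrow = TRUE)
  y <- c(0L, 1L, 1L, 0L)
  train_head <- function(kind) {
    spec <- vae_spec(latent_dim = 2, n_pixels = 16,
                     heads = classifier_spec(kind, 2, hidden_units = 16))
    m <- init_vae(spec, seed = 5)
    hd <- m$params$heads[[1]]
    st <- rdgeom:::adam_state(hd)
    for (t in 1:800) {
      fwd <- rdgeom:::head_forward(hd, z)
      ce <- rdgeom:::softmax_xent(fwd$logits, y)
      dl <- ce$dlogits
      g <- list(kind = hd$kind,
                h2 = list(W = crossprod(fwd$H1, dl), b = colSums(dl)))
      dH1 <- dl %*% t(hd$h2$W)
      if (hd$kind == "nonlinear") dH1 <- dH1 * rdgeom:::dlrelu(fwd$A1)
      g$h1 <- list(W = crossprod(z, dH1), b = colSums(dH1))
      upd <- rdgeom:::adam_step(hd, st, g, 5e-3, t)
      hd <- upd$p; st <- upd$s
    }
    yhat <- max.col(rdgeom:::head_forward(hd, z)$logits) - 1L
    mean(yhat == y)
  }
  expect_equal(train_head("nonlinear"), 1.0)
  expect_lte(train_head("linear"), 0.75)
})

test_that("the total loss decomposes as reconstruction + capacity + classification", {
  spec <- vae_spec(heads = classifier_spec("linear", 2))
  m <- init_vae(spec, seed = 6)
  set.seed(9)
  X <- matrix(rbinom(4 * 169, 1, 0.3), 4)
  y <- c(0L, 1L, 1L, 0L)
  eps <- matrix(rnorm(20), 4)
  lb <- total_loss(m, X, c_target = 0.2, gamma = 50, task_labels = list(y),
                   eps = eps)
  # independent arithmetic from the exported primitives
  post <- encode(m, X)
  z <- sample_latent(post, eps)
  recon <- reconstruction_loss(X, decode(m, z), "sum")
  kl <- mean(kl_divergence(post))
  logits <- classify(m, z)
  ce <- mean(log(rowSums(exp(logits))) - logits[cbind(1:4, y + 1L)])
  expect_equal(lb$recon, recon)
  expect_equal(lb$kl, kl)
  expect_equal(lb$capacity, 50 * abs(kl - 0.2))
  expect_equal(lb$classifier, ce, tolerance = 1e-10)
  expect_equal(lb$total, recon + 50 * abs(kl - 0.2) + ce)
  # every component is non-negative
  expect_gte(lb$recon, 0); expect_gte(lb$capacity, 0); expect_gte(lb$classifier, 0)
  # gamma = 0 decouples the KL term
  lb0 <- total_loss(m, X, c_target = 0.2, gamma = 0, task_labels = list(y),
                    eps = eps)
  expect_equal(lb0$total, lb0$recon + lb0$classifier)
})
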