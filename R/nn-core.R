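# Internal dense-network machinery: initialization, forward passes,
# analytic gradients and Adam updates. All arrays are batch-major
# (rows = samples). Kept free of side effects so gradients can be checked
# against finite differences.

LRELU_SLOPE <- 0.01

lrelu <- function(x) x * (LRELU_SLOPE + (1 - LRELU_SLOPE) * (x > 0))
dlrelu <- function(x) LRELU_SLOPE + (1 - LRELU_SLOPE) * (x > 0)

dense_init <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, scale), n_in, n_out),
       b = rep(0, n_out))
}

affine <- function(X, layer) {
  M <- X %*% layer$W
  M + rep(layer$b, each = nrow(M))
}

# Encoder: n_in -> hidden[1] -> hidden[2] -> (mu, logvar), leaky-ReLU hiddens.
encoder_forward <- function(params, X) {
  A1 <- affine(X, params$enc1); H1 <- lrelu(A1)
  A2 <- affine(H1, params$enc2); H2 <- lrelu(A2)
  mu <- affine(H2, params$mu)
  logvar <- pmin(pmax(affine(H2, params$lv), -15), 15)
  list(A1 = A1, H1 = H1, A2 = A2, H2 = H2, mu = mu, logvar = logvar)
}

# Decoder: latent -> hidden[2] -> hidden[1] -> n_in logits -> sigmoid.
decoder_forward <- function(params, Z) {
  A1 <- affine(Z, params$dec1); H1 <- lrelu(A1)
  A2 <- affine(H1, params$dec2); H2 <- lrelu(A2)
  logits <- affine(H2, params$out)
  list(A1 = A1, H1 = H1, A2 = A2, H2 = H2,
       probs = 1 / (1 + exp(-logits)))
}

# Classifier head: latent -> hidden -> n_classes logits. The linear head has
# no activation anywhere, so it composes to a single affine map; the
# nonlinear head applies a leaky ReLU after the hidden layer.
head_forward <- function(head, Z) {
  A1 <- affine(Z, head$h1)
  H1 <- if (head$kind == "nonlinear") lrelu(A1) else A1
  list(A1 = A1, H1 = H1, logits = affine(H1, head$h2))
}

# Mean softmax cross-entropy and gradient w.r.t. logits. y is 0-based.
softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  M <- logits - apply(logits, 1, max)
  E <- exp(M)
  Z <- rowSums(E)
  pick <- cbind(seq_len(n), y + 1L)
  loss <- mean(log(Z) - M[pick])
  G <- E / Z
  G[pick] <- G[pick] - 1
  list(loss = loss, dlogits = G / n)
}

# Closed-form KL( N(mu, diag(exp(logvar))) || N(0, I) ), per sample (nats).
kl_rows <- function(mu, logvar) {
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

# Full loss and (optionally) gradients of the capacity-constrained hybrid
# objective for one batch:
#   mean_recon_BCE_sum + gamma * |mean_KL - C| + sum_i mean_xent_i.
# `eps` is the reparameterization noise (same shape as mu); passing it in
# keeps the function deterministic, which the finite-difference gradient
# tests rely on.
vae_batch_loss <- function(params, X, eps, C, gamma, ylist = list(),
                           want_grads = TRUE) {
  B <- nrow(X)
  enc <- encoder_forward(params, X)
  sd <- exp(enc$logvar / 2)
  Z <- enc$mu + sd * eps
  dec <- decoder_forward(params, Z)
  P <- pmin(pmax(dec$probs, 1e-7), 1 - 1e-7)
  recon <- mean(rowSums(-X * log(P) - (1 - X) * log(1 - P)))
  kl <- mean(kl_rows(enc$mu, enc$logvar))
  capacity <- gamma * abs(kl - C)

  head_fwd <- lapply(seq_along(params$heads), function(i)
    head_forward(params$heads[[i]], Z))
  head_ce <- lapply(seq_along(params$heads), function(i)
    softmax_xent(head_fwd[[i]]$logits, ylist[[i]]))
  clf <- if (length(head_ce)) sum(vapply(head_ce, `[[`, 0, "loss")) else 0

  out <- list(recon = recon, kl = kl, capacity = capacity, classifier = clf,
              total = recon + capacity + clf)
  if (!want_grads) return(out)

  g <- list()
  dlogits <- (dec$probs - X) / B
  g$out <- list(W = crossprod(dec$H2, dlogits), b = colSums(dlogits))
  dH2 <- dlogits %*% t(params$out$W) * dlrelu(dec$A2)
  g$dec2 <- list(W = crossprod(dec$H1, dH2), b = colSums(dH2))
  dH1 <- dH2 %*% t(params$dec2$W) * dlrelu(dec$A1)
  g$dec1 <- list(W = crossprod(Z, dH1), b = colSums(dH1))
  dZ <- dH1 %*% t(params$dec1$W)

  g$heads <- vector("list", length(params$heads))
  for (i in seq_along(params$heads)) {
    hd <- params$heads[[i]]
    hf <- head_fwd[[i]]
    dl <- head_ce[[i]]$dlogits
    gh <- list(kind = hd$kind,
               h2 = list(W = crossprod(hf$H1, dl), b = colSums(dl)))
    dH1h <- dl %*% t(hd$h2$W)
    if (hd$kind == "nonlinear") dH1h <- dH1h * dlrelu(hf$A1)
    gh$h1 <- list(W = crossprod(Z, dH1h), b = colSums(dH1h))
    g$heads[[i]] <- gh
    dZ <- dZ + dH1h %*% t(hd$h1$W)
  }

  s <- gamma * sign(kl - C)
  dmu <- dZ + s * enc$mu / B
  dlv <- dZ * eps * 0.5 * sd + s * 0.5 * (exp(enc$logvar) - 1) / B
  g$mu <- list(W = crossprod(enc$H2, dmu), b = colSums(dmu))
  g$lv <- list(W = crossprod(enc$H2, dlv), b = colSums(dlv))
  dH2e <- (dmu %*% t(params$mu$W) + dlv %*% t(params$lv$W)) * dlrelu(enc$A2)
  g$enc2 <- list(W = crossprod(enc$H1, dH2e), b = colSums(dH2e))
  dH1e <- dH2e %*% t(params$enc2$W) * dlrelu(enc$A1)
  g$enc1 <- list(W = crossprod(X, dH1e), b = colSums(dH1e))

  out$grads <- g
  out
}

# --- Adam ------------------------------------------------------------------

adam_state <- function(params) {
  walk <- function(p) {
    if (is.list(p) && !is.null(p$W))
      return(list(W = list(m = p$W * 0, v = p$W * 0),
                  b = list(m = p$b * 0, v = p$b * 0)))
    if (is.list(p)) {
      out <- vector("list", length(p)); names(out) <- names(p)
      for (k in seq_along(p)) {
        if (identical(names(p)[k], "kind")) { out[[k]] <- p[[k]]; next }
        out[[k]] <- walk(p[[k]])
      }
      return(out)
    }
    p
  }
  walk(params)
}

# Update parameters in place (functionally); `t` is the 1-based step count.
adam_step <- function(params, state, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, s, g) {
    if (is.list(p) && !is.null(p$W)) {
      for (nm in c("W", "b")) {
        s[[nm]]$m <- beta1 * s[[nm]]$m + (1 - beta1) * g[[nm]]
        s[[nm]]$v <- beta2 * s[[nm]]$v + (1 - beta2) * g[[nm]]^2
        mhat <- s[[nm]]$m / (1 - beta1^t)
        vhat <- s[[nm]]$v / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      return(list(p = p, s = s))
    }
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else as.character(seq_along(p))
      for (k in seq_along(p)) {
        gk <- if (!is.null(names(g))) g[[keys[k]]] else g[[k]]
        if (identical(keys[k], "kind") || is.null(gk)) next
        sk <- if (!is.null(names(s))) s[[keys[k]]] else s[[k]]
        r <- walk(p[[k]], sk, gk)
        p[[k]] <- r$p
        if (!is.null(names(s))) s[[keys[k]]] <- r$s else s[[k]] <- r$s
      }
      return(list(p = p, s = s))
    }
    list(p = p, s = s)
  }
  walk(params, state, grads)
}
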