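test_that("distortion ratios obey identity, homogeneity and rigid-motion invariance", {
  set.seed(21)
  z <- matrix(rnorm(40 * 5), 40)
  emb <- as_embedding(z)
  # identity
  expect_equal(unique(distortion_ratios(emb, emb)$rho), 1)
  # uniform scaling multiplies every ratio by the scale
  emb2 <- as_embedding(2 * z)
  expect_equal(distortion_ratios(emb, emb2)$rho, rep(2, choose(40, 2)))
  # rotation + translation leaves distances, hence ratios, unchanged
  R <- random_orthogonal(5)
  emb3 <- as_embedding(z %*% R + rep(c(3, -1, 2, 0, 5), each = 40))
  expect_equal(distortion_ratios(emb, emb3)$rho, rep(1, choose(40, 2)))
  # applying the scaled rigid motion to the *reference* divides ratios by s
  emb4 <- as_embedding(3 * z %*% R)
  expect_equal(distortion_ratios(emb4, emb)$rho, rep(1 / 3, choose(40, 2)))
  # near-zero reference distances are excluded and counted
  zdup <- rbind(z, z[1, , drop = FALSE])
  embd <- as_embedding(zdup)
  embd2 <- as_embedding(2 * zdup)
  r <- distortion_ratios(embd, embd2)
  expect_equal(r$n_excluded, 1L)
  expect_error(distortion_ratios(emb, as_embedding(z, index = 2:41)),
               "mismatched")
})

test_that("item distortion matrix equals hand and brute-force aggregation", {
  # 4-point example with two labels, means computed by hand
  za <- matrix(c(0, 0, 1, 0, 0, 2, 3, 2), 4, 2, byrow = TRUE)
  zb <- za; zb[, 1] <- zb[, 1] * 2  # stretch the first axis
  emb_a <- as_embedding(za, label = c(0L, 0L, 1L, 1L))
  emb_b <- as_embedding(zb, label = c(0L, 0L, 1L, 1L))
  rho <- distortion_ratios(emb_a, emb_b)
  m <- item_distortion_matrix(rho, emb_a$label, n_labels = 2L)
  d <- function(p, q) sqrt(sum((p - q)^2))
  r_by_hand <- function(i, j) d(zb[i, ], zb[j, ]) / d(za[i, ], za[j, ])
  expect_equal(m$mean[1, 1], r_by_hand(1, 2))
  expect_equal(m$mean[2, 2], r_by_hand(3, 4))
  expect_equal(m$mean[1, 2], mean(c(r_by_hand(1, 3), r_by_hand(1, 4),
                                    r_by_hand(2, 3), r_by_hand(2, 4))))
  expect_equal(m$mean[1, 2], m$mean[2, 1])
  expect_equal(m$count, matrix(c(2L, 4L, 4L, 2L), 2))

  # oracle equivalence: brute-force double loop over all image pairs
  set.seed(22)
  n <- 200
  za <- matrix(rnorm(n * 5), n)
  zb <- matrix(rnorm(n * 5), n) + za
  labels <- sample(0:168, n, replace = TRUE)
  emb_a <- as_embedding(za, label = labels)
  emb_b <- as_embedding(zb, label = labels)
  m <- item_distortion_matrix(distortion_ratios(emb_a, emb_b), labels)
  acc <- matrix(0, 169, 169); cnt <- matrix(0, 169, 169)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- d(zb[i, ], zb[j, ]) / d(za[i, ], za[j, ])
    a <- labels[i] + 1; b <- labels[j] + 1
    acc[a, b] <- acc[a, b] + r; cnt[a, b] <- cnt[a, b] + 1
    acc[b, a] <- acc[b, a] + r; cnt[b, a] <- cnt[b, a] + 1
  }
  oracle <- acc / cnt
  oracle[cnt == 0] <- NA
  expect_equal(m$mean, oracle, tolerance = 1e-12)
  expect_equal(m$count, cnt)
})

test_that("class distortion matrix recovers planted within-class dilations", {
  set.seed(23)
  # class 1 points are scaled by 2 about the origin: within-1 ratios are
  # exactly 2, within-0 exactly 1
  z0 <- matrix(rnorm(30 * 5), 30)
  z1 <- matrix(rnorm(20 * 5), 20)
  za <- rbind(z0, z1)
  zb <- rbind(z0, 2 * z1)
  cls <- c(rep(0L, 30), rep(1L, 20))
  emb_a <- as_embedding(za, label = cls)
  emb_b <- as_embedding(zb, label = cls)
  rho <- distortion_ratios(emb_a, emb_b)
  m <- class_distortion_matrix(rho, cls)
  expect_equal(m$mean[1, 1], 1)
  expect_equal(m$mean[2, 2], 2)
  # class matrix is the pair-count-weighted aggregation of the item matrix
  item <- item_distortion_matrix(rho, cls, n_labels = 2L)
  expect_equal(m$mean, item$mean)
  expect_equal(m$count, item$count)
  # within/between summary agrees
  wb <- within_between_distortion(rho, cls)
  expect_equal(unname(wb["within"]),
               sum(m$mean[1, 1] * m$count[1, 1], m$mean[2, 2] * m$count[2, 2]) /
                 sum(m$count[1, 1], m$count[2, 2]))
})

test_that("metric MDS recovers embeddable configurations up to rigid motion", {
  set.seed(24)
  # exactly 2-D configuration
  pts <- matrix(rnorm(15 * 2), 15)
  fit <- mds_project(dist(pts), k = 2)
  proc <- vegan::procrustes(pts, fit$points, symmetric = TRUE)
  expect_lt(proc$ss, 1e-6)
  # three equidistant points form an equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  tri <- mds_project(d3, k = 2)$points
  sides <- as.vector(dist(tri))
  expect_equal(max(sides) / min(sides), 1, tolerance = 1e-4)
  # stress is non-increasing in the output dimension on random 5-D data
  z5 <- matrix(rnorm(25 * 5), 25)
  d5 <- dist(z5)
  expect_lte(mds_project(d5, k = 3)$stress, mds_project(d5, k = 2)$stress + 1e-8)
  # validation of malformed input
  bad <- matrix(rnorm(9), 3)
  expect_error(mds_project(bad), "symmetric")
})

test_that("channel maps average activations per position pair", {
  ds <- probe_dataset()
  m <- init_vae(vae_spec(), seed = 30)
  # constant encoder: zero out the posterior-mean layer entirely
  m$params$mu$W[] <- 0; m$params$mu$b[] <- c(1, 2, 3, 4, 5)
  cm <- channel_activation_maps(m, ds, split = "all")
  expect_true(all(cm$counts >= 1))
  for (k in 1:5) expect_equal(cm$maps[[k]], matrix(k, 13, 13))

  # a hand-built encoder reading out the upper corridor position is
  # axis-selective along rows only
  m2 <- init_vae(vae_spec(), seed = 30)
  m2$params <- within(m2$params, {
    enc1$W[] <- 0; enc1$b[] <- 0
    enc2$W[] <- 0; enc2$b[] <- 0
    mu$W[] <- 0; mu$b[] <- 0
  })
  # wire pixel (row 0, column c) -> hidden 1 unit c with weight c
  m2$params$enc1$W[1:13, 1] <- 0:12
  m2$params$enc2$W[1, 1] <- 1
  m2$params$mu$W[1, 1] <- 1
  cm2 <- channel_activation_maps(m2, ds, split = "all")
  sel <- axis_selectivity(cm2$maps[[1]])
  expect_gt(sel[["rows"]], 0.9)
  expect_lt(sel[["cols"]], 0.1)
  # a channel mixing both corridors is not axis-selective
  m2$params$enc1$W[7 * 13 + 1:13, 1] <- 0:12  # add lower-corridor row too
  cm3 <- channel_activation_maps(m2, ds, split = "all")
  sel3 <- axis_selectivity(cm3$maps[[1]])
  expect_lt(max(sel3), 0.8)
})

test_that("active channel counting keys on per-dimension KL", {
  ds <- probe_dataset()
  m <- init_vae(vae_spec(), seed = 33)
  # encoder emitting exactly the prior: mu = 0, logvar = 0
  m$params <- within(m$params, {
    enc1$W[] <- 0; enc1$b[] <- 0; enc2$W[] <- 0; enc2$b[] <- 0
    mu$W[] <- 0; mu$b[] <- 0; lv$W[] <- 0; lv$b[] <- 0
  })
  expect_equal(as.integer(active_channel_count(m, ds, split = "all")), 0L)
  # waking one channel up: shifted mean on channel 2
  m$params$mu$b[2] <- 1
  a <- active_channel_count(m, ds, split = "all")
  expect_equal(as.integer(a), 1L)
  expect_equal(unname(attr(a, "kl_per_dim")[2]), 0.5)
  # degenerate threshold
  expect_equal(as.integer(active_channel_count(m, ds, threshold = Inf,
                                               split = "all")), 0L)
})

test_that("embedding tables are deterministic with one row per image", {
  ds <- generate_dataset(300, seed = 55)
  m <- init_vae(vae_spec(), seed = 1)
  emb <- embed_dataset(m, ds, split = "all")
  expect_equal(nrow(emb), 300)
  # duplicate images embed identically
  ds$images[2, ] <- ds$images[1, ]
  emb2 <- embed_dataset(m, ds, split = "all")
  expect_equal(unlist(emb2[2, 1:5]), unlist(emb2[1, 1:5]),
               ignore_attr = TRUE)
})

test_that("silhouette-selected k-means finds planted cluster counts", {
  set.seed(26)
  centers <- matrix(c(0, 0, 0, 0, 0,
                      8, 0, 0, 0, 0,
                      0, 8, 0, 0, 0,
                      8, 8, 0, 0, 0), 4, 5, byrow = TRUE)
  z <- centers[rep(1:4, each = 50), ] + matrix(rnorm(200 * 5, 0, 0.3), 200)
  emb <- as_embedding(z)
  k <- latent_cluster_count(emb, k_range = 2:8)
  expect_equal(as.integer(k), 4L)
})
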