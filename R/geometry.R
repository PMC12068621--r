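#' Embed a dataset in latent space
#'
#' One 5-D posterior-mean vector per image, with positions, the scalar
#' position label and all task labels carried along.
#'
#' @param model A trained `corridor_vae`.
#' @param dataset A `corridors_dataset`.
#' @param split `"test"`, `"train"` or `"all"`.
#' @return A data.frame of class `embedding_table` with columns
#'   `z1..z<latent_dim>`, `x_uc`, `x_lc`, `label`, `T1`..`T4` and the
#'   source row index `index`.
#' @export
embed_dataset <- function(model, dataset, split = c("test", "train", "all")) {
  stopifnot(inherits(model, "corridor_vae"), inherits(dataset, "corridors_dataset"))
  split <- match.arg(split)
  idx <- switch(split, test = dataset$test, train = dataset$train,
                all = seq_len(nrow(dataset$images)))
  mu <- encode(model, dataset$images[idx, , drop = FALSE])$mu
  colnames(mu) <- paste0("z", seq_len(ncol(mu)))
  out <- data.frame(mu, x_uc = dataset$x_uc[idx], x_lc = dataset$x_lc[idx],
                    label = dataset$label[idx], dataset$tasks[idx, , drop = FALSE],
                    index = idx)
  class(out) <- c("embedding_table", "data.frame")
  out
}

embedding_matrix <- function(emb) {
  as.matrix(emb[, grep("^z[0-9]+$", names(emb)), drop = FALSE])
}

#' Metric multidimensional scaling of a dissimilarity matrix
#'
#' Classical scaling provides the starting configuration, which is then
#' refined by metric least-squares MDS (stress minimization via
#' [vegan::monoMDS()] with a linear model). Configurations that embed
#' exactly in `k` dimensions are recovered up to rigid motion.
#'
#' @param d A symmetric non-negative dissimilarity matrix (zero diagonal)
#'   or a `dist` object.
#' @param k Output dimensionality (2 or 3).
#' @return A list with `points` (n x k coordinates) and `stress`.
#' @export
mds_project <- function(d, k = 2L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), k %in% c(2L, 3L))
  if (any(d < 0) || max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-8))
    stop("d must be symmetric and non-negative with a zero diagonal")
  init <- stats::cmdscale(d, k = k)
  if (ncol(init) < k)  # degenerate (e.g. all points coincide)
    init <- cbind(init, matrix(0, nrow(d), k - ncol(init)))
  init_stress <- linear_stress(d, init)
  fit <- tryCatch(
    vegan::monoMDS(stats::as.dist(d), y = init, k = k, model = "linear"),
    error = function(e) NULL)
  pts <- init
  # keep the classical configuration when the stress-minimization pass
  # does not improve on it (e.g. the configuration is already exact)
  if (!is.null(fit)) {
    cand <- fit$points[, seq_len(k), drop = FALSE]
    if (linear_stress(d, cand) < init_stress) pts <- cand
  }
  list(points = pts, stress = linear_stress(d, pts))
}

# Kruskal stress-1 of a configuration under the best linear (through-origin
# plus intercept) regression of configuration distances on dissimilarities.
linear_stress <- function(d, points) {
  dd <- as.vector(stats::as.dist(d))
  cd <- as.vector(stats::dist(points))
  dhat <- stats::fitted(stats::lm(cd ~ dd))
  denom <- sum(cd^2)
  if (denom < .Machine$double.eps) return(0)
  sqrt(sum((cd - dhat)^2) / denom)
}

#' Pairwise distance-distortion ratios between two embeddings
#'
#' For every unordered pair of images (u, v), the ratio
#' `rho(u, v) = d_B(u, v) / d_A(u, v)` of Euclidean latent distances in
#' embedding B relative to reference embedding A. Ratios above 1 indicate
#' dilation in B, below 1 compression. Pairs whose reference distance is
#' at most `eps` are excluded (and counted) rather than divided through.
#'
#' @param emb_a,emb_b `embedding_table`s over the same images (matched by
#'   `index`).
#' @param eps Exclusion threshold on the reference distance.
#' @return A list of class `distortion_ratios`: `rho` (vector), `i`, `j`
#'   (pair row indices into `emb_a`), `n_excluded`.
#' @export
distortion_ratios <- function(emb_a, emb_b, eps = 1e-8) {
  stopifnot(inherits(emb_a, "embedding_table"), inherits(emb_b, "embedding_table"))
  if (!identical(emb_a$index, emb_b$index))
    stop("embeddings cover different images (mismatched index columns)")
  da <- stats::dist(embedding_matrix(emb_a))
  db <- stats::dist(embedding_matrix(emb_b))
  keep <- da > eps
  n <- nrow(emb_a)
  ij <- pair_indices(n)
  list_out <- list(rho = as.vector(db[keep] / da[keep]),
                   i = ij$i[keep], j = ij$j[keep],
                   n_excluded = sum(!keep))
  class(list_out) <- "distortion_ratios"
  list_out
}

# Row/column indices of dist's lower-triangle ordering for n points.
pair_indices <- function(n) {
  j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- sequence((n - 1L):1L) + j
  list(i = i, j = j)
}

#' Aggregate distortion ratios over position labels
#'
#' Cell (a, b) holds the mean rho over all image pairs where one image has
#' position label a and the other label b (symmetric; cells with no pairs
#' are `NA`).
#'
#' @param rho A `distortion_ratios` object.
#' @param labels Per-image labels aligned with the embeddings the ratios
#'   came from (position labels 0..168 for the item matrix).
#' @param n_labels Number of distinct labels (matrix dimension).
#' @return A list of class `distortion_matrix` with `mean` (n_labels x
#'   n_labels) and `count` matrices.
#' @export
item_distortion_matrix <- function(rho, labels, n_labels = 169L) {
  stopifnot(inherits(rho, "distortion_ratios"))
  la <- labels[rho$i]
  lb <- labels[rho$j]
  acc <- matrix(0, n_labels, n_labels)
  cnt <- matrix(0L, n_labels, n_labels)
  # accumulate symmetrically via a flat index
  f1 <- la * n_labels + lb + 1L
  f2 <- lb * n_labels + la + 1L
  s1 <- rowsum(c(rho$rho, rho$rho), c(f1, f2))
  acc[as.integer(rownames(s1))] <- s1
  c1 <- rowsum(rep(1L, 2L * length(rho$rho)), c(f1, f2))
  cnt[as.integer(rownames(c1))] <- c1
  m <- acc / cnt
  m[cnt == 0L] <- NA_real_
  # the flat index above fills the matrix with label a as the row block:
  # reshape so rows index the first label
  m <- t(matrix(m, n_labels, n_labels))
  cnt <- t(matrix(cnt, n_labels, n_labels))
  structure(list(mean = m, count = cnt), class = "distortion_matrix")
}

#' @rdname item_distortion_matrix
#' @param class_labels Per-image class labels (0-based) from the
#'   experiment context: frequency classes for the unbalanced-data models,
#'   task classes for the classifier models.
#' @export
class_distortion_matrix <- function(rho, class_labels) {
  k <- max(class_labels) + 1L
  item_distortion_matrix(rho, class_labels, n_labels = k)
}

#' Latent channel-activation maps
#'
#' For each latent channel, a 13x13 matrix whose (i, j) element is the
#' mean posterior-mean activation of that channel over all test images
#' with corridors at positions (i, j) (i indexes the upper corridor).
#'
#' @param model A trained `corridor_vae`.
#' @param dataset A `corridors_dataset`; the test split should cover all
#'   169 position pairs for complete maps.
#' @param split Evaluation split.
#' @return A list of class `channel_maps`: `maps` (list of `latent_dim`
#'   matrices), `counts` (images per cell). Cells with no images are `NA`
#'   (with a warning).
#' @export
channel_activation_maps <- function(model, dataset,
                                    split = c("test", "train", "all")) {
  split <- match.arg(split)
  emb <- embed_dataset(model, dataset, split)
  mu <- embedding_matrix(emb)
  g <- dataset$spec$config$grid_size
  cell <- factor(emb$x_uc * g + emb$x_lc, levels = 0:(g * g - 1L))
  counts <- matrix(as.integer(table(cell)), g, g, byrow = TRUE)
  if (any(counts == 0L))
    warning(sum(counts == 0L), " position pair(s) absent from the ", split,
            " split; their map cells are NA")
  maps <- lapply(seq_len(ncol(mu)), function(k) {
    s <- tapply(mu[, k], cell, mean)
    matrix(as.numeric(s), g, g, byrow = TRUE)
  })
  names(maps) <- colnames(mu)
  structure(list(maps = maps, counts = counts), class = "channel_maps")
}

#' Count active latent channels
#'
#' A channel is active when its mean per-dimension KL over the evaluation
#' split exceeds `threshold` nats. The per-channel KLs are returned so the
#' count is auditable.
#'
#' @param model A trained `corridor_vae`.
#' @param dataset A `corridors_dataset`.
#' @param threshold Activity threshold in nats.
#' @param split Evaluation split.
#' @return Integer count with attribute `kl_per_dim`.
#' @export
active_channel_count <- function(model, dataset, threshold = 0.05,
                                 split = c("test", "train", "all")) {
  split <- match.arg(split)
  ev <- evaluate(model, dataset, split = split, tasks = character(0))
  structure(sum(ev$kl_per_dim > threshold), kl_per_dim = ev$kl_per_dim)
}

#' Axis selectivity of a channel map
#'
#' Share of a map's total variance explained by its row means (upper
#' corridor) or column means (lower corridor). A perfectly disentangled
#' channel has selectivity near 1 along one axis and near 0 along the
#' other.
#'
#' @param map A 13x13 channel map.
#' @return Named vector `c(rows = ..., cols = ...)`.
#' @export
axis_selectivity <- function(map) {
  tot <- stats::var(as.vector(map))
  if (tot < .Machine$double.eps) return(c(rows = NA_real_, cols = NA_real_))
  n <- nrow(map)
  c(rows = stats::var(rep(rowMeans(map), each = ncol(map))) / tot,
    cols = stats::var(rep(colMeans(map), times = nrow(map))) / tot)
}

#' Silhouette-selected cluster count of an embedding
#'
#' Operationalizes cluster-count statements about latent spaces: k-means
#' (25 restarts) for each k in `k_range` on the latent vectors, keeping
#' the k with the highest mean silhouette width. Reported as descriptive
#' evidence of prototypization, not a hard statistic.
#'
#' @param emb An `embedding_table`.
#' @param k_range Candidate cluster counts.
#' @param max_points Subsample cap (silhouette cost is quadratic).
#' @param seed Seed for subsampling and k-means restarts.
#' @return Selected k with attribute `silhouette` (named by k).
#' @export
latent_cluster_count <- function(emb, k_range = 2:8, max_points = 1500L,
                                 seed = 1L) {
  stopifnot(inherits(emb, "embedding_table"))
  mu <- embedding_matrix(emb)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (nrow(mu) > max_points) mu <- mu[sample(nrow(mu), max_points), ]
  d <- stats::dist(mu)
  sil <- vapply(k_range, function(k) {
    km <- stats::kmeans(mu, centers = k, nstart = 25, iter.max = 50)
    mean(cluster::silhouette(km$cluster, d)[, 3])
  }, numeric(1))
  names(sil) <- k_range
  structure(k_range[which.max(sil)], silhouette = sil)
}
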