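#' Specify a Corridors dataset
#'
#' @param n_images Number of images to generate.
#' @param weighting Position-pair frequency scheme; see [sample_positions()].
#' @param seed Integer seed controlling both the position draws and the
#'   pixel noise.
#' @param config A [corridor_config()].
#' @param test_fraction Fraction of images held out as a test split. The
#'   split is stratified by position label and deterministic given `seed`.
#' @return An object of class `corridors_dataset_spec`.
#' @export
dataset_spec <- function(n_images, weighting = "balanced", seed = 1L,
                         config = corridor_config(), test_fraction = 0.1) {
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images <= 0L) stop("n_images must be > 0")
  weighting <- match.arg(weighting, c("balanced", "lower_left_10x", "aligned_10x"))
  stopifnot(inherits(config, "corridor_config"),
            test_fraction >= 0, test_fraction < 1)
  structure(
    list(n_images = n_images, weighting = weighting, seed = as.integer(seed),
         config = config, test_fraction = test_fraction),
    class = "corridors_dataset_spec")
}

#' Generate a Corridors dataset
#'
#' Draws `n_images` position pairs i.i.d. under the requested frequency
#' scheme, renders the binary images, and attaches the scalar position
#' label and all four task labels. A stratified train/test split (90/10 by
#' default) is computed at generation time so every downstream consumer
#' evaluates on the same held-out images.
#'
#' @param spec A [dataset_spec()], or a number of images (in which case the
#'   remaining arguments are used to build the spec).
#' @param weighting,seed,config Passed to [dataset_spec()] when `spec` is
#'   a count.
#' @return An object of class `corridors_dataset`: a list with
#'   * `images`: `n x grid_size^2` 0/1 matrix, one row-major pixel vector
#'     per image;
#'   * `x_uc`, `x_lc`: integer position vectors;
#'   * `label`: scalar position labels `13 * x_uc + x_lc`;
#'   * `tasks`: `n x 4` integer matrix of task labels (columns T1..T4);
#'   * `train`, `test`: index vectors of the stratified split;
#'   * `spec`: the generating spec.
#' @examples
#' ds <- generate_dataset(500, seed = 7)
#' nrow(ds$images)
#' @export
generate_dataset <- function(spec, weighting = "balanced", seed = 1L,
                             config = corridor_config()) {
  if (!inherits(spec, "corridors_dataset_spec"))
    spec <- dataset_spec(spec, weighting = weighting, seed = seed, config = config)
  cfg <- spec$config
  g <- cfg$grid_size
  n <- spec$n_images
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  pos <- sample_positions(n, spec$weighting, cfg)
  profs <- vapply(seq_len(g) - 1L, corridor_profile, numeric(g), config = cfg)
  # profs: grid_size x grid_size, column mu+1 holds the profile for position mu
  up <- t(profs)[pos$x_uc + 1L, , drop = FALSE]  # n x g per-column probabilities
  lo <- t(profs)[pos$x_lc + 1L, , drop = FALSE]
  X <- matrix(0L, n, g * g)
  for (r in seq_len(g) - 1L) {
    cols <- (r * g + 1L):(r * g + g)
    if (r == cfg$divider_row) {
      X[, cols] <- 1L
    } else {
      p <- if (r < cfg$divider_row) up else lo
      X[, cols] <- (matrix(stats::runif(n * g), n, g) < p | p >= 1) + 0L
    }
  }

  tasks <- cbind(T1 = task_label("T1", pos$x_uc, pos$x_lc),
                 T2 = task_label("T2", pos$x_uc, pos$x_lc),
                 T3 = task_label("T3", pos$x_uc, pos$x_lc),
                 T4 = task_label("T4", pos$x_uc, pos$x_lc))
  lab <- position_label(pos$x_uc, pos$x_lc, g)
  test <- stratified_test_indices(lab, spec$test_fraction)

  structure(
    list(images = X, x_uc = pos$x_uc, x_lc = pos$x_lc, label = lab,
         tasks = tasks, train = setdiff(seq_len(n), test), test = test,
         spec = spec),
    class = "corridors_dataset")
}

# Hold out ~frac of the images within each position label.
stratified_test_indices <- function(label, frac) {
  if (frac <= 0) return(integer(0))
  idx <- split(seq_along(label), label)
  sort(unlist(lapply(idx, function(i) {
    k <- round(length(i) * frac)
    if (k == 0L) return(integer(0))
    sample(i, k)
  }), use.names = FALSE))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.corridors_dataset <- function(x, ...) {
  cat(sprintf("Corridors dataset: %d images (%s), %d train / %d test, seed %d\n",
              nrow(x$images), x$spec$weighting, length(x$train), length(x$test),
              x$spec$seed))
  invisible(x)
}

#' Write / read a Corridors dataset archive
#'
#' The archive is a directory holding `data.csv` (one row per image:
#' index, positions, labels, task labels, then the 0/1 pixels in row-major
#' order) and `manifest.yaml` recording the generating spec, so a dataset
#' round-trips bit-identically.
#'
#' @param dataset A `corridors_dataset`.
#' @param path Directory to create (write) or read.
#' @return `read_dataset` returns the reconstructed `corridors_dataset`;
#'   `write_dataset` returns `path` invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "corridors_dataset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(dataset$images)
  meta <- data.frame(index = seq_len(n), x_uc = dataset$x_uc, x_lc = dataset$x_lc,
                     label = dataset$label)
  tab <- cbind(meta, as.data.frame(dataset$tasks),
               as.data.frame(dataset$images))
  data.table::fwrite(tab, file.path(path, "data.csv"))
  sp <- dataset$spec
  yaml::write_yaml(list(
    format = "corridors-archive-1",
    n_images = sp$n_images, weighting = sp$weighting, seed = sp$seed,
    test_fraction = sp$test_fraction,
    grid_size = sp$config$grid_size, divider_row = sp$config$divider_row,
    sigma = sp$config$sigma, profile = sp$config$profile,
    test_indices = dataset$test),
    file.path(path, "manifest.yaml"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  mpath <- file.path(path, "manifest.yaml")
  dpath <- file.path(path, "data.csv")
  if (!file.exists(mpath) || !file.exists(dpath))
    stop("not a Corridors dataset archive (missing manifest.yaml/data.csv): ", path)
  man <- yaml::read_yaml(mpath)
  if (!identical(man$format, "corridors-archive-1"))
    stop("unrecognised archive format in ", mpath)
  tab <- data.table::fread(dpath, data.table = FALSE)
  g <- man$grid_size
  npix <- g * g
  fixed <- c("index", "x_uc", "x_lc", "label", "T1", "T2", "T3", "T4")
  if (!all(fixed %in% names(tab)) || ncol(tab) != length(fixed) + npix)
    stop("corrupt archive: unexpected columns in ", dpath)
  spec <- dataset_spec(man$n_images, man$weighting, man$seed,
                       corridor_config(g, man$divider_row, man$sigma, man$profile),
                       man$test_fraction)
  X <- as.matrix(tab[, setdiff(names(tab), fixed), drop = FALSE])
  dimnames(X) <- NULL
  storage.mode(X) <- "integer"
  test <- as.integer(unlist(man$test_indices))
  structure(
    list(images = X, x_uc = as.integer(tab$x_uc), x_lc = as.integer(tab$x_lc),
         label = as.integer(tab$label),
         tasks = cbind(T1 = as.integer(tab$T1), T2 = as.integer(tab$T2),
                       T3 = as.integer(tab$T3), T4 = as.integer(tab$T4)),
         train = setdiff(seq_len(nrow(X)), test), test = test, spec = spec),
    class = "corridors_dataset")
}
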