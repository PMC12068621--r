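#' Sample corridor position pairs under a frequency scheme
#'
#' Draws i.i.d. position pairs (x_UC, x_LC) from the 169 possible
#' combinations. `"balanced"` is uniform. `"lower_left_10x"` gives every
#' pair with the lower corridor on the left (x_LC <= 6) ten times the
#' per-pair probability of the remaining pairs. `"aligned_10x"` gives every
#' aligned pair (x_LC == x_UC) ten times the per-pair probability of
#' non-aligned pairs. The 10:1 weights reproduce, in expectation, datasets
#' in which the favoured images appear ten times more often.
#'
#' @param n Number of pairs to draw.
#' @param weighting One of `"balanced"`, `"lower_left_10x"`, `"aligned_10x"`.
#' @param config A [corridor_config()].
#' @return A data.frame with integer columns `x_uc` and `x_lc`.
#' @examples
#' set.seed(1)
#' table(sample_positions(1000, "lower_left_10x")$x_lc <= 6)
#' @export
sample_positions <- function(n, weighting = c("balanced", "lower_left_10x", "aligned_10x"),
                             config = corridor_config()) {
  weighting <- match.arg(weighting)
  g <- config$grid_size
  pairs <- expand.grid(x_uc = seq_len(g) - 1L, x_lc = seq_len(g) - 1L)
  w <- position_pair_weights(weighting, config)
  idx <- sample.int(nrow(pairs), n, replace = TRUE, prob = w)
  data.frame(x_uc = pairs$x_uc[idx], x_lc = pairs$x_lc[idx])
}

# Per-pair sampling weights (unnormalized), ordered as expand.grid(x_uc, x_lc).
position_pair_weights <- function(weighting, config = corridor_config()) {
  g <- config$grid_size
  pairs <- expand.grid(x_uc = seq_len(g) - 1L, x_lc = seq_len(g) - 1L)
  w <- rep(1, nrow(pairs))
  mid <- (g - 1L) %/% 2L
  if (weighting == "lower_left_10x") w[pairs$x_lc <= mid] <- 10
  else if (weighting == "aligned_10x") w[pairs$x_lc == pairs$x_uc] <- 10
  else if (weighting != "balanced") stop("unknown weighting: ", weighting)
  w
}

#' Scalar position label of an image
#'
#' Combines the two corridor positions into a single label
#' `l = 13 * x_uc + x_lc`, ranging over 0..168.
#'
#' @param x_uc,x_lc Integer vectors of corridor positions (0..12).
#' @param grid_size Side length of the grid.
#' @return Integer vector of labels.
#' @export
position_label <- function(x_uc, x_lc, grid_size = 13L) {
  stopifnot(all(x_uc >= 0 & x_uc < grid_size), all(x_lc >= 0 & x_lc < grid_size))
  as.integer(grid_size) * as.integer(x_uc) + as.integer(x_lc)
}

#' Classification-task labels for corridor images
#'
#' The four tasks defined on the corridor positions:
#' * `T1` (binary): 1 iff `x_uc <= x_lc` (upper corridor left of, or
#'   aligned with, the lower corridor).
#' * `T2` (binary): 1 iff `x_uc < 6`, or (`x_uc >= 6` and `x_lc >= 6`).
#' * `T3` (binary): 1 iff the corridors are aligned (`x_uc == x_lc`).
#' * `T4` (25 classes): both positions are binned into the intervals
#'   `[0,1], [2,4], [5,7], [8,10], [11,12]` (bins 0..4) and the label is
#'   `upper_bin * 5 + lower_bin`. E.g. positions (6, 11) fall in bins 2 and
#'   4, giving label 14.
#'
#' @param task Task identifier: `"T1"`, `"T2"`, `"T3"` or `"T4"`.
#' @param x_uc,x_lc Integer vectors of corridor positions (0..12).
#' @return Integer vector of 0-based class labels.
#' @examples
#' task_label("T4", 6, 11)  # 14
#' task_label("T1", 0, 12)  # 1
#' @export
task_label <- function(task, x_uc, x_lc) {
  task <- match.arg(task, c("T1", "T2", "T3", "T4"))
  stopifnot(length(x_uc) == length(x_lc),
            all(x_uc >= 0 & x_uc <= 12), all(x_lc >= 0 & x_lc <= 12))
  switch(task,
    T1 = as.integer(x_uc <= x_lc),
    T2 = as.integer(x_uc < 6 | (x_uc >= 6 & x_lc >= 6)),
    T3 = as.integer(x_uc == x_lc),
    T4 = position_bin(x_uc) * 5L + position_bin(x_lc))
}

# Bin a position 0..12 into the five task-4 bins [0,1],[2,4],[5,7],[8,10],[11,12].
position_bin <- function(x) {
  findInterval(x, c(0, 2, 5, 8, 11)) - 1L
}

#' Number of classes of a task
#' @param task Task identifier (`"T1"`..`"T4"`).
#' @return Integer class count (2 for T1-T3, 25 for T4).
#' @export
task_n_classes <- function(task) {
  task <- match.arg(task, c("T1", "T2", "T3", "T4"))
  if (task == "T4") 25L else 2L
}
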