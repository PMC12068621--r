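#' Configuration of the Corridors image generator
#'
#' A Corridors image is a 13x13 binary grid split into an upper and a lower
#' section by an all-white divider row. Each section contains one vertical
#' "corridor": a deterministic white core column at an integer position
#' 0..12, surrounded by white noise pixels drawn independently per pixel
#' from a Bernoulli distribution whose success probability follows a
#' Gaussian profile centred on the core column.
#'
#' @param grid_size Side length of the square pixel grid. The analyses in
#'   this package assume 13; other values are accepted for plumbing only.
#' @param divider_row 0-based index of the all-white horizontal divider row.
#'   The default, `(grid_size - 1) / 2`, is the only symmetric split with a
#'   width-1 line (rows 0-5 upper section, row 6 divider, rows 7-12 lower
#'   section for a 13-pixel grid).
#' @param sigma Standard deviation, in pixels, of the Gaussian profile that
#'   drives the Bernoulli pixel noise around each corridor core.
#' @param profile How the Gaussian is mapped to a Bernoulli probability:
#'   `"peak"` rescales it to 1 at the core column so that the core is
#'   deterministically white; `"density"` uses the raw normal density capped
#'   at 1.
#' @return An object of class `corridor_config`.
#' @examples
#' cfg <- corridor_config()
#' corridor_profile(6, cfg)
#' @export
corridor_config <- function(grid_size = 13L, divider_row = NULL, sigma = 1.2,
                            profile = c("peak", "density")) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 3L) stop("grid_size must be at least 3")
  if (is.null(divider_row)) divider_row <- (grid_size - 1L) %/% 2L
  divider_row <- as.integer(divider_row)
  if (divider_row < 0L || divider_row >= grid_size)
    stop("divider_row must lie in [0, grid_size)")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  structure(
    list(grid_size = grid_size, divider_row = divider_row, sigma = sigma,
         profile = match.arg(profile)),
    class = "corridor_config")
}

#' @export
print.corridor_config <- function(x, ...) {
  cat(sprintf("Corridors config: %dx%d grid, divider row %d, sigma = %g (%s profile)\n",
              x$grid_size, x$grid_size, x$divider_row, x$sigma, x$profile))
  invisible(x)
}

#' Bernoulli probability profile of a corridor
#'
#' Probability that each pixel of a section row is white, for a corridor
#' centred at `mu`. With the default `"peak"` profile this is
#' `exp(-(x - mu)^2 / (2 sigma^2))`, i.e. a Gaussian rescaled to peak 1 so
#' that the core column is always white.
#'
#' @param mu Integer corridor position (0-based column index).
#' @param config A [corridor_config()].
#' @return Numeric vector of length `grid_size` with values in (0, 1].
#' @export
corridor_profile <- function(mu, config = corridor_config()) {
  stopifnot(inherits(config, "corridor_config"))
  if (length(mu) != 1L || !is.numeric(mu) || mu != round(mu) ||
      mu < 0 || mu > config$grid_size - 1L)
    stop("mu must be a single integer in [0, ", config$grid_size - 1L, "]")
  x <- seq_len(config$grid_size) - 1L
  g <- exp(-(x - mu)^2 / (2 * config$sigma^2))
  if (config$profile == "density") {
    g <- pmin(g / (config$sigma * sqrt(2 * pi)), 1)
  }
  g
}

#' Render a single Corridors image
#'
#' @param x_uc,x_lc Integer positions (0..12) of the upper and lower
#'   corridor core columns.
#' @param config A [corridor_config()].
#' @return A `grid_size` x `grid_size` binary matrix (class
#'   `corridor_image`) with attributes `x_uc` and `x_lc`. Row 1 of the
#'   matrix is image row 0.
#' @details The divider row is all white. Within each section every pixel is
#'   an independent Bernoulli draw with probability given by
#'   [corridor_profile()] for that section's corridor; the core column has
#'   probability 1 and is therefore deterministically white. Uses the R
#'   random number generator; seed it for reproducibility.
#' @export
render_image <- function(x_uc, x_lc, config = corridor_config()) {
  stopifnot(inherits(config, "corridor_config"))
  n <- config$grid_size
  p_up <- corridor_profile(x_uc, config)
  p_lo <- corridor_profile(x_lc, config)
  img <- matrix(0L, n, n)
  for (r in seq_len(n) - 1L) {
    p <- if (r == config$divider_row) rep(1, n)
         else if (r < config$divider_row) p_up else p_lo
    img[r + 1L, ] <- as.integer(stats::runif(n) < p | p >= 1)
  }
  structure(img, x_uc = as.integer(x_uc), x_lc = as.integer(x_lc),
            class = c("corridor_image", "matrix", "array"))
}

#' Flatten images to pixel-vector rows / restore a pixel vector to a grid
#'
#' Pixel vectors are row-major: entry `r * grid_size + c + 1` holds pixel
#' (row r, column c), 0-based.
#'
#' @param img A `grid_size` x `grid_size` matrix.
#' @param v A numeric vector of length `grid_size^2`.
#' @param grid_size Side length of the grid.
#' @return `image_to_vec`: a numeric vector; `vec_to_image`: a matrix.
#' @keywords internal
#' @export
image_to_vec <- function(img) as.vector(t(unclass(img)))

#' @rdname image_to_vec
#' @export
vec_to_image <- function(v, grid_size = 13L) {
  matrix(v, grid_size, grid_size, byrow = TRUE)
}
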