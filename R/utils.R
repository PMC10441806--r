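#' Derive a reproducible child seed from a seed chain
#'
#' Deterministically maps a master seed plus any number of integer or
#' character keys (experiment names, cell indices, realization indices) to a
#' positive 31-bit seed, so that every random component of an experiment has
#' its own reproducible stream.
#'
#' @param ... integers or strings forming the seed chain; the first element
#'   is conventionally the master seed.
#' @return a single positive integer seed.
#' @export
#' @examples
#' derive_seed(1, "fig4_sweep", 3, 7)
derive_seed <- function(...) {
  keys <- lapply(list(...), function(k) {
    if (is.character(k)) utf8ToInt(paste(k, collapse = "|")) else as.integer(k)
  })
  hash_seed_cpp(unlist(keys))
}

# evaluate code under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Gaussian smoothing of a regularly sampled trace
#'
#' Convolves a trace with a normalized Gaussian kernel, using reflection
#' padding at the edges so the output has the same length as the input.
#'
#' @param x numeric trace sampled on a regular grid.
#' @param sigma kernel standard deviation, in the same units as `dt`.
#' @param dt sample spacing.
#' @return smoothed numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, sigma, dt = 1) {
  n <- length(x)
  sd_samp <- sigma / dt
  if (sd_samp <= 0 || n < 3) {
    return(x)
  }
  half <- min(ceiling(4 * sd_samp), n - 1L)
  k <- dnorm(seq(-half, half), sd = sd_samp)
  k <- k / sum(k)
  xp <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(half + 1):(half + n)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
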