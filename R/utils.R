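#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.75 -> 0.8 at one decimal), matching how printed perfusion-rate
#' and MBF values are reported, unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_out(c(0.75, -0.75, 6.25), 1)
round_half_out <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Trapezoidal integral of y(x) over [lo, hi], interpolating the window
# edges linearly when they fall between samples. Window is clipped to the
# support of x; caller decides whether clipping is acceptable.
trapz_window <- function(x, y, lo, hi) {
  stopifnot(length(x) == length(y), !is.unsorted(x))
  lo <- max(lo, x[1L])
  hi <- min(hi, x[length(x)])
  if (hi <= lo) return(0)
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y,
          y[inside],
          stats::approx(x, y, xout = hi)$y)
  pracma::trapz(xs, ys)
}

# Deterministic per-replicate seed derivation from a master seed.
# Kept strictly below 2^31 - 1 so the result is a valid R integer seed.
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) %% 2147483647 + 10007 * as.numeric(index)) %% 2147483562) + 1L
}

# Evaluate expr under a temporary RNG state; restores .Random.seed after.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
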