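#' Time-activity curve
#'
#' A sampled activity-concentration curve for one region of interest,
#' tagged with its role (blood pool / tissue), scan (rest or stress) and
#' measurement of origin.
#'
#' @param times sample times, s (frame midpoints or a uniform grid),
#'   strictly increasing, length >= 2.
#' @param values concentrations, MBq/mL, finite.
#' @param roi region label, e.g. `"AIF"`, `"MYO1"`.
#' @param scan `"rest"` or `"stress"`.
#' @param measurement_id identifier of the measurement the curve came from.
#' @param injected_activity injected activity of the measurement, MBq
#'   (NA when unknown, e.g. a rest scan).
#' @param meta free-form metadata list (frame layout, processing log).
#' @return an object of class `tac`.
#' @export
tac <- function(times, values, roi, scan = "stress",
                measurement_id = "m1", injected_activity = NA_real_,
                meta = list()) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2)
    stop("a TAC needs at least 2 samples", call. = FALSE)
  if (length(times) != length(values))
    stop("times and values differ in length", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("TAC times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("TAC values must be finite", call. = FALSE)
  if (!scan %in% c("rest", "stress"))
    stop("scan must be 'rest' or 'stress'", call. = FALSE)
  structure(list(times = times, values = values, roi = roi, scan = scan,
                 measurement_id = measurement_id,
                 injected_activity = injected_activity, meta = meta),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC [%s, %s, %s]: %d samples over %.1f-%.1f s, peak %.4g MBq/mL\n",
              x$measurement_id, x$scan, x$roi, length(x$times),
              min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(measurement_id = x$measurement_id, scan = x$scan, roi = x$roi,
             time_s = x$times, value_MBq_per_mL = x$values)
}

#' Normalise a TAC to a reference injected activity
#'
#' Measurements with injected activities in a range around the nominal dose
#' are made comparable by scaling each curve by
#' `reference_activity / injected_activity`.
#'
#' @param x a [tac()] with known `injected_activity`.
#' @param reference_activity reference dose, MBq.
#' @return the scaled TAC; the factor is recorded in
#'   `meta$normalization_factor`.
#' @export
normalize_to_injected <- function(x, reference_activity = 500) {
  stopifnot(inherits(x, "tac"))
  if (is.na(x$injected_activity) || x$injected_activity <= 0)
    stop("TAC has no (positive) injected_activity; cannot normalize",
         call. = FALSE)
  f <- reference_activity / x$injected_activity
  x$values <- x$values * f
  x$meta$normalization_factor <- f
  x$injected_activity <- reference_activity
  x
}

#' Resample a TAC onto a uniform grid by linear interpolation
#'
#' @param x a [tac()].
#' @param dt grid step, s.
#' @return TAC on `seq(min(times), max(times), by = dt)` (the original end
#'   point is appended if the span is not a multiple of `dt`, so both
#'   endpoints are preserved exactly).
#' @export
resample_linear <- function(x, dt = 0.5) {
  stopifnot(inherits(x, "tac"), dt > 0)
  grid <- seq(x$times[1], x$times[length(x$times)], by = dt)
  last <- x$times[length(x$times)]
  if (last - grid[length(grid)] > 1e-9) grid <- c(grid, last)
  vals <- stats::approx(x$times, x$values, xout = grid)$y
  x$times <- grid
  x$values <- vals
  x$meta$resampled_dt <- dt
  x
}

#' Locate the peak of a TAC by spline interpolation
#'
#' Fits a cubic spline through the curve and returns the abscissa of its
#' maximum within the sampled range, refined to better than 0.01 s. A
#' maximum on the boundary raises a boundary-peak warning and returns the
#' boundary time.
#'
#' @param x a [tac()].
#' @return peak time, s.
#' @export
locate_peak <- function(x) {
  stopifnot(inherits(x, "tac"))
  f <- stats::splinefun(x$times, x$values, method = "fmm")
  grid <- seq(x$times[1], x$times[length(x$times)], length.out =
                max(1000L, ceiling(diff(range(x$times)) / 0.01) + 1L))
  i <- which.max(f(grid))
  if (i == 1L || i == length(grid)) {
    warning("boundary peak: curve maximum lies on the sampled boundary",
            call. = FALSE)
    return(grid[i])
  }
  opt <- stats::optimize(f, lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = 1e-4)
  opt$maximum
}

#' Align measurements on their arterial-peak times
#'
#' Shifts each measurement's time axis so that all arterial input function
#' (AIF) peaks coincide at the mean peak time, and applies the identical
#' shift to the measurement's tissue curves.
#'
#' @param aifs list of AIF [tac()]s, one per measurement.
#' @param paired_trfs list (same length/order) of TAC sets: each element is
#'   a list of the tissue curves belonging to that measurement. May be
#'   omitted when only AIFs are aligned.
#' @return list with elements `aifs`, `trf_sets` (time-shifted copies) and
#'   `shifts` (s, one per measurement).
#' @export
align_curves <- function(aifs, paired_trfs = NULL) {
  stopifnot(length(aifs) >= 1,
            all(vapply(aifs, inherits, logical(1), "tac")))
  if (!is.null(paired_trfs) && length(paired_trfs) != length(aifs))
    stop("every TRF set must be paired with one AIF (lengths differ)",
         call. = FALSE)
  peaks <- vapply(aifs, locate_peak, numeric(1))
  shifts <- mean(peaks) - peaks
  shift_tac <- function(tc, s) {
    tc$times <- tc$times + s
    tc$meta$alignment_shift <- s
    tc
  }
  aifs2 <- Map(shift_tac, aifs, shifts)
  trfs2 <- NULL
  if (!is.null(paired_trfs)) {
    trfs2 <- Map(function(set, s) lapply(set, shift_tac, s = s),
                 paired_trfs, shifts)
  }
  list(aifs = aifs2, trf_sets = trfs2, shifts = shifts)
}

#' Subtract the rest-scan background from a stress TAC
#'
#' Residual activity from earlier measurements (measured by the rest scan)
#' is removed pointwise; the rest curve is linearly resampled onto the
#' stress grid first. Negative differences are floored at 0 and the number
#' of floored samples is recorded in `meta$n_floored`.
#'
#' @param stress stress-scan [tac()].
#' @param rest rest-scan [tac()] of the same ROI.
#' @return background-subtracted stress TAC.
#' @export
subtract_background <- function(stress, rest) {
  stopifnot(inherits(stress, "tac"), inherits(rest, "tac"))
  if (!identical(stress$roi, rest$roi))
    stop("ROI mismatch: stress '", stress$roi, "' vs rest '", rest$roi, "'",
         call. = FALSE)
  bg <- stats::approx(rest$times, rest$values, xout = stress$times,
                      rule = 2)$y
  diff <- stress$values - bg
  n_floored <- sum(diff < 0)
  stress$values <- pmax(diff, 0)
  stress$meta$background_subtracted <- TRUE
  stress$meta$n_floored <- n_floored
  stress
}

#' Ensemble mean/SD curves and AUC statistics
#'
#' Pointwise sample mean and standard deviation over a set of curves that
#' share a common grid, plus the per-curve trapezoidal area under the curve
#' over a stated window and its ensemble mean/SD. The windows of the
#' retention model are the natural choice: the blood-pool phase
#' `[0, t1]` for AIFs and the tissue phase `[t2, t3]` for TRFs.
#'
#' @param curves list of [tac()]s on identical time grids.
#' @param window integration window `c(lo, hi)`, s. Default picks
#'   `[0, 60]` when all curves are AIFs and `[60, 120]` otherwise.
#' @param params [retention_params()] supplying the default window limits.
#' @return list with `mean_tac`, `sd_tac`, `auc` (per curve), `auc_mean`,
#'   `auc_sd`, `window`, `n`, and `single_curve` flag (SD reported as 0
#'   when only one curve is given).
#' @export
ensemble_stats <- function(curves, window = NULL,
                           params = retention_params()) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, logical(1), "tac")))
  t0 <- curves[[1]]$times
  same <- all(vapply(curves, function(x)
    length(x$times) == length(t0) && max(abs(x$times - t0)) < 1e-6,
    logical(1)))
  if (!same)
    stop("curves are not on a common grid; align and resample first",
         call. = FALSE)
  if (is.null(window)) {
    all_aif <- all(vapply(curves, function(x) x$roi == "AIF", logical(1)))
    window <- if (all_aif) c(0, params$t1) else c(params$t2, params$t3)
  }
  vals <- vapply(curves, function(x) x$values, numeric(length(t0)))
  vals <- matrix(vals, nrow = length(t0))
  m <- rowMeans(vals)
  single <- ncol(vals) == 1L
  s <- if (single) rep(0, length(t0)) else apply(vals, 1, stats::sd)
  aucs <- vapply(curves, function(x)
    trapz_window(x$times, x$values, window[1], window[2]), numeric(1))
  proto <- curves[[1]]
  mk <- function(v, tag) tac(t0, v, roi = proto$roi, scan = proto$scan,
                             measurement_id = tag,
                             meta = list(ensemble_n = length(curves)))
  list(mean_tac = mk(m, "ensemble_mean"),
       sd_tac = mk(s, "ensemble_sd"),
       auc = aucs,
       auc_mean = mean(aucs),
       auc_sd = if (single) 0 else stats::sd(aucs),
       window = window,
       n = length(curves),
       single_curve = single)
}

# Resample a list of TACs onto the common overlap grid (used after
# alignment shifts, which shrink the shared span).
common_grid <- function(curves, dt = 0.5) {
  lo <- max(vapply(curves, function(x) x$times[1], numeric(1)))
  hi <- min(vapply(curves, function(x) max(x$times), numeric(1)))
  if (hi <= lo) stop("curves share no common time span", call. = FALSE)
  grid <- seq(lo, hi, by = dt)
  lapply(curves, function(x) {
    x$values <- stats::approx(x$times, x$values, xout = grid)$y
    x$times <- grid
    x
  })
}
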