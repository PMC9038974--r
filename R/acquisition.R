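#' Dynamic frame schedule
#'
#' @param durations ordered frame durations in seconds; frames are
#'   contiguous and start at 0.
#' @return an object of class `frame_schedule` with columns `start` and
#'   `duration`.
#' @export
frame_schedule <- function(durations) {
  durations <- as.numeric(durations)
  if (length(durations) < 1 || any(!is.finite(durations)) ||
      any(durations <= 0))
    stop("frame durations must be positive and finite", call. = FALSE)
  starts <- cumsum(c(0, durations[-length(durations)]))
  structure(data.frame(start = starts, duration = durations),
            class = c("frame_schedule", "data.frame"))
}

#' The clinical 32-frame re-binning schedule
#'
#' List-mode data of the 6-minute dynamic scan re-binned into 32 frames:
#' 21 frames of 3 s, one frame each of 9, 15, 21 and 27 s, then 7 frames of
#' 30 s, totalling 345 s.
#'
#' @return a [frame_schedule()] of 32 frames.
#' @export
#' @examples
#' sched <- default_frame_schedule()
#' nrow(sched); sum(sched$duration)
default_frame_schedule <- function() {
  frame_schedule(c(rep(3, 21), 9, 15, 21, 27, rep(30, 7)))
}

#' Acquisition forward model
#'
#' Maps true compartment concentrations to measured region-of-interest
#' values: partial-volume loss on the tissue signal, spillover between the
#' blood-pool and tissue signals, a constant residual background from
#' earlier measurements, and Poisson counting noise.
#'
#' @param pv_true recovery coefficient applied to the tissue signal,
#'   in (0, 1]. Default equals the correction constant used at estimation
#'   (0.63) so matched forward/correction runs are bias-free by design.
#' @param spill_blood_to_myo fraction of the blood-pool signal added to the
#'   tissue signal, in `[0, 1)`.
#' @param spill_myo_to_blood fraction of the tissue signal added to the
#'   blood-pool signal, in `[0, 1)`.
#' @param sensitivity counts per MBq.s; sets the Poisson noise level.
#' @param background_level residual tissue concentration per segment left by
#'   previous measurements, MBq/mL (length 1 or 3).
#' @param noise_enabled draw Poisson frame counts if TRUE.
#' @param seed integer seed for the noise draws (required for reproducible
#'   noisy acquisitions).
#' @return an object of class `acquisition_model`.
#' @export
acquisition_model <- function(pv_true = 0.63,
                              spill_blood_to_myo = 0.4,
                              spill_myo_to_blood = 0,
                              sensitivity = 10,
                              background_level = 0,
                              noise_enabled = FALSE,
                              seed = NULL) {
  if (pv_true <= 0 || pv_true > 1)
    stop("pv_true must be in (0, 1]", call. = FALSE)
  if (spill_blood_to_myo < 0 || spill_blood_to_myo >= 1 ||
      spill_myo_to_blood < 0 || spill_myo_to_blood >= 1)
    stop("spill fractions must be in [0, 1)", call. = FALSE)
  if (sensitivity <= 0) stop("sensitivity must be > 0", call. = FALSE)
  if (!length(background_level) %in% c(1, 3) || any(background_level < 0))
    stop("background_level must be length 1 or 3, non-negative",
         call. = FALSE)
  structure(list(pv_true = pv_true,
                 spill_blood_to_myo = spill_blood_to_myo,
                 spill_myo_to_blood = spill_myo_to_blood,
                 sensitivity = sensitivity,
                 background_level = rep(background_level, length.out = 3),
                 noise_enabled = isTRUE(noise_enabled),
                 seed = seed),
            class = "acquisition_model")
}

# Frame-average a dense curve over a schedule. dt of the simulation grid is
# assumed to divide frame boundaries to within dt/2 (true for the defaults).
frame_average <- function(times, values, schedule) {
  vapply(seq_len(nrow(schedule)), function(j) {
    lo <- schedule$start[j]
    hi <- lo + schedule$duration[j]
    idx <- times >= lo - 1e-9 & times < hi - 1e-9
    mean(values[idx])
  }, numeric(1))
}

#' Acquire a measured time-activity curve from a simulation
#'
#' Per frame, averages the true concentration of the requested region (AIF:
#' LVC concentration; MYO i: free+trapped segment activity over the tissue
#' VOI volume, plus the residual background), applies the forward
#' partial-volume/spillover model, and optionally replaces each frame value
#' by a Poisson draw of its expected counts
#' (`sensitivity * value * duration`) converted back to concentration.
#' Frame timestamps are the frame midpoints.
#'
#' @param truth a `simulation_result`.
#' @param roi one of `"AIF"`, `"MYO1"`, `"MYO2"`, `"MYO3"`.
#' @param schedule a [frame_schedule()]; must lie within the simulated span.
#' @param model an [acquisition_model()].
#' @param scan `"rest"` or `"stress"` tag.
#' @param measurement_id identifier carried into the TAC metadata.
#' @return a [tac()] object.
#' @export
acquire_tac <- function(truth, roi = c("AIF", "MYO1", "MYO2", "MYO3"),
                        schedule = default_frame_schedule(),
                        model = acquisition_model(),
                        scan = "stress",
                        measurement_id = "m1") {
  roi <- match.arg(roi)
  stopifnot(inherits(truth, "simulation_result"),
            inherits(schedule, "frame_schedule"),
            inherits(model, "acquisition_model"))
  span_end <- max(schedule$start + schedule$duration)
  if (span_end > max(truth$time_grid) + 1e-9)
    stop("frame schedule (", span_end, " s) exceeds simulated span (",
         max(truth$time_grid), " s)", call. = FALSE)

  aif_true <- frame_average(truth$time_grid, lvc_concentration(truth),
                            schedule)
  if (roi == "AIF") {
    tis <- rowMeans(vapply(1:3, function(i) {
      frame_average(truth$time_grid,
                    segment_tissue_concentration(truth, i) +
                      model$background_level[i], schedule)
    }, numeric(nrow(schedule))))
    observed <- aif_true + model$spill_myo_to_blood * tis
  } else {
    i <- as.integer(substring(roi, 4))
    tis <- frame_average(truth$time_grid,
                         segment_tissue_concentration(truth, i), schedule) +
      model$background_level[i]
    observed <- model$pv_true * tis + model$spill_blood_to_myo * aif_true
  }

  if (model$noise_enabled) {
    draw <- function() {
      lam <- model$sensitivity * pmax(observed, 0) * schedule$duration
      stats::rpois(length(lam), lam) /
        (model$sensitivity * schedule$duration)
    }
    observed <- if (!is.null(model$seed)) with_seed(model$seed, draw())
    else draw()
  }

  tac(times = schedule$start + schedule$duration / 2,
      values = observed,
      roi = roi, scan = scan, measurement_id = measurement_id,
      injected_activity = truth$injected_total,
      meta = list(frame_start = schedule$start,
                  frame_duration = schedule$duration))
}

#' Acquire all four ROIs of one scan
#'
#' @inheritParams acquire_tac
#' @return named list of [tac()] objects (`AIF`, `MYO1`, `MYO2`, `MYO3`).
#'   With noise enabled and a seed on the model, the four ROI draws are a
#'   single reproducible stream.
#' @export
acquire_tac_set <- function(truth, schedule = default_frame_schedule(),
                            model = acquisition_model(),
                            scan = "stress", measurement_id = "m1") {
  rois <- c("AIF", "MYO1", "MYO2", "MYO3")
  run <- function() {
    m <- model
    m$seed <- NULL  # seeding handled at set level
    stats::setNames(lapply(rois, function(r)
      acquire_tac(truth, r, schedule, m, scan, measurement_id)), rois)
  }
  if (model$noise_enabled && !is.null(model$seed))
    with_seed(model$seed, run())
  else run()
}

#' Acquire a paired rest/stress measurement
#'
#' The rest scan has no injection (its truth is a zero-activity simulation)
#' and measures only the residual background plus noise; the stress scan
#' follows the bolus. Both scans share the forward model, so the rest scan
#' can serve as the background-subtraction baseline.
#'
#' @param truth_rest zero-injection `simulation_result`.
#' @param truth_stress bolus `simulation_result`.
#' @param schedule a [frame_schedule()] shared by both scans.
#' @param model an [acquisition_model()].
#' @param measurement_id identifier for the measurement pair.
#' @return list with elements `rest` and `stress`, each a TAC set.
#' @export
acquire_rest_stress_pair <- function(truth_rest, truth_stress,
                                     schedule = default_frame_schedule(),
                                     model = acquisition_model(),
                                     measurement_id = "m1") {
  stopifnot(inherits(truth_rest, "simulation_result"),
            inherits(truth_stress, "simulation_result"))
  m_rest <- model
  m_stress <- model
  if (!is.null(model$seed)) {
    m_rest$seed <- derive_seed(model$seed, 1)
    m_stress$seed <- derive_seed(model$seed, 2)
  }
  list(rest = acquire_tac_set(truth_rest, schedule, m_rest,
                              scan = "rest", measurement_id = measurement_id),
       stress = acquire_tac_set(truth_stress, schedule, m_stress,
                                scan = "stress",
                                measurement_id = measurement_id))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("Frame schedule: %d frames, %.0f s total\n",
              nrow(x), sum(x$duration)))
  cat("  durations:", paste(rle(x$duration)$lengths, "x",
                            rle(x$duration)$values, collapse = ", "), "s\n")
  invisible(x)
}
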