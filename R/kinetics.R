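#' Parameters of the net-retention blood-flow model
#'
#' Integration limits and correction constants of the retention estimator:
#' `t1` ends the blood-pool phase of the arterial integral, `[t2, t3]`
#' bounds the tissue-uptake average, `PV` is the myocardial
#' partial-volume recovery coefficient, `CF` the blood-pool
#' cross-calibration factor, and `Sm`/`Sb` the spillover fractions from
#' blood to myocardium and back.
#'
#' @param t1 end of blood-pool integration, s.
#' @param t2,t3 tissue integration limits, s, `t2 < t3`.
#' @param PV recovery coefficient, in (0, 1].
#' @param CF cross-calibration factor, > 0.
#' @param Sm spillover fraction blood -> myocardium, in `[0, 1)`.
#' @param Sb spillover fraction myocardium -> blood, in `[0, 1)`.
#' @return an object of class `retention_params`.
#' @export
retention_params <- function(t1 = 60, t2 = 60, t3 = 120,
                             PV = 0.63, CF = 1, Sm = 0.4, Sb = 0) {
  if (t1 <= 0) stop("t1 must be > 0", call. = FALSE)
  if (t2 >= t3) stop("t2 must be < t3", call. = FALSE)
  if (PV <= 0 || PV > 1) stop("PV must be in (0, 1]", call. = FALSE)
  if (CF <= 0) stop("CF must be > 0", call. = FALSE)
  if (Sm < 0 || Sm >= 1 || Sb < 0 || Sb >= 1)
    stop("Sm and Sb must be in [0, 1)", call. = FALSE)
  structure(list(t1 = t1, t2 = t2, t3 = t3, PV = PV, CF = CF,
                 Sm = Sm, Sb = Sb),
            class = "retention_params")
}

#' Net retention rate from an AIF/TRF pair
#'
#' Computes the retention rate
#' \deqn{R = \frac{\frac{1}{PV\,(t_3-t_2)}\int_{t_2}^{t_3}
#'   \bigl(P(t) - S_m C_a(t)\bigr)\,dt}
#'   {CF \int_0^{t_1} \bigl(C_a(t) - S_b P(t)\bigr)\,dt}}
#' with trapezoidal integration on a uniform resampled grid, converted from
#' per-second to per-minute. Under the retention model, `R = MBF * E` with
#' extraction fraction E.
#'
#' Curves should be background-subtracted and on the native scan clock;
#' both must cover the tissue window up to `t3` (values before the first
#' sample, i.e. before the first frame midpoint, are taken as the first
#' sample value — effectively zero for a pre-bolus AIF).
#'
#' @param aif arterial input [tac()] (blood-pool concentration).
#' @param trf tissue response [tac()].
#' @param params a [retention_params()].
#' @param dt resampling step for the integrals, s.
#' @return retention rate R, mL/g/min (per mL of tissue at density 1 g/mL).
#' @export
#' @examples
#' t <- seq(0, 120, 0.5)
#' a <- tac(t, rep(1, length(t)), "AIF")
#' p <- tac(t, rep(1, length(t)), "MYO1")
#' retention_rate(a, p)  # 60*(1-0.4)/(0.63*60*1) = 0.952
retention_rate <- function(aif, trf, params = retention_params(), dt = 0.5) {
  stopifnot(inherits(aif, "tac"), inherits(trf, "tac"),
            inherits(params, "retention_params"))
  if (max(aif$times) < params$t1 - 1e-6)
    stop("AIF does not cover the blood-pool window [0, t1]", call. = FALSE)
  if (max(trf$times) < params$t3 - 1e-6)
    stop("TRF does not cover the tissue window [t2, t3]", call. = FALSE)
  grid <- seq(0, params$t3, by = dt)
  ca <- stats::approx(aif$times, aif$values, xout = grid, rule = 2)$y
  p <- stats::approx(trf$times, trf$values, xout = grid, rule = 2)$y
  num <- trapz_window(grid, p - params$Sm * ca, params$t2, params$t3) /
    (params$PV * (params$t3 - params$t2))
  den <- params$CF * trapz_window(grid, ca - params$Sb * p, 0, params$t1)
  if (den <= 0)
    stop("non-physical AIF: blood-pool integral is <= 0", call. = FALSE)
  60 * num / den
}

#' Myocardial blood flow from a retention rate
#'
#' The retention model expresses myocardial uptake as the product of blood
#' flow and the first-pass extraction fraction, `R = MBF * E`; inverting
#' with an assumed extraction gives the flow estimate.
#'
#' @param R retention rate, mL/g/min.
#' @param assumed_extraction extraction fraction in (0, 1].
#' @param renkin_crone optional Renkin-Crone correction hook: a function
#'   `f(mbf_initial)` returning a flow-dependent extraction used for one
#'   refinement step. Off (NULL) by default.
#' @return MBF estimate, mL/g/min.
#' @export
mbf_from_retention <- function(R, assumed_extraction,
                               renkin_crone = NULL) {
  if (assumed_extraction <= 0 || assumed_extraction > 1)
    stop("assumed_extraction must be in (0, 1]", call. = FALSE)
  mbf <- R / assumed_extraction
  if (!is.null(renkin_crone)) {
    e2 <- renkin_crone(mbf)
    if (e2 <= 0 || e2 > 1)
      stop("renkin_crone hook returned an extraction outside (0, 1]",
           call. = FALSE)
    mbf <- R / e2
  }
  mbf
}

#' Ground-truth myocardial blood flow of a segment
#'
#' Flow sensor readout divided by the perfused tissue mass: the set volume
#' flux through a tissue volume of interest at the assumed density.
#'
#' @param flux segment volume flux, mL/min.
#' @param tissue_volume analysed tissue volume, mL.
#' @param density tissue density, g/mL.
#' @return MBF in mL/g/min (full precision; attribute `rounded` carries the
#'   one-decimal half-away-from-zero value used in reports).
#' @export
#' @examples
#' ground_truth_mbf(80)   # 1.509..., reported as 1.5
#' ground_truth_mbf(40)   # 0.754..., reported as 0.8
ground_truth_mbf <- function(flux, tissue_volume = 53, density = 1.0) {
  if (tissue_volume <= 0 || density <= 0)
    stop("tissue_volume and density must be > 0", call. = FALSE)
  v <- flux / (density * tissue_volume)
  attr(v, "rounded") <- round_half_out(v, 1)
  v
}

#' AHA 17-segment map of the phantom territories
#'
#' Maps the basal and mid-cavity AHA segments 1-12 to the three coronary
#' territories mimicked by the phantom: segments 1, 2, 7, 8 to the LAD
#' region, 3, 4, 9, 10 to the RCA region and 5, 6, 11, 12 to the LCX
#' region. The apical segments (13-17) are excluded because the phantom
#' does not mimic the apex.
#'
#' @return an object of class `aha_segment_map`: list with `territories`
#'   (named list of segment vectors) and `excluded`.
#' @export
aha_segment_map <- function() {
  structure(list(
    territories = list(LAD = c(1, 2, 7, 8),
                       RCA = c(3, 4, 9, 10),
                       LCX = c(5, 6, 11, 12)),
    excluded = 13:17
  ), class = "aha_segment_map")
}

# Which phantom myocardial segment feeds which territory: the three
# identical segments correspond to the LAD, RCA and LCX branches in order.
phantom_territory <- function(segment_index) {
  c("LAD", "RCA", "LCX")[segment_index]
}

#' Spread per-territory values onto AHA segments 1-12
#'
#' Each phantom myocardial segment is homogeneous, so its value maps
#' uniformly onto the four AHA segments of its territory.
#'
#' @param territory_values named numeric (`LAD`, `RCA`, `LCX`).
#' @param map an [aha_segment_map()].
#' @return named numeric over segments `"1"`..`"12"`.
#' @export
expand_to_aha <- function(territory_values, map = aha_segment_map()) {
  stopifnot(all(c("LAD", "RCA", "LCX") %in% names(territory_values)))
  out <- numeric(12)
  names(out) <- as.character(1:12)
  for (terr in names(map$territories))
    out[as.character(map$territories[[terr]])] <- territory_values[[terr]]
  out
}

#' Aggregate per-AHA-segment values into territory statistics
#'
#' @param per_segment_values numeric named by AHA segment number; all of
#'   1-12 must be present. Excluded apical segments never contribute.
#' @param map an [aha_segment_map()].
#' @param ground_truth optional named numeric of true territory MBF
#'   (`LAD`, `RCA`, `LCX`) attached to the report with absolute errors.
#' @return data.frame of class `mbf_report` with one row per territory:
#'   `territory`, `mbf_mean`, `mbf_sd`, and when ground truth is given,
#'   `mbf_true` and `abs_error`.
#' @export
aggregate_territories <- function(per_segment_values,
                                  map = aha_segment_map(),
                                  ground_truth = NULL) {
  stopifnot(inherits(map, "aha_segment_map"))
  need <- as.character(unlist(map$territories))
  have <- names(per_segment_values)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing AHA segment value(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  rows <- lapply(names(map$territories), function(terr) {
    segs <- as.character(map$territories[[terr]])
    v <- as.numeric(per_segment_values[segs])
    data.frame(territory = terr, mbf_mean = mean(v), mbf_sd = stats::sd(v))
  })
  out <- do.call(rbind, rows)
  if (!is.null(ground_truth)) {
    out$mbf_true <- as.numeric(ground_truth[out$territory])
    out$abs_error <- abs(out$mbf_mean - out$mbf_true)
  }
  class(out) <- c("mbf_report", "data.frame")
  out
}

#' Polar-map style segment table
#'
#' 12-sector table mirroring the polar-map layout: one row per analysed
#' AHA segment with its territory and value; excluded apical sectors are
#' listed with blank values.
#'
#' @param per_segment_values numeric named by AHA segment number (1-12).
#' @param map an [aha_segment_map()].
#' @param digits decimals for the printed value.
#' @return data.frame with columns `segment`, `territory`, `value`.
#' @export
polar_map_table <- function(per_segment_values, map = aha_segment_map(),
                            digits = 1) {
  terr_of <- rep(NA_character_, 17)
  for (terr in names(map$territories))
    terr_of[map$territories[[terr]]] <- terr
  value <- rep(NA_real_, 17)
  idx <- as.integer(names(per_segment_values))
  value[idx] <- round_half_out(as.numeric(per_segment_values), digits)
  data.frame(segment = 1:17,
             territory = ifelse(1:17 %in% map$excluded, "apex (excluded)",
                                terr_of),
             value = ifelse(1:17 %in% map$excluded, NA, value))
}
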