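#' End-to-end experiment configuration
#'
#' Bundles every parameter block needed to run a full simulated phantom
#' measurement campaign: circuit, sorbents, injection, frame schedule,
#' acquisition forward model, retention-model constants, replicate count
#' and the master seed from which per-replicate seeds are derived.
#'
#' The default mirrors the optimised normal-perfusion protocol row
#' (7 g activated carbon per segment, 80/80/80 mL/min at 4 L/min arterial
#' flow, recirculation filters at efficiency 0.9).
#'
#' @param circuit a [circuit_config()].
#' @param sorbents list of three [sorbent_config()].
#' @param injection an [injection_protocol()].
#' @param schedule a [frame_schedule()].
#' @param acquisition an [acquisition_model()].
#' @param retention a [retention_params()].
#' @param n_replicates number of simulated measurements.
#' @param master_seed integer; replicate seeds are derived from it.
#' @param duration,dt simulation span and step, s.
#' @param injected_activity_range per-measurement injected activity is drawn
#'   uniformly from this range (MBq), emulating dose variation across
#'   measurements; curves are later normalised back to 500 MBq.
#' @param output_dir optional directory for CSV artifacts.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(circuit = circuit_config(),
                              sorbents = default_sorbents(),
                              injection = injection_protocol(),
                              schedule = default_frame_schedule(),
                              acquisition = acquisition_model(
                                background_level = 0.02,
                                noise_enabled = TRUE),
                              retention = retention_params(),
                              n_replicates = 20,
                              master_seed = 42,
                              duration = 360,
                              dt = 0.05,
                              injected_activity_range = c(468, 551),
                              output_dir = NULL) {
  stopifnot(inherits(circuit, "circuit_config"),
            inherits(injection, "injection_protocol"),
            inherits(schedule, "frame_schedule"),
            inherits(acquisition, "acquisition_model"),
            inherits(retention, "retention_params"),
            n_replicates >= 1,
            length(injected_activity_range) == 2,
            injected_activity_range[1] <= injected_activity_range[2])
  structure(list(circuit = circuit, sorbents = sorbents,
                 injection = injection, schedule = schedule,
                 acquisition = acquisition, retention = retention,
                 n_replicates = as.integer(n_replicates),
                 master_seed = as.integer(master_seed),
                 duration = duration, dt = dt,
                 injected_activity_range = injected_activity_range,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Serialise / restore an experiment configuration as YAML
#'
#' @param config an [experiment_config()].
#' @param path file to write / read.
#' @return `write_experiment_config` returns the path invisibly;
#'   `read_experiment_config` returns an [experiment_config()]. Round-trip
#'   is lossless.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  doc <- list(
    circuit = unclass(config$circuit),
    sorbents = lapply(config$sorbents, unclass),
    injection = unclass(config$injection)[
      setdiff(names(config$injection), "bolus_duration")],
    schedule = list(durations = config$schedule$duration),
    acquisition = unclass(config$acquisition),
    retention = unclass(config$retention),
    n_replicates = config$n_replicates,
    master_seed = config$master_seed,
    duration = config$duration,
    dt = config$dt,
    injected_activity_range = config$injected_activity_range
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  doc <- yaml::read_yaml(path)
  experiment_config(
    circuit = do.call(circuit_config, doc$circuit),
    sorbents = lapply(doc$sorbents, function(s) do.call(sorbent_config, s)),
    injection = do.call(injection_protocol, doc$injection),
    schedule = frame_schedule(doc$schedule$durations),
    acquisition = do.call(acquisition_model,
                          doc$acquisition[setdiff(names(doc$acquisition),
                                                  character(0))]),
    retention = do.call(retention_params, doc$retention),
    n_replicates = doc$n_replicates,
    master_seed = doc$master_seed,
    duration = doc$duration,
    dt = doc$dt,
    injected_activity_range = unlist(doc$injected_activity_range)
  )
}

# Stable hash of a configuration for provenance logging.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_experiment_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run a full simulated phantom experiment
#'
#' Simulates the rest (no injection) and stress (bolus) scans once,
#' then for each replicate: draws an injected activity, scales the stress
#' truth accordingly (tracer linearity), acquires noisy rest/stress TAC
#' sets, subtracts the rest background, normalises to 500 MBq, computes
#' the retention rate and MBF per myocardial segment, and maps the result
#' onto the AHA territories. Territory statistics are aggregated across
#' replicates against ground truth.
#'
#' The assumed extraction used to convert retention to MBF is each
#' segment's configured closed-form extraction
#' `k_ads*V / (Q + k_ads*V)`.
#'
#' @param config an [experiment_config()].
#' @param output_dir directory for CSV artifacts (defaults to
#'   `config$output_dir`; NULL writes nothing).
#' @return list of class `experiment_result`:
#'   `replicates` (per replicate x segment estimates),
#'   `territory_report` (per territory mean/SD/truth/error across
#'   replicates), `segment_report` (per AHA segment), `polar_map`,
#'   `ensemble` (aligned mean/SD AIF and TRF curves with AUC stats),
#'   `truth` (the stress simulation), `config_hash`, `seeds`.
#' @export
run_experiment <- function(config, output_dir = config$output_dir) {
  stopifnot(inherits(config, "experiment_config"))
  stress_truth <- simulate_circuit(config$circuit, config$sorbents,
                                   config$injection,
                                   duration = config$duration,
                                   dt = config$dt)
  rest_inj <- config$injection
  rest_inj$activity <- 0
  rest_truth <- simulate_circuit(config$circuit, config$sorbents, rest_inj,
                                 duration = config$duration, dt = config$dt)

  e_assumed <- vapply(1:3, function(i)
    expected_extraction(config$circuit, config$sorbents[[i]], i), numeric(1))
  gt <- vapply(config$circuit$segment_flows, function(q)
    as.numeric(ground_truth_mbf(q, config$circuit$tissue_voi_volume,
                                config$circuit$tissue_density)), numeric(1))
  names(gt) <- phantom_territory(1:3)

  seeds <- vapply(seq_len(config$n_replicates), function(r)
    derive_seed(config$master_seed, r), integer(1))

  rep_rows <- list()
  aifs <- list()
  trfs <- list()
  tac_log <- list()
  for (r in seq_len(config$n_replicates)) {
    injected_r <- with_seed(seeds[r],
                            stats::runif(1, config$injected_activity_range[1],
                                         config$injected_activity_range[2]))
    truth_r <- scale_simulation(stress_truth,
                                injected_r / config$injection$activity)
    model_r <- config$acquisition
    model_r$seed <- derive_seed(seeds[r], 7)
    mid <- sprintf("rep%02d", r)
    pair <- acquire_rest_stress_pair(rest_truth, truth_r, config$schedule,
                                     model_r, measurement_id = mid)
    tac_log[[r]] <- c(pair$rest, pair$stress)

    aif_bs <- subtract_background(pair$stress$AIF, pair$rest$AIF)
    aif_bs$injected_activity <- injected_r
    aif_n <- normalize_to_injected(aif_bs, 500)
    aifs[[r]] <- aif_n

    seg_tacs <- list()
    for (i in 1:3) {
      roi <- paste0("MYO", i)
      trf_bs <- subtract_background(pair$stress[[roi]], pair$rest[[roi]])
      trf_bs$injected_activity <- injected_r
      trf_n <- normalize_to_injected(trf_bs, 500)
      seg_tacs[[roi]] <- trf_n
      R <- retention_rate(aif_n, trf_n, config$retention)
      mbf <- mbf_from_retention(R, e_assumed[i])
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        replicate = r, seed = seeds[r], segment = roi,
        territory = phantom_territory(i),
        injected_MBq = injected_r,
        retention_rate = R, assumed_extraction = e_assumed[i],
        mbf = mbf, mbf_true = gt[[phantom_territory(i)]],
        abs_error = abs(mbf - gt[[phantom_territory(i)]]))
    }
    trfs[[r]] <- seg_tacs
  }
  replicates <- do.call(rbind, rep_rows)

  # territory statistics across replicates
  terr_rows <- lapply(c("LAD", "RCA", "LCX"), function(terr) {
    v <- replicates$mbf[replicates$territory == terr]
    data.frame(territory = terr,
               mbf_mean = mean(v),
               mbf_sd = if (length(v) > 1) stats::sd(v) else 0,
               mbf_true = gt[[terr]],
               abs_error = abs(mean(v) - gt[[terr]]),
               mean_abs_error = mean(abs(v - gt[[terr]])))
  })
  territory_report <- do.call(rbind, terr_rows)
  class(territory_report) <- c("mbf_report", "data.frame")

  seg_values <- expand_to_aha(stats::setNames(
    territory_report$mbf_mean, territory_report$territory))
  segment_report <- data.frame(
    segment = as.integer(names(seg_values)),
    territory = rep(NA_character_, 12),
    mbf_mean = as.numeric(seg_values))
  map <- aha_segment_map()
  for (terr in names(map$territories))
    segment_report$territory[segment_report$segment %in%
                               map$territories[[terr]]] <- terr
  segment_report$mbf_true <- gt[segment_report$territory]
  segment_report$abs_error <- abs(segment_report$mbf_mean -
                                    segment_report$mbf_true)

  # ensemble curves: align AIF peaks across replicates, carry shifts to TRFs
  ensemble <- NULL
  if (config$n_replicates >= 2) {
    al <- align_curves(aifs, trfs)
    aif_grid <- common_grid(al$aifs, dt = 0.5)
    ens_aif <- ensemble_stats(aif_grid, params = config$retention)
    ens_trf <- lapply(paste0("MYO", 1:3), function(roi) {
      ensemble_stats(common_grid(lapply(al$trf_sets, `[[`, roi), dt = 0.5),
                     params = config$retention)
    })
    names(ens_trf) <- paste0("MYO", 1:3)
    ensemble <- list(aif = ens_aif, trf = ens_trf, shifts = al$shifts)
  }

  hash <- config_hash(config)
  result <- structure(list(
    replicates = replicates,
    territory_report = territory_report,
    segment_report = segment_report,
    polar_map = polar_map_table(seg_values),
    ensemble = ensemble,
    truth = stress_truth,
    config = config,
    config_hash = hash,
    seeds = seeds
  ), class = "experiment_result")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- function(df) { df$config_hash <- hash; df }
    utils::write.csv(stamp(replicates),
                     file.path(output_dir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(as.data.frame(territory_report)),
                     file.path(output_dir, "territory_report.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(segment_report),
                     file.path(output_dir, "segment_report.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(result$polar_map),
                     file.path(output_dir, "polar_map.csv"),
                     row.names = FALSE)
    write_tac_csv(unlist(tac_log, recursive = FALSE),
                  file.path(output_dir, "tacs.csv"))
    prov <- c(
      sprintf("config_hash: %s", hash),
      sprintf("package_version: %s",
              as.character(utils::packageVersion("mpiphantom"))),
      sprintf("r_version: %s", R.version.string),
      sprintf("master_seed: %d", config$master_seed),
      sprintf("replicate_seeds: %s", paste(seeds, collapse = ",")))
    writeLines(prov, file.path(output_dir, "provenance.log"))
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Phantom experiment: %d replicates, config %s\n",
              x$config$n_replicates, substr(x$config_hash, 1, 8)))
  df <- as.data.frame(x$territory_report)
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write / read time-activity curves as CSV
#'
#' Fixed dialect: comma-separated, header row, UTF-8, '.' decimal; columns
#' `measurement_id, scan, roi, frame_start_s, frame_duration_s,
#' value_MBq_per_mL` plus optional `injected_MBq`. Unknown extra columns
#' survive a read/write round trip.
#'
#' @param tacs list of [tac()] objects.
#' @param path CSV file path.
#' @return `write_tac_csv` returns the path invisibly; `load_tac_csv`
#'   returns a named list of [tac()]s (names `measurement_id/scan/roi`).
#' @export
write_tac_csv <- function(tacs, path) {
  stopifnot(length(tacs) >= 1,
            all(vapply(tacs, inherits, logical(1), "tac")))
  rows <- lapply(tacs, function(x) {
    fs <- x$meta$frame_start
    fd <- x$meta$frame_duration
    if (is.null(fs) || is.null(fd)) {
      # uniform-grid curve: encode the grid as zero-gap frames
      step <- if (length(x$times) > 1) diff(x$times)[1] else 1
      fd <- rep(step, length(x$times))
      fs <- x$times - step / 2
    }
    df <- data.frame(measurement_id = x$measurement_id, scan = x$scan,
                     roi = x$roi, frame_start_s = fs, frame_duration_s = fd,
                     value_MBq_per_mL = x$values,
                     injected_MBq = x$injected_activity)
    extra <- x$meta$extra_columns
    if (!is.null(extra)) df <- cbind(df, extra)
    df
  })
  common <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(df) {
    df[setdiff(common, names(df))] <- NA
    df[common]
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
load_tac_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e)
                   stop("malformed or empty TAC CSV '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0)
    stop("empty TAC CSV: ", path, call. = FALSE)
  need <- c("measurement_id", "scan", "roi", "frame_start_s",
            "frame_duration_s", "value_MBq_per_mL")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("TAC CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num_cols <- c("frame_start_s", "frame_duration_s", "value_MBq_per_mL")
  for (cn in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(bad))
      stop("malformed TAC CSV row ", bad[1] + 1L, " (file line incl. header): ",
           "non-numeric ", cn, call. = FALSE)
    df[[cn]] <- as.numeric(df[[cn]])
  }
  extra_names <- setdiff(names(df), c(need, "injected_MBq"))
  key <- interaction(df$measurement_id, df$scan, df$roi, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$frame_start_s), ]
    tac(times = g$frame_start_s + g$frame_duration_s / 2,
        values = g$value_MBq_per_mL,
        roi = g$roi[1], scan = g$scan[1],
        measurement_id = g$measurement_id[1],
        injected_activity = if ("injected_MBq" %in% names(g))
          g$injected_MBq[1] else NA_real_,
        meta = list(frame_start = g$frame_start_s,
                    frame_duration = g$frame_duration_s,
                    extra_columns = if (length(extra_names))
                      g[extra_names] else NULL))
  })
  names(out) <- vapply(out, function(x)
    paste(x$measurement_id, x$scan, x$roi, sep = "/"), character(1))
  out
}
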