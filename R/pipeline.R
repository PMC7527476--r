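# Pipeline orchestration: run every stage per channel from one config,
# write tidy CSV outputs plus a manifest, and provide the normality-gated
# transformation used before group statistics are delegated.

#' Run the full analysis pipeline
#'
#' Executes, per channel: line-notch filtering, SO band-passing, Up/Down
#' state detection, SO metrics, normalized-cycle band power for the
#' configured bands, spindle detection (all channels) and ripple
#' detection (channels whose region is in `ripple_regions`), and - when
#' spikes are supplied - state-resolved firing metrics and spike-SO
#' coherence. Writes `states.csv`, `so_metrics.csv`, `band_power.csv`,
#' `events.csv`, `event_summary.csv`, `unit_metrics.csv` (when spikes
#' exist), `metrics_long.csv` and `manifest.json` to the output
#' directory. Outputs are deterministic: re-running on identical inputs
#' reproduces every file byte for byte.
#'
#' @param config A named list or path to a YAML file. Recognized keys:
#'   `simulate` (a list of [synth_config()] arguments) or `input` (with
#'   `recording_dir` and optionally `spikes_csv`), `output_dir`
#'   (required), `bands` (character, default `c("beta", "gamma",
#'   "high_gamma")`), `uds` (arguments of [detect_uds()]), `events`
#'   (list with `high_amp_mult`, `ripple_regions`), `spikes` (list with
#'   `min_rate_per_min`, `coherence_min_rate_per_min`, `segment_s`,
#'   `overlap`), `line_hz` (default 50).
#' @return Invisibly, a list with all result tibbles plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir
  if (is.null(out_dir)) abort("`config$output_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  spikes <- NULL
  if (!is.null(config$simulate)) {
    scfg <- do.call(synth_config, config$simulate)
    sim <- simulate_recording(scfg)
    rec <- sim$recording
    spikes <- sim$spikes
  } else if (!is.null(config$input)) {
    rec <- read_recording(config$input$recording_dir)
    if (!is.null(config$input$spikes_csv)) {
      spikes <- read_spikes(config$input$spikes_csv)
    }
  } else {
    abort("Config must contain either `simulate` or `input`.")
  }

  bands <- config$bands %||% c("beta", "gamma", "high_gamma")
  uds_args <- config$uds %||% list()
  ev_cfg <- config$events %||% list()
  ripple_regions <- ev_cfg$ripple_regions %||% "CA1"
  high_amp_mult <- ev_cfg$high_amp_mult %||% 5
  line_hz <- config$line_hz %||% 50

  rec <- notch_line(rec, line_hz = line_hz)
  dur <- duration_s(rec)

  states_l <- list(); so_l <- list(); bp_l <- list()
  ev_l <- list(); evs_l <- list(); seg_by_ch <- list()
  for (i in seq_len(nrow(rec$channels))) {
    ch <- rec$channels$channel_id[i]
    region <- rec$channels$region[i]
    res <- tryCatch({
      x <- rec$samples[i, ]
      so_f <- so_filter(x, rec$fs_hz)
      seg <- do.call(detect_uds, c(
        list(so_filtered = so_f, fs_hz = rec$fs_hz, raw = x,
             boundaries_s = rec$boundaries_s),
        uds_args
      ))
      som <- so_metrics(seg, so_f)
      pv <- build_phase_vector(seg)
      z <- zscore_channel(x)
      bp <- purrr::map_dfr(bands, function(bn) {
        pw <- morlet_band_power(z, bn, rec$fs_hz)
        prof <- align_power_to_cycle(pw, pv, band = bn)
        dplyr::bind_cols(tibble(band = bn), summarize_cycle_power(prof))
      })
      presets <- list(spindle = spindle_params())
      if (region %in% ripple_regions) presets$ripple <- ripple_params()
      evs <- purrr::map(presets, function(p) {
        ev <- detect_envelope_events(x, rec$fs_hz, p,
                                     boundaries_s = rec$boundaries_s,
                                     channel_id = ch)
        list(events = event_latency(ev, pv),
             summary = compute_event_metrics(
               event_latency(ev, pv), seg = seg,
               high_amp_mult = high_amp_mult
             ))
      })
      list(seg = seg, som = som, bp = bp, evs = evs)
    }, error = function(e) {
      abort(sprintf("Pipeline failed on channel `%s`: %s", ch,
                    conditionMessage(e)))
    })
    seg_by_ch[[ch]] <- res$seg
    states_l[[ch]] <- dplyr::mutate(res$seg$states, channel_id = ch,
                                    .before = 1)
    so_l[[ch]] <- dplyr::mutate(res$som, channel_id = ch, .before = 1)
    bp_l[[ch]] <- dplyr::mutate(res$bp, channel_id = ch, .before = 1)
    for (kind in names(res$evs)) {
      ev_l[[paste(ch, kind)]] <- res$evs[[kind]]$events
      evs_l[[paste(ch, kind)]] <- dplyr::mutate(
        res$evs[[kind]]$summary, channel_id = ch, kind = kind,
        .before = 1
      )
    }
  }

  states <- dplyr::bind_rows(states_l)
  so_tbl <- dplyr::bind_rows(so_l)
  bp_tbl <- dplyr::bind_rows(bp_l)
  ev_tbl <- dplyr::bind_rows(ev_l)
  evs_tbl <- dplyr::bind_rows(evs_l)

  unit_tbl <- NULL
  if (!is.null(spikes) && nrow(spikes) > 0) {
    sp_cfg <- config$spikes %||% list()
    min_rate <- sp_cfg$min_rate_per_min %||% 10
    coh_rate <- sp_cfg$coherence_min_rate_per_min %||% 30
    seg1 <- seg_by_ch[[1]]
    so_f1 <- so_filter(rec$samples[1, ], rec$fs_hz)
    kept <- filter_units(spikes[, c("unit_id", "time_s")], dur, min_rate)
    if (nrow(kept) > 0) {
      unit_tbl <- state_firing_metrics(kept, seg1, dur)
      coh_units <- filter_units(kept, dur, coh_rate)
      coh <- coh_units |>
        dplyr::group_by(.data$unit_id) |>
        dplyr::reframe({
          cr <- tryCatch(
            spike_so_coherence(.data$time_s, so_f1, rec$fs_hz,
                               segment_s = sp_cfg$segment_s %||% 60,
                               overlap = sp_cfg$overlap %||% 0.5),
            error = function(e) NULL
          )
          if (is.null(cr)) {
            tibble(max_coherence = NA_real_, max_coh_freq_hz = NA_real_)
          } else {
            tibble(max_coherence = cr$max_coherence,
                   max_coh_freq_hz = cr$max_freq_hz)
          }
        })
      unit_tbl <- dplyr::left_join(unit_tbl, coh, by = "unit_id")
    }
  }

  long <- metrics_long(so_tbl, bp_tbl, evs_tbl, unit_tbl, rec$channels)

  readr::write_csv(states, file.path(out_dir, "states.csv"))
  readr::write_csv(so_tbl, file.path(out_dir, "so_metrics.csv"))
  readr::write_csv(bp_tbl, file.path(out_dir, "band_power.csv"))
  write_events(ev_tbl, file.path(out_dir, "events.csv"))
  readr::write_csv(evs_tbl, file.path(out_dir, "event_summary.csv"))
  if (!is.null(unit_tbl)) {
    readr::write_csv(unit_tbl, file.path(out_dir, "unit_metrics.csv"))
  }
  readr::write_csv(long, file.path(out_dir, "metrics_long.csv"))

  manifest <- list(
    package = "sleeposc",
    version = as.character(utils::packageVersion("sleeposc")),
    config_hash =
      rlang::hash(config[setdiff(names(config), "output_dir")]),
    n_channels = nrow(rec$channels),
    fs_hz = rec$fs_hz,
    duration_s = dur,
    files = c("states.csv", "so_metrics.csv", "band_power.csv",
              "events.csv", "event_summary.csv",
              if (!is.null(unit_tbl)) "unit_metrics.csv",
              "metrics_long.csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(recording = rec, states = states, so_metrics = so_tbl,
                 band_power = bp_tbl, events = ev_tbl,
                 event_summary = evs_tbl, unit_metrics = unit_tbl,
                 metrics_long = long, manifest = manifest))
}

# Collect every per-channel metric into one long tidy table
# (channel_id, region, metric, value).
metrics_long <- function(so_tbl, bp_tbl, evs_tbl, unit_tbl, channels) {
  pivot_num <- function(df, extra_id = NULL) {
    df |>
      tidyr::pivot_longer(
        cols = dplyr::where(is.numeric),
        names_to = "metric", values_to = "value"
      ) |>
      dplyr::mutate(metric = if (is.null(extra_id)) .data$metric else
        paste(.data[[extra_id]], .data$metric, sep = "_")) |>
      dplyr::select(dplyr::all_of("channel_id"), dplyr::all_of(c("metric", "value")))
  }
  out <- dplyr::bind_rows(
    pivot_num(so_tbl),
    pivot_num(bp_tbl, extra_id = "band"),
    pivot_num(evs_tbl, extra_id = "kind")
  )
  if (!is.null(unit_tbl)) {
    u <- unit_tbl |>
      tidyr::pivot_longer(dplyr::where(is.numeric),
                          names_to = "metric", values_to = "value") |>
      dplyr::mutate(channel_id = NA_character_,
                    metric = paste(.data$unit_id, .data$metric, sep = "_")) |>
      dplyr::select(dplyr::all_of(c("channel_id", "metric", "value")))
    out <- dplyr::bind_rows(out, u)
  }
  dplyr::left_join(out,
                   channels[, c("channel_id", "region")],
                   by = "channel_id") |>
    dplyr::select(dplyr::all_of(c("channel_id", "region", "metric", "value")))
}

#' Normality-gated variable transformation
#'
#' Tests the sample for normality (Kolmogorov-Smirnov against a normal
#' with the sample's mean and SD); if rejected at `alpha`, applies a log
#' transform (skipped unless all values are positive) and re-tests; if
#' still rejected, applies a square-root transform (requires nonnegative
#' values); the first passing transform wins. If none passes, the sample
#' is flagged for nonparametric handling.
#'
#' @param x Numeric sample (length >= 3).
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return A list: `transform` (`"none"`, `"log"`, `"sqrt"` or
#'   `"nonparametric"`), `values` (transformed sample, or the original
#'   when flagged nonparametric), `p_values` (named, per transform
#'   tried), `normal` (logical).
#' @export
select_transform <- function(x, alpha = 0.05) {
  if (length(x) < 3) abort("Need at least 3 values.")
  ks_p <- function(v) {
    suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v))$p.value)
  }
  p <- c(none = ks_p(x))
  if (p["none"] >= alpha) {
    return(list(transform = "none", values = x, p_values = p,
                normal = TRUE))
  }
  if (all(x > 0)) {
    lx <- log(x)
    p["log"] <- ks_p(lx)
    if (p["log"] >= alpha) {
      return(list(transform = "log", values = lx, p_values = p,
                  normal = TRUE))
    }
  }
  if (all(x >= 0)) {
    sx <- sqrt(x)
    p["sqrt"] <- ks_p(sx)
    if (p["sqrt"] >= alpha) {
      return(list(transform = "sqrt", values = sx, p_values = p,
                  normal = TRUE))
    }
  }
  list(transform = "nonparametric", values = x, p_values = p,
       normal = FALSE)
}
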