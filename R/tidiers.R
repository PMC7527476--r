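# broom-style tidiers for the package's result objects.

#' Tidy a UDS segmentation
#'
#' @param x A `uds_segmentation`.
#' @param ... Unused.
#' @return Tibble of states (`label`, `start_s`, `end_s`, `chunk`).
#' @method tidy uds_segmentation
#' @export
tidy.uds_segmentation <- function(x, ...) x$states

#' One-row summary of a UDS segmentation
#'
#' @param x A `uds_segmentation`.
#' @param ... Unused.
#' @return Tibble: `n_states`, `n_cycles`, `so_freq_hz`, `mean_up_s`,
#'   `mean_down_s`, `mean_cycle_s`, `polarity`.
#' @method glance uds_segmentation
#' @export
glance.uds_segmentation <- function(x, ...) {
  cyc <- complete_cycles(x)
  up_len <- cyc$up_end_s - cyc$up_start_s
  down_len <- cyc$up_start_s - cyc$down_start_s
  tibble(
    n_states = nrow(x$states),
    n_cycles = nrow(cyc),
    so_freq_hz = if (nrow(cyc)) nrow(cyc) / sum(up_len + down_len) else
      NA_real_,
    mean_up_s = mean(up_len),
    mean_down_s = mean(down_len),
    mean_cycle_s = mean(up_len + down_len),
    polarity = x$polarity
  )
}

#' Tidy a phase vector
#'
#' @param x A `phase_vector`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `value`, `bin`, `cycle` per sample.
#' @method tidy phase_vector
#' @export
tidy.phase_vector <- function(x, ...) {
  tibble(
    time_s = (seq_len(x$n_samples) - 1) / x$fs_hz,
    value = x$values, bin = x$bin, cycle = x$cycle
  )
}

#' Tidy a normalized-cycle power profile
#'
#' @param x A `cycle_power_profile`.
#' @param ... Unused.
#' @return The per-bin tibble with `bin`, `value`, `n_samples`, plus
#'   `phase_pct` (bin center) and `state`.
#' @method tidy cycle_power_profile
#' @export
tidy.cycle_power_profile <- function(x, ...) {
  dplyr::mutate(
    x$per_bin,
    phase_pct = .data$bin * 1.25 + 0.625,
    state = ifelse(.data$bin < 40, "Down", "Up")
  )
}

#' @rdname summarize_cycle_power
#' @param x A `cycle_power_profile`.
#' @param ... Unused.
#' @method glance cycle_power_profile
#' @export
glance.cycle_power_profile <- function(x, ...) summarize_cycle_power(x)

#' Tidy a coherence result
#'
#' @param x A `coherence_result`.
#' @param ... Unused.
#' @return The spectrum tibble (`freq_hz`, `coherence`).
#' @method tidy coherence_result
#' @export
tidy.coherence_result <- function(x, ...) x$spectrum

#' One-row summary of a coherence result
#'
#' @param x A `coherence_result`.
#' @param ... Unused.
#' @return Tibble: `max_coherence`, `max_freq_hz`, `n_segments`,
#'   `n_disjoint_segments`.
#' @method glance coherence_result
#' @export
glance.coherence_result <- function(x, ...) {
  tibble(max_coherence = x$max_coherence, max_freq_hz = x$max_freq_hz,
         n_segments = x$n_segments,
         n_disjoint_segments = x$n_disjoint_segments)
}

#' Tidy an event-matching report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return The per-match tibble.
#' @method tidy match_report
#' @export
tidy.match_report <- function(x, ...) x$matches

#' One-row summary of an event-matching report
#'
#' @param x A `match_report`.
#' @param ... Unused.
#' @return Tibble: `n_truth`, `n_detected`, `n_matched`, `precision`,
#'   `recall`, `mean_onset_error_ms`.
#' @method glance match_report
#' @export
glance.match_report <- function(x, ...) {
  tibble(
    n_truth = x$n_truth, n_detected = x$n_detected,
    n_matched = x$n_matched, precision = x$precision, recall = x$recall,
    mean_onset_error_ms = if (nrow(x$matches)) {
      mean(x$matches$onset_error_ms)
    } else NA_real_
  )
}
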