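#' Snap a time to the monitor frame grid
#'
#' Stop signals can only be drawn on a display refresh, so stop-signal delays
#' live on a grid of multiples of the frame duration (8.3 ms at 120 Hz).
#' Returns the nearest multiple of `frame_ms`; exact midpoints round up.
#'
#' @param t_ms Time(s) in ms.
#' @param frame_ms Frame duration in ms (> 0).
#' @return `t_ms` snapped to the frame grid.
#' @export
#' @examples
#' quantize_to_frame(30, 8.3)   # 33.2: 4 frames
quantize_to_frame <- function(t_ms, frame_ms = 8.3) {
  stopifnot(frame_ms > 0)
  floor(t_ms / frame_ms + 0.5) * frame_ms
}

#' Create a stop-signal-delay staircase
#'
#' One-up-one-down tracker of the stop-signal delay (SSD), measured from trial
#' onset. After a successful stop the SSD increases by one (frame-quantized)
#' step, moving the stop signal closer to the pacing tone and making stopping
#' harder; after a failed stop it decreases by the same amount. The tracker
#' converges on the SSD at which stopping succeeds on about half of the stop
#' trials. SSD and step are kept on the frame grid; updates saturate at the
#' bounds.
#'
#' @param config A [block_config()]; the initial SSD is
#'   `pacing_onset_ms - 200`, frame-snapped.
#' @param step_ms Nominal step size before frame quantization.
#' @param frame_ms Display frame duration.
#' @param lower_bound_ms,upper_bound_ms Saturation bounds for the SSD. The
#'   defaults keep the stop signal within the trial and strictly before the
#'   pacing tone.
#' @return A `staircase` object with fields `ssd_ms`, `step_ms`, `frame_ms`,
#'   bounds, and an update `history` data frame.
#' @export
#' @examples
#' s <- staircase_new()
#' s$ssd_ms                       # 199.2 (200 snapped to the 8.3 ms grid)
#' update_ssd(s, TRUE)$ssd_ms     # 232.4: one 33.2 ms step harder
staircase_new <- function(config = block_config(),
                          step_ms = 30,
                          frame_ms = 8.3,
                          lower_bound_ms = 0,
                          upper_bound_ms = config$pacing_onset_ms - frame_ms) {
  st <- list(
    ssd_ms = initial_ssd(config, frame_ms = frame_ms),
    step_ms = quantize_to_frame(step_ms, frame_ms),
    frame_ms = frame_ms,
    lower_bound_ms = lower_bound_ms,
    upper_bound_ms = upper_bound_ms,
    history = data.frame(ssd_ms = numeric(0), success = logical(0))
  )
  class(st) <- "staircase"
  st
}

#' Initial stop-signal delay
#'
#' The first stop signal of a block is placed 200 ms before the pacing tone,
#' snapped to the frame grid.
#'
#' @param config A [block_config()].
#' @param frame_ms Display frame duration.
#' @return Initial SSD in ms from trial onset.
#' @export
initial_ssd <- function(config = block_config(), frame_ms = 8.3) {
  if (config$pacing_onset_ms <= 200) {
    stop("initial_ssd: pacing_onset_ms must exceed 200 ms", call. = FALSE)
  }
  quantize_to_frame(config$pacing_onset_ms - 200, frame_ms)
}

#' Update the staircase after a stop trial
#'
#' @param state A `staircase` object.
#' @param stop_succeeded `TRUE` if the response was successfully withheld.
#' @return The updated `staircase`; the pre-update SSD and the outcome are
#'   appended to `history`.
#' @export
update_ssd <- function(state, stop_succeeded) {
  stopifnot(inherits(state, "staircase"), is.logical(stop_succeeded))
  state$history <- rbind(
    state$history,
    data.frame(ssd_ms = state$ssd_ms, success = stop_succeeded)
  )
  new_ssd <- state$ssd_ms + if (stop_succeeded) state$step_ms else -state$step_ms
  # saturate, then snap inward so the grid invariant survives off-grid bounds
  if (new_ssd > state$upper_bound_ms) {
    new_ssd <- floor(state$upper_bound_ms / state$frame_ms) * state$frame_ms
  } else if (new_ssd < state$lower_bound_ms) {
    new_ssd <- ceiling(state$lower_bound_ms / state$frame_ms) * state$frame_ms
  }
  state$ssd_ms <- new_ssd
  state
}

#' Run a staircase against a stationary race-model agent
#'
#' Simulates a sequence of stop trials in which a fixed-SSRT stopping process
#' races go finishes drawn from a stationary Gaussian: the defining property
#' of the one-up-one-down tracker is that the realized stop-success
#' proportion converges to about 0.5. Used for convergence checks and for
#' parameter-recovery experiments on the integration-method SSRT.
#'
#' @param n_stop Number of stop trials.
#' @param go_mean_ms,go_sd_ms Mean and SD of the go finish time (ms, from
#'   trial onset).
#' @param ssrt_ms Fixed stopping latency of the agent.
#' @param config A [block_config()] (sets the initial SSD and bounds).
#' @param step_ms,frame_ms Staircase step and frame grid.
#' @return Data frame with one row per stop trial: `ssd_ms`, `go_finish_ms`,
#'   `responded`.
#' @export
#' @examples
#' set.seed(1)
#' run <- simulate_staircase_run(300)
#' mean(!run$responded)  # ~0.5
simulate_staircase_run <- function(n_stop, go_mean_ms = 330, go_sd_ms = 30,
                                   ssrt_ms = 150, config = block_config(),
                                   step_ms = 30, frame_ms = 8.3) {
  st <- staircase_new(config, step_ms = step_ms, frame_ms = frame_ms)
  ssd <- numeric(n_stop)
  go <- stats::rnorm(n_stop, go_mean_ms, go_sd_ms)
  responded <- logical(n_stop)
  for (i in seq_len(n_stop)) {
    ssd[i] <- st$ssd_ms
    race <- run_stop_trial(go[i], st$ssd_ms, ssrt_ms)
    responded[i] <- race$responded
    st <- update_ssd(st, !race$responded)
  }
  data.frame(ssd_ms = ssd, go_finish_ms = go, responded = responded)
}
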