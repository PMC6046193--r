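#' Response-to-pacing asynchrony
#'
#' Signed synchronization error: `t_r - t_ps`. Negative values mean the
#' response anticipated the pacing tone (the negative mean asynchrony of the
#' synchronization literature); positive values mean it followed the tone.
#'
#' @param t_r Response time(s).
#' @param t_ps Pacing-signal time(s), on the same clock.
#' @return `t_r - t_ps` in the input units.
#' @export
#' @examples
#' asynchrony(338.53, 400)  # -61.47
asynchrony <- function(t_r, t_ps) {
  t_r - t_ps
}

#' Label go types within one block
#'
#' Classifies trials by their position relative to stop signals: the
#' familiarization prefix, the first and second go trial after each stop
#' signal, all remaining go trials, and the stop trials themselves. A new
#' stop signal restarts the first/second count; go trials not preceded by any
#' stop are `other_go`.
#'
#' @param trial_kind Character vector of `"go"`/`"stop"` in presentation order.
#' @param trial_index Trial indices (must be sorted ascending).
#' @param n_familiarization Length of the familiarization prefix.
#' @return Character vector of labels: `"familiarization"`,
#'   `"first_go_after_stop"`, `"second_go_after_stop"`, `"other_go"`, `"stop"`.
#' @export
#' @examples
#' label_go_types(c("stop", "go", "go", "go"), 11:14)
label_go_types <- function(trial_kind, trial_index = seq_along(trial_kind),
                           n_familiarization = 10) {
  if (is.unsorted(trial_index, strictly = TRUE)) {
    stop("label_go_types: events must be sorted by trial_index", call. = FALSE)
  }
  labels <- character(length(trial_kind))
  since_stop <- Inf  # go trials seen since the last stop
  for (i in seq_along(trial_kind)) {
    if (trial_index[i] <= n_familiarization) {
      labels[i] <- "familiarization"
      next
    }
    if (trial_kind[i] == "stop") {
      labels[i] <- "stop"
      since_stop <- 0
    } else {
      since_stop <- since_stop + 1
      labels[i] <- if (since_stop == 1) {
        "first_go_after_stop"
      } else if (since_stop == 2) {
        "second_go_after_stop"
      } else {
        "other_go"
      }
    }
  }
  labels
}

#' Label a trial-event table and attach calibrated asynchronies
#'
#' Applies [label_go_types()] per participant x block and computes, for every
#' trial with a response, the calibrated asynchrony
#' `calibrate(raw_response) - pacing_onset` and the calibrated time-into-trial
#' `calibrate(raw_response) - trial_onset` (the synchronized-response time
#' used by the SSRT integration method). Ignored stop signals in irrelevant
#' blocks keep the `stop` label but carry an asynchrony, mirroring the
#' instruction to treat them as go trials.
#'
#' @param events Trial-event data frame (see [simulate_session()] /
#'   [read_events()]).
#' @param offsets A [calibration_offsets()].
#' @param n_familiarization Familiarization prefix length.
#' @return `events` with added columns `go_type`, `asynchrony_ms`, `sr_ms`.
#' @export
label_events <- function(events, offsets = calibration_offsets(),
                         n_familiarization = 10) {
  stopifnot(is.data.frame(events))
  key <- paste(events$participant_id, events$block_index)
  events$go_type <- NA_character_
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(events$trial_index[idx])]
    events$go_type[idx] <- label_go_types(events$trial_kind[idx],
                                          events$trial_index[idx],
                                          n_familiarization)
  }
  calibrated <- calibrate_response(events$raw_response_ms, events$modality, offsets)
  events$asynchrony_ms <- asynchrony(calibrated, events$pacing_onset_ms)
  events$sr_ms <- calibrated - events$trial_onset_ms
  events
}

#' Per-condition asynchrony summaries
#'
#' Aggregates in two stages, matching repeated-measures reporting: first a
#' mean per participant within each design cell, then the across-participant
#' mean, standard error and t-based 95% CI. Familiarization trials, misses
#' and any go types in `drop_go_types` are always excluded; stop-labelled
#' trials are excluded unless explicitly requested via `by = c(..., "go_type")`
#' summaries of go types only.
#'
#' @param labeled Output of [label_events()].
#' @param by Character vector of cell keys (any of `block_type`, `modality`,
#'   `phase`, `go_type`).
#' @param drop_go_types Go types excluded from the summaries (default:
#'   familiarization only; the headline condition means additionally drop
#'   `first_go_after_stop`).
#' @param participants Optional character vector restricting to included
#'   participants.
#' @return Data frame with the cell keys plus `n`, `mean_ms`, `se_ms`,
#'   `ci95_lo_ms`, `ci95_hi_ms`. Cells with a single participant get `NA`
#'   SE/CI; empty cells are absent.
#' @export
condition_means <- function(labeled,
                            by = c("block_type", "modality"),
                            drop_go_types = "familiarization",
                            participants = NULL) {
  stopifnot(all(by %in% c("block_type", "modality", "phase", "go_type")))
  keep_types <- setdiff(c("first_go_after_stop", "second_go_after_stop", "other_go"),
                        drop_go_types)
  d <- labeled[labeled$go_type %in% keep_types & !is.na(labeled$asynchrony_ms), ]
  if (!is.null(participants)) {
    d <- d[d$participant_id %in% participants, ]
  }
  if (nrow(d) == 0) {
    stop("condition_means: no analyzable trials after exclusions", call. = FALSE)
  }
  per_subj <- stats::aggregate(
    d["asynchrony_ms"],
    by = d[c("participant_id", by)],
    FUN = mean
  )
  out <- do.call(rbind, lapply(
    split(per_subj, per_subj[by], drop = TRUE),
    function(cell) {
      x <- cell$asynchrony_ms
      n <- length(x)
      m <- mean(x)
      se <- if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
      half <- if (n > 1) stats::qt(0.975, n - 1) * se else NA_real_
      cbind(cell[1, by, drop = FALSE],
            data.frame(n = n, mean_ms = m, se_ms = se,
                       ci95_lo_ms = m - half, ci95_hi_ms = m + half))
    }
  ))
  rownames(out) <- NULL
  out
}

#' Proactive inhibition difference score
#'
#' Anticipatory response slowing induced by stop-signal relevance, measured
#' as the relevant-minus-irrelevant difference of condition mean
#' asynchronies. Positive values indicate slowing (reduced anticipation) when
#' stop signals must be obeyed. Because calibration is a rigid within-modality
#' shift, this score is calibration-invariant.
#'
#' @param mean_relevant Mean asynchrony in relevant-stop blocks (ms).
#' @param mean_irrelevant Mean asynchrony in irrelevant-stop blocks (ms).
#' @return `mean_relevant - mean_irrelevant` (ms).
#' @export
#' @examples
#' proactive_inhibition(-70.24, -128.29)  # 58.05
#' proactive_inhibition(-35.37, -61.47)   # 26.10
proactive_inhibition <- function(mean_relevant, mean_irrelevant) {
  mean_relevant - mean_irrelevant
}

#' Per-participant proactive inhibition
#'
#' Computes, for every participant and modality, the mean asynchrony in
#' relevant and irrelevant blocks (over the go types in `go_types`; the
#' headline analysis uses second-go and other-go trials) and their
#' [proactive_inhibition()] difference.
#'
#' @param labeled Output of [label_events()].
#' @param go_types Go types entering the means.
#' @param participants Optional inclusion restriction.
#' @return Data frame with `participant_id`, `modality`, `mean_relevant_ms`,
#'   `mean_irrelevant_ms`, `proactive_inhibition_ms`.
#' @export
proactive_inhibition_by_participant <- function(labeled,
                                                go_types = c("second_go_after_stop",
                                                             "other_go"),
                                                participants = NULL) {
  d <- labeled[labeled$go_type %in% go_types & !is.na(labeled$asynchrony_ms), ]
  if (!is.null(participants)) d <- d[d$participant_id %in% participants, ]
  agg <- stats::aggregate(d["asynchrony_ms"],
                          by = d[c("participant_id", "modality", "block_type")],
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = c("participant_id", "modality"),
                         timevar = "block_type", direction = "wide")
  names(wide)[names(wide) == "asynchrony_ms.relevant"] <- "mean_relevant_ms"
  names(wide)[names(wide) == "asynchrony_ms.irrelevant"] <- "mean_irrelevant_ms"
  wide$proactive_inhibition_ms <- proactive_inhibition(wide$mean_relevant_ms,
                                                       wide$mean_irrelevant_ms)
  rownames(wide) <- NULL
  wide[order(wide$participant_id, wide$modality), ]
}

#' Stop-success screening
#'
#' Valid race-model estimates require stopping to succeed on roughly half the
#' stop trials, so participants whose overall stop-success percentage falls
#' outside `bounds` are excluded. Success is computed over relevant-stop
#' blocks, pooled across modalities and phases by default.
#'
#' @param events Trial-event data frame.
#' @param bounds Inclusive inclusion bounds in percent (default `c(40, 60)`).
#' @param per_modality If `TRUE`, screen each modality separately; a
#'   participant is included only if every modality passes.
#' @return Data frame with `participant_id`, `stop_success_pct`, `included`
#'   (plus `modality` when `per_modality`).
#' @export
inclusion_filter <- function(events, bounds = c(40, 60), per_modality = FALSE) {
  st <- events[events$trial_kind == "stop" & events$block_type == "relevant", ]
  if (nrow(st) == 0) {
    stop("inclusion_filter: no relevant-stop stop trials", call. = FALSE)
  }
  keys <- if (per_modality) c("participant_id", "modality") else "participant_id"
  agg <- stats::aggregate(list(stop_success_pct = st$stop_outcome == "success"),
                          by = st[keys], FUN = function(x) 100 * mean(x))
  agg$included <- agg$stop_success_pct >= bounds[1] & agg$stop_success_pct <= bounds[2]
  agg[order(agg$participant_id), ]
}

#' Included participants
#'
#' @param events Trial-event data frame.
#' @param ... Passed to [inclusion_filter()].
#' @return Character vector of participant ids passing the screen.
#' @export
included_participants <- function(events, ...) {
  rep_tab <- inclusion_filter(events, ...)
  agg <- stats::aggregate(list(ok = rep_tab$included),
                          by = rep_tab["participant_id"], FUN = all)
  agg$participant_id[agg$ok]
}

#' Go-miss rate in a cell
#'
#' Percentage of analyzable go trials (familiarization excluded) with no
#' response.
#'
#' @param labeled Output of [label_events()].
#' @param block_type,modality Optional cell restriction.
#' @return Miss percentage (0-100).
#' @export
miss_rate <- function(labeled, block_type = NULL, modality = NULL) {
  d <- labeled[labeled$trial_kind == "go" & labeled$go_type != "familiarization", ]
  if (!is.null(block_type)) d <- d[d$block_type == block_type, ]
  if (!is.null(modality)) d <- d[d$modality == modality, ]
  if (nrow(d) == 0) stop("miss_rate: empty cell", call. = FALSE)
  100 * mean(is.na(d$raw_response_ms))
}
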