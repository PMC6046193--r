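#' Probability of responding on stop trials
#'
#' @param stop_outcomes Character vector of `"success"`/`"fail"` outcomes for
#'   the stop trials of one block.
#' @return Failed stops divided by total stop trials.
#' @export
p_respond <- function(stop_outcomes) {
  stop_outcomes <- stop_outcomes[!is.na(stop_outcomes)]
  if (length(stop_outcomes) == 0) {
    stop("p_respond: no stop trials", call. = FALSE)
  }
  mean(stop_outcomes == "fail")
}

#' Integration-method SSRT for one block
#'
#' The stop-signal reaction time is the latency of the covert stopping
#' process. The integration method estimates the stop process's finishing
#' time as the p(respond) quantile of the go synchronized-response
#' distribution: the go SRs are rank-ordered ascending, the `n`th is selected
#' with `n = ceiling(p * N)` (clamped to `[1, N]`), and the block's SSD is
#' subtracted.
#'
#' @param go_srs Go synchronized-response times-into-trial (calibrated) for
#'   the block; need not be sorted.
#' @param p Probability of responding on stop trials, from [p_respond()].
#' @param ssd_ms The block's (mean realized) stop-signal delay.
#' @param rounding Rule turning `p * N` into a rank: `"ceiling"` (default),
#'   `"floor"` or `"round"`.
#' @return SSRT estimate in ms.
#' @export
#' @examples
#' ssrt_integration(c(300, 320, 340, 360, 380), p = 0.4, ssd_ms = 200)  # 120
ssrt_integration <- function(go_srs, p, ssd_ms,
                             rounding = c("ceiling", "floor", "round")) {
  rounding <- match.arg(rounding)
  go_srs <- go_srs[!is.na(go_srs)]
  if (length(go_srs) == 0) {
    stop("ssrt_integration: empty go distribution", call. = FALSE)
  }
  stopifnot(p >= 0, p <= 1, is.finite(ssd_ms))
  if (p == 0) {
    warning("ssrt_integration: p(respond) = 0 is degenerate; using the fastest go SR",
            call. = FALSE)
  }
  srs <- sort(go_srs)
  n_total <- length(srs)
  n <- switch(rounding,
              ceiling = ceiling(p * n_total),
              floor = floor(p * n_total),
              round = round(p * n_total))
  n <- min(max(n, 1L), n_total)
  srs[n] - ssd_ms
}

#' Participant-level SSRT
#'
#' Per-block SSRTs are computed first, then averaged (unweighted) across
#' blocks.
#'
#' @param block_ssrts Numeric vector of per-block SSRT estimates.
#' @return Mean SSRT in ms.
#' @export
ssrt_participant <- function(block_ssrts) {
  block_ssrts <- block_ssrts[!is.na(block_ssrts)]
  if (length(block_ssrts) == 0) {
    stop("ssrt_participant: no block estimates", call. = FALSE)
  }
  mean(block_ssrts)
}

#' Reactive-inhibition summary per participant and modality
#'
#' For every relevant-stop block: p(respond), the mean realized SSD and the
#' integration-method SSRT from that block's analyzable go distribution
#' (calibrated times-into-trial from non-familiarization go trials; misses
#' and failed-stop responses excluded by default). Block SSRTs are then
#' averaged per participant and modality. SSRT is defined only where stopping
#' was required, so irrelevant blocks never contribute.
#'
#' @param labeled Output of [label_events()].
#' @param rounding Rank rounding rule, see [ssrt_integration()].
#' @param miss_replace If `TRUE`, each go miss enters the go distribution as
#'   the block's maximum SR (a conservative convention); default drops misses.
#' @param participants Optional inclusion restriction.
#' @return List with `blocks` (one row per participant x modality x block:
#'   `p_respond`, `mean_ssd_ms`, `ssrt_ms`) and `participants` (one row per
#'   participant x modality: `ssrt_participant_ms`).
#' @export
inhibition_summary <- function(labeled, rounding = "ceiling",
                               miss_replace = FALSE, participants = NULL) {
  d <- labeled[labeled$block_type == "relevant", ]
  if (!is.null(participants)) d <- d[d$participant_id %in% participants, ]
  key <- interaction(d$participant_id, d$block_index, drop = TRUE)
  rows <- lapply(split(d, key), function(blk) {
    stops <- blk[blk$trial_kind == "stop", ]
    gos <- blk[blk$trial_kind == "go" & blk$go_type != "familiarization", ]
    go_srs <- gos$sr_ms[!is.na(gos$sr_ms)]
    if (miss_replace && any(is.na(gos$sr_ms)) && length(go_srs) > 0) {
      go_srs <- c(go_srs, rep(max(go_srs), sum(is.na(gos$sr_ms))))
    }
    p <- p_respond(stops$stop_outcome)
    mean_ssd <- mean(stops$ssd_ms)
    data.frame(participant_id = blk$participant_id[1],
               modality = blk$modality[1],
               block_index = blk$block_index[1],
               phase = blk$phase[1],
               p_respond = p,
               mean_ssd_ms = mean_ssd,
               ssrt_ms = ssrt_integration(go_srs, p, mean_ssd, rounding = rounding))
  })
  blocks <- do.call(rbind, rows)
  rownames(blocks) <- NULL
  blocks <- blocks[order(blocks$participant_id, blocks$modality, blocks$block_index), ]
  parts <- stats::aggregate(list(ssrt_participant_ms = blocks$ssrt_ms),
                            by = blocks[c("participant_id", "modality")],
                            FUN = ssrt_participant)
  list(blocks = blocks,
       participants = parts[order(parts$participant_id, parts$modality), ])
}

#' Race-model assumption check
#'
#' Under the independent horse race, responses that escape inhibition on stop
#' trials are the fast tail of the go distribution, so per participant the
#' mean failed-stop asynchrony should fall below the mean go asynchrony in
#' relevant-stop blocks. Returns the per-participant means, their difference,
#' and a cohort-level paired t test.
#'
#' @param labeled Output of [label_events()].
#' @param participants Optional inclusion restriction.
#' @return List with `by_participant` (columns `participant_id`,
#'   `failed_stop_mean_ms`, `go_mean_ms`, `diff_ms`) and `test`
#'   (a [paired_t()] result). Participants with no failed stop are omitted
#'   with a message.
#' @export
race_check <- function(labeled, participants = NULL) {
  d <- labeled[labeled$block_type == "relevant", ]
  if (!is.null(participants)) d <- d[d$participant_id %in% participants, ]
  rows <- lapply(split(d, d$participant_id), function(pd) {
    failed <- pd$asynchrony_ms[pd$trial_kind == "stop" &
                                 !is.na(pd$stop_outcome) &
                                 pd$stop_outcome == "fail"]
    gos <- pd$asynchrony_ms[pd$trial_kind == "go" &
                              pd$go_type != "familiarization" &
                              !is.na(pd$asynchrony_ms)]
    if (length(failed) == 0 || length(gos) == 0) {
      message("race_check: omitting ", pd$participant_id[1],
              " (no failed stop or no analyzable go)")
      return(NULL)
    }
    data.frame(participant_id = pd$participant_id[1],
               failed_stop_mean_ms = mean(failed),
               go_mean_ms = mean(gos),
               diff_ms = mean(failed) - mean(gos))
  })
  by_participant <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(by_participant) <- NULL
  test <- if (nrow(by_participant) >= 2) {
    paired_t(by_participant$failed_stop_mean_ms, by_participant$go_mean_ms)
  } else {
    NULL
  }
  list(by_participant = by_participant, test = test)
}
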