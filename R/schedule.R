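#' Block configuration
#'
#' Describes one block of the combined synchronization / stop-signal task:
#' `n_trials` paced trials of `inter_onset_interval_ms` each, an auditory
#' pacing signal `pacing_onset_ms` into every trial, `n_stop` stop trials,
#' and an all-go familiarization prefix of `n_familiarization` trials that is
#' excluded from analysis. Stop trials are separated by at least
#' `min_go_after_stop` and (between consecutive stops) at most
#' `max_go_after_stop` go trials.
#'
#' @param n_trials Total trials per block.
#' @param n_stop Number of stop trials per block.
#' @param n_familiarization Length of the all-go familiarization prefix.
#' @param inter_onset_interval_ms Trial duration / pacing inter-onset interval.
#' @param pacing_onset_ms Time of the pacing tone within a trial (ms).
#' @param min_go_after_stop Minimum go trials between consecutive stop trials.
#' @param max_go_after_stop Maximum go trials between consecutive stop trials
#'   (waived after the final stop of the block).
#' @return A `block_config` object (a validated list).
#' @export
#' @examples
#' cfg <- block_config()
#' cfg$n_trials
block_config <- function(n_trials = 80,
                         n_stop = 20,
                         n_familiarization = 10,
                         inter_onset_interval_ms = 1250,
                         pacing_onset_ms = 400,
                         min_go_after_stop = 1,
                         max_go_after_stop = 10) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    n_stop = as.integer(n_stop),
    n_familiarization = as.integer(n_familiarization),
    inter_onset_interval_ms = as.numeric(inter_onset_interval_ms),
    pacing_onset_ms = as.numeric(pacing_onset_ms),
    min_go_after_stop = as.integer(min_go_after_stop),
    max_go_after_stop = as.integer(max_go_after_stop)
  )
  class(cfg) <- "block_config"
  validate_block_config(cfg)
  cfg
}

validate_block_config <- function(cfg) {
  stopifnot(inherits(cfg, "block_config"))
  if (cfg$inter_onset_interval_ms <= 0) {
    stop("block_config: inter_onset_interval_ms must be > 0", call. = FALSE)
  }
  if (cfg$pacing_onset_ms <= 0) {
    stop("block_config: pacing_onset_ms must be > 0", call. = FALSE)
  }
  if (cfg$pacing_onset_ms >= cfg$inter_onset_interval_ms) {
    stop("block_config: pacing_onset_ms must fall inside the trial", call. = FALSE)
  }
  if (cfg$n_familiarization >= cfg$n_trials) {
    stop("block_config: n_familiarization must be < n_trials", call. = FALSE)
  }
  if (cfg$n_stop < 0 || cfg$n_familiarization < 0) {
    stop("block_config: counts must be non-negative", call. = FALSE)
  }
  if (cfg$min_go_after_stop < 0 || cfg$max_go_after_stop < cfg$min_go_after_stop) {
    stop("block_config: need 0 <= min_go_after_stop <= max_go_after_stop",
         call. = FALSE)
  }
  n_free <- cfg$n_trials - cfg$n_familiarization
  n_go_free <- n_free - cfg$n_stop
  if (n_go_free < 0) {
    stop("block_config: infeasible - more stop trials than post-familiarization slots",
         call. = FALSE)
  }
  if (cfg$n_stop > 1 && n_go_free < (cfg$n_stop - 1) * cfg$min_go_after_stop) {
    stop(paste0("block_config: infeasible - min_go_after_stop=",
                cfg$min_go_after_stop, " cannot be honoured between ",
                cfg$n_stop, " stop trials with only ", n_go_free, " go trials"),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Generate one block's trial-kind sequence
#'
#' Constructive placement: the gaps between consecutive stop trials start at
#' `min_go_after_stop` go trials each, and the remaining go trials are
#' distributed one at a time, uniformly at random, over the lead-in segment,
#' the internal gaps (up to `max_go_after_stop` each) and the tail after the
#' last stop. The familiarization prefix is always all-go, and the maximum-gap
#' constraint is waived after the final stop.
#'
#' Consumes the R random-number stream; call [set.seed()] first for a
#' reproducible schedule.
#'
#' @param config A [block_config()].
#' @return Character vector of length `n_trials` with entries `"go"`/`"stop"`.
#' @export
#' @examples
#' set.seed(1)
#' table(generate_block_schedule(block_config()))
generate_block_schedule <- function(config = block_config()) {
  validate_block_config(config)
  n_free <- config$n_trials - config$n_familiarization
  if (config$n_stop == 0) {
    return(rep("go", config$n_trials))
  }
  n_go_free <- n_free - config$n_stop
  n_gaps <- config$n_stop - 1
  # slot 1 = lead-in, slots 2..(n_gaps+1) = internal gaps, last = tail
  gaps <- c(0L, rep(config$min_go_after_stop, n_gaps), 0L)
  caps <- c(n_go_free, rep(config$max_go_after_stop, n_gaps), n_go_free)
  extra <- n_go_free - sum(gaps)
  while (extra > 0L) {
    open <- which(gaps < caps)
    pick <- open[sample.int(length(open), 1L)]
    gaps[pick] <- gaps[pick] + 1L
    extra <- extra - 1L
  }
  kinds <- character(0)
  for (i in seq_len(config$n_stop)) {
    kinds <- c(kinds, rep("go", gaps[i]), "stop")
  }
  kinds <- c(rep("go", config$n_familiarization), kinds, rep("go", gaps[length(gaps)]))
  stopifnot(length(kinds) == config$n_trials)
  kinds
}

#' Absolute pacing-onset times
#'
#' Trial `k` starts at `(k - 1) * inter_onset_interval_ms` on the session
#' clock; its pacing tone sounds `pacing_onset_ms` later.
#'
#' @param config A [block_config()].
#' @param n Number of trials.
#' @return Numeric vector of absolute pacing-onset times (ms).
#' @export
pacing_times <- function(config = block_config(), n) {
  stopifnot(n >= 1)
  (seq_len(n) - 1) * config$inter_onset_interval_ms + config$pacing_onset_ms
}

#' Trial onset times
#'
#' @param config A [block_config()].
#' @param n Number of trials.
#' @return Numeric vector of absolute trial-onset times (ms).
#' @export
trial_onsets <- function(config = block_config(), n) {
  stopifnot(n >= 1)
  (seq_len(n) - 1) * config$inter_onset_interval_ms
}

#' Generate a pseudo-randomized session design
#'
#' A session has two phases of four blocks each. Within a phase the two
#' stop-block types (`relevant`, `irrelevant`) appear as consecutive pairs,
#' and within a pair one response modality is immediately followed by the
#' other modality under the same stop-block type before the block type
#' switches. Which block type leads, and the modality order inside each pair,
#' are drawn from the random stream.
#'
#' @param config A [block_config()] attached to every block.
#' @return A `session_design`: data frame with columns `phase`, `block_index`,
#'   `block_type`, `modality`, plus the block config as an attribute.
#' @export
#' @examples
#' set.seed(7)
#' generate_session_design()
generate_session_design <- function(config = block_config()) {
  one_phase <- function() {
    types <- sample(c("relevant", "irrelevant"))
    out <- list()
    for (ty in types) {
      mods <- sample(c("finger", "vocal"))
      out[[length(out) + 1L]] <- data.frame(block_type = ty, modality = mods)
    }
    do.call(rbind, out)
  }
  des <- rbind(cbind(phase = 1L, one_phase()), cbind(phase = 2L, one_phase()))
  des$block_index <- seq_len(nrow(des))
  des <- des[, c("phase", "block_index", "block_type", "modality")]
  attr(des, "block_config") <- config
  class(des) <- c("session_design", "data.frame")
  validate_session_design(des)
  des
}

validate_session_design <- function(design) {
  stopifnot(is.data.frame(design))
  if (nrow(design) != 8L) {
    stop("session_design: expected 8 blocks (2 phases x 4)", call. = FALSE)
  }
  for (ph in unique(design$phase)) {
    d <- design[design$phase == ph, ]
    cells <- paste(d$block_type, d$modality)
    if (anyDuplicated(cells) || length(cells) != 4L) {
      stop("session_design: each (block_type, modality) pair must appear once per phase",
           call. = FALSE)
    }
    # pairs: blocks 1-2 and 3-4 of a phase share a block type, alternate modality
    for (pair_start in c(1L, 3L)) {
      a <- d[pair_start, ]; b <- d[pair_start + 1L, ]
      if (a$block_type != b$block_type) {
        stop("session_design: a block type must complete both modalities before switching",
             call. = FALSE)
      }
      if (a$modality == b$modality) {
        stop("session_design: within a stop-block pair the modality must alternate",
             call. = FALSE)
      }
    }
  }
  invisible(design)
}
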