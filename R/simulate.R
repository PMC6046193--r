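#' Generative parameters for one simulated participant
#'
#' The participant model is an independent horse race. On every trial a
#' synchronization ("go") process plans a response around the pacing tone with
#' mean asynchrony `mu_asynchrony_ms` (negative = anticipation) and
#' trial-to-trial SD `sigma_trial_ms`. In blocks where stop signals are
#' relevant, anticipatory slowing shifts the planned response later by
#' `proactive_shift_ms` (proactive inhibition as a pure location shift). On
#' relevant-block stop trials a stopping process with latency drawn around
#' `ssrt_mean_ms` races the go process: the response escapes iff the go
#' process finishes strictly before `SSD + SSRT`. Responses that would be
#' emitted can be lost as misses with probability `miss_prob`.
#'
#' All per-modality arguments are named vectors with entries `finger` and
#' `vocal`; `miss_prob` is a 2x2 matrix (modality x block type).
#'
#' @param mu_asynchrony_ms Mean asynchrony per modality (ms, relative to the
#'   pacing tone).
#' @param sigma_trial_ms Trial-to-trial SD per modality (ms, >= 0).
#' @param proactive_shift_ms Slowing added in relevant-stop blocks (ms).
#' @param ssrt_mean_ms Mean stop-signal reaction time per modality (ms, > 0).
#' @param ssrt_sd_ms Trial-to-trial SSRT SD per modality (draws are truncated
#'   at 1 ms).
#' @param miss_prob Matrix of miss probabilities with rownames
#'   `c("finger", "vocal")` and colnames `c("relevant", "irrelevant")`.
#' @param go_dist Go-finish noise family: `"gaussian"` (default) or
#'   `"lognormal"` (right-skewed, same mean and SD).
#' @param seed Optional per-participant seed used by [simulate_session()].
#' @return A `participant_params` object.
#' @export
participant_params <- function(mu_asynchrony_ms = c(finger = -128.29, vocal = -61.47),
                               sigma_trial_ms = c(finger = 30, vocal = 30),
                               proactive_shift_ms = c(finger = 58.05, vocal = 26.10),
                               ssrt_mean_ms = c(finger = 152.95, vocal = 187.81),
                               ssrt_sd_ms = c(finger = 10, vocal = 10),
                               miss_prob = default_miss_prob(),
                               go_dist = c("gaussian", "lognormal"),
                               seed = NULL) {
  go_dist <- match.arg(go_dist)
  mods <- c("finger", "vocal")
  for (v in list(mu_asynchrony_ms, sigma_trial_ms, proactive_shift_ms,
                 ssrt_mean_ms, ssrt_sd_ms)) {
    stopifnot(all(mods %in% names(v)))
  }
  stopifnot(all(sigma_trial_ms >= 0), all(ssrt_mean_ms > 0), all(ssrt_sd_ms >= 0))
  stopifnot(is.matrix(miss_prob), all(mods %in% rownames(miss_prob)),
            all(c("relevant", "irrelevant") %in% colnames(miss_prob)),
            all(miss_prob >= 0 & miss_prob <= 1))
  out <- list(mu_asynchrony_ms = mu_asynchrony_ms,
              sigma_trial_ms = sigma_trial_ms,
              proactive_shift_ms = proactive_shift_ms,
              ssrt_mean_ms = ssrt_mean_ms,
              ssrt_sd_ms = ssrt_sd_ms,
              miss_prob = miss_prob,
              go_dist = go_dist,
              seed = seed)
  class(out) <- "participant_params"
  out
}

#' Default miss probabilities per modality and block type
#'
#' Go-miss rates observed in the paradigm the generator emulates: 3% / 9%
#' for finger (relevant / irrelevant) and 1% / 0.4% for vocal.
#'
#' @return 2x2 numeric matrix, modality x block type.
#' @export
default_miss_prob <- function() {
  matrix(c(0.03, 0.09, 0.01, 0.004), nrow = 2, byrow = TRUE,
         dimnames = list(c("finger", "vocal"), c("relevant", "irrelevant")))
}

#' Draw planned go-finish times relative to the pacing tone
#'
#' Mean structure: `mu_asynchrony + proactive_shift * [block is relevant]`,
#' with additive noise of SD `sigma_trial` (Gaussian, or a mean/SD-matched
#' shifted log-normal when `go_dist = "lognormal"`).
#'
#' @param params A [participant_params()].
#' @param modality `"finger"` or `"vocal"`.
#' @param block_type `"relevant"` or `"irrelevant"`.
#' @param n Number of draws.
#' @return Numeric vector: planned response times relative to the pacing tone
#'   (negative = before the tone).
#' @export
draw_go_finish <- function(params, modality, block_type, n = 1) {
  stopifnot(inherits(params, "participant_params"))
  modality <- match.arg(modality, c("finger", "vocal"))
  block_type <- match.arg(block_type, c("relevant", "irrelevant"))
  mu <- params$mu_asynchrony_ms[[modality]] +
    if (block_type == "relevant") params$proactive_shift_ms[[modality]] else 0
  sigma <- params$sigma_trial_ms[[modality]]
  if (sigma == 0) {
    return(rep(mu, n))
  }
  if (params$go_dist == "gaussian") {
    stats::rnorm(n, mean = mu, sd = sigma)
  } else {
    # shifted log-normal with matched mean and SD, cv fixed at 0.35
    cv <- 0.35
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(sigma / cv) - sdlog^2 / 2
    mu - sigma / cv + stats::rlnorm(n, meanlog, sdlog)
  }
}

#' Race one stop trial
#'
#' Independent horse race: the response is emitted (failed stop) iff the go
#' process finishes strictly before `ssd_ms + ssrt_draw_ms`; otherwise the
#' stop process wins and the response is withheld. Exact ties resolve to a
#' successful stop (a zero-probability event under continuous noise, fixed
#' for determinism).
#'
#' @param go_finish_ms Planned go-finish time, measured from trial onset.
#' @param ssd_ms Stop-signal delay, measured from trial onset.
#' @param ssrt_draw_ms Stopping latency for this trial (> 0).
#' @return List with `responded` (logical) and `response_ms` (the go finish
#'   time if responded, else `NA`). Vectorized over its arguments.
#' @export
#' @examples
#' run_stop_trial(350, 200, 160)$responded  # TRUE: 350 < 360
#' run_stop_trial(350, 150, 160)$responded  # FALSE: 350 >= 310
run_stop_trial <- function(go_finish_ms, ssd_ms, ssrt_draw_ms) {
  stopifnot(all(is.finite(go_finish_ms)), all(is.finite(ssd_ms)),
            all(ssrt_draw_ms > 0))
  responded <- go_finish_ms < ssd_ms + ssrt_draw_ms
  list(responded = responded,
       response_ms = ifelse(responded, go_finish_ms, NA_real_))
}

#' Simulate one participant's session
#'
#' Composes the block schedules, the per-modality SSD staircases and the race
#' rule into a long-format trial-event table. Stop trials in relevant blocks
#' drive that modality's staircase in presentation order; in irrelevant
#' blocks the stop signal is presented (at the block-initial SSD) but never
#' withholds the response. Emitted response times are *uncalibrated*: the
#' device offsets in `device_offsets` are added so that the calibration stage
#' of the analysis pipeline is exercised end to end.
#'
#' @param params A [participant_params()].
#' @param design A session design from [generate_session_design()].
#' @param participant_id Identifier written into the event table.
#' @param device_offsets A [calibration_offsets()] added to emitted responses.
#' @param carry_over_blocks If `TRUE`, a modality's staircase carries its SSD
#'   across that modality's relevant blocks; default starts fresh per block.
#' @param seed Optional seed (defaults to `params$seed` if set).
#' @return Data frame of trial events, one row per trial, with columns
#'   `participant_id`, `phase`, `block_index`, `block_type`, `modality`,
#'   `trial_index`, `trial_kind`, `trial_onset_ms`, `pacing_onset_ms`,
#'   `ssd_ms`, `raw_response_ms`, `stop_outcome`.
#' @export
simulate_session <- function(params,
                             design = NULL,
                             participant_id = "p01",
                             device_offsets = calibration_offsets(),
                             carry_over_blocks = FALSE,
                             seed = params$seed) {
  stopifnot(inherits(params, "participant_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design)) design <- generate_session_design()
  cfg <- attr(design, "block_config")
  if (is.null(cfg)) cfg <- block_config()
  carried <- list()  # per-modality staircases when carry_over_blocks
  blocks <- vector("list", nrow(design))

  for (b in seq_len(nrow(design))) {
    mod <- design$modality[b]
    btype <- design$block_type[b]
    kinds <- generate_block_schedule(cfg)
    n <- cfg$n_trials
    asyn <- draw_go_finish(params, mod, btype, n)
    go_finish_trial <- cfg$pacing_onset_ms + asyn  # time into trial
    is_stop <- kinds == "stop"
    n_stop <- sum(is_stop)
    ssrt_draws <- pmax(1, stats::rnorm(n_stop, params$ssrt_mean_ms[[mod]],
                                       params$ssrt_sd_ms[[mod]]))
    miss <- stats::runif(n) < params$miss_prob[mod, btype]

    if (btype == "relevant") {
      st <- if (carry_over_blocks && !is.null(carried[[mod]])) {
        carried[[mod]]
      } else {
        staircase_new(cfg)
      }
    } else {
      st <- staircase_new(cfg)  # presented but never updated
    }

    ssd <- rep(NA_real_, n)
    responded <- !is_stop & !miss
    outcome <- rep(NA_character_, n)
    stop_i <- 0L
    for (i in which(is_stop)) {
      stop_i <- stop_i + 1L
      ssd[i] <- st$ssd_ms
      if (btype == "relevant") {
        race <- run_stop_trial(go_finish_trial[i], st$ssd_ms, ssrt_draws[stop_i])
        responded[i] <- race$responded
        outcome[i] <- if (race$responded) "fail" else "success"
        st <- update_ssd(st, !race$responded)
      } else {
        responded[i] <- !miss[i]
        outcome[i] <- "none"
      }
    }
    if (carry_over_blocks && btype == "relevant") carried[[mod]] <- st

    onset <- trial_onsets(cfg, n)
    offset <- if (mod == "finger") total_button_offset(device_offsets) else {
      device_offsets$audio_pipeline_ms
    }
    raw <- ifelse(responded, onset + go_finish_trial + offset, NA_real_)
    blocks[[b]] <- data.frame(
      participant_id = participant_id,
      phase = design$phase[b],
      block_index = design$block_index[b],
      block_type = btype,
      modality = mod,
      trial_index = seq_len(n),
      trial_kind = kinds,
      trial_onset_ms = onset,
      pacing_onset_ms = onset + cfg$pacing_onset_ms,
      ssd_ms = ssd,
      raw_response_ms = raw,
      stop_outcome = outcome,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Population-level cohort profile
#'
#' Means and between-participant SDs from which [generate_cohort()] draws
#' per-participant parameters. The default (`reference_profile()`) centres
#' every parameter on the condition means reported for the paradigm the
#' generator emulates (finger/vocal asynchronies -128.29 / -61.47 ms in
#' irrelevant-stop blocks, proactive shifts 58.05 / 26.10 ms, SSRTs 152.95 /
#' 187.81 ms, go-miss rates 3-9% / 0.4-1%) with between-participant SD
#' recovered from the reported standard errors as `SE * sqrt(30)`.
#'
#' @param mu_mean,mu_sd Mean and between-participant SD of the baseline
#'   (irrelevant-block) asynchrony, per modality.
#' @param shift_mean,shift_sd Mean and SD of the proactive shift, per modality.
#' @param ssrt_mean,ssrt_sd Mean and SD of the participant-level mean SSRT.
#' @param sigma_trial Within-participant trial-to-trial SD (shared by all
#'   participants).
#' @param ssrt_sd_within Within-participant SSRT SD.
#' @param miss_prob Miss-probability matrix, see [default_miss_prob()].
#' @param cross_modality_cor Correlation between a participant's finger and
#'   vocal values of each latent parameter. Timing anticipation, anticipatory
#'   slowing and stopping speed are participant traits shared across
#'   effectors; the default 0.6 matches the magnitude implied by the reported
#'   within-subject cross-modality contrasts (a paired difference of
#'   proactive shifts with mean 31.95 ms and t(29) = 4.50 implies a
#'   paired-difference SD near 39 ms, i.e. a correlation near 0.57 given the
#'   marginal SDs).
#' @return A `cohort_profile` object.
#' @export
reference_profile <- function(mu_mean = c(finger = -128.29, vocal = -61.47),
                              mu_sd = c(finger = 9.19, vocal = 5.92) * sqrt(30),
                              shift_mean = c(finger = 58.05, vocal = 26.10),
                              shift_sd = c(finger = 8.57, vocal = 5.99) * sqrt(30),
                              ssrt_mean = c(finger = 152.95, vocal = 187.81),
                              ssrt_sd = c(finger = 6.60, vocal = 9.52) * sqrt(30),
                              sigma_trial = c(finger = 30, vocal = 30),
                              ssrt_sd_within = c(finger = 10, vocal = 10),
                              miss_prob = default_miss_prob(),
                              cross_modality_cor = 0.6) {
  stopifnot(cross_modality_cor >= -1, cross_modality_cor <= 1)
  out <- list(mu_mean = mu_mean, mu_sd = mu_sd,
              shift_mean = shift_mean, shift_sd = shift_sd,
              ssrt_mean = ssrt_mean, ssrt_sd = ssrt_sd,
              sigma_trial = sigma_trial, ssrt_sd_within = ssrt_sd_within,
              miss_prob = miss_prob,
              cross_modality_cor = cross_modality_cor)
  class(out) <- "cohort_profile"
  out
}

#' Draw one participant's parameters from a cohort profile
#'
#' Gaussian draws around the population means; each latent parameter's finger
#' and vocal values are drawn from a bivariate normal with correlation
#' `cross_modality_cor`. SSRT means are truncated at 1 ms. Consumes the R
#' random stream.
#'
#' @param profile A [reference_profile()].
#' @param seed Seed stored in (and later used by) the returned params.
#' @return A [participant_params()].
#' @export
draw_participant_params <- function(profile = reference_profile(), seed = NULL) {
  stopifnot(inherits(profile, "cohort_profile"))
  rho <- profile$cross_modality_cor
  draw2 <- function(mean, sd) {
    z1 <- stats::rnorm(1)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(1)
    v <- mean[c("finger", "vocal")] + sd[c("finger", "vocal")] * c(z1, z2)
    names(v) <- c("finger", "vocal")
    v
  }
  participant_params(
    mu_asynchrony_ms = draw2(profile$mu_mean, profile$mu_sd),
    sigma_trial_ms = profile$sigma_trial,
    proactive_shift_ms = draw2(profile$shift_mean, profile$shift_sd),
    ssrt_mean_ms = pmax(draw2(profile$ssrt_mean, profile$ssrt_sd), 1),
    ssrt_sd_ms = profile$ssrt_sd_within,
    miss_prob = profile$miss_prob,
    seed = seed
  )
}

#' Simulate a cohort
#'
#' Draws `n_participants` independent parameter sets from `profile` and
#' simulates one session each (each participant gets an independently
#' pseudo-randomized block order). Reproducible: participant substream seeds
#' are derived from `seed`.
#'
#' @param n_participants Number of participants (default 30).
#' @param profile A [reference_profile()].
#' @param block_cfg A [block_config()] shared by all blocks.
#' @param device_offsets Offsets added to emitted raw responses.
#' @param seed Master seed.
#' @return Combined trial-event data frame (one session per participant),
#'   with the drawn `participant_params` attached as attribute `"params"`.
#' @export
#' @examples
#' \donttest{
#' events <- generate_cohort(n_participants = 2, seed = 1)
#' nrow(events)  # 2 * 8 * 80
#' }
generate_cohort <- function(n_participants = 30,
                            profile = reference_profile(),
                            block_cfg = block_config(),
                            device_offsets = calibration_offsets(),
                            seed = 1) {
  stopifnot(n_participants >= 1)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  ids <- sprintf("p%02d", seq_len(n_participants))
  params_list <- vector("list", n_participants)
  sessions <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(sub_seeds[i])
    params_list[[i]] <- draw_participant_params(profile, seed = sub_seeds[i])
    design <- generate_session_design(block_cfg)
    sessions[[i]] <- simulate_session(params_list[[i]], design,
                                      participant_id = ids[i],
                                      device_offsets = device_offsets,
                                      seed = NULL)
  }
  out <- do.call(rbind, sessions)
  rownames(out) <- NULL
  names(params_list) <- ids
  attr(out, "params") <- params_list
  out
}
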