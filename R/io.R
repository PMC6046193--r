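EVENT_COLUMNS <- c("participant_id", "phase", "block_index", "block_type",
                   "modality", "trial_index", "trial_kind", "trial_onset_ms",
                   "pacing_onset_ms", "ssd_ms", "raw_response_ms",
                   "stop_outcome")

#' Write a trial-event table
#'
#' Comma-delimited text with a header row; absent values (no SSD on go
#' trials, no response on misses and successful stops) are written as empty
#' strings. The write/read round trip is lossless.
#'
#' @param events Trial-event data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(all(EVENT_COLUMNS %in% names(events)))
  utils::write.csv(events[EVENT_COLUMNS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial-event table
#'
#' Parses and validates the long-format event file written by
#' [write_events()]. Schema violations are reported with the offending
#' column and (for value errors) data line numbers.
#'
#' @param path Event file path.
#' @return Validated trial-event data frame.
#' @export
read_events <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing_cols) > 0) {
    stop("read_events: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("phase", "block_index", "trial_index", "trial_onset_ms",
                "pacing_onset_ms", "ssd_ms", "raw_response_ms")
  for (cl in num_cols) {
    raw <- events[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & raw != "")
    if (length(bad) > 0) {
      stop("read_events: non-numeric '", cl, "' at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    val[raw == ""] <- NA_real_
    events[[cl]] <- val
  }
  events$stop_outcome[events$stop_outcome == ""] <- NA_character_
  for (ic in c("phase", "block_index", "trial_index")) {
    events[[ic]] <- as.integer(events[[ic]])
  }
  validate_events(events)
  events
}

#' Validate a trial-event table
#'
#' Checks enum domains and schema rules; an SSD recorded on a go trial is a
#' warning (the value is ignored downstream), unknown enum values are errors.
#'
#' @param events Trial-event data frame.
#' @return `events`, invisibly.
#' @export
validate_events <- function(events) {
  bad_kind <- which(!events$trial_kind %in% c("go", "stop"))
  if (length(bad_kind) > 0) {
    stop("validate_events: unknown trial_kind at data line(s) ",
         paste(utils::head(bad_kind, 5), collapse = ", "), call. = FALSE)
  }
  bad_mod <- which(!events$modality %in% c("finger", "vocal"))
  if (length(bad_mod) > 0) {
    stop("validate_events: unknown modality at data line(s) ",
         paste(utils::head(bad_mod, 5), collapse = ", "), call. = FALSE)
  }
  bad_bt <- which(!events$block_type %in% c("relevant", "irrelevant"))
  if (length(bad_bt) > 0) {
    stop("validate_events: unknown block_type at data line(s) ",
         paste(utils::head(bad_bt, 5), collapse = ", "), call. = FALSE)
  }
  bad_out <- which(!is.na(events$stop_outcome) &
                     !events$stop_outcome %in% c("success", "fail", "none"))
  if (length(bad_out) > 0) {
    stop("validate_events: unknown stop_outcome at data line(s) ",
         paste(utils::head(bad_out, 5), collapse = ", "), call. = FALSE)
  }
  ssd_on_go <- which(events$trial_kind == "go" & !is.na(events$ssd_ms))
  if (length(ssd_on_go) > 0) {
    warning("validate_events: ssd_ms present on go trial(s), e.g. data line ",
            ssd_on_go[1], call. = FALSE)
  }
  invisible(events)
}

#' Default run configuration
#'
#' Nested list of every tunable parameter of the pipeline: block/session
#' design, staircase, calibration offsets, generator profile and analysis
#' switches. Defaults are the paradigm's stated values.
#'
#' @return Named nested list.
#' @export
default_run_config <- function() {
  list(
    block = list(n_trials = 80, n_stop = 20, n_familiarization = 10,
                 inter_onset_interval_ms = 1250, pacing_onset_ms = 400,
                 min_go_after_stop = 1, max_go_after_stop = 10),
    staircase = list(step_ms = 30, frame_ms = 8.3, carry_over_blocks = FALSE),
    calibration = list(audio_pipeline_ms = 67.43, keypad_mechanical_ms = 8.4),
    cohort = list(n_participants = 30),
    analysis = list(ssrt_rounding = "ceiling", miss_replace = FALSE,
                    inclusion_bounds = c(40, 60), inclusion_per_modality = FALSE),
    seed = 1
  )
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take the defaults from
#' [default_run_config()].
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (section in names(user)) {
    if (!section %in% names(cfg)) {
      stop("read_run_config: unknown section '", section, "'", call. = FALSE)
    }
    if (!is.list(cfg[[section]])) {
      cfg[[section]] <- user[[section]]
      next
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]])) {
        stop("read_run_config: unknown key '", section, ".", key, "'",
             call. = FALSE)
      }
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  do.call(block_config, cfg$block)  # errors if infeasible
  stopifnot(cfg$staircase$step_ms > 0, cfg$staircase$frame_ms > 0)
  stopifnot(cfg$calibration$audio_pipeline_ms >= 0,
            cfg$calibration$keypad_mechanical_ms >= 0)
  stopifnot(cfg$cohort$n_participants >= 1)
  b <- cfg$analysis$inclusion_bounds
  stopifnot(length(b) == 2, b[1] >= 0, b[2] <= 100, b[1] <= b[2])
  stopifnot(cfg$analysis$ssrt_rounding %in% c("ceiling", "floor", "round"))
  invisible(cfg)
}

#' Run the full analysis pipeline on a trial-event table
#'
#' Calibrates and labels the events, screens participants on stop success,
#' and computes the headline outputs: condition mean asynchronies (block type
#' x modality, first-go-after-stop excluded), per-participant proactive
#' inhibition with a cross-modality paired t test, integration-method SSRT
#' summaries with a cross-modality paired t test, the race-model assumption
#' check, and the within-subject ANOVAs (go type x block type x modality x
#' phase on all go types; block type x modality x phase with the first go
#' excluded) with Bonferroni post hocs on the block-type x modality cells.
#'
#' @param events Trial-event data frame ([simulate_session()],
#'   [generate_cohort()] or [read_events()]).
#' @param offsets A [calibration_offsets()].
#' @param inclusion_bounds Stop-success screening bounds in percent.
#' @param ssrt_rounding Rank rounding rule for [ssrt_integration()].
#' @return List with components `inclusion`, `included`, `condition_summary`,
#'   `proactive`, `proactive_test`, `inhibition`, `ssrt_test`, `race`,
#'   `anova_go_type`, `anova_condition`, `posthoc_condition`, `miss_rates`.
#' @export
analyze_events <- function(events,
                           offsets = calibration_offsets(),
                           inclusion_bounds = c(40, 60),
                           ssrt_rounding = "ceiling") {
  labeled <- label_events(events, offsets)
  inclusion <- inclusion_filter(events, bounds = inclusion_bounds)
  included <- inclusion$participant_id[inclusion$included]
  lab_inc <- labeled[labeled$participant_id %in% included, ]

  condition_summary <- condition_means(
    lab_inc, by = c("block_type", "modality"),
    drop_go_types = c("familiarization", "first_go_after_stop"))

  proactive <- proactive_inhibition_by_participant(lab_inc)
  pro_wide <- stats::reshape(
    proactive[c("participant_id", "modality", "proactive_inhibition_ms")],
    idvar = "participant_id", timevar = "modality", direction = "wide")
  proactive_test <- paired_t(pro_wide$proactive_inhibition_ms.vocal,
                             pro_wide$proactive_inhibition_ms.finger)

  inhibition <- inhibition_summary(lab_inc, rounding = ssrt_rounding)
  ssrt_wide <- stats::reshape(inhibition$participants, idvar = "participant_id",
                              timevar = "modality", direction = "wide")
  ssrt_test <- paired_t(ssrt_wide$ssrt_participant_ms.vocal,
                        ssrt_wide$ssrt_participant_ms.finger)

  race <- race_check(lab_inc)

  go_cells <- lab_inc[lab_inc$go_type %in% c("first_go_after_stop",
                                             "second_go_after_stop", "other_go") &
                        !is.na(lab_inc$asynchrony_ms), ]
  anova_go_type <- rm_anova(go_cells, dv = "asynchrony_ms",
                            within = c("go_type", "block_type", "modality", "phase"))
  no_first <- go_cells[go_cells$go_type != "first_go_after_stop", ]
  anova_condition <- rm_anova(no_first, dv = "asynchrony_ms",
                              within = c("block_type", "modality", "phase"))
  posthoc_condition <- bonferroni_pairwise(no_first, dv = "asynchrony_ms",
                                           cells = c("block_type", "modality"))

  miss_rates <- expand.grid(block_type = c("relevant", "irrelevant"),
                            modality = c("finger", "vocal"),
                            stringsAsFactors = FALSE)
  miss_rates$miss_pct <- mapply(function(bt, mo) {
    miss_rate(lab_inc, block_type = bt, modality = mo)
  }, miss_rates$block_type, miss_rates$modality)

  list(inclusion = inclusion, included = included,
       condition_summary = condition_summary,
       proactive = proactive, proactive_test = proactive_test,
       inhibition = inhibition, ssrt_test = ssrt_test,
       race = race,
       anova_go_type = anova_go_type, anova_condition = anova_condition,
       posthoc_condition = posthoc_condition,
       miss_rates = miss_rates)
}
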