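test_that("asynchrony is the signed response-minus-pacing difference", {
  expect_equal(asynchrony(400, 400), 0)
  expect_equal(asynchrony(338.53, 400), -61.47)
  expect_equal(asynchrony(400, 338.53), 61.47)  # antisymmetry
})

test_that("go types are labelled relative to the preceding stop signal", {
  # post-familiarization block segment: stop, then 1st/2nd/other go
  expect_equal(label_go_types(c("stop", "go", "go", "go"), 11:14),
               c("stop", "first_go_after_stop", "second_go_after_stop",
                 "other_go"))
  # a second stop restarts the count
  expect_equal(label_go_types(c("stop", "go", "stop", "go"), 11:14),
               c("stop", "first_go_after_stop", "stop", "first_go_after_stop"))
  # go trials with no preceding stop are other_go
  expect_equal(label_go_types(c("go", "go"), 11:12),
               c("other_go", "other_go"))
  # familiarization prefix wins over everything
  expect_equal(label_go_types(c("go", "go", "stop"), c(1, 10, 11)),
               c("familiarization", "familiarization", "stop"))
  expect_error(label_go_types(c("go", "go"), c(12, 11)), "sorted")
})

test_that("labels partition every trial and reconcile with the schedule", {
  ev <- simulate_session(participant_params(seed = 13))
  lab <- label_events(ev)
  expect_false(anyNA(lab$go_type))
  expect_equal(sum(lab$go_type == "stop"), 160)
  expect_equal(sum(lab$go_type == "familiarization"), 8 * 10)
  tab <- table(lab$go_type)
  expect_equal(sum(tab), 640)
  # asynchrony present iff a response exists
  expect_equal(is.na(lab$asynchrony_ms), is.na(lab$raw_response_ms))
})

test_that("noise-free cohorts pass configured means through the pipeline", {
  prof <- reference_profile(
    mu_sd = c(finger = 0, vocal = 0), shift_sd = c(finger = 0, vocal = 0),
    ssrt_sd = c(finger = 0, vocal = 0),
    sigma_trial = c(finger = 0, vocal = 0),
    ssrt_sd_within = c(finger = 0, vocal = 0),
    miss_prob = default_miss_prob() * 0)
  coh <- generate_cohort(n_participants = 3, profile = prof, seed = 6)
  lab <- label_events(coh)
  cm <- condition_means(lab, by = c("block_type", "modality"),
                        drop_go_types = c("familiarization",
                                          "first_go_after_stop"))
  get <- function(bt, mo) cm$mean_ms[cm$block_type == bt & cm$modality == mo]
  expect_equal(get("irrelevant", "finger"), -128.29)
  expect_equal(get("irrelevant", "vocal"), -61.47)
  expect_equal(get("relevant", "finger"), -70.24)
  expect_equal(get("relevant", "vocal"), -35.37)
})

test_that("single-participant cells have undefined SE and CI", {
  coh <- tiny_cohort(n = 1, seed = 3)
  cm <- condition_means(label_events(coh), by = c("block_type", "modality"))
  expect_true(all(is.na(cm$se_ms)))
  expect_true(all(cm$n == 1))
})

test_that("CI width shrinks roughly as 1/sqrt(n) across cohort sizes", {
  width <- function(n, seed) {
    cm <- condition_means(label_events(generate_cohort(n, seed = seed)),
                          by = "modality")
    mean(cm$ci95_hi_ms - cm$ci95_lo_ms)
  }
  set.seed(1)
  w10 <- width(10, seed = 101)
  w40 <- width(40, seed = 102)
  ratio <- w10 / w40
  expect_gt(ratio, 1.2)  # noisy, but must clearly shrink
  expect_lt(ratio, 3.5)  # and not collapse faster than sampling allows
})

test_that("proactive inhibition is the relevant-minus-irrelevant difference", {
  expect_equal(proactive_inhibition(-70.24, -128.29), 58.05)
  expect_equal(proactive_inhibition(-35.37, -61.47), 26.10)
  expect_equal(proactive_inhibition(-50, -50), 0)
})

test_that("estimated proactive inhibition recovers the configured shifts", {
  coh <- generate_cohort(n_participants = 30, seed = 1)
  pro <- proactive_inhibition_by_participant(label_events(coh))
  for (mod in c("finger", "vocal")) {
    x <- pro$proactive_inhibition_ms[pro$modality == mod]
    se <- sd(x) / sqrt(length(x))
    truth <- reference_profile()$shift_mean[[mod]]
    expect_lt(abs(mean(x) - truth), 2 * se + 1e-9)
  }
})

test_that("inclusion screening applies inclusive 40-60% bounds", {
  mk <- function(n_success, n_total, id = "p1") {
    data.frame(participant_id = id, trial_kind = "stop",
               block_type = "relevant",
               modality = "finger",
               stop_outcome = rep(c("success", "fail"),
                                  c(n_success, n_total - n_success)))
  }
  expect_true(inclusion_filter(mk(80, 160))$included)
  expect_false(inclusion_filter(mk(62, 160))$included)  # 38.75%
  expect_true(inclusion_filter(mk(64, 160))$included)   # exactly 40%
  expect_true(inclusion_filter(mk(96, 160))$included)   # exactly 60%
  expect_false(inclusion_filter(mk(97, 160))$included)
  expect_error(inclusion_filter(mk(1, 2)[0, ]), "stop trials")
})

test_that("miss rates match the configured generator probabilities", {
  mp <- default_miss_prob()
  mp[, ] <- 0.09
  coh <- generate_cohort(n_participants = 8, seed = 12,
                         profile = reference_profile(miss_prob = mp))
  lab <- label_events(coh)
  observed <- miss_rate(lab)
  # 8 participants x 8 blocks x ~60 analyzable go trials: binomial SE ~ 0.46pp
  expect_equal(observed, 9, tolerance = 1.5)
  expect_equal(miss_rate(label_events(generate_cohort(
    2, profile = reference_profile(miss_prob = mp * 0), seed = 3))), 0)
})
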