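noise_free_params <- function(...) {
  participant_params(sigma_trial_ms = c(finger = 0, vocal = 0),
                     ssrt_sd_ms = c(finger = 0, vocal = 0),
                     miss_prob = default_miss_prob() * 0, ...)
}

test_that("go finishes have the configured mean structure", {
  p <- noise_free_params()
  expect_equal(draw_go_finish(p, "finger", "irrelevant"), -128.29)
  # proactive shift adds in relevant blocks: -128.29 + 58.05
  expect_equal(draw_go_finish(p, "finger", "relevant"), -70.24)
  expect_equal(draw_go_finish(p, "vocal", "relevant"), -35.37)
})

test_that("Monte-Carlo mean matches the closed form within 3 MC SEs", {
  p <- participant_params()
  for (dist in c("gaussian", "lognormal")) {
    p$go_dist <- dist
    set.seed(3)
    draws <- draw_go_finish(p, "vocal", "irrelevant", n = 10000)
    expect_equal(mean(draws), -61.47, tolerance = 1)  # sigma/sqrt(n) = 0.3
    expect_equal(sd(draws), 30, tolerance = 1.5)
  }
})

test_that("the race rule decides stop-trial outcomes", {
  expect_true(run_stop_trial(350, 200, 160)$responded)   # 350 < 360
  expect_equal(run_stop_trial(350, 200, 160)$response_ms, 350)
  expect_false(run_stop_trial(350, 150, 160)$responded)  # 350 >= 310
  expect_true(is.na(run_stop_trial(350, 150, 160)$response_ms))
  expect_false(run_stop_trial(360, 200, 160)$responded)  # exact tie stops
})

test_that("race outcome is monotone in SSD and SSRT", {
  set.seed(8)
  go <- rnorm(4000, 330, 30)
  p_fail <- function(ssd, ssrt) mean(run_stop_trial(go, ssd, ssrt)$responded)
  ssds <- seq(100, 300, by = 25)
  expect_true(all(diff(sapply(ssds, p_fail, ssrt = 150)) >= 0))
  ssrts <- seq(100, 250, by = 25)
  expect_true(all(diff(sapply(ssrts, function(s) p_fail(200, s))) >= 0))
})

test_that("a session has one event per trial with coherent stop bookkeeping", {
  p <- participant_params(seed = 21)
  ev <- simulate_session(p)
  expect_equal(nrow(ev), 640)
  expect_equal(sum(ev$trial_kind == "stop"), 160)
  # SSD only on stop trials, on the frame grid within the trial
  expect_true(all(is.na(ev$ssd_ms[ev$trial_kind == "go"])))
  stop_ssd <- ev$ssd_ms[ev$trial_kind == "stop"]
  expect_false(anyNA(stop_ssd))
  expect_equal(stop_ssd, round(stop_ssd / 8.3) * 8.3)
  expect_true(all(stop_ssd < 400))
  # successful stops have no response; failed stops do
  succ <- ev$stop_outcome == "success" & !is.na(ev$stop_outcome)
  fail <- ev$stop_outcome == "fail" & !is.na(ev$stop_outcome)
  expect_true(all(is.na(ev$raw_response_ms[succ])))
  expect_false(anyNA(ev$raw_response_ms[fail]))
  # irrelevant-block stop signals never withhold
  irr_stop <- ev$trial_kind == "stop" & ev$block_type == "irrelevant"
  expect_true(all(ev$stop_outcome[irr_stop] == "none"))
})

test_that("zero miss probability leaves no missing non-withheld responses", {
  p <- participant_params(miss_prob = default_miss_prob() * 0, seed = 4)
  ev <- simulate_session(p)
  withheld <- !is.na(ev$stop_outcome) & ev$stop_outcome == "success"
  expect_false(anyNA(ev$raw_response_ms[!withheld]))
})

test_that("sessions and cohorts are reproducible from their seeds", {
  p <- participant_params(seed = 77)
  expect_identical(simulate_session(p), simulate_session(p))
  a <- tiny_cohort(n = 2, seed = 5)
  b <- tiny_cohort(n = 2, seed = 5)
  attr(a, "params") <- NULL; attr(b, "params") <- NULL
  expect_identical(a, b)
})

test_that("cohorts have one session per participant", {
  coh <- tiny_cohort(n = 3, seed = 2)
  expect_equal(length(unique(coh$participant_id)), 3)
  expect_equal(nrow(coh), 3 * 640)
  expect_length(attr(coh, "params"), 3)
})

test_that("zero population SD returns the population means", {
  prof <- reference_profile(mu_sd = c(finger = 0, vocal = 0),
                            shift_sd = c(finger = 0, vocal = 0),
                            ssrt_sd = c(finger = 0, vocal = 0))
  set.seed(1)
  p <- draw_participant_params(prof)
  expect_equal(p$mu_asynchrony_ms, c(finger = -128.29, vocal = -61.47))
  expect_equal(p$proactive_shift_ms, c(finger = 58.05, vocal = 26.10))
  expect_equal(p$ssrt_mean_ms, c(finger = 152.95, vocal = 187.81))
})

test_that("failed-stop responses are stochastically earlier than go responses", {
  p <- participant_params(miss_prob = default_miss_prob() * 0, seed = 31)
  ev <- simulate_session(p)
  lab <- label_events(ev)
  failed <- lab$asynchrony_ms[!is.na(lab$stop_outcome) & lab$stop_outcome == "fail"]
  gos <- lab$asynchrony_ms[lab$trial_kind == "go" &
                             lab$block_type == "relevant" &
                             lab$go_type != "familiarization"]
  expect_gt(length(failed), 10)
  expect_lt(mean(failed), mean(gos))
})

test_that("pipeline recovers the configured vocal-irrelevant population mean", {
  coh <- generate_cohort(n_participants = 30, seed = 1)
  res <- analyze_events(coh)
  cell <- res$condition_summary
  cell <- cell[cell$block_type == "irrelevant" & cell$modality == "vocal", ]
  expect_lt(abs(cell$mean_ms - (-61.47)), 2 * cell$se_ms)
})
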