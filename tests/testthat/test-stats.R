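test_that("paired t matches the textbook formula and is antisymmetric", {
  res <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t_stat, 2 * sqrt(3))
  expect_equal(res$df, 2)
  swapped <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(swapped$mean_diff, -res$mean_diff)
  expect_equal(swapped$t_stat, -res$t_stat)
  expect_equal(swapped$p_value, res$p_value)
  degen <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_equal(degen$mean_diff, 0)
})

test_that("a two-level within factor reproduces the paired t (F = t^2)", {
  set.seed(4)
  d <- data.frame(participant_id = rep(sprintf("s%02d", 1:12), each = 2),
                  cond = rep(c("a", "b"), 12),
                  y = rnorm(24))
  an <- rm_anova(d, dv = "y", within = "cond")
  tt <- paired_t(d$y[d$cond == "a"], d$y[d$cond == "b"])
  expect_equal(an$F, tt$t_stat^2)
  expect_equal(an$p, tt$p_value)
  expect_equal(an$gg_epsilon, 1)
})

test_that("within-subject decomposition agrees with aov error strata", {
  set.seed(10)
  d <- expand.grid(participant_id = sprintf("s%02d", 1:10),
                   a = c("a1", "a2", "a3"), b = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), sd = 2) +
    as.numeric(factor(d$a)) + 2 * (d$b == "b2") +
    rep(rnorm(10), times = 6)  # subject effect
  mine <- rm_anova(d, dv = "y", within = c("a", "b"))
  ref <- summary(aov(y ~ a * b + Error(participant_id / (a * b)), data = d))
  ref_f <- c(
    a = ref[["Error: participant_id:a"]][[1]]["a", "F value"],
    b = ref[["Error: participant_id:b"]][[1]]["b", "F value"],
    `a:b` = ref[["Error: participant_id:a:b"]][[1]]["a:b", "F value"])
  for (eff in names(ref_f)) {
    expect_equal(mine$F[mine$effect == eff], unname(ref_f[eff]),
                 tolerance = 1e-8)
  }
  expect_equal(mine$df_num, c(2, 1, 2))
  expect_equal(mine$df_den, c(18, 9, 18))
})

test_that("constant responses yield zero F everywhere", {
  d <- expand.grid(participant_id = sprintf("s%02d", 1:6),
                   a = c("a1", "a2", "a3"), stringsAsFactors = FALSE)
  d$y <- 5
  an <- rm_anova(d, dv = "y", within = "a")
  expect_equal(an$F, 0)
  expect_equal(an$ss_effect, 0)
  expect_equal(an$partial_eta_sq, 0)
})

test_that("GG correction never lowers the p value and epsilon <= 1", {
  set.seed(11)
  d <- expand.grid(participant_id = sprintf("s%02d", 1:14),
                   a = paste0("a", 1:4), stringsAsFactors = FALSE)
  # heterogeneous variances (sphericity violation) plus a real level effect,
  # so that F > 1 and the df shrinkage must inflate the p value
  subj <- rnorm(14)
  d$y <- rnorm(nrow(d)) * rep(c(1, 1, 2, 4), each = 14) +
    rep(c(0, 1, 2, 4), each = 14) +
    subj[as.integer(factor(d$participant_id))]
  an <- rm_anova(d, dv = "y", within = "a")
  expect_lt(an$gg_epsilon, 1)
  expect_gte(an$gg_epsilon, 1 / an$df_num)
  expect_gt(an$F, 1)
  expect_gte(an$p_gg, an$p)
})

test_that("unbalanced designs are rejected with the offending cells", {
  d <- data.frame(participant_id = c("s1", "s1", "s2"),
                  a = c("a1", "a2", "a1"), y = 1:3)
  expect_error(rm_anova(d, dv = "y", within = "a"), "s2 / a2")
})

test_that("null simulations give approximately uniform uncorrected p", {
  set.seed(100)
  n_sim <- 1000
  p_vals <- replicate(n_sim, {
    d <- expand.grid(participant_id = sprintf("s%02d", 1:10),
                     a = c("a1", "a2", "a3"), stringsAsFactors = FALSE)
    d$y <- rnorm(nrow(d))
    rm_anova(d, dv = "y", within = "a")$p
  })
  rate <- mean(p_vals < 0.05)
  # binomial 95% band around 0.05 at 1000 sims: ~ [0.036, 0.064]
  expect_gt(rate, 0.036)
  expect_lt(rate, 0.064)
  expect_gt(ks.test(p_vals, "punif")$p.value, 0.01)
})

test_that("Bonferroni adjustment multiplies and clamps", {
  d <- expand.grid(participant_id = sprintf("s%02d", 1:8),
                   g = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  set.seed(6)
  d$y <- rnorm(nrow(d)) + 3 * (d$g == "g3")
  out <- bonferroni_pairwise(d, dv = "y", cells = "g")
  expect_equal(out$m, rep(3, 3))
  expect_equal(out$p_bonferroni, pmin(1, out$p * 3))
  single <- bonferroni_pairwise(d[d$g != "g3", ], dv = "y", cells = "g")
  expect_equal(single$p_bonferroni, single$p)  # m = 1 is the identity
})
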