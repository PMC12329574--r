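test_that("d-prime matches standard-normal landmarks", {
  expect_equal(dprime(50, 50, 50, 50)$dprime, 0)
  # rates at +/- 1 SD of the standard normal give d' = 2
  r <- dprime(84134, 15866, 15866, 84134)
  expect_equal(r$dprime, 2, tolerance = 1e-3)
})

test_that("extreme rates are corrected by the 1/(2N) rule", {
  r <- dprime(10, 0, 0, 10)
  expect_equal(r$hit_rate, 0.95)
  expect_equal(r$fa_rate, 0.05)
  expect_equal(round(r$dprime, 2), 3.29)
  expect_true(is.finite(r$dprime))
  expect_error(dprime(0, 0, 5, 5), "at least one")
})

test_that("d-prime is antisymmetric under hit/false-alarm exchange", {
  for (pair in list(c(18, 6), c(10, 0), c(7, 7))) {
    a <- dprime(pair[1], 24 - pair[1], pair[2], 24 - pair[2])
    b <- dprime(pair[2], 24 - pair[2], pair[1], 24 - pair[1])
    expect_equal(a$dprime, -b$dprime, tolerance = 1e-12)
  }
})

test_that("condition summaries match a brute-force group-by oracle", {
  d <- generate_design(design_spec(n_subjects = 6), seed = 71)
  tr <- generate_behavior(d, seed = 72)
  cs <- condition_summary(tr)
  for (cond in dual_task_conditions) {
    per_subj <- c()
    for (s in unique(tr$subject)) {
      rows <- tr$subject == s & tr$condition == cond
      per_subj <- c(per_subj, sum(tr$speech_correct[rows]) / sum(rows))
    }
    row <- cs[cs$condition == cond & cs$task == "speech", ]
    expect_equal(row$mean, mean(per_subj), tolerance = 1e-12)
    expect_equal(row$sd, sd(per_subj), tolerance = 1e-12)
  }
})

test_that("all-correct trials summarize to mean 1 and SD 0", {
  d <- generate_design(design_spec(n_subjects = 3), seed = 73)
  d$speech_correct <- 1L
  d$visual_correct <- 1L
  cs <- condition_summary(d)
  expect_true(all(cs$mean == 1))
  expect_true(all(cs$sd == 0))
})

test_that("TD response curves recover planted slopes", {
  d <- generate_design(design_spec(), seed = 74)
  # hard-visual TD sensitivity as observed: rejection rises with TD only
  # under the hard visual task; crossing near 11 degrees
  cf_vis <- c(intercept = 2.2, speech = 0, visual = -4.4, interaction = 0,
              td = 0, td_visual = 0.2)
  tr <- generate_behavior(d, coef_visual = cf_vis, subject_sd = 0, seed = 75)
  fit <- td_curve(tr, "visual")
  expect_false(fit$separation)
  slope_hard <- fit$coefficients["td"] + fit$coefficients["td:vh"]
  se_hard <- sqrt(sum(fit$se[c("td", "td:vh")]^2))
  expect_lt(abs(slope_hard - 0.2), 2 * se_hard)
  expect_gt(slope_hard, 0)
  # crossing point of the fitted hard-visual curve lies in the TD range
  crossing <- fit$crossing_td(sh = 0, vh = 1)
  expect_gt(crossing, 6)
  expect_lte(crossing, 18)
})

test_that("a zero TD slope is recovered as null", {
  d <- generate_design(design_spec(), seed = 76)
  tr <- generate_behavior(d, coef_visual = coef_from_means(rep(0.7, 4)),
                          subject_sd = 0, seed = 77)
  fit <- td_curve(tr, "visual")
  expect_lt(abs(fit$coefficients["td"]), 2 * fit$se["td"])
})

test_that("degenerate TD data is rejected", {
  d <- generate_design(design_spec(n_subjects = 2), seed = 78)
  d$td[d$is_target == 0] <- 12
  d$speech_correct <- 1L
  d$visual_correct <- 1L
  expect_error(td_curve(d, "visual"), "distinct TD")
})

test_that("brain-behavior correlation handles exact linear dependence", {
  x <- seq(-2, 2, length.out = 22)
  r <- brain_behavior_corr(x, 2 * x + 1)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
})

test_that("correlations match the closed-form covariance ratio oracle", {
  set.seed(79)
  x <- rnorm(22)
  y <- 0.3 * x + rnorm(22)
  r <- brain_behavior_corr(x, y)
  expect_equal(r$r, cov(x, y) / sqrt(var(x) * var(y)), tolerance = 1e-12)
  expect_equal(r$slope, cov(x, y) / var(x), tolerance = 1e-12)
  tstat <- r$r * sqrt((22 - 2) / (1 - r$r^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), 20), tolerance = 1e-12)
})

test_that("independent noise rarely produces strong correlations", {
  set.seed(80)
  strong <- 0
  for (i in 1:200) {
    r <- brain_behavior_corr(rnorm(22), rnorm(22))
    if (abs(r$r) >= 0.6) strong <- strong + 1
  }
  expect_lte(strong / 200, 0.05)
})

test_that("degenerate correlation inputs are errors", {
  expect_error(brain_behavior_corr(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(brain_behavior_corr(1:2, 1:2), "at least 3")
})
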