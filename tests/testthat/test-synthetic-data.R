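test_that("the default design has the stated trial arithmetic", {
  d <- generate_design(design_spec(), seed = 3)
  expect_equal(nrow(d), 25 * 6 * 8 * 6)
  per_subject <- table(d$subject)
  expect_true(all(per_subject == 288))
  per_cond <- table(d$condition, d$subject)
  expect_true(all(per_cond == 72))
  # 3 targets in every block of 6 trials
  tgt <- aggregate(is_target ~ subject + run + block, data = d, FUN = sum)
  expect_true(all(tgt$is_target == 3))
})

test_that("nontarget TDs lie in the stated condition intervals", {
  d <- generate_design(design_spec(n_subjects = 5), seed = 4)
  nt <- d[d$is_target == 0, ]
  hard <- nt[visual_hard(nt$condition) == 1, "td"]
  easy <- nt[visual_hard(nt$condition) == 0, "td"]
  expect_true(all(hard > 6 & hard <= 18))
  expect_true(all(easy > 48 & easy <= 60))
  expect_true(all(d$td[d$is_target == 1] == 0))
})

test_that("no condition occupies more than two consecutive blocks", {
  d <- generate_design(design_spec(n_subjects = 10), seed = 5)
  blocks <- unique(d[, c("subject", "run", "block", "condition")])
  for (s in unique(blocks$subject)) {
    for (r in unique(blocks$run)) {
      ord <- blocks$condition[blocks$subject == s & blocks$run == r]
      expect_lte(max(rle(ord)$lengths), 2)
    }
  }
})

test_that("a design with blocks not divisible by 4 is rejected", {
  expect_error(design_spec(blocks_per_run = 6), "divisible by 4")
})

test_that("generation is deterministic: identical seeds give identical TSVs", {
  f1 <- tempfile(); f2 <- tempfile()
  write_tsv(generate_design(design_spec(n_subjects = 3), seed = 9), f1)
  write_tsv(generate_design(design_spec(n_subjects = 3), seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("a null behavior generator yields chance-level responses", {
  d <- generate_design(design_spec(), seed = 6)
  zero <- setNames(rep(0, 6), names(coef_from_means(rep(0.5, 4))))
  tr <- generate_behavior(d, zero, zero, subject_sd = 0, seed = 7)
  n <- nrow(tr)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(tr$speech_correct) - 0.5), 3 * se)
  expect_lt(abs(mean(tr$visual_correct) - 0.5), 3 * se)
})

test_that("a planted TD slope is recovered with the correct sign", {
  d <- generate_design(design_spec(), seed = 8)
  cf <- coef_from_means(c(0.6, 0.6, 0.6, 0.6))
  cf["td"] <- 0.15
  tr <- generate_behavior(d, coef_speech = coef_from_means(rep(0.6, 4)),
                          coef_visual = cf, subject_sd = 0, seed = 9)
  nt <- tr[tr$is_target == 0, ]
  fit <- glm(visual_correct ~ td, data = nt, family = binomial())
  expect_gt(coef(fit)["td"], 0)
  expect_gt(coef(fit)["td"] / sqrt(diag(vcov(fit)))["td"], 2)
})

test_that("condition-mean targeting reproduces the requested accuracies", {
  d <- generate_design(design_spec(), seed = 10)
  want <- c(SpE_VisE = 0.857, SpE_VisH = 0.870, SpH_VisE = 0.533,
            SpH_VisH = 0.568)
  # exact targeting contract: fixed-effects means equal the targets
  tr0 <- generate_behavior(d, coef_speech = coef_from_means(
    c(0.857, 0.870, 0.533, 0.568)), subject_sd = 0, seed = 11)
  sp0 <- condition_summary(tr0)
  sp0 <- sp0[sp0$task == "speech", ]
  for (cond in names(want)) {
    row <- sp0[sp0$condition == cond, ]
    se <- row$sd / sqrt(row$n_subjects)
    expect_lt(abs(row$mean - want[[cond]]), 3 * se)
  }
  # with random subject intercepts the population means equal the
  # logit-normal average E[plogis(l + sigma Z)], computed here by
  # numerical integration as the oracle
  sigma <- 0.8
  tr <- generate_behavior(d, coef_speech = coef_from_means(
    c(0.857, 0.870, 0.533, 0.568)), subject_sd = sigma, seed = 11)
  sp <- condition_summary(tr)
  sp <- sp[sp$task == "speech", ]
  logit_normal_mean <- function(l, s) {
    integrate(function(z) plogis(l + s * z) * dnorm(z), -8, 8)$value
  }
  for (cond in names(want)) {
    row <- sp[sp$condition == cond, ]
    se <- row$sd / sqrt(row$n_subjects)
    expected <- logit_normal_mean(qlogis(want[[cond]]), sigma)
    expect_lt(abs(row$mean - expected), 3 * se)
  }
})

test_that("planted parcel effects are recovered by direct contrast", {
  es <- effect_spec(effect_size = 1.5, suppression = 0)
  fm <- generate_parcel_tables(es, design_spec(), seed = 12)
  sp_rows <- speech_hard(fm$condition) == 1
  for (p in es$speech_parcels) {
    diff <- mean(fm$values[sp_rows, p]) - mean(fm$values[!sp_rows, p])
    se <- sqrt(var(fm$values[sp_rows, p]) / sum(sp_rows) +
               var(fm$values[!sp_rows, p]) / sum(!sp_rows))
    expect_lt(abs(diff - 1.5), 3 * se)
  }
})

test_that("effect sizes converge to the planted profile as noise vanishes", {
  es <- effect_spec(effect_size = 2, subject_sd = 0.01, noise_sd = 0.01)
  fm <- generate_parcel_tables(es, design_spec(), seed = 13)
  planted <- planted_means(es)
  for (cond in dual_task_conditions) {
    got <- colMeans(fm$values[fm$condition == cond, , drop = FALSE])
    expect_equal(got, planted[cond, ], tolerance = 0.02,
                 ignore_attr = TRUE)
  }
})

test_that("invalid effect specifications are rejected", {
  expect_error(effect_spec(n_parcels = 10, visual_parcels = 9:12), "within")
  expect_error(effect_spec(general_parcels = 1:4, speech_parcels = 4:6),
               "disjoint")
})

test_that("the sentence pool has the two-corpus structure", {
  pool <- generate_sentence_pool()
  expect_equal(nrow(pool), 606)
  expect_equal(as.vector(table(pool$corpus)[c("BKB", "ASL")]), c(336, 270))
  expect_false(anyDuplicated(pool$sentence_id) > 0)
})

test_that("sentence draws are without replacement and exhaustible", {
  pool <- generate_sentence_pool()
  all606 <- draw_sentences(pool, 606, seed = 1)
  expect_equal(sort(all606$sentence_id), sort(pool$sentence_id))
  expect_error(draw_sentences(pool, 1, seed = 1,
                              exclude = all606$sentence_id), "exhausted")
})

test_that("the post-scan fixture splits 96 old / 32 new, balanced", {
  pool <- generate_sentence_pool()
  main <- draw_sentences(pool, 288, seed = 2)
  main$condition <- rep(dual_task_conditions, each = 72)
  ps <- postscan_split(main, pool, seed = 3)
  expect_equal(nrow(ps), 128)
  expect_equal(sum(ps$is_old), 96)
  expect_equal(sum(ps$is_old == 0), 32)
  expect_true(all(table(ps$condition[ps$is_old == 1]) == 24))
  expect_false(any(ps$sentence_id[ps$is_old == 0] %in% main$sentence_id))
})
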