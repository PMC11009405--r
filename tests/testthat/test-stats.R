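# Mixed models, correlations, effect sizes, exclusion filters.

test_that("mixed model recovers known effects", {
  # the stim coefficient under the interaction model has SE ~ 0.024 per
  # dataset; average over replicates so the check is on the estimator's
  # bias, not one draw
  set.seed(15)
  ests <- replicate(8, {
    d <- simulate_trial_table(stim_effect = 0.05, subject_sd = 0.1)
    f <- suppressMessages(
      fit_mixed_model(d, model_spec("log_velocity", c("drawing", "stim"))))
    f$coefficients[f$coefficients$term == "stimon", "estimate"]
  })
  expect_lt(abs(mean(ests) - 0.05), 0.02)
})

test_that("degenerate zero-variance subjects reduce to OLS", {
  set.seed(16)
  d <- simulate_trial_table(subject_sd = 0)
  f <- suppressMessages(
    fit_mixed_model(d, model_spec("log_velocity", c("drawing", "stim"))))
  ols <- coef(lm(log_velocity ~ drawing * stim, d))
  expect_equal(unname(f$coefficients$estimate), unname(ols),
               tolerance = 1e-6)
})

test_that("singular random slope is dropped with a flag", {
  set.seed(17)
  d <- simulate_trial_table()
  d$amp <- rnorm(nrow(d))
  f <- suppressMessages(fit_mixed_model(
    d, model_spec("log_velocity", c("stim", "amp"),
                  random_slope = "amp")))
  expect_true(f$slope_dropped || !f$singular)
})

test_that("post hoc contrasts are Bonferroni-adjusted and monotone", {
  set.seed(18)
  d <- simulate_trial_table()
  f <- fit_mixed_model(d, model_spec("log_velocity", c("drawing", "stim")),
                       posthoc = c("drawing", "stim"))
  ct <- f$contrasts
  expect_identical(nrow(ct), 6L) # 4 cells -> 6 pairs
  expect_true(all(ct$p_adj >= ct$p))
  expect_equal(ct$p_adj, pmin(1, ct$p * 6))
  expect_true(all(diff(ct$p_adj[order(ct$p)]) >= -1e-12))
})

test_that("spearman correlations: monotone, reversed, recovery", {
  pairs <- list(up = data.frame(x = 1:10, y = exp(1:10)),
                down = data.frame(x = 1:10, y = -(1:10)))
  r <- spearman_correlations(pairs)
  expect_equal(r$rho, c(1, -1))
  expect_equal(r$p_adj, pmin(1, r$p * 2))

  set.seed(19)
  rhos <- replicate(40, {
    x <- rnorm(19); y <- 0.6 * x + rnorm(19) * sqrt(1 - 0.36)
    suppressWarnings(cor(x, y, method = "spearman"))
  })
  expect_equal(mean(rhos), 0.58, tolerance = 0.1)

  ties <- list(t = data.frame(x = rep(1, 6), y = 1:6))
  expect_true(spearman_correlations(ties)$flagged)
  expect_error(spearman_correlations(list(s = data.frame(x = 1:3, y = 1:3))),
               "fewer than")
})

test_that("effect sizes: printed clinical example, identities, scaling", {
  expect_equal(round(pooled_effect_size(25.16, 8.74, 19.05, 7.43), 2), 0.75)
  expect_equal(pooled_effect_size(5, 2, 5, 3), 0)
  expect_equal(pooled_effect_size(7, 2, 4, 2), 1.5)
  d1 <- pooled_effect_size(25.16, 8.74, 19.05, 7.43)
  d2 <- pooled_effect_size(251.6, 87.4, 190.5, 74.3)
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("paired CI reproduces the printed clinical interval", {
  ci <- paired_ci(25.16 - 19.05, 6.374, 19)
  expect_equal(ci, c(4.09, 8.12), tolerance = 0.01)
  expect_error(paired_ci(1, 0, 10), "undefined")
})

test_that("exclusion filters: identity, counts, empty-cell error", {
  set.seed(20)
  tab <- expand.grid(subject = sprintf("S%02d", 1:5),
                     drawing = c("free", "template"),
                     stim = c("off", "on"), trial = 1:5,
                     stringsAsFactors = FALSE)
  tab$inaccurate <- FALSE
  tab$tremor_subject <- tab$subject %in% c("S01", "S02")
  r0 <- exclusion_filters(tab)
  expect_identical(r0$data, tab)
  tab$inaccurate[sample(nrow(tab), 10)] <- TRUE
  r1 <- exclusion_filters(tab, drop_inaccurate = TRUE)
  expect_identical(nrow(r1$data), nrow(tab) - 10L)
  expect_identical(sum(r1$report$n_removed), 10L)
  r2 <- exclusion_filters(tab, drop_tremor_subjects = TRUE)
  expect_false(any(r2$data$tremor_subject))
  tab2 <- tab[!(tab$drawing == "free" & tab$stim == "on"), ]
  tab2$inaccurate <- FALSE
  expect_error(exclusion_filters(rbind(
    tab2, transform(tab2[1, ], drawing = "free", stim = "on",
                    inaccurate = TRUE)), drop_inaccurate = TRUE),
    "design cell")
})

test_that("velocity contrast sign is robust to exclusion versions", {
  cfg <- simulation_config(n_subjects = 4, trials_per_condition = 3,
                           fs_lfp = 256, seed = 21)
  ds <- simulate_cohort(cfg)
  tab <- ds$trials
  tab$log_velocity <- sapply(tab$trial_id, function(id)
    trial_summary(tangential_velocity(preprocess_position(
      ds$kinematics[[id]])))$log_velocity)
  contrast <- function(d)
    mean(d$log_velocity[d$drawing == "free"]) -
      mean(d$log_velocity[d$drawing == "template"])
  full <- contrast(tab)
  acc <- contrast(exclusion_filters(tab, drop_inaccurate = TRUE)$data)
  notr <- contrast(exclusion_filters(tab, drop_tremor_subjects = TRUE)$data)
  expect_true(all(sign(c(full, acc, notr)) == sign(full)))
  expect_gt(full, 0)
})
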