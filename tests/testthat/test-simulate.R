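test_that("noiseless perfect simulant reports exactly at the target", {
  plan <- build_session(seed = 1)
  pars <- flat_params(p_ident = 1, p_swap = 0, sigma = 1e-9, p_guess = 0)
  resp <- simulate_responses(plan, pars, seed = 2)
  outc <- score_trials(resp, plan)
  expect_true(all(outc$identified))
  expect_lt(max(outc$gross_error_deg), 1e-6)
  expect_equal(sum(outc$is_swap, na.rm = TRUE), 0)
  expect_equal(summarize_subjects(outc)$ident_pct, 100)
})

test_that("identification follows the condition-dependent probabilities", {
  plan <- stack_plan(build_session(seed = 3), sprintf("S%02d", 1:40))
  pars <- response_model_params(
    p_ident = dplyr::bind_rows(
      expand.grid(n_items = 1, delay_s = c(1, 4), block = 1:2, p = 0.95),
      expand.grid(n_items = 3, delay_s = c(1, 4), block = 1:2, p = 0.75)
    ),
    p_swap = expand.grid(delay_s = c(1, 4), block = 1:2, p = 0),
    sigma_deg = 1, p_guess = 0
  )
  resp <- simulate_responses(plan, pars, seed = 4)
  outc <- dplyr::filter(score_trials(resp, plan), phase != "practice")
  by_load <- tapply(outc$identified, outc$n_items, mean)
  # 2 binomial SE at n = 40 subjects x 20/80 trials
  expect_lt(abs(by_load[["1"]] - 0.95), 2 * sqrt(0.95 * 0.05 / 800))
  expect_lt(abs(by_load[["3"]] - 0.75), 2 * sqrt(0.75 * 0.25 / 3200))
})

test_that("swap classification rate matches the mixture expectation (MC oracle)", {
  g <- screen_geometry()
  p_swap <- 0.5; sigma <- 0.5
  plan <- stack_plan(build_session(seed = 5), sprintf("S%02d", 1:25))
  pars <- flat_params(p_ident = 1, p_swap = p_swap, sigma = sigma, p_guess = 0)
  resp <- simulate_responses(plan, pars, seed = 6)
  outc <- dplyr::filter(score_trials(resp, plan), phase != "practice", n_items == 3)
  obs <- mean(outc$is_swap)
  expected <- withr::with_seed(7, oracle_swap_classification_prob(p_swap, 0, sigma, g, nsim = 4000))
  n <- nrow(outc)
  tol <- 2 * (sqrt(obs * (1 - obs) / n) + sqrt(expected * (1 - expected) / 4000))
  expect_lt(abs(obs - expected), tol)
})

test_that("gross localization error increases with report noise", {
  plan <- stack_plan(build_session(seed = 8), sprintf("S%02d", 1:10))
  means <- vapply(c(0.5, 1.5, 3, 5), function(s) {
    pars <- flat_params(p_ident = 1, p_swap = 0, sigma = s, p_guess = 0)
    resp <- simulate_responses(plan, pars, seed = 9)
    mean(score_trials(resp, plan)$gross_error_deg)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohort simulation is deterministic and orders identification by group", {
  small <- c(control = 5, asymptomatic = 5, symptomatic = 5)
  a <- simulate_cohort(n_per_group = small, seed = 10)
  b <- simulate_cohort(n_per_group = small, seed = 10)
  expect_identical(a$subjects[setdiff(names(a$subjects), "params")],
                   b$subjects[setdiff(names(b$subjects), "params")])
  expect_identical(a$responses, b$responses)
  expect_identical(a$sessions, b$sessions)

  # ordering needs enough subjects: the preset gaps are a few points
  a <- simulate_cohort(n_per_group = c(control = 60, asymptomatic = 60, symptomatic = 60),
                       seed = 10)
  outc <- score_trials(a$responses, a$sessions)
  summ <- dplyr::left_join(summarize_subjects(outc),
                           a$subjects[c("participant_id", "group")],
                           by = "participant_id")
  ident <- tapply(summ$ident_pct, summ$group, mean)
  expect_gt(ident[["control"]], ident[["asymptomatic"]])
  expect_gt(ident[["asymptomatic"]], ident[["symptomatic"]])
})

test_that("preset covariates match their generating distributions", {
  presets <- default_group_presets()
  co <- simulate_cohort(presets, n_per_group = c(symptomatic = 200), seed = 11)
  vol <- co$subjects$hippo_volume_cm3
  se <- presets$symptomatic$hippo_volume_sd / sqrt(200)
  expect_lt(abs(mean(vol) - presets$symptomatic$hippo_volume_mean), 3 * se)
})

test_that("smaller hippocampal volumes mean more swap errors within carriers", {
  co <- simulate_cohort(n_per_group = c(asymptomatic = 100, symptomatic = 100), seed = 12)
  outc <- score_trials(co$responses, co$sessions)
  summ <- dplyr::left_join(summarize_subjects(outc),
                           co$subjects[c("participant_id", "hippo_volume_cm3")],
                           by = "participant_id")
  expect_lt(cor(summ$hippo_volume_cm3, summ$swap_pct), 0)
})

test_that("invalid generative parameters are rejected up front", {
  expect_error(flat_params(p_ident = 1.2), "\\[0, 1\\]")
  expect_error(flat_params(p_swap = 0.8, p_guess = 0.4), "exceed 1")
  expect_error(flat_params(sigma = -1), "positive")
  expect_error(
    simulate_cohort(n_per_group = c(bogus = 5), seed = 1),
    "named with preset labels"
  )
  p <- default_group_presets()$control
  expect_error(
    group_preset("asymptomatic", p$params, 6, 0.7, 1450, 140, 37, 4, 0.5, 30, 9,
                 volume_swap_slope = 0.5),
    "<= 0"
  )
})

test_that("reports always land on screen", {
  plan <- build_session(seed = 13)
  pars <- flat_params(p_ident = 0.8, p_swap = 0.3, sigma = 6, p_guess = 0.2)
  resp <- simulate_responses(plan, pars, seed = 14)
  expect_true(all(abs(resp$x_deg) <= 31 & abs(resp$y_deg) <= 17.5))
})
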