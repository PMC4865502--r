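# geometry: two items 12 deg apart on the x axis, well clear of constraints
two_item_plan <- function() {
  make_manual_plan(list(
    list(n_items = 3, items = c("F01", "F02", "F03"),
         xs = c(0, 12, -12), ys = c(10, 10, 10),
         target_slot = 1, foil_id = "F10")
  ))
}

test_that("identification is scored against the target identity", {
  plan <- two_item_plan()
  ok <- score_trials(make_response(plan, 1, "F01", 0, 10), plan)
  expect_true(ok$identified)
  wrong <- score_trials(make_response(plan, 1, "F10", 0, 10), plan)
  expect_false(wrong$identified)
  expect_true(is.na(wrong$gross_error_deg) && is.na(wrong$nn_error_deg) && is.na(wrong$is_swap))
  expect_error(
    score_trials(make_response(plan, 1, "F99", 0, 10), plan),
    "outside the \\{target, foil\\} pair"
  )
})

test_that("gross error is the Euclidean distance to the true target location", {
  plan <- make_manual_plan(list(
    list(n_items = 1, items = "F01", xs = 0, ys = 10, target_slot = 1, foil_id = "F02")
  ))
  out <- score_trials(make_response(plan, 1, "F01", 3, 14), plan)
  expect_equal(out$gross_error_deg, 5) # 3-4-5 triangle
  expect_equal(out$nn_error_deg, 5)    # single candidate: nn equals gross
  zero <- score_trials(make_response(plan, 1, "F01", 0, 10), plan)
  expect_equal(zero$gross_error_deg, 0)
})

test_that("nearest-neighbour error ignores identity and never exceeds gross error", {
  plan <- two_item_plan()
  # report exactly at a non-target: nn 0, gross = separation, swap flagged
  out <- score_trials(make_response(plan, 1, "F01", 12, 10), plan)
  expect_equal(out$nn_error_deg, 0)
  expect_equal(out$gross_error_deg, 12)
  expect_true(out$is_swap)
  expect_equal(out$swap_partner, 2L)

  # property: nn <= gross for arbitrary reports
  set.seed(20)
  xs <- runif(500, -31, 31); ys <- runif(500, -17.5, 17.5)
  for (i in c(1, 250, 500)) {
    o <- score_trials(make_response(plan, 1, "F01", xs[i], ys[i]), plan)
    expect_lte(o$nn_error_deg, o$gross_error_deg)
  }
  plan40 <- stack_plan(build_session(seed = 21), "Q01")
  pars <- flat_params(p_ident = 1, p_swap = 0.3, sigma = 4, p_guess = 0.2)
  r <- simulate_responses(plan40, pars, seed = 22)
  o <- score_trials(r, plan40)
  expect_true(all(o$nn_error_deg <= o$gross_error_deg + 1e-12, na.rm = TRUE))
})

test_that("swap boundary is inclusive at exactly 4.5 degrees", {
  plan <- two_item_plan()
  at_boundary <- score_trials(make_response(plan, 1, "F01", 12, 10 + 4.5), plan)
  expect_true(at_boundary$is_swap)
  outside <- score_trials(make_response(plan, 1, "F01", 12, 10 + 4.51), plan)
  expect_false(outside$is_swap)
  at_target <- score_trials(make_response(plan, 1, "F01", 0, 10), plan)
  expect_false(at_target$is_swap)
})

test_that("swap rate is percentage of eligible trials and flags empty denominators", {
  outc <- tibble::tibble(
    participant_id = "A", trial_id = 1:40, phase = "block1", block = 1L,
    n_items = 3L, delay_s = 1L, identified = TRUE,
    gross_error_deg = 1, nn_error_deg = 1,
    is_swap = c(rep(TRUE, 8), rep(FALSE, 32)), swap_partner = NA_integer_
  )
  expect_equal(swap_rate(outc)$swap_pct, 20)
  one_item <- dplyr::mutate(outc, n_items = 1L, is_swap = NA)
  expect_warning(res <- swap_rate(one_item), "no eligible trials")
  expect_true(is.na(res$swap_pct))
})

test_that("subject summaries apply the 70% inclusion boundary inclusively", {
  base <- tibble::tibble(
    participant_id = "A", trial_id = 1:100, phase = "block1", block = 1L,
    n_items = 3L, delay_s = 1L,
    gross_error_deg = NA_real_, nn_error_deg = NA_real_,
    is_swap = NA, swap_partner = NA_integer_
  )
  at70 <- dplyr::mutate(base, identified = trial_id <= 70)
  expect_true(summarize_subjects(at70)$included)
  at69 <- dplyr::mutate(base, identified = trial_id <= 69)
  expect_false(summarize_subjects(at69)$included)
})

test_that("summaries keep empty cells as NA and report per-cell denominators", {
  plan <- build_session(seed = 23)
  pars <- flat_params(p_ident = 1, p_swap = 0.2, sigma = 2, p_guess = 0.05)
  resp <- simulate_responses(plan, pars, seed = 24)
  outc <- score_trials(resp, plan)
  # drop every 4-second three-item trial in block 1: that cell must go NA
  drop <- outc$phase != "practice" & outc$block %in% 1 & outc$delay_s == 4 & outc$n_items == 3
  cells <- summarize_subjects(outc[!drop, ], by = c("block", "n_items", "delay_s"))
  gone <- cells[cells$block == 1 & cells$delay_s == 4 & cells$n_items == 3, ]
  expect_equal(nrow(gone), 0) # cell absent entirely rather than silently zero
  present <- cells[cells$block == 2 & cells$delay_s == 4 & cells$n_items == 3, ]
  expect_equal(present$n_trials, 20)
  # a cell with trials but no eligible ones reports NA swap rate
  one <- cells[cells$n_items == 1 & cells$block == 1 & cells$delay_s == 1, ]
  expect_true(is.na(one$swap_pct))
  expect_equal(one$n_eligible, 0)
})

test_that("practice trials are excluded from summaries by default", {
  plan <- build_session(seed = 25)
  pars <- flat_params(p_ident = 1, p_swap = 0, sigma = 1, p_guess = 0)
  resp <- simulate_responses(plan, pars, seed = 26)
  outc <- score_trials(resp, plan)
  expect_equal(summarize_subjects(outc)$n_trials, 100)
  expect_equal(summarize_subjects(outc, include_practice = TRUE)$n_trials, 110)
})

test_that("chance correction subtracts the geometric null and never exceeds the raw rate", {
  plan <- stack_plan(build_session(seed = 27), "C01")
  pars <- flat_params(p_ident = 1, p_swap = 0.3, sigma = 0.5, p_guess = 0)
  resp <- simulate_responses(plan, pars, seed = 28)
  outc <- score_trials(resp, plan)
  cc <- chance_corrected_swap_rate(outc, resp, plan, n_null = 150, seed = 29)
  expect_lte(cc$corrected_pct, cc$swap_pct)
  expect_gt(cc$null_mean_pct, 0)
  expect_gt(cc$mc_se_pct, 0)

  # noiseless perfect reports: observed 0, corrected reported (possibly) negative,
  # clamped version at 0
  perfect <- simulate_responses(plan, flat_params(), seed = 30)
  po <- score_trials(perfect, plan)
  ccp <- chance_corrected_swap_rate(po, perfect, plan, n_null = 150, seed = 31)
  expect_equal(ccp$swap_pct, 0)
  expect_lte(ccp$corrected_pct, 0)
  ccl <- chance_corrected_swap_rate(po, perfect, plan, n_null = 150, seed = 31, clamp_zero = TRUE)
  expect_equal(ccl$corrected_pct, 0)
})

test_that("chance-corrected rate matches a brute-force mixture oracle", {
  g <- screen_geometry()
  p_swap <- 0.3; sigma <- 0.5
  plan <- stack_plan(build_session(seed = 32), sprintf("D%02d", 1:10))
  pars <- flat_params(p_ident = 1, p_swap = p_swap, sigma = sigma, p_guess = 0)
  resp <- simulate_responses(plan, pars, seed = 33)
  outc <- score_trials(resp, plan)
  cc <- chance_corrected_swap_rate(outc, resp, plan, n_null = 200, seed = 34)
  pooled <- sum(cc$corrected_pct * cc$n_eligible) / sum(cc$n_eligible)

  # oracle: expected observed rate from the mixture minus the null rate for
  # reports drawn from the same mixture against re-sampled non-targets
  exp_obs <- withr::with_seed(35, oracle_swap_classification_prob(p_swap, 0, sigma, g, nsim = 3000))
  # null expectation: reports around the target (prob .7) almost never hit a
  # resampled non-target (>= 9 deg away); swap-anchored reports sit at a
  # point >= 9 deg from the target, so the null hit rate is the chance a
  # fresh constrained non-target pair covers that point
  null_hit <- withr::with_seed(36, {
    hits <- vapply(seq_len(2000), function(i) {
      arr <- oracle_array(3, g)
      anchor <- if (runif(1) < p_swap) arr[2, ] else arr[1, ]
      rep_xy <- anchor + rnorm(2, 0, sigma)
      nts <- rbind(oracle_point(g, arr[1, , drop = FALSE]))
      nts <- rbind(nts, oracle_point(g, rbind(arr[1, ], nts)))
      any(sqrt(rowSums((nts - rep(rep_xy, each = 2))^2)) <= g$swap_radius_deg)
    }, logical(1))
    mean(hits)
  })
  expected <- 100 * (exp_obs - null_hit)
  n_elig <- sum(cc$n_eligible)
  tol <- 2 * 100 * (sqrt(exp_obs * (1 - exp_obs)) * (1 / sqrt(n_elig) + 1 / sqrt(3000)) +
                      sqrt(null_hit * (1 - null_hit) / 2000))
  expect_lt(abs(pooled - expected), tol)
})
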