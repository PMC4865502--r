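test_that("BCa interval collapses for degenerate data and brackets the estimate", {
  ci <- bca_bootstrap_ci(rep(3.5, 10), mean, n_boot = 200, seed = 1)
  expect_equal(c(ci$lower, ci$upper), c(3.5, 3.5))

  set.seed(2)
  for (i in 1:25) {
    x <- rnorm(8 + i, sd = runif(1, 0.5, 3))
    ci <- bca_bootstrap_ci(x, mean, n_boot = 300)
    expect_lte(ci$lower, ci$estimate)
    expect_gte(ci$upper, ci$estimate)
  }
})

test_that("with z0 = a = 0 the BCa interval is the percentile interval", {
  set.seed(3)
  t_boot <- rnorm(2000)
  got <- vstmbind:::.bca_interval(0, t_boot, jack = NULL, alpha = 0.05, z0 = 0, a = 0)
  want <- quantile(t_boot, c(0.025, 0.975), names = FALSE, type = 6)
  expect_equal(c(got$lower, got$upper), want)
})

test_that("BCa agrees with the reference implementation on a fixed sample", {
  set.seed(4)
  x <- rexp(40)
  ours <- bca_bootstrap_ci(x, mean, n_boot = 4000, seed = 5)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  # two independent 4000-replicate runs of the same estimator
  expect_lt(abs(ours$lower - ref[1]), 0.05)
  expect_lt(abs(ours$upper - ref[2]), 0.05)
})

test_that("adjusted comparison recovers a known group difference with covariates", {
  set.seed(6)
  n <- 60
  df <- tibble::tibble(
    group = rep(c("control", "fad"), each = n),
    nart = rnorm(2 * n, 30, 8),
    sex = sample(c("M", "F"), 2 * n, TRUE),
    y = 5 + 0.1 * nart + 2 * (group == "fad") + rnorm(2 * n)
  )
  cmp <- adjusted_group_comparison(df, "y", c("control", "fad"))
  expect_equal(cmp$estimate, 2, tolerance = 0.15)
  expect_equal(cmp$stat_type, "t")
  expect_lt(cmp$p_value, 1e-6)
  td <- tidy(cmp)
  expect_equal(td$estimate, cmp$estimate)
  expect_equal(glance(cmp)$n_reference, n)
})

test_that("constant outcomes give a zero difference and a degenerate interval", {
  df <- tibble::tibble(
    group = rep(c("a", "b"), each = 10),
    nart = rnorm(20), sex = rep(c("M", "F"), 10),
    y = 7
  )
  # lm warns about the perfect fit on purpose-built constant data
  cmp <- suppressWarnings(
    adjusted_group_comparison(df, "y", c("a", "b"), n_boot = 200, seed = 7)
  )
  expect_equal(cmp$estimate, 0, tolerance = 1e-10)
  expect_equal(c(cmp$ci$lower, cmp$ci$upper), c(0, 0), tolerance = 1e-10)
})

test_that("binomial family reports z statistics and odds ratios for identification", {
  set.seed(8)
  df <- tibble::tibble(
    group = rep(c("control", "fad"), each = 30),
    nart = rnorm(60, 30, 8),
    sex = sample(c("M", "F"), 60, TRUE),
    total = 100L,
    correct = stats::rbinom(60, 100, ifelse(group == "fad", 0.85, 0.92))
  )
  cmp <- adjusted_group_comparison(df, "correct", c("control", "fad"),
                                   family = "binomial", trials_col = "total")
  expect_equal(cmp$stat_type, "z")
  expect_lt(cmp$odds_ratio, 1)
  expect_lt(cmp$p_value, 0.05)
})

test_that("comparison error paths name the problem", {
  df <- tibble::tibble(group = c("a", "a", "b"), nart = 1:3, sex = "M", y = 1:3)
  expect_error(adjusted_group_comparison(df, "y", c("a", "b")), "at least 3 subjects")
  set.seed(9)
  df2 <- tibble::tibble(
    group = rep(c("a", "b"), each = 5), nart = rnorm(10),
    dup = nart, sex = "M", y = rnorm(10)
  )
  expect_error(
    adjusted_group_comparison(df2, "y", c("a", "b"), covariates = c("nart", "dup")),
    "collinear"
  )
  expect_error(adjusted_group_comparison(df2, "nope", c("a", "b")), "not found")
})

test_that("single-factor interaction test reduces to the squared two-sample t", {
  set.seed(10)
  df <- tibble::tibble(
    participant_id = sprintf("S%02d", 1:30),
    group = rep(c("a", "b"), each = 15),
    y = rnorm(30) + rep(c(0, 1), each = 15)
  )
  ft <- factorial_interaction_test(df, "y", between = "group", within = character(0),
                                   term = "group")
  tt <- stats::t.test(y ~ group, data = df, var.equal = TRUE)
  expect_equal(ft$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("the group x block x load interaction is detected when simulated", {
  co <- simulate_cohort(n_per_group = c(control = 15, symptomatic = 15), seed = 11)
  outc <- score_trials(co$responses, co$sessions)
  cells <- summarize_subjects(outc, by = c("block", "n_items")) |>
    dplyr::left_join(co$subjects[c("participant_id", "group")], by = "participant_id")
  ft <- factorial_interaction_test(cells, "gross_err_deg",
                                   between = "group", within = c("block", "n_items"))
  expect_equal(ft$term, "group:block:n_items")
  expect_true(is.finite(ft$statistic) && ft$statistic >= 0)
  expect_true(ft$p_value > 0 && ft$p_value <= 1)
  td <- tidy(ft)
  expect_equal(td$statistic, ft$statistic)
})

test_that("interaction test refuses incomplete within-subject cells", {
  set.seed(12)
  df <- tidyr::expand_grid(
    participant_id = sprintf("S%02d", 1:10),
    block = 1:2, load = c(1, 3)
  )
  df$group <- rep(c("a", "b"), each = 20)
  df$y <- rnorm(40)
  df <- df[-1, ] # knock out one subject's cell
  expect_error(
    factorial_interaction_test(df, "y", within = c("block", "load")),
    "empty within-subject cell"
  )
})

test_that("volume association recovers slope signs and the log-scale percentage", {
  set.seed(13)
  n <- 80
  df <- tibble::tibble(
    group = rep(c("control", "fad"), each = n),
    age = rnorm(2 * n, 40, 5), sex = sample(c("M", "F"), 2 * n, TRUE),
    tiv_cm3 = rnorm(2 * n, 1450, 120),
    hippo_volume_cm3 = rnorm(2 * n, 5.7, 0.6),
    # FAD outcome falls 20% per cm3; controls flat
    y = exp(log(8) + ifelse(group == "fad", log(0.8), 0) * (hippo_volume_cm3 - 5.7) +
              rnorm(2 * n, 0, 0.15))
  )
  assoc <- volume_outcome_association(df, "y", transform = "log")
  td <- tidy(assoc)
  fad <- td[td$group == "fad", ]
  ctl <- td[td$group == "control", ]
  expect_equal(fad$pct_change_per_cm3, -20, tolerance = 0.25)
  expect_gt(ctl$p.value, 0.01)
  expect_lt(fad$p.value, 1e-4)
  expect_equal(assoc$interactions$contrast, "fad - control")
})

test_that("volume association drops incomplete subjects and rejects collinearity", {
  set.seed(14)
  df <- tibble::tibble(
    group = rep(c("a", "b"), each = 10),
    age = rnorm(20, 40, 5), sex = sample(c("M", "F"), 20, TRUE),
    tiv_cm3 = rnorm(20, 1450, 120),
    hippo_volume_cm3 = c(NA, rnorm(19, 5.7, 0.6)),
    y = rexp(20) + 1
  )
  assoc <- volume_outcome_association(df, "y", transform = "sqrt")
  expect_equal(assoc$n_dropped, 1)
  expect_equal(assoc$n, 19)
  df$tiv_cm3 <- df$hippo_volume_cm3 * 250
  expect_error(volume_outcome_association(df, "y"), "collinear")
})

test_that("sqrt transform refuses negative outcomes and log refuses zeros", {
  df <- tibble::tibble(
    group = rep(c("a", "b"), each = 5),
    age = rnorm(10), sex = "M", tiv_cm3 = rnorm(10, 1450, 50),
    hippo_volume_cm3 = rnorm(10, 5.7, 0.5), y = c(-1, rexp(9))
  )
  expect_error(volume_outcome_association(df, "y", transform = "sqrt"), "non-negative")
  df$y <- c(0, rexp(9))
  expect_error(volume_outcome_association(df, "y", transform = "log"), "positive")
})
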