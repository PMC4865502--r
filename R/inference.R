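.check_columns <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(paste0(what, " column(s) not found: ", paste(missing, collapse = ", ")))
  }
}

.check_rank <- function(mm) {
  qrd <- qr(mm)
  if (qrd$rank < ncol(mm)) {
    dropped <- colnames(mm)[qrd$pivot[(qrd$rank + 1):ncol(mm)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
}

#' Covariate-adjusted comparison of two groups
#'
#' Compares one subject-level outcome between two diagnostic groups with a
#' (generalized) linear model adjusted for covariates, the approach used for
#' all behavioural contrasts in this package: a Gaussian linear model on
#' continuous outcomes (localization errors, swap rates) reporting a
#' t statistic, or a binomial logistic model on per-subject correct/total
#' counts (identification) reporting a z statistic and odds ratio. A
#' stratified BCa bootstrap interval for the adjusted difference (subjects
#' resampled within group, model refitted per resample) is attached when
#' `n_boot > 0`.
#'
#' @param data Subject-level data frame (one row per subject).
#' @param outcome Name of the outcome column; for `family = "binomial"` the
#'   column of success counts.
#' @param groups Length-2 character vector: reference group first, compared
#'   group second.
#' @param group_col Name of the group column.
#' @param covariates Character vector of adjustment columns (default NART
#'   and sex, as used for the behavioural contrasts).
#' @param family `"gaussian"` or `"binomial"`.
#' @param trials_col For the binomial family, the column of per-subject
#'   trial totals.
#' @param n_boot BCa bootstrap replications for the group-difference CI
#'   (0 = none; 2000 when reported).
#' @param alpha CI miss probability.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `vstm_comparison` with the adjusted estimate
#'   (difference, or log odds ratio with `odds_ratio`), its SE, test
#'   statistic, df, p-value, optional `ci`, and the fitted model. Methods:
#'   [generics::tidy()], [generics::glance()], `print`, `autoplot`.
#' @examples
#' co <- simulate_cohort(n_per_group = c(control = 8, symptomatic = 8), seed = 1)
#' outc <- score_trials(co$responses, co$sessions)
#' summ <- summarize_subjects(outc) |>
#'   dplyr::left_join(co$subjects, by = "participant_id")
#' adjusted_group_comparison(summ, "gross_err_deg", c("control", "symptomatic"))
#' @export
adjusted_group_comparison <- function(data, outcome,
                                      groups, group_col = "group",
                                      covariates = c("nart", "sex"),
                                      family = c("gaussian", "binomial"),
                                      trials_col = NULL,
                                      n_boot = 0, alpha = 0.05, seed = NULL) {
  family <- match.arg(family)
  if (length(groups) != 2) abort("`groups` must name exactly two groups")
  .check_columns(data, c(outcome, group_col, covariates), "model")
  if (family == "binomial" && is.null(trials_col)) {
    abort("binomial family needs `trials_col` (per-subject trial totals)")
  }

  df <- data[data[[group_col]] %in% groups, , drop = FALSE]
  counts <- table(df[[group_col]])
  if (any(!groups %in% names(counts)) || any(counts[groups] < 3)) {
    abort("each compared group needs at least 3 subjects")
  }
  df$.group <- factor(df[[group_col]], levels = groups)

  rhs <- paste(c(".group", covariates), collapse = " + ")
  fit_fun <- function(d) {
    if (family == "gaussian") {
      fml <- as.formula(paste(outcome, "~", rhs))
      lm(fml, data = d)
    } else {
      fml <- as.formula(paste0("cbind(", outcome, ", ", trials_col, " - ", outcome, ") ~ ", rhs))
      glm(fml, family = binomial(), data = d)
    }
  }
  fit <- fit_fun(df)
  .check_rank(model.matrix(fit))

  co <- summary(fit)$coefficients
  term <- paste0(".group", groups[2])
  est <- co[term, 1]
  se <- co[term, 2]
  stat <- co[term, 3]
  p <- co[term, 4]
  dfree <- if (family == "gaussian") fit$df.residual else NA_real_

  ci <- NULL
  if (n_boot > 0) {
    stat_fun <- function(d) {
      d$.group <- factor(d$.group, levels = groups)
      if (any(table(d$.group) < 2)) return(NA_real_)
      f <- tryCatch(fit_fun(d), error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      unname(coef(f)[term])
    }
    ci <- bca_bootstrap_ci(df, stat_fun, n_boot = n_boot, alpha = alpha,
                           strata = df$.group, seed = seed)
  }

  structure(
    list(
      outcome = outcome, groups = groups, covariates = covariates,
      family = family, estimate = est, se = se,
      statistic = stat, stat_type = if (family == "gaussian") "t" else "z",
      df = dfree, p_value = p,
      odds_ratio = if (family == "binomial") exp(est) else NULL,
      ci = ci, n = unname(counts[groups]), model = fit
    ),
    class = "vstm_comparison"
  )
}

#' @export
print.vstm_comparison <- function(x, ...) {
  cat(sprintf("Adjusted comparison of %s: %s vs %s (n = %d/%d)\n",
              x$outcome, x$groups[2], x$groups[1], x$n[2], x$n[1]))
  cat(sprintf("  estimate %.4g (SE %.3g), %s = %.3f%s, p = %.4g\n",
              x$estimate, x$se, x$stat_type, x$statistic,
              if (is.finite(x$df)) sprintf(" (df = %.0f)", x$df) else "", x$p_value))
  if (!is.null(x$odds_ratio)) cat(sprintf("  odds ratio %.3f\n", x$odds_ratio))
  if (!is.null(x$ci)) {
    cat(sprintf("  BCa %.0f%% CI [%.4g, %.4g] (B = %d)\n",
                100 * (1 - x$ci$alpha), x$ci$lower, x$ci$upper, x$ci$n_boot))
  }
  cat("  adjusted for:", paste(x$covariates, collapse = ", "),
      "; p-values are raw (no multiplicity correction)\n")
  invisible(x)
}

#' Factorial interaction test on subject-by-cell means
#'
#' Repeated-measures analysis of variance on per-subject condition-cell
#' means: between-subject factor `group`, within-subject factors such as
#' block and memory load, with an `Error(subject/within)` stratum structure.
#' Returns the F test for a requested term (by default the highest-order
#' group-by-within interaction, e.g. group x block x load). Covariates, if
#' given, enter the between-subject stratum.
#'
#' @param data Subject-by-cell data (e.g. [summarize_subjects()] with
#'   `by = c("block", "n_items")` joined to group labels). All factor cells
#'   must be populated for every subject.
#' @param outcome Name of the outcome column.
#' @param between Name of the group column.
#' @param within Character vector of within-subject factor columns.
#' @param subject Name of the subject-identifier column.
#' @param covariates Optional between-subject adjustment columns.
#' @param term The model term to report, in `aov` notation
#'   (default `between:within1:...:withink`).
#' @return An object of class `vstm_interaction` with `statistic` (F),
#'   `df1`, `df2`, `p_value`, the requested `term`, and the full `aov`
#'   table. Methods: [generics::tidy()], `print`.
#' @export
factorial_interaction_test <- function(data, outcome, between = "group",
                                       within = c("block", "n_items"),
                                       subject = "participant_id",
                                       covariates = NULL, term = NULL) {
  .check_columns(data, c(outcome, between, within, subject, covariates), "model")
  df <- as.data.frame(data)
  df[[between]] <- factor(df[[between]])
  for (w in within) df[[w]] <- factor(df[[w]])
  df[[subject]] <- factor(df[[subject]])

  if (length(within)) {
    cells <- interaction(df[within], drop = FALSE)
    tab <- table(df[[subject]], cells)
    if (any(tab == 0)) {
      missing_cells <- unique(colnames(tab)[colSums(tab == 0) > 0])
      abort(paste0("empty within-subject cell(s): ", paste(missing_cells, collapse = ", ")))
    }
  }

  fx <- paste(c(between, within), collapse = " * ")
  if (!is.null(covariates)) fx <- paste(c(covariates, fx), collapse = " + ")
  if (length(within)) {
    err <- paste0("Error(", subject, "/(", paste(within, collapse = " * "), "))")
    fml <- as.formula(paste(outcome, "~", fx, "+", err))
  } else {
    fml <- as.formula(paste(outcome, "~", fx))
  }
  fit <- aov(fml, data = df)

  if (is.null(term)) term <- paste(c(between, within), collapse = ":")
  strata <- if (inherits(fit, "aovlist")) summary(fit) else list(summary(fit))
  found <- NULL
  for (s in strata) {
    st <- as.data.frame(s[[1]])
    rn <- trimws(rownames(st))
    hit <- match(term, rn)
    if (!is.na(hit)) {
      resid_row <- match("Residuals", rn)
      found <- list(
        F = st[hit, "F value"], df1 = st[hit, "Df"],
        df2 = if (!is.na(resid_row)) st[resid_row, "Df"] else NA_real_,
        p = st[hit, "Pr(>F)"]
      )
      break
    }
  }
  if (is.null(found)) abort(paste0("term '", term, "' not found in the aov table"))

  structure(
    list(term = term, statistic = found$F, df1 = found$df1, df2 = found$df2,
         p_value = found$p, outcome = outcome, between = between,
         within = within, model = fit),
    class = "vstm_interaction"
  )
}

#' @export
print.vstm_interaction <- function(x, ...) {
  cat(sprintf("Interaction test for %s on %s: F(%g, %g) = %.3f, p = %.4g\n",
              x$term, x$outcome, x$df1, x$df2, x$statistic, x$p_value))
  invisible(x)
}

#' Hippocampal-volume association with a task outcome
#'
#' Regresses a per-subject outcome on total hippocampal volume with
#' group-specific slopes, adjusted for age, sex and TIV. The outcome scale
#' follows the reporting convention for each measure: localization errors
#' are modelled on the log scale so slopes translate to percent change per
#' cm^3 (`transform = "log"`); swap rates are square-root transformed before
#' regression (`transform = "sqrt"`). Subjects with missing volumes or
#' covariates are dropped and counted.
#'
#' @param data Subject-level data with outcome, volume, group and
#'   covariates.
#' @param outcome Name of the outcome column.
#' @param transform `"identity"`, `"sqrt"` or `"log"`.
#' @param volume Name of the hippocampal-volume column (cm^3).
#' @param group_col Name of the group column.
#' @param covariates Adjustment columns (default age, sex, TIV).
#' @return An object of class `vstm_association`: per-group slope estimates
#'   with SEs and p-values (`slopes`), pairwise slope-difference contrasts
#'   (`interactions`), for the log scale additionally percent change per
#'   cm^3, the transform, the dropped-subject count, and the fitted model.
#'   Methods: [generics::tidy()], `print`.
#' @export
volume_outcome_association <- function(data, outcome,
                                       transform = c("identity", "sqrt", "log"),
                                       volume = "hippo_volume_cm3",
                                       group_col = "group",
                                       covariates = c("age", "sex", "tiv_cm3")) {
  transform <- match.arg(transform)
  .check_columns(data, c(outcome, volume, group_col, covariates), "model")
  df <- as.data.frame(data)
  keep <- complete.cases(df[, c(outcome, volume, group_col, covariates)])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 5) abort("too few subjects with complete volume and covariate data")

  y <- df[[outcome]]
  df$.y <- switch(transform,
    identity = y,
    sqrt = { if (any(y < 0)) abort("sqrt transform needs non-negative outcomes"); sqrt(y) },
    log = { if (any(y <= 0)) abort("log transform needs positive outcomes"); log(y) }
  )
  df$.group <- factor(df[[group_col]])
  df$.vol <- df[[volume]]

  one_group <- nlevels(df$.group) == 1
  fml <- if (one_group) {
    as.formula(paste(".y ~ .vol +", paste(covariates, collapse = " + ")))
  } else {
    as.formula(paste(".y ~ .group + .group:.vol +", paste(covariates, collapse = " + ")))
  }
  fit <- lm(fml, data = df)
  .check_rank(model.matrix(fit))

  co <- summary(fit)$coefficients
  slope_terms <- if (one_group) ".vol" else paste0(".group", levels(df$.group), ":.vol")
  slopes <- tibble::tibble(
    group = levels(df$.group),
    slope = unname(co[slope_terms, 1]),
    se = unname(co[slope_terms, 2]),
    statistic = unname(co[slope_terms, 3]),
    p_value = unname(co[slope_terms, 4])
  )
  if (transform == "log") {
    slopes$pct_change_per_cm3 <- 100 * (exp(slopes$slope) - 1)
  }

  interactions <- tibble::tibble(
    contrast = character(), difference = numeric(), se = numeric(),
    statistic = numeric(), p_value = numeric()
  )
  V <- vcov(fit)
  combos <- if (one_group) matrix(integer(), 2, 0) else utils::combn(seq_along(slope_terms), 2)
  if (ncol(combos) > 0) interactions <- purrr::map_dfr(seq_len(ncol(combos)), function(j) {
    i1 <- combos[1, j]; i2 <- combos[2, j]
    d <- unname(co[slope_terms[i2], 1] - co[slope_terms[i1], 1])
    se <- sqrt(V[slope_terms[i1], slope_terms[i1]] + V[slope_terms[i2], slope_terms[i2]] -
                 2 * V[slope_terms[i1], slope_terms[i2]])
    tstat <- d / se
    tibble::tibble(
      contrast = paste(levels(df$.group)[i2], "-", levels(df$.group)[i1]),
      difference = d, se = se, statistic = tstat,
      p_value = 2 * pt(-abs(tstat), fit$df.residual)
    )
  })

  structure(
    list(outcome = outcome, transform = transform, volume = volume,
         covariates = covariates, slopes = slopes, interactions = interactions,
         n = nrow(df), n_dropped = n_dropped, model = fit),
    class = "vstm_association"
  )
}

#' @export
print.vstm_association <- function(x, ...) {
  cat(sprintf("Volume association for %s (%s scale), n = %d (%d dropped)\n",
              x$outcome, x$transform, x$n, x$n_dropped))
  print(as.data.frame(x$slopes), row.names = FALSE, digits = 3)
  cat("slope-difference contrasts:\n")
  print(as.data.frame(x$interactions), row.names = FALSE, digits = 3)
  invisible(x)
}
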