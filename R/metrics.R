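#' Score trials: identification, localization and swap classification
#'
#' Joins a response table to its session plan and computes the per-trial
#' outcomes of the 'What was where?' task:
#'
#' * `identified` — whether the chosen identity equals the target's
#'   (two-alternative forced choice).
#' * `gross_error_deg` — Euclidean distance between the reported and true
#'   target location; defined only on correctly identified trials.
#' * `nn_error_deg` — distance from the report to the *nearest* item of the
#'   original memory array regardless of identity (localization precision,
#'   insensitive to swaps); never exceeds `gross_error_deg`.
#' * `is_swap` / `swap_partner` — whether the report falls within
#'   `swap_radius_deg` (inclusive) of a non-target's original location, and
#'   which item slot it was attributed to. Defined only on correctly
#'   identified trials with at least two items. Because items are separated
#'   by more than twice the swap radius, at most one partner can qualify;
#'   two qualifying partners indicate a corrupt plan and raise an error.
#'
#' Wrong-identification trials contribute to identification only: their
#' reported locations are ignored (all localization outcomes are `NA`).
#'
#' @param responses Response tibble (`participant_id`, `trial_id`,
#'   `chosen_id`, `x_deg`, `y_deg`).
#' @param plan Session plan from [build_session()] covering the same
#'   participants and trials.
#' @param geometry The [screen_geometry()] (supplies the swap radius).
#' @return A tibble with one row per response: ids, condition columns
#'   (`phase`, `block`, `n_items`, `delay_s`), `identified`,
#'   `gross_error_deg`, `nn_error_deg`, `is_swap`, `swap_partner`.
#' @examples
#' plan <- build_session(seed = 1)
#' resp <- simulate_responses(plan, default_group_presets()$control$params, seed = 2)
#' outcomes <- score_trials(resp, plan)
#' @export
score_trials <- function(responses, plan, geometry = screen_geometry()) {
  wide <- .plan_wide(plan)
  meta <- wide$meta
  key <- match(
    paste(responses$participant_id, responses$trial_id, sep = "\r"),
    wide$key
  )
  if (anyNA(key)) {
    bad <- responses$trial_id[is.na(key)]
    abort(paste0("response trial(s) missing from the plan: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  meta <- meta[key, ]
  X <- wide$X[key, , drop = FALSE]
  Y <- wide$Y[key, , drop = FALSE]
  m <- nrow(meta)

  bad <- !(responses$chosen_id == meta$target_id | responses$chosen_id == meta$foil_id)
  if (any(bad)) {
    abort(paste0(
      "chosen_id outside the {target, foil} pair on trial(s): ",
      paste(utils::head(meta$trial_id[bad], 5), collapse = ", ")
    ))
  }

  D <- sqrt((X - responses$x_deg)^2 + (Y - responses$y_deg)^2)
  rows <- seq_len(m)
  gross <- D[cbind(rows, meta$target_slot)]
  nn <- do.call(pmin, c(lapply(seq_len(ncol(D)), function(j) D[, j]), list(na.rm = TRUE)))

  near <- D <= geometry$swap_radius_deg + 1e-12
  near[cbind(rows, meta$target_slot)] <- FALSE
  n_near <- rowSums(near, na.rm = TRUE)
  if (any(n_near > 1)) {
    abort(paste0(
      "report within swap radius of two items on trial(s) ",
      paste(utils::head(meta$trial_id[n_near > 1], 5), collapse = ", "),
      "; plan violates the separation constraint"
    ))
  }
  partner <- rep(NA_integer_, m)
  hit <- which(n_near == 1L)
  if (length(hit)) partner[hit] <- max.col(near[hit, , drop = FALSE], "first")

  identified <- responses$chosen_id == meta$target_id
  is_swap <- ifelse(identified & meta$n_items >= 2, n_near == 1L, NA)

  tibble::tibble(
    participant_id = meta$participant_id,
    trial_id = meta$trial_id,
    phase = meta$phase, block = meta$block,
    n_items = meta$n_items, delay_s = meta$delay_s,
    identified = identified,
    gross_error_deg = ifelse(identified, gross, NA_real_),
    nn_error_deg = ifelse(identified, nn, NA_real_),
    is_swap = is_swap,
    swap_partner = ifelse(!is.na(is_swap) & is_swap, partner, NA_integer_)
  )
}

#' Swap-error rate over a set of scored trials
#'
#' Percentage of eligible trials (correctly identified, at least two items)
#' classified as swaps. Refuses to return a silent zero when no trial is
#' eligible.
#'
#' @param outcomes Scored trials from [score_trials()].
#' @param by Optional character vector of grouping columns.
#' @return A tibble with columns `by`..., `n_eligible`, `swap_pct`; with an
#'   empty group the rate is `NA` and a warning names the group.
#' @export
swap_rate <- function(outcomes, by = NULL) {
  grouped <- if (is.null(by)) outcomes else dplyr::group_by(outcomes, dplyr::across(dplyr::all_of(by)))
  res <- grouped |>
    dplyr::summarise(
      n_eligible = sum(!is.na(.data$is_swap)),
      swap_pct = ifelse(.data$n_eligible > 0,
                        100 * sum(.data$is_swap, na.rm = TRUE) / .data$n_eligible,
                        NA_real_),
      .groups = "drop"
    )
  if (any(res$n_eligible == 0)) {
    warn("swap_rate: group(s) with no eligible trials; rate reported as NA")
  }
  res
}

#' Chance-corrected swap-error rate
#'
#' Reports raw swap rates minus the rate expected by chance under a
#' geometric null: each eligible trial is re-scored against `n_null`
#' replacement sets of non-target locations, redrawn by the same constrained
#' sampler conditional on the trial's true target location (so the null
#' preserves the trial's geometry and every placement constraint). The
#' corrected rate is observed minus mean null rate and may legitimately be
#' negative; `clamp_zero = TRUE` truncates at zero. The Monte-Carlo /
#' sampling standard error combines the binomial error of the observed rate
#' with the between-replicate error of the null mean.
#'
#' @param outcomes Scored trials from [score_trials()].
#' @param responses The response table used for scoring (supplies report
#'   coordinates).
#' @param plan The session plan.
#' @param geometry A [screen_geometry()].
#' @param n_null Number of null replicates (at least 100).
#' @param clamp_zero Truncate negative corrected rates at zero.
#' @param null_method Null-generation method; currently only
#'   `"resample_nontargets"` is implemented (the switch isolates the
#'   published appendix calculation should an alternative be added).
#' @param include_practice Include practice trials (default FALSE, as for
#'   all summaries).
#' @param seed Optional integer seed.
#' @return A tibble with one row per participant: `n_eligible`, `swap_pct`,
#'   `null_mean_pct`, `corrected_pct`, `mc_se_pct`.
#' @examples
#' plan <- build_session(seed = 1)
#' resp <- simulate_responses(plan, default_group_presets()$control$params, seed = 2)
#' outc <- score_trials(resp, plan)
#' chance_corrected_swap_rate(outc, resp, plan, n_null = 100, seed = 3)
#' @export
chance_corrected_swap_rate <- function(outcomes, responses, plan,
                                       geometry = screen_geometry(),
                                       n_null = 500, clamp_zero = FALSE,
                                       null_method = "resample_nontargets",
                                       include_practice = FALSE,
                                       seed = NULL) {
  null_method <- match.arg(null_method)
  if (n_null < 100) abort("n_null must be at least 100")
  if (!include_practice) outcomes <- dplyr::filter(outcomes, .data$phase != "practice")
  run <- function() .chance_corrected_impl(outcomes, responses, plan, geometry, n_null, clamp_zero)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.chance_corrected_impl <- function(outcomes, responses, plan, geometry, n_null, clamp_zero) {
  eligible <- outcomes |>
    dplyr::filter(!is.na(.data$is_swap)) |>
    dplyr::select("participant_id", "trial_id", "n_items", "is_swap")
  if (nrow(eligible) == 0) abort("no eligible trials (identified, >= 2 items) for chance correction")

  targets <- plan |>
    dplyr::filter(.data$is_target) |>
    dplyr::select("participant_id", "trial_id", tx = "x_deg", ty = "y_deg")
  elig <- eligible |>
    dplyr::inner_join(targets, by = c("participant_id", "trial_id")) |>
    dplyr::inner_join(dplyr::select(responses, "participant_id", "trial_id",
                                    rep_x = "x_deg", rep_y = "y_deg"),
                      by = c("participant_id", "trial_id"))

  purrr::map(split(elig, elig$participant_id), function(df) {
    m <- nrow(df)
    reps <- n_null
    # rows = trial x null replicate; redraw the (n_items - 1) non-targets
    # conditional on the realized target location
    n_nt <- unique(df$n_items) - 1L
    if (length(n_nt) != 1L) {
      # mixed loads: process per load and pool trials
      parts <- split(df, df$n_items)
    } else {
      parts <- list(df)
    }
    null_hits <- matrix(NA, 0, reps)
    for (part in parts) {
      k <- nrow(part)
      nt_count <- part$n_items[1] - 1L
      fixed <- cbind(rep(part$tx, reps), rep(part$ty, reps))
      hit <- matrix(FALSE, k * reps, 1)
      existing <- list(fixed)
      within <- rep(FALSE, k * reps)
      for (j in seq_len(nt_count)) {
        ntj <- .sample_next_point(k * reps, geometry, existing)
        existing[[length(existing) + 1L]] <- ntj
        dx <- rep(part$rep_x, reps) - ntj[, 1]
        dy <- rep(part$rep_y, reps) - ntj[, 2]
        within <- within | (dx * dx + dy * dy) <= geometry$swap_radius_deg^2 + 1e-12
      }
      null_hits <- rbind(null_hits, matrix(within, k, reps))
    }
    rep_rates <- colMeans(null_hits)
    obs <- mean(df$is_swap)
    corrected <- obs - mean(rep_rates)
    if (clamp_zero) corrected <- max(corrected, 0)
    se <- sqrt(obs * (1 - obs) / m + var(rep_rates) / reps)
    tibble::tibble(
      participant_id = df$participant_id[1],
      n_eligible = m,
      swap_pct = 100 * obs,
      null_mean_pct = 100 * mean(rep_rates),
      corrected_pct = 100 * corrected,
      mc_se_pct = 100 * se
    )
  }) |>
    dplyr::bind_rows()
}

#' Per-subject outcome summaries with the inclusion criterion
#'
#' Aggregates scored trials to per-subject summaries, either overall
#' (`by = NULL`) or per condition cell. Practice trials are excluded by
#' default. The overall identification rate is compared against the
#' pre-defined inclusion criterion (70% by default, boundary inclusive):
#' subjects below it are flagged `included = FALSE` but still summarised.
#' Cells with no eligible trials yield `NA` aggregates, never zeros.
#'
#' @param outcomes Scored trials from [score_trials()].
#' @param by Character vector of condition columns to stratify by
#'   (subset of `"block"`, `"n_items"`, `"delay_s"`), or `NULL` for overall
#'   summaries.
#' @param min_ident Inclusion threshold on overall identification,
#'   as a proportion (default 0.70).
#' @param include_practice Include practice trials in the aggregates.
#' @return A tibble with one row per participant (per cell when `by` is
#'   given): `n_trials`, `ident_pct`, `gross_err_deg`, `nn_err_deg`,
#'   `n_eligible`, `swap_pct`, plus `included` (computed on the subject's
#'   overall identification whatever `by` is).
#' @examples
#' plan <- build_session(seed = 1)
#' resp <- simulate_responses(plan, default_group_presets()$control$params, seed = 2)
#' summarize_subjects(score_trials(resp, plan))
#' @export
summarize_subjects <- function(outcomes, by = NULL, min_ident = 0.70,
                               include_practice = FALSE) {
  if (!include_practice) outcomes <- dplyr::filter(outcomes, .data$phase != "practice")
  if (nrow(outcomes) == 0) abort("no scorable trials after excluding practice")

  overall_ident <- outcomes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(overall_ident = mean(.data$identified), .groups = "drop")

  keys <- c("participant_id", by)
  res <- outcomes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      ident_pct = 100 * mean(.data$identified),
      gross_err_deg = ifelse(any(.data$identified),
                             mean(.data$gross_error_deg[.data$identified]), NA_real_),
      nn_err_deg = ifelse(any(.data$identified),
                          mean(.data$nn_error_deg[.data$identified]), NA_real_),
      n_eligible = sum(!is.na(.data$is_swap)),
      swap_pct = ifelse(.data$n_eligible > 0,
                        100 * sum(.data$is_swap, na.rm = TRUE) / .data$n_eligible,
                        NA_real_),
      .groups = "drop"
    )
  res |>
    dplyr::left_join(overall_ident, by = "participant_id") |>
    dplyr::mutate(included = .data$overall_ident >= min_ident - 1e-12) |>
    dplyr::select(-"overall_ident")
}
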