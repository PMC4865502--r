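.logit <- function(p) log(p / (1 - p))
.inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulate responses to a session plan
#'
#' Generates one participant's trial-by-trial behaviour under the
#' target/swap/guess mixture model (see [response_model_params()]). Each
#' trial yields the chosen identity (target or foil) and a reported 2-D
#' location in degrees of visual angle. Reports anchored on an item add
#' isotropic Gaussian noise and are resampled until on-screen (truncation,
#' not clipping); guesses and wrong-identification reports are uniform over
#' the screen. Practice trials are simulated with block-1 parameters.
#'
#' @param plan A session plan from [build_session()].
#' @param params A [response_model_params()].
#' @param geometry The [screen_geometry()] of the task.
#' @param seed Optional integer seed.
#' @return A tibble with one row per trial: `participant_id`, `trial_id`,
#'   `chosen_id`, `x_deg`, `y_deg`.
#' @examples
#' plan <- build_session(seed = 1)
#' pars <- default_group_presets()$control$params
#' simulate_responses(plan, pars, seed = 2)
#' @export
simulate_responses <- function(plan, params, geometry = screen_geometry(), seed = NULL) {
  stopifnot(inherits(params, "response_model_params"))
  sim <- function() .simulate_responses_impl(plan, params, geometry)
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

.simulate_responses_impl <- function(plan, params, geometry) {
  hw <- geometry$width_deg / 2
  hh <- geometry$height_deg / 2

  wide <- .plan_wide(plan)
  trials <- wide$meta
  trials$block_eff <- ifelse(is.na(trials$block), 1L, trials$block)

  trials <- trials |>
    dplyr::left_join(
      dplyr::rename(params$p_ident, p_ident = "p", block_eff = "block"),
      by = c("n_items", "delay_s", "block_eff")
    ) |>
    dplyr::left_join(
      dplyr::rename(params$p_swap, p_swap = "p", block_eff = "block"),
      by = c("delay_s", "block_eff")
    )
  if (anyNA(trials$p_ident)) abort("p_ident table does not cover all condition cells in the plan")
  trials$p_swap[trials$n_items < 2 | is.na(trials$p_swap)] <- 0

  n <- nrow(trials)
  identified <- runif(n) < trials$p_ident
  chosen_id <- ifelse(identified, trials$target_id, trials$foil_id)

  # report anchor: target / swap (uniform non-target) / guess
  u <- runif(n)
  kind <- ifelse(!identified, "uniform",
                 ifelse(u < trials$p_swap, "swap",
                        ifelse(u < trials$p_swap + params$p_guess, "uniform", "target")))

  ax <- trials$tx
  ay <- trials$ty
  swap_i <- which(kind == "swap")
  if (length(swap_i)) {
    # k-th non-target slot, uniform among the n_items - 1 others
    k <- 1L + floor(runif(length(swap_i)) * (trials$n_items[swap_i] - 1L))
    slot <- k + (k >= trials$target_slot[swap_i])
    ax[swap_i] <- wide$X[cbind(swap_i, slot)]
    ay[swap_i] <- wide$Y[cbind(swap_i, slot)]
  }

  rx <- ry <- numeric(n)
  unif <- kind == "uniform"
  rx[unif] <- runif(sum(unif), -hw, hw)
  ry[unif] <- runif(sum(unif), -hh, hh)

  todo <- which(!unif)
  while (length(todo)) { # truncated Gaussian: resample off-screen reports
    px <- ax[todo] + rnorm(length(todo), 0, params$sigma_deg)
    py <- ay[todo] + rnorm(length(todo), 0, params$sigma_deg)
    ok <- abs(px) <= hw & abs(py) <= hh
    rx[todo[ok]] <- px[ok]
    ry[todo[ok]] <- py[ok]
    todo <- todo[!ok]
  }

  tibble::tibble(
    participant_id = trials$participant_id,
    trial_id = trials$trial_id,
    chosen_id = chosen_id,
    x_deg = rx, y_deg = ry
  )
}

#' Simulate a full cohort: subjects, session plans and responses
#'
#' Draws subjects from diagnostic-group presets, builds each subject a fresh
#' session design, and simulates their responses. Covariates (age, sex,
#' NART, total hippocampal volume, TIV) come from the preset distributions;
#' within carrier groups the subject's realized swap probabilities are
#' adjusted through a logit-linear link to the subject's hippocampal volume
#' (`volume_swap_slope` logits per cm^3, centred at the group mean volume),
#' so that smaller hippocampi produce more misbinding.
#'
#' All randomness derives from `seed`: subject-level draws and each
#' subject's session and responses use per-subject streams, so cohorts are
#' byte-for-byte reproducible.
#'
#' @param presets Named list of [group_preset()]s (default the packaged
#'   calibrated presets).
#' @param n_per_group Named integer vector of subjects per group; names must
#'   match preset labels. Default is the published cohort structure
#'   (62 controls, 12 asymptomatic and 8 symptomatic carriers).
#' @param geometry A [screen_geometry()].
#' @param library_size Stimulus-library size for the session designs.
#' @param seed Integer seed (required for reproducibility; may be NULL).
#' @return A list with tibbles `subjects` (one row per subject, including a
#'   list-column `params` of realized [response_model_params()]), `sessions`
#'   (stacked session plans) and `responses` (stacked response tables).
#' @examples
#' co <- simulate_cohort(n_per_group = c(control = 2, asymptomatic = 1), seed = 1)
#' co$subjects
#' @export
simulate_cohort <- function(presets = default_group_presets(),
                            n_per_group = c(control = 62, asymptomatic = 12, symptomatic = 8),
                            geometry = screen_geometry(),
                            library_size = 60,
                            seed = NULL) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% names(presets))) {
    abort("n_per_group must be named with preset labels")
  }
  if (any(n_per_group < 1)) abort("n_per_group entries must be >= 1")
  for (p in presets) stopifnot(inherits(p, "group_preset"))
  run <- function() .simulate_cohort_impl(presets, n_per_group, geometry, library_size)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Draw simulated subjects (covariates and realized parameters) only
#'
#' The subject-level half of [simulate_cohort()]: covariates from the preset
#' distributions and realized [response_model_params()] after the
#' volume-to-misbinding adjustment, without building sessions or responses.
#' Useful for simulation studies that pair many subject draws with a shared
#' session design.
#'
#' @inheritParams simulate_cohort
#' @return A tibble of subjects with a `params` list-column.
#' @export
simulate_subjects <- function(presets = default_group_presets(),
                              n_per_group = c(control = 62, asymptomatic = 12, symptomatic = 8),
                              seed = NULL) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% names(presets))) {
    abort("n_per_group must be named with preset labels")
  }
  run <- function() .simulate_subjects_impl(presets, n_per_group)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.simulate_subjects_impl <- function(presets, n_per_group) {
  subjects <- purrr::imap(n_per_group, function(n, grp) {
    preset <- presets[[grp]]
    tibble::tibble(
      group = grp,
      age = rnorm(n, preset$age_mean, preset$age_sd),
      sex = ifelse(runif(n) < preset$sex_p_male, "M", "F"),
      nart = rnorm(n, preset$nart_mean, preset$nart_sd),
      hippo_volume_cm3 = rnorm(n, preset$hippo_volume_mean, preset$hippo_volume_sd),
      tiv_cm3 = rnorm(n, preset$tiv_mean, preset$tiv_sd)
    )
  }) |>
    dplyr::bind_rows()
  subjects$participant_id <- sprintf("S%03d", seq_len(nrow(subjects)))

  subjects$params <- purrr::pmap(
    list(subjects$group, subjects$hippo_volume_cm3),
    function(grp, vol) {
      preset <- presets[[grp]]
      pars <- preset$params
      if (preset$volume_swap_slope != 0) {
        shift <- preset$volume_swap_slope * (vol - preset$hippo_volume_mean)
        p <- pars$p_swap$p
        p_adj <- .inv_logit(.logit(pmin(pmax(p, 1e-6), 1 - 1e-6)) + shift)
        # keep the mixture valid after the volume adjustment
        pars$p_swap$p <- pmin(p_adj, 1 - pars$p_guess)
      }
      pars
    }
  )
  subjects[c("participant_id", "group", "age", "sex", "nart",
             "hippo_volume_cm3", "tiv_cm3", "params")]
}

.simulate_cohort_impl <- function(presets, n_per_group, geometry, library_size) {
  subjects <- .simulate_subjects_impl(presets, n_per_group)
  sub_seeds <- sample.int(.Machine$integer.max, nrow(subjects))
  sessions <- vector("list", nrow(subjects))
  responses <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    withr::with_seed(sub_seeds[i], {
      plan <- .build_session_impl(geometry, as.integer(library_size), subjects$participant_id[i])
      resp <- .simulate_responses_impl(plan, subjects$params[[i]], geometry)
    })
    sessions[[i]] <- plan
    responses[[i]] <- resp
  }

  list(
    subjects = subjects,
    sessions = dplyr::bind_rows(sessions),
    responses = dplyr::bind_rows(responses)
  )
}
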