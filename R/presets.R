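#' Generative response-model parameters
#'
#' Parameters of the target/swap/guess mixture model that generates one
#' participant's reports. On each trial the participant identifies the
#' target in the two-alternative test array with condition-dependent
#' probability `p_ident`; on correctly identified trials the reported
#' location is anchored on the target, on a uniformly chosen non-target
#' (a swap, probability `p_swap`, three-item trials only), or drawn
#' uniformly over the screen (a guess, probability `p_guess`). Non-uniform
#' reports add isotropic Gaussian noise with standard deviation `sigma_deg`
#' and are resampled if they fall off-screen. Wrong-identification trials
#' produce a uniform report (their locations are never scored).
#'
#' @param p_ident Data frame with columns `n_items` (1/3), `delay_s` (1/4),
#'   `block` (1/2) and `p`: probability of correct identification per
#'   condition cell (8 rows). Practice trials use the block-1 values.
#' @param p_swap Data frame with columns `delay_s`, `block` and `p`:
#'   probability that a correctly identified three-item report anchors on a
#'   non-target (4 rows). Swaps are impossible at load 1.
#' @param sigma_deg Standard deviation of report noise, degrees of visual
#'   angle.
#' @param p_guess Probability of a uniform guess on correctly identified
#'   trials.
#' @return An object of class `response_model_params`.
#' @examples
#' pars <- response_model_params(
#'   p_ident = expand.grid(n_items = c(1, 3), delay_s = c(1, 4), block = 1:2, p = 0.95),
#'   p_swap = expand.grid(delay_s = c(1, 4), block = 1:2, p = 0.1),
#'   sigma_deg = 2, p_guess = 0.05
#' )
#' @export
response_model_params <- function(p_ident, p_swap, sigma_deg, p_guess) {
  p_ident <- tibble::as_tibble(p_ident)[c("n_items", "delay_s", "block", "p")]
  p_swap <- tibble::as_tibble(p_swap)[c("delay_s", "block", "p")]
  if (nrow(dplyr::distinct(p_ident[1:3])) != nrow(p_ident)) abort("duplicate p_ident condition cells")
  if (nrow(dplyr::distinct(p_swap[1:2])) != nrow(p_swap)) abort("duplicate p_swap condition cells")
  if (any(p_ident$p < 0 | p_ident$p > 1) || any(p_swap$p < 0 | p_swap$p > 1)) {
    abort("identification and swap probabilities must lie in [0, 1]")
  }
  if (!is.numeric(sigma_deg) || sigma_deg <= 0) abort("sigma_deg must be positive")
  if (p_guess < 0 || p_guess > 1) abort("p_guess must lie in [0, 1]")
  if (any(p_swap$p + p_guess > 1)) abort("p_swap + p_guess must not exceed 1 in any condition")
  structure(
    list(p_ident = p_ident, p_swap = p_swap,
         sigma_deg = sigma_deg, p_guess = p_guess),
    class = "response_model_params"
  )
}

#' @export
print.response_model_params <- function(x, ...) {
  cat("<response_model_params> sigma_deg =", x$sigma_deg, ", p_guess =", x$p_guess, "\n")
  cat("identification (by load, delay, block):\n")
  print(tidyr::pivot_wider(x$p_ident, names_from = "block", values_from = "p", names_prefix = "block"))
  cat("swap probability (by delay, block; three-item trials):\n")
  print(tidyr::pivot_wider(x$p_swap, names_from = "block", values_from = "p", names_prefix = "block"))
  invisible(x)
}

#' Diagnostic-group presets for cohort simulation
#'
#' A `group_preset` holds one diagnostic group's generative behaviour
#' ([response_model_params()]) together with the covariate distributions the
#' cohort simulator draws from (total hippocampal volume, total intracranial
#' volume, age, sex, premorbid-IQ NART score) and, for mutation-carrier
#' groups, the strength of the hippocampal-volume link to misbinding:
#' `volume_swap_slope` is the change in logit swap probability per cm^3 of
#' hippocampal volume above the group mean (non-positive for carriers).
#'
#' `default_group_presets()` loads the package's calibrated presets for the
#' control, asymptomatic-carrier and symptomatic familial-Alzheimer's
#' groups. Their expected task metrics approximate the published group
#' means (e.g. overall swap rates near 10.6% for controls and 21.3% for
#' symptomatic carriers); the constants live in
#' `inst/extdata/group_presets.yaml`, not in code.
#'
#' @param label Group label: `"control"`, `"asymptomatic"` or
#'   `"symptomatic"`.
#' @param params A [response_model_params()].
#' @param hippo_volume_mean,hippo_volume_sd Total hippocampal volume, cm^3.
#' @param tiv_mean,tiv_sd Total intracranial volume, cm^3.
#' @param age_mean,age_sd Age, years.
#' @param sex_p_male Probability a simulated subject is male.
#' @param nart_mean,nart_sd NART score distribution.
#' @param volume_swap_slope Change in logit swap probability per cm^3
#'   (0 for controls, <= 0 for carriers).
#' @return An object of class `group_preset`; `default_group_presets()`
#'   returns a named list of three.
#' @examples
#' presets <- default_group_presets()
#' names(presets)
#' @export
group_preset <- function(label, params,
                         hippo_volume_mean, hippo_volume_sd,
                         tiv_mean, tiv_sd, age_mean, age_sd,
                         sex_p_male, nart_mean, nart_sd,
                         volume_swap_slope = 0) {
  stopifnot(inherits(params, "response_model_params"))
  if (hippo_volume_mean <= 0 || tiv_mean <= 0) abort("volumes must be positive")
  carrier <- label %in% c("asymptomatic", "symptomatic")
  if (carrier && volume_swap_slope > 0) {
    abort("volume_swap_slope must be <= 0 for carrier groups")
  }
  structure(
    list(
      label = label, params = params,
      hippo_volume_mean = hippo_volume_mean, hippo_volume_sd = hippo_volume_sd,
      tiv_mean = tiv_mean, tiv_sd = tiv_sd,
      age_mean = age_mean, age_sd = age_sd,
      sex_p_male = sex_p_male, nart_mean = nart_mean, nart_sd = nart_sd,
      volume_swap_slope = volume_swap_slope
    ),
    class = "group_preset"
  )
}

#' @rdname group_preset
#' @param file Path to a YAML preset file; defaults to the packaged
#'   calibrated presets.
#' @export
default_group_presets <- function(file = system.file("extdata", "group_presets.yaml",
                                                     package = "vstmbind")) {
  raw <- yaml::read_yaml(file)
  presets <- lapply(raw$groups, function(g) {
    group_preset(
      label = g$label,
      params = response_model_params(
        p_ident = dplyr::bind_rows(lapply(g$p_ident, tibble::as_tibble)),
        p_swap = dplyr::bind_rows(lapply(g$p_swap, tibble::as_tibble)),
        sigma_deg = g$sigma_deg, p_guess = g$p_guess
      ),
      hippo_volume_mean = g$hippo_volume_mean, hippo_volume_sd = g$hippo_volume_sd,
      tiv_mean = g$tiv_mean, tiv_sd = g$tiv_sd,
      age_mean = g$age_mean, age_sd = g$age_sd,
      sex_p_male = g$sex_p_male, nart_mean = g$nart_mean, nart_sd = g$nart_sd,
      volume_swap_slope = g$volume_swap_slope
    )
  })
  names(presets) <- vapply(presets, `[[`, character(1), "label")
  presets
}
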