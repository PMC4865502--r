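#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy methods for fitted comparison and association objects
#'
#' Broom-style one-row-per-term summaries of the package's fitted objects.
#' `tidy()` returns estimates, standard errors, statistics and p-values;
#' `glance()` returns a one-row model-level summary.
#'
#' @param x A `vstm_comparison`, `vstm_interaction`, `vstm_association` or
#'   `vstm_bca` object.
#' @param ... Unused.
#' @return A tibble.
#' @name vstm_tidiers
NULL

#' @rdname vstm_tidiers
#' @method tidy vstm_comparison
#' @export
tidy.vstm_comparison <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    contrast = paste(x$groups[2], "-", x$groups[1]),
    estimate = x$estimate,
    std.error = x$se,
    statistic = x$statistic,
    stat.type = x$stat_type,
    df = x$df,
    p.value = x$p_value,
    odds.ratio = if (is.null(x$odds_ratio)) NA_real_ else x$odds_ratio,
    conf.low = if (is.null(x$ci)) NA_real_ else x$ci$lower,
    conf.high = if (is.null(x$ci)) NA_real_ else x$ci$upper
  )
}

#' @rdname vstm_tidiers
#' @method glance vstm_comparison
#' @export
glance.vstm_comparison <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    n_reference = x$n[1],
    n_comparison = x$n[2],
    covariates = paste(x$covariates, collapse = "+"),
    n_boot = if (is.null(x$ci)) 0L else x$ci$n_boot
  )
}

#' @rdname vstm_tidiers
#' @method tidy vstm_interaction
#' @export
tidy.vstm_interaction <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, term = x$term,
    statistic = x$statistic, df1 = x$df1, df2 = x$df2,
    p.value = x$p_value
  )
}

#' @rdname vstm_tidiers
#' @method tidy vstm_association
#' @export
tidy.vstm_association <- function(x, ...) {
  out <- x$slopes
  names(out) <- sub("^slope$", "estimate", names(out))
  names(out) <- sub("^se$", "std.error", names(out))
  names(out) <- sub("^p_value$", "p.value", names(out))
  out$outcome <- x$outcome
  out$transform <- x$transform
  dplyr::relocate(out, "outcome", "transform")
}

#' @rdname vstm_tidiers
#' @method glance vstm_association
#' @export
glance.vstm_association <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    outcome = x$outcome, transform = x$transform,
    n = x$n, n_dropped = x$n_dropped,
    r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
    sigma = s$sigma
  )
}

#' @rdname vstm_tidiers
#' @method tidy vstm_bca
#' @export
tidy.vstm_bca <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, conf.low = x$lower, conf.high = x$upper,
    z0 = x$z0, acceleration = x$a, n_boot = x$n_boot, alpha = x$alpha
  )
}
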