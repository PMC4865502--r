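#' Plot the spatial layout of session trials
#'
#' Draws item locations for a handful of trials on the screen outline, with
#' the edge-margin rectangle, the central exclusion zone and the swap radius
#' around each item, to eyeball the placement constraints.
#'
#' @param plan A session plan from [build_session()].
#' @param geometry The matching [screen_geometry()].
#' @param trials Trial ids to show (default the first 6 three-item trials).
#' @return A ggplot object.
#' @export
plot_session <- function(plan, geometry = screen_geometry(), trials = NULL) {
  if (is.null(trials)) {
    trials <- utils::head(unique(plan$trial_id[plan$n_items == 3]), 6)
  }
  df <- dplyr::filter(plan, .data$trial_id %in% trials)
  hw <- geometry$width_deg / 2
  hh <- geometry$height_deg / 2
  m <- geometry$edge_margin_deg
  circle <- function(r, n = 90) {
    th <- seq(0, 2 * pi, length.out = n)
    tibble::tibble(x = r * cos(th), y = r * sin(th))
  }
  centre <- circle(geometry$centre_exclusion_deg)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_deg, .data$y_deg)) +
    ggplot2::geom_rect(xmin = -hw, xmax = hw, ymin = -hh, ymax = hh,
                       fill = NA, colour = "grey30") +
    ggplot2::geom_rect(xmin = -hw + m, xmax = hw - m, ymin = -hh + m, ymax = hh - m,
                       fill = NA, colour = "grey70", linetype = 2) +
    ggplot2::geom_path(data = centre, ggplot2::aes(.data$x, .data$y),
                       colour = "grey70", linetype = 2, inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_target), size = 2) +
    ggplot2::facet_wrap(~trial_id, labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", shape = "target") +
    ggplot2::theme_minimal()
}

#' Plot group-level outcome summaries
#'
#' Group means with standard-error bars for a chosen outcome, optionally
#' split by condition columns.
#'
#' @param summaries Per-subject summaries from [summarize_subjects()]
#'   joined to a `group` column.
#' @param outcome Outcome column to plot (e.g. `"swap_pct"`).
#' @param by Optional condition column for faceting (e.g. `"block"`).
#' @return A ggplot object.
#' @export
plot_group_outcome <- function(summaries, outcome = "swap_pct", by = NULL) {
  keys <- c("group", by)
  df <- summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data[[outcome]], na.rm = TRUE),
      se = sd(.data[[outcome]], na.rm = TRUE) / sqrt(sum(!is.na(.data[[outcome]]))),
      .groups = "drop"
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey75") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se), width = 0.2) +
    ggplot2::labs(x = NULL, y = outcome) +
    ggplot2::theme_minimal()
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(by, labeller = ggplot2::label_both)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a fitted group comparison
#'
#' Point estimate of the adjusted group difference with its BCa interval
#' (when bootstrapped) or a normal-approximation interval otherwise.
#'
#' @param object A `vstm_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vstm_comparison
#' @export
autoplot.vstm_comparison <- function(object, ...) {
  td <- tidy(object)
  if (is.na(td$conf.low)) {
    td$conf.low <- td$estimate - 1.96 * td$std.error
    td$conf.high <- td$estimate + 1.96 * td$std.error
  }
  ggplot2::ggplot(td, ggplot2::aes(.data$estimate, .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::labs(x = paste("adjusted difference in", object$outcome), y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a volume-outcome association
#'
#' Scatter of the (transformed) outcome against hippocampal volume with the
#' fitted per-group slopes at covariate means.
#'
#' @param object A `vstm_association`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vstm_association
#' @export
autoplot.vstm_association <- function(object, ...) {
  mf <- object$model$model
  df <- tibble::tibble(
    y = mf$.y, vol = mf$.vol, group = mf$.group
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$vol, .data$y, colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "total hippocampal volume (cm³)",
      y = paste0(object$outcome, " (", object$transform, " scale)")
    ) +
    ggplot2::theme_minimal()
}
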