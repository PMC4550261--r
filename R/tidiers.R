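# broom-style tidiers and plot methods for fitted objects.

glmmtmb_coef_tbl <- function(fit, part_label) {
  cf <- summary(fit)$coefficients$cond
  tibble::tibble(
    part = part_label,
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "z value"]),
    p.value = unname(cf[, "Pr(>|z|)"])
  )
}

#' Tidy a hurdle fit into a coefficient table
#'
#' One row per fixed-effect coefficient of each fitted part, with z
#' statistics and Wald p-values, in the broom column convention.
#'
#' @param x A [fit_hurdle()] object.
#' @param ... Unused.
#' @return A tibble: `part` (`binary` / `count`), `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.hurdle_fit <- function(x, ...) {
  dplyr::bind_rows(
    if (!is.null(x$binary)) glmmtmb_coef_tbl(x$binary, "binary"),
    if (!is.null(x$count)) glmmtmb_coef_tbl(x$count, "count")
  )
}

#' One-row summary of a hurdle fit
#'
#' @param x A [fit_hurdle()] object.
#' @param ... Unused.
#' @return A tibble: response, sample sizes, per-part and total
#'   log-likelihoods, total parameter count, convergence and
#'   degeneracy/refusal flags.
#' @export
glance.hurdle_fit <- function(x, ...) {
  ll <- hurdle_loglik(x)
  tibble::tibble(
    response = x$response, n = x$n, n_positive = x$n_positive,
    loglik_binary = ll$binary, loglik_count = ll$count,
    loglik_total = ll$total, df = ll$df,
    converged = x$converged,
    binary_degenerate = x$binary_degenerate,
    count_refused = !is.null(x$count_refusal)
  )
}

#' Tidy a Gaussian mixed-model fit
#'
#' Fixed effects with t statistics; p-values use the normal approximation to
#' the t distribution (the crossed-design degrees of freedom are not
#' well-defined), which is the convention the z-tests of the hurdle parts
#' follow as well.
#'
#' @param x A [fit_lme()] object.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.lme_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std.error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p.value = unname(2 * stats::pnorm(-abs(cf[, "t value"])))
  )
}

#' One-row summary of a Gaussian mixed-model fit
#'
#' @param x A [fit_lme()] object.
#' @param ... Unused.
#' @return A tibble with log-likelihood, parameter count, sample size and
#'   the singular-fit flag.
#' @export
glance.lme_fit <- function(x, ...) {
  ll <- logLik(x$fit)
  tibble::tibble(
    response = x$response, n = stats::nobs(x$fit),
    loglik = as.numeric(ll), df = attr(ll, "df"),
    singular = x$singular
  )
}

#' Tidy a collinearity screen
#'
#' @param x A [screen_collinearity()] result.
#' @param ... Unused.
#' @return The pairwise report tibble (`behavior_a`, `behavior_b`, `phi`,
#'   `pearson`, `flagged`).
#' @export
tidy.collinearity_screen <- function(x, ...) x$report

# shared mean +/- SEM period summary
period_summary <- function(data, value_col) {
  data |>
    dplyr::filter(.data$period %in% period_levels()) |>
    dplyr::group_by(period = factor(.data$period, levels = period_levels())) |>
    dplyr::summarise(mean = mean(.data[[value_col]]),
                     sem = sem(.data[[value_col]]), .groups = "drop")
}

#' Plot per-period occurrence probability of a behavior
#'
#' Observed mean probability of detecting the behavior per focal, with
#' standard-error-of-the-mean bars, across the three reproductive periods.
#'
#' @param focals Wide focal tibble with a `period` column.
#' @param response Behavior count column.
#' @return A ggplot object.
#' @export
plot_occurrence_probability <- function(focals, response) {
  df <- focals |>
    dplyr::mutate(.occ = as.numeric(.data[[response]] > 0)) |>
    period_summary(".occ")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = "Reproductive period",
                  y = sprintf("P(%s observed) per focal", response),
                  title = sprintf("Occurrence of %s by reproductive period",
                                  response)) +
    ggplot2::theme_minimal()
}

#' Plot per-period means of a continuous outcome
#'
#' Mean with standard-error-of-the-mean bars per reproductive period, for
#' color or hormone outcomes.
#'
#' @param data Tibble with `period` and the outcome column.
#' @param response Outcome column name (e.g. `"luminance"`, `"rg_ratio"`).
#' @return A ggplot object.
#' @export
plot_outcome_means <- function(data, response) {
  df <- period_summary(data, response)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$period, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.12) +
    ggplot2::labs(x = "Reproductive period", y = response,
                  title = sprintf("%s by reproductive period", response)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_occurrence_probability
#' @param object A [fit_hurdle()] object.
#' @param ... Unused.
#' @export
autoplot.hurdle_fit <- function(object, ...) {
  plot_occurrence_probability(object$data, object$response)
}

#' @rdname plot_outcome_means
#' @param object A [fit_lme()] object.
#' @param ... Unused.
#' @export
autoplot.lme_fit <- function(object, ...) {
  plot_outcome_means(object$data, object$response)
}

#' Plot a female's PdG series with the detected windows
#'
#' Hormone profile with the detected rise, peri-ovulatory and fertile
#' windows, and the estimated conception date marked.
#'
#' @param hormones Tibble `female_id`, `date`, `pdg_ug_g` for one female.
#' @param timeline A [reproductive_timeline()] (its first matching female row
#'   is used).
#' @return A ggplot object.
#' @export
plot_hormone_timeline <- function(hormones, timeline) {
  fid <- hormones$female_id[1]
  conc <- timeline$conceptions |> dplyr::filter(.data$female_id == fid)
  p <- ggplot2::ggplot(hormones, ggplot2::aes(x = .data$date,
                                              y = .data$pdg_ug_g)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 1)
  if (nrow(conc) == 1 && !is.na(conc$rise_date)) {
    p <- p +
      ggplot2::annotate("rect", xmin = conc$rise_date - 6,
                        xmax = conc$rise_date - 2, ymin = -Inf, ymax = Inf,
                        alpha = 0.15, fill = "steelblue") +
      ggplot2::geom_vline(xintercept = conc$rise_date, linetype = 2) +
      ggplot2::geom_vline(xintercept = conc$conception_date,
                          color = "firebrick")
  }
  p + ggplot2::labs(x = NULL, y = "PdG (µg/g dry feces)",
                    title = sprintf("PdG profile and fertile window, %s", fid)) +
    ggplot2::theme_minimal()
}
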