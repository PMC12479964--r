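#' Tidy an evolution run
#'
#' @param x An `evolution_trace`.
#' @param type `"trace"` (default; per-strain within-day trajectories),
#'   `"output"` (population output `P(t)` on the full grid), `"days"`
#'   (day-endpoint snapshots), or `"endpoints"` (day-endpoint output with
#'   `P0` prepended at time zero, the series the tau metrics use).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.evolution_trace <- function(x, type = c("trace", "output", "days",
                                             "endpoints"), ...) {
  type <- match.arg(type)
  switch(type,
         trace = x$trace,
         output = x$output,
         days = dplyr::select(x$days, -"strain_N"),
         endpoints = endpoint_series(x))
}

#' One-row summary of an evolution run
#'
#' @param x An `evolution_trace`.
#' @param ... Unused.
#' @return The [design_metrics()] row plus `days` and `n_strain`.
#' @export
glance.evolution_trace <- function(x, ...) {
  dplyr::bind_cols(design_metrics(x),
                   tibble::tibble(days = nrow(x$days),
                                  n_strain = nrow(x$scheme$states)))
}

#' Plot the population output of an evolution run
#'
#' The full within-day output trajectory (grey; it swings during each
#' regrowth phase) with the day-endpoint envelope (points and line) on
#' which the longevity metrics are defined, and the 10 percent band around
#' the initial output.
#'
#' @param object An `evolution_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evolution_trace <- function(object, ...) {
  ep <- endpoint_series(object, unit = "day")
  full <- object$output
  full$day <- full$time / object$protocol$day_length
  ggplot2::ggplot(ep, ggplot2::aes(x = .data$day, y = .data$P)) +
    ggplot2::geom_line(data = full, colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(0.9, 1.1) * object$P0,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$time), size = 1) +
    ggplot2::labs(x = "time (days)", y = "population output P (molecules)",
                  title = sprintf("%s evolution run", object$circuit$topology))
}

#' Plot the strain composition of a run
#'
#' Day-endpoint population sizes per mutation state, stacked: the takeover
#' of low- and non-functional strains over evolutionary time.
#'
#' @param run An `evolution_trace`.
#' @return A ggplot.
#' @export
plot_population <- function(run) {
  stopifnot(inherits(run, "evolution_trace"))
  comp <- run$days |>
    dplyr::mutate(strain_N = purrr::map(.data$strain_N, function(N) {
      tibble::tibble(label = run$scheme$states$label, N = N)
    })) |>
    dplyr::select("day", "strain_N") |>
    tidyr::unnest("strain_N")
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$day, y = .data$N,
                                     fill = .data$label)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::labs(x = "day", y = "cells", fill = "mutation state")
}

#' @export
tidy.mutation_scheme <- function(x, ...) {
  idx <- which(x$matrix > 0, arr.ind = TRUE)
  tibble::tibble(
    from = rownames(x$matrix)[idx[, 1]],
    to = colnames(x$matrix)[idx[, 2]],
    rate = x$matrix[idx]
  )
}

#' @export
tidy.pareto_front <- function(x, ...) x$front

#' @export
glance.pareto_front <- function(x, ...) {
  tibble::tibble(topology = x$topology, n_B = x$n_B,
                 n_designs = nrow(x$front), n_eval = x$n_eval,
                 seed = x$seed,
                 pop_size = x$settings$pop_size,
                 generations = x$settings$generations)
}

#' Plot a Pareto front
#'
#' Half-life against initial output, coloured by the short-term metric:
#' the production/longevity trade-off surface the optimiser explores.
#'
#' @param object A `pareto_front`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pareto_front <- function(object, ...) {
  ggplot2::ggplot(object$front,
                  ggplot2::aes(x = .data$P0, y = .data$tau_50,
                               colour = .data$tau_pm10)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initial output P0 (molecules)",
                  y = "half-life tau50 (days)",
                  colour = "tau+/-10 (days)",
                  title = sprintf("%s Pareto designs (n_B = %d aa)",
                                  object$topology, object$n_B))
}

#' @export
tidy.openloop_reference <- function(x, ...) x$branch

#' Plot the open-loop reference
#'
#' The retained (non-overburdened) open-loop branch: longevity metrics
#' against initial output.
#'
#' @param object An `openloop_reference`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.openloop_reference <- function(object, ...) {
  long <- object$branch |>
    tidyr::pivot_longer(dplyr::all_of(intersect(c("tau_pm10", "tau_50"),
                                                names(object$branch))),
                        names_to = "metric", values_to = "tau")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$P0, y = .data$tau,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "initial output P0 (molecules)", y = "tau (days)")
}

#' @export
tidy.robustness_report <- function(x, ...) x$per_design

#' @export
glance.robustness_report <- function(x, ...) x$front

#' Plot per-design robustness
#'
#' Mean and standard deviation of the percentage change in the half-life
#' for each design, per perturbation level.
#'
#' @param object A `robustness_report`.
#' @param metric One of `"P0"`, `"tau_pm10"`, `"tau_50"`, `"tau_90"`,
#'   `"P_max"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.robustness_report <- function(object, metric = "tau_50", ...) {
  mcol <- paste0("pct_", metric)
  df <- object$per_design
  df$mean <- df[[paste0(mcol, "_mean")]]
  df$sd <- df[[paste0(mcol, "_sd")]]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$design), y = .data$mean,
                                   colour = factor(.data$X))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "design", y = sprintf("%% change in %s", metric),
                  colour = "+/- X%")
}
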