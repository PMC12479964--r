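#' Population-wide output
#'
#' The total number of output protein molecules across the whole population:
#' `P = sum_i N_i * p_A_i`.
#'
#' @param N Cells per strain.
#' @param p_A Per-cell output protein per strain (mc).
#' @return Scalar `P` (molecules).
#' @export
total_output <- function(N, p_A) {
  if (length(N) != length(p_A)) {
    stop("`N` and `p_A` must have the same length", call. = FALSE)
  }
  sum(N * p_A)
}

#' Longevity crossing times of an output trajectory
#'
#' Computes the evolutionary-longevity metrics from a sampled output series
#' `P(t)`:
#' \describe{
#'   \item{tau_pm10}{first time `P` exits the band `[0.9 P0, 1.1 P0]`
#'     (either boundary).}
#'   \item{tau_90}{first time `P` falls below `0.9 P0`.}
#'   \item{tau_50}{first time `P` falls below `0.5 P0` (the functional
#'     half-life).}
#'   \item{P_max}{maximum of `P` over the trace.}
#' }
#' Crossings are located by linear interpolation between samples. A metric
#' whose threshold is never crossed is returned as `Inf` with its
#' `*_reached` flag set `FALSE` -- never as the trace horizon. A trace that
#' rises above the band before falling has `tau_pm10 < tau_90`; the
#' `band_exit_upper` flag records this.
#'
#' @param time,P Numeric vectors sampling the output trajectory. The first
#'   sample should be `(0, P0)` -- [endpoint_series()] builds exactly that
#'   series for an evolution run.
#' @param P0 Initial output (> 0).
#'
#' @return A one-row tibble: `tau_pm10`, `tau_90`, `tau_50`, `P_max`,
#'   logical flags `tau_pm10_reached`, `tau_90_reached`, `tau_50_reached`,
#'   `band_exit_upper`.
#' @export
crossing_times <- function(time, P, P0) {
  if (!is.numeric(P0) || length(P0) != 1 || P0 <= 0) {
    stop("`P0` must be a single positive number", call. = FALSE)
  }
  if (length(time) != length(P) || length(time) < 2) {
    stop("`time` and `P` must be equal-length vectors (>= 2 samples)",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("`time` must be strictly increasing",
                                 call. = FALSE)
  first_down <- function(thr) {
    below <- P < thr
    if (!any(below)) return(NA_real_)
    i <- which(below)[1]
    if (i == 1) return(time[1])
    time[i - 1] + (time[i] - time[i - 1]) * (P[i - 1] - thr) / (P[i - 1] - P[i])
  }
  first_up <- function(thr) {
    above <- P > thr
    if (!any(above)) return(NA_real_)
    i <- which(above)[1]
    if (i == 1) return(time[1])
    time[i - 1] + (time[i] - time[i - 1]) * (thr - P[i - 1]) / (P[i] - P[i - 1])
  }
  t90 <- first_down(0.9 * P0)
  t_up <- first_up(1.1 * P0)
  t50 <- first_down(0.5 * P0)
  cand <- c(t90, t_up)
  tpm <- if (all(is.na(cand))) NA_real_ else min(cand, na.rm = TRUE)
  upper <- !is.na(t_up) && (is.na(t90) || t_up < t90)
  tibble::tibble(
    tau_pm10 = ifelse(is.na(tpm), Inf, tpm),
    tau_90 = ifelse(is.na(t90), Inf, t90),
    tau_50 = ifelse(is.na(t50), Inf, t50),
    P_max = max(P),
    tau_pm10_reached = !is.na(tpm),
    tau_90_reached = !is.na(t90),
    tau_50_reached = !is.na(t50),
    band_exit_upper = upper
  )
}

#' Cumulative output of an evolution run
#'
#' The total production of output protein across the whole culture:
#' `Q = sum_i integral_0^t_end T_L_A_i(t) * N_i(t) dt`, computed by
#' trapezoidal quadrature on the stored trace grid. `t_end` is the point
#' where the daily-endpoint output falls below `stop_fraction` of `P0`
#' (located by linear interpolation); if never reached, the full trace is
#' integrated.
#'
#' @param run An `evolution_trace` from [run_evolution()], or a tibble with
#'   columns `time`, `strain`, `N`, `T_L_A` (then `t_end` must be given).
#' @param t_end Optional integration end time (min); computed from the run's
#'   stop rule when omitted.
#' @param stop_fraction Output fraction of `P0` defining `t_end`
#'   (default 0.01).
#'
#' @return Scalar `Q` (molecules).
#' @export
cumulative_output <- function(run, t_end = NULL, stop_fraction = 0.01) {
  if (inherits(run, "evolution_trace")) {
    trace <- run$trace
    if (is.null(t_end)) {
      ep <- rbind(
        tibble::tibble(time = 0, P = run$P0),
        run$days[, c("time", "P")]
      )
      below <- ep$P < stop_fraction * run$P0
      t_end <- if (any(below)) {
        i <- which(below)[1]
        thr <- stop_fraction * run$P0
        ep$time[i - 1] + (ep$time[i] - ep$time[i - 1]) *
          (ep$P[i - 1] - thr) / (ep$P[i - 1] - ep$P[i])
      } else {
        max(trace$time)
      }
    }
  } else {
    trace <- run
    if (is.null(t_end)) stop("`t_end` required for a bare trace", call. = FALSE)
  }
  if (!all(c("time", "strain", "N", "T_L_A") %in% names(trace))) {
    stop("trace must carry time, strain, N and the translation flux T_L_A",
         call. = FALSE)
  }
  grp <- intersect(c("day", "time"), names(trace))
  flux <- trace |>
    dplyr::summarise(f = sum(.data$N * .data$T_L_A), .by = dplyr::all_of(grp)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::filter(.data$time <= t_end)
  # at day boundaries two samples share one clock time (pre/post dilution);
  # their trapezoid segment has zero width, which integrates the jump exactly
  tt <- flux$time
  ff <- flux$f
  if (length(tt) < 2) return(0)
  sum(diff(tt) * (ff[-1] + ff[-length(ff)]) / 2)
}

#' Day-endpoint output series of a run
#'
#' The daily-endpoint output `P` with the ancestral output `P0` prepended at
#' time zero: the series on which the longevity metrics are computed (the
#' within-day trace swings several-fold during regrowth after each dilution,
#' so the day-scale envelope is the meaningful signal).
#'
#' @param run An `evolution_trace`.
#' @param unit `"min"` or `"day"` for the time axis.
#' @return Tibble with `time` and `P`.
#' @export
endpoint_series <- function(run, unit = c("min", "day")) {
  unit <- match.arg(unit)
  stopifnot(inherits(run, "evolution_trace"))
  out <- rbind(tibble::tibble(time = 0, P = run$P0),
               run$days[, c("time", "P")])
  if (unit == "day") out$time <- out$time / run$protocol$day_length
  out
}

#' Longevity and production metrics of an evolution run
#'
#' @param run An `evolution_trace` from [run_evolution()].
#' @param unit Time unit for the tau metrics (`"day"` default, or `"min"`).
#' @return One-row tibble: `topology`, `P0`, `tau_pm10`, `tau_90`, `tau_50`
#'   (in `unit`), `P_max`, `Q`, and the reached/band flags from
#'   [crossing_times()].
#' @export
design_metrics <- function(run, unit = c("day", "min")) {
  unit <- match.arg(unit)
  stopifnot(inherits(run, "evolution_trace"))
  ep <- endpoint_series(run, unit = unit)
  ct <- crossing_times(ep$time, ep$P, run$P0)
  tibble::tibble(
    topology = run$circuit$topology,
    P0 = run$P0,
    ct[, c("tau_pm10", "tau_90", "tau_50", "P_max")],
    Q = cumulative_output(run, stop_fraction = run$protocol$stop_fraction),
    ct[, c("tau_pm10_reached", "tau_90_reached", "tau_50_reached",
           "band_exit_upper")]
  )
}

#' Build the equal-output open-loop reference
#'
#' To judge a controller fairly it must be compared against an open-loop
#' system of the *same initial output* `P0` (simply turning transcription
#' down always "improves" longevity). The reference is built by sweeping the
#' open-loop maximal transcription rate `omega_A` over a wide range,
#' computing `(P0, tau_pm10, tau_50, tau_90, Q)` for each design, removing
#' the overburdened branch (designs past the `P0` maximum in `omega_A`,
#' where output and longevity fall together), and interpolating each metric
#' linearly in `P0`.
#'
#' @param sweep A tibble with columns `omega_A`, `P0`, `tau_pm10`, `tau_50`,
#'   and optionally `tau_90` and `Q`, ordered or orderable by `omega_A` --
#'   typically from [sweep_designs()] over an open-loop grid.
#'
#' @return An `openloop_reference` object with the filtered branch and
#'   interpolators; query it with [percent_change_vs_openloop()] or
#'   `predict()`.
#' @export
build_openloop_reference <- function(sweep) {
  need <- c("omega_A", "P0", "tau_pm10", "tau_50")
  if (!all(need %in% names(sweep))) {
    stop("sweep needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  sweep <- dplyr::arrange(sweep, .data$omega_A)
  keep <- seq_len(which.max(sweep$P0))   # prefix up to the P0 argmax
  branch <- sweep[keep, ]
  if (any(diff(branch$P0) <= 0)) {
    branch <- branch[c(TRUE, diff(branch$P0) > 0), ]  # enforce single-valued
  }
  if (nrow(branch) < 2) stop("fewer than 2 designs on the retained branch",
                             call. = FALSE)
  structure(list(branch = branch,
                 metrics = intersect(c("tau_pm10", "tau_50", "tau_90", "Q"),
                                     names(branch))),
            class = "openloop_reference")
}

#' @export
print.openloop_reference <- function(x, ...) {
  cat(sprintf(
    "<openloop_reference> %d designs on the non-overburdened branch; P0 in [%.4g, %.4g]\n",
    nrow(x$branch), min(x$branch$P0), max(x$branch$P0)))
  invisible(x)
}

#' @export
predict.openloop_reference <- function(object, P0, metric = "tau_50", ...) {
  if (!metric %in% object$metrics) {
    stop(sprintf("metric `%s` not in reference (have: %s)", metric,
                 paste(object$metrics, collapse = ", ")), call. = FALSE)
  }
  rng <- range(object$branch$P0)
  if (any(P0 < rng[1] | P0 > rng[2])) {
    stop(sprintf("P0 outside the reference domain [%.4g, %.4g]; no extrapolation",
                 rng[1], rng[2]), call. = FALSE)
  }
  stats::approx(object$branch$P0, object$branch[[metric]], xout = P0)$y
}

#' Percentage change of a controller vs the equal-output open loop
#'
#' For each longevity/production metric, the relative improvement of a
#' controller design over an open-loop system of identical initial output:
#' `100 * (tau_controller - tau_OL(P0)) / tau_OL(P0)`.
#'
#' @param metrics A one-row design-metrics tibble (from [design_metrics()]).
#' @param ref An `openloop_reference`.
#' @return The input tibble with `pct_tau_pm10`, `pct_tau_50` (and
#'   `pct_Q` where the reference carries `Q`) columns appended.
#' @export
percent_change_vs_openloop <- function(metrics, ref) {
  stopifnot(inherits(ref, "openloop_reference"))
  out <- metrics
  for (m in intersect(c("tau_pm10", "tau_50", "Q"), ref$metrics)) {
    base <- predict(ref, metrics$P0, metric = m)
    out[[paste0("pct_", m)]] <- 100 * (metrics[[m]] - base) / base
  }
  out
}
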