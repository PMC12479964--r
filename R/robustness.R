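#' Uniformly perturbed parameter replicates
#'
#' Generates `n` replicates of a design by drawing each parameter uniformly
#' from `[u_i (1 - X/100), u_i (1 + X/100)]`, then clipping to the design
#' bounds: draws that land outside `[L_i, U_i]` are set to exactly the
#' boundary value, so the perturbation never explores parameter space that
#' the optimiser could not.
#'
#' @param u Named numeric design vector.
#' @param X Perturbation level in percent (e.g. 10 or 25).
#' @param lower,upper Bounds (named like `u`); defaults of `-Inf`/`Inf`
#'   disable clipping.
#' @param n Number of replicates.
#' @param seed Integer seed; reproducible draws.
#' @return A tibble with `n` rows, one column per parameter.
#' @export
perturb_parameters <- function(u, X, lower = NULL, upper = NULL, n = 100,
                               seed = 1) {
  if (X < 0) stop("`X` must be >= 0", call. = FALSE)
  nm <- names(u)
  lower <- lower %||% stats::setNames(rep(-Inf, length(u)), nm)
  upper <- upper %||% stats::setNames(rep(Inf, length(u)), nm)
  set.seed(seed)
  out <- matrix(0, n, length(u), dimnames = list(NULL, nm))
  for (j in seq_along(u)) {
    lo <- u[[j]] * (1 - X / 100)
    hi <- u[[j]] * (1 + X / 100)
    out[, j] <- pmin(pmax(stats::runif(n, lo, hi), lower[[nm[j]]]),
                     upper[[nm[j]]])
  }
  tibble::as_tibble(out)
}

ROBUSTNESS_METRICS <- c("P0", "tau_50", "tau_pm10", "tau_90", "P_max")

#' Summarise robustness of a design front to parametric uncertainty
#'
#' Given baseline metrics for each design of a front and the metrics of
#' perturbed replicates, computes the percentage change of five metrics
#' (`P0`, `tau_50`, `tau_pm10`, `tau_90`, `P_max`) of every replicate versus
#' its own stored baseline, then:
#' \itemize{
#'   \item per design and perturbation level: mean and standard deviation of
#'     each percentage change;
#'   \item front-wide (pooling all replicates of all designs) standard
#'     deviation per level -- the headline robustness number;
#'   \item the fraction of replicates that lose the `tau_pm10 = tau_90`
#'     property (a discrete short-term failure mode).
#' }
#' Baseline designs with `tau_pm10 != tau_90` (exceedingly poor short-term
#' performance) are excluded from the baseline set. Replicates with a
#' "not reached" (non-finite) value for a metric are excluded from that
#' metric's statistics, with the exclusion count reported.
#'
#' @param baseline Tibble: one row per design with a `design` id column and
#'   the five metric columns (plus optionally `tau_pm10_reached` etc.).
#' @param perturbed Tibble: one row per replicate with `design`, `X`
#'   (perturbation level in percent), `replicate`, and the five metric
#'   columns.
#' @return A `robustness_report`: list with `per_design` (design x level
#'   stats), `front` (level-wide standard deviations and failure fractions),
#'   `excluded_designs`, `n_excluded_values`.
#' @export
robustness_summary <- function(baseline, perturbed) {
  need <- c("design", ROBUSTNESS_METRICS)
  if (!all(need %in% names(baseline))) {
    stop("baseline needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c(need, "X") %in% names(perturbed))) {
    stop("perturbed needs columns: ", paste(c(need, "X"), collapse = ", "),
         call. = FALSE)
  }
  eq_tol <- 1e-8
  base_ok <- abs(baseline$tau_pm10 - baseline$tau_90) <=
    eq_tol * pmax(1, abs(baseline$tau_90))
  excluded <- baseline$design[!base_ok]
  baseline <- baseline[base_ok, ]
  perturbed <- perturbed[perturbed$design %in% baseline$design, ]

  pct <- perturbed |>
    dplyr::inner_join(baseline[, need], by = "design",
                      suffix = c("", "_base"))
  for (m in ROBUSTNESS_METRICS) {
    pct[[paste0("pct_", m)]] <-
      100 * (pct[[m]] - pct[[paste0(m, "_base")]]) / pct[[paste0(m, "_base")]]
  }
  pct$fail_band <- abs(pct$tau_pm10 - pct$tau_90) >
    eq_tol * pmax(1, abs(pct$tau_90))

  n_excluded_values <- sum(!is.finite(as.matrix(
    pct[, paste0("pct_", ROBUSTNESS_METRICS)])))

  per_design <- pct |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(paste0("pct_", ROBUSTNESS_METRICS)),
                    list(mean = ~mean(.x[is.finite(.x)]),
                         sd = ~stats::sd(.x[is.finite(.x)]))),
      fail_fraction = mean(.data$fail_band),
      n = dplyr::n(),
      .by = c("design", "X"))

  front <- pct |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(paste0("pct_", ROBUSTNESS_METRICS)),
                    ~stats::sd(.x[is.finite(.x)]), .names = "{.col}_sd"),
      fail_fraction = mean(.data$fail_band),
      n = dplyr::n(),
      .by = "X")

  structure(list(per_design = per_design, front = front,
                 excluded_designs = excluded,
                 n_excluded_values = n_excluded_values),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  for (i in seq_len(nrow(x$front))) {
    r <- x$front[i, ]
    cat(sprintf(
      "  +/-%g%%: sd(P0) %.1f%%, sd(tau_pm10) %.1f%%, sd(tau_50) %.1f%%; %.1f%% lose tau_pm10 = tau_90\n",
      r$X, r$pct_P0_sd, r$pct_tau_pm10_sd, r$pct_tau_50_sd,
      100 * r$fail_fraction))
  }
  if (length(x$excluded_designs) > 0) {
    cat("  excluded baseline designs (tau_pm10 != tau_90):",
        length(x$excluded_designs), "\n")
  }
  invisible(x)
}

#' Robustness analysis of a Pareto front by simulation
#'
#' For each design of a front (excluding those with baseline
#' `tau_pm10 != tau_90`), generates `n` perturbed replicates per
#' perturbation level via [perturb_parameters()] (clipped to the topology's
#' design-space bounds), re-evaluates every replicate through the full
#' evolutionary simulation, and summarises with [robustness_summary()].
#' Percentage changes are computed against the stored baseline metrics of
#' the front, not re-evaluated baselines.
#'
#' @param front A `pareto_front` from [pareto_optimize()], or a tibble of
#'   designs with decision-variable columns plus the five metric columns.
#' @param topology,n_B Required when `front` is a bare tibble.
#' @param X Perturbation levels in percent (default `c(10, 25)`).
#' @param n Replicates per design per level (default 100).
#' @param seed Integer seed.
#' @inheritParams evaluate_design
#' @return A `robustness_report` (see [robustness_summary()]), with the raw
#'   `perturbed` evaluations attached.
#' @export
robustness_analysis <- function(front, topology = NULL, n_B = 300,
                                X = c(10, 25), n = 100, seed = 1,
                                host = host_params(), scheme = NULL,
                                protocol = batch_protocol(),
                                record_every = 20, k_seq = 0.1) {
  if (inherits(front, "pareto_front")) {
    topology <- front$topology
    n_B <- front$n_B
    designs <- front$front
    space <- front$space
  } else {
    if (is.null(topology)) stop("`topology` required for a bare design table",
                                call. = FALSE)
    designs <- tibble::as_tibble(front)
    space <- design_space(topology)
  }
  pars <- intersect(space$param, names(designs))
  lower <- stats::setNames(space$lower, space$param)[pars]
  upper <- stats::setNames(space$upper, space$param)[pars]
  designs$design <- seq_len(nrow(designs))

  reps <- list()
  for (i in designs$design) {
    base <- designs[i, ]
    if (abs(base$tau_pm10 - base$tau_90) >
        1e-8 * max(1, abs(base$tau_90))) next
    u <- unlist(base[, pars])
    for (x_lvl in X) {
      uu <- perturb_parameters(u, x_lvl, lower, upper, n = n,
                               seed = seed + 1000 * i + x_lvl)
      for (r in seq_len(nrow(uu))) {
        met <- tryCatch(
          evaluate_design(topology, unlist(uu[r, ]), n_B = n_B, host = host,
                          scheme = scheme, protocol = protocol,
                          record_every = record_every, k_seq = k_seq),
          error = function(e) NULL)
        if (is.null(met)) next
        reps[[length(reps) + 1]] <- dplyr::bind_cols(
          tibble::tibble(design = i, X = x_lvl, replicate = r),
          met[, c(ROBUSTNESS_METRICS)])
      }
    }
  }
  perturbed <- dplyr::bind_rows(reps)
  rep_summary <- robustness_summary(
    designs[, c("design", ROBUSTNESS_METRICS)], perturbed)
  rep_summary$perturbed <- perturbed
  rep_summary
}
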