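test_that("population output is the strain-weighted protein sum", {
  expect_equal(total_output(c(10, 20), c(5, 1)), 70)
  expect_equal(total_output(c(10, 20), c(0, 0)), 0)
  set.seed(1)
  N <- runif(8, 0, 1e4); p <- runif(8, 0, 1e3)
  o <- sample(8)
  expect_equal(total_output(N[o], p[o]), total_output(N, p))
  expect_error(total_output(1:3, 1:2), "same length")
})

test_that("crossing times match closed forms on synthetic traces", {
  t <- seq(0, 100, by = 0.5)
  # linear decline P0*(1 - t/100): band exit and 90%-crossing at t=10,
  # half-life at t=50
  ct <- crossing_times(t, 100 * (1 - t / 100), P0 = 100)
  expect_equal(ct$tau_pm10, 10)
  expect_equal(ct$tau_90, 10)
  expect_equal(ct$tau_50, 50)
  expect_false(ct$band_exit_upper)
  # rising trace P0*(1 + t/50): exits the band upward at t=5; the falling
  # thresholds are never reached
  ct <- crossing_times(t, 100 * (1 + t / 50), P0 = 100)
  expect_equal(ct$tau_pm10, 5)
  expect_true(ct$band_exit_upper)
  expect_equal(ct$tau_90, Inf)
  expect_equal(ct$tau_50, Inf)
  expect_false(ct$tau_50_reached)
  # constant trace: nothing is ever crossed
  ct <- crossing_times(t, rep(100, length(t)), P0 = 100)
  expect_false(any(ct$tau_pm10_reached, ct$tau_90_reached, ct$tau_50_reached))
  expect_equal(ct$P_max, 100)
  expect_error(crossing_times(t, t, P0 = 0), "positive")
})

test_that("tau metrics are invariant under uniform output rescaling", {
  t <- seq(0, 60, by = 1)
  P <- 100 * exp(-t / 20) * (1 + 0.05 * sin(t))
  a <- crossing_times(t, P, 100)
  b <- crossing_times(t, 1e6 * P, 1e8)
  expect_equal(a$tau_pm10, b$tau_pm10)
  expect_equal(a$tau_90, b$tau_90)
  expect_equal(a$tau_50, b$tau_50)
})

test_that("cumulative output integrates flux times population", {
  # constant flux rectangle: T_L_A = 2 per cell/min, N = 1000, 10 min
  trace <- tidyr::crossing(time = seq(0, 10, by = 1), strain = 1) |>
    dplyr::mutate(N = 1000, T_L_A = 2)
  expect_equal(cumulative_output(trace, t_end = 10), 20000)
  # additivity over strains: two half-sized strains equal one merged strain
  half <- tidyr::crossing(time = seq(0, 10, by = 1), strain = 1:2) |>
    dplyr::mutate(N = 500, T_L_A = 2)
  expect_equal(cumulative_output(half, t_end = 10), 20000)
  expect_error(cumulative_output(trace), "t_end")
  expect_error(cumulative_output(dplyr::select(trace, -"T_L_A"), t_end = 1),
               "T_L_A")
})

test_that("quadrature refinement barely changes a smooth cumulative output", {
  f <- function(t) 3 * exp(-t / 200)
  mk <- function(dt) {
    tidyr::crossing(time = seq(0, 400, by = dt), strain = 1) |>
      dplyr::mutate(N = 800, T_L_A = f(.data$time))
  }
  q_coarse <- cumulative_output(mk(20), t_end = 400)
  q_fine <- cumulative_output(mk(10), t_end = 400)
  expect_lt(abs(q_fine - q_coarse) / q_fine, 1e-3)
})

test_that("open-loop reference interpolates the non-overburdened branch", {
  sweep <- tibble::tibble(
    omega_A = c(1, 2, 3),
    P0 = c(1, 2, 3),
    tau_pm10 = c(110, 90, 70),
    tau_50 = c(100, 80, 60))
  ref <- build_openloop_reference(sweep)
  expect_equal(predict(ref, 2.5, metric = "tau_50"), 70)
  expect_equal(predict(ref, 2.5, metric = "tau_pm10"), 80)
  expect_error(predict(ref, 10), "outside the reference domain")
  expect_error(predict(ref, 2.5, metric = "Q"), "not in reference")

  # a folded sweep: only the prefix up to the P0 argmax is retained
  folded <- tibble::tibble(
    omega_A = 1:6,
    P0 = c(1, 3, 6, 8, 5, 2),              # overburdened beyond omega_A = 4
    tau_pm10 = c(60, 50, 40, 30, 20, 10),
    tau_50 = c(65, 55, 45, 35, 25, 15))
  ref2 <- build_openloop_reference(folded)
  expect_equal(nrow(ref2$branch), 4)
  expect_equal(max(ref2$branch$omega_A), 4)
  # retained tau is non-increasing in P0
  expect_true(all(diff(ref2$branch$tau_50) <= 0))
})

test_that("percentage change against the equal-output open loop", {
  sweep <- tibble::tibble(omega_A = 1:3, P0 = c(1, 2, 3),
                          tau_pm10 = c(110, 90, 70),
                          tau_50 = c(100, 80, 60),
                          Q = c(10, 20, 30))
  ref <- build_openloop_reference(sweep)
  self <- tibble::tibble(P0 = 2, tau_pm10 = 90, tau_50 = 80, Q = 20)
  out <- percent_change_vs_openloop(self, ref)
  expect_equal(out$pct_tau_pm10, 0)
  expect_equal(out$pct_tau_50, 0)
  expect_equal(out$pct_Q, 0)
  doubled <- tibble::tibble(P0 = 2, tau_pm10 = 90, tau_50 = 160, Q = 20)
  expect_equal(percent_change_vs_openloop(doubled, ref)$pct_tau_50, 100)
  worse <- tibble::tibble(P0 = 2, tau_pm10 = 45, tau_50 = 40, Q = 5)
  out <- percent_change_vs_openloop(worse, ref)
  expect_lt(out$pct_tau_50, 0)             # under-performing designs go negative
  expect_lt(out$pct_Q, 0)
})

test_that("design metrics of a run assemble the endpoint-series crossings", {
  run <- toy_run_ol()
  m <- design_metrics(run)
  ep <- endpoint_series(run, unit = "day")
  ct <- crossing_times(ep$time, ep$P, run$P0)
  expect_equal(m$tau_50, ct$tau_50)
  expect_equal(m$tau_pm10, ct$tau_pm10)
  expect_equal(m$P0, run$P0)
  expect_gte(m$P_max, m$P0 * 0.999)
  expect_gt(m$Q, 0)
  # Q is additive over time segments: integrating to an interior day plus
  # the remainder equals the whole
  t_mid <- run$days$time[2]
  t_end <- max(run$trace$time)
  q_all <- cumulative_output(run$trace, t_end = t_end)
  q_a <- cumulative_output(dplyr::filter(run$trace, .data$time <= t_mid),
                           t_end = t_mid)
  q_b <- cumulative_output(dplyr::filter(run$trace, .data$time >= t_mid),
                           t_end = t_end)
  expect_equal(q_a + q_b, q_all, tolerance = 1e-10)
})
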