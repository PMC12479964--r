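test_that("strain competition matches the exponential closed form", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  scheme <- mutation_scheme(1, base_rate = 0)      # pure competition
  lat <- ol_lattice_steady()
  cells <- do.call(rbind, lapply(lat, `[[`, "state"))
  colnames(cells) <- circ$species
  lambdas <- vapply(lat, `[[`, numeric(1), "lambda")
  N0 <- c(1000, 1000, 1000, 1000)
  built <- evostab:::make_population_rhs(host, circ, scheme)
  # huge substrate bolus: consumption over 100 min is negligible, so each
  # strain stays on its balanced-growth path and N_i(t) = N_i(0) e^(lambda_i t)
  y0 <- c(1e18, N0, as.numeric(cells))
  out <- deSolve::ode(y = y0, times = c(0, 100), func = built$rhs,
                      parms = NULL, method = "lsoda",
                      atol = 1e-12, rtol = 1e-10)
  N_end <- out[2, 1 + built$i_N]
  expected <- N0 * exp(lambdas * 100)
  expect_equal(as.numeric(N_end), expected, tolerance = 1e-6)
  # pairwise ratio oracle, e.g. strains 1 vs 4
  expect_equal(N_end[[1]] / N_end[[4]],
               exp((lambdas[1] - lambdas[4]) * 100), tolerance = 1e-6)
})

test_that("mutation redistributes cells without creating them at equal growth", {
  host <- toy_host()
  # omega_A = 0 makes all four strains dynamically identical (equal lambda)
  circ <- toy_ol_circuit(0)
  ss <- as.numeric(toy_ol_steady(0))
  cells <- matrix(rep(ss, each = 4), 4, dimnames = list(NULL, circ$species))
  run_total <- function(base_rate) {
    scheme <- mutation_scheme(1, base_rate = base_rate)
    built <- evostab:::make_population_rhs(host, circ, scheme)
    y0 <- c(1e18, c(1000, 0, 0, 0), as.numeric(cells))
    out <- deSolve::ode(y = y0, times = c(0, 200), func = built$rhs,
                        parms = NULL, method = "lsoda",
                        atol = 1e-10, rtol = 1e-10)
    sum(out[2, 1 + built$i_N])
  }
  expect_equal(run_total(0), run_total(2e-3), tolerance = 1e-8)
})

test_that("a day without substrate produces no growth", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  scheme <- mutation_scheme(1, base_rate = 0)
  # starved cells: no external substrate, exhausted internal pools
  cells <- matrix(rep(as.numeric(toy_ol_steady(5)), each = 4), 4,
                  dimnames = list(NULL, circ$species))
  cells[, "s_i"] <- 0
  cells[, "a"] <- 0
  pop <- list(s_X = 0, N = c(1000, 0, 0, 0), cells = cells)
  day <- run_batch_day(pop, host, circ, scheme,
                       protocol = batch_protocol(day_length = 480))
  expect_equal(sum(day$end$N), 1000, tolerance = 1e-6)
})

test_that("substrate is consumed monotonically while cells import", {
  cfg <- fixture_toy_system("OL")
  run <- toy_run_ol()
  sx <- run$trace |>
    dplyr::filter(.data$strain == 1, .data$day == 1)
  expect_lt(sx$s_X[nrow(sx)], sx$s_X[1])
  expect_true(all(diff(sx$s_X) <= 1e-6 * max(sx$s_X)))
})

test_that("final day-1 population grows with the substrate bolus", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  scheme <- mutation_scheme(1, base_rate = 0)
  cells <- matrix(rep(as.numeric(toy_ol_steady(5)), each = 4), 4,
                  dimnames = list(NULL, circ$species))
  totals <- vapply(c(5e10, 2e11, 8e11), function(sx) {
    pop <- list(s_X = sx, N = c(500, 0, 0, 0), cells = cells)
    day <- run_batch_day(pop, host, circ, scheme,
                         protocol = batch_protocol(day_length = 1440))
    sum(day$end$N)
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("dilution rescales strains proportionally and resets substrate", {
  proto <- batch_protocol(sample_size = 1000, substrate_reset = 1e12)
  pop <- list(s_X = 3, N = c(9000, 3000), cells = matrix(1, 2, 3), H = 6)
  d <- dilute(pop, proto)
  expect_equal(d$N, c(750, 250))
  expect_equal(d$s_X, 1e12)
  expect_equal(d$cells, pop$cells)          # intracellular states carried over
  pop1 <- list(s_X = 3, N = 5e6, cells = matrix(1, 1, 3))
  d1 <- dilute(pop1, proto)
  expect_equal(d1$N, 1000)
  expect_error(dilute(list(s_X = 1, N = c(0, 0)), proto), "extinct")
})

test_that("multinomial dilution is seeded and reproducible", {
  proto <- batch_protocol(sample_size = 1000)
  pop <- list(s_X = 3, N = c(9000, 3000), cells = matrix(1, 2, 3))
  d1 <- dilute(pop, proto, mode = "multinomial", seed = 11)
  d2 <- dilute(pop, proto, mode = "multinomial", seed = 11)
  d3 <- dilute(pop, proto, mode = "multinomial", seed = 12)
  expect_identical(d1$N, d2$N)
  expect_false(identical(d1$N, d3$N))
  expect_equal(sum(d1$N), 1000)
})

test_that("without mutation the daily-endpoint output is constant", {
  cfg <- fixture_toy_system("OL")
  run <- run_evolution(cfg$circuit, cfg$host_params,
                       scheme = mutation_scheme(1, base_rate = 0),
                       protocol = cfg$batch_protocol,
                       record_every = cfg$record_every)
  P <- run$days$P
  expect_equal(nrow(run$days), cfg$batch_protocol$max_days)  # no stop triggered
  expect_true(all(abs(P / P[1] - 1) < 1e-3))       # constant to 0.1 percent
  expect_equal(P[1], run$P0, tolerance = 1e-3)
})

test_that("stored population output is recomputable from the trace", {
  run <- toy_run_ol()
  recomputed <- run$trace |>
    dplyr::summarise(P = sum(.data$N * .data$p_A), .by = c("day", "time"))
  expect_equal(run$output$P, recomputed$P)
  # day endpoints agree with the trace at the same instants
  at_days <- recomputed |>
    dplyr::filter(.data$time == .data$day * run$protocol$day_length)
  expect_equal(at_days$P, run$days$P, tolerance = 1e-6)
})

test_that("the trace is stable under halving the sampling interval", {
  cfg <- fixture_toy_system("OL")
  proto <- batch_protocol(day_length = 480, sample_size = 500,
                          substrate_reset = 2e11, max_days = 2)
  r1 <- run_evolution(cfg$circuit, cfg$host_params, scheme = cfg$scheme,
                      protocol = proto, record_every = 40)
  r2 <- run_evolution(cfg$circuit, cfg$host_params, scheme = cfg$scheme,
                      protocol = proto, record_every = 20)
  expect_equal(r1$days$P, r2$days$P, tolerance = 1e-6)
  expect_equal(r1$P0, r2$P0, tolerance = 1e-6)
})

test_that("population_odes exposes consistent derivatives and diagnostics", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  scheme <- mutation_scheme(1)
  cells <- matrix(rep(as.numeric(toy_ol_steady(5)), each = 4), 4,
                  dimnames = list(NULL, circ$species))
  pop <- list(s_X = 1e12, N = c(1000, 0, 0, 0), cells = cells)
  d <- population_odes(pop, host, circ, scheme)
  expect_named(d, c("ds_X", "dN", "dcells", "lambda", "P"))
  expect_lt(d$ds_X, 0)
  expect_equal(d$P, 1000 * cells[1, "p_A"], ignore_attr = TRUE)
  # ancestral strain grows, mutation drains a little into strain 2
  expect_gt(d$dN[2], 0)
  expect_error(population_odes(list(s_X = 1, N = 1:3, cells = cells),
                               host, circ, scheme), "strains")
  expect_error(run_evolution(circ, host, scheme = mutation_scheme(2)),
               "mutable promoter")
})
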