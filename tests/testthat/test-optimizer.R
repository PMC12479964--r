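# Analytic two-objective toy: maximise f1 = u, f2 = 1 - u on [0, 1].
# Every u is Pareto-optimal; the true front is the segment f1 + f2 = 1.
toy_fn <- function(u) c(u[["x"]], 1 - u[["x"]], 0)

test_that("NSGA-II recovers the analytic front of the toy problem", {
  res <- nsga2(toy_fn, lower = c(x = 0), upper = c(x = 1), n_obj = 3,
               settings = ga_settings(pop_size = 24, generations = 12),
               seed = 7, log_scale = FALSE)
  expect_gt(nrow(res$X), 5)
  expect_gte(min(res$X[, "x"]), 0)
  expect_lte(max(res$X[, "x"]), 1)
  # front spans most of [0,1]
  expect_lt(min(res$X[, "x"]), 0.15)
  expect_gt(max(res$X[, "x"]), 0.85)
  # brute-force dominance check: no grid point dominates a returned point
  grid <- seq(0, 1, by = 0.001)
  gobj <- cbind(grid, 1 - grid, 0)
  for (i in seq_len(nrow(res$obj))) {
    dominated <- (gobj[, 1] >= res$obj[i, 1]) & (gobj[, 2] >= res$obj[i, 2]) &
      ((gobj[, 1] > res$obj[i, 1]) | (gobj[, 2] > res$obj[i, 2]))
    expect_equal(sum(dominated), 0)
  }
  # no returned point dominates another
  fr <- evostab:::non_dominated_sort(res$obj)
  expect_true(all(fr == 1))
})

test_that("NSGA-II is deterministic given a seed", {
  a <- nsga2(toy_fn, c(x = 0), c(x = 1), 3,
             ga_settings(pop_size = 16, generations = 6), seed = 3,
             log_scale = FALSE)
  b <- nsga2(toy_fn, c(x = 0), c(x = 1), 3,
             ga_settings(pop_size = 16, generations = 6), seed = 3,
             log_scale = FALSE)
  expect_identical(a$X, b$X)
  expect_identical(a$obj, b$obj)
})

test_that("larger populations do not shrink the toy front's hypervolume", {
  hv <- function(res) {
    # 2-D hypervolume against reference (0,0) for a maximisation front
    o <- res$obj[order(res$obj[, 1]), 1:2, drop = FALSE]
    sum(diff(c(0, o[, 1])) * o[, 2])
  }
  small <- nsga2(toy_fn, c(x = 0), c(x = 1), 3,
                 ga_settings(pop_size = 8, generations = 10), seed = 5,
                 log_scale = FALSE)
  big <- nsga2(toy_fn, c(x = 0), c(x = 1), 3,
               ga_settings(pop_size = 32, generations = 10), seed = 5,
               log_scale = FALSE)
  expect_gte(hv(big), hv(small) - 0.02)
})

test_that("non-dominated sorting and crowding behave on known sets", {
  obj <- rbind(c(1, 1), c(2, 0.5), c(0.5, 2),   # mutually non-dominated
               c(0.5, 0.5), c(0.25, 0.25))      # dominated layers
  fr <- evostab:::non_dominated_sort(obj)
  expect_equal(fr, c(1, 1, 1, 2, 3))
  cd <- evostab:::crowding_distance(obj[fr == 1, ])
  expect_true(all(is.infinite(cd[c(2, 3)])))    # extremes kept
  expect_true(is.finite(cd[1]))
})

test_that("decision vectors map onto circuits faithfully", {
  u <- c(omega_A = 12, omega_C = 80, k_B = 250, b_B = 0.5)
  circ <- design_circuit("CLpATL", u, n_B = 600)
  expect_equal(circ$omega[["A"]], 12)
  expect_equal(circ$omega[["C"]], 80)
  expect_equal(circ$genes$B$b, 0.5)
  expect_equal(circ$genes$B$n_aa, 600)
  expect_equal(circ$genes$A$n_aa, 300)
  expect_equal(circ$params$k_B, 250)
  expect_error(design_circuit("CLpATL", c(omega_A = 12, omega_C = 80,
                                          b_B = 0.5)), "k_B")
  # every topology has a coherent design space
  for (topo in topologies()) {
    sp <- design_space(topo)
    expect_true(all(sp$upper > sp$lower))
    u_mid <- stats::setNames(sqrt(sp$lower * sp$upper), sp$param)
    expect_s3_class(design_circuit(topo, u_mid), "circuit_spec")
  }
})

test_that("a one-point sweep equals a direct evaluation", {
  cfg <- fixture_toy_system("OL")
  tab <- sweep_designs("OL", tibble::tibble(omega_A = 5),
                       host = cfg$host_params, scheme = cfg$scheme,
                       protocol = cfg$batch_protocol,
                       record_every = cfg$record_every)
  expect_equal(nrow(tab), 1)
  expect_false(tab$failed)
  direct <- evaluate_design("OL", c(omega_A = 5), host = cfg$host_params,
                            scheme = cfg$scheme,
                            protocol = cfg$batch_protocol,
                            record_every = cfg$record_every)
  expect_equal(tab$P0, direct$P0)
  expect_equal(tab$tau_50, direct$tau_50)
  expect_equal(tab$Q, direct$Q)
})

test_that("sweep evaluation is order-independent and failure-tolerant", {
  cfg <- fixture_toy_system("OL")
  grid <- tibble::tibble(omega_A = c(2, 8))
  t1 <- sweep_designs("OL", grid, host = cfg$host_params, scheme = cfg$scheme,
                      protocol = cfg$batch_protocol,
                      record_every = cfg$record_every)
  t2 <- sweep_designs("OL", grid[2:1, ], host = cfg$host_params,
                      scheme = cfg$scheme, protocol = cfg$batch_protocol,
                      record_every = cfg$record_every)
  expect_equal(dplyr::arrange(t1, .data$omega_A),
               dplyr::arrange(t2, .data$omega_A))
  # an invalid design is flagged, not fatal
  bad <- sweep_designs("OL", tibble::tibble(omega_A = c(5, -1)),
                       host = cfg$host_params, scheme = cfg$scheme,
                       protocol = cfg$batch_protocol,
                       record_every = cfg$record_every)
  expect_equal(bad$failed, c(FALSE, TRUE))
  expect_true(!is.na(bad$error[2]))
})
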