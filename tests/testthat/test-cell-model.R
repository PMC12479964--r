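test_that("a source-free circuit contributes only decay terms", {
  host <- toy_host()
  circ0 <- toy_ol_circuit(0)
  # circuit species at zero stay exactly at zero
  ss <- initial_cell_state(host, circ0)
  expect_identical(unname(ss[c("m_A", "c_A", "p_A")]), c(0, 0, 0))
  d <- cell_odes(ss, host, circ0)
  expect_identical(unname(d[c("m_A", "c_A", "p_A")]), c(0, 0, 0))
  # a stray protein with no source just dilutes away at rate lambda
  st <- ss
  st["p_A"] <- 500
  d <- cell_odes(st, host, circ0)
  lam <- growth_rate(st, host, circ0)$lambda
  expect_equal(d[["p_A"]], -lam * 500)
})

test_that("transcription-energy flag at zero coefficient is a no-op", {
  circ <- toy_ol_circuit(5)
  st <- random_cell_state(circ)
  h_off <- host_params(transcription_cost = FALSE)
  h_on0 <- host_params(transcription_cost = TRUE, xi_nt = 0)
  expect_identical(cell_odes(st, h_off, circ), cell_odes(st, h_on0, circ))
})

test_that("transcription-energy burden lowers steady-state growth", {
  circ <- toy_ol_circuit(5)
  h_on <- host_params(transcription_cost = TRUE, xi_nt = 0.2)
  ss_on <- initial_cell_state(h_on, circ)
  ss_off <- toy_ol_steady(5)
  expect_lt(attr(ss_on, "lambda"), attr(ss_off, "lambda"))
})

test_that("growth rate follows the elongation law", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  st <- random_cell_state(circ)
  # no translation complexes -> no growth
  st0 <- st
  st0[grep("^c_", names(st0))] <- 0
  expect_equal(growth_rate(st0, host, circ)$lambda, 0)
  # anabolite exhausted -> no growth
  st_a <- st
  st_a["a"] <- 0
  expect_equal(growth_rate(st_a, host, circ)$lambda, 0)
  # saturating anabolite: lambda -> gamma_max * c_tot / M in closed form
  st_big <- st
  st_big["a"] <- 1e12
  ctot <- sum(st_big[grep("^c_", names(st_big))])
  expect_equal(growth_rate(st_big, host, circ)$lambda,
               host$gamma_max * ctot / host$M, tolerance = 1e-9)
  # monotone non-decreasing in the anabolite pool
  lams <- vapply(c(0.1, 1, 10, 100, 1e4), function(a) {
    s <- st; s["a"] <- a
    growth_rate(s, host, circ)$lambda
  }, numeric(1))
  expect_true(all(diff(lams) > 0))
  # per-gene translation flux for the process gene
  gr <- growth_rate(st, host, circ)
  gam <- host$gamma_max * st[["a"]] / (host$K_gamma + st[["a"]])
  expect_equal(unname(gr$T_L["A"]), gam * st[["c_A"]] / 300)
})

test_that("steady-state initialisation lands on a fixed point", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  ss <- toy_ol_steady(5)
  expect_lt(attr(ss, "residual"), 1e-9)
  # integrating 100 min forward barely moves any state
  rhs <- function(t, y, p) {
    list(cell_odes(setNames(pmax(y, 0), circ$species), host, circ))
  }
  out <- deSolve::ode(y = as.numeric(ss), times = c(0, 100), func = rhs,
                      parms = NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-8)
  drift <- abs(out[2, -1] - as.numeric(ss)) / (abs(as.numeric(ss)) + 1)
  expect_lt(max(drift), 1e-6)
})

test_that("transient integration from an arbitrary start reaches the same fixed point", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  ss <- toy_ol_steady(5)
  y0 <- random_cell_state(circ, seed = 7)
  rhs <- function(t, y, p) {
    list(cell_odes(setNames(pmax(y, 0), circ$species), host, circ))
  }
  out <- deSolve::ode(y = as.numeric(y0), times = c(0, 2e5), func = rhs,
                      parms = NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-8, maxsteps = 5e5)
  y_end <- out[nrow(out), -1]
  expect_equal(as.numeric(y_end), as.numeric(ss), tolerance = 1e-4)
})

test_that("steady-state growth declines with circuit burden", {
  host <- toy_host()
  lams <- vapply(c(0, 2, 10, 50), function(w) {
    attr(initial_cell_state(host, toy_ol_circuit(w)), "lambda")
  }, numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("ribosome bookkeeping balances at arbitrary states", {
  # d/dt(free ribosomes + all complexes) = ribosome synthesis - dilution:
  # binding/unbinding/release fluxes must cancel pairwise
  host <- toy_host()
  circ <- build_circuit(
    "CLpATL",
    genes = list(A = gene_spec(omega = 50), B = gene_spec(),
                 C = srna_spec(omega = 100)),
    params = controller_params(k_B = 500))
  for (seed in 1:5) {
    st <- random_cell_state(circ, seed)
    d <- cell_odes(st, host, circ)
    gr <- growth_rate(st, host, circ)
    gam <- host$gamma_max * st[["a"]] / (host$K_gamma + st[["a"]])
    nu_r <- gam * st[["c_r"]] / host$n_r
    c_cols <- grep("^c_", names(st), value = TRUE)
    pool <- d[["R"]] + sum(d[c_cols])
    expect_equal(pool,
                 nu_r - gr$lambda * (st[["R"]] + sum(st[c_cols])),
                 tolerance = 1e-10)
  }
})

test_that("binding fluxes appear with opposite signs in mRNA and complex", {
  # flux consistency: perturbing only the binding rate changes dm and dc by
  # equal and opposite amounts
  host1 <- host_params(k_b = 1)
  host2 <- host_params(k_b = 1.5)
  circ <- toy_ol_circuit(5)
  st <- random_cell_state(circ, 3)
  d1 <- cell_odes(st, host1, circ)
  d2 <- cell_odes(st, host2, circ)
  for (g in c("r", "t", "m", "q")) {
    dm <- d2[[paste0("m_", g)]] - d1[[paste0("m_", g)]]
    dc <- d2[[paste0("c_", g)]] - d1[[paste0("c_", g)]]
    expect_equal(dm, -dc, tolerance = 1e-10)
  }
})

test_that("cell state validation catches malformed inputs", {
  host <- toy_host()
  circ <- toy_ol_circuit(5)
  st <- random_cell_state(circ)
  bad <- st
  names(bad)[3] <- "mystery"
  expect_error(cell_odes(bad, host, circ), "species mismatch")
  neg <- st
  neg[1] <- -1
  expect_error(cell_odes(neg, host, circ), "non-negative")
  expect_error(cell_odes(st[-1], host, circ), "species mismatch")
  expect_error(cell_odes(st, host, circ,
                         mutation_levels = c(Z = 0.5)), "non-mutable")
})
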