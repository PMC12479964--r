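test_that("circuit builders register the right species and mutable promoters", {
  ol <- build_circuit("OL", genes = list(A = gene_spec(omega = 5)))
  expect_equal(ol$n_mutable, 1)
  expect_true(all(c("m_A", "c_A", "p_A") %in% ol$species))
  expect_false("r_C" %in% ol$species)

  clpatl <- build_circuit(
    "CLpATL",
    genes = list(A = gene_spec(omega = 50), B = gene_spec(n_aa = 300),
                 C = srna_spec(omega = 100)),
    params = controller_params(k_B = 500))
  expect_equal(clpatl$n_mutable, 2)                   # process + sRNA
  expect_setequal(clpatl$mutable_promoters, c("A", "C"))
  expect_true(all(c("m_B", "c_B", "p_B", "r_C") %in% clpatl$species))
  # sRNA silences both transcripts of the shared process promoter
  expect_setequal(clpatl$srna_targets, c("m_A", "m_B"))

  cllamtl <- build_circuit(
    "CLlamTL",
    genes = list(A = gene_spec(omega = 50), B = gene_spec(omega = 20),
                 C = srna_spec(omega = 100)),
    params = controller_params(k_B = 500, k_lambda = 0.005))
  expect_equal(cllamtl$n_mutable, 3)
  expect_equal(cllamtl$srna_targets, "m_A")
})

test_that("every topology builds and declares consistent species", {
  u <- c(omega_A = 10, omega_B = 10, omega_C = 50, k_A = 1000, k_B = 500,
         k_B1 = 500, k_B2 = 500, k_lambda = 0.005, k_P = 1e8,
         b_B = 1, b_B1 = 1, b_B2 = 1, k_syn = 1)
  for (topo in topologies()) {
    circ <- design_circuit(topo, u)
    expect_s3_class(circ, "circuit_spec")
    # the species consumed by the ODEs are exactly those declared
    st <- random_cell_state(circ)
    d <- cell_odes(st, toy_host(), circ, population_output = 1e6,
                   autoinducer = 100)
    expect_named(d, circ$species)
    expect_true(all(is.finite(d)))
    expect_true(circ$n_mutable %in% 1:3)
  }
})

test_that("build_circuit validates inputs", {
  expect_error(build_circuit("nope", genes = list()), "unknown topology")
  expect_error(build_circuit("OL", genes = list()), "requires genes: A")
  expect_error(
    build_circuit("OL", genes = list(A = gene_spec(omega = 5),
                                     B = gene_spec())),
    "does not use")
  expect_error(
    build_circuit("CLpATX",
                  genes = list(A = gene_spec(omega = 5), B = gene_spec())),
    "k_B")
  expect_warning(
    build_circuit("OL", genes = list(A = gene_spec(omega = 5)),
                  params = controller_params(k_B = 10)),
    "unused")
})

test_that("effective transcription applies the topology's regulation", {
  host <- toy_host()
  ol <- toy_ol_circuit(5)
  st <- initial_cell_state(host, ol)
  gr <- growth_rate(st, host, ol)
  # open loop: w = omega for any state
  expect_equal(unname(effective_transcription(ol, st, gr)["A"]), 5)
  st2 <- st; st2["p_A"] <- 12 * st[["p_A"]]
  expect_equal(unname(effective_transcription(ol, st2, gr)["A"]), 5)

  # product feedback at half-saturation halves the rate
  pa <- build_circuit("PHEN_PA", genes = list(A = gene_spec(omega = 8)),
                      params = controller_params(k_A = st[["p_A"]]))
  stp <- st[pa$species]
  expect_equal(unname(effective_transcription(pa, stp, gr)["A"]), 4)

  # dual-input factor is the product of the single-input factors
  lam <- build_circuit("PHEN_LAMBDA", genes = list(A = gene_spec(omega = 8)),
                       params = controller_params(k_lambda = 0.01))
  dual <- build_circuit("PHEN_DUAL", genes = list(A = gene_spec(omega = 8)),
                        params = controller_params(k_A = st[["p_A"]],
                                                   k_lambda = 0.01))
  w_pa <- effective_transcription(pa, stp, gr)["A"] / 8
  w_lam <- effective_transcription(lam, stp, gr)["A"] / 8
  w_dual <- effective_transcription(dual, stp, gr)["A"] / 8
  expect_equal(unname(w_dual), unname(w_pa * w_lam), tolerance = 1e-12)
})

test_that("regulatory factors stay in [0,1] across random states", {
  host <- toy_host()
  u <- c(omega_A = 10, omega_B = 10, omega_C = 50, k_A = 1000, k_B = 500,
         k_B1 = 500, k_B2 = 500, k_lambda = 0.005, k_P = 1e8,
         b_B = 1, b_B1 = 1, b_B2 = 1, k_syn = 1)
  for (topo in c("PHEN_PA", "PHEN_POP", "CLpATX", "CLlamTL", "CLpATLlamTX")) {
    circ <- design_circuit(topo, u)
    for (seed in 1:5) {
      st <- random_cell_state(circ, seed)
      gr <- growth_rate(st, host, circ)
      w <- effective_transcription(circ, st, gr, population_output = 10^seed)
      expect_true(all(w >= 0 & w <= circ$omega + 1e-12))
    }
  }
})

test_that("sequestration flux is bilinear and mass-balanced", {
  expect_equal(sequestration_flux(100, 0, 1e-3), 0)
  expect_equal(sequestration_flux(100, 50, 1e-3), 5)
  expect_error(sequestration_flux(-1, 2, 1), ">= 0")

  # in the assembled ODEs the flux removes one mRNA and one sRNA per event
  host <- toy_host()
  circ <- build_circuit(
    "CLpATL",
    genes = list(A = gene_spec(omega = 50), B = gene_spec(),
                 C = srna_spec(omega = 100)),
    params = controller_params(k_B = 500, k_seq = 0.2))
  circ0 <- build_circuit(
    "CLpATL",
    genes = list(A = gene_spec(omega = 50), B = gene_spec(),
                 C = srna_spec(omega = 100)),
    params = controller_params(k_B = 500, k_seq = 0))
  st <- random_cell_state(circ)
  d1 <- cell_odes(st, host, circ)
  d0 <- cell_odes(st, host, circ0)
  flux_A <- 0.2 * st[["m_A"]] * st[["r_C"]]
  flux_B <- 0.2 * st[["m_B"]] * st[["r_C"]]
  expect_equal(d1[["m_A"]] - d0[["m_A"]], -flux_A)
  expect_equal(d1[["m_B"]] - d0[["m_B"]], -flux_B)
  expect_equal(d1[["r_C"]] - d0[["r_C"]], -(flux_A + flux_B))
})

test_that("limiting controllers collapse to the uncontrolled co-expression system", {
  host <- toy_host()
  # CLpATX with k_B -> infinity: repression vanishes...
  cl_tx <- build_circuit("CLpATX",
                         genes = list(A = gene_spec(omega = 5), B = gene_spec()),
                         params = controller_params(k_B = 1e12))
  ss_tx <- initial_cell_state(host, cl_tx)
  gr <- growth_rate(ss_tx, host, cl_tx)
  expect_equal(unname(effective_transcription(cl_tx, ss_tx, gr)["A"]) / 5, 1,
               tolerance = 1e-6)
  # ...and CLpATL with no sRNA production and no sequestration: both reduce
  # to the same two-gene co-expression system without control
  cl_tl <- build_circuit("CLpATL",
                         genes = list(A = gene_spec(omega = 5), B = gene_spec(),
                                      C = srna_spec(omega = 0)),
                         params = controller_params(k_B = 500, k_seq = 0))
  ss_tl <- initial_cell_state(host, cl_tl)
  expect_equal(ss_tl[["p_A"]], ss_tx[["p_A"]], tolerance = 1e-6)
  expect_equal(attr(ss_tl, "lambda"), attr(ss_tx, "lambda"), tolerance = 1e-6)
  # the co-expressed controller protein still costs ribosomes, so growth sits
  # below the single-gene open loop
  expect_lt(attr(ss_tx, "lambda"), attr(toy_ol_steady(5), "lambda"))
})

test_that("host parameter YAML round-trips exactly", {
  hp <- host_params(w_r = 931.5, xi_nt = 0.25, transcription_cost = TRUE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_host_params(hp, path)
  hp2 <- read_host_params(path)
  expect_identical(unclass(hp), unclass(hp2))
  # unknown keys rejected
  writeLines("host:\n  nonsense: 1", path)
  expect_error(read_host_params(path), "unknown host parameter")
})
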