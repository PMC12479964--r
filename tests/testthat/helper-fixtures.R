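# Shared fixtures: built once per test session, memoised by name.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

toy_host <- function() fixture("host", host_params)

toy_ol_circuit <- function(omega = 5) {
  fixture(paste0("ol_", omega), function() {
    build_circuit("OL", genes = list(A = gene_spec(omega = omega)))
  })
}

# Ancestral steady state for an open-loop circuit (expensive; memoised)
toy_ol_steady <- function(omega = 5) {
  fixture(paste0("ol_ss_", omega), function() {
    initial_cell_state(toy_host(), toy_ol_circuit(omega))
  })
}

toy_run_ol <- function() {
  fixture("toy_run_ol", function() simulate_config(fixture_toy_system("OL")))
}

toy_run_clpatl <- function() {
  fixture("toy_run_clpatl", function() {
    simulate_config(fixture_toy_system("CLpATL"))
  })
}

# Per-strain steady states for the open-loop lattice: each strain at its own
# balanced-growth fixed point (mutated omega), used to pin growth rates.
ol_lattice_steady <- function() {
  fixture("ol_lattice_steady", function() {
    host <- toy_host()
    lapply(c(1, 0.67, 0.33, 0), function(lv) {
      circ <- build_circuit("OL", genes = list(A = gene_spec(omega = 5 * lv)))
      ss <- initial_cell_state(host, circ)
      list(state = as.numeric(ss), lambda = attr(ss, "lambda"))
    })
  })
}

# A small random cell state (valid, positive) for a circuit
random_cell_state <- function(circuit, seed = 1) {
  set.seed(seed)
  stats::setNames(stats::runif(length(circuit$species), 0, 1000),
                  circuit$species)
}
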