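# Host species, fixed order. s_i internal substrate, a anabolite/energy,
# R free ribosomes, then (mRNA, translation complex, protein) for the
# transporter (t), metabolic (m) and housekeeping (q) classes; ribosomes have
# no separate protein species (R is the protein).
HOST_SPECIES <- c("s_i", "a", "R",
                  "m_r", "c_r",
                  "m_t", "c_t", "p_t",
                  "m_m", "c_m", "p_m",
                  "m_q", "c_q", "p_q")

SRNA_NT_LENGTH <- 100  # nt, used only by the transcription-energy extension

# Vectorised single-cell field: one row of `Y` per strain, columns named by
# circuit$species. Everything downstream (public cell_odes, the population
# ODE) is a thin wrapper around this.
#
# omega_scale: matrix (strains x mutable promoters) of functional levels in
# [0,1]; NULL means fully functional.
#
# Returns list(dY, lambda, T_L (strains x protein genes, proteins/min),
# import (strains), qs_synth (strains; autoinducer synthesis per cell)).
cell_field <- function(Y, host, circuit, s_X, P = 0, H = 0, omega_scale = NULL) {
  hp <- host
  genes <- names(circuit$proteins)
  has_srna <- !is.null(circuit$srna)

  a <- Y[, "a"]
  a_pos <- pmax(a, 0)
  si_pos <- pmax(Y[, "s_i"], 0)
  sx_pos <- max(s_X, 0)
  R <- Y[, "R"]

  gam <- hp$gamma_max * a_pos / (hp$K_gamma + a_pos)

  c_cols <- paste0("c_", c("r", "t", "m", "q", genes))
  ctot <- rowSums(Y[, c_cols, drop = FALSE])
  lambda <- gam * ctot / hp$M

  # substrate import and catabolism
  import <- Y[, "p_t"] * hp$v_t * sx_pos / (hp$K_t + sx_pos)
  vcat <- Y[, "p_m"] * hp$v_m * si_pos / (hp$K_m + si_pos)

  # host transcription (anabolite-saturated; housekeeping autoinhibited)
  sat_r <- a_pos / (hp$theta_r + a_pos)
  sat_nr <- a_pos / (hp$theta_nr + a_pos)
  tx_r <- hp$w_r * sat_r
  tx_t <- hp$w_t * sat_nr
  tx_m <- hp$w_m * sat_nr
  tx_q <- hp$w_q * sat_nr / (1 + (pmax(Y[, "p_q"], 0) / hp$K_q)^hp$h_q)

  # circuit transcription: effective maximal promoter rates under mutation
  # scaling and the controller's regulatory factors, then host saturation
  sp <- lapply(paste0("p_", genes), function(cn) Y[, cn])
  names(sp) <- paste0("p_", genes)
  fac <- regulatory_factors(circuit$topology, circuit$params, sp, lambda,
                            P = P, H = H)
  n_strain <- nrow(Y)
  w_prom <- matrix(rep(circuit$omega, each = n_strain), nrow = n_strain,
                   dimnames = list(NULL, circuit$promoters))
  if (!is.null(omega_scale)) {
    for (pr in colnames(omega_scale)) {
      w_prom[, pr] <- w_prom[, pr] * omega_scale[, pr]
    }
  }
  for (pr in names(fac)) w_prom[, pr] <- w_prom[, pr] * fac[[pr]]

  dY <- Y * 0

  # ribosome pool bookkeeping accumulators
  bind_sum <- 0
  unbind_sum <- 0
  nu_sum <- 0

  host_gene <- function(m, c, tx, kb, ku, n_aa, dm) {
    bind <- kb * R * Y[, m]
    unbind <- ku * Y[, c]
    nu <- gam * Y[, c] / n_aa
    dY[, m] <<- dY[, m] + tx - bind + unbind + nu - dm * Y[, m] - lambda * Y[, m]
    dY[, c] <<- dY[, c] + bind - unbind - nu - lambda * Y[, c]
    bind_sum <<- bind_sum + bind
    unbind_sum <<- unbind_sum + unbind
    nu_sum <<- nu_sum + nu
    nu
  }

  nu_r <- host_gene("m_r", "c_r", tx_r, hp$k_b, hp$k_u, hp$n_r, hp$d_m)
  nu_t <- host_gene("m_t", "c_t", tx_t, hp$k_b, hp$k_u, hp$n_t, hp$d_m)
  nu_m <- host_gene("m_m", "c_m", tx_m, hp$k_b, hp$k_u, hp$n_m, hp$d_m)
  nu_q <- host_gene("m_q", "c_q", tx_q, hp$k_b, hp$k_u, hp$n_q, hp$d_m)
  dY[, "p_t"] <- nu_t - lambda * Y[, "p_t"]
  dY[, "p_m"] <- nu_m - lambda * Y[, "p_m"]
  dY[, "p_q"] <- nu_q - lambda * Y[, "p_q"]

  tx_cost <- 0
  if (hp$transcription_cost && hp$xi_nt > 0) {
    tx_cost <- hp$xi_nt * (3 * hp$n_r * tx_r + 3 * hp$n_t * tx_t +
                             3 * hp$n_m * tx_m + 3 * hp$n_q * tx_q)
  }

  T_L <- matrix(0, n_strain, length(genes), dimnames = list(NULL, genes))
  for (g in genes) {
    gs <- circuit$genes[[g]]
    pr <- circuit$proteins[[g]]
    tx_g <- w_prom[, pr] * sat_nr
    m <- paste0("m_", g); cc <- paste0("c_", g); p <- paste0("p_", g)
    nu_g <- host_gene(m, cc, tx_g, gs$b, gs$k_u, gs$n_aa, gs$d_m)
    dY[, p] <- nu_g - lambda * Y[, p]
    T_L[, g] <- nu_g
    if (hp$transcription_cost && hp$xi_nt > 0) {
      tx_cost <- tx_cost + hp$xi_nt * 3 * gs$n_aa * tx_g
    }
  }

  qs_synth <- rep(0, n_strain)
  if (circuit$qs) {
    qs_synth <- circuit$params$k_syn * pmax(Y[, "p_B"], 0)
  }

  if (has_srna) {
    tx_c <- w_prom[, "C"] * sat_nr
    r <- Y[, "r_C"]
    dr <- tx_c - circuit$srna$d_r * r - lambda * r
    for (m in circuit$srna_targets) {
      seq_flux <- circuit$params$k_seq * Y[, m] * r
      dY[, m] <- dY[, m] - seq_flux
      dr <- dr - seq_flux
    }
    dY[, "r_C"] <- dr
    if (hp$transcription_cost && hp$xi_nt > 0) {
      tx_cost <- tx_cost + hp$xi_nt * SRNA_NT_LENGTH * tx_c
    }
  }

  # free ribosomes: synthesis (nu_r) + release on every completion
  dY[, "R"] <- nu_r + nu_sum - bind_sum + unbind_sum - lambda * R

  dY[, "s_i"] <- import - vcat - lambda * Y[, "s_i"]
  dY[, "a"] <- hp$n_s * vcat - gam * ctot - tx_cost - lambda * a

  list(dY = dY, lambda = lambda, T_L = T_L, import = import,
       qs_synth = qs_synth)
}

#' Time-derivatives of a single cell's molecular state
#'
#' The mechanistic single-cell model: transcription at controller-regulated
#' effective rates (scaled by anabolite availability), ribosome binding and
#' unbinding, translation completion that consumes anabolites and releases
#' ribosome plus protein, mRNA/sRNA degradation, sRNA sequestration, and
#' dilution of every species by growth `lambda * species`. Growth rate is
#' emergent: total translation flux normalised by cell mass.
#'
#' @param state Named numeric vector over exactly the species registered by
#'   the circuit (see `circuit$species`), all finite and non-negative, in
#'   molecules per cell.
#' @param host A [host_params()] object.
#' @param circuit A `circuit_spec` from [build_circuit()].
#' @param s_X External substrate pool (molecules).
#' @param population_output Population-wide output `P` (molecules), input to
#'   population-based controllers.
#' @param autoinducer Shared quorum-sensing autoinducer pool (molecules).
#' @param mutation_levels Optional named vector of functional levels in
#'   `[0, 1]` for the circuit's mutable promoters (default: fully
#'   functional).
#'
#' @return Named numeric vector of time-derivatives (mc min^-1), same
#'   layout as `state`.
#' @export
cell_odes <- function(state, host, circuit, s_X = 1e12,
                      population_output = 0, autoinducer = 0,
                      mutation_levels = NULL) {
  stopifnot(inherits(host, "host_params"), inherits(circuit, "circuit_spec"))
  check_cell_state(state, circuit)
  omega_scale <- NULL
  if (!is.null(mutation_levels)) {
    bad <- setdiff(names(mutation_levels), circuit$mutable_promoters)
    if (length(bad) > 0) {
      stop("mutation level given for non-mutable promoter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    omega_scale <- matrix(1, 1, length(circuit$mutable_promoters),
                          dimnames = list(NULL, circuit$mutable_promoters))
    omega_scale[1, names(mutation_levels)] <- mutation_levels
  }
  Y <- matrix(state[circuit$species], 1, length(circuit$species),
              dimnames = list(NULL, circuit$species))
  f <- cell_field(Y, host, circuit, s_X, P = population_output,
                  H = autoinducer, omega_scale = omega_scale)
  stats::setNames(as.numeric(f$dY[1, ]), circuit$species)
}

check_cell_state <- function(state, circuit) {
  if (is.null(names(state)) || !setequal(names(state), circuit$species) ||
      length(state) != length(circuit$species)) {
    missing <- setdiff(circuit$species, names(state))
    extra <- setdiff(names(state), circuit$species)
    stop(sprintf(
      "state species mismatch for topology %s%s%s", circuit$topology,
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else ""
    ), call. = FALSE)
  }
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("cell state must be finite and non-negative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Growth rate and per-gene translation fluxes
#'
#' Growth is total translation flux normalised by cell mass:
#' `lambda = gamma(a) * (sum of all translation complexes) / M`, where
#' `gamma(a)` is the anabolite-saturated elongation rate. With no translation
#' complexes, or with the anabolite pool exhausted, `lambda = 0`. The
#' translation flux of gene `g` is `T_L_g = gamma(a) * c_g / n_g`
#' (proteins cell^-1 min^-1); for the process gene this is the per-cell
#' production rate used by the cumulative-output metric.
#'
#' @inheritParams cell_odes
#' @param circuit Optional `circuit_spec`; when supplied, per-gene
#'   translation fluxes for the circuit genes are reported.
#'
#' @return A `growth_output` list: `lambda` (min^-1) and `T_L`, a named
#'   vector of per-gene translation fluxes (host classes and circuit genes).
#' @export
growth_rate <- function(state, host, circuit = NULL) {
  stopifnot(inherits(host, "host_params"))
  if (any(!is.finite(state)) || any(state < 0)) {
    stop("cell state must be finite and non-negative", call. = FALSE)
  }
  a <- max(state[["a"]], 0)
  gam <- host$gamma_max * a / (host$K_gamma + a)
  c_cols <- grep("^c_", names(state), value = TRUE)
  ctot <- sum(state[c_cols])
  lambda <- gam * ctot / host$M
  n_by <- c(c_r = host$n_r, c_t = host$n_t, c_m = host$n_m, c_q = host$n_q)
  if (!is.null(circuit)) {
    for (g in names(circuit$proteins)) {
      n_by[[paste0("c_", g)]] <- circuit$genes[[g]]$n_aa
    }
  }
  T_L <- vapply(c_cols, function(cn) {
    if (cn %in% names(n_by)) gam * state[[cn]] / n_by[[cn]] else NA_real_
  }, numeric(1))
  names(T_L) <- sub("^c_", "", c_cols)
  structure(list(lambda = lambda, T_L = T_L), class = "growth_output")
}

#' Ancestral steady-state cell state
#'
#' Computes the balanced-growth steady state of [cell_odes()] under
#' nutrient-replete conditions (fixed external substrate), used as the day-0
#' state of the fully functional strain. The state is found by long stiff
#' integration (to `t_max` min) with a convergence check on the residual
#' derivative; if the residual has not fallen below `tol` the integration is
#' extended once before failing with the final residual.
#'
#' Circuit species are seeded at zero, so a circuit with zero transcription
#' keeps them exactly zero.
#'
#' @inheritParams cell_odes
#' @param n_context Number of cells assumed when a population-coupled input
#'   (population output, autoinducer pool) must be made self-consistent at
#'   steady state (default: the batch protocol's sample size, 1000).
#' @param t_max Integration horizon (min).
#' @param tol Convergence tolerance on `max |dx/dt| / (|x| + 1)` (min^-1).
#'
#' @return Named numeric steady-state vector over `circuit$species`, with
#'   attributes `lambda` (steady-state growth rate), `residual`, and, for
#'   quorum-sensing circuits, `autoinducer`.
#' @export
initial_cell_state <- function(host, circuit, s_X = 1e12, n_context = 1000,
                               t_max = 1e5, tol = 1e-9) {
  stopifnot(inherits(host, "host_params"), inherits(circuit, "circuit_spec"))
  sp <- circuit$species
  y0 <- stats::setNames(rep(0, length(sp)), sp)
  y0[HOST_SPECIES] <- c(s_i = 100, a = 100, R = 10,
                        m_r = 1, c_r = 1, m_t = 1, c_t = 1, p_t = 10,
                        m_m = 1, c_m = 1, p_m = 10,
                        m_q = 1, c_q = 1, p_q = 10)[HOST_SPECIES]
  qs <- circuit$qs
  if (qs) y0 <- c(y0, H = 0)

  rhs <- function(t, y, parms) {
    Y <- matrix(y[sp], 1, dimnames = list(NULL, sp))
    P <- if (circuit$topology == "PHEN_POP") n_context * max(y[["p_A"]], 0) else 0
    H <- if (qs) max(y[["H"]], 0) else 0
    f <- cell_field(Y, host, circuit, s_X, P = P, H = H)
    dy <- as.numeric(f$dY[1, ])
    if (qs) {
      dH <- n_context * f$qs_synth[1] - circuit$params$d_H * y[["H"]]
      dy <- c(dy, dH)
    }
    list(dy)
  }

  integrate_leg <- function(y, t_end) {
    out <- deSolve::ode(y = y, times = c(0, t_end), func = rhs, parms = NULL,
                        method = "lsoda", atol = 1e-10, rtol = 1e-8,
                        maxsteps = 5e5)
    yy <- out[nrow(out), -1]
    stats::setNames(as.numeric(yy), names(y))
  }

  resid_of <- function(y) {
    dy <- rhs(0, y, NULL)[[1]]
    max(abs(dy) / (abs(y) + 1))
  }

  y <- integrate_leg(y0, t_max)
  res <- resid_of(y)
  if (res > tol) {
    y <- integrate_leg(y, 10 * t_max)
    res <- resid_of(y)
  }
  if (res > tol) {
    stop(sprintf(
      "steady-state initialisation did not converge: residual %.3g > tol %.3g",
      res, tol), call. = FALSE)
  }
  H <- if (qs) y[["H"]] else NULL
  out <- pmax(y[sp], 0)
  gr <- growth_rate(out, host, circuit)
  attr(out, "lambda") <- gr$lambda
  attr(out, "residual") <- res
  if (qs) attr(out, "autoinducer") <- max(H, 0)
  out
}
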