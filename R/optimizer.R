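#' Decision-variable space of a controller topology
#'
#' The tunable kinetic parameters searched when designing each controller,
#' with biologically feasible bounds. Rate-like parameters span decades and
#' are searched in log10 space.
#'
#' @param topology Topology identifier (see [topologies()]).
#' @return A tibble: `param`, `lower`, `upper`, `log` (search in log space).
#' @export
design_space <- function(topology) {
  def <- topology_def(topology)   # validates the name
  b <- function(param, lower, upper) {
    tibble::tibble(param = param, lower = lower, upper = upper, log = TRUE)
  }
  omega <- function(p) b(p, 0.1, 1000)        # mc min^-1
  kprot <- function(p) b(p, 1, 1e5)           # mc
  bbind <- function(p) b(p, 1e-3, 10)         # mc^-1 min^-1
  klam <- b("k_lambda", 1e-4, 0.1)            # min^-1
  kpop <- b("k_P", 1e6, 1e12)                 # molecules
  sp <- switch(topology,
    OL          = omega("omega_A"),
    PHEN_PA     = rbind(omega("omega_A"), kprot("k_A")),
    PHEN_LAMBDA = rbind(omega("omega_A"), klam),
    PHEN_POP    = rbind(omega("omega_A"), kpop),
    PHEN_DUAL   = rbind(omega("omega_A"), kprot("k_A"), klam),
    CLpATX      = rbind(omega("omega_A"), kprot("k_B"), bbind("b_B")),
    CLpATL      = rbind(omega("omega_A"), omega("omega_C"), kprot("k_B"),
                        bbind("b_B")),
    CLlamTX     = rbind(omega("omega_A"), omega("omega_B"), kprot("k_B"),
                        bbind("b_B"), klam),
    CLlamTL     = rbind(omega("omega_A"), omega("omega_B"), omega("omega_C"),
                        kprot("k_B"), bbind("b_B"), klam),
    CLlamPF     = rbind(omega("omega_A"), omega("omega_C"), klam),
    QS_POP      = rbind(omega("omega_A"), kpop, bbind("b_B"),
                        b("k_syn", 0.01, 10)),
    CLpATXlamTL = rbind(omega("omega_A"), omega("omega_B"), omega("omega_C"),
                        kprot("k_B1"), kprot("k_B2"), bbind("b_B1"),
                        bbind("b_B2"), klam),
    CLpATLlamTX = rbind(omega("omega_A"), omega("omega_B"), omega("omega_C"),
                        kprot("k_B1"), kprot("k_B2"), bbind("b_B1"),
                        bbind("b_B2"), klam),
    CLpATLlamTL = rbind(omega("omega_A"), omega("omega_B"), omega("omega_C"),
                        kprot("k_B1"), kprot("k_B2"), bbind("b_B1"),
                        bbind("b_B2"), klam),
    CLpATXlamTX = rbind(omega("omega_A"), omega("omega_B"), kprot("k_B1"),
                        kprot("k_B2"), bbind("b_B1"), bbind("b_B2"), klam),
    CLpATLlamPF = rbind(omega("omega_A"), omega("omega_C"), kprot("k_B1"),
                        bbind("b_B1"), klam)
  )
  sp
}

#' Build a circuit from a named decision vector
#'
#' Maps the optimiser's decision vector `u` (named as in [design_space()])
#' onto a [build_circuit()] call: `omega_X` set promoter strengths, `b_X`
#' ribosome binding rates of controller proteins, `k_*` controller
#' regulation constants.
#'
#' @param topology Topology identifier.
#' @param u Named numeric decision vector.
#' @param n_B Controller protein length (aa) applied to every controller
#'   protein gene (1, 300 and 600 aa are the standard scan values).
#' @param n_A Process protein length (aa).
#' @param k_seq sRNA sequestration rate constant.
#' @param d_H Autoinducer decay rate (quorum topology only).
#' @return A `circuit_spec`.
#' @export
design_circuit <- function(topology, u, n_B = 300, n_A = 300, k_seq = 0.1,
                           d_H = 0.05) {
  def <- topology_def(topology)
  u <- as.list(u)
  gene_names <- names(def$proteins)
  genes <- list()
  for (g in gene_names) {
    owns <- which(unlist(def$proteins) == def$proteins[[g]])[1] == match(g, gene_names)
    omega_key <- paste0("omega_", def$proteins[[g]])
    genes[[g]] <- gene_spec(
      omega = if (owns) (u[[omega_key]] %||% NA_real_) else NA_real_,
      b = u[[paste0("b_", g)]] %||% 1,
      n_aa = if (g == "A") n_A else n_B
    )
  }
  if (!is.null(def$srna)) {
    genes$C <- srna_spec(omega = u[["omega_C"]] %||% NA_real_)
  }
  par_args <- list(k_seq = k_seq)
  for (nm in def$params) {
    if (nm == "k_seq") next
    if (nm == "d_H") { par_args$d_H <- u[["d_H"]] %||% d_H; next }
    par_args[[nm]] <- u[[nm]] %||%
      stop(sprintf("decision vector is missing `%s`", nm), call. = FALSE)
  }
  suppressWarnings(
    build_circuit(topology, genes, do.call(controller_params, par_args))
  )
}

#' Evaluate one controller design
#'
#' Runs the full evolutionary simulation for a design and returns its
#' longevity/production metrics. The "not reached" tau values are reported as
#' `Inf` with flags; [pareto_optimize()] caps them at the simulation horizon
#' when ranking.
#'
#' @inheritParams design_circuit
#' @param host,scheme,protocol Passed to [run_evolution()]; `scheme`
#'   defaults to the topology's lattice at the default mutation rates.
#' @param record_every Trace sampling interval (min).
#' @return A one-row tibble: the decision vector columns, then the metrics
#'   of [design_metrics()].
#' @export
evaluate_design <- function(topology, u, n_B = 300, host = host_params(),
                            scheme = NULL, protocol = batch_protocol(),
                            record_every = 20, k_seq = 0.1) {
  circuit <- design_circuit(topology, u, n_B = n_B, k_seq = k_seq)
  run <- run_evolution(circuit, host, scheme = scheme, protocol = protocol,
                       record_every = record_every)
  dplyr::bind_cols(tibble::as_tibble(as.list(u)), design_metrics(run))
}

#' Full-factorial design sweep
#'
#' Evaluates every design in a parameter grid through the evolutionary
#' simulation. Evaluation is order-independent; designs whose simulation
#' fails are kept as rows flagged `failed` with the error message, not
#' dropped.
#'
#' @param topology Topology identifier.
#' @param grid A data frame with one column per decision variable (e.g. from
#'   [expand.grid()] or [tidyr::crossing()]) and one row per design.
#' @inheritParams evaluate_design
#' @param .progress Print a line per design.
#' @return A tibble: grid columns, metrics columns, `failed`, `error`.
#' @export
sweep_designs <- function(topology, grid, n_B = 300, host = host_params(),
                          scheme = NULL, protocol = batch_protocol(),
                          record_every = 20, k_seq = 0.1, .progress = FALSE) {
  grid <- tibble::as_tibble(grid)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    u <- unlist(grid[i, ])
    res <- tryCatch(
      evaluate_design(topology, u, n_B = n_B, host = host, scheme = scheme,
                      protocol = protocol, record_every = record_every,
                      k_seq = k_seq),
      error = function(e) {
        dplyr::bind_cols(grid[i, ],
                         tibble::tibble(topology = topology,
                                        failed = TRUE,
                                        error = conditionMessage(e)))
      })
    if (!"failed" %in% names(res)) {
      res$failed <- FALSE
      res$error <- NA_character_
    }
    if (.progress) {
      message(sprintf("[%d/%d] %s", i, nrow(grid),
                      paste(names(u), signif(u, 3), sep = "=", collapse = " ")))
    }
    res
  })
  dplyr::bind_rows(rows)
}

#' Sweep the open-loop transcription rate
#'
#' Convenience wrapper: log-spaced `omega_A` sweep of the open loop, the
#' input of [build_openloop_reference()]. The default grid size (30) is a
#' desk-scale setting; the full-reproduction setting uses thousands of
#' designs over the same range.
#'
#' @param n Number of designs.
#' @param range `omega_A` range (mc min^-1), default 0.1 to 1000.
#' @inheritParams sweep_designs
#' @return The [sweep_designs()] table.
#' @export
sweep_openloop <- function(n = 30, range = c(0.1, 1000), host = host_params(),
                           scheme = NULL, protocol = batch_protocol(),
                           record_every = 20, .progress = FALSE) {
  grid <- tibble::tibble(omega_A = 10^seq(log10(range[1]), log10(range[2]),
                                          length.out = n))
  sweep_designs("OL", grid, host = host, scheme = scheme, protocol = protocol,
                record_every = record_every, .progress = .progress)
}

## ---- NSGA-II ---------------------------------------------------------------

#' Genetic-algorithm settings for multi-objective design
#'
#' Defaults follow the reference setting (population 250, Pareto fraction
#' 0.4); `ga_settings_desk()` is a scaled-down preset for desk-scale runs.
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param pareto_fraction Fraction of the population returned as the front.
#' @param eta_c,eta_m SBX crossover / polynomial mutation distribution
#'   indices.
#' @param p_c Crossover probability.
#' @param p_m Per-variable mutation probability (default `1/n_var`).
#' @return A `ga_settings` list.
#' @export
ga_settings <- function(pop_size = 250, generations = 100,
                        pareto_fraction = 0.4, eta_c = 15, eta_m = 20,
                        p_c = 0.9, p_m = NULL) {
  structure(list(pop_size = pop_size, generations = generations,
                 pareto_fraction = pareto_fraction, eta_c = eta_c,
                 eta_m = eta_m, p_c = p_c, p_m = p_m),
            class = "ga_settings")
}

#' @rdname ga_settings
#' @export
ga_settings_desk <- function() ga_settings(pop_size = 40, generations = 30)

# Fast non-dominated sort (maximisation). Returns integer front index per row.
non_dominated_sort <- function(obj) {
  n <- nrow(obj)
  dominated_by <- integer(n)            # count of points dominating i
  dominates <- vector("list", n)        # indices i dominates
  for (i in seq_len(n)) {
    oi <- obj[i, ]
    ge <- sweep(obj, 2, oi, `>=`)
    gt <- sweep(obj, 2, oi, `>`)
    dom_over_i <- rowSums(ge) == ncol(obj) & rowSums(gt) > 0   # j dominates i
    le <- sweep(obj, 2, oi, `<=`)
    lt <- sweep(obj, 2, oi, `<`)
    i_dom <- rowSums(le) == ncol(obj) & rowSums(lt) > 0        # i dominates j
    dominated_by[i] <- sum(dom_over_i)
    dominates[[i]] <- which(i_dom)
  }
  front <- integer(n)
  current <- which(dominated_by == 0)
  level <- 1L
  remaining <- dominated_by
  while (length(current) > 0) {
    front[current] <- level
    nxt <- integer(0)
    for (i in current) {
      for (j in dominates[[i]]) {
        remaining[j] <- remaining[j] - 1L
        if (remaining[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- unique(nxt)
    level <- level + 1L
  }
  front
}

# Crowding distance within one front (maximisation or not -- symmetric).
crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2)], k]) / rng
    }
  }
  d
}

# SBX crossover of two parents in [0,1]^n
sbx_crossover <- function(p1, p2, eta) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

# Polynomial mutation in [0,1]^n
poly_mutation <- function(x, p_m, eta) {
  mutate <- stats::runif(length(x)) < p_m
  if (!any(mutate)) return(x)
  u <- stats::runif(sum(mutate))
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  x[mutate] <- pmin(pmax(x[mutate] + delta, 0), 1)
  x
}

#' NSGA-II multi-objective maximisation
#'
#' A standard real-coded NSGA-II (fast non-dominated sorting, crowding
#' distance, binary tournament, simulated binary crossover, polynomial
#' mutation), maximising all objectives, deterministic given `seed`.
#'
#' @param fn Function mapping a named numeric vector (within bounds) to a
#'   numeric vector of objectives to maximise. Evaluation failures should be
#'   handled inside `fn`; see [pareto_optimize()].
#' @param lower,upper Named bound vectors.
#' @param n_obj Number of objectives.
#' @param settings A [ga_settings()].
#' @param seed Integer seed.
#' @param log_scale Logical vector: search that variable in log10 space.
#' @param vectorize_cache Memoise evaluations by parameter value.
#' @return A list: `X` (matrix of evaluated decision vectors on the final
#'   non-dominated front), `obj` (their objectives), `front` (front index of
#'   the final population), `n_eval`.
#' @export
nsga2 <- function(fn, lower, upper, n_obj, settings = ga_settings(),
                  seed = 1, log_scale = rep(TRUE, length(lower)),
                  vectorize_cache = TRUE) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  n_var <- length(lower)
  p_m <- settings$p_m %||% (1 / n_var)
  set.seed(seed)

  lo <- ifelse(log_scale, log10(lower), lower)
  hi <- ifelse(log_scale, log10(upper), upper)
  decode <- function(z) {
    x <- lo + z * (hi - lo)
    x <- ifelse(log_scale, 10^x, x)
    names(x) <- names(lower)
    x
  }

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  eval_z <- function(z) {
    key <- paste(format(z, digits = 12), collapse = ",")
    if (vectorize_cache && !is.null(cache[[key]])) return(cache[[key]])
    val <- fn(decode(z))
    n_eval <<- n_eval + 1L
    if (vectorize_cache) cache[[key]] <- val
    val
  }

  Z <- matrix(stats::runif(settings$pop_size * n_var), settings$pop_size)
  O <- t(apply(Z, 1, eval_z))
  if (n_obj == 1) O <- matrix(O, ncol = 1)

  for (gen in seq_len(settings$generations)) {
    fr <- non_dominated_sort(O)
    cd <- numeric(nrow(O))
    for (f in unique(fr)) {
      idx <- which(fr == f)
      cd[idx] <- crowding_distance(O[idx, , drop = FALSE])
    }
    tournament <- function() {
      ij <- sample.int(nrow(Z), 2)
      i <- ij[1]; j <- ij[2]
      if (fr[i] < fr[j] || (fr[i] == fr[j] && cd[i] > cd[j])) i else j
    }
    kids <- matrix(0, settings$pop_size, n_var)
    k <- 1
    while (k <= settings$pop_size) {
      p1 <- Z[tournament(), ]; p2 <- Z[tournament(), ]
      if (stats::runif(1) < settings$p_c) {
        cr <- sbx_crossover(p1, p2, settings$eta_c)
      } else {
        cr <- list(p1, p2)
      }
      kids[k, ] <- poly_mutation(cr[[1]], p_m, settings$eta_m)
      if (k + 1 <= settings$pop_size) {
        kids[k + 1, ] <- poly_mutation(cr[[2]], p_m, settings$eta_m)
      }
      k <- k + 2
    }
    Ok <- t(apply(kids, 1, eval_z))
    if (n_obj == 1) Ok <- matrix(Ok, ncol = 1)
    Zall <- rbind(Z, kids)
    Oall <- rbind(O, Ok)
    fr <- non_dominated_sort(Oall)
    keep <- integer(0)
    for (f in sort(unique(fr))) {
      idx <- which(fr == f)
      if (length(keep) + length(idx) <= settings$pop_size) {
        keep <- c(keep, idx)
      } else {
        cdf <- crowding_distance(Oall[idx, , drop = FALSE])
        need <- settings$pop_size - length(keep)
        keep <- c(keep, idx[order(cdf, decreasing = TRUE)[seq_len(need)]])
        break
      }
    }
    Z <- Zall[keep, , drop = FALSE]
    O <- Oall[keep, , drop = FALSE]
  }

  fr <- non_dominated_sort(O)
  nd <- which(fr == 1)
  dec <- apply(Z[nd, , drop = FALSE], 1, decode)
  X <- if (n_var == 1) matrix(dec, ncol = 1) else t(dec)
  colnames(X) <- names(lower)
  list(X = X, obj = O[nd, , drop = FALSE], front = fr, n_eval = n_eval)
}

#' Tri-objective Pareto design of a controller
#'
#' Maximises `(P0, tau_pm10, tau_50)` over the topology's decision space
#' (see [design_space()]) with NSGA-II, each evaluation being a full
#' evolutionary simulation. Evaluations are cached by parameter value;
#' failed simulations receive worst-case fitness rather than aborting the
#' run; "not reached" tau values enter the optimiser capped at the
#' simulation horizon and are flagged in the returned table.
#'
#' @param topology Topology identifier.
#' @param n_B Controller protein length (aa).
#' @param settings A [ga_settings()] (use [ga_settings_desk()] for
#'   desk-scale runs).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param space Optional overriding design space (tibble as in
#'   [design_space()]).
#' @inheritParams evaluate_design
#' @return A `pareto_front` object: `front` (tibble of decision variables +
#'   metrics for the returned non-dominated designs, at most
#'   `pop_size * pareto_fraction` rows, crowding-selected), `settings`,
#'   `seed`, `n_eval`, `topology`, `n_B`.
#' @export
pareto_optimize <- function(topology, n_B = 300, settings = ga_settings_desk(),
                            seed = 1, host = host_params(), scheme = NULL,
                            protocol = batch_protocol(), record_every = 20,
                            k_seq = 0.1, space = NULL) {
  space <- space %||% design_space(topology)
  lower <- stats::setNames(space$lower, space$param)
  upper <- stats::setNames(space$upper, space$param)
  horizon <- protocol$max_days
  details <- new.env(parent = emptyenv())

  fn <- function(u) {
    key <- paste(format(u, digits = 12), collapse = ",")
    res <- tryCatch(
      evaluate_design(topology, u, n_B = n_B, host = host, scheme = scheme,
                      protocol = protocol, record_every = record_every,
                      k_seq = k_seq),
      error = function(e) NULL
    )
    if (is.null(res)) {
      details[[key]] <- NULL
      return(c(-Inf, -Inf, -Inf))
    }
    details[[key]] <- res
    c(res$P0, min(res$tau_pm10, horizon), min(res$tau_50, horizon))
  }

  raw <- nsga2(fn, lower, upper, n_obj = 3, settings = settings, seed = seed,
               log_scale = space$log)

  # crowding-select the reported front to pop_size * pareto_fraction
  n_keep <- max(1, min(nrow(raw$X),
                       ceiling(settings$pop_size * settings$pareto_fraction)))
  if (nrow(raw$X) > n_keep) {
    cd <- crowding_distance(raw$obj)
    sel <- order(cd, decreasing = TRUE)[seq_len(n_keep)]
  } else {
    sel <- seq_len(nrow(raw$X))
  }
  rows <- purrr::map(sel, function(i) {
    u <- raw$X[i, ]
    key <- paste(format(u, digits = 12), collapse = ",")
    details[[key]] %||%
      evaluate_design(topology, u, n_B = n_B, host = host, scheme = scheme,
                      protocol = protocol, record_every = record_every,
                      k_seq = k_seq)
  })
  structure(
    list(front = dplyr::bind_rows(rows), topology = topology, n_B = n_B,
         settings = settings, seed = seed, n_eval = raw$n_eval,
         space = space),
    class = "pareto_front"
  )
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf(
    "<pareto_front> %s (n_B = %d aa): %d design(s), %d evaluation(s), seed %d\n",
    x$topology, x$n_B, nrow(x$front), x$n_eval, x$seed))
  invisible(x)
}
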