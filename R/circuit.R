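#' Specify a circuit protein-coding gene
#'
#' @param omega Maximal transcription rate of the gene's promoter
#'   (mc min^-1). Ignored (with a warning at build time) for genes that are
#'   co-expressed from another gene's promoter.
#' @param b Ribosome binding rate of the transcript (mc^-1 min^-1).
#' @param k_u Ribosome unbinding rate (min^-1).
#' @param n_aa Protein length (aa). Controller proteins are typically scanned
#'   at 1, 300 or 600 aa.
#' @param d_m mRNA degradation rate (min^-1).
#'
#' @return A `gene_spec` object.
#' @export
gene_spec <- function(omega = NA_real_, b = 1, k_u = 1, n_aa = 300, d_m = 0.1) {
  if (!is.na(omega) && omega < 0) stop("`omega` must be >= 0", call. = FALSE)
  if (b < 0) stop("`b` must be >= 0", call. = FALSE)
  if (k_u < 0) stop("`k_u` must be >= 0", call. = FALSE)
  if (n_aa < 1) stop("`n_aa` must be >= 1 aa", call. = FALSE)
  if (d_m < 0) stop("`d_m` must be >= 0", call. = FALSE)
  structure(list(omega = omega, b = b, k_u = k_u, n_aa = n_aa, d_m = d_m),
            class = "gene_spec")
}

#' Specify a small-RNA gene
#'
#' sRNA genes produce a non-translated regulatory RNA: they have no ribosome
#' binding and no protein product, so they impose essentially no translational
#' burden -- the property that makes sRNA-mediated controllers cheap for the
#' host.
#'
#' @param omega Maximal transcription rate (mc min^-1).
#' @param d_r sRNA degradation rate (min^-1).
#' @return An `srna_spec` object.
#' @export
srna_spec <- function(omega = NA_real_, d_r = 0.1) {
  if (!is.na(omega) && omega < 0) stop("`omega` must be >= 0", call. = FALSE)
  if (d_r < 0) stop("`d_r` must be >= 0", call. = FALSE)
  structure(list(omega = omega, d_r = d_r), class = "srna_spec")
}

#' Controller kinetic parameters
#'
#' Regulation constants consumed by the controller topologies. Only the
#' constants referenced by the active topology are used; supplying a constant
#' a topology does not use triggers a warning at build time.
#'
#' @param k_A Intra-circuit (product) feedback threshold (mc).
#' @param k_lambda Growth feedback threshold (min^-1).
#' @param k_P Population feedback threshold (molecules).
#' @param k_B,k_B1,k_B2 Controller-protein regulation thresholds (mc).
#' @param h Hill coefficient shared by all regulatory factors (default 2).
#' @param k_seq sRNA-mRNA sequestration rate constant (mc^-1 min^-1).
#' @param k_syn Quorum-sensing autoinducer synthesis rate per synthase
#'   protein (min^-1).
#' @param d_H Autoinducer decay rate (min^-1).
#' @return A `controller_params` object.
#' @export
controller_params <- function(k_A = NA_real_, k_lambda = NA_real_,
                              k_P = NA_real_,
                              k_B = NA_real_, k_B1 = NA_real_, k_B2 = NA_real_,
                              h = 2, k_seq = 0.1,
                              k_syn = NA_real_, d_H = NA_real_) {
  p <- list(k_A = k_A, k_lambda = k_lambda, k_P = k_P,
            k_B = k_B, k_B1 = k_B1, k_B2 = k_B2,
            h = h, k_seq = k_seq, k_syn = k_syn, d_H = d_H)
  for (nm in setdiff(names(p), c("h", "k_seq"))) {
    if (!is.na(p[[nm]]) && p[[nm]] <= 0) {
      stop(sprintf("controller parameter `%s` must be > 0 where supplied", nm),
           call. = FALSE)
    }
  }
  if (p$h <= 0) stop("`h` must be > 0", call. = FALSE)
  if (p$k_seq < 0) stop("`k_seq` must be >= 0", call. = FALSE)
  structure(p, class = "controller_params")
}

#' sRNA-mRNA sequestration flux
#'
#' Irreversible bimolecular co-degradation: an sRNA molecule binds a target
#' mRNA and both are removed (the mRNA is silenced and degraded, preventing
#' its translation). The flux is bilinear in the two species.
#'
#' @param m Target mRNA level (mc).
#' @param r sRNA level (mc).
#' @param rate_constant Second-order rate constant (mc^-1 min^-1).
#' @return Flux in mc min^-1; each flux unit removes one mRNA and one sRNA.
#' @export
sequestration_flux <- function(m, r, rate_constant) {
  if (any(m < 0) || any(r < 0)) stop("`m` and `r` must be >= 0", call. = FALSE)
  rate_constant * m * r
}

## ---- topology registry -----------------------------------------------------

#' Names of all supported circuit/controller topologies
#' @return Character vector of topology identifiers.
#' @export
topologies <- function() {
  c("OL",
    "PHEN_PA", "PHEN_LAMBDA", "PHEN_POP", "PHEN_DUAL",
    "CLpATX", "CLpATL", "CLlamTX", "CLlamTL", "CLlamPF", "QS_POP",
    "CLpATXlamTL", "CLpATLlamTX", "CLpATLlamTL", "CLpATXlamTX", "CLpATLlamPF")
}

# Shorthand for a regulation rule: `op` is how the signal acts on the
# promoter ("repress"/"activate"), `input` is where the signal comes from
# ("species" = a per-cell protein, "lambda" = growth rate, "P" = population
# output, "H" = shared autoinducer), `k` names the controller parameter
# holding the threshold.
rule <- function(promoter, op, input, k, species = NA_character_) {
  list(promoter = promoter, op = op, input = input, k = k, species = species)
}

# Internal: static description of each topology.
#  proteins: named list gene -> promoter that drives it
#  srna: promoter of the sRNA gene C (or NULL)
#  mutable: mutable promoters
#  params: controller parameter names the topology consumes
#  rules: regulation rules; factors on the same promoter multiply
#  qs: has a shared autoinducer pool
topology_def <- function(topology) {
  defs <- list(
    OL          = list(proteins = list(A = "A"), srna = NULL, mutable = "A",
                       params = character(), rules = list()),
    PHEN_PA     = list(proteins = list(A = "A"), srna = NULL, mutable = "A",
                       params = "k_A",
                       rules = list(rule("A", "repress", "species", "k_A", "p_A"))),
    PHEN_LAMBDA = list(proteins = list(A = "A"), srna = NULL, mutable = "A",
                       params = "k_lambda",
                       rules = list(rule("A", "activate", "lambda", "k_lambda"))),
    PHEN_POP    = list(proteins = list(A = "A"), srna = NULL, mutable = "A",
                       params = "k_P",
                       rules = list(rule("A", "repress", "P", "k_P"))),
    PHEN_DUAL   = list(proteins = list(A = "A"), srna = NULL, mutable = "A",
                       params = c("k_A", "k_lambda"),
                       rules = list(rule("A", "repress", "species", "k_A", "p_A"),
                                    rule("A", "activate", "lambda", "k_lambda"))),
    CLpATX      = list(proteins = list(A = "A", B = "A"), srna = NULL,
                       mutable = "A", params = "k_B",
                       rules = list(rule("A", "repress", "species", "k_B", "p_B"))),
    CLpATL      = list(proteins = list(A = "A", B = "A"), srna = "C",
                       mutable = c("A", "C"), params = c("k_B", "k_seq"),
                       rules = list(rule("C", "activate", "species", "k_B", "p_B"))),
    CLlamTX     = list(proteins = list(A = "A", B = "B"), srna = NULL,
                       mutable = c("A", "B"), params = c("k_B", "k_lambda"),
                       rules = list(rule("A", "repress", "species", "k_B", "p_B"),
                                    rule("B", "repress", "lambda", "k_lambda"))),
    CLlamTL     = list(proteins = list(A = "A", B = "B"), srna = "C",
                       mutable = c("A", "B", "C"),
                       params = c("k_B", "k_lambda", "k_seq"),
                       rules = list(rule("B", "repress", "lambda", "k_lambda"),
                                    rule("C", "activate", "species", "k_B", "p_B"))),
    CLlamPF     = list(proteins = list(A = "A"), srna = "C",
                       mutable = c("A", "C"), params = c("k_lambda", "k_seq"),
                       rules = list(rule("C", "repress", "lambda", "k_lambda"))),
    QS_POP      = list(proteins = list(A = "A", B = "A"), srna = NULL,
                       mutable = "A", params = c("k_P", "k_syn", "d_H"),
                       rules = list(rule("A", "repress", "H", "k_P")),
                       qs = TRUE),
    CLpATXlamTL = list(proteins = list(A = "A", B1 = "A", B2 = "B"), srna = "C",
                       mutable = c("A", "B", "C"),
                       params = c("k_B1", "k_B2", "k_lambda", "k_seq"),
                       rules = list(rule("A", "repress", "species", "k_B1", "p_B1"),
                                    rule("B", "repress", "lambda", "k_lambda"),
                                    rule("C", "activate", "species", "k_B2", "p_B2"))),
    CLpATLlamTX = list(proteins = list(A = "A", B1 = "A", B2 = "B"), srna = "C",
                       mutable = c("A", "B", "C"),
                       params = c("k_B1", "k_B2", "k_lambda", "k_seq"),
                       rules = list(rule("A", "repress", "species", "k_B2", "p_B2"),
                                    rule("B", "repress", "lambda", "k_lambda"),
                                    rule("C", "activate", "species", "k_B1", "p_B1"))),
    CLpATLlamTL = list(proteins = list(A = "A", B1 = "A", B2 = "B"), srna = "C",
                       mutable = c("A", "B", "C"),
                       params = c("k_B1", "k_B2", "k_lambda", "k_seq"),
                       rules = list(rule("B", "repress", "lambda", "k_lambda"),
                                    rule("C", "activate", "species", "k_B1", "p_B1"),
                                    rule("C", "activate", "species", "k_B2", "p_B2"))),
    CLpATXlamTX = list(proteins = list(A = "A", B1 = "A", B2 = "B"), srna = NULL,
                       mutable = c("A", "B"),
                       params = c("k_B1", "k_B2", "k_lambda"),
                       rules = list(rule("A", "repress", "species", "k_B1", "p_B1"),
                                    rule("A", "repress", "species", "k_B2", "p_B2"),
                                    rule("B", "repress", "lambda", "k_lambda"))),
    CLpATLlamPF = list(proteins = list(A = "A", B1 = "A"), srna = "C",
                       mutable = c("A", "C"),
                       params = c("k_B1", "k_lambda", "k_seq"),
                       rules = list(rule("C", "repress", "lambda", "k_lambda"),
                                    rule("C", "activate", "species", "k_B1", "p_B1")))
  )
  if (!topology %in% names(defs)) {
    stop(sprintf("unknown topology `%s`; see topologies()", topology),
         call. = FALSE)
  }
  d <- defs[[topology]]
  d$qs <- isTRUE(d$qs)
  d$topology <- topology
  d
}

# Internal: per-promoter regulatory factors, vectorised across strains.
# `sp` is a named list of species vectors (p_A, p_B, p_B1, p_B2 as present),
# `lambda` a vector, `P` the scalar population-wide output, `H` the scalar
# autoinducer pool. Returns a named list of factors (promoters absent from
# the list are unregulated, factor 1); factors from multiple rules on the
# same promoter multiply (cooperative multi-input control).
regulatory_factors <- function(topology, pars, sp, lambda, P = 0, H = 0) {
  h <- pars$h
  out <- list()
  for (r in topology_def(topology)$rules) {
    x <- switch(r$input,
                species = pmax(sp[[r$species]], 0),
                lambda = pmax(lambda, 0),
                P = max(P, 0),
                H = max(H, 0))
    k <- pars[[r$k]]
    if (is.na(k)) {
      stop(sprintf("topology %s needs controller parameter `%s`",
                   topology, r$k), call. = FALSE)
    }
    f <- if (r$op == "repress") hill_repress(x, k, h) else hill_activate(x, k, h)
    out[[r$promoter]] <- (out[[r$promoter]] %||% 1) * f
  }
  out
}

#' Build a validated circuit/controller specification
#'
#' Assembles a circuit topology, its gene kinetics and its controller
#' parameters into the object consumed by [cell_odes()] and the population
#' simulator. The species registry, the list of mutable promoters (which
#' fixes the mutation-lattice size at `4^g`), and the regulatory wiring are
#' all derived from the topology.
#'
#' Topologies with a co-expressed controller protein (e.g. `CLpATX`,
#' `CLpATL`) model the shared promoter as producing two independently
#' ribosome-binding mRNA species at the same effective transcription rate.
#' Where a topology carries an sRNA (`C`), the sRNA sequesters every
#' transcript produced from the process promoter `A` (irreversible
#' co-degradation at rate `k_seq`), or only the process transcript for the
#' growth-sensing topologies whose controller genes sit on their own
#' promoters.
#'
#' @param topology Topology identifier; see [topologies()].
#' @param genes Named list of [gene_spec()] / [srna_spec()] objects. Must
#'   contain an entry for every gene of the topology (e.g. `A`, `B`, `C` for
#'   `CLlamTL`). The promoter-owning gene's `omega` sets the promoter's
#'   maximal rate; co-expressed genes inherit their promoter's rate.
#' @param params A [controller_params()] object supplying every regulation
#'   constant the topology references.
#'
#' @return A `circuit_spec` object: topology, gene table, promoter table,
#'   species registry, mutable promoters, controller parameters.
#' @export
#' @examples
#' build_circuit("OL", genes = list(A = gene_spec(omega = 5)))
build_circuit <- function(topology, genes, params = controller_params()) {
  def <- topology_def(topology)
  stopifnot(inherits(params, "controller_params"))

  gene_names <- names(def$proteins)
  srna_name <- if (!is.null(def$srna)) "C" else NULL
  needed <- c(gene_names, srna_name)
  if (!all(needed %in% names(genes))) {
    stop(sprintf("topology %s requires genes: %s", topology,
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(genes), needed)
  if (length(extra) > 0) {
    stop(sprintf("topology %s does not use gene(s): %s", topology,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (g in gene_names) {
    if (!inherits(genes[[g]], "gene_spec")) {
      stop(sprintf("gene `%s` must be a gene_spec", g), call. = FALSE)
    }
  }
  if (!is.null(srna_name) && !inherits(genes[[srna_name]], "srna_spec")) {
    stop("gene `C` must be an srna_spec", call. = FALSE)
  }

  # promoters and their maximal rates (owned by the first gene they drive)
  promoters <- unique(c(unlist(def$proteins), if (!is.null(def$srna)) def$srna))
  omega <- vapply(promoters, function(pr) {
    if (!is.null(def$srna) && pr == def$srna) {
      genes$C$omega
    } else {
      owner <- gene_names[which(unlist(def$proteins) == pr)[1]]
      genes[[owner]]$omega
    }
  }, numeric(1))
  if (any(is.na(omega))) {
    stop("every promoter-owning gene needs a numeric `omega`", call. = FALSE)
  }
  # co-expressed genes must not carry their own conflicting omega
  for (g in gene_names[-match(promoters, unlist(def$proteins), nomatch = 0)]) {
    if (!is.na(genes[[g]]$omega)) {
      warning(sprintf(
        "gene `%s` is co-expressed from promoter %s; its own `omega` is ignored",
        g, def$proteins[[g]]), call. = FALSE)
    }
  }

  # controller parameter completeness / surplus
  missing_par <- def$params[vapply(def$params,
                                   function(nm) is.na(params[[nm]]), logical(1))]
  if (length(missing_par) > 0) {
    stop(sprintf("topology %s needs controller parameter(s): %s", topology,
                 paste(missing_par, collapse = ", ")), call. = FALSE)
  }
  supplied <- names(params)[!vapply(params, is.na, logical(1))]
  surplus <- setdiff(setdiff(supplied, c("h", "k_seq")), def$params)
  if (length(surplus) > 0) {
    warning(sprintf("controller parameter(s) unused by %s ignored: %s",
                    topology, paste(surplus, collapse = ", ")), call. = FALSE)
  }

  species <- c(HOST_SPECIES,
               as.vector(vapply(gene_names,
                                function(g) paste0(c("m_", "c_", "p_"), g),
                                character(3))),
               if (!is.null(srna_name)) "r_C")

  # sRNA targets: all transcripts from the process promoter A
  srna_targets <- if (is.null(srna_name)) character() else {
    paste0("m_", gene_names[unlist(def$proteins) == "A"])
  }

  structure(
    list(
      topology = topology,
      genes = genes[gene_names],
      srna = if (!is.null(srna_name)) genes$C else NULL,
      proteins = def$proteins,
      promoters = promoters,
      omega = omega,
      mutable_promoters = def$mutable,
      n_mutable = length(def$mutable),
      params = params,
      species = species,
      srna_targets = srna_targets,
      qs = def$qs
    ),
    class = "circuit_spec"
  )
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("<circuit_spec> %s: %d gene(s)%s, promoters {%s}, mutable {%s} (%d strains)\n",
              x$topology, length(x$genes),
              if (!is.null(x$srna)) " + sRNA", paste(x$promoters, collapse = ","),
              paste(x$mutable_promoters, collapse = ","), 4^x$n_mutable))
  invisible(x)
}

#' Effective transcription rates under the active controller
#'
#' Applies the topology's regulatory factors to the maximal transcription
#' rate of each promoter: `w = omega * factor(state)`, where the factor
#' depends on the controller input (per-cell output `p_A` or controller
#' protein, growth rate `lambda`, or population-wide output `P`). The open
#' loop returns `w = omega` unchanged. The returned rates are the effective
#' *maximal* rates; inside [cell_odes()] they are additionally scaled by the
#' host's anabolite-dependent transcription saturation.
#'
#' @param spec A `circuit_spec` from [build_circuit()].
#' @param state Named numeric cell state (see [initial_cell_state()]).
#' @param growth A `growth_output` from [growth_rate()] (or a list with
#'   element `lambda`); required by growth-sensing topologies.
#' @param population_output Scalar population-wide output `P` (molecules),
#'   used by population-based controllers.
#' @param autoinducer Scalar shared autoinducer pool (molecules), used by the
#'   quorum-sensing topology.
#'
#' @return Named numeric vector of effective transcription rates, one per
#'   promoter (mc min^-1).
#' @export
effective_transcription <- function(spec, state, growth = NULL,
                                    population_output = 0, autoinducer = 0) {
  stopifnot(inherits(spec, "circuit_spec"))
  lambda <- if (is.null(growth)) {
    growth_rate(state, attr(spec, "host") %||% host_params(), spec)$lambda
  } else {
    growth$lambda
  }
  sp <- as.list(state[grep("^p_", names(state), value = TRUE)])
  fac <- regulatory_factors(spec$topology, spec$params, sp, lambda,
                            P = population_output, H = autoinducer)
  w <- spec$omega
  for (pr in names(fac)) w[pr] <- w[pr] * fac[[pr]]
  w
}
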