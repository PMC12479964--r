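#' Host cell parameterisation
#'
#' Parameters of the single-cell resource-allocation model of bacterial gene
#' expression and growth. The host expresses four gene classes -- ribosomes
#' (`r`), substrate transporters (`t`), metabolic enzymes (`m`) and
#' housekeeping proteins (`q`) -- whose transcripts compete for a shared
#' ribosome pool and whose translation consumes a shared anabolite (energy)
#' pool. Growth rate is total translation flux normalised by cell mass, so
#' any synthetic circuit bolted onto the host reduces growth ("burden") by
#' sequestering ribosomes and consuming anabolites. All species are in
#' molecules per cell (mc) and all times in minutes.
#'
#' Defaults are the published calibration of the Weisse et al. (2015)
#' mechanistic cell model for *E. coli*.
#'
#' @param v_t Maximal substrate import rate per transporter (min^-1).
#' @param K_t Import half-saturation w.r.t. external substrate (molecules).
#' @param v_m Maximal catabolic rate per metabolic enzyme (min^-1).
#' @param K_m Catabolism half-saturation w.r.t. internal substrate (mc).
#' @param n_s Anabolite yield per internal substrate molecule catabolised.
#' @param w_r,w_t,w_m,w_q Maximal transcription rates of the host gene
#'   classes (mc min^-1).
#' @param theta_r,theta_nr Transcription anabolite thresholds for ribosomal
#'   and non-ribosomal genes (mc).
#' @param K_q,h_q Autoinhibition constant (mc) and Hill coefficient of
#'   housekeeping transcription.
#' @param k_b,k_u Ribosome-mRNA binding (mc^-1 min^-1) and unbinding
#'   (min^-1) rates for host transcripts.
#' @param d_m mRNA degradation rate (min^-1).
#' @param gamma_max Maximal translation elongation rate (aa min^-1).
#' @param K_gamma Elongation half-saturation w.r.t. anabolite (mc).
#' @param n_r,n_t,n_m,n_q Protein lengths (aa).
#' @param M Total cell mass normalisation (aa).
#' @param transcription_cost If `TRUE`, transcription consumes anabolites at
#'   `xi_nt` per nucleotide (an optional extension; off by default, matching
#'   the assumption that translational demand dominates burden).
#' @param xi_nt Per-nucleotide transcription energy cost (anabolite
#'   molecules per nt); ignored unless `transcription_cost` is `TRUE`.
#'
#' @return An object of class `host_params` (a validated named list).
#' @references Weisse, A.Y., Oyarzun, D.A., Danos, V., Swain, P.S. (2015)
#'   Mechanistic links between cellular trade-offs, gene expression, and
#'   growth. PNAS 112:E1038-E1047.
#' @export
host_params <- function(v_t = 726, K_t = 1000,
                        v_m = 5800, K_m = 1000,
                        n_s = 0.5,
                        w_r = 930, w_t = 4.14, w_m = 4.14, w_q = 948.93,
                        theta_r = 426.87, theta_nr = 4.38,
                        K_q = 152219, h_q = 4,
                        k_b = 1, k_u = 1,
                        d_m = 0.1,
                        gamma_max = 1260, K_gamma = 7,
                        n_r = 7459, n_t = 300, n_m = 300, n_q = 300,
                        M = 1e8,
                        transcription_cost = FALSE, xi_nt = 0) {
  hp <- list(
    v_t = v_t, K_t = K_t, v_m = v_m, K_m = K_m, n_s = n_s,
    w_r = w_r, w_t = w_t, w_m = w_m, w_q = w_q,
    theta_r = theta_r, theta_nr = theta_nr,
    K_q = K_q, h_q = h_q,
    k_b = k_b, k_u = k_u, d_m = d_m,
    gamma_max = gamma_max, K_gamma = K_gamma,
    n_r = n_r, n_t = n_t, n_m = n_m, n_q = n_q,
    M = M,
    transcription_cost = isTRUE(transcription_cost), xi_nt = xi_nt
  )
  validate_host_params(hp)
}

validate_host_params <- function(hp) {
  rates <- c("v_t", "v_m", "n_s", "w_r", "w_t", "w_m", "w_q",
             "k_b", "k_u", "d_m", "gamma_max", "xi_nt")
  for (nm in rates) {
    if (!is.numeric(hp[[nm]]) || length(hp[[nm]]) != 1 || hp[[nm]] < 0) {
      stop(sprintf("host parameter `%s` must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  pos <- c("K_t", "K_m", "theta_r", "theta_nr", "K_q", "h_q", "K_gamma", "M")
  for (nm in pos) {
    if (!is.numeric(hp[[nm]]) || length(hp[[nm]]) != 1 || hp[[nm]] <= 0) {
      stop(sprintf("host parameter `%s` must be a single positive number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("n_r", "n_t", "n_m", "n_q")) {
    if (hp[[nm]] < 1) stop(sprintf("protein length `%s` must be >= 1 aa", nm),
                           call. = FALSE)
  }
  structure(hp, class = "host_params")
}

#' @export
print.host_params <- function(x, ...) {
  cat("<host_params> resource-allocation host model;",
      sprintf("gamma_max = %g aa/min, M = %g aa, transcription cost %s\n",
              x$gamma_max, x$M, if (x$transcription_cost) "on" else "off"))
  invisible(x)
}

#' Read / write host parameters as YAML
#'
#' Host parameter blocks are serialised keyed by their symbol names so a
#' parameterisation round-trips exactly.
#'
#' @param path File path of a YAML file whose top level is a `host:` block or
#'   a flat mapping of parameter names.
#' @return `read_host_params()` returns a `host_params` object;
#'   `write_host_params()` writes `host` to `path` and returns it invisibly.
#' @export
read_host_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$host)) raw <- raw$host
  known <- names(formals(host_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown host parameter key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(host_params, raw)
}

#' @rdname read_host_params
#' @param host A `host_params` object.
#' @export
write_host_params <- function(host, path) {
  stopifnot(inherits(host, "host_params"))
  yaml::write_yaml(list(host = unclass(host)), path,
                   precision = 17L, handlers = list(logical = yaml::verbatim_logical))
  invisible(host)
}
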