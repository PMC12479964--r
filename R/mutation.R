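#' @keywords internal
MUTATION_LEVELS <- c(100, 67, 33, 0)

#' Enumerate mutation states over a circuit's mutable promoters
#'
#' Each mutable promoter of a circuit can be in one of four functional levels,
#' 100, 67, 33 or 0 percent of its designed maximal transcription rate. A
#' *mutation state* (strain) is a tuple of one level per mutable promoter, so
#' a circuit with `g` mutable promoters has `4^g` strains.
#'
#' States are ordered lexicographically with levels descending (the fully
#' functional strain first, the fully non-functional strain last), and the
#' order is deterministic.
#'
#' @param n_promoters Number of mutable promoters (1, 2 or 3).
#'
#' @return A tibble with one row per mutation state: `state` (index),
#'   `label` (e.g. `"100/33"`), and one `level_<i>` column per promoter
#'   holding the percent functional level.
#' @export
#' @examples
#' enumerate_states(1)  # 4 states
#' enumerate_states(2)  # 16 states
enumerate_states <- function(n_promoters) {
  if (!is.numeric(n_promoters) || length(n_promoters) != 1 ||
      n_promoters != round(n_promoters) || !(n_promoters %in% 1:3)) {
    stop("`n_promoters` must be 1, 2 or 3", call. = FALSE)
  }
  grids <- rep(list(MUTATION_LEVELS), n_promoters)
  names(grids) <- paste0("level_", seq_len(n_promoters))
  # expand.grid varies the first factor fastest; we want the first promoter
  # slowest so the fully functional state is row 1 and order is lexicographic.
  df <- rev(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE))
  out <- tibble::as_tibble(df)
  out$label <- apply(as.matrix(df), 1, paste, collapse = "/")
  out$state <- seq_len(nrow(out))
  out[, c("state", "label", paste0("level_", seq_len(n_promoters)))]
}

#' Mutation transition rate between two states
#'
#' Transitions are only allowed if the destination differs from the source at
#' exactly one promoter and is *less* functional there: mutations are
#' function-reducing and affect a single promoter at a time. The rate falls
#' geometrically with the number of functional levels skipped, so more extreme
#' mutations are less likely.
#'
#' @param from,to Numeric vectors of levels (one per promoter), each drawn
#'   from `c(100, 67, 33, 0)`.
#' @param base_rate Rate (min^-1) of a single-level drop at one promoter.
#' @param attenuation Multiplicative factor per *extra* level skipped
#'   (default 0.1): a two-level jump has rate `base_rate * attenuation`, a
#'   three-level jump `base_rate * attenuation^2`.
#'
#' @return A single non-negative rate (min^-1); 0 for disallowed transitions
#'   (self, function-increasing, or multi-promoter).
#' @export
transition_rate <- function(from, to, base_rate = 5e-5, attenuation = 0.1) {
  if (length(from) != length(to)) {
    stop("`from` and `to` must have the same number of promoters", call. = FALSE)
  }
  lv <- MUTATION_LEVELS
  if (!all(from %in% lv) || !all(to %in% lv)) {
    stop("levels must be drawn from {100, 67, 33, 0}", call. = FALSE)
  }
  changed <- which(from != to)
  if (length(changed) != 1) return(0)
  i_from <- match(from[changed], lv)
  i_to <- match(to[changed], lv)
  jump <- i_to - i_from            # positive = function-reducing
  if (jump <= 0) return(0)
  base_rate * attenuation^(jump - 1)
}

#' Build the full strain-to-strain mutation rate matrix
#'
#' @param states A state table from [enumerate_states()].
#' @inheritParams transition_rate
#'
#' @return A square matrix `M` (rows = source strain, columns = destination)
#'   with `M[i, j] = transition_rate(state_i, state_j, ...)`. The fully
#'   non-functional strain's row is all zero (it is absorbing).
#' @export
build_transition_matrix <- function(states, base_rate = 5e-5, attenuation = 0.1) {
  lev_cols <- grep("^level_", names(states), value = TRUE)
  L <- as.matrix(states[, lev_cols, drop = FALSE])
  n <- nrow(L)
  M <- matrix(0, n, n, dimnames = list(states$label, states$label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        M[i, j] <- transition_rate(L[i, ], L[j, ], base_rate, attenuation)
      }
    }
  }
  M
}

#' Mutation scheme: states plus transition structure
#'
#' Bundles the mutation-state lattice of a circuit with its transition-rate
#' matrix. The rates act as continuous first-order transfer terms
#' `N_i * M[i, j]` between strain populations in the population ODE.
#'
#' @param n_promoters Number of mutable promoters (1-3), usually taken from a
#'   circuit built with [build_circuit()].
#' @inheritParams transition_rate
#'
#' @return An object of class `mutation_scheme`: a list with `states`
#'   (tibble), `matrix` (rate matrix), `levels` (per-strain level matrix as a
#'   fraction of design, rows = strains), `base_rate`, `attenuation`.
#' @export
mutation_scheme <- function(n_promoters, base_rate = 5e-5, attenuation = 0.1) {
  if (base_rate < 0) stop("`base_rate` must be >= 0", call. = FALSE)
  if (attenuation < 0) stop("`attenuation` must be >= 0", call. = FALSE)
  states <- enumerate_states(n_promoters)
  M <- build_transition_matrix(states, base_rate, attenuation)
  lev_cols <- grep("^level_", names(states), value = TRUE)
  levels <- as.matrix(states[, lev_cols, drop = FALSE]) / 100
  structure(
    list(
      states = states, matrix = M, levels = levels,
      n_promoters = n_promoters,
      base_rate = base_rate, attenuation = attenuation
    ),
    class = "mutation_scheme"
  )
}

#' @export
print.mutation_scheme <- function(x, ...) {
  cat(sprintf(
    "<mutation_scheme> %d promoter(s), %d strains, base rate %g min^-1, attenuation %g\n",
    x$n_promoters, nrow(x$states), x$base_rate, x$attenuation
  ))
  invisible(x)
}
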