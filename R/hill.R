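#' Hill repression factor
#'
#' Quasi-steady-state repressive regulation: the fraction of promoter activity
#' remaining when a repressor (or repressive signal) is present at level `x`.
#'
#' @param x Signal level (concentration-like, >= 0). Vectorised.
#' @param k Half-saturation constant in the same units as `x` (> 0).
#' @param h Hill coefficient (> 0, default 2).
#'
#' @return A value in `[0, 1]`: `k^h / (k^h + x^h)`. Equals 1 at `x = 0` and
#'   0.5 at `x = k`, and decreases monotonically in `x`.
#' @seealso [hill_activate()], which is its exact complement.
#' @export
#' @examples
#' hill_repress(0, 10)     # 1
#' hill_repress(10, 10)    # 0.5
hill_repress <- function(x, k, h = 2) {
  if (any(k <= 0)) stop("Hill constant `k` must be > 0", call. = FALSE)
  if (any(h <= 0)) stop("Hill coefficient `h` must be > 0", call. = FALSE)
  if (any(x < 0)) stop("signal `x` must be >= 0", call. = FALSE)
  # computed via the activation form to keep the pair exactly complementary
  1 - hill_activate(x, k, h)
}

#' Hill activation factor
#'
#' Quasi-steady-state activating regulation: the fraction of maximal promoter
#' activity reached when an activator (or activating signal) is at level `x`.
#'
#' `hill_activate(x, k, h) + hill_repress(x, k, h) == 1` exactly (to machine
#' precision), since both are computed from the same ratio.
#'
#' @inheritParams hill_repress
#' @return A value in `[0, 1]`: `x^h / (k^h + x^h)`.
#' @export
hill_activate <- function(x, k, h = 2) {
  if (any(k <= 0)) stop("Hill constant `k` must be > 0", call. = FALSE)
  if (any(h <= 0)) stop("Hill coefficient `h` must be > 0", call. = FALSE)
  if (any(x < 0)) stop("signal `x` must be >= 0", call. = FALSE)
  r <- (x / k)^h
  r / (1 + r)
}
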