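#' @keywords internal
logit <- function(p) log(p) - log1p(-p)

#' @keywords internal
invlogit <- function(x) 1 / (1 + exp(-x))

#' Numerically stable log-sum-exp
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Continuity correction for boundary fractions
#'
#' Replaces observed fractions of exactly 0 or 1 by `1/(2 n)` and
#' `1 - 1/(2 n)` respectively, where `n` is the number of cells the fraction
#' was computed from. Keeps logit transforms finite without altering interior
#' values.
#'
#' @param f numeric vector of fractions in \[0, 1\].
#' @param n_cells cell counts underlying each fraction (recycled).
#' @return corrected fractions, strictly inside (0, 1).
#' @export
continuity_correct <- function(f, n_cells) {
  n_cells <- pmax(rep_len(n_cells, length(f)), 1)
  eps <- 1 / (2 * n_cells)
  out <- f
  out[!is.na(f) & f <= 0] <- eps[!is.na(f) & f <= 0]
  out[!is.na(f) & f >= 1] <- (1 - eps)[!is.na(f) & f >= 1]
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_prob <- function(x, name) {
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
assert_nonneg <- function(x, name) {
  if (any(!is.na(x) & x < 0))
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  invisible(x)
}
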