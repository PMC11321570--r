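# Derived quantities: clonal half-lives from net loss rates, population
# (size-)weighted mean lifespans computed per posterior draw, and the two
# quick lifespan estimators (from the early BrdU upslope and from Ki67
# frequencies). All posterior summaries are computed per draw and then
# summarised, never on posterior means.

#' Clonal half-life from net loss rate
#'
#' The time for a cohort of cells entering a population to halve in size,
#' accounting for self-renewal: `ln(2) / lambda` with net loss rate
#' `lambda = delta - alpha`. When `delta <= alpha` the population is
#' sustained indefinitely and `Inf` is returned as an explicit marker.
#'
#' @param delta loss rate, per day.
#' @param alpha division (self-renewal) rate, per day.
#' @return half-life in days (`Inf` when `lambda <= 0`); vectorised.
#' @export
clonal_half_life <- function(delta, alpha) {
  lambda <- delta - alpha
  ifelse(lambda > 0, log(2) / lambda, Inf)
}

#' @keywords internal
subpop_weights <- function(structure, params, stages = 1) {
  df <- as.data.frame(steady_state(structure, params, stages))
  agg <- tapply(df$count, df$subpop, sum)
  agg / sum(agg)
}

#' Population-weighted mean lifespan from a fitted posterior
#'
#' For each posterior draw, computes the average loss rate of fast and slow
#' cells weighted by their steady-state population sizes, and reports the
#' inverse (the mean cell lifespan). When fits for several timecourses
#' (e.g. host and donor, or T_CM and T_EM) are supplied, their loss rates
#' are averaged with the given abundance weights before inversion —
#' lifespans are inverse rates, so aggregation weights rates, not
#' lifespans.
#'
#' @param fits a single `posterior_draws` object or a list of them.
#' @param weights abundance weights for the fits (e.g. population sizes or
#'   an EM:CM ratio expressed as sizes); default equal. Normalised to sum
#'   to 1.
#' @param n_draws number of posterior draws used (default: all draws of the
#'   smallest fit).
#' @return object of class `lifespan_summary`: per-draw mean loss rates and
#'   lifespans, quantile summaries, and the weights used.
#' @export
weighted_mean_lifespan <- function(fits, weights = NULL, n_draws = NULL) {
  if (inherits(fits, "posterior_draws")) fits <- list(fits)
  k <- length(fits)
  weights <- weights %||% rep(1, k)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  zero <- weights == 0
  if (any(zero)) {
    warning("fits with zero weight excluded from the aggregate",
            call. = FALSE)
  }
  weights <- weights / sum(weights)
  n_draws <- n_draws %||% min(vapply(fits, function(f) nrow(f$draws),
                                     integer(1)))
  per_fit_rate <- matrix(NA_real_, n_draws, k)
  for (j in seq_len(k)) {
    f <- fits[[j]]
    st <- model_structure(f$structure)
    idx <- seq_len(n_draws)
    for (i in idx) {
      nat <- f$draws[i, ]
      p <- params_from_natural(st, nat)
      w <- subpop_weights(st, p, f$stages %||% 1)
      dl <- vapply(names(w), function(sp)
        loss_rate(st, p, sp, is_hi = FALSE), numeric(1))
      if (st$name == "temporal") {
        # loss depends on Ki67 state: weight by hi/lo occupancy
        df <- as.data.frame(steady_state(st, p, f$stages %||% 1))
        hi <- sum(df$count[startsWith(df$kstage, "hi")]) / sum(df$count)
        per_fit_rate[i, j] <- hi * p$delta_hi + (1 - hi) * p$delta_lo
      } else {
        per_fit_rate[i, j] <- sum(w * dl)
      }
    }
  }
  agg_rate <- as.vector(per_fit_rate %*% weights)
  lifespan <- 1 / agg_rate
  qs <- function(x) stats::quantile(x, c(0.025, 0.5, 0.975))
  out <- list(rate_draws = per_fit_rate, aggregate_rate = agg_rate,
              lifespan_draws = lifespan,
              lifespan = qs(lifespan),
              per_fit_lifespan = apply(1 / per_fit_rate, 2, qs),
              weights = weights)
  class(out) <- "lifespan_summary"
  out
}

#' @export
print.lifespan_summary <- function(x, ...) {
  cat("<lifespan_summary> aggregate mean lifespan (days):\n")
  print(round(x$lifespan, 2))
  invisible(x)
}

#' Mean lifespan from the early BrdU upslope
#'
#' At steady state the total production rate (division + influx) balances
#' the average loss rate, so the mean lifespan is approximately
#' `2 epsilon / p`, where `epsilon` is the per-division BrdU labelling
#' efficiency and `p` the early rate of increase of the BrdU-positive
#' fraction. `p` is estimated by least squares through the origin on
#' observations within the early window.
#'
#' @param timecourse data.frame with columns `day` and `f_brdu`.
#' @param epsilon BrdU labelling efficiency.
#' @param window early window in days (default `c(0, 4)`).
#' @return estimated mean lifespan, days (`NA` when the fitted slope is
#'   not positive); the slope is attached as `attr(-, "p")`.
#' @export
lifespan_from_upslope <- function(timecourse, epsilon, window = c(0, 4)) {
  sel <- !is.na(timecourse$f_brdu) & timecourse$day >= window[1] &
    timecourse$day <= window[2] & timecourse$day > 0
  if (sum(sel) < 3)
    stop("need at least 3 early observations in the window", call. = FALSE)
  x <- timecourse$day[sel]; y <- timecourse$f_brdu[sel]
  p <- sum(x * y) / sum(x * x)
  out <- if (p > 0) 2 * epsilon / p else NA_real_
  attr(out, "p") <- p
  out
}

#' Mean lifespan from Ki67 frequencies
#'
#' If a fraction `k` of cells expresses Ki67, which is retained for `T`
#' days after division or entry, the per-capita production rate at steady
#' state is approximately `-ln(1 - k/2) / T`, which balances the loss rate;
#' its inverse is the mean lifespan. Given Ki67-high fractions for T_CM and
#' T_EM and their relative abundance, per-subset loss rates are averaged
#' with abundance weights and inverted (rates are weighted, not lifespans;
#' the lifespan-weighted alternative is also reported).
#'
#' @param k_tcm,k_tem Ki67-high fractions, in (0, 1).
#' @param T_ki67 duration of Ki67-high expression, days (default 3.1).
#' @param em_cm_ratio abundance of T_EM relative to T_CM (default 7.5).
#' @param cap lifespans above this cap are reported as `Inf` (the `k -> 0`
#'   limit carries no production information); default 1e6 days.
#' @return list with `lifespan` (aggregate, rate-weighted), `per_subset`
#'   (named lifespans), `rates` (per-subset loss rates),
#'   `lifespan_weighted_alt` (aggregate obtained by weighting lifespans).
#' @export
lifespan_from_ki67 <- function(k_tcm, k_tem, T_ki67 = 3.1,
                               em_cm_ratio = 7.5, cap = 1e6) {
  for (k in c(k_tcm, k_tem))
    if (is.na(k) || k < 0 || k >= 1)
      stop("Ki67-high fractions must lie in [0, 1)", call. = FALSE)
  if (T_ki67 <= 0 || em_cm_ratio < 0)
    stop("T_ki67 must be positive and em_cm_ratio non-negative",
         call. = FALSE)
  rate <- function(k) -log(1 - k / 2) / T_ki67
  r <- c(TCM = rate(k_tcm), TEM = rate(k_tem))
  w <- c(TCM = 1, TEM = em_cm_ratio) / (1 + em_cm_ratio)
  per_subset <- ifelse(r > 1 / cap, 1 / r, Inf)
  agg_rate <- sum(w * r)
  lifespan <- if (agg_rate > 1 / cap) 1 / agg_rate else Inf
  alt <- if (all(is.finite(per_subset))) sum(w * per_subset) else Inf
  list(lifespan = lifespan, per_subset = per_subset, rates = r,
       weights = w, lifespan_weighted_alt = alt)
}
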