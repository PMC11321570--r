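# Affine-invariant ensemble sampler (Goodman & Weare stretch move) and
# convergence diagnostics. The ensemble sampler needs only log-posterior
# evaluations, which suits a posterior whose likelihood runs an ODE solve;
# walkers double as chains for split-R-hat and effective-sample-size checks.

#' Affine-invariant ensemble MCMC
#'
#' Samples from a target density using the stretch move: a walker is updated
#' by proposing along the line through a randomly chosen companion walker,
#' with scale drawn from `g(z) ~ 1/sqrt(z)` on `[1/a, a]`. The move is
#' affine-invariant, so correlated, anisotropic posteriors (typical for
#' partially identified kinetic parameters) need no tuning beyond `a`.
#'
#' @param log_post function taking a parameter vector, returning the
#'   unnormalised log posterior (`-Inf` allowed outside support).
#' @param init numeric matrix `n_walkers x d` of starting positions, or a
#'   single vector around which walkers are jittered.
#' @param n_steps number of ensemble sweeps.
#' @param n_walkers number of walkers (default `max(2 d + 2, 24)`, even).
#' @param a stretch scale (default 2).
#' @param burnin sweeps discarded from the front.
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed integer seed; the run is fully deterministic given the seed.
#' @param init_jitter additive jitter SD used when `init` is a single
#'   vector (applied on the sampling scale).
#' @return list with `draws` (kept draws stacked over walkers,
#'   rows = draws), `lp` (log posterior per kept draw), `chains` (array
#'   kept-iterations x walkers x d, for diagnostics), `accept_rate`.
#' @export
ensemble_mcmc <- function(log_post, init, n_steps = 1000, n_walkers = NULL,
                          a = 2, burnin = floor(n_steps / 2), thin = 1,
                          seed = 1, init_jitter = 0.2) {
  set.seed(seed)
  if (is.null(dim(init))) {
    d <- length(init)
    n_walkers <- n_walkers %||% max(2L * d + 2L, 24L)
    init <- matrix(rep(init, each = n_walkers), n_walkers, d) +
      init_jitter * matrix(stats::rnorm(n_walkers * d), n_walkers, d)
  }
  X <- as.matrix(init)
  n_walkers <- nrow(X); d <- ncol(X)
  if (n_walkers < d + 2)
    stop("need at least d + 2 walkers", call. = FALSE)
  lp <- apply(X, 1, log_post)
  if (all(!is.finite(lp)))
    stop("no walker started inside the support", call. = FALSE)
  # pull walkers stuck at -Inf onto the best start
  bad <- !is.finite(lp)
  if (any(bad)) {
    best <- which.max(lp)
    X[bad, ] <- matrix(rep(X[best, ], each = sum(bad)), sum(bad), d) *
      (1 + 0.001 * matrix(stats::rnorm(sum(bad) * d), sum(bad), d))
    lp[bad] <- apply(X[bad, , drop = FALSE], 1, log_post)
  }

  keep_iter <- seq(burnin + 1, n_steps, by = thin)
  chains <- array(NA_real_, c(length(keep_iter), n_walkers, d))
  lp_keep <- matrix(NA_real_, length(keep_iter), n_walkers)
  n_acc <- 0; n_prop <- 0; ki <- 0

  gamma_de <- 2.38 / sqrt(2 * d)
  for (step in seq_len(n_steps)) {
    for (w in seq_len(n_walkers)) {
      n_prop <- n_prop + 1
      if (stats::runif(1) < 0.5) {
        # stretch move
        j <- sample.int(n_walkers - 1L, 1L)
        if (j >= w) j <- j + 1L
        z <- ((a - 1) * stats::runif(1) + 1)^2 / a
        y <- X[j, ] + z * (X[w, ] - X[j, ])
        log_hastings <- (d - 1) * log(z)
      } else {
        # differential-evolution move (symmetric): step along the
        # difference of two other walkers, occasionally at full length to
        # allow mode-to-mode jumps
        jk <- sample.int(n_walkers - 1L, 2L)
        jk[jk >= w] <- jk[jk >= w] + 1L
        g <- if (stats::runif(1) < 0.1) 1 else gamma_de
        y <- X[w, ] + g * (X[jk[1], ] - X[jk[2], ]) +
          1e-4 * stats::rnorm(d)
        log_hastings <- 0
      }
      lpy <- log_post(y)
      if (is.finite(lpy) &&
          log(stats::runif(1)) < log_hastings + lpy - lp[w]) {
        X[w, ] <- y; lp[w] <- lpy; n_acc <- n_acc + 1
      }
    }
    if (step %in% keep_iter) {
      ki <- ki + 1
      chains[ki, , ] <- X
      lp_keep[ki, ] <- lp
    }
  }
  draws <- matrix(chains, length(keep_iter) * n_walkers, d)
  list(draws = draws, lp = as.vector(lp_keep), chains = chains,
       accept_rate = n_acc / n_prop)
}

#' Split R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so that within-chain drift is detected as well as between-chain
#' disagreement.
#'
#' @param ch matrix of iterations x chains for one scalar quantity.
#' @return split R-hat (1 at perfect mixing).
#' @export
split_rhat <- function(ch) {
  ch <- as.matrix(ch)
  n <- nrow(ch)
  half <- floor(n / 2)
  sp <- cbind(ch[seq_len(half), , drop = FALSE],
              ch[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  s2 <- apply(sp, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Bulk effective sample size
#'
#' Multi-chain effective sample size using Geyer's initial monotone positive
#' sequence on the chain-averaged autocorrelations.
#'
#' @param ch matrix of iterations x chains for one scalar quantity.
#' @return estimated effective sample size.
#' @export
ess_bulk <- function(ch) {
  ch <- as.matrix(ch)
  n <- nrow(ch); m <- ncol(ch)
  if (n < 4) return(NA_real_)
  if (stats::sd(as.vector(ch)) == 0) return(m * n)
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(ch[, j], lag.max = n - 1, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  W <- mean(apply(ch, 2, stats::var))
  var_plus <- (n - 1) / n * W + if (m > 1) stats::var(colMeans(ch)) else 0
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive, enforce monotonicity
  tau <- -1; prev <- Inf; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / max(tau, 1e-12), 1)
}
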