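# Likelihood construction and Bayesian fitting.

make_noisefree_dataset <- function(truth, days = c(1, 3, 5, 7, 10, 14, 17,
                                                   21, 24, 28, 31, 35)) {
  des <- study_design("young", days = days, mice_per_point = 1,
                      sigma_frac = 0, sigma_count = 0)
  ds <- generate_labelling_dataset("branched", list(host = truth,
                                                    donor = truth),
                                   des, seed = 1, lineages = "host")
  ds
}

test_that("noise-free data sit at the likelihood maximum with zero residuals", {
  tru <- params_recovery_truth()
  ds <- make_noisefree_dataset(tru)
  noise <- list(sigma_ki67 = 0.2, sigma_brdu = 0.2, sigma_count = 0.2)
  ll <- log_likelihood("branched", tru, ds, noise = noise)
  # every pointwise contribution equals the kernel maximum for its scale
  expected <- rep(c(rep(stats::dnorm(0, 0, 0.2, log = TRUE), 4),
                    stats::dnorm(0, 0, 0.2, log = TRUE)), nrow(ds))
  expect_equal(as.vector(ll$pointwise), expected, tolerance = 1e-6)

  # perturbing one parameter strictly lowers the likelihood
  worse <- update(tru, alpha_B = tru$alpha_B * 0.8)
  expect_lt(log_likelihood("branched", worse, ds, noise = noise)$total,
            ll$total)
})

test_that("doubling a residual lowers its contribution by the quadratic increment", {
  tru <- params_recovery_truth()
  ds <- make_noisefree_dataset(tru, days = c(2, 5, 9, 14, 21))
  sigma <- 0.25
  noise <- list(sigma_ki67 = sigma, sigma_brdu = sigma, sigma_count = 0.2)
  base <- log_likelihood("branched", tru, ds, noise = noise)
  pred <- stats::qlogis(ds$f_ki67hi[1])
  bump <- function(r) {
    d2 <- ds
    d2$f_ki67hi[1] <- stats::plogis(pred + r)
    log_likelihood("branched", tru, d2, noise = noise)$pointwise[["1.f_ki67hi"]]
  }
  r <- 0.3
  drop1 <- base$pointwise[["1.f_ki67hi"]] - bump(r)
  drop2 <- base$pointwise[["1.f_ki67hi"]] - bump(2 * r)
  expect_equal(drop1, r^2 / (2 * sigma^2), tolerance = 1e-6)
  expect_equal(drop2, (2 * r)^2 / (2 * sigma^2), tolerance = 1e-6)
})

test_that("total log-likelihood equals an independent straight-sum oracle", {
  tru <- params_recovery_truth()
  des <- study_design("young", days = c(2, 6, 12, 20, 30),
                      mice_per_point = 1)
  ds <- generate_labelling_dataset("branched",
                                   list(host = tru, donor = tru), des,
                                   seed = 9, lineages = "host")
  ds$f_brdu_in_ki67lo[3] <- NA   # one undefined observation
  noise <- list(sigma_ki67 = 0.3, sigma_brdu = 0.25, sigma_count = 0.15)
  ll <- log_likelihood("branched", tru, ds, noise = noise)

  # oracle: direct per-row summation from first principles
  tr <- integrate_labelling("branched", update(tru, chi0 = 0, f_d = 0),
                            labelling_schedule(), unique(ds$day),
                            method = "lsoda")
  ob <- suppressWarnings(observables(tr, pool_lineages = TRUE))
  ob <- ob[ob$lineage == "all", ]
  tot <- 0
  for (i in seq_len(nrow(ds))) {
    prow <- ob[ob$day == ds$day[i], ]
    nc <- max(ds$n_cells[i], 1)
    for (cn in c("f_ki67hi", "f_brdu", "f_brdu_in_ki67hi",
                 "f_brdu_in_ki67lo")) {
      o <- ds[[cn]][i]
      if (is.na(o)) next
      sg <- if (cn == "f_ki67hi") 0.3 else 0.25
      tot <- tot + stats::dnorm(
        stats::qlogis(continuity_correct(o, nc)),
        stats::qlogis(continuity_correct(prow[[cn]], nc)), sg, log = TRUE)
    }
    tot <- tot + stats::dnorm(log(ds$n_cells[i]), log(prow$n_cells),
                              0.15, log = TRUE)
  }
  expect_equal(ll$total, tot, tolerance = 1e-6)
  expect_equal(attr(ll$pointwise, "n_undefined"), 1L)
  # the undefined observation contributes exactly 0
  expect_equal(unname(ll$pointwise[["3.f_brdu_in_ki67lo"]]), 0)
})

test_that("permuting dataset rows leaves the total log-likelihood unchanged", {
  tru <- params_recovery_truth()
  des <- study_design("young", days = c(1, 4, 9, 15, 22, 30))
  ds <- generate_labelling_dataset("branched",
                                   list(host = tru, donor = tru), des,
                                   seed = 12, lineages = "host")
  set.seed(1)
  perm <- sample(nrow(ds))
  l1 <- log_likelihood("branched", tru, ds)
  l2 <- log_likelihood("branched", tru, ds[perm, ])
  expect_equal(l1$total, l2$total, tolerance = 1e-10)
})

test_that("prior draws integrate without failure for at least 99% of 1000 draws", {
  pr <- default_priors("branched")
  transforms <- memkin:::param_spec(model_structure("branched"))
  set.seed(77)
  ok <- 0
  n <- 1000
  sch <- labelling_schedule()
  for (i in seq_len(n)) {
    nat <- vapply(names(transforms),
                  function(nm) memkin:::prior_draw(pr[[nm]]), numeric(1))
    # respect the sampler's A-slow ordering convention
    if (nat[["alpha_A"]] >= nat[["alpha_B"]]) {
      tmp <- nat[["alpha_A"]]
      nat[["alpha_A"]] <- nat[["alpha_B"]]; nat[["alpha_B"]] <- tmp
    }
    p <- memkin:::params_from_natural(model_structure("branched"), nat)
    ok <- ok + tryCatch({
      tr <- memkin:::single_population_trajectory("branched", p, sch,
                                                  c(2, 10, 21, 30))
      is.finite(sum(tr$states))
    }, error = function(e) FALSE)
  }
  expect_gte(ok / n, 0.99)
})

test_that("a zero-noise fit concentrates tightly around the generating parameters", {
  tru <- params_recovery_truth()
  ds <- make_noisefree_dataset(tru)
  # pin the error scales (the zero-residual limit makes free scales a
  # funnel); concentration of the kinetic parameters is the property under
  # test
  pri <- c(tight_influx_prior(tru),
           list(sigma_ki67 = list(dist = "lognormal",
                                  meanlog = log(0.05), sdlog = 0.01),
                sigma_brdu = list(dist = "lognormal",
                                  meanlog = log(0.05), sdlog = 0.01),
                sigma_count = list(dist = "lognormal",
                                   meanlog = log(0.05), sdlog = 0.01)))
  fit <- suppressWarnings(
    fit_model("branched", ds, priors = pri,
              sampler_config = fast_fit_config(), seed = 8))
  # posterior mass concentrates: narrow intervals containing the truth for
  # the well-identified parameters
  for (nm in c("beta", "epsilon", "N0")) {
    tv <- switch(nm, beta = 1 / 3.1, epsilon = 0.5, N0 = 1e6)
    width <- (fit$ci[nm, 3] - fit$ci[nm, 1]) / tv
    expect_lt(width, 0.6)   # far narrower than the priors
    expect_gt(tv, fit$ci[nm, 1] * 0.85)
    expect_lt(tv, fit$ci[nm, 3] * 1.15)
  }
  expect_lt(abs(fit$map[["epsilon"]] - 0.5), 0.1)
})

test_that("fits are reproducible given the seed", {
  tru <- params_recovery_truth()
  des <- study_design("young", days = c(2, 7, 14, 21, 30))
  ds <- generate_labelling_dataset("branched",
                                   list(host = tru, donor = tru), des,
                                   seed = 5, lineages = "host")
  cfg <- list(n_steps = 60, n_walkers = 16, burnin = 30, thin = 2,
              optim_maxit = 50)
  f1 <- suppressWarnings(fit_model("branched", ds,
                                   priors = tight_influx_prior(tru),
                                   sampler_config = cfg, seed = 31))
  f2 <- suppressWarnings(fit_model("branched", ds,
                                   priors = tight_influx_prior(tru),
                                   sampler_config = cfg, seed = 31))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$log_lik, f2$log_lik)
})
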