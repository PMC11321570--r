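# Derived quantities: clonal half-lives, weighted mean lifespans, quick
# estimators.

test_that("clonal half-life is ln2 over the net loss rate, with explicit markers", {
  expect_equal(clonal_half_life(0.02, 0.01), log(2) / 0.01)
  expect_equal(clonal_half_life(0.11, 0.10), 69.3, tolerance = 1e-3)
  # balanced self-renewal: population sustained indefinitely
  expect_identical(clonal_half_life(0.05, 0.05), Inf)
  expect_identical(clonal_half_life(0.03, 0.05), Inf)
  expect_equal(clonal_half_life(c(0.02, 0.05), c(0.01, 0.05)),
               c(log(2) / 0.01, Inf))
})

make_mini_fit <- function(truth, seed = 21) {
  des <- study_design("young", days = c(1, 3, 5, 7, 10, 14, 17, 21, 24,
                                        28, 31, 35))
  ds <- generate_labelling_dataset("branched",
                                   list(host = truth, donor = truth), des,
                                   seed = seed, lineages = "host")
  suppressWarnings(fit_model("branched", ds,
                             priors = tight_influx_prior(truth),
                             sampler_config = fast_fit_config(),
                             seed = seed))
}

test_that("weighted mean lifespan matches a brute-force per-draw oracle", {
  tru <- params_recovery_truth()
  fit <- make_mini_fit(tru)
  ls <- suppressWarnings(weighted_mean_lifespan(fit))

  # brute force: recompute per draw from first principles
  n <- nrow(fit$draws)
  brute <- numeric(n)
  for (i in seq_len(n)) {
    d <- fit$draws[i, ]
    p <- memkin:::params_from_natural(model_structure("branched"), d)
    df <- as.data.frame(steady_state("branched", p))
    nA <- sum(df$count[df$subpop == "A"])
    nB <- sum(df$count[df$subpop == "B"])
    brute[i] <- 1 / ((nA * p$delta_A + nB * p$delta_B) / (nA + nB))
  }
  expect_equal(unname(ls$lifespan_draws[seq_len(n)]), brute,
               tolerance = 1e-8)

  # per-draw-then-summarise differs from the deliberately wrong order
  # (computing from posterior means)
  mean_draw <- colMeans(fit$draws)
  p_mean <- memkin:::params_from_natural(model_structure("branched"),
                                         mean_draw)
  df <- as.data.frame(steady_state("branched", p_mean))
  nA <- sum(df$count[df$subpop == "A"]); nB <- sum(df$count[df$subpop == "B"])
  wrong_order <- 1 / ((nA * p_mean$delta_A + nB * p_mean$delta_B) /
                        (nA + nB))
  expect_gt(abs(stats::median(ls$lifespan_draws) - wrong_order), 1e-6)
})

test_that("two equal subpopulations with loss 0.1 and 0.02 give a 16.7-day lifespan", {
  # direct check of the rate-weighting identity on a synthetic posterior
  draws <- cbind(alpha_A = 0.01, lambda_A = 0.01, alpha_B = 0.08,
                 lambda_B = 0.02, psi = NA, beta = 1 / 3.1, epsilon = 0.5,
                 phi_rate = NA, N0 = 1e6, sigma_ki67 = 0.2,
                 sigma_brdu = 0.2, sigma_count = 0.2)
  # choose psi so the steady-state sizes are equal: psi/lam_A = (1-psi)/lam_B
  lamA <- 0.01; lamB <- 0.02
  psi <- lamA / (lamA + lamB)
  draws[, "psi"] <- psi
  draws[, "phi_rate"] <- NA
  fit <- list(draws = draws[rep(1, 5), , drop = FALSE],
              structure = "branched", stages = 1)
  class(fit) <- "posterior_draws"
  # delta_A = 0.01 + 0.01 = 0.02, delta_B = 0.08 + 0.02 = 0.1; influx set
  # to the balancing value
  fit$draws[, "phi_rate"] <- NA
  for (i in seq_len(nrow(fit$draws))) {
    p0 <- kinetic_params(alpha_A = 0.01, delta_A = 0.02, alpha_B = 0.08,
                         delta_B = 0.1, psi = psi, N0 = 1e6, Phi = 1,
                         chi0 = 0, f_d = 0)
    fit$draws[i, "phi_rate"] <-
      balance_influx("branched", p0)$Phi / 1e6
  }
  ls <- weighted_mean_lifespan(fit)
  expect_equal(unname(stats::median(ls$lifespan_draws)), 1 / 0.06,
               tolerance = 1e-6)
})

test_that("single-population lifespan is the inverse loss rate", {
  draws <- cbind(alpha_A = 0.02, lambda_A = 0.03, alpha_B = 0.2,
                 lambda_B = 0.05, psi = 1, beta = 0.3, epsilon = 0.5,
                 phi_rate = 0.03, N0 = 1e5, sigma_ki67 = 0.2,
                 sigma_brdu = 0.2, sigma_count = 0.2)
  fit <- list(draws = draws[rep(1, 3), , drop = FALSE],
              structure = "branched", stages = 1)
  class(fit) <- "posterior_draws"
  ls <- weighted_mean_lifespan(fit)
  expect_equal(unname(ls$lifespan[["50%"]]), 1 / 0.05, tolerance = 1e-8)
})

test_that("upslope estimator evaluates 2 epsilon / p and is linear in epsilon", {
  tc <- data.frame(day = c(1, 2, 3, 4), f_brdu = 0.04 * c(1, 2, 3, 4))
  est <- lifespan_from_upslope(tc, epsilon = 0.5)
  expect_equal(as.numeric(est), 25)
  expect_equal(attr(est, "p"), 0.04)
  expect_equal(as.numeric(lifespan_from_upslope(tc, epsilon = 1)), 50)
  expect_error(lifespan_from_upslope(tc[1:2, ], 0.5), "3 early")
})

test_that("upslope estimator tracks the weighted lifespan with a bounded upward bias", {
  # The quick estimator reads production off the early BrdU upslope; the
  # upslope saturates within the window and the influx is barely labelled
  # early on, so the estimator overestimates the lifespan. The same
  # direction and rough size of bias is visible in the study's own
  # summary numbers, where the upslope-based population estimate (about
  # 25 d) sits well above the model-weighted one (about 18 d).
  for (l in c("host", "donor")) {
    tru <- study_truth("TEM", "young")[[l]]
    tt <- c(0.5, 1, 2, 3, 4)
    tr <- memkin:::single_population_trajectory("branched", tru,
                                                labelling_schedule(), tt)
    pr <- memkin:::predict_observables(tr)
    est <- lifespan_from_upslope(data.frame(day = tt,
                                            f_brdu = pr[, "f_brdu"]),
                                 epsilon = tru$epsilon)
    df <- as.data.frame(steady_state("branched", tru))
    nA <- sum(df$count[df$subpop == "A"])
    nB <- sum(df$count[df$subpop == "B"])
    truth_ls <- 1 / ((nA * tru$delta_A + nB * tru$delta_B) / (nA + nB))
    expect_gt(as.numeric(est), truth_ls)               # upward bias
    expect_lt(abs(est - truth_ls) / truth_ls, 0.6)     # bounded
  }
})

test_that("Ki67 estimator evaluates the closed form and its limits", {
  out <- lifespan_from_ki67(0.2, 0.2, T_ki67 = 3.1, em_cm_ratio = 1)
  expect_equal(unname(out$per_subset["TCM"]), 3.1 / -log(0.9),
               tolerance = 1e-10)
  expect_equal(unname(out$per_subset["TCM"]), 29.4, tolerance = 1e-2)

  # k -> 0: no production, lifespan diverges
  out0 <- lifespan_from_ki67(1e-12, 1e-12)
  expect_identical(unname(out0$per_subset[["TCM"]]), Inf)
  expect_identical(out0$lifespan, Inf)

  # aggregation limits: ratio -> 0 gives the TCM value, -> large the TEM
  lo <- lifespan_from_ki67(0.4, 0.2, em_cm_ratio = 1e-12)
  hi <- lifespan_from_ki67(0.4, 0.2, em_cm_ratio = 1e12)
  expect_equal(lo$lifespan, unname(lo$per_subset["TCM"]), tolerance = 1e-9)
  expect_equal(hi$lifespan, unname(hi$per_subset["TEM"]), tolerance = 1e-9)

  expect_error(lifespan_from_ki67(1.2, 0.2), "fractions")
})
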