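# Donor-replacement analysis: chimerism, replacement fits, influx priors
# and the precursor-ordering comparison.

test_that("normalized chimerism handles raw, referenced and degenerate inputs", {
  expect_equal(normalized_chimerism(70, 30), 0.70)
  expect_equal(as.numeric(normalized_chimerism(70, 30, 0.70)), 1.00)
  expect_equal(normalized_chimerism(0, 50), 0)
  expect_warning(f <- normalized_chimerism(0, 0), "undefined")
  expect_true(is.na(f))
  # above-reference values are flagged, not clipped
  f2 <- normalized_chimerism(90, 10, 0.7)
  expect_gt(as.numeric(f2), 1)
  expect_true(attr(f2, "above_one"))
  expect_error(normalized_chimerism(1, 1, 0), "reference")
})

test_that("first-order replacement fit recovers a noise-free curve within 1%", {
  cur <- generate_chimerism_dataset(list(phi = 0.03, f_d = 0.8,
                                         F0 = 0.001),
                                    days = seq(20, 300, 20),
                                    mice_per_point = 1, noise = 0, seed = 1)
  # zero noise: points lie exactly on the analytic solution
  f_obs <- with(cur$data, donor_count / (donor_count + host_count))
  expect_equal(f_obs,
               0.8 + (0.001 - 0.8) * exp(-0.03 * cur$data$days_post_bmt),
               tolerance = 1e-12)
  fit <- suppressWarnings(fit_replacement(cur, seed = 4))
  expect_lt(abs(fit$summary["phi", "50%"] - 0.03) / 0.03, 0.01)
  expect_lt(abs(fit$summary["f_d", "50%"] - 0.8) / 0.8, 0.01)
})

test_that("a source matching the starting fraction leaves chimerism constant", {
  F0 <- 0.35
  expect_equal(memkin:::replacement_solution(c(0, 50, 400), phi = 0.02,
                                             f_d = F0, F0 = F0),
               rep(F0, 3))
})

test_that("fitted replacement curves stay in [0,1] and rise monotonically to the source", {
  cur <- generate_chimerism_dataset(list(phi = 0.012, f_d = 0.7, F0 = 0.01),
                                    days = seq(40, 400, 40),
                                    mice_per_point = 2, noise = 0.25,
                                    seed = 6)
  fit <- suppressWarnings(fit_replacement(cur, seed = 2))
  tt <- seq(0, 500, by = 10)
  for (i in seq(1, nrow(fit$draws), length.out = 50)) {
    d <- fit$draws[round(i), ]
    Ft <- memkin:::replacement_solution(tt, d[["phi"]], d[["f_d"]],
                                        d[["F0"]])
    expect_true(all(Ft >= 0 & Ft <= 1))
    if (d[["f_d"]] >= d[["F0"]]) expect_true(all(diff(Ft) >= -1e-12))
  }
})

test_that("late-time saturation levels are recovered within the credible interval", {
  # curves generated with the study-like asymptotes: T_CM ~ 0.7, T_EM ~ 0.6
  for (case in list(list(pop = "TCM", f_d = 0.7, phi = 0.012),
                    list(pop = "TEM", f_d = 0.6, phi = 0.008))) {
    cur <- generate_chimerism_dataset(list(phi = case$phi, f_d = case$f_d,
                                           F0 = 0.01),
                                      days = seq(40, 600, 40),
                                      mice_per_point = 2, noise = 0.25,
                                      seed = 11, population = case$pop)
    fit <- suppressWarnings(fit_replacement(cur, seed = 3))
    expect_gt(case$f_d, fit$summary["f_d", "2.5%"])
    expect_lt(case$f_d, fit$summary["f_d", "97.5%"])
  }
})

test_that("chimerism-derived priors transfer the replacement-rate posterior", {
  cur <- generate_chimerism_dataset(list(phi = 0.02, f_d = 0.75, F0 = 0.01),
                                    days = seq(40, 400, 40),
                                    mice_per_point = 2, noise = 0.2,
                                    seed = 8)
  fit <- suppressWarnings(fit_replacement(cur, seed = 5))
  pri <- influx_prior(fit)
  expect_equal(pri$phi_rate$dist, "lognormal")
  expect_equal(exp(pri$phi_rate$meanlog), 0.02, tolerance = 0.35)
  expect_gt(pri$phi_rate$sdlog, 0)
})

test_that("precursor ranking identifies the naive -> TCM -> TEM ordering", {
  # observed chimerism of candidate precursors, emulating the young cohort:
  # DP1 highest, then naive, then TCM itself
  set.seed(20)
  candidates <- list(DP1 = stats::rnorm(6, 0.95, 0.02),
                     naive = stats::rnorm(6, 0.85, 0.03),
                     TCM = stats::rnorm(6, 0.45, 0.04))
  n_top <- 0
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    # influx into TCM carries naive-like chimerism; influx into TEM
    # carries TCM-like chimerism
    cur_tcm <- generate_chimerism_dataset(
      list(phi = 0.015, f_d = 0.85, F0 = 0.02),
      days = seq(40, 400, 40), mice_per_point = 2, noise = 0.25,
      seed = 300 + r, population = "TCM")
    cur_tem <- generate_chimerism_dataset(
      list(phi = 0.01, f_d = 0.45, F0 = 0.02),
      days = seq(40, 400, 40), mice_per_point = 2, noise = 0.25,
      seed = 600 + r, population = "TEM")
    fit_tcm <- suppressWarnings(fit_replacement(cur_tcm, seed = r))
    fit_tem <- suppressWarnings(fit_replacement(cur_tem, seed = r + 50))
    ok_tcm <- rank_precursors(fit_tcm, candidates)$candidate[1] == "naive"
    ok_tem <- rank_precursors(fit_tem, candidates)$candidate[1] == "TCM"
    n_top <- n_top + (ok_tcm && ok_tem)
  }
  expect_gte(n_top / n_rep, 0.8)
})

test_that("replacement fits refuse sparse timecourses", {
  cur <- generate_chimerism_dataset(list(phi = 0.02, f_d = 0.7),
                                    days = c(50, 100, 150),
                                    mice_per_point = 3, seed = 1)
  expect_error(fit_replacement(cur), "5 distinct timepoints")
})
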