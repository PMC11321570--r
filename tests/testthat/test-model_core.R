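# Core ODE machinery: steady states, labelling kinetics, observables.

test_that("steady-state Ki67 fractions match closed forms and long-time integration", {
  # balanced single population, no influx: k* = 2a / (a + beta + d)
  p <- params_single_balanced(alpha = 0.05)
  k <- ki67_steady_fraction("branched", p)
  expect_equal(k, 2 * 0.05 / (0.05 + 1 / 3.1 + 0.05), tolerance = 1e-10)

  # influx-fed population, influx all Ki67-high, Phi = (d - a) N0:
  # k* = (d + a) / (a + beta + d)
  p2 <- kinetic_params(alpha_A = 0.05, delta_A = 0.1, psi = 1,
                       Phi = 0.05 * 1e5, N0 = 1e5, beta = 1 / 3.1,
                       chi0 = 0.4)
  k2 <- ki67_steady_fraction("branched", p2)
  expect_equal(k2, (0.1 + 0.05) / (0.05 + 1 / 3.1 + 0.1), tolerance = 1e-8)

  # oracle: long-time integration reaches the same fraction
  sch <- labelling_schedule(t_pulse_end = 0, t_chase_end = 1e4, s_max = 0)
  tr <- integrate_labelling("branched", p2, sch, times = c(0, 1e4),
                            method = "lsoda")
  ob <- observables(tr, pool_lineages = TRUE)
  k_long <- ob$f_ki67hi[ob$lineage == "all" & ob$day == 1e4]
  expect_equal(k_long, k2, tolerance = 1e-6)

  # agreement between the analytic accessor and the steady_state solve
  st <- steady_state("branched", p2)
  df <- as.data.frame(st)
  expect_equal(sum(df$count[startsWith(df$kstage, "hi")]) / sum(df$count),
               k2, tolerance = 1e-10)
})

test_that("branched steady state splits influx across subpopulations by psi", {
  lamA <- 0.02 - 0.01; lamB <- 0.25 - 0.2
  N0 <- 0.3 * 100 / lamA + 0.7 * 100 / lamB
  p <- kinetic_params(alpha_A = 0.01, delta_A = 0.02, alpha_B = 0.2,
                      delta_B = 0.25, psi = 0.3, Phi = 100, N0 = N0,
                      chi0 = 0.5)
  df <- as.data.frame(steady_state("branched", p))
  expect_equal(sum(df$count[df$subpop == "A"]), 0.3 * 100 / lamA,
               tolerance = 1e-8)
  expect_equal(sum(df$count[df$subpop == "B"]), 0.7 * 100 / lamB,
               tolerance = 1e-8)
  expect_equal(sum(df$count), N0, tolerance = 1e-8)
  # implied influx equals the prescribed influx when sizes are consistent
  expect_equal(implied_influx("branched", p), 100, tolerance = 1e-8)
  # donor/host split consistent with chi0
  expect_equal(sum(df$count[df$lineage == "donor"]) / sum(df$count), 0.5,
               tolerance = 1e-12)
})

test_that("non-equilibrating parameters raise an explicit failure", {
  # fast subpopulation with division > loss and no efflux: unbounded
  expect_error(
    steady_state("branched", kinetic_params(alpha_B = 0.3, delta_B = 0.2,
                                            psi = 0.5, Phi = 100)),
    "no non-negative steady state")
  # closed population with unbalanced rates has no non-trivial equilibrium
  expect_error(
    steady_state("branched", kinetic_params(alpha_A = 0.05, delta_A = 0.1,
                                            psi = 1, Phi = 0)),
    "no non-trivial steady state")
  expect_error(ki67_steady_fraction("branched",
                                    kinetic_params(alpha_B = 0.3,
                                                   delta_B = 0.2,
                                                   psi = 0.5, Phi = 100)),
               "steady state")
})

test_that("BrdU uptake follows 1 - exp(-2 alpha t) for epsilon = 1, Phi = 0", {
  p <- params_single_balanced(alpha = 0.1, epsilon = 1, chi0 = 0)
  sch <- labelling_schedule(21, 35)
  tt <- c(0, 1, 2, 5, 10, 15, 21)
  tr <- integrate_labelling("branched", p, sch, tt)
  ob <- suppressWarnings(observables(tr))  # donor lineage empty by design
  h <- ob[ob$lineage == "host", ]
  expect_equal(h$f_brdu, 1 - exp(-2 * 0.1 * h$day), tolerance = 1e-6)
  expect_equal(h$f_brdu[h$day == 5], 0.632, tolerance = 1e-3)
  # total size constant for a balanced population
  expect_equal(h$n_cells, rep(p$N0, length(tt)), tolerance = 1e-6)
})

test_that("no labelling pathway means no labelled cells", {
  p <- params_single_balanced(alpha = 0.1, epsilon = 0)
  sch <- labelling_schedule(21, 35, s_max = 0)
  tr <- integrate_labelling("branched", p, sch, c(0, 5, 21, 30))
  ob <- observables(tr, pool_lineages = TRUE)
  expect_true(all(ob$f_brdu == 0))
})

test_that("branched pulse kinetics show the study's qualitative signatures", {
  # BrdU within Ki67-high rises steeply towards an asymptote < 1 when
  # epsilon < 1; BrdU+ Ki67-low cells appear only after a Ki67-lifetime
  # delay
  tru <- study_truth("TCM", "young")$donor
  sch <- labelling_schedule()
  tt <- c(0.5, 1, 2, 4, 7, 14, 21)
  tr <- single_population_trajectory("branched", tru, sch, tt)
  pr <- predict_observables(tr)
  f_hi <- pr[, "f_brdu_in_ki67hi"]
  expect_true(all(diff(f_hi) > -1e-9))          # monotone rise
  expect_gt(f_hi[4], 0.5)                        # steep early rise
  expect_lt(max(f_hi), 0.97)                     # asymptote below 1
  f_lo <- pr[, "f_brdu_in_ki67lo"]
  expect_lt(f_lo[1], 0.02)                       # delayed appearance
  expect_gt(f_lo[7], 0.1)
})

test_that("mass balance holds along trajectories for every structure", {
  sch <- labelling_schedule()
  cases <- list(
    branched = balance_influx("branched", kinetic_params(
      N0 = 1e5, chi0 = 0.4, f_d = 0.6, Phi = 1)),
    linear = balance_influx("linear", kinetic_params(
      alpha_A = 0.2, delta_A = 0.25, alpha_B = 0.01, delta_B = 0.02,
      gamma = 0.05, N0 = 1e5, chi0 = 0.4, f_d = 0.6, Phi = 1)),
    burst = balance_influx("burst", kinetic_params(
      alpha_A = 0.01, delta_A = 0.02, alpha_B = 0.3, delta_B = 0.35,
      omega = 0.01, rho = 0.05, N0 = 1e5, chi0 = 0.4, f_d = 0.6, Phi = 1)),
    temporal = balance_influx("temporal", kinetic_params(
      alpha_A = 0.05, delta_hi = 0.12, delta_lo = 0.06, N0 = 1e5,
      chi0 = 0.4, f_d = 0.6, Phi = 1)))
  for (nm in names(cases)) {
    p <- cases[[nm]]
    tt <- seq(0, 35, by = 0.5)
    tr <- integrate_labelling(nm, p, sch, tt)
    N <- rowSums(tr$states)
    # numerical dN/dt vs Phi + sum_i (alpha_i - delta_i) N_i
    comp <- tr$comp
    st <- as_structure(nm)
    for (j in c(10, 30, 50)) {
      dN <- (N[j + 1] - N[j - 1]) / (tt[j + 1] - tt[j - 1])
      x <- tr$states[j, ]
      flux <- p$Phi
      for (sp in unique(comp$subpop)) for (hi in c(TRUE, FALSE)) {
        sel <- comp$subpop == sp & comp$is_hi == hi
        flux <- flux +
          (memkin:::division_rate(st, p, sp) -
             memkin:::loss_rate(st, p, sp, hi)) * sum(x[sel])
      }
      expect_equal(dN, flux, tolerance = 1e-3 * max(abs(flux), 1),
                   label = paste(nm, "mass balance"))
    }
    # quasi-equilibrium: balanced influx keeps N and Ki67 constant over 35 d
    ob <- observables(tr, pool_lineages = TRUE)
    oa <- ob[ob$lineage == "all", ]
    expect_lt(diff(range(oa$n_cells)) / p$N0, 1e-6)
    expect_lt(diff(range(oa$f_ki67hi)), 1e-6)
  }
})

test_that("BrdU fraction within Ki67-high is non-decreasing during the pulse", {
  for (tru in list(study_truth("TCM", "young")$host,
                   study_truth("TEM", "old")$donor)) {
    tr <- single_population_trajectory("branched", tru,
                                       labelling_schedule(),
                                       seq(0.5, 21, by = 0.5))
    f <- predict_observables(tr)[, "f_brdu_in_ki67hi"]
    expect_true(all(diff(f) > -1e-9))
  }
})

test_that("observables handle trivial and undefined cases explicitly", {
  p <- params_single_balanced(chi0 = 0.3, epsilon = 0)
  tr <- integrate_labelling("branched", p,
                            labelling_schedule(s_max = 0), c(0, 5))
  ob <- observables(tr)
  expect_true(all(ob$f_brdu == 0))               # all unlabelled

  # state with equal counts in all 16 compartments: every fraction 0.5
  comp <- memkin:::compartment_table(model_structure("branched"), 1)
  st0 <- memkin:::new_label_state(rep(2, nrow(comp)), comp,
                                  model_structure("branched"), 1)
  tr2 <- tr; tr2$states[1, ] <- rep(2, nrow(comp)); tr2$comp <- comp
  ob2 <- observables(tr2)
  expect_equal(ob2$f_ki67hi[1], 0.5)
  expect_equal(ob2$f_brdu[1], 0.5)
  expect_equal(ob2$f_brdu_in_ki67hi[1], 0.5)
  expect_equal(ob2$f_brdu_in_ki67lo[1], 0.5)

  # empty donor lineage: undefined fractions are NA with a warning
  p0 <- params_single_balanced(chi0 = 0)
  tr0 <- integrate_labelling("branched", p0, labelling_schedule(), c(0, 5))
  expect_warning(ob0 <- observables(tr0), "undefined")
  expect_true(all(is.na(ob0$f_ki67hi[ob0$lineage == "donor"])))
  expect_false(anyNA(ob0$f_ki67hi[ob0$lineage == "host"]))
})

test_that("Erlang-staged Ki67 preserves totals and matches the reference integrator", {
  p <- balance_influx("branched",
                      kinetic_params(N0 = 1e5, chi0 = 0.4, f_d = 0.6,
                                     Phi = 1), stages = 3)
  sch <- labelling_schedule()
  tt <- c(0, 2, 5, 10, 21, 28, 35)
  tr <- integrate_labelling("branched", p, sch, tt, stages = 3)
  tr2 <- integrate_labelling("branched", p, sch, tt, stages = 3,
                             method = "lsoda")
  expect_lt(max(abs(tr$states - tr2$states)) / p$N0, 1e-6)
  expect_lt(diff(range(rowSums(tr$states))) / p$N0, 1e-6)
  # the mean Ki67-high duration is 1/beta regardless of staging; the
  # steady-state fraction shifts only moderately with the duration's shape
  k1 <- ki67_steady_fraction("branched", p, stages = 1)
  k3 <- ki67_steady_fraction("branched", p, stages = 3)
  expect_lt(abs(k1 - k3) / k1, 0.25)
})

test_that("exact eigendecomposition route agrees with lsoda across structures", {
  sch <- labelling_schedule()
  tt <- c(0, 1, 3, 8, 15, 21, 26, 35)
  cases <- list(
    branched = balance_influx("branched", kinetic_params(
      N0 = 1e5, chi0 = 0.4, f_d = 0.6, Phi = 1)),
    temporal = balance_influx("temporal", kinetic_params(
      alpha_A = 0.05, delta_hi = 0.12, delta_lo = 0.06,
      N0 = 1e5, chi0 = 0.4, f_d = 0.6, Phi = 1)))
  for (nm in names(cases)) {
    tr1 <- integrate_labelling(nm, cases[[nm]], sch, tt, method = "eigen")
    tr2 <- integrate_labelling(nm, cases[[nm]], sch, tt, method = "lsoda")
    expect_lt(max(abs(tr1$states - tr2$states)) / 1e5, 1e-6)
  }
})

test_that("a Gillespie simulation of the reaction scheme reproduces ODE observables", {
  p <- balance_influx("branched", kinetic_params(
    alpha_A = 0.01, delta_A = 0.02, alpha_B = 0.2, delta_B = 0.25,
    psi = 0.4, epsilon = 0.5, beta = 1 / 3.1, N0 = 1e4, chi0 = 0,
    f_d = 0, Phi = 1))
  sch <- labelling_schedule()
  checkpoints <- c(2, 5, 8, 11, 14)
  n_rep <- 4
  sims <- lapply(seq_len(n_rep), function(r)
    gillespie_labelling("branched", p, sch, checkpoints, seed = 400 + r))
  tr <- single_population_trajectory("branched", p, sch, checkpoints)
  pr <- predict_observables(tr)
  for (obs in c("ki67", "brdu")) {
    ode_col <- c(ki67 = "f_ki67hi", brdu = "f_brdu")[[obs]]
    for (i in seq_along(checkpoints)) {
      vals <- vapply(sims, function(s) s[[obs]][i], numeric(1))
      mc_se <- stats::sd(vals) / sqrt(n_rep)
      expect_lt(abs(mean(vals) - pr[i, ode_col]),
                3 * max(mc_se, 0.005),
                label = sprintf("%s at day %g", obs, checkpoints[i]))
    }
  }
})
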