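# Observation model: logit-normal errors on fractions, log-normal errors on
# cell counts. Each fitted timecourse is treated as one population (the
# study fitted host- and donor-derived timecourses separately), so model
# predictions pool the lineage compartments.

OBSERVABLE_FRACTIONS <- c("f_ki67hi", "f_brdu", "f_brdu_in_ki67hi",
                          "f_brdu_in_ki67lo")

# Fast single-population trajectory for likelihood evaluation: one lineage,
# exact eigendecomposition route with lsoda fallback.
#' @keywords internal
single_population_trajectory <- function(structure, params, schedule, days,
                                         stages = 1) {
  structure <- as_structure(structure)
  cache <- get_model_cache(structure, stages)
  comp <- cache$comp
  M <- assemble_matrix(cache$tm1, structure, params, epsilon_eff = 0)
  p1 <- unclass(params); p1$Phi <- 1
  b <- assemble_influx(cache, structure, p1, brdu = FALSE)$unlab
  shape <- if (params$Phi > 0) steady_shape_influx(structure, M, b,
                                                   cache$comp1)
           else steady_shape_closed(structure, params, M, cache$comp1)
  if (any(shape < -1e-9)) stop("no non-negative steady state", call. = FALSE)
  shape <- pmax(shape, 0); shape <- shape / sum(shape)
  x0 <- numeric(nrow(comp))
  x0[cache$uidx] <- params$N0 * shape[match(cache$keyU, cache$key1)]
  A_pulse <- assemble_matrix(cache$tm, structure, params,
                             epsilon_eff = params$epsilon)
  A_chase <- assemble_matrix(cache$tm, structure, params, epsilon_eff = 0)
  bv <- assemble_influx(cache, structure, params, brdu = TRUE)
  days <- sort(unique(days))
  tp <- min(schedule$t_pulse_end, schedule$t_chase_end)
  states <- if (is.null(schedule$custom_fn))
    integrate_eigen(A_pulse, A_chase, bv, schedule, x0, days, tp) else NULL
  if (is.null(states))
    states <- integrate_lsoda(A_pulse, A_chase, bv, schedule, x0, days, tp,
                              rtol = 1e-8, atol = 1e-10 * max(params$N0, 1))
  states[states < 0] <- 0
  list(days = days, states = states, comp = comp)
}

# Predicted observables (pooled population) as a matrix days x 5.
#' @keywords internal
predict_observables <- function(traj) {
  comp <- traj$comp
  st <- traj$states
  N <- rowSums(st)
  hi <- rowSums(st[, comp$is_hi, drop = FALSE])
  lab <- rowSums(st[, comp$brdu == "L", drop = FALSE])
  lab_hi <- rowSums(st[, comp$is_hi & comp$brdu == "L", drop = FALSE])
  sdiv <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  cbind(day = traj$days, n_cells = N,
        f_ki67hi = sdiv(hi, N), f_brdu = sdiv(lab, N),
        f_brdu_in_ki67hi = sdiv(lab_hi, hi),
        f_brdu_in_ki67lo = sdiv(lab - lab_hi, N - hi))
}

#' Log-likelihood of a labelling timecourse
#'
#' Sum of per-observation contributions for one timecourse under a given
#' structure and parameter set. Fractions are compared on the logit scale
#' with normal errors (after a continuity correction replacing observed or
#' predicted 0/1 by `1/(2 n_cells)` from the boundary); counts are compared
#' on the log scale. Observations recorded as `NA` (undefined, e.g. a
#' fraction of an empty gate) contribute 0 and are counted in
#' `attr(pointwise, "n_undefined")`.
#'
#' @param structure a [model_structure()] or name.
#' @param params a [kinetic_params()].
#' @param dataset a labelling dataset (see [generate_labelling_dataset()]);
#'   treated as a single timecourse.
#' @param noise list of error scales: `sigma_ki67` (logit scale, Ki67-high
#'   fraction), `sigma_brdu` (logit scale, the three BrdU fractions),
#'   `sigma_count` (log scale, cell counts).
#' @param schedule a [labelling_schedule()].
#' @param stages Ki67-high Erlang stages.
#' @return list with `total` and `pointwise` (named vector, one entry per
#'   observed scalar, in row-major dataset order).
#' @export
log_likelihood <- function(structure, params, dataset,
                           noise = list(sigma_ki67 = 0.25, sigma_brdu = 0.25,
                                        sigma_count = 0.2),
                           schedule = labelling_schedule(), stages = 1) {
  traj <- single_population_trajectory(structure, params, schedule,
                                       dataset$day, stages)
  pred <- predict_observables(traj)
  pr <- pred[match(dataset$day, pred[, "day"]), , drop = FALSE]
  n <- nrow(dataset)
  obs_names <- c(OBSERVABLE_FRACTIONS, "n_cells")
  pw <- matrix(NA_real_, n, length(obs_names),
               dimnames = list(NULL, obs_names))
  n_undef <- 0L
  nc <- pmax(dataset$n_cells, 1)
  for (ob in OBSERVABLE_FRACTIONS) {
    o <- dataset[[ob]]
    p <- pr[, ob]
    sigma <- if (ob == "f_ki67hi") noise$sigma_ki67 else noise$sigma_brdu
    ok <- !is.na(o) & !is.na(p)
    n_undef <- n_undef + sum(!ok)
    pw[!ok, ob] <- 0
    pw[ok, ob] <- stats::dnorm(logit(continuity_correct(o[ok], nc[ok])),
                               logit(continuity_correct(p[ok], nc[ok])),
                               sigma, log = TRUE)
  }
  okc <- !is.na(dataset$n_cells) & dataset$n_cells > 0
  n_undef <- n_undef + sum(!okc)
  pw[!okc, "n_cells"] <- 0
  pw[okc, "n_cells"] <- stats::dnorm(log(dataset$n_cells[okc]),
                                     log(pr[okc, "n_cells"]),
                                     noise$sigma_count, log = TRUE)
  pointwise <- as.vector(t(pw))
  names(pointwise) <- paste(rep(seq_len(n), each = length(obs_names)),
                            rep(obs_names, n), sep = ".")
  attr(pointwise, "n_undefined") <- n_undef
  list(total = sum(pointwise), pointwise = pointwise)
}
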