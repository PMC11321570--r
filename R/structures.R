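#' Model structures for kinetic heterogeneity within a memory subset
#'
#' Four candidate architectures for the sub-structure of a memory T cell
#' population fed by constant influx:
#'
#' * `"branched"` — new cells immediately bifurcate into two independent
#'   subpopulations A and B with distinct division and loss rates; a fraction
#'   `psi` of the influx enters A. Convention: A is the slow subpopulation,
#'   B the fast one.
#' * `"linear"` — cells enter as phenotype A (the fast entry state) and
#'   mature into a kinetically distinct phenotype B (slow descendant) at rate
#'   `gamma`; maturation preserves Ki67 and BrdU status.
#' * `"burst"` — quiescent cells (A) are triggered into a short-lived,
#'   rapidly dividing state (B) at rate `omega` and return at rate `rho`;
#'   influx enters the burst state B (new memory cells have recently divided).
#' * `"temporal"` — a single kinetic population whose loss rate depends on
#'   Ki67 expression (`delta_hi` vs `delta_lo`); division rate `alpha_A` is
#'   uniform.
#'
#' @param name one of `"branched"`, `"linear"`, `"burst"`, `"temporal"`.
#' @return an object of class `model_structure`.
#' @export
model_structure <- function(name = c("branched", "linear", "burst", "temporal")) {
  name <- match.arg(name)
  structure(
    list(
      name = name,
      active = switch(name,
        branched = c("alpha_A", "delta_A", "alpha_B", "delta_B", "psi"),
        linear   = c("alpha_A", "delta_A", "alpha_B", "delta_B", "gamma"),
        burst    = c("alpha_A", "delta_A", "alpha_B", "delta_B", "omega", "rho"),
        temporal = c("alpha_A", "delta_hi", "delta_lo")
      )
    ),
    class = "model_structure"
  )
}

#' @export
print.model_structure <- function(x, ...) {
  cat("<model_structure> ", x$name, "\n  active kinetic parameters: ",
      paste(x$active, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @keywords internal
as_structure <- function(x) {
  if (inherits(x, "model_structure")) x else model_structure(x)
}

#' Kinetic parameters for one memory subset
#'
#' All rates are per day; fractions are dimensionless in \[0, 1\]. Parameters
#' not used by a given [model_structure()] are ignored (they need not be zero).
#'
#' @param alpha_A,delta_A division and loss rate of subpopulation A.
#' @param alpha_B,delta_B division and loss rate of subpopulation B.
#' @param psi fraction of the influx entering A (branched structure only).
#' @param gamma A to B maturation rate (linear structure only).
#' @param omega,rho quiescent-to-burst and burst-to-quiescent transition rates
#'   (burst structure only).
#' @param beta Ki67-high to Ki67-low transition rate; the mean duration of
#'   Ki67-high expression is `T = 1/beta` (about 3.1 days in fitted values).
#' @param epsilon per-division BrdU labelling efficiency.
#' @param Phi total influx of new memory cells, cells/day.
#' @param f_d donor fraction of the influx (the chimerism of the source).
#' @param N0 total population size at the start of the pulse, cells.
#' @param chi0 donor fraction of the standing population at pulse start.
#' @param delta_hi,delta_lo loss rates of Ki67-high / Ki67-low cells
#'   (temporal structure only).
#' @return an object of class `kinetic_params` (a named list).
#' @export
kinetic_params <- function(alpha_A = 0.01, delta_A = 0.02,
                           alpha_B = 0.2, delta_B = 0.25,
                           psi = 0.5, gamma = 0.01,
                           omega = 0.01, rho = 0.01,
                           beta = 1 / 3.1, epsilon = 0.5,
                           Phi = 0, f_d = 0.5,
                           N0 = 1e6, chi0 = 0.5,
                           delta_hi = 0.05, delta_lo = 0.02) {
  p <- list(alpha_A = alpha_A, delta_A = delta_A,
            alpha_B = alpha_B, delta_B = delta_B,
            psi = psi, gamma = gamma, omega = omega, rho = rho,
            beta = beta, epsilon = epsilon,
            Phi = Phi, f_d = f_d, N0 = N0, chi0 = chi0,
            delta_hi = delta_hi, delta_lo = delta_lo)
  rates <- c("alpha_A", "delta_A", "alpha_B", "delta_B", "gamma", "omega",
             "rho", "beta", "Phi", "N0", "delta_hi", "delta_lo")
  fracs <- c("psi", "epsilon", "f_d", "chi0")
  for (r in rates) assert_nonneg(p[[r]], r)
  for (f in fracs) assert_prob(p[[f]], f)
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  v <- unlist(x)
  print(round(v, 6))
  invisible(x)
}

#' Update a parameter set
#' @param object a [kinetic_params()] object.
#' @param ... named parameter values to replace.
#' @return updated `kinetic_params`.
#' @export
update.kinetic_params <- function(object, ...) {
  repl <- list(...)
  do.call(kinetic_params, utils::modifyList(unclass(object), repl))
}

#' BrdU labelling schedule
#'
#' The study design is a pulse of BrdU in drinking water starting at day 0
#' (after an initial injection), maintained to `t_pulse_end`, followed by a
#' chase to `t_chase_end` with no label available. The BrdU content of the
#' influx of new memory cells is described by a parametric saturation curve
#' `s(t) = s_max (1 - exp(-r_s t))` during the pulse and exponential decay
#' `s(t_pulse_end) exp(-r_s (t - t_pulse_end))` during the chase, reflecting
#' gradual labelling and de-labelling of the precursor population.
#'
#' @param t_pulse_end end of BrdU administration, days (default 21).
#' @param t_chase_end end of the observation window, days (default 35).
#' @param s_max asymptotic labelled fraction of the influx.
#' @param r_s rate of approach to `s_max` (and of post-pulse decay), per day.
#' @param source_label_fn optional replacement function `f(t)` giving the
#'   labelled fraction of the influx; overrides the parametric form. Using a
#'   non-parametric function forces the slower general-purpose integrator.
#' @return an object of class `labelling_schedule`.
#' @export
labelling_schedule <- function(t_pulse_end = 21, t_chase_end = 35,
                               s_max = 0.3, r_s = 0.1,
                               source_label_fn = NULL) {
  if (t_pulse_end < 0 || t_chase_end < t_pulse_end)
    stop("need 0 <= t_pulse_end <= t_chase_end", call. = FALSE)
  assert_prob(s_max, "s_max")
  assert_nonneg(r_s, "r_s")
  sch <- structure(
    list(t_pulse_end = t_pulse_end, t_chase_end = t_chase_end,
         s_max = s_max, r_s = r_s, custom_fn = source_label_fn),
    class = "labelling_schedule"
  )
  sch
}

#' Labelled fraction of the influx at time t
#' @param schedule a [labelling_schedule()].
#' @param t time in days since the start of the pulse.
#' @return labelled fraction(s) in \[0, 1\].
#' @export
source_label <- function(schedule, t) {
  if (!is.null(schedule$custom_fn)) {
    out <- vapply(t, schedule$custom_fn, numeric(1))
    assert_prob(out, "source_label_fn(t)")
    return(out)
  }
  tp <- schedule$t_pulse_end
  s_pe <- schedule$s_max * (1 - exp(-schedule$r_s * tp))
  ifelse(t <= tp,
         schedule$s_max * (1 - exp(-schedule$r_s * t)),
         s_pe * exp(-schedule$r_s * (t - tp)))
}
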