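# Study-shaped synthetic data: BrdU/Ki67 labelling timecourses and
# donor-replacement curves generated from known ground truth, so that every
# stage of the analysis is testable without the original measurements.
# Defaults emulate the study design: a 21-day BrdU pulse with a 14-day
# chase, 2 mice per timepoint per lineage, two age cohorts labelled at
# different times after bone-marrow transplant, quasi-equilibrium population
# sizes, and multiplicative (logit / log scale) measurement noise.

#' Study design for a labelling experiment
#'
#' @param cohort `"young"` (labelled about 56-91 days post-BMT) or `"old"`
#'   (about 246-260 days post-BMT).
#' @param days observation days since BrdU start, within \[0, 35\].
#' @param mice_per_point mice per timepoint per lineage (default 2).
#' @param sigma_frac logit-scale noise SD for fraction observables
#'   (default 0.25, chosen to match the scatter of the study timecourses).
#' @param sigma_count log-scale noise SD for cell counts (default 0.2).
#' @param t_pulse_end,t_chase_end pulse and chase boundaries, days.
#' @param bmt_offset days between BMT and the start of labelling (defaults
#'   to 75 for the young cohort, 250 for the old).
#' @return object of class `study_design`.
#' @export
study_design <- function(cohort = c("young", "old"),
                         days = c(1, 3, 5, 7, 10, 14, 17, 21, 24, 28, 31, 35),
                         mice_per_point = 2,
                         sigma_frac = 0.25, sigma_count = 0.2,
                         t_pulse_end = 21, t_chase_end = 35,
                         bmt_offset = NULL) {
  cohort <- match.arg(cohort)
  if (any(days < 0 | days > t_chase_end))
    stop("observation days must lie in [0, t_chase_end]", call. = FALSE)
  if (mice_per_point < 1) stop("need at least 1 mouse per point",
                               call. = FALSE)
  structure(list(cohort = cohort, days = sort(days),
                 mice_per_point = as.integer(mice_per_point),
                 sigma_frac = sigma_frac, sigma_count = sigma_count,
                 t_pulse_end = t_pulse_end, t_chase_end = t_chase_end,
                 bmt_offset = bmt_offset %||%
                   if (cohort == "young") 75 else 250),
            class = "study_design")
}

#' Ground-truth parameters emulating the study conditions
#'
#' Per-lineage branched-model parameter sets for one memory subset and age
#' cohort, calibrated so the synthetic populations reproduce the headline
#' features of the data: steady-state Ki67-high fractions around 0.4 (T_CM)
#' and 0.2 (T_EM) with donor cells expressing Ki67 more frequently than
#' host in the young cohort; fast cells dividing and dying over days and
#' slow cells over months; per-capita influx of a few percent per day; and
#' standing chimerism lower in the young cohort than the old. Donor/host
#' differences are carried by the influx split between fast and slow
#' subpopulations (donor pools, being younger, are enriched for fast
#' cells).
#'
#' @param subset `"TCM"` or `"TEM"`.
#' @param cohort `"young"` or `"old"`.
#' @return list with elements `host` and `donor`, each a
#'   [kinetic_params()] describing that lineage as a single population
#'   (its `N0` is the lineage pool size, its `Phi` the lineage influx).
#' @export
study_truth <- function(subset = c("TCM", "TEM"),
                        cohort = c("young", "old")) {
  subset <- match.arg(subset)
  cohort <- match.arg(cohort)
  # subset-level kinetics: fast cells (B) turn over in days, slow (A) in
  # months; T_EM slow cells divide a little more than T_CM slow cells
  base <- list(
    TCM = list(alpha_A = 0.005, delta_A = 0.012,
               alpha_B = 0.24, delta_B = 0.254, N = 4e5),
    TEM = list(alpha_A = 0.008, delta_A = 0.015,
               alpha_B = 0.15, delta_B = 0.164, N = 3e6))[[subset]]
  # fraction of influx entering the slow subpopulation, per lineage:
  # donor (younger clones) skewed towards fast; host/donor converge with
  # cohort age
  psi_slow <- if (subset == "TCM") {
    if (cohort == "young") c(host = 0.283, donor = 0.053)
    else c(host = 0.283, donor = 0.25)
  } else {
    if (cohort == "young") c(host = 0.61, donor = 0.294)
    else c(host = 0.61, donor = 0.45)
  }
  chi0 <- if (cohort == "young") {
    if (subset == "TCM") 0.40 else 0.30
  } else {
    if (subset == "TCM") 0.65 else 0.55
  }
  f_d <- if (cohort == "young") {
    if (subset == "TCM") 0.85 else 0.45
  } else {
    if (subset == "TCM") 0.80 else 0.70
  }
  out <- list()
  for (l in c("host", "donor")) {
    frac <- if (l == "donor") chi0 else 1 - chi0
    p <- kinetic_params(alpha_A = base$alpha_A, delta_A = base$delta_A,
                        alpha_B = base$alpha_B, delta_B = base$delta_B,
                        psi = psi_slow[[l]], beta = 1 / 3.1, epsilon = 0.5,
                        N0 = base$N * frac, chi0 = 0, f_d = 0, Phi = 1)
    out[[l]] <- balance_influx("branched", p)
  }
  attr(out, "subset") <- subset
  attr(out, "cohort") <- cohort
  attr(out, "population_f_d") <- f_d
  out
}

#' @keywords internal
as_truth_list <- function(truth) {
  if (inherits(truth, "kinetic_params")) {
    list(host = update(truth, N0 = truth$N0 * (1 - truth$chi0),
                       Phi = truth$Phi * (1 - truth$f_d), chi0 = 0, f_d = 0),
         donor = update(truth, N0 = truth$N0 * truth$chi0,
                        Phi = truth$Phi * truth$f_d, chi0 = 0, f_d = 0))
  } else truth
}

#' Generate a synthetic BrdU/Ki67 labelling dataset
#'
#' Integrates the model for each lineage from its quasi-equilibrium initial
#' state, evaluates the flow-cytometry observables at the design days, and
#' adds logit-normal noise to fractions and log-normal noise to counts
#' (noise scale 0 reproduces the model observables exactly; logit-space
#' noise keeps generated fractions strictly inside (0, 1)). The ground
#' truth is stored in `attr(dataset, "truth")` for recovery tests.
#'
#' @param structure a [model_structure()] or name.
#' @param truth either a single [kinetic_params()] (lineages split via its
#'   `chi0` and `f_d`), a list with elements `host` and `donor`, or the
#'   output of [study_truth()].
#' @param design a [study_design()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @param subset,cohort labels stored in the dataset (defaults taken from
#'   `truth` when generated by [study_truth()]).
#' @param lineages lineages to generate (default both).
#' @param stages Ki67-high Erlang stages.
#' @return data.frame with columns `mouse_id`, `cohort`, `subset`,
#'   `lineage`, `day`, `n_cells`, `f_ki67hi`, `f_brdu`,
#'   `f_brdu_in_ki67hi`, `f_brdu_in_ki67lo`.
#' @export
generate_labelling_dataset <- function(structure, truth, design, seed = 1,
                                       subset = NULL, cohort = NULL,
                                       lineages = c("host", "donor"),
                                       stages = 1) {
  structure <- as_structure(structure)
  truth <- as_truth_list(truth)
  subset <- subset %||% attr(truth, "subset") %||% "TCM"
  cohort <- cohort %||% attr(truth, "cohort") %||% design$cohort
  schedule <- labelling_schedule(design$t_pulse_end, design$t_chase_end)
  set.seed(seed)
  rows <- list()
  for (l in lineages) {
    p <- truth[[l]]
    if (is.null(p) || p$N0 <= 0) next   # lineage absent from this design
    traj <- single_population_trajectory(structure, p, schedule,
                                         design$days, stages)
    pred <- predict_observables(traj)
    for (i in seq_along(design$days)) {
      for (m in seq_len(design$mice_per_point)) {
        noisy_frac <- function(f) {
          if (is.na(f)) return(NA_real_)
          f <- continuity_correct(f, pred[i, "n_cells"])
          invlogit(stats::rnorm(1, logit(f), design$sigma_frac))
        }
        rows[[length(rows) + 1]] <- data.frame(
          mouse_id = sprintf("%s_d%02d_m%d", cohort, design$days[i], m),
          cohort = cohort, subset = subset, lineage = l,
          day = design$days[i],
          n_cells = exp(stats::rnorm(1, log(pred[i, "n_cells"]),
                                     design$sigma_count)),
          f_ki67hi = noisy_frac(pred[i, "f_ki67hi"]),
          f_brdu = noisy_frac(pred[i, "f_brdu"]),
          f_brdu_in_ki67hi = noisy_frac(pred[i, "f_brdu_in_ki67hi"]),
          f_brdu_in_ki67lo = noisy_frac(pred[i, "f_brdu_in_ki67lo"]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  attr(out, "structure") <- structure$name
  out
}

#' Generate a synthetic donor-replacement (chimerism) dataset
#'
#' Points on the closed-form first-order replacement curve
#' `F(t) = f_d + (F0 - f_d) exp(-phi t)` with logit-normal noise, returned
#' as donor/host counts of a population of roughly constant total size.
#'
#' @param truth list with `phi` (per-capita replacement rate, per day),
#'   `f_d` (asymptotic donor fraction of the influx), `F0` (starting donor
#'   fraction, default 0.01), `N` (population size, default 1e5).
#' @param days days post-BMT at which mice are sampled (may be empty).
#' @param mice_per_point mice per timepoint.
#' @param noise logit-scale SD added to the donor fraction (0 gives points
#'   exactly on the analytic curve).
#' @param seed integer seed.
#' @param population population label.
#' @return a [replacement_curve()]; ground truth in `attr(-, "truth")`.
#' @export
generate_chimerism_dataset <- function(truth, days = seq(40, 400, by = 40),
                                       mice_per_point = 3, noise = 0.3,
                                       seed = 1, population = "TCM") {
  truth <- utils::modifyList(list(F0 = 0.01, N = 1e5), truth)
  set.seed(seed)
  rows <- list()
  for (t in days) {
    mu <- replacement_solution(t, truth$phi, truth$f_d, truth$F0)
    for (m in seq_len(mice_per_point)) {
      f <- if (noise > 0) invlogit(stats::rnorm(1, logit(mu), noise)) else mu
      n <- truth$N
      rows[[length(rows) + 1]] <- data.frame(
        mouse_id = sprintf("bmt_d%03d_m%d", t, m),
        days_post_bmt = t,
        donor_count = f * n, host_count = (1 - f) * n)
    }
  }
  d <- if (length(rows)) do.call(rbind, rows)
       else data.frame(mouse_id = character(), days_post_bmt = numeric(),
                       donor_count = numeric(), host_count = numeric())
  out <- replacement_curve(d, population = population)
  attr(out, "truth") <- truth
  out
}
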