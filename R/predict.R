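# Forward predictions for the two validation experiments: dilution of a
# heritable reporter (mTom) within memory subsets driven by labelled influx
# from their precursors, and the Ki67 kinetics of transferred cohorts
# stratified by a division-linked label (YFP).

#' Empirical curve for the labelled fraction of naive CD4 T cells
#'
#' Fits `g(t) = f_inf + (f0 - f_inf) exp(-r t)` to an observed timecourse
#' of the mTom-positive fraction within naive CD4 T cells after tamoxifen;
#' dilution is driven by unlabelled thymic influx, so the curve is
#' non-increasing.
#'
#' @param obs data.frame with columns `day` and `f_label`; alternatively
#'   supply `coef` directly and omit `obs`.
#' @param coef optional named vector `c(f0, f_inf, r)`.
#' @return object of class `naive_label_curve`; use it as a function via
#'   `predict(curve, t)` or `curve$g(t)`.
#' @export
naive_label_curve <- function(obs = NULL, coef = NULL) {
  if (is.null(coef)) {
    if (is.null(obs) || nrow(obs) < 4)
      stop("need >= 4 observations (or explicit coefficients)",
           call. = FALSE)
    f0_start <- max(min(obs$f_label[which.min(obs$day)], 0.99), 0.01)
    fi_start <- max(min(obs$f_label), 0.005)
    fit <- tryCatch(
      stats::nls(f_label ~ f_inf + (f0 - f_inf) * exp(-r * day), data = obs,
                 start = list(f0 = f0_start, f_inf = 0.8 * fi_start,
                              r = 0.05),
                 lower = c(0, 0, 0), upper = c(1, 1, 10),
                 algorithm = "port"),
      error = function(e) NULL)
    if (is.null(fit)) {
      ss <- function(p) sum((obs$f_label -
                               (p[2] + (p[1] - p[2]) * exp(-p[3] * obs$day)))^2)
      op <- stats::optim(c(f0_start, fi_start, 0.05), ss,
                         method = "L-BFGS-B", lower = c(0, 0, 0),
                         upper = c(1, 1, 10))
      coef <- c(f0 = op$par[1], f_inf = op$par[2], r = op$par[3])
    } else {
      coef <- stats::coef(fit)[c("f0", "f_inf", "r")]
    }
  }
  coef <- coef[c("f0", "f_inf", "r")]
  if (coef[["f_inf"]] > coef[["f0"]])
    warning("fitted curve is increasing; label dilution expects f0 >= f_inf",
            call. = FALSE)
  g <- function(t) pmin(pmax(
    coef[["f_inf"]] + (coef[["f0"]] - coef[["f_inf"]]) *
      exp(-coef[["r"]] * t), 0), 1)
  structure(list(coef = coef, g = g, obs = obs),
            class = "naive_label_curve")
}

#' @export
predict.naive_label_curve <- function(object, t, ...) object$g(t)

#' @export
print.naive_label_curve <- function(x, ...) {
  cat("<naive_label_curve> g(t) = f_inf + (f0 - f_inf) exp(-r t)\n")
  print(round(x$coef, 4))
  invisible(x)
}

# Heritable-label dynamics for one subset: labelled counts evolve under the
# same generator as the population (division preserves the label), with
# influx labelled at the source fraction. Returns the machinery needed to
# integrate (L, N) jointly.
#' @keywords internal
label_system <- function(structure, params, stages = 1) {
  structure <- as_structure(structure)
  comp1 <- compartment_table(structure, stages, brdu = FALSE,
                             lineages = "host")
  p1 <- unclass(params); p1$Phi <- 1
  M <- build_rate_matrix(structure, params, stages, epsilon_eff = 0,
                         comp = comp1)
  b_unit <- build_influx_vectors(structure, p1, stages, comp = comp1)$unlab
  shape <- if (params$Phi > 0) steady_shape_influx(structure, M, b_unit,
                                                   comp1)
           else steady_shape_closed(structure, params, M, comp1)
  shape <- pmax(shape, 0); shape <- shape / sum(shape)
  list(M = M, b = b_unit * params$Phi, n0 = shape * params$N0, comp = comp1)
}

#' Predict reporter (mTom) dilution within T_CM and T_EM
#'
#' For each posterior draw, evolves the labelled fraction of each memory
#' subset under the fitted influx/division/loss rates: division preserves
#' the heritable label, loss removes labelled and unlabelled cells alike,
#' and only the influx changes the labelled fraction, towards the label
#' content of the source. The T_CM source is the naive curve `g(t)`; the
#' T_EM source is, by default, the predicted T_CM labelled fraction
#' (naive -> T_CM -> T_EM pathway), or `g(t)` when
#' `tem_source = "naive"`.
#'
#' @param fit_tcm,fit_tem `posterior_draws` fits for T_CM and T_EM (a
#'   single [kinetic_params()] plus `structure` is also accepted for
#'   deterministic prediction).
#' @param naive_curve a [naive_label_curve()].
#' @param initial_fractions named vector `c(TCM = , TEM = )` of day-0
#'   labelled fractions within the memory subsets.
#' @param times days post-tamoxifen at which to report predictions.
#' @param n_draws posterior draws sampled for the uncertainty band
#'   (default up to 1000).
#' @param tem_source `"tcm"` (default) or `"naive"`.
#' @param structure model structure (only needed with raw parameter input).
#' @param seed seed for the draw subsample.
#' @return data.frame with `day`, `subset`, `median`, `lo`, `hi`
#'   (2.5/97.5 percentiles over draws).
#' @export
predict_mtom <- function(fit_tcm, fit_tem, naive_curve, initial_fractions,
                         times = seq(0, 126, by = 7), n_draws = 1000,
                         tem_source = c("tcm", "naive"), structure = NULL,
                         seed = 1) {
  tem_source <- match.arg(tem_source)
  if (is.null(initial_fractions) ||
      !all(c("TCM", "TEM") %in% names(initial_fractions)))
    stop("initial_fractions must supply day-0 values for TCM and TEM",
         call. = FALSE)
  draws_of <- function(f) {
    if (inherits(f, "posterior_draws"))
      list(structure = model_structure(f$structure), draws = f$draws,
           stages = f$stages %||% 1)
    else
      list(structure = as_structure(structure %||% "branched"),
           draws = NULL, params = f, stages = 1)
  }
  ft <- draws_of(fit_tcm); fe <- draws_of(fit_tem)
  set.seed(seed)
  n_avail <- if (is.null(ft$draws)) 1L
             else min(nrow(ft$draws), nrow(fe$draws))
  ids <- if (is.null(ft$draws)) 1L
         else sample.int(n_avail, min(n_draws, n_avail))
  g <- naive_curve$g

  one_draw <- function(i) {
    p_cm <- if (is.null(ft$draws)) ft$params
            else params_from_natural(ft$structure, ft$draws[i, ])
    p_em <- if (is.null(fe$draws)) fe$params
            else params_from_natural(fe$structure, fe$draws[i, ])
    sys_cm <- label_system(ft$structure, p_cm, ft$stages)
    sys_em <- label_system(fe$structure, p_em, fe$stages)
    ncm <- length(sys_cm$n0); nem <- length(sys_em$n0)
    y0 <- c(initial_fractions[["TCM"]] * sys_cm$n0, sys_cm$n0,
            initial_fractions[["TEM"]] * sys_em$n0, sys_em$n0)
    rhs <- function(t, y, parms) {
      Lcm <- y[seq_len(ncm)]
      Ncm <- y[ncm + seq_len(ncm)]
      Lem <- y[2 * ncm + seq_len(nem)]
      Nem <- y[2 * ncm + nem + seq_len(nem)]
      m_cm <- sum(Lcm) / max(sum(Ncm), 1e-12)
      src_em <- if (tem_source == "tcm") m_cm else g(t)
      list(c(sys_cm$M %*% Lcm + sys_cm$b * g(t),
             sys_cm$M %*% Ncm + sys_cm$b,
             sys_em$M %*% Lem + sys_em$b * src_em,
             sys_em$M %*% Nem + sys_em$b))
    }
    sol <- deSolve::ode(y0, unique(c(0, times)), rhs, NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    tt <- sol[, 1]
    keep <- match(times, tt)
    Lcm <- rowSums(sol[, 1 + seq_len(ncm), drop = FALSE])
    Ncm <- rowSums(sol[, 1 + ncm + seq_len(ncm), drop = FALSE])
    Lem <- rowSums(sol[, 1 + 2 * ncm + seq_len(nem), drop = FALSE])
    Nem <- rowSums(sol[, 1 + 2 * ncm + nem + seq_len(nem), drop = FALSE])
    cbind(TCM = (Lcm / Ncm)[keep], TEM = (Lem / Nem)[keep])
  }

  preds <- lapply(ids, one_draw)
  out <- list()
  for (s in c("TCM", "TEM")) {
    mat <- vapply(preds, function(m) m[, s], numeric(length(times)))
    mat <- matrix(mat, nrow = length(times))
    out[[s]] <- data.frame(
      day = times, subset = s,
      median = apply(mat, 1, stats::median),
      lo = apply(mat, 1, stats::quantile, 0.025),
      hi = apply(mat, 1, stats::quantile, 0.975))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a cohort-transfer experiment with a division-linked label
#'
#' Builds the pre-transfer population at its fitted steady state, marks
#' cells that are Ki67-high at tamoxifen as YFP-positive, lets the intact
#' population evolve for `pre_transfer_days` in the donor (influx on), and
#' then follows the transferred cohort for `horizon` days either with the
#' fitted influx (bulk transfer, precursors present; influx is
#' YFP-negative and Ki67-high) or without it (purified transfer). Reports
#' the Ki67-high fraction within the whole cohort and within the YFP+ and
#' YFP- fractions.
#'
#' @param fit a `posterior_draws` object, or a [kinetic_params()] (with
#'   `structure` supplied) for a deterministic run.
#' @param with_influx logical: keep the fitted influx after transfer.
#' @param days readout days post-transfer (default `0:7`).
#' @param pre_transfer_days days between tamoxifen and transfer (default 3).
#' @param structure model structure (only needed with raw parameter input).
#' @param n_draws posterior draws for uncertainty bands (default 200).
#' @param stages Ki67-high Erlang stages.
#' @param seed seed for the draw subsample.
#' @return for parameter input: data.frame `day`, `ki67_bulk`,
#'   `ki67_yfp_pos`, `ki67_yfp_neg`; for posterior input the same with
#'   `_lo`/`_hi` 2.5/97.5 percent bands.
#' @export
simulate_cohort_transfer <- function(fit, with_influx = TRUE, days = 0:7,
                                     pre_transfer_days = 3,
                                     structure = NULL, n_draws = 200,
                                     stages = 1, seed = 1) {
  one_run <- function(struct, params) {
    sys <- label_system(struct, params, stages)
    if (sum(sys$n0) <= 0) stop("empty cohort", call. = FALSE)
    hi <- startsWith(sys$comp$kstage, "hi")
    n <- length(sys$n0)
    evolve <- function(y_pos, y_neg, tt, influx_on) {
      rhs <- function(t, y, parms) {
        yp <- y[seq_len(n)]; yn <- y[n + seq_len(n)]
        list(c(sys$M %*% yp,
               sys$M %*% yn + if (influx_on) sys$b else 0))
      }
      sol <- deSolve::ode(c(y_pos, y_neg), tt, rhs, NULL, method = "lsoda",
                          rtol = 1e-10, atol = 1e-10 * max(sum(sys$n0), 1))
      sol[, -1, drop = FALSE]
    }
    # tamoxifen marks Ki67-high cells; donor mouse evolves intact
    y_pos <- ifelse(hi, sys$n0, 0)
    y_neg <- ifelse(hi, 0, sys$n0)
    if (pre_transfer_days > 0) {
      st <- evolve(y_pos, y_neg, c(0, pre_transfer_days), influx_on = TRUE)
      y_pos <- st[2, seq_len(n)]; y_neg <- st[2, n + seq_len(n)]
    }
    tt <- unique(c(0, days))
    st <- evolve(y_pos, y_neg, tt, influx_on = with_influx)
    keep <- match(days, tt)
    yp <- st[, seq_len(n), drop = FALSE]
    yn <- st[, n + seq_len(n), drop = FALSE]
    kfrac <- function(m) rowSums(m[, hi, drop = FALSE]) /
      pmax(rowSums(m), 1e-12)
    data.frame(day = days,
               ki67_bulk = kfrac(yp + yn)[keep],
               ki67_yfp_pos = kfrac(yp)[keep],
               ki67_yfp_neg = kfrac(yn)[keep])
  }

  if (inherits(fit, "posterior_draws")) {
    set.seed(seed)
    ids <- sample.int(nrow(fit$draws), min(n_draws, nrow(fit$draws)))
    st <- model_structure(fit$structure)
    runs <- lapply(ids, function(i)
      one_run(st, params_from_natural(st, fit$draws[i, ])))
    out <- data.frame(day = days)
    for (col in c("ki67_bulk", "ki67_yfp_pos", "ki67_yfp_neg")) {
      mat <- vapply(runs, `[[`, numeric(length(days)), col)
      mat <- matrix(mat, nrow = length(days))
      out[[col]] <- apply(mat, 1, stats::median)
      out[[paste0(col, "_lo")]] <- apply(mat, 1, stats::quantile, 0.025)
      out[[paste0(col, "_hi")]] <- apply(mat, 1, stats::quantile, 0.975)
    }
    out
  } else {
    one_run(as_structure(structure %||% "branched"), fit)
  }
}
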