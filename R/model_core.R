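# Core compartmental model of BrdU uptake/loss and Ki67 expression in a
# memory T cell subset fed by constant influx. The state space is
# {subpopulation} x {Ki67-high stage(s), Ki67-low} x {BrdU+, BrdU-} x
# {host, donor}. All dynamics are linear in the state, with a (piecewise)
# exponential forcing term from the labelled fraction of the influx, which is
# what makes the exact eigendecomposition solution route possible.

LINEAGES <- c("host", "donor")

#' @keywords internal
subpops_for <- function(structure) {
  if (structure$name == "temporal") "A" else c("A", "B")
}

#' @keywords internal
ki67_classes <- function(stages) c(paste0("hi", seq_len(stages)), "lo")

# Compartment table: one row per state-space dimension, in a fixed order.
#' @keywords internal
compartment_table <- function(structure, stages = 1, brdu = TRUE,
                              lineages = LINEAGES) {
  sp <- subpops_for(structure)
  kc <- ki67_classes(stages)
  bl <- if (brdu) c("U", "L") else "U"
  g <- expand.grid(brdu = bl, kstage = kc, subpop = sp, lineage = lineages,
                   stringsAsFactors = FALSE)
  g <- g[, c("lineage", "subpop", "kstage", "brdu")]
  g$name <- with(g, paste(lineage, subpop, kstage, brdu, sep = "."))
  g$is_hi <- startsWith(g$kstage, "hi")
  g
}

# Influx split across subpopulations, by structure.
#' @keywords internal
influx_weights <- function(structure, params) {
  switch(structure$name,
    branched = c(A = params$psi, B = 1 - params$psi),
    linear   = c(A = 1, B = 0),
    burst    = c(A = 0, B = 1),
    temporal = c(A = 1)
  )
}

#' @keywords internal
division_rate <- function(structure, params, subpop) {
  if (structure$name == "temporal") return(params$alpha_A)
  if (subpop == "A") params$alpha_A else params$alpha_B
}

#' @keywords internal
loss_rate <- function(structure, params, subpop, is_hi) {
  if (structure$name == "temporal")
    return(if (is_hi) params$delta_hi else params$delta_lo)
  if (subpop == "A") params$delta_A else params$delta_B
}

# Linear generator of the labelling system (per the full compartment table).
# `epsilon_eff` is the effective per-division labelling probability (the
# pulse value during BrdU administration, 0 during the chase).
#' @keywords internal
build_rate_matrix <- function(structure, params, stages = 1,
                              epsilon_eff = params$epsilon,
                              comp = compartment_table(structure, stages)) {
  n <- nrow(comp)
  A <- matrix(0, n, n, dimnames = list(comp$name, comp$name))
  idx <- function(lineage, subpop, kstage, brdu)
    which(comp$lineage == lineage & comp$subpop == subpop &
            comp$kstage == kstage & comp$brdu == brdu)
  m <- sum(startsWith(ki67_classes(stages), "hi"))
  stage_rate <- m * params$beta
  has_brdu <- any(comp$brdu == "L")

  for (r in seq_len(n)) {
    l <- comp$lineage[r]; sp <- comp$subpop[r]
    k <- comp$kstage[r]; b <- comp$brdu[r]
    alpha <- division_rate(structure, params, sp)
    delta <- loss_rate(structure, params, sp, comp$is_hi[r])

    # loss
    A[r, r] <- A[r, r] - delta

    # division: parent leaves its compartment; two Ki67-high (stage 1)
    # daughters appear, labelled according to the parent's BrdU state and
    # the labelling efficiency
    A[r, r] <- A[r, r] - alpha
    if (has_brdu) {
      if (b == "L") {
        A[idx(l, sp, "hi1", "L"), r] <- A[idx(l, sp, "hi1", "L"), r] + 2 * alpha
      } else {
        A[idx(l, sp, "hi1", "L"), r] <-
          A[idx(l, sp, "hi1", "L"), r] + 2 * alpha * epsilon_eff
        A[idx(l, sp, "hi1", "U"), r] <-
          A[idx(l, sp, "hi1", "U"), r] + 2 * alpha * (1 - epsilon_eff)
      }
    } else {
      A[idx(l, sp, "hi1", "U"), r] <- A[idx(l, sp, "hi1", "U"), r] + 2 * alpha
    }

    # Ki67 stage progression (Erlang chain, total mean duration 1/beta)
    if (comp$is_hi[r]) {
      j <- as.integer(sub("hi", "", k))
      dest <- if (j < m) paste0("hi", j + 1) else "lo"
      A[idx(l, sp, dest, b), r] <- A[idx(l, sp, dest, b), r] + stage_rate
      A[r, r] <- A[r, r] - stage_rate
    }

    # structure-specific transitions, preserving Ki67 stage and BrdU state
    if (structure$name == "linear" && sp == "A") {
      A[idx(l, "B", k, b), r] <- A[idx(l, "B", k, b), r] + params$gamma
      A[r, r] <- A[r, r] - params$gamma
    } else if (structure$name == "burst") {
      if (sp == "A") {
        A[idx(l, "B", k, b), r] <- A[idx(l, "B", k, b), r] + params$omega
        A[r, r] <- A[r, r] - params$omega
      } else {
        A[idx(l, "A", k, b), r] <- A[idx(l, "A", k, b), r] + params$rho
        A[r, r] <- A[r, r] - params$rho
      }
    }
  }
  A
}

# Influx vectors. New memory cells enter Ki67-high stage 1, split across
# subpopulations by the structure, across lineages by f_d, and across BrdU
# states by the labelled fraction s(t) of the source:
#   b(t) = b_unlab + s(t) * b_swap
#' @keywords internal
build_influx_vectors <- function(structure, params, stages = 1,
                                 comp = compartment_table(structure, stages)) {
  n <- nrow(comp)
  b_unlab <- numeric(n); b_swap <- numeric(n)
  w <- influx_weights(structure, params)
  has_donor <- "donor" %in% comp$lineage
  for (l in unique(comp$lineage)) {
    phi_l <- if (!has_donor || length(unique(comp$lineage)) == 1) params$Phi
             else params$Phi * if (l == "donor") params$f_d else 1 - params$f_d
    for (sp in names(w)) {
      if (w[[sp]] == 0) next
      iU <- which(comp$lineage == l & comp$subpop == sp &
                    comp$kstage == "hi1" & comp$brdu == "U")
      b_unlab[iU] <- b_unlab[iU] + phi_l * w[[sp]]
      iL <- which(comp$lineage == l & comp$subpop == sp &
                    comp$kstage == "hi1" & comp$brdu == "L")
      if (length(iL)) {
        b_swap[iU] <- b_swap[iU] - phi_l * w[[sp]]
        b_swap[iL] <- b_swap[iL] + phi_l * w[[sp]]
      }
    }
  }
  list(unlab = b_unlab, swap = b_swap)
}

#' Pre-pulse steady state of the unlabelled system
#'
#' Solves the zero-derivative balance equations of the BrdU-free system for
#' the subpopulation sizes and Ki67-high fractions, scales the resulting
#' structure to total size `N0`, and splits every compartment between host
#' and donor according to the standing chimerism `chi0`. The returned state
#' is an exact fixed point of the dynamics when `Phi` equals the implied
#' influx `sum((delta_i - alpha_i) N_i)` (see [implied_influx()]); this is
#' the quasi-equilibrium assumption under which the labelling experiment is
#' modelled.
#'
#' @param structure a [model_structure()] or its name.
#' @param params a [kinetic_params()] object.
#' @param stages number of Ki67-high Erlang stages (default 1, i.e.
#'   exponentially distributed Ki67-high duration).
#' @return a `label_state`: named non-negative vector of compartment counts
#'   (all BrdU-negative) with the compartment table attached.
#' @export
steady_state <- function(structure, params, stages = 1) {
  structure <- as_structure(structure)
  comp1 <- compartment_table(structure, stages, brdu = FALSE,
                            lineages = "host")
  # single-lineage unlabelled system with unit-rate bookkeeping
  p1 <- unclass(params); p1$Phi <- 1
  M <- build_rate_matrix(structure, params, stages,
                         epsilon_eff = 0, comp = comp1)
  b <- build_influx_vectors(structure, p1, stages, comp = comp1)$unlab

  shape <- if (params$Phi > 0) {
    steady_shape_influx(structure, M, b, comp1)
  } else {
    steady_shape_closed(structure, params, M, comp1)
  }
  if (any(shape < -1e-9)) {
    stop("no non-negative steady state exists for these parameters",
         call. = FALSE)
  }
  shape <- pmax(shape, 0)
  shape <- shape / sum(shape)

  comp <- compartment_table(structure, stages, brdu = TRUE)
  x <- numeric(nrow(comp))
  names(x) <- comp$name
  for (r in seq_len(nrow(comp1))) {
    sel <- comp$subpop == comp1$subpop[r] & comp$kstage == comp1$kstage[r] &
      comp$brdu == "U"
    x[sel & comp$lineage == "host"]  <- shape[r] * params$N0 * (1 - params$chi0)
    x[sel & comp$lineage == "donor"] <- shape[r] * params$N0 * params$chi0
  }
  new_label_state(x, comp, structure, stages)
}

# Steady-state structure for an influx-fed population: solve M n = -b.
# For the branched structure the subpopulations are uncoupled, so each block
# is solved separately (a subpopulation receiving no influx is empty at
# steady state provided it is not self-sustaining).
#' @keywords internal
steady_shape_influx <- function(structure, M, b, comp1) {
  solve_block <- function(Mb, bb) {
    n <- tryCatch(solve(Mb, -bb), error = function(e) NULL)
    if (is.null(n) || any(n < -1e-9 * max(abs(n), 1)))
      stop("no non-negative steady state exists: the influx-fed system has ",
           "no stable equilibrium (e.g. a subpopulation with division rate ",
           ">= loss rate and no compensating efflux)", call. = FALSE)
    n
  }
  if (structure$name == "branched") {
    out <- numeric(nrow(comp1))
    for (sp in unique(comp1$subpop)) {
      sel <- comp1$subpop == sp
      if (all(b[sel] == 0)) {
        ev <- eigen(M[sel, sel, drop = FALSE], only.values = TRUE)$values
        if (max(Re(ev)) > 1e-12)
          stop("no non-negative steady state: unfed subpopulation ", sp,
               " grows without bound", call. = FALSE)
        out[sel] <- 0
      } else {
        out[sel] <- solve_block(M[sel, sel, drop = FALSE], b[sel])
      }
    }
    out
  } else {
    solve_block(M, b)
  }
}

# Steady-state structure for a closed (Phi = 0) population: requires a
# balanced system, i.e. a zero eigenvalue of the generator; the associated
# eigenvector gives the Ki67/subpopulation structure.
#' @keywords internal
steady_shape_closed <- function(structure, params, M, comp1, tol = 1e-10) {
  null_shape <- function(Mb) {
    ev <- eigen(Mb)
    i <- which.max(Re(ev$values))
    lam <- Re(ev$values[i])
    if (lam > tol)
      stop("no steady state: closed population grows without bound",
           call. = FALSE)
    if (lam < -tol)
      stop("no non-trivial steady state: closed population decays ",
           "(division and loss are not balanced)", call. = FALSE)
    v <- Re(ev$vectors[, i])
    if (max(v) < -min(v)) v <- -v
    if (any(v < -1e-8 * max(abs(v))))
      stop("no non-negative steady state for these parameters", call. = FALSE)
    pmax(v, 0) / sum(pmax(v, 0))
  }
  if (structure$name %in% c("branched", "temporal")) {
    # uncoupled subpopulations: masses follow the influx split convention
    shares <- influx_weights(structure, params)
    out <- numeric(nrow(comp1))
    for (sp in names(shares)) {
      sel <- comp1$subpop == sp
      if (shares[[sp]] == 0) { out[sel] <- 0; next }
      out[sel] <- shares[[sp]] * null_shape(M[sel, sel, drop = FALSE])
    }
    out
  } else {
    null_shape(M)
  }
}

#' @keywords internal
new_label_state <- function(x, comp, structure, stages) {
  structure(x, comp = comp, model = structure$name, stages = stages,
            class = "label_state")
}

#' @export
print.label_state <- function(x, ...) {
  cat("<label_state> ", attr(x, "model"), " model, total = ",
      format(sum(x), digits = 6), " cells\n", sep = "")
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.label_state <- function(x, ...) {
  comp <- attr(x, "comp")
  comp$count <- as.numeric(x)
  comp[, c("lineage", "subpop", "kstage", "brdu", "count")]
}

#' Influx implied by the quasi-equilibrium assumption
#'
#' The total influx that would hold the steady-state structure of
#' [steady_state()] exactly constant at total size `N0`:
#' `Phi* = sum_i (delta_i - alpha_i) N_i` over subpopulations.
#'
#' @inheritParams steady_state
#' @return implied influx, cells/day.
#' @export
implied_influx <- function(structure, params, stages = 1) {
  structure <- as_structure(structure)
  st <- steady_state(structure, params, stages)
  df <- as.data.frame(st)
  tot <- 0
  for (sp in unique(df$subpop)) {
    for (hi in c(TRUE, FALSE)) {
      sel <- df$subpop == sp & startsWith(df$kstage, "hi") == hi
      ni <- sum(df$count[sel])
      alpha <- division_rate(structure, params, sp)
      delta <- loss_rate(structure, params, sp, hi)
      tot <- tot + (delta - alpha) * ni
    }
  }
  tot
}

#' Set the influx to its quasi-equilibrium value
#'
#' Returns the parameter set with `Phi` replaced by [implied_influx()], so
#' that [steady_state()] is an exact fixed point and population size and
#' Ki67 structure are constant over the labelling window.
#'
#' @inheritParams steady_state
#' @return updated [kinetic_params()].
#' @export
balance_influx <- function(structure, params, stages = 1) {
  if (params$Phi <= 0) {
    # seed the structure solve with any positive influx; the implied value
    # is scale-invariant in the structure
    params <- update(params, Phi = 1)
  }
  phi <- implied_influx(structure, params, stages)
  if (phi < 0)
    stop("implied influx is negative: the population is self-sustaining ",
         "or growing; quasi-equilibrium with influx does not apply",
         call. = FALSE)
  update(params, Phi = phi)
}

#' Integrate the BrdU/Ki67 labelling system
#'
#' Integrates the full compartmental system from the pre-pulse steady state
#' through the BrdU pulse and chase. During the pulse, both daughters of an
#' unlabelled dividing cell become BrdU-positive with probability `epsilon`
#' (expectation-level fluxes `2 epsilon alpha U` and `2 (1-epsilon) alpha U`);
#' daughters of labelled cells are labelled; during the chase `epsilon` is
#' treated as 0. Ki67-high cells transition to Ki67-low at rate `beta`
#' (optionally through Erlang stages); influx enters Ki67-high split by
#' `f_d` across lineages and by the schedule's source labelled fraction
#' across BrdU states.
#'
#' Because the system is linear and piecewise-autonomous with exponential
#' forcing, the default `"eigen"` method solves it exactly by
#' eigendecomposition of an augmented generator; it falls back to the
#' stiff-capable `lsoda` integrator when the eigenbasis is ill-conditioned,
#' and `method = "lsoda"` forces the numerical route (also used for custom
#' source label functions).
#'
#' @inheritParams steady_state
#' @param schedule a [labelling_schedule()].
#' @param times observation times in days since pulse start, within
#'   `[0, t_chase_end]`.
#' @param method `"eigen"` (exact, default) or `"lsoda"`.
#' @param init optional initial `label_state`; defaults to [steady_state()].
#' @param rtol,atol_scale integration tolerances for the `lsoda` route;
#'   absolute tolerance is `atol_scale * N0`.
#' @return a `label_trajectory`: times, state matrix (rows = times), and
#'   model metadata.
#' @export
integrate_labelling <- function(structure, params, schedule, times,
                                stages = 1, method = c("eigen", "lsoda"),
                                init = NULL, rtol = 1e-8,
                                atol_scale = 1e-10) {
  structure <- as_structure(structure)
  method <- match.arg(method)
  if (any(times < 0 | times > schedule$t_chase_end + 1e-9))
    stop("times must lie within [0, t_chase_end]", call. = FALSE)
  times <- sort(unique(times))
  if (!is.null(schedule$custom_fn)) method <- "lsoda"

  comp <- compartment_table(structure, stages)
  x0 <- if (is.null(init)) steady_state(structure, params, stages) else init
  if (length(x0) != nrow(comp))
    stop("initial state does not match the model's compartment layout",
         call. = FALSE)

  A_pulse <- build_rate_matrix(structure, params, stages,
                               epsilon_eff = params$epsilon, comp = comp)
  A_chase <- build_rate_matrix(structure, params, stages,
                               epsilon_eff = 0, comp = comp)
  bv <- build_influx_vectors(structure, params, stages, comp = comp)

  tp <- min(schedule$t_pulse_end, schedule$t_chase_end)
  out <- matrix(NA_real_, length(times), nrow(comp),
                dimnames = list(NULL, comp$name))

  if (method == "lsoda") {
    states <- integrate_lsoda(A_pulse, A_chase, bv, schedule, as.numeric(x0),
                              times, tp, rtol,
                              atol = atol_scale * max(params$N0, 1))
  } else {
    states <- integrate_eigen(A_pulse, A_chase, bv, schedule, as.numeric(x0),
                              times, tp)
    if (is.null(states)) {
      states <- integrate_lsoda(A_pulse, A_chase, bv, schedule,
                                as.numeric(x0), times, tp, rtol,
                                atol = atol_scale * max(params$N0, 1))
    }
  }
  neg_tol <- 1e-6 * max(sum(x0), 1)
  if (any(states < -neg_tol))
    stop("integration produced negative compartments beyond tolerance",
         call. = FALSE)
  states[states < 0] <- 0
  out[] <- states

  structure(list(times = times, states = out, comp = comp,
                 model = structure$name, stages = stages,
                 params = params, schedule = schedule),
            class = "label_trajectory")
}

# Exact piecewise solution via eigendecomposition of the augmented generator
#   d/dt (x, u0, u1) = [[A, B0, B1], [0, 0, 0], [0, 0, -r]] (x, u0, u1)
# where b(tau) = B0 + B1 exp(-r tau) is the influx forcing within a segment.
# Returns NULL if any segment's eigenbasis is ill-conditioned.
#' @keywords internal
integrate_eigen <- function(A_pulse, A_chase, bv, schedule, x0, times, tp) {
  n <- length(x0)
  s_max <- schedule$s_max; r_s <- schedule$r_s
  s_pe <- s_max * (1 - exp(-r_s * tp))

  solve_segment <- function(A, B0, B1, r, x_start, taus) {
    M <- rbind(cbind(A, B0, B1), 0, 0)
    M[n + 2, n + 2] <- -r
    E <- eigen(M)
    Vinv <- tryCatch(solve(E$vectors), error = function(e) NULL)
    if (is.null(Vinv)) return(NULL)
    recon <- E$vectors %*% (E$values * Vinv)   # V Lambda V^-1
    if (max(abs(Re(recon) - M)) + max(abs(Im(recon))) >
          1e-7 * (1 + max(abs(M)))) return(NULL)
    cc <- Vinv %*% c(x_start, 1, 1)
    grow <- exp(outer(E$values, taus))         # (n+2) x length(taus)
    X <- E$vectors %*% (grow * as.vector(cc))
    Re(t(X)[, seq_len(n), drop = FALSE])
  }

  out <- matrix(NA_real_, length(times), n)
  in_pulse <- times <= tp + 1e-12

  # pulse segment: s(tau) = s_max - s_max exp(-r_s tau)
  pulse_taus <- c(times[in_pulse], tp)
  B0 <- bv$unlab + s_max * bv$swap
  B1 <- -s_max * bv$swap
  seg1 <- solve_segment(A_pulse, B0, B1, r_s, x0, pulse_taus)
  if (is.null(seg1)) return(NULL)
  if (any(in_pulse)) out[in_pulse, ] <- seg1[seq_len(sum(in_pulse)), ]
  x_tp <- seg1[length(pulse_taus), ]

  if (any(!in_pulse)) {
    # chase segment: s(tau) = s_pe exp(-r_s tau), tau = t - tp
    B0c <- bv$unlab
    B1c <- s_pe * bv$swap
    seg2 <- solve_segment(A_chase, B0c, B1c, r_s, x_tp, times[!in_pulse] - tp)
    if (is.null(seg2)) return(NULL)
    out[!in_pulse, ] <- seg2
  }
  out
}

#' @keywords internal
integrate_lsoda <- function(A_pulse, A_chase, bv, schedule, x0, times, tp,
                            rtol, atol) {
  rhs <- function(t, y, parms) {
    A <- if (t <= tp) A_pulse else A_chase
    s <- source_label(schedule, t)
    list(as.vector(A %*% y + bv$unlab + s * bv$swap))
  }
  run <- function(x_start, tt, t0) {
    utt <- unique(c(t0, tt))
    if (length(utt) == 1)
      return(matrix(x_start, length(tt), length(x_start), byrow = TRUE))
    sol <- deSolve::ode(y = x_start, times = utt, func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("stiff integration failed (lsoda istate ",
           attr(sol, "istate")[1], ")", call. = FALSE)
    sol <- sol[, -1, drop = FALSE]
    sol[match(tt, utt), , drop = FALSE]
  }
  in_pulse <- times <= tp + 1e-12
  out <- matrix(NA_real_, length(times), length(x0))
  seg1 <- run(x0, c(times[in_pulse], tp), 0)
  if (any(in_pulse)) out[in_pulse, ] <- seg1[seq_len(sum(in_pulse)), ]
  x_tp <- seg1[nrow(seg1), ]
  if (any(!in_pulse)) out[!in_pulse, ] <- run(x_tp, times[!in_pulse], tp)
  out
}

#' Flow-cytometry style observables along a trajectory
#'
#' Per time point and lineage: total cell count, Ki67-high fraction,
#' BrdU-positive fraction overall, and BrdU-positive fractions within
#' Ki67-high and Ki67-low cells. Fractions whose denominator is an empty
#' compartment are returned as `NA` (an explicit undefined marker) with a
#' warning, never silently propagated.
#'
#' @param trajectory a `label_trajectory` from [integrate_labelling()].
#' @param pool_lineages also include rows with `lineage = "all"` pooling
#'   host and donor cells (default `FALSE`).
#' @return a data.frame with columns `day`, `lineage`, `n_cells`,
#'   `f_ki67hi`, `f_brdu`, `f_brdu_in_ki67hi`, `f_brdu_in_ki67lo`.
#' @export
observables <- function(trajectory, pool_lineages = FALSE) {
  if (!inherits(trajectory, "label_trajectory") ||
      length(trajectory$times) == 0)
    stop("need a non-empty label_trajectory", call. = FALSE)
  comp <- trajectory$comp
  lineages <- unique(comp$lineage)
  if (pool_lineages) lineages <- c(lineages, "all")
  rows <- list()
  undefined <- FALSE
  frac <- function(num, den) {
    if (den <= 0) { undefined <<- TRUE; return(NA_real_) }
    min(max(num / den, 0), 1)
  }
  for (i in seq_along(trajectory$times)) {
    x <- trajectory$states[i, ]
    for (l in lineages) {
      sel <- if (l == "all") rep(TRUE, nrow(comp)) else comp$lineage == l
      N <- sum(x[sel])
      hi <- sum(x[sel & comp$is_hi])
      lab <- sum(x[sel & comp$brdu == "L"])
      lab_hi <- sum(x[sel & comp$is_hi & comp$brdu == "L"])
      lab_lo <- sum(x[sel & !comp$is_hi & comp$brdu == "L"])
      rows[[length(rows) + 1]] <- data.frame(
        day = trajectory$times[i], lineage = l, n_cells = N,
        f_ki67hi = frac(hi, N), f_brdu = frac(lab, N),
        f_brdu_in_ki67hi = frac(lab_hi, hi),
        f_brdu_in_ki67lo = frac(lab_lo, N - hi))
    }
  }
  if (undefined)
    warning("empty denominator(s): undefined fractions returned as NA",
            call. = FALSE)
  do.call(rbind, rows)
}

#' Analytic steady-state Ki67-high fraction
#'
#' The Ki67-high fraction implied by the balance equations of the unlabelled
#' system, for one subpopulation or the whole subset. Agrees with the
#' structure returned by [steady_state()] (it is computed from the same
#' balance solve) and, for a single-stage Ki67 model with influx entering
#' Ki67-high, with the closed form `(delta + alpha - phi_excess)` balance;
#' e.g. a single balanced population with influx `Phi = (delta - alpha) N0`
#' has Ki67-high fraction `(delta + alpha) / (alpha + beta + delta)`.
#'
#' @inheritParams steady_state
#' @param subpop `"A"`, `"B"` or `"all"`.
#' @return Ki67-high fraction in \[0, 1\].
#' @export
ki67_steady_fraction <- function(structure, params, subpop = "all",
                                 stages = 1) {
  st <- steady_state(structure, params, stages)
  df <- as.data.frame(st)
  if (subpop != "all") df <- df[df$subpop == subpop, ]
  tot <- sum(df$count)
  if (tot <= 0) stop("subpopulation is empty at steady state", call. = FALSE)
  sum(df$count[startsWith(df$kstage, "hi")]) / tot
}
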