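# Independent stochastic oracle: an exact Gillespie (SSA) simulation of the
# BrdU/Ki67 reaction scheme for a single population, written directly from
# the reaction list (division with probabilistic labelling of both
# daughters, Ki67-high decay, loss, structure transitions, labelled influx).
# It shares no code with the ODE integrator.

gillespie_labelling <- function(structure_name, params, schedule,
                                checkpoints, seed) {
  set.seed(seed)
  subpops <- if (structure_name == "temporal") "A" else c("A", "B")
  comp <- expand.grid(brdu = c("U", "L"), k = c("hi", "lo"),
                      subpop = subpops, stringsAsFactors = FALSE)
  nc <- nrow(comp)
  id <- function(sp, k, b) which(comp$subpop == sp & comp$k == k &
                                   comp$brdu == b)
  alpha <- function(sp) if (structure_name == "temporal") params$alpha_A
  else if (sp == "A") params$alpha_A else params$alpha_B
  delta <- function(sp, k) {
    if (structure_name == "temporal")
      return(if (k == "hi") params$delta_hi else params$delta_lo)
    if (sp == "A") params$delta_A else params$delta_B
  }
  w_in <- switch(structure_name,
                 branched = c(A = params$psi, B = 1 - params$psi),
                 linear = c(A = 1, B = 0), burst = c(A = 0, B = 1),
                 temporal = c(A = 1))

  # initial state: multinomial draw from the deterministic steady-state
  # structure (oracle for the trajectory, not for the initial condition)
  st <- steady_state(structure_name, params)
  df <- as.data.frame(st)   # pooled over lineages below
  probs <- numeric(nc)
  for (i in seq_len(nc)) {
    probs[i] <- sum(df$count[df$subpop == comp$subpop[i] &
                               startsWith(df$kstage, "hi") ==
                                 (comp$k[i] == "hi") &
                               df$brdu == comp$brdu[i]])
  }
  x <- as.vector(stats::rmultinom(1, round(params$N0), probs / sum(probs)))

  # per-compartment channel constants: division, ki67 decay, loss,
  # structure transition
  res <- matrix(NA_real_, length(checkpoints), 5,
                dimnames = list(NULL, c("t", "N", "ki67", "brdu", "brdu_hi")))
  record <- function(ci, t) {
    hi <- comp$k == "hi"; lab <- comp$brdu == "L"
    res[ci, ] <<- c(t, sum(x), sum(x[hi]) / sum(x), sum(x[lab]) / sum(x),
                    sum(x[hi & lab]) / max(sum(x[hi]), 1))
  }
  t <- 0
  ci <- 1
  tmax <- max(checkpoints)
  repeat {
    while (ci <= length(checkpoints) && t >= checkpoints[ci] - 1e-12) {
      record(ci, t); ci <- ci + 1
    }
    if (ci > length(checkpoints) || t > tmax) break
    rdiv <- vapply(seq_len(nc), function(i) alpha(comp$subpop[i]) * x[i],
                   numeric(1))
    rki <- ifelse(comp$k == "hi", params$beta * x, 0)
    rdie <- vapply(seq_len(nc), function(i)
      delta(comp$subpop[i], comp$k[i]) * x[i], numeric(1))
    rtrans <- numeric(nc)
    if (structure_name == "linear")
      rtrans[comp$subpop == "A"] <- params$gamma * x[comp$subpop == "A"]
    if (structure_name == "burst") {
      rtrans[comp$subpop == "A"] <- params$omega * x[comp$subpop == "A"]
      rtrans[comp$subpop == "B"] <- params$rho * x[comp$subpop == "B"]
    }
    rates <- c(rdiv, rki, rdie, rtrans, params$Phi)
    tot <- sum(rates)
    if (tot <= 0) { t <- tmax + 1; next }
    t <- t + stats::rexp(1, tot)
    ev <- sample.int(length(rates), 1, prob = rates)
    in_pulse <- t <= schedule$t_pulse_end
    if (ev <= nc) {                       # division
      i <- ev
      x[i] <- x[i] - 1
      eps_eff <- if (in_pulse) params$epsilon else 0
      lab_child <- if (comp$brdu[i] == "L") TRUE
                   else stats::runif(1) < eps_eff
      j <- id(comp$subpop[i], "hi", if (lab_child) "L" else "U")
      x[j] <- x[j] + 2
    } else if (ev <= 2 * nc) {            # Ki67 high -> low
      i <- ev - nc
      x[i] <- x[i] - 1
      j <- id(comp$subpop[i], "lo", comp$brdu[i])
      x[j] <- x[j] + 1
    } else if (ev <= 3 * nc) {            # loss
      i <- ev - 2 * nc
      x[i] <- x[i] - 1
    } else if (ev <= 4 * nc) {            # structure transition
      i <- ev - 3 * nc
      x[i] <- x[i] - 1
      dest <- if (comp$subpop[i] == "A") "B" else "A"
      j <- id(dest, comp$k[i], comp$brdu[i])
      x[j] <- x[j] + 1
    } else {                              # influx (Ki67 high)
      sp <- sample(names(w_in), 1, prob = w_in)
      lab <- stats::runif(1) < source_label(schedule, t)
      j <- id(sp, "hi", if (lab) "L" else "U")
      x[j] <- x[j] + 1
    }
  }
  as.data.frame(res)
}
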