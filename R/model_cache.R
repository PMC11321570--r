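# Per-structure cached model machinery. The generator matrix is linear in
# each rate (bilinear in alpha * epsilon), so it decomposes exactly into
# fixed templates scaled by parameter values; templates are built once per
# (structure, stages) from the reference constructors and reused across
# likelihood evaluations.

.model_cache <- new.env(parent = emptyenv())

#' @keywords internal
unit_params <- function(vals) {
  p <- list(alpha_A = 0, delta_A = 0, alpha_B = 0, delta_B = 0, psi = 0.5,
            gamma = 0, omega = 0, rho = 0, beta = 0, epsilon = 0, Phi = 0,
            f_d = 0, N0 = 1, chi0 = 0, delta_hi = 0, delta_lo = 0)
  utils::modifyList(p, vals)
}

#' @keywords internal
rate_templates <- function(structure, stages, comp) {
  tm <- list()
  base <- function(vals) build_rate_matrix(structure, unit_params(vals),
                                           stages, epsilon_eff =
                                             vals$epsilon %||% 0,
                                           comp = comp)
  if (structure$name == "temporal") {
    tm$alpha_A <- base(list(alpha_A = 1))
    tm$alpha_A_eps <- base(list(alpha_A = 1, epsilon = 1)) - tm$alpha_A
    tm$delta_hi <- base(list(delta_hi = 1))
    tm$delta_lo <- base(list(delta_lo = 1))
  } else {
    tm$alpha_A <- base(list(alpha_A = 1))
    tm$alpha_A_eps <- base(list(alpha_A = 1, epsilon = 1)) - tm$alpha_A
    tm$alpha_B <- base(list(alpha_B = 1))
    tm$alpha_B_eps <- base(list(alpha_B = 1, epsilon = 1)) - tm$alpha_B
    tm$delta_A <- base(list(delta_A = 1))
    tm$delta_B <- base(list(delta_B = 1))
    if (structure$name == "linear") tm$gamma <- base(list(gamma = 1))
    if (structure$name == "burst") {
      tm$omega <- base(list(omega = 1))
      tm$rho <- base(list(rho = 1))
    }
  }
  tm$beta <- base(list(beta = 1))
  tm
}

#' @keywords internal
get_model_cache <- function(structure, stages = 1) {
  key <- paste0(structure$name, ".", stages)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  comp <- compartment_table(structure, stages, brdu = TRUE,
                            lineages = "host")
  comp1 <- compartment_table(structure, stages, brdu = FALSE,
                             lineages = "host")
  sp <- subpops_for(structure)
  entry <- function(cc) {
    out <- list()
    for (s in sp) {
      out[[s]] <- list(
        U = which(cc$subpop == s & cc$kstage == "hi1" & cc$brdu == "U"),
        L = which(cc$subpop == s & cc$kstage == "hi1" & cc$brdu == "L"))
    }
    out
  }
  .model_cache[[key]] <- list(
    comp = comp, comp1 = comp1,
    tm = rate_templates(structure, stages, comp),
    tm1 = rate_templates(structure, stages, comp1),
    entry = entry(comp), entry1 = entry(comp1),
    is_hi = comp$is_hi, is_lab = comp$brdu == "L",
    subpop_of1 = comp1$subpop,
    key1 = paste(comp1$subpop, comp1$kstage),
    keyU = paste(comp$subpop, comp$kstage)[comp$brdu == "U"],
    uidx = which(comp$brdu == "U"))
  .model_cache[[key]]
}

# Assemble the generator from templates for given parameter values.
#' @keywords internal
assemble_matrix <- function(tm, structure, params, epsilon_eff) {
  if (structure$name == "temporal") {
    A <- params$alpha_A * tm$alpha_A +
      (params$alpha_A * epsilon_eff) * tm$alpha_A_eps +
      params$delta_hi * tm$delta_hi + params$delta_lo * tm$delta_lo
  } else {
    A <- params$alpha_A * tm$alpha_A +
      (params$alpha_A * epsilon_eff) * tm$alpha_A_eps +
      params$alpha_B * tm$alpha_B +
      (params$alpha_B * epsilon_eff) * tm$alpha_B_eps +
      params$delta_A * tm$delta_A + params$delta_B * tm$delta_B
    if (structure$name == "linear") A <- A + params$gamma * tm$gamma
    if (structure$name == "burst")
      A <- A + params$omega * tm$omega + params$rho * tm$rho
  }
  A + params$beta * tm$beta
}

# Influx vectors (single lineage, total influx Phi) from cached indices.
#' @keywords internal
assemble_influx <- function(cache, structure, params, brdu = TRUE) {
  w <- influx_weights(structure, params)
  ent <- if (brdu) cache$entry else cache$entry1
  n <- if (brdu) nrow(cache$comp) else nrow(cache$comp1)
  b_unlab <- numeric(n); b_swap <- numeric(n)
  for (s in names(w)) {
    if (w[[s]] == 0) next
    amt <- params$Phi * w[[s]]
    b_unlab[ent[[s]]$U] <- b_unlab[ent[[s]]$U] + amt
    if (brdu && length(ent[[s]]$L)) {
      b_swap[ent[[s]]$U] <- b_swap[ent[[s]]$U] - amt
      b_swap[ent[[s]]$L] <- b_swap[ent[[s]]$L] + amt
    }
  }
  list(unlab = b_unlab, swap = b_swap)
}
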