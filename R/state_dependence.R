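## Resting/inactivated affinity and state-dependence from steady-state
## availability curves, under the modulated-receptor four-state model.
##
## Two independent estimators of the inactivated-state affinity Ki are
## implemented: inversion of the drug-induced hyperpolarizing shift of
## the availability midpoint (Bean/Cohen/Tsien), and inversion of the
## apparent affinity measured at a partially inactivating pre-pulse
## potential (Kuo/Bean). Their agreement on the same cells is itself a
## consistency check of the model.

#' Boltzmann fit of an availability curve
#'
#' Fits `y(V) = bottom + (top - bottom) / (1 + exp((V - V1/2)/k))` by
#' nonlinear least squares, with `k > 0` so that availability falls with
#' depolarization. `bottom` is fixed at 0 by default (availability
#' vanishes at strongly depolarized pre-pulses); `top` is free, so the
#' same parameterization fits drug curves whose plateau is depressed to
#' `1/(1 + D/Kr)`.
#'
#' @param voltages pre-pulse voltages, mV (>= 6 points spanning the
#'   transition).
#' @param current normalized currents at `voltages`.
#' @param fix_bottom fix the depolarized asymptote at 0 (default).
#' @return An object of class `boltzmann_fit`: list with `V_half_mV`,
#'   `k_mV`, `top`, `bottom`, `rmse` and `fitted(V)`.
#' @export
fit_boltzmann <- function(voltages, current, fix_bottom = TRUE) {
  stopifnot(length(voltages) == length(current))
  if (length(voltages) < 6L) .stopf("at least 6 points are required for a Boltzmann fit")
  top0 <- max(current)
  if (top0 <= 0 || (top0 - min(current)) < 0.2 * top0)
    .stopf("no availability transition in the fitted voltage range (flat curve)")
  v0 <- voltages[which.min(abs(current - top0 / 2))]
  df <- data.frame(V = voltages, y = current)
  fit <- tryCatch({
    if (fix_bottom)
      minpack.lm::nlsLM(y ~ top / (1 + exp((V - vh) / k)), data = df,
                        start = list(top = top0, vh = v0, k = 8),
                        lower = c(1e-6, -200, 0.5), upper = c(2, 50, 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ bot + (top - bot) / (1 + exp((V - vh) / k)), data = df,
                        start = list(bot = 0, top = top0, vh = v0, k = 8),
                        lower = c(-0.2, 1e-6, -200, 0.5), upper = c(0.5, 2, 50, 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) e)
  if (inherits(fit, "error"))
    .stopf("Boltzmann fit did not converge: %s", conditionMessage(fit))
  cf <- stats::coef(fit)
  bottom <- if (fix_bottom) 0 else unname(cf["bot"])
  out <- list(V_half_mV = unname(cf["vh"]), k_mV = unname(cf["k"]),
              top = unname(cf["top"]), bottom = bottom,
              rmse = sqrt(mean(stats::residuals(fit)^2)))
  out$fitted <- function(V)
    out$bottom + (out$top - out$bottom) / (1 + exp((V - out$V_half_mV) / out$k_mV))
  class(out) <- "boltzmann_fit"
  out
}

#' Resting-state affinity from hyperpolarized inhibition
#'
#' At a strongly hyperpolarized pre-pulse (-150 mV) essentially all
#' channels are resting, so the rearranged Hill equation applied to the
#' inhibition there gives the resting dissociation constant directly:
#' `Kr = (1 - Inh) * cc / Inh`.
#'
#' @param Inh_minus150 inhibited fraction at the -150 mV pre-pulse,
#'   strictly inside (0, 1).
#' @param cc tested concentration, uM.
#' @return Kr in uM.
#' @export
kr_from_hyperpolarized <- function(Inh_minus150, cc) {
  if (any(Inh_minus150 <= 0 | Inh_minus150 >= 1))
    .stopf("Inh at -150 mV must be strictly inside (0, 1)")
  ic50_single_point(Inh_minus150, cc)
}

#' Inactivated-state affinity from the availability-curve shift
#'
#' Inverts the four-state midpoint-shift relation
#' `dV1/2 = -k * log((1 + cc/Ki)/(1 + cc/Kr))` for Ki:
#' `Ki = cc / ((1 + cc/Kr) * exp(-dV1/2 / k) - 1)`.
#' A hyperpolarizing (negative) shift is expected for drugs preferring
#' the inactivated state; `dV_half = 0` returns `Ki = Kr`.
#'
#' @param dV_half availability midpoint shift, drug minus control, mV.
#' @param k Boltzmann slope factor of the control fit, mV (> 0).
#' @param Kr resting affinity, uM.
#' @param cc tested concentration, uM.
#' @return Ki in uM.
#' @export
ki_from_shift <- function(dV_half, k, Kr, cc) {
  stopifnot(k > 0, Kr > 0, cc > 0)
  den <- (1 + cc / Kr) * exp(-dV_half / k) - 1
  if (den <= 0)
    .stopf(paste("no resolvable inactivated-state preference:",
                 "shift inconsistent with Kr at this concentration"))
  cc / den
}

#' Forward midpoint shift for given affinities (used in round-trip checks)
#'
#' @param Kr,Ki resting and inactivated affinity, uM.
#' @param cc concentration, uM.
#' @param k Boltzmann slope factor, mV.
#' @return Shift in mV (negative for Ki < Kr).
#' @export
shift_forward <- function(Kr, Ki, cc, k) {
  -k * log((1 + cc / Ki) / (1 + cc / Kr))
}

#' Inactivated-state affinity from the apparent affinity
#'
#' At a pre-pulse potential where the drug-free availability is `h`, the
#' apparent dissociation constant `Kapp = (1 - Inh) * cc / Inh` mixes the
#' two state affinities harmonically, `1/Kapp = h/Kr + (1 - h)/Ki`;
#' inverting gives `Ki = (1 - h) / (1/Kapp - h/Kr)`.
#'
#' @param Inh_V inhibited fraction at the chosen pre-pulse potential,
#'   strictly inside (0, 1).
#' @param cc tested concentration, uM.
#' @param h drug-free availability at the same potential, in `[0, 1)`.
#' @param Kr resting affinity, uM.
#' @return Ki in uM.
#' @export
ki_from_kapp <- function(Inh_V, cc, h, Kr) {
  stopifnot(cc > 0, Kr > 0)
  if (any(Inh_V <= 0 | Inh_V >= 1))
    .stopf("Inh at the chosen pre-pulse potential must be strictly inside (0, 1)")
  if (h < 0 || h >= 1 - 1e-6)
    .stopf("drug-free availability h must be in [0, 1)")
  Kapp <- ic50_single_point(Inh_V, cc)
  den <- 1 / Kapp - h / Kr
  if (den <= 0)
    .stopf("apparent affinity is weaker than the resting-state contribution; Ki unresolvable")
  (1 - h) / den
}

#' State-dependence ratio
#'
#' `SD = Kr / Ki`: how much more tightly the drug binds the inactivated
#' conformation than the resting one. Large values are linked to
#' selective inhibition of pathologically active tissue.
#'
#' @param Kr resting affinity, uM.
#' @param Ki_kapp inactivated affinity (apparent-affinity method), uM.
#' @return Dimensionless ratio.
#' @export
state_dependence_ratio <- function(Kr, Ki_kapp) {
  if (any(Kr <= 0) || any(Ki_kapp <= 0)) .stopf("affinities must be > 0")
  Kr / Ki_kapp
}

## per-cell affinity extraction from one control/drug curve pair
.cell_availability_properties <- function(curves, cc, prepulse_for_kapp = -60,
                                          hyperpolarized_V = -150) {
  ctrl <- curves[curves$condition == "control", ]
  drug <- curves[curves$condition == "drug", ]
  if (nrow(ctrl) == 0L || nrow(drug) == 0L)
    .stopf("cell lacks a control or drug availability curve")
  fc <- fit_boltzmann(ctrl$prepulse_voltage_mV, ctrl$normalized_current)
  fd <- fit_boltzmann(drug$prepulse_voltage_mV, drug$normalized_current)
  dV <- fd$V_half_mV - fc$V_half_mV
  ## inhibition read off the fitted curves: robust to single-point noise
  inh_at <- function(V) 1 - fd$fitted(V) / fc$fitted(V)
  Inh150 <- inh_at(hyperpolarized_V)
  Kr <- kr_from_hyperpolarized(Inh150, cc)
  Ki_dV <- ki_from_shift(dV, fc$k_mV, Kr, cc)
  h <- fc$fitted(prepulse_for_kapp) / fc$top  # drug-free availability, unit amplitude
  Ki_kapp <- ki_from_kapp(inh_at(prepulse_for_kapp), cc, h, Kr)
  data.frame(Inh_150 = Inh150, dV_half_mV = dV, k_mV = fc$k_mV,
             Kr_uM = Kr, Ki_dV_uM = Ki_dV, Ki_kapp_uM = Ki_kapp,
             SD = state_dependence_ratio(Kr, Ki_kapp))
}

#' Availability-protocol profile for one drug
#'
#' Per cell: Boltzmann fits of the control and drug curves, the midpoint
#' shift, `Kr` from the fitted inhibition at -150 mV, and both Ki
#' estimators. Affinities are aggregated across cells by geometric mean
#' (arithmetic means with SEM are also reported); the shift by
#' arithmetic mean. Cells whose extraction fails (e.g. unresolvable Ki)
#' are excluded with a warning. Curves measured at different
#' concentrations of the same drug are combined across all cells, as
#' affinities are concentration-independent.
#'
#' @param curves data.frame in [read_availability()] layout, one drug.
#' @param cc tested concentration (uM): a single value, or a named vector
#'   indexed by `cell_id` when cells were measured at different
#'   concentrations.
#' @param prepulse_for_kapp pre-pulse potential for the apparent-affinity
#'   estimator, mV (default -60).
#' @return One-row data.frame; per-cell table attached as attribute
#'   `"cells"`.
#' @export
profile_availability <- function(curves, cc, prepulse_for_kapp = -60) {
  stopifnot(is.data.frame(curves), nrow(curves) > 0L)
  code <- unique(curves$drug_code)
  if (length(code) != 1L) .stopf("profile_availability expects a single drug")
  cells <- split(curves, curves$cell_id)
  cc_for <- function(id) {
    if (length(cc) == 1L && is.null(names(cc))) return(unname(cc))
    if (!id %in% names(cc)) .stopf("no concentration supplied for cell '%s'", id)
    unname(cc[[id]])
  }
  per <- lapply(names(cells), function(id) {
    tryCatch(cbind(cell_id = id, cc_uM = cc_for(id),
                   .cell_availability_properties(cells[[id]], cc_for(id),
                                                 prepulse_for_kapp)),
             error = function(e) {
               .warnf("drug %s cell %s excluded: %s", code, id, conditionMessage(e))
               NULL
             })
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L)
    .stopf("drug %s: no usable availability cells", code)
  agg <- data.frame(
    drug_code = code, n_cells = nrow(per),
    Inh_150 = mean(per$Inh_150), Inh_150_sem = sem(per$Inh_150),
    dV_half_mV = mean(per$dV_half_mV), dV_half_sem = sem(per$dV_half_mV),
    Kr_uM = geometric_mean(per$Kr_uM), Kr_arith_uM = mean(per$Kr_uM),
    Kr_sem = sem(per$Kr_uM),
    Ki_dV_uM = geometric_mean(per$Ki_dV_uM),
    Ki_kapp_uM = geometric_mean(per$Ki_kapp_uM),
    SD = geometric_mean(per$Kr_uM) / geometric_mean(per$Ki_kapp_uM),
    stringsAsFactors = FALSE)
  attr(agg, "cells") <- per
  agg
}

#' Merge train- and availability-protocol profiles into one table
#'
#' @param train_profiles data.frame of [profile_train()] rows.
#' @param availability_profiles data.frame of [profile_availability()]
#'   rows.
#' @return Merged data.frame keyed by `drug_code` (outer join; drugs
#'   present in only one protocol keep NA for the other block).
#' @export
merge_profiles <- function(train_profiles, availability_profiles) {
  out <- merge(train_profiles,
               availability_profiles[, setdiff(names(availability_profiles), "n_cells")],
               by = "drug_code", all = TRUE)
  out[order(out$drug_code), , drop = FALSE]
}
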