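## Extraction of Inh, IC50, Rev, UD, tau_on, tau_off from the 5 Hz train
## protocol. Five anchor amplitudes define the scalar properties:
##   A1, A2  first/fifth-pulse amplitude at control steady state
##   A3, A4  first/fifth-pulse amplitude at drug steady state
##   A5      first-pulse amplitude at washout steady state
## Each anchor is averaged over the last few trains of its phase
## (3 by default) for noise robustness.

#' Extract anchor amplitudes from one cell's train recording
#'
#' @param recording data.frame in [read_recordings()] layout for a single
#'   cell (all three phases present).
#' @param n_anchor_trains how many trains at the end of each phase to
#'   average (default 3); every phase must contain at least this many.
#' @return An object of class `train_anchors`: list with `A1`..`A5`.
#' @export
extract_anchors <- function(recording, n_anchor_trains = 3) {
  stopifnot(is.data.frame(recording))
  missing <- setdiff(.PHASES, unique(recording$phase))
  if (length(missing) > 0L)
    .stopf("recording is missing phase(s): %s", paste(missing, collapse = ", "))
  pick <- function(phase, pulse) {
    sub <- recording[recording$phase == phase & recording$pulse_index == pulse, ]
    trains <- sort(unique(sub$train_index))
    if (length(trains) < n_anchor_trains)
      .stopf("phase '%s' has %d trains; need at least %d",
             phase, length(trains), n_anchor_trains)
    last <- utils::tail(trains, n_anchor_trains)
    mean(sub$peak_amplitude[sub$train_index %in% last])
  }
  out <- list(A1 = pick("control", 1L), A2 = pick("control", 5L),
              A3 = pick("drug", 1L), A4 = pick("drug", 5L),
              A5 = pick("washout", 1L))
  if (out$A1 <= 0) .stopf("control first-pulse anchor A1 must be > 0")
  structure(out, class = "train_anchors")
}

#' Inhibited fraction from anchor amplitudes
#'
#' `Inh = (A1 - A3)/A1`, clipped to `[0, 1]`.
#'
#' @param anchors a `train_anchors` object (or list with `A1`, `A3`).
#' @return Inhibited fraction in `[0, 1]`.
#' @export
inhibition <- function(anchors) {
  if (is.null(anchors$A1) || anchors$A1 == 0) .stopf("A1 must be > 0")
  min(max((anchors$A1 - anchors$A3) / anchors$A1, 0), 1)
}

#' Single-point IC50 from the rearranged Hill equation
#'
#' Assuming one-to-one binding, a single fractional inhibition `Inh`
#' measured at concentration `cc` determines `IC50 = (1 - Inh) * cc / Inh`.
#'
#' @param Inh inhibited fraction, strictly inside (0, 1).
#' @param cc tested concentration, uM.
#' @return IC50 in uM.
#' @export
#' @examples
#' ic50_single_point(0.5, 100) # 100: half-maximal by construction
ic50_single_point <- function(Inh, cc) {
  stopifnot(cc > 0)
  if (any(Inh <= 0))
    .stopf("Inh <= 0: drug too weak at the tested concentration for a single-point IC50")
  if (any(Inh >= 1))
    .stopf("Inh >= 1: drug too strong at the tested concentration for a single-point IC50")
  (1 - Inh) * cc / Inh
}

#' Reversibility from anchor amplitudes
#'
#' `Rev = A5/A1`: 1 means full washout, 0 apparent irreversibility.
#'
#' @param anchors a `train_anchors` object.
#' @return Reversibility (>= 0, typically <= 1).
#' @export
reversibility <- function(anchors) {
  if (is.null(anchors$A1) || anchors$A1 == 0) .stopf("A1 must be > 0")
  anchors$A5 / anchors$A1
}

#' Use-dependence from anchor amplitudes
#'
#' `UD = (A3/A4)/(A1/A2)`: the within-train amplitude decline in drug
#' relative to the decline in control. 1 means no use-dependence.
#'
#' @param anchors a `train_anchors` object.
#' @return Use-dependence ratio.
#' @export
use_dependence <- function(anchors) {
  if (is.null(anchors$A2) || is.null(anchors$A4) || anchors$A2 == 0 || anchors$A4 == 0)
    .stopf("A2 and A4 must be > 0")
  (anchors$A3 / anchors$A4) / (anchors$A1 / anchors$A2)
}

#' Monoexponential time-constant fit
#'
#' Least-squares fit of `y(t) = y_inf + (y0 - y_inf) * exp(-t/tau)` to
#' first-pulse amplitudes of consecutive trains, used for both drug onset
#' and washout. The fitted tau is clipped to `clip_bounds` (3 and 500 s
#' by default: onsets faster than the 20 s train period cannot be
#' resolved, and no recovery is observable beyond the washout duration);
#' clipping is flagged in the result.
#'
#' @param times times of the fitted points, s (relative to phase start).
#' @param amplitudes peak amplitudes at `times`.
#' @param direction `"onset"` (decaying amplitude) or `"offset"`
#'   (recovering amplitude); used for starting values only.
#' @param clip_bounds reporting bounds for tau, s.
#' @return List with `tau_s` (clipped), `tau_raw_s`, `clipped`,
#'   `converged`, `y0`, `y_inf`, `rmse`. On non-convergence `tau_s` is
#'   `NA` and `converged` is `FALSE`.
#' @export
fit_exponential_tau <- function(times, amplitudes,
                                direction = c("onset", "offset"),
                                clip_bounds = c(3, 500)) {
  direction <- match.arg(direction)
  stopifnot(length(times) == length(amplitudes))
  if (length(times) < 4L) .stopf("at least 4 points are required for a tau fit")
  t0 <- times - min(times)
  ## the model is linear in (y_inf, amplitude) given tau, so tau is
  ## profiled out: coarse log-spaced grid, then golden-section
  ## refinement. This converges even when the decay is faster than the
  ## sampling interval (a step), where free 3-parameter optimizers hit a
  ## singular gradient.
  sse_fit <- function(tau) {
    X <- cbind(1, exp(-t0 / tau))
    fit <- stats::lm.fit(X, amplitudes)
    list(sse = sum(fit$residuals^2), coef = fit$coefficients)
  }
  grid <- exp(seq(log(0.1), log(1e4), length.out = 241L))
  sse <- vapply(grid, function(tau) sse_fit(tau)$sse, numeric(1))
  if (!any(is.finite(sse)))
    return(list(tau_s = NA_real_, tau_raw_s = NA_real_, clipped = FALSE,
                converged = FALSE, y0 = NA_real_, y_inf = NA_real_, rmse = NA_real_))
  i <- which.min(sse)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(function(lt) sse_fit(exp(lt))$sse, c(log(lo), log(hi)),
                         tol = 1e-10)
  tau <- exp(opt$minimum)
  best <- sse_fit(tau)
  ## on an SSE plateau (decay unresolvably fast) report the grid argmin,
  ## which the plateau makes the smallest indistinguishable tau
  if (sse[i] <= best$sse) { tau <- grid[i]; best <- sse_fit(tau) }
  clipped <- tau < clip_bounds[1] || tau > clip_bounds[2]
  cf <- best$coef
  list(tau_s = min(max(tau, clip_bounds[1]), clip_bounds[2]),
       tau_raw_s = tau, clipped = clipped, converged = TRUE,
       y0 = unname(cf[1] + cf[2]), y_inf = unname(cf[1]),
       rmse = sqrt(best$sse / length(amplitudes)))
}

## per-cell property extraction for one train recording
.cell_train_properties <- function(recording, cc, n_anchor_trains = 3,
                                   clip_bounds = c(3, 500)) {
  a <- extract_anchors(recording, n_anchor_trains)
  Inh <- inhibition(a)
  first <- recording[recording$pulse_index == 1L, ]
  fit_phase <- function(phase, direction) {
    sub <- first[first$phase == phase, ]
    fit_exponential_tau(sub$sweep_time_s, sub$peak_amplitude,
                        direction = direction, clip_bounds = clip_bounds)
  }
  on <- fit_phase("drug", "onset")
  off <- fit_phase("washout", "offset")
  data.frame(
    Inh = Inh,
    IC50_uM = if (Inh > 0 && Inh < 1) ic50_single_point(Inh, cc) else NA_real_,
    Rev = reversibility(a), UD = use_dependence(a),
    tau_on_s = on$tau_s, tau_on_clipped = on$clipped,
    tau_off_s = off$tau_s, tau_off_clipped = off$clipped)
}

#' Train-protocol profile for one drug
#'
#' Computes the five train-protocol properties per cell, then aggregates
#' across cells: arithmetic mean with SEM for `Inh`, `Rev`, `UD` and the
#' time constants; geometric mean for `IC50` (the convention of the
#' reference tables; the arithmetic mean is also reported). Cells whose
#' extraction fails are excluded with a warning.
#'
#' @param recordings data.frame in [read_recordings()] layout, one drug,
#'   one or more cells.
#' @param cc tested concentration, uM.
#' @param n_anchor_trains trains averaged per anchor.
#' @param clip_bounds tau reporting bounds, s.
#' @return One-row data.frame with the aggregated properties plus
#'   `n_cells`; the per-cell table is attached as attribute `"cells"`.
#' @export
profile_train <- function(recordings, cc, n_anchor_trains = 3,
                          clip_bounds = c(3, 500)) {
  stopifnot(is.data.frame(recordings), nrow(recordings) > 0L)
  code <- unique(recordings$drug_code)
  if (length(code) != 1L) .stopf("profile_train expects a single drug")
  cells <- split(recordings, recordings$cell_id)
  per <- lapply(names(cells), function(id) {
    tryCatch(cbind(cell_id = id,
                   .cell_train_properties(cells[[id]], cc, n_anchor_trains, clip_bounds)),
             error = function(e) {
               .warnf("drug %s cell %s excluded: %s", code, id, conditionMessage(e))
               NULL
             })
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L)
    .stopf("drug %s: no usable cells", code)
  agg <- data.frame(
    drug_code = code, cc_uM = cc, n_cells = nrow(per),
    Inh = mean(per$Inh), Inh_sem = sem(per$Inh),
    IC50_uM = geometric_mean(per$IC50_uM),
    IC50_arith_uM = mean(per$IC50_uM, na.rm = TRUE),
    Rev = mean(per$Rev), Rev_sem = sem(per$Rev),
    UD = mean(per$UD), UD_sem = sem(per$UD),
    tau_on_s = mean(per$tau_on_s, na.rm = TRUE), tau_on_sem = sem(per$tau_on_s),
    tau_off_s = mean(per$tau_off_s, na.rm = TRUE), tau_off_sem = sem(per$tau_off_s),
    stringsAsFactors = FALSE)
  attr(agg, "cells") <- per
  agg
}
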