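## Four-state equilibrium simulator.
##
## The model has four states: resting (R), inactivated (I), drug-bound
## resting (RD) and drug-bound inactivated (ID). Gating follows a
## Boltzmann voltage dependence with midpoint V1/2 and slope k; drug
## binding is at equilibrium with dissociation constants Kr (resting)
## and Ki (inactivated). The available (current-passing) fraction at a
## pre-pulse voltage V with drug concentration D is
##
##   f(V, D) = 1 / (1 + D/Kr + exp((V - V1/2)/k) * (1 + D/Ki))
##
## which reduces to the drug-free Boltzmann availability
## h(V) = 1/(1 + exp((V - V1/2)/k)) at D = 0. Use-dependence within 5 Hz
## trains is modeled phenomenologically (per-pulse increments), because
## no within-train kinetic scheme is part of the equilibrium model.

#' Ground-truth parameters for the four-state simulator
#'
#' @param V_half_mV midpoint of the drug-free availability curve (mV).
#' @param k_mV Boltzmann slope factor (mV, > 0).
#' @param Kr_uM dissociation constant from the resting state (uM).
#' @param Ki_uM dissociation constant from the inactivated state (uM).
#'   `Ki_uM > Kr_uM` (inverse state-dependence) is allowed but flagged
#'   with a warning.
#' @param drug_concentration_uM applied drug concentration (uM).
#' @param tau_on_s,tau_off_s monoexponential equilibration time constants
#'   of drug onset and washout at the holding potential (s).
#' @param ud_increment fractional extra block accumulated per pulse
#'   within a drug-phase train (>= 0); 0 means no use-dependence.
#' @param ud_recovery fraction of within-train block recovered between
#'   trains, in `[0, 1]`; 1 means trains are independent.
#' @param rev_residual fraction of the control amplitude still blocked at
#'   the washout plateau; reversibility extracted downstream is
#'   approximately `1 - rev_residual`.
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   measurement noise applied to every peak amplitude.
#' @param cell_cv lognormal cell-to-cell scatter (sdlog) of Kr and Ki in
#'   [simulate_cohort()].
#' @param seed optional RNG seed used by the `simulate_*` functions.
#' @return An object of class `four_state_params`.
#' @export
#' @examples
#' p <- four_state_params(Kr_uM = 600, Ki_uM = 6, drug_concentration_uM = 100)
#' equilibrium_available_fraction(-65, p, D = 0) # 0.5 at the midpoint
four_state_params <- function(V_half_mV = -65, k_mV = 8,
                              Kr_uM, Ki_uM, drug_concentration_uM,
                              tau_on_s = 15, tau_off_s = 25,
                              ud_increment = 0, ud_recovery = 1,
                              rev_residual = 0,
                              noise_cv = 0, cell_cv = 0, seed = NULL) {
  if (k_mV == 0) .stopf("k_mV must be non-zero")
  stopifnot(k_mV > 0, Kr_uM > 0, Ki_uM > 0, drug_concentration_uM >= 0,
            tau_on_s > 0, tau_off_s > 0, ud_increment >= 0, ud_increment < 1,
            ud_recovery >= 0, ud_recovery <= 1,
            rev_residual >= 0, rev_residual < 1, noise_cv >= 0, cell_cv >= 0)
  if (Ki_uM > Kr_uM)
    .warnf("Ki_uM > Kr_uM: drug prefers the resting state (inverse state-dependence)")
  structure(list(V_half_mV = V_half_mV, k_mV = k_mV, Kr_uM = Kr_uM, Ki_uM = Ki_uM,
                 drug_concentration_uM = drug_concentration_uM,
                 tau_on_s = tau_on_s, tau_off_s = tau_off_s,
                 ud_increment = ud_increment, ud_recovery = ud_recovery,
                 rev_residual = rev_residual,
                 noise_cv = noise_cv, cell_cv = cell_cv, seed = seed),
            class = "four_state_params")
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Equilibrium available fraction of the four-state model
#'
#' @param V pre-pulse voltage(s), mV.
#' @param params a [four_state_params()] object.
#' @param D drug concentration (uM); defaults to the concentration in
#'   `params`. `D = 0` gives the drug-free Boltzmann availability.
#' @return Available fraction in (0, 1), vectorized over `V`.
#' @export
equilibrium_available_fraction <- function(V, params, D = params$drug_concentration_uM) {
  stopifnot(inherits(params, "four_state_params"))
  if (params$k_mV == 0) .stopf("k_mV must be non-zero")
  e <- exp((V - params$V_half_mV) / params$k_mV)
  1 / (1 + D / params$Kr_uM + e * (1 + D / params$Ki_uM))
}

#' Closed-form availability midpoint shift caused by the drug
#'
#' For the four-state model the drug curve keeps the Boltzmann shape and
#' slope, with midpoint shifted by
#' `-k * log((1 + D/Ki) / (1 + D/Kr))` (negative = hyperpolarizing for
#' inactivated-state-preferring drugs).
#'
#' @inheritParams equilibrium_available_fraction
#' @return Shift in mV.
#' @export
availability_shift <- function(params, D = params$drug_concentration_uM) {
  stopifnot(inherits(params, "four_state_params"))
  -params$k_mV * log((1 + D / params$Ki_uM) / (1 + D / params$Kr_uM))
}

#' Simulate one cell's availability-curve pair (control and drug)
#'
#' Control currents follow the drug-free Boltzmann availability, drug
#' currents the four-state fraction, both with multiplicative Gaussian
#' noise; both curves are then normalized to the maximum of the drug-free
#' curve, as instrument exports are.
#'
#' @param params a [four_state_params()] object.
#' @param voltages pre-pulse voltages, mV (>= 6 points, increasing).
#' @param drug_code,cell_id identifiers stamped on the output rows.
#' @return A data.frame in [read_availability()] layout.
#' @export
simulate_availability <- function(params, voltages = seq(-150, -30, by = 10),
                                  drug_code = "SYN", cell_id = "cell1") {
  stopifnot(inherits(params, "four_state_params"))
  if (length(voltages) < 6L) .stopf("at least 6 pre-pulse voltages are required")
  voltages <- sort(voltages)
  .with_seed(params$seed, {
    h <- equilibrium_available_fraction(voltages, params, D = 0)
    f <- equilibrium_available_fraction(voltages, params)
    nz <- function(y) pmax(y * (1 + stats::rnorm(length(y), 0, params$noise_cv)), 0)
    ctrl <- nz(h); drug <- nz(f)
    top <- max(ctrl)
    ctrl <- ctrl / top; drug <- drug / top
    rbind(
      data.frame(drug_code = drug_code, cell_id = cell_id,
                 prepulse_voltage_mV = voltages, normalized_current = ctrl,
                 condition = "control", stringsAsFactors = FALSE),
      data.frame(drug_code = drug_code, cell_id = cell_id,
                 prepulse_voltage_mV = voltages, normalized_current = drug,
                 condition = "drug", stringsAsFactors = FALSE))
  })
}

#' Simulate one cell's 5 Hz train recording
#'
#' Three phases of `n_trains_per_phase` trains (control, drug, washout),
#' trains every `train_period_s` seconds, five pulses per train at 5 Hz.
#' The first-pulse amplitude relaxes monoexponentially from the control
#' level toward the inhibited steady state `1/(1 + D/Kr)` during the drug
#' phase (time constant `tau_on_s`) and back toward the washout plateau
#' `1 - rev_residual` during washout (`tau_off_s`). Within drug-phase
#' trains, pulses 2..5 decline by a factor `(1 - ud_increment)` per
#' pulse; a fraction `1 - ud_recovery` of the within-train decline
#' carries over to the next train's first pulse. Multiplicative noise is
#' applied last.
#'
#' @param params a [four_state_params()] object.
#' @param n_trains_per_phase trains per phase (default 10).
#' @param train_period_s train repetition period, s.
#' @param pulse_interval_s interval between pulses within a train, s.
#' @param drug_code,cell_id identifiers stamped on the output rows.
#' @param kr_mix mixing weight in `[0, 1]` for the holding-potential
#'   dissociation constant: 0 (default) uses `Kr`; larger values mix in
#'   `Ki` harmonically, `1/K = (1-w)/Kr + w/Ki`.
#' @return A data.frame in [read_recordings()] layout.
#' @export
simulate_train <- function(params, n_trains_per_phase = 10, train_period_s = 20,
                           pulse_interval_s = 0.2, drug_code = "SYN",
                           cell_id = "cell1", kr_mix = 0) {
  stopifnot(inherits(params, "four_state_params"),
            n_trains_per_phase >= 1, kr_mix >= 0, kr_mix <= 1)
  D <- params$drug_concentration_uM
  K_hold <- 1 / ((1 - kr_mix) / params$Kr_uM + kr_mix / params$Ki_uM)
  block_ss <- D / (D + K_hold)
  ss_drug <- 1 - block_ss
  plateau <- max(1 - params$rev_residual, ss_drug)

  n <- n_trains_per_phase
  t_drug <- n * train_period_s        # drug application time
  t_wash <- 2 * n * train_period_s    # washout start
  envelope <- function(t) {
    if (t < t_drug) return(1)
    if (t < t_wash) return(ss_drug + (1 - ss_drug) * exp(-(t - t_drug) / params$tau_on_s))
    a0 <- ss_drug + (1 - ss_drug) * exp(-(t_wash - t_drug) / params$tau_on_s)
    plateau + (a0 - plateau) * exp(-(t - t_wash) / params$tau_off_s)
  }

  rows <- vector("list", 3L * n)
  carry <- 0 # accumulated unrecovered within-train block
  idx <- 0L
  for (g in seq_len(3L * n)) {
    phase <- .PHASES[(g - 1L) %/% n + 1L]
    t0 <- (g - 1L) * train_period_s
    first <- envelope(t0) * (1 - carry)
    ud <- if (phase == "drug") params$ud_increment else 0
    amps <- first * (1 - ud)^(0:4)
    carry <- (1 - params$ud_recovery) * (carry + (1 - (1 - ud)^4) * (1 - carry))
    idx <- idx + 1L
    rows[[idx]] <- data.frame(
      drug_code = drug_code, cell_id = cell_id,
      sweep_time_s = t0 + (0:4) * pulse_interval_s,
      train_index = g, pulse_index = 1:5, phase = phase,
      peak_amplitude = amps, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  .with_seed(params$seed, {
    out$peak_amplitude <- pmax(
      out$peak_amplitude * (1 + stats::rnorm(nrow(out), 0, params$noise_cv)), 0)
    out
  })
}

#' Parameter grid for a standard synthetic cohort
#'
#' Draws `n_drugs` synthetic drugs with resting affinity log-uniform over
#' `Kr_range` and state-dependence log-uniform over `SD_range`
#' (`Ki = Kr / SD`). The tested concentration is `Kr / 3`, i.e. about 25%
#' resting-state inhibition, mimicking how test concentrations are chosen
#' in practice.
#'
#' @param n_drugs number of synthetic drugs.
#' @param Kr_range,SD_range ranges for the log-uniform draws.
#' @param tau_on_s,tau_off_s,ud_increment,rev_residual shared kinetic and
#'   washout parameters.
#' @param noise_cv,cell_cv noise and cell-scatter levels.
#' @param seed RNG seed for the draws.
#' @return A data.frame with one row per drug (codes `S01`, `S02`, ...).
#' @export
cohort_param_grid <- function(n_drugs = 20, Kr_range = c(30, 3000),
                              SD_range = c(1, 200),
                              tau_on_s = 12, tau_off_s = 25,
                              ud_increment = 0.03, rev_residual = 0.1,
                              noise_cv = 0.02, cell_cv = 0.10, seed = 1) {
  .with_seed(seed, {
    Kr <- exp(stats::runif(n_drugs, log(Kr_range[1]), log(Kr_range[2])))
    SD <- exp(stats::runif(n_drugs, log(SD_range[1]), log(SD_range[2])))
    data.frame(drug_code = sprintf("S%02d", seq_len(n_drugs)),
               Kr_uM = Kr, Ki_uM = Kr / SD, SD = SD,
               drug_concentration_uM = Kr / 3,
               tau_on_s = tau_on_s, tau_off_s = tau_off_s,
               ud_increment = ud_increment, rev_residual = rev_residual,
               noise_cv = noise_cv, cell_cv = cell_cv,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a synthetic cohort of drugs
#'
#' For each drug in `param_table` and each cell, per-cell Kr and Ki are
#' jittered lognormally (`sdlog = cell_cv`) and one train recording plus
#' one availability-curve pair is generated. One RNG stream seeded from
#' `seed` assigns an independent sub-seed to every cell, so output is
#' deterministic for a fixed seed and insensitive to evaluation order.
#'
#' @param param_table data.frame with columns `drug_code`, `Kr_uM`,
#'   `Ki_uM`, `drug_concentration_uM` and optionally the other
#'   [four_state_params()] fields (e.g. from [cohort_param_grid()]).
#' @param cells_per_drug cells per drug.
#' @param seed master RNG seed.
#' @param voltages availability pre-pulse voltages.
#' @param n_trains_per_phase trains per phase in the train protocol.
#' @return A list with elements `recordings`, `availability` (long
#'   data.frames) and `truth` (the input table).
#' @export
simulate_cohort <- function(param_table, cells_per_drug = 4, seed = 1,
                            voltages = seq(-150, -30, by = 10),
                            n_trains_per_phase = 10) {
  stopifnot(is.data.frame(param_table),
            all(c("drug_code", "Kr_uM", "Ki_uM", "drug_concentration_uM") %in%
                  names(param_table)))
  n_cells <- nrow(param_table) * cells_per_drug
  seeds <- .with_seed(seed, matrix(sample.int(.Machine$integer.max, 3L * n_cells),
                                   ncol = 3L))
  opt <- function(row, field, default)
    if (field %in% names(param_table)) row[[field]] else default
  recs <- vector("list", n_cells); avail <- vector("list", n_cells)
  k <- 0L
  for (i in seq_len(nrow(param_table))) {
    row <- param_table[i, ]
    cv <- opt(row, "cell_cv", 0)
    for (j in seq_len(cells_per_drug)) {
      k <- k + 1L
      jit <- .with_seed(seeds[k, 1L], stats::rlnorm(2, 0, cv))
      p <- four_state_params(
        V_half_mV = opt(row, "V_half_mV", -65), k_mV = opt(row, "k_mV", 8),
        Kr_uM = row$Kr_uM * jit[1], Ki_uM = row$Ki_uM * jit[2],
        drug_concentration_uM = row$drug_concentration_uM,
        tau_on_s = opt(row, "tau_on_s", 12), tau_off_s = opt(row, "tau_off_s", 25),
        ud_increment = opt(row, "ud_increment", 0),
        ud_recovery = opt(row, "ud_recovery", 1),
        rev_residual = opt(row, "rev_residual", 0),
        noise_cv = opt(row, "noise_cv", 0), cell_cv = cv,
        seed = seeds[k, 2L])
      cell <- sprintf("%s_c%d", row$drug_code, j)
      recs[[k]] <- simulate_train(p, n_trains_per_phase = n_trains_per_phase,
                                  drug_code = row$drug_code, cell_id = cell)
      p$seed <- seeds[k, 3L]
      avail[[k]] <- simulate_availability(p, voltages = voltages,
                                          drug_code = row$drug_code, cell_id = cell)
    }
  }
  list(recordings = do.call(rbind, recs),
       availability = do.call(rbind, avail),
       truth = param_table)
}
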