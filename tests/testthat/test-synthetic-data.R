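test_that("equilibrium availability reduces to the Boltzmann curve without drug", {
  p <- noiseless_params()
  expect_equal(equilibrium_available_fraction(p$V_half_mV, p, D = 0), 0.5)
  expect_equal(equilibrium_available_fraction(-1e4, p, D = 0), 1, tolerance = 1e-10)
  expect_equal(equilibrium_available_fraction(1e4, p, D = 0), 0, tolerance = 1e-10)
})

test_that("drug-bound availability matches the closed-form midpoint shift", {
  p <- noiseless_params() # Kr 600, Ki 6, D 100, k 8
  shift <- availability_shift(p)
  expect_equal(shift, -8 * log((1 + 100 / 6) / (1 + 100 / 600)), tolerance = 1e-12)
  expect_equal(shift, -21.74, tolerance = 1e-3)
  # the drug curve is a scaled Boltzmann with the shifted midpoint
  V <- seq(-150, -30, by = 1)
  f <- equilibrium_available_fraction(V, p)
  top <- 1 / (1 + 100 / 600)
  expect_equal(f, top / (1 + exp((V - (p$V_half_mV + shift)) / p$k_mV)), tolerance = 1e-12)
})

test_that("availability is monotone in voltage and drug load, and below drug-free", {
  set.seed(5)
  for (i in 1:20) {
    p <- suppressWarnings( # Ki may exceed Kr in this sweep; flag expected
      four_state_params(Kr_uM = exp(runif(1, log(30), log(3000))),
                        Ki_uM = exp(runif(1, log(1), log(500))),
                        drug_concentration_uM = exp(runif(1, log(1), log(1000))),
                        k_mV = runif(1, 4, 12)))
    V <- seq(-150, -30, by = 5)
    f <- equilibrium_available_fraction(V, p)
    h <- equilibrium_available_fraction(V, p, D = 0)
    expect_true(all(diff(f) < 0))
    expect_true(all(f <= h))
    # increasing D can only reduce availability
    f2 <- equilibrium_available_fraction(V, p, D = 2 * p$drug_concentration_uM)
    expect_true(all(f2 <= f))
  }
})

test_that("simulated availability curves have the model's limits at zero noise", {
  p0 <- noiseless_params()
  p0$drug_concentration_uM <- 0
  av0 <- simulate_availability(p0)
  ctrl <- av0[av0$condition == "control", "normalized_current"]
  drug <- av0[av0$condition == "drug", "normalized_current"]
  expect_equal(ctrl, drug, tolerance = 1e-12) # no drug, no noise: identical

  av <- simulate_availability(noiseless_params())
  at150 <- av[av$condition == "drug" & av$prepulse_voltage_mV == -150, "normalized_current"]
  expect_equal(at150, 1 / (1 + 100 / 600), tolerance = 1e-2) # hyperpolarized limit
  expect_error(simulate_availability(noiseless_params(), voltages = c(-150, -90, -30)),
               "at least 6")
})

test_that("train simulation reaches forward-model steady states", {
  # drug at cc = Kr: steady first-pulse amplitude = 1/(1 + D/Kr) = 0.5
  p <- four_state_params(Kr_uM = 600, Ki_uM = 6, drug_concentration_uM = 600,
                         tau_on_s = 10, tau_off_s = 20, noise_cv = 0)
  rec <- simulate_train(p)
  a <- extract_anchors(rec)
  expect_equal(a$A3 / a$A1, 0.5, tolerance = 1e-3)
  expect_equal(use_dependence(a), 1, tolerance = 1e-9) # ud_increment = 0

  # tau_on recovered from the noiseless onset within 2%
  first <- rec[rec$pulse_index == 1 & rec$phase == "drug", ]
  fit <- fit_exponential_tau(first$sweep_time_s, first$peak_amplitude, "onset")
  expect_equal(fit$tau_s, 10, tolerance = 0.02)

  # washout plateau expresses the residual-block parameter
  prr <- four_state_params(Kr_uM = 600, Ki_uM = 6, drug_concentration_uM = 600,
                           tau_on_s = 5, tau_off_s = 10, rev_residual = 0.3,
                           noise_cv = 0)
  arr <- extract_anchors(simulate_train(prr))
  expect_equal(reversibility(arr), 0.7, tolerance = 0.02)
})

test_that("use-dependence accumulates per pulse as configured", {
  p <- four_state_params(Kr_uM = 600, Ki_uM = 6, drug_concentration_uM = 600,
                         ud_increment = 0.05, noise_cv = 0)
  a <- extract_anchors(simulate_train(p))
  expect_equal(use_dependence(a), (1 - 0.05)^-4, tolerance = 1e-6)
})

test_that("cohort simulation is deterministic and sized as requested", {
  grid <- cohort_param_grid(n_drugs = 5, seed = 3)
  c1 <- simulate_cohort(grid, cells_per_drug = 2, seed = 9, n_trains_per_phase = 3)
  c2 <- simulate_cohort(grid, cells_per_drug = 2, seed = 9, n_trains_per_phase = 3)
  expect_identical(c1, c2)
  expect_equal(length(unique(paste(c1$recordings$drug_code, c1$recordings$cell_id))),
               5L * 2L)
  # zero cell scatter and zero noise: all cells of a drug identical
  grid0 <- grid; grid0$cell_cv <- 0; grid0$noise_cv <- 0
  c0 <- simulate_cohort(grid0, cells_per_drug = 2, seed = 9, n_trains_per_phase = 3)
  by_cell <- split(c0$recordings$peak_amplitude, c0$recordings$cell_id)
  expect_equal(by_cell[["S01_c1"]], by_cell[["S01_c2"]], tolerance = 1e-12)
})

test_that("parameter validation catches degenerate inputs", {
  expect_error(four_state_params(k_mV = 0, Kr_uM = 100, Ki_uM = 10,
                                 drug_concentration_uM = 10), "k_mV")
  expect_warning(four_state_params(Kr_uM = 10, Ki_uM = 100,
                                   drug_concentration_uM = 10), "inverse state-dependence")
})
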