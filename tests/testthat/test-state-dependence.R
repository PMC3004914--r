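test_that("Boltzmann fit recovers exact parameters and rejects flat curves", {
  V <- seq(-150, -30, by = 10)
  y <- 1 / (1 + exp((V + 65) / 8))
  fit <- fit_boltzmann(V, y)
  expect_equal(fit$V_half_mV, -65, tolerance = 0.1)
  expect_equal(fit$k_mV, 8, tolerance = 0.1)
  expect_gt(fit$k_mV, 0)
  expect_error(fit_boltzmann(V, rep(0.98, length(V))), "flat")
  expect_error(fit_boltzmann(V[1:5], y[1:5]), "at least 6")
})

test_that("fitted drug curves show the closed-form hyperpolarizing shift", {
  av <- simulate_availability(noiseless_params()) # Kr 600, Ki 6, D 100, k 8
  ctrl <- av[av$condition == "control", ]
  drug <- av[av$condition == "drug", ]
  fc <- fit_boltzmann(ctrl$prepulse_voltage_mV, ctrl$normalized_current)
  fd <- fit_boltzmann(drug$prepulse_voltage_mV, drug$normalized_current)
  expect_equal(fd$V_half_mV - fc$V_half_mV, -21.74, tolerance = 0.05)
})

test_that("resting affinity comes from hyperpolarized inhibition via the Hill form", {
  expect_equal(kr_from_hyperpolarized(0.5, 300), 300)
  # fluoxetine row: Inh 0.13 at 30 uM; printed Kr 210.5 is the per-cell
  # geometric mean, the point estimate lands within a few percent
  expect_equal(kr_from_hyperpolarized(0.13, 30), 200.77, tolerance = 1e-4)
  expect_error(kr_from_hyperpolarized(0, 300), "strictly inside")
  expect_error(kr_from_hyperpolarized(1, 300), "strictly inside")
})

test_that("shift-based Ki inverts the forward shift formula", {
  expect_equal(ki_from_shift(0, k = 8, Kr = 600, cc = 100), 600) # no shift, no preference
  expect_equal(ki_from_shift(-21.74, k = 8, Kr = 600, cc = 100), 6, tolerance = 1e-3)
  expect_error(ki_from_shift(2.5, k = 8, Kr = 600, cc = 100), "no resolvable")
})

test_that("forward and inverse shift formulas are mutually exact", {
  set.seed(21)
  for (i in 1:50) {
    Kr <- exp(runif(1, log(20), log(5000)))
    Ki <- Kr / exp(runif(1, log(1), log(300)))
    cc <- Kr * runif(1, 0.05, 2)
    k <- runif(1, 4, 12)
    dV <- shift_forward(Kr, Ki, cc, k)
    expect_equal(ki_from_shift(dV, k, Kr, cc), Ki, tolerance = 1e-10)
  }
})

test_that("apparent-affinity Ki inverts the two-state mixing formula", {
  # forward: Kr 600, Ki 6, h 0.5 -> Kapp = 1/(h/Kr + (1-h)/Ki)
  Kapp <- 1 / (0.5 / 600 + 0.5 / 6)
  expect_equal(Kapp, 11.88, tolerance = 1e-3)
  Inh <- 100 / (100 + Kapp) # inhibition this Kapp predicts at cc 100
  expect_equal(ki_from_kapp(Inh, cc = 100, h = 0.5, Kr = 600), 6, tolerance = 1e-9)
  # h = 0: fully inactivating pre-pulse, Ki is the apparent affinity itself
  Inh0 <- 100 / (100 + 6)
  expect_equal(ki_from_kapp(Inh0, cc = 100, h = 0, Kr = 600), 6, tolerance = 1e-9)
  expect_error(ki_from_kapp(0.05, cc = 100, h = 0.9999999, Kr = 600), "availability h")
  # apparent affinity weaker than the resting contribution is infeasible
  expect_error(ki_from_kapp(0.01, cc = 100, h = 0.9, Kr = 10), "unresolvable")

  set.seed(22)
  for (i in 1:50) {
    Kr <- exp(runif(1, log(20), log(5000)))
    Ki <- Kr / exp(runif(1, log(1), log(300)))
    cc <- Kr * runif(1, 0.05, 2)
    h <- runif(1, 0.05, 0.95)
    Kapp <- 1 / (h / Kr + (1 - h) / Ki)
    expect_equal(ki_from_kapp(cc / (cc + Kapp), cc, h, Kr), Ki, tolerance = 1e-10)
  }
})

test_that("state-dependence ratio behaves and reproduces printed rows", {
  expect_equal(state_dependence_ratio(10, 10), 1)
  expect_equal(round(state_dependence_ratio(210.5, 6.05), 1), 34.8)  # fluoxetine
  expect_equal(round(state_dependence_ratio(24.19, 0.73)), 33)       # paroxetine
  expect_error(state_dependence_ratio(-1, 2), "> 0")
})

test_that("noiseless availability profiling recovers ground-truth affinities within 1%", {
  av <- simulate_availability(noiseless_params())
  prof <- profile_availability(av, cc = 100)
  expect_equal(prof$Kr_uM, 600, tolerance = 0.01)
  expect_equal(prof$Ki_dV_uM, 6, tolerance = 0.01)
  expect_equal(prof$Ki_kapp_uM, 6, tolerance = 0.01)
  expect_equal(prof$SD, 100, tolerance = 0.02)
})

test_that("multi-cell availability profiles aggregate by geometric mean", {
  grid <- data.frame(drug_code = "SYN", Kr_uM = 300, Ki_uM = 30,
                     drug_concentration_uM = 100, noise_cv = 0, cell_cv = 0.1)
  coh <- simulate_cohort(grid, cells_per_drug = 4, seed = 6)
  prof <- profile_availability(coh$availability, cc = 100)
  expect_equal(prof$n_cells, 4L)
  expect_equal(prof$Kr_uM, 300, tolerance = 0.12) # 4 cells at 10% scatter
  per <- attr(prof, "cells")
  expect_equal(prof$Kr_uM, exp(mean(log(per$Kr_uM))), tolerance = 1e-12)
  # identical cells: geometric mean equals the cell value
  grid0 <- grid; grid0$cell_cv <- 0
  coh0 <- simulate_cohort(grid0, cells_per_drug = 3, seed = 6)
  prof0 <- profile_availability(coh0$availability, cc = 100)
  expect_equal(prof0$Kr_uM, attr(prof0, "cells")$Kr_uM[1], tolerance = 1e-9)
})

test_that("per-cell concentrations are honoured when cells differ in cc", {
  g <- data.frame(drug_code = "SYN", Kr_uM = 300, Ki_uM = 10,
                  drug_concentration_uM = c(30), noise_cv = 0, cell_cv = 0)
  a30 <- simulate_cohort(g, cells_per_drug = 1, seed = 8)$availability
  g$drug_concentration_uM <- 100
  a100 <- simulate_cohort(g, cells_per_drug = 1, seed = 9)$availability
  a100$cell_id <- "SYN_c2"
  both <- rbind(a30, a100)
  prof <- profile_availability(both, cc = c(SYN_c1 = 30, SYN_c2 = 100))
  # affinities are concentration-independent: both cells agree on Kr
  expect_equal(prof$Kr_uM, 300, tolerance = 0.01)
  expect_equal(prof$Ki_kapp_uM, 10, tolerance = 0.01)
})
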