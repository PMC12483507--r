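test_that("quasi-steady force: quadratic law, zero cases, hand value", {
  p <- aero_params(C_F_alpha = 1.5 / sin(0.8))   # so sin(a) C_Fa = 1.5 at 0.8
  f1 <- quasi_steady_force(1e-10, 650, 0.8, p)
  f2 <- quasi_steady_force(1e-10, 1300, 0.8, p)
  expect_equal(f2$F_per_wing / f1$F_per_wing, 4, tolerance = 1e-12)
  expect_equal(quasi_steady_force(0, 650, 0.8, p)$F_total, 0)
  # hand evaluation: 0.5 * 1.225 * 1e-10 * 650^2 * 1.5 = 3.8817e-5 N
  expect_equal(f1$F_per_wing, 0.5 * 1.225 * 1e-10 * 650^2 * 1.5,
               tolerance = 1e-12)
  expect_equal(f1$F_per_wing, 3.88171875e-5, tolerance = 1e-9)
  expect_equal(f1$F_total, 2 * f1$F_per_wing)
  expect_error(quasi_steady_force(-1, 650, 0.8), "invalid")
  expect_error(quasi_steady_force(1e-10, 650, 3.5), "alpha")
})

test_that("compact and decomposed force paths agree to machine precision", {
  set.seed(2)
  for (i in 1:50) {
    R <- stats::runif(1, 0.004, 0.015); cb <- stats::runif(1, 0.001, 0.005)
    s2s <- stats::runif(1, 0.2, 0.5); f <- stats::runif(1, 120, 280)
    A <- stats::runif(1, 1.2, 2.2); al <- stats::runif(1, 0.4, 1.2)
    p <- aero_params(C_F_alpha = stats::runif(1, 1, 3))
    a <- quasi_steady_force(R^3 * cb * s2s, 2 * f * A, al, p)
    b <- quasi_steady_force_decomposed(R, cb, s2s, f, A, al, p)
    expect_equal(a$F_total, b$F_total, tolerance = 1e-12)
  }
})

test_that("weight support ratio and coefficient calibration", {
  p <- aero_params()
  expect_equal(weight_support_ratio(4.905e-4, 50, p), 1, tolerance = 1e-9)
  expect_equal(weight_support_ratio(0, 50, p), 0)
  m <- 50e-6 * 9.81
  expect_equal(weight_support_ratio(m, 50, p), 1, tolerance = 1e-12)
  # calibration drives the mass-weighted mean ratio to 1
  set.seed(3)
  S2 <- stats::runif(6, 5e-12, 4e-10); om <- stats::runif(6, 400, 900)
  al <- stats::runif(6, 0.5, 1); mass <- stats::runif(6, 5, 100)
  cal <- calibrate_cfalpha(S2, om, al, mass, p)
  r <- weight_support_ratio(quasi_steady_force(S2, om, al, cal)$F_total,
                            mass, cal)
  expect_equal(sum(mass * r) / sum(mass), 1, tolerance = 1e-10)
})

test_that("frequency rescaling is quadratic and commutes with the model", {
  expect_equal(frequency_rescale(1, 186, 186), 1)
  expect_equal(frequency_rescale(1, 372, 186), 4)
  expect_equal(frequency_rescale(1, 150, 186), (150 / 186)^2,
               tolerance = 1e-12)
  expect_equal(frequency_rescale(1, 150, 186), 0.6504, tolerance = 1e-4)
  # computing at f directly equals computing at f_mean then rescaling
  p <- aero_params()
  direct <- quasi_steady_force_decomposed(0.0096, 0.0032, 0.34, 150,
                                          100 * pi / 180, 0.73, p)$F_total
  ref <- quasi_steady_force_decomposed(0.0096, 0.0032, 0.34, 186,
                                       100 * pi / 180, 0.73, p)$F_total
  expect_equal(frequency_rescale(ref, 150, 186), direct, tolerance = 1e-12)
})

test_that("baseline exponents make force scale exactly with mass", {
  # plugging a_ws into the full model with all else at similarity gives
  # F ~ m with slope 1 on a log-spaced mass grid
  m <- 10^seq(log10(3), log10(132), length.out = 12)
  rel <- (m / 30)
  p <- aero_params()
  for (metric in c("S2", "R", "c_bar", "S2_star", "f", "A_phi", "alpha")) {
    b <- expected_exponents(metric)
    ex <- list(R = 1 / 3, c_bar = 1 / 3, S2_star = 0, f = 0, A_phi = 0,
               alpha = 0)
    if (metric == "S2") {
      # distribute the S2 weight-support exponent onto R (others isometric)
      ex$R <- (b$a_ws - 1 / 3) / 3
    } else {
      ex[[metric]] <- b$a_ws
    }
    R <- 0.0096 * rel^ex$R; cb <- 0.0032 * rel^ex$c_bar
    s2s <- 0.34 * rel^ex$S2_star; f <- 186 * rel^ex$f
    A <- (100 * pi / 180) * rel^ex$A_phi
    # reference sin(alpha) small enough that sin(alpha) ~ m^a_ws never
    # saturates at 1 over the mass grid
    al <- asin(sin(0.4) * rel^ex$alpha)
    Fv <- quasi_steady_force_decomposed(R, cb, s2s, f, A, al, p)$F_total
    sl <- unname(coef(ols_loglog(m, Fv))["slope"])
    expect_equal(sl, 1, tolerance = 1e-6)
  }
})

test_that("expected exponents match the symbolic derivations", {
  expect_equal(expected_exponents("S2")$a_sim, 4 / 3)
  expect_equal(expected_exponents("S2")$a_ws, 1)
  expect_equal(expected_exponents("R")$a_sim, 1 / 3)
  expect_equal(expected_exponents("R")$a_ws, 2 / 9)
  expect_equal(expected_exponents("c_bar")$a_ws, 0)
  expect_equal(expected_exponents("S2_star")$a_ws, -1 / 3)
  for (m in c("f", "A_phi", "omega_bar"))
    expect_equal(expected_exponents(m)$a_ws, -1 / 6)
  expect_equal(expected_exponents("alpha")$a_ws, -1 / 3)
  expect_equal(expected_exponents("S2_omega2")$a_sim, 4 / 3)
  expect_error(expected_exponents("wing_loading"), "unknown metric")
})

test_that("relative scaling factor: anchors and linearity", {
  expect_equal(relative_scaling_factor(4 / 3, 4 / 3, 1), 0)
  expect_equal(relative_scaling_factor(1, 4 / 3, 1), 100)
  expect_error(relative_scaling_factor(1, 0.5, 0.5), "undefined baseline")
  # linearity in a_allo
  a1 <- 0.9; a2 <- 1.4; lam <- 0.3
  expect_equal(
    relative_scaling_factor(lam * a1 + (1 - lam) * a2, 4 / 3, 1),
    lam * relative_scaling_factor(a1, 4 / 3, 1) +
      (1 - lam) * relative_scaling_factor(a2, 4 / 3, 1),
    tolerance = 1e-10)
})

test_that("contribution decomposition reproduces structure and errors", {
  sim_fits <- list(
    f = scaling_fit(0, -0.1, 0.1, 8), R = scaling_fit(1 / 3, 0.2, 0.5, 8),
    c_bar = scaling_fit(1 / 3, 0.2, 0.5, 8),
    S2_star = scaling_fit(0, -0.1, 0.1, 8))
  dec <- contribution_decomposition(sim_fits)
  expect_true(all(dec$table$a_star == 0))
  expect_equal(dec$component_sum, 0)
  expect_error(contribution_decomposition(list(R = sim_fits$R)),
               "configuration error")
  # noiseless morphology-compensated synthetic set: S2 contribution 100%
  ss <- generate_species_set(scenario_config(
    seed = 5, scenario = "morphology_compensated", noise_sd_log10 = 0))
  fit_s2 <- ols_loglog(ss$traits$mass_mg, ss$traits$S2_mm4, metric = "S2")
  fit_f <- scaling_fit(0, n = nrow(ss$traits), metric = "f")
  dec2 <- contribution_decomposition(list(S2 = fit_s2, f = fit_f))
  a_s2 <- dec2$table$a_star[dec2$table$metric == "S2"]
  expect_equal(a_s2, 100, tolerance = 1)
})
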