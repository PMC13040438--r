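params <- thermo_params()

test_that("standard free energies reproduce the model's anchor reactions", {
  co2_formate <- get_couple("co2_formate")
  h2 <- get_couple("h2")
  mq <- get_couple("mq")
  ch2thf <- get_couple("methylene_thf")

  # formate oxidation to H2 + CO2 at the Fdh-Ech complex: close to equilibrium
  dg_fdh_ech <- delta_g_standard(co2_formate, h2, 2, params)
  expect_equal(dg_fdh_ech, -2 * 96.485 * (-414 + 432) / 1000, tolerance = 1e-12)
  expect_equal(round_half_away(dg_fdh_ech), -3)

  # menaquinol -> methylene-THF, the endergonic leg of the Type IV MTHFR
  dg_mq <- delta_g_standard(mq, ch2thf, 2, params)
  expect_equal(round_half_away(dg_mq, 1), 24.3)

  # identical potentials transfer no energy
  expect_equal(delta_g_standard(h2, h2, 2, params), 0)
})

test_that("delta_g_standard is antisymmetric and linear in n", {
  set.seed(101)
  for (i in 1:20) {
    a <- make_couple(runif(1, -550, 0))
    b <- make_couple(runif(1, -550, 0))
    n <- sample(1:4, 1)
    expect_equal(
      delta_g_standard(a, b, n, params),
      -delta_g_standard(b, a, n, params)
    )
    expect_equal(
      delta_g_standard(a, b, n, params),
      n * delta_g_standard(a, b, 1, params)
    )
  }
})

test_that("cellular potentials are used on request and errors name the couple", {
  nadp <- get_couple("nadp")
  co2f <- get_couple("co2_formate")
  dg_std <- delta_g_standard(nadp, co2f, 2, params)
  dg_cell <- delta_g_standard(nadp, co2f, 2, params, potential = "cellular")
  # standard NADPH (-320) reducing CO2/formate (-432) is strongly uphill;
  # at the cellular -370 mV the gap narrows
  expect_gt(dg_std, dg_cell)
  expect_equal(dg_cell, -2 * 96.485 * (-432 + 370) / 1000)
  broken <- redox_couple("broken", 0)
  broken$e0_prime <- NA_real_
  expect_error(delta_g_standard(broken, co2f, 2, params), "broken")
})

test_that("concentration correction follows R*T*ln(Q) and is additive", {
  expect_equal(delta_g_prime(-3.47, 1, params), -3.47)
  expect_equal(
    delta_g_prime(-3.47, 100, params),
    -3.47 + 8.314e-3 * 298.15 * log(100),
    tolerance = 1e-12
  )
  expect_equal(delta_g_prime(0, 10, params), 5.708, tolerance = 1e-3)
  # additivity over quotient factors
  set.seed(7)
  for (i in 1:10) {
    q1 <- runif(1, 0.01, 50)
    q2 <- runif(1, 0.01, 50)
    expect_equal(
      delta_g_prime(-3.47, q1 * q2, params),
      delta_g_prime(-3.47, q1, params) +
        params$gas_constant * params$temperature * log(q2)
    )
  }
  expect_error(delta_g_prime(-3.47, 0, params), "quotient")
  expect_error(delta_g_prime(-3.47, -1, params), "quotient")
})

test_that("H2 electrode potential follows the Nernst slope of 29.58 mV/decade", {
  expect_equal(h2_potential(1, params), -414)
  expect_equal(h2_nernst_slope(params), 29.58, tolerance = 1e-3)
  expect_equal(h2_potential(1e-4, params), -414 + 4 * h2_nernst_slope(params))
  expect_equal(h2_potential(10, params), -414 - h2_nernst_slope(params))
  # strictly monotone in log pressure with constant slope
  p <- 10^seq(-6, 1, 0.25)
  e <- h2_potential(p, params)
  slopes <- diff(e) / diff(log10(p))
  expect_true(all(abs(slopes + h2_nernst_slope(params)) < 1e-9))
  expect_error(h2_potential(0, params), "> 0")
})

test_that("feasibility sweep finds the crossover and equilibration pressures", {
  nadp <- get_couple("nadp")
  p <- 10^seq(-6, 1, 0.5)

  sw <- feasibility_sweep(nadp, p, params)
  # H2-equilibrated reduction of CO2/formate turns endergonic where the H2
  # couple passes -432 mV, just above atmospheric pressure
  expect_equal(
    attr(sw, "crossover_p_h2"),
    10^(18 / h2_nernst_slope(params)), # E_H2 reaches -432 mV just above 4 atm
    tolerance = 1e-4
  )
  # H2 can hold the NADPH pool at its cellular -370 mV only above ~0.03 atm
  expect_equal(attr(sw, "equilibration_p_h2"), 0.0325, tolerance = 1e-2)
  # dG' increases as pressure falls
  expect_true(all(diff(sw$dg_prime_kj) < 0)) # rows are sorted by rising p

  # crossover agrees with a dense grid sign change within one grid step
  grid <- 10^seq(-6, 1, 0.01)
  dg_grid <- feasibility_sweep(nadp, grid, params)$dg_prime_kj
  flip <- grid[which(diff(sign(dg_grid)) != 0)[1] + c(0, 1)]
  expect_gte(attr(sw, "crossover_p_h2"), flip[1])
  expect_lte(attr(sw, "crossover_p_h2"), flip[2])
})

test_that("fixed-potential reductants are pressure-independent", {
  fd_low <- make_couple(-500, "fd_low")
  sw <- feasibility_sweep(fd_low, 10^seq(-6, 1, 0.5), params, reductant = "fixed")
  expect_true(all(sw$dg_prime_kj < 0)) # -500 mV always below -432
  expect_true(all(sw$dg_prime_kj == sw$dg_prime_kj[1]))

  match_couple <- make_couple(-432, "match")
  sw1 <- feasibility_sweep(match_couple, 1, params, reductant = "fixed")
  expect_equal(sw1$dg_prime_kj, 0)

  expect_error(feasibility_sweep(fd_low, numeric(0), params), "non-empty")
  expect_error(feasibility_sweep(fd_low, c(1, -1), params), "> 0")
})
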