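test_that("all built-in scenarios validate with zero violations", {
  for (builder in scenario_catalog()) {
    s <- builder(scenario_options())
    expect_length(validate_scenario(s), 0)
    # independent double-precision accumulation agrees
    expect_true(all(abs(oracle_net_carriers(s)) < 1e-12))
  }
})

test_that("net reactions match the acetogenic chemistry", {
  high <- net_as_double(net_reaction(build_high_h2()))
  expect_equal(
    high,
    c(CO2 = -2, H2 = -4, H2O = 2, acetate = 1)[names(high)]
  )
  low <- net_as_double(net_reaction(build_low_h2()))
  expect_equal(low, high[names(low)]) # same overall chemistry as high H2

  co <- net_as_double(net_reaction(build_co()))
  expect_equal(
    co,
    c(CO = -4, CO2 = 2, H2O = -2, acetate = 1)[names(co)]
  )
})

test_that("chemiosmotic ATP yields reproduce the model's proton counts", {
  # high H2: 1 H+ (NADH dehydrogenase) + 1 H+ (redox loop) -> 0.5 ATP at 4 H+/ATP
  rep_high <- atp_yield(build_high_h2())
  expect_true(rep_high$protons_translocated == 2)
  expect_true(rep_high$atp_chemiosmotic == rational(1, 2))
  expect_true(rep_high$atp_substrate_level == 0) # formyl-THF synthetase vs acetate kinase

  # low H2 at x = 0: same proton count as high H2
  rep_low <- atp_yield(build_low_h2())
  expect_true(rep_low$protons_translocated == 2)

  # CO: five H+ at the NADH dehydrogenase alone, six in total -> 1.5 ATP
  s_co <- build_co()
  nadh_dh <- Filter(function(e) e$step$id == "nadh_dh", s_co$steps)[[1]]
  expect_true(nadh_dh$flux * nadh_dh$step$protons_out == 5)
  rep_co <- atp_yield(s_co)
  expect_true(rep_co$protons_translocated == 6)
  expect_true(rep_co$atp_chemiosmotic == rational(3, 2))
})

test_that("the unknown Fdh-Ech proton number x shifts yields as a parameter", {
  # forward Fdh-Ech (high H2, CO): +x protons
  rep_x2 <- atp_yield(build_high_h2(scenario_options(ech_protons = 2)))
  expect_true(rep_x2$protons_translocated == 4)
  expect_true(rep_x2$atp_chemiosmotic == 1)
  rep_co_x2 <- atp_yield(build_co(scenario_options(ech_protons = 2)))
  expect_true(rep_co_x2$protons_translocated == 8)

  # reversed Fdh-Ech (low H2): x costs protons; at x = 2 the yield vanishes
  rep_low_x2 <- atp_yield(build_low_h2(scenario_options(ech_protons = 2)))
  expect_true(rep_low_x2$protons_translocated == 0)
  expect_true(rep_low_x2$atp_chemiosmotic == 0)

  # identical net chemistry, different ATP once x > 0
  expect_equal(
    net_as_double(net_reaction(build_high_h2(scenario_options(ech_protons = 2)))),
    net_as_double(net_reaction(build_low_h2(scenario_options(ech_protons = 2))))
  )
  expect_false(isTRUE(rep_x2$atp_chemiosmotic == rep_low_x2$atp_chemiosmotic))
})

test_that("NADPH bookkeeping of the high-H2 ledger closes 5 = 2 + 1 + 2", {
  s <- build_high_h2()
  produced <- rational(0)
  consumed <- rational(0)
  for (e in s$steps) {
    coefs <- e$step$carriers
    if (is.null(coefs) || !"NADPH" %in% names(coefs)) next
    x <- coefs["NADPH"] * e$flux
    if (x > 0) produced <- produced + x else consumed <- consumed + abs(x)
  }
  expect_true(produced == 5)
  expect_true(consumed == 5) # 2 (Fdh) + 1 (methylene-THF DH) + 2 (Nfn)
})

test_that("every scenario turns over four electron pairs per acetate", {
  for (builder in scenario_catalog()) {
    ep <- electron_pair_total(builder(scenario_options()))
    expect_true(ep$acetate_produced == 1)
    expect_true(ep$pairs_in == 4)
    expect_true(ep$pairs_out == 4)
  }
})

test_that("deleting any single step breaks closure (mutation test)", {
  for (builder in scenario_catalog()) {
    s <- builder(scenario_options())
    for (drop in seq_along(s$steps)) {
      mutant <- s
      mutant$steps <- mutant$steps[-drop]
      expect_gt(length(validate_scenario(mutant)), 0)
    }
  }
})

test_that("the formate cycle is closed, proton-configurable, and off at low H2", {
  base <- atp_yield(build_high_h2())
  cycled <- apply_formate_cycle(build_high_h2(), loop_protons_per_formate = 0)
  expect_length(validate_scenario(cycled), 0)
  rep0 <- atp_yield(cycled)
  # neutral toggle: no configured protons, identical yield and net chemistry
  expect_true(rep0$atp_total == base$atp_total)
  expect_equal(net_as_double(rep0$net_reaction), net_as_double(base$net_reaction))

  # the added steps themselves net zero formate and zero CO2
  added <- cycled$steps[(length(build_high_h2()$steps) + 1):length(cycled$steps)]
  net_added <- rep(0, 2)
  names(net_added) <- c("formate", "CO2")
  for (e in added) {
    coefs <- e$step$metabolites
    for (nm in intersect(names(coefs), names(net_added))) {
      net_added[nm] <- net_added[nm] + as.double(coefs[nm]) * as.double(e$flux)
    }
  }
  expect_equal(unname(net_added), c(0, 0))

  # configured loop protons add chemiosmotic yield
  rep2 <- atp_yield(apply_formate_cycle(build_high_h2(), loop_protons_per_formate = 2))
  expect_true(rep2$protons_translocated == 4)

  expect_error(apply_formate_cycle(build_low_h2()), "not active")
  expect_error(build_low_h2(scenario_options(formate_cycle = TRUE)), "not active")

  no_mthfr <- scenario(
    "toy", list(list(step = reaction_step("s", "e", metabolites = c(H2 = -1),
                                          carriers = c(NADPH = 1),
                                          pairs_transferred = 1), flux = 1)),
    external_species = "H2"
  )
  expect_error(apply_formate_cycle(no_mthfr), "MTHFR")
})

test_that("scenarios survive a YAML round trip bit for bit", {
  path <- withr::local_tempfile(fileext = ".yaml")
  s <- build_co(scenario_options(ech_protons = 1))
  write_scenario_yaml(s, path)
  s2 <- read_scenario_yaml(path)
  expect_length(validate_scenario(s2), 0)
  expect_equal(net_as_double(net_reaction(s2)), net_as_double(net_reaction(s)))
  expect_true(atp_yield(s2)$atp_total == atp_yield(s)$atp_total)
})
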