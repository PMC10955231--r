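# Model assembly, integration, audits and population wrapper.

test_that("model assembly is deterministic with the documented state count", {
  sc <- scenario_spec(0.375, "solution", horizon_h = 24)
  m1 <- build_model(default_compounds(), default_physiology(), sc)
  m2 <- build_model(default_compounds(), default_physiology(), sc)
  # 4 luminal pools x 9 segments + 3 enterocyte compounds x 7 segments +
  # 4 compounds x 4 systemic compartments + 2 activity states +
  # 4 compounds x 15 flux accumulators
  expect_equal(m1$n_states, 4 * 9 + 3 * 7 + 4 * 4 + 2 + 4 * 15)
  expect_identical(m1$ix, m2$ix)
  expect_identical(m1$y0, m2$y0)
  expect_identical(m1$ent_ids, c("DABE", "BIBR0951", "BIBR1087"))
})

test_that("routing validation rejects unresolved products and cycles", {
  cps <- default_compounds()
  cps$DABE$gut_pathways[[1]]$product <- "NOT_A_COMPOUND"
  sc <- scenario_spec(0.375, "solution")
  expect_error(build_model(cps, default_physiology(), sc), "unresolved")
  cyc <- default_compounds()
  cyc$DAB$plasma_t_half_min <- 60
  cyc$DAB$plasma_product <- "DABE"
  expect_error(build_model(cyc, default_physiology(), sc), "cycle")
})

test_that("the right-hand side is identically zero before any dose", {
  sc <- scenario_spec(0.375, "solution", dose_times_h = 96, horizon_h = 100)
  m <- build_model(default_compounds(), default_physiology(), sc)
  dy <- m$rhs(1.0, m$y0, NULL)[[1]]
  expect_true(all(dy == 0))
})

test_that("whole-system mass balance closes to the dose", {
  expect_lt(sim_micro()$mass_balance_residual, 1e-6)
  expect_lt(sim_ther()$mass_balance_residual, 1e-6)
  expect_lt(sim_micro_ctc()$mass_balance_residual, 1e-6)
})

test_that("states and outputs stay non-negative and accumulators monotone", {
  sim <- sim_ther()
  expect_true(all(sim$plasma >= 0))
  acc <- sim$states[, grepl("^acc\\.", colnames(sim$states))]
  # monotone up to the dense-output interpolation error of the solver
  # (~1e-11 of the dose on a ~500 umol run)
  expect_true(all(diff(acc) > -1e-6))
})

test_that("a degenerate one-compartment tracer matches the Bateman solution", {
  expect_lt(bateman_error(), 0.001)
})

test_that("integration is converged and grid-insensitive", {
  sc6 <- scenario_spec(0.375, "solution", horizon_h = 24, rtol = 1e-6, atol = 1e-9)
  sc9 <- scenario_spec(0.375, "solution", horizon_h = 24, rtol = 1e-9, atol = 1e-12)
  a6 <- nca_of(simulate_scenario(scenario = sc6))$auc_0_inf
  a9 <- nca_of(simulate_scenario(scenario = sc9))$auc_0_inf
  expect_lt(abs(a6 - a9) / a9, 0.001)
  # doubling the output grid density leaves the metrics essentially unchanged
  scd <- scenario_spec(0.375, "solution", horizon_h = 24, dt_out_h = 0.125)
  ad <- nca_of(simulate_scenario(scenario = scd))$auc_0_inf
  base <- nca_of(sim_micro())$auc_0_inf
  expect_lt(abs(ad - base) / base, 0.005)
})

test_that("zero transporter capacity equals the transporter-free model exactly", {
  sc <- scenario_spec(0.375, "solution", horizon_h = 24)
  no_pgp <- default_compounds(); no_pgp$DABE$pgp <- NULL
  zero_jmax <- default_compounds(overrides = list(
    DABE = list(pgp = transporter_pathway(jmax = 0, km_um = 2.6))))
  s0 <- simulate_scenario(no_pgp, scenario = sc)
  s1 <- simulate_scenario(zero_jmax, scenario = sc)
  expect_equal(s0$plasma, s1$plasma, tolerance = 1e-12)
})

test_that("knocking out the gut oxidative pathway sends the intermediate's Fg to 1", {
  ko <- default_compounds(overrides = list(BIBR0951 = list(gut_pathways = list(
    enzyme_pathway("CYP3A4", "gut", vmax = 0, km_u = 2)))))
  sim <- simulate_scenario(ko, scenario = scenario_spec(0.375, "solution",
                                                        horizon_h = 24))
  expect_equal(sim$summary$fg[sim$summary$compound == "BIBR0951"], 1,
               tolerance = 1e-6)
})

test_that("fraction absorbed falls and the intermediate's Fg rises with dose", {
  fa <- fg <- numeric(0)
  for (d in c(1, 30, 300)) {
    s <- simulate_scenario(scenario = scenario_spec(d, "solid", horizon_h = 30,
                                                    dt_out_h = 0.5))
    fa <- c(fa, s$summary$fa[1])
    fg <- c(fg, s$summary$fg[2])
  }
  expect_true(all(diff(fa) < 0))   # solubility-limited absorption
  expect_true(all(diff(fg) > 0))   # saturable gut oxidation
})

test_that("therapeutic dosing drives jejunal luminal levels toward the mM scale", {
  sim <- sim_ther()
  m <- build_model(default_compounds(), default_physiology(),
                   scenario_spec(300, "solid", horizon_h = 36))
  vl <- default_physiology()$segments$fluid_volume_ml[3] / 1000
  peak_um <- max(sim$states[, m$ix[["dis.jejunum_1"]]]) / vl
  expect_gt(peak_um, 500)
})

test_that("population simulation is seed-reproducible and collapses at zero CV", {
  sc <- scenario_spec(0.375, "solution", horizon_h = 12, dt_out_h = 1)
  p0 <- simulate_population(scenario = sc, cv_map = c(clearance = 0, vss = 0),
                            n_subjects = 2, n_trials = 2, seed = 42)
  base <- simulate_scenario(scenario = sc)
  for (i in 1:4)
    expect_equal(p0$profiles[i, ], unname(base$plasma[, "DAB"]), tolerance = 1e-10)
  p1 <- simulate_population(scenario = sc, cv_map = c(clearance = 30, vss = 20),
                            n_subjects = 2, n_trials = 2, seed = 42)
  p2 <- simulate_population(scenario = sc, cv_map = c(clearance = 30, vss = 20),
                            n_subjects = 2, n_trials = 2, seed = 42)
  expect_identical(p1$profiles, p2$profiles)
  expect_false(identical(p1$profiles[1, ], p1$profiles[2, ]))
  expect_true(all(p1$lower <= p1$upper))
  expect_equal(p1$trial, rep(1:2, each = 2))
})

test_that("compound parameter sets round-trip through YAML", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  cps <- default_compounds()
  write_compounds(cps, path)
  back <- read_compounds(path)
  expect_equal(names(back), names(cps))
  expect_equal(back$BIBR0951$bile_clint_ul_min_1e6, 273)
  expect_equal(back$DABE$pgp$km_um, 2.6)
  expect_equal(back$DABE$csr, 17.9)
  # a model built from the round-tripped set is identical
  sc <- scenario_spec(0.375, "solution", horizon_h = 12)
  m1 <- build_model(cps, default_physiology(), sc)
  m2 <- build_model(back, default_physiology(), sc)
  expect_identical(m1$y0, m2$y0)
  expect_equal(m1$rhs(1, m1$y0 + 0.01, NULL)[[1]],
               m2$rhs(1, m2$y0 + 0.01, NULL)[[1]], tolerance = 1e-12)
  unlink(path)
})
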