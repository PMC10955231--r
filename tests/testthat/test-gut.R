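# Intestinal absorption primitives.

test_that("transit rates are reciprocal residence times", {
  expect_equal(transit_rate(0.5), 2)
  expect_equal(transit_rate(1e9), 1e-9)  # static compartment limit
  expect_error(transit_rate(0), "positive")
  # configured small-intestinal transit times sum to 3.5 h
  seg <- default_physiology()$segments
  expect_equal(sum(seg$transit_time_h[seg$absorptive]), 3.5)
})

test_that("diffusion-layer dissolution respects equilibrium and geometry", {
  kd <- dissolution_rate_coef(10, 1.2, 628, 478)
  expect_equal(dissolution_flux(100, 4.78, 4.78, kd), 0)  # at solubility
  expect_equal(dissolution_flux(0, 0, 4.78, kd), 0)       # nothing to dissolve
  expect_gt(dissolution_flux(100, 0, 4.78, kd), 0)
  # supersaturated solution: clamped at zero, never reverse-dissolves
  expect_equal(dissolution_flux(100, 50, 4.78, kd), 0)
  # halving the particle radius at fixed mass doubles the rate coefficient
  expect_equal(dissolution_rate_coef(5, 1.2, 628, 478),
               2 * dissolution_rate_coef(10, 1.2, 628, 478))
  expect_error(dissolution_flux(-1, 0, 4.78, kd), "negative")
})

test_that("precipitation is latched on the critical supersaturation ratio", {
  # ratio 10 with CSR 17.9 and no prior trigger: nothing precipitates
  expect_lt(supersaturation_trigger(10 * 4.78, 4.78, 17.9), 1e-10)
  expect_equal(precipitation_flux(10 * 4.78, 4.78, 2.88, 0.1, latched = 0), 0)
  # once triggered: first-order in the excess over solubility
  expect_equal(precipitation_flux(95.6, 4.78, 2.88, 0.1, latched = 1),
               2.88 * (95.6 - 4.78) * 0.1, tolerance = 1e-12)
  expect_equal(round(precipitation_flux(95.6, 4.78, 2.88, 0.1, latched = 1), 1),
               26.2)
  # relaxed to solubility: flux stops
  expect_equal(precipitation_flux(4.78, 4.78, 2.88, 0.1, latched = 1), 0)
  expect_gt(supersaturation_trigger(20 * 4.78, 4.78, 17.9), 0.999)
})

test_that("cylindrical absorption rate constant is 2 Peff / r", {
  expect_equal(absorption_rate_constant(1, 1), 0.72)
  expect_equal(absorption_rate_constant(1, 2), 0.36)  # doubling radius halves
  expect_equal(absorption_rate_constant(0, 1), 0)
  expect_error(absorption_rate_constant(1, 0), "positive")
})

test_that("P-gp efflux saturates and shifts Km under inhibition", {
  expect_equal(pgp_efflux(0, 150, 2.6), 0)
  expect_equal(pgp_efflux(2.6, 150, 2.6, weight = 0.1), 0.1 * 150 / 2,
               tolerance = 1e-12)  # half-saturation
  expect_equal(pgp_efflux(1e7, 150, 2.6, weight = 0.1), 0.1 * 150,
               tolerance = 1e-4)   # plateau independent of Km
  # plateau unchanged by a competitive inhibitor
  expect_equal(pgp_efflux(1e8, 150, 2.6, 0.1, inhibition_factor = 10),
               pgp_efflux(1e8, 150, 2.6, 0.1), tolerance = 1e-4)
  expect_error(pgp_efflux(1, 150, 2.6, 1, inhibition_factor = 0.5), ">= 1")
})

test_that("enterocyte metabolism distributes, saturates and routes", {
  phys <- default_physiology()
  seg <- phys$segments
  cyp <- seg$cyp3a_frac[seg$absorptive]
  ces <- seg$ces2_frac[seg$absorptive]
  pws <- list(
    enzyme_pathway("CES2", "gut", vmax = 100, km_u = 50, product = "BIBR0951"),
    enzyme_pathway("CYP3A4", "gut", vmax = 30, km_u = 2)
  )
  # half-saturation per pathway at its own Km (single segment carries all mass)
  one <- c(1, rep(0, 6))
  m50 <- enterocyte_metabolism(rep(50, 7), pws, one, one)
  expect_equal(unname(m50["BIBR0951", 1]), 100 / 2, tolerance = 1e-12)
  m2 <- enterocyte_metabolism(rep(2, 7), pws, one, one)
  expect_equal(unname(m2["oxidative_sink", 1]), 30 / 2, tolerance = 1e-12)
  # linear limit: total rate slope = sum Vmax/Km per segment fraction
  lo <- enterocyte_metabolism(rep(1e-6, 7), pws, cyp, ces)
  expect_equal(sum(lo) / 1e-6, 100 / 50 + 30 / 2, tolerance = 1e-6)
  # full mechanism-based knockdown removes CYP flux, spares the esterase
  ko <- enterocyte_metabolism(rep(2, 7), pws, cyp, ces, cyp_activity = 0)
  expect_equal(sum(ko["oxidative_sink", ]), 0)
  expect_gt(sum(ko["BIBR0951", ]), 0)
  # competitive factor applies to the CYP Km only
  inh <- enterocyte_metabolism(rep(2, 7), pws, cyp, ces, cyp_km_factor = 3)
  expect_equal(inh["BIBR0951", ], ko["BIBR0951", ], tolerance = 1e-12)
  expect_lt(sum(inh["oxidative_sink", ]), sum(m2["oxidative_sink", ]) * 7)
  expect_error(enterocyte_metabolism(rep(1, 7), pws, cyp, ces,
                                     cyp_activity = 2), "\\[0, 1\\]")
})

test_that("first-pass summary turns flux accounting into Fa and Fg", {
  led <- data.frame(abs_in = c(10, 0), efflux = c(2, 0),
                    ent_formed = c(0, 6), bl_out = c(4, 3))
  rownames(led) <- c("PARENT", "MET")
  fp <- first_pass_summary(led, c(PARENT = 10, MET = 0))
  expect_equal(fp$fa[1], 0.8)          # net apical (10 - 2) over dose
  expect_equal(fp$fg[1], 4 / 8)        # basolateral over enterocyte input
  expect_equal(fp$fa[2], 1)            # gut-formed metabolite: Fa reported 1
  expect_equal(fp$fg[2], 0.5)
  # nothing absorbed: undefined flag, not a crash
  led0 <- data.frame(abs_in = 0, efflux = 0, ent_formed = 0, bl_out = 0)
  rownames(led0) <- "X"
  expect_true(first_pass_summary(led0, c(X = 1))$undefined)
})
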