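# Systemic disposition primitives and hepatic first-pass accounting.

test_that("well-stirred clearance has the right limits and plug-in value", {
  low <- well_stirred_clh(97, 0.4, 1)       # restrictive: CLh ~ fu * CLint
  expect_equal(low$clh, 97 * 0.4 / (97 + 0.4), tolerance = 1e-12)
  expect_lt(abs(low$clh - 0.4) / 0.4, 0.005)
  hi <- well_stirred_clh(97, 1, 1e9)        # flow limit
  expect_equal(hi$clh, 97, tolerance = 1e-6)
  expect_equal(hi$fh, 0, tolerance = 1e-6)
  mid <- well_stirred_clh(97, 0.378, 100)
  expect_equal(round(mid$clh, 1), 27.2)
  expect_equal(mid$fh, 1 - mid$clh / 97)
})

test_that("plasma esterase conversion is first order and spares stable pools", {
  k <- c(DABE = halflife_to_rate(364), BIBR0951 = halflife_to_rate(55),
         BIBR1087 = 0, DAB = 0)
  a <- c(DABE = 2, BIBR0951 = 1, BIBR1087 = 5, DAB = 3)
  f <- plasma_conversion(a, k)
  expect_equal(unname(f["DABE"]), 2 * k[["DABE"]])
  expect_equal(plasma_conversion(2 * a, k), 2 * f)       # linearity
  expect_equal(unname(f["BIBR1087"]), 0)                 # stable in plasma
  # identical fractional conversion regardless of concentration scale
  expect_equal(unname(f["BIBR0951"] / a["BIBR0951"]),
               unname(plasma_conversion(a * 100, k)["BIBR0951"] / (a["BIBR0951"] * 100)))
})

test_that("organ Vmax scaling honours the source basis", {
  phys <- default_physiology()
  per_mg <- enzyme_pathway("CES1", "liver", vmax = 1000, km_u = 50,
                           product = "DAB", source = "per_mg")
  expect_equal(liver_pathway_vmax(per_mg, phys),
               1000 * 40 * 1650 * 60 / 1e6)  # pmol/min -> umol/h
  org <- enzyme_pathway("CES1", "liver", vmax = 123, km_u = 50,
                        product = "DAB", source = "organ")
  expect_equal(liver_pathway_vmax(org, phys), 123)
  per_pmol <- enzyme_pathway("CYP3A4", "liver", vmax = 5, km_u = 2,
                             isef = 0.5, source = "per_pmol")
  expect_equal(liver_pathway_vmax(per_pmol, phys),
               5 * 0.5 * 137 * 40 * 1650 * 60 / 1e6)
  gut_pp <- enzyme_pathway("CYP3A4", "gut", vmax = 5, km_u = 2,
                           isef = 0.5, source = "per_pmol")
  expect_equal(gut_pathway_vmax(gut_pp, phys), 5 * 0.5 * 66 * 1000 * 60 / 1e6)
  gut_mg <- enzyme_pathway("CES2", "gut", vmax = 5, km_u = 2, source = "per_mg")
  expect_error(gut_pathway_vmax(gut_mg, phys), "per-mg")
})

test_that("hepatic availability from flux accounting matches the well-stirred form", {
  # tracer-regime simulation: the ethyl-ester intermediate's cumulative
  # liver outflow / inflow must reproduce 1 - E from its scaled CLint
  sim <- sim_micro()
  phys <- default_physiology()
  cps <- default_compounds()
  cp <- cps$BIBR0951
  clint <- sum(vapply(cp$liver_pathways, liver_pathway_vmax, 0, phys = phys) /
                 vapply(cp$liver_pathways, `[[`, 0, "km_u")) +
    scale_clint_bile(cp$bile_clint_ul_min_1e6, phys$hepatocellularity_1e6_g,
                     phys$liver_mass_g)
  fub <- fu_blood(cp$binding$fu_plasma, cp$binding$bp_ratio)
  expected <- well_stirred_clh(phys$qh_l_h, fub, clint)$fh
  got <- sim$summary$fh[sim$summary$compound == "BIBR0951"]
  expect_equal(got, expected, tolerance = 0.02)
})

test_that("a compound without hepatic pathways passes the liver unextracted", {
  sim <- sim_micro()
  expect_equal(sim$summary$fh[sim$summary$compound == "DAB"], 1,
               tolerance = 1e-3)
  expect_equal(sim$summary$fh[sim$summary$compound == "DABE"], 1,
               tolerance = 1e-3)
})

test_that("removing hepatic oxidation raises the active-metabolite yield", {
  # competition removed: more of the intermediate converts to the acid
  base <- sim_micro()
  no_cyp <- simulate_scenario(
    default_compounds(overrides = list(BIBR0951 = list(liver_pathways = list(
      enzyme_pathway("CES1", "liver", vmax = 50000, km_u = 50,
                     product = "DAB", source = "per_mg"))))),
    scenario = scenario_spec(0.375, "solution", horizon_h = 36))
  expect_gt(no_cyp$ledger["DAB", "liver_formed"], base$ledger["DAB", "liver_formed"])
})

test_that("tracer-limit metabolite fraction matches the intrinsic-clearance shares", {
  # at tracer concentrations the fraction of hepatic elimination routed to
  # the acid equals CLint,CES / (CLint,CES + CLint,CYP + CLint,bile)
  sim <- sim_micro()
  phys <- default_physiology()
  cp <- default_compounds()$BIBR0951
  cl <- vapply(cp$liver_pathways, liver_pathway_vmax, 0, phys = phys) /
    vapply(cp$liver_pathways, `[[`, 0, "km_u")
  names(cl) <- vapply(cp$liver_pathways, `[[`, "", "product")
  cl_bile <- scale_clint_bile(cp$bile_clint_ul_min_1e6,
                              phys$hepatocellularity_1e6_g, phys$liver_mass_g)
  fm_expected <- cl[["DAB"]] / (sum(cl) + cl_bile)
  led <- sim$ledger["BIBR0951", ]
  fm_got <- led$liver_ces / (led$liver_ces + led$liver_sink + led$bile)
  expect_equal(fm_got, fm_expected, tolerance = 0.02)
})
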