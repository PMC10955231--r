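# Perpetrator exposure, inhibition terms and DDI outcomes.

test_that("inhibition terms carry exactly the fields of their mechanism", {
  expect_s3_class(inhibition_term("CYP3A", "both", "competitive", ki_u = 16),
                  "inhibition_term")
  expect_error(inhibition_term("CYP3A", "both", "competitive",
                               ki_u = 1, kinact = 1), "ki_u only")
  expect_error(inhibition_term("CYP3A", "gut", "mbi", ki_u = 1),
               "kinact and ki_app_u")
  expect_error(inhibition_term("P-gp", "gut", "mbi", kinact = 1, ki_app_u = 1),
               "CYP3A only")
})

test_that("competitive factors add over co-present inhibitors", {
  expect_equal(competitive_factor(0, 2), 1)
  expect_equal(competitive_factor(2, 2), 2)
  # parent at its Ki plus hydroxy-metabolite at its Ki: factor 3
  expect_equal(competitive_factor(c(2, 5), c(2, 5)), 3)
  expect_error(competitive_factor(-1, 2), ">= 0")
})

test_that("enzyme turnover under inactivation matches its closed form", {
  # no inhibitor: relaxation to baseline at kdeg
  expect_equal(mbi_rhs(0.5, 0, 2, 15, 0.03), 0.03 * 0.5)
  # steady state from ODE integration equals the closed form to 1e-8
  for (iu in c(0.3, 1, 5)) {
    f <- function(t, y, p) list(mbi_rhs(y, iu, 2, 15, 0.03))
    out <- deSolve::lsoda(c(e = 1), seq(0, 3000, 50), f, NULL,
                          rtol = 1e-12, atol = 1e-14)
    expect_equal(unname(out[nrow(out), "e"]),
                 mbi_steady_state(iu, 2, 15, 0.03), tolerance = 1e-8)
  }
  # saturation limit
  expect_equal(mbi_steady_state(1e12, 2, 15, 0.03), 0.03 / (0.03 + 2),
               tolerance = 1e-9)
})

test_that("perpetrator exposure is causal, superposed and time-invariant", {
  phys <- default_physiology()
  ctc <- default_perpetrators()$CTC
  pre <- perpetrator_exposure(ctc, c(-1, 0), phys)
  expect_true(all(pre$sys_u == 0) && all(pre$ent == 0) && all(pre$lumen == 0))

  # t1/2 ~ 4.3 h << 24 h: troughs reach within 5% of steady state by day 4
  tr <- perpetrator_exposure(ctc, c(4 * 24, 5 * 24), phys)
  expect_lt(abs(tr$sys_u[1] - tr$sys_u[2]) / tr$sys_u[2], 0.05)

  # shifting the first dose 1 h earlier shifts the whole curve exactly 1 h
  vp <- default_perpetrators()$VP
  vp_early <- vp; vp_early$start_h <- 0; vp$start_h <- 1
  tt <- seq(2, 12, by = 0.5)
  a <- perpetrator_exposure(vp, tt, phys)
  b <- perpetrator_exposure(vp_early, tt - 1, phys)
  expect_equal(a$sys_u, b$sys_u, tolerance = 1e-12)
  expect_equal(a$ent, b$ent, tolerance = 1e-12)
})

test_that("a perpetrator with no interaction terms reproduces the control run", {
  inert <- perpetrator_spec("INERT", 747.95, dose_mg = 500, n_doses = 2,
                            interval_h = 12, ka_h = 0.5, v_f_l = 250,
                            cl_f_l_h = 40, fu_plasma = 0.3)
  sc0 <- scenario_spec(0.375, "solution", horizon_h = 24)
  sc1 <- scenario_spec(0.375, "solution", perpetrators = list(inert),
                       horizon_h = 24)
  s0 <- simulate_scenario(scenario = sc0)
  s1 <- simulate_scenario(scenario = sc1)
  expect_identical(s0$plasma, s1$plasma)
  expect_true(all(s1$e_gut == 1) && all(s1$e_liver == 1))
})

test_that("DDI outcome ratios are unity for identical runs and guarded", {
  s <- sim_micro()
  o <- ddi_outcome(s, s)
  expect_equal(o$auc_ratio, 1)
  expect_equal(o$cmax_ratio, 1)
  expect_true(all(abs(o$first_pass$fg_ratio - 1) < 1e-12, na.rm = TRUE))
  other <- sim_ther()
  expect_error(ddi_outcome(s, other), "different substrate")
})

test_that("pure inhibition never decreases the active-metabolite exposure", {
  o_m <- ddi_outcome(sim_micro(), sim_micro_ctc())
  o_t <- ddi_outcome(sim_ther(), sim_ther_ctc())
  expect_gt(o_m$auc_ratio, 1)
  expect_gt(o_t$auc_ratio, 1)
  expect_gt(o_m$cmax_ratio, 1)
})

test_that("the DDI disparity concentrates in the gut metabolite's Fg ratio", {
  o_m <- ddi_outcome(sim_micro(), sim_micro_ctc())
  o_t <- ddi_outcome(sim_ther(), sim_ther_ctc())
  fg_m <- o_m$first_pass
  # the intermediate's Fg ratio dominates every other first-pass ratio
  r0951 <- fg_m$fg_ratio[fg_m$compound == "BIBR0951"]
  expect_gt(r0951, fg_m$fg_ratio[fg_m$compound == "DABE"])
  expect_gt(r0951, fg_m$fa_ratio[fg_m$compound == "DABE"])
  expect_gt(r0951, fg_m$fh_ratio[fg_m$compound == "BIBR0951"])
  # and shrinks markedly from the microdose to the therapeutic dose
  expect_gt(r0951 / o_t$first_pass$fg_ratio[fg_m$compound == "BIBR0951"], 1.5)
})
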