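# In vitro -> in vivo extrapolation helpers.

test_that("half-life conversion follows the ln(2) identity", {
  expect_equal(halflife_to_rate(60), log(2), tolerance = 1e-12)
  expect_equal(halflife_to_rate(364), log(2) * 60 / 364, tolerance = 1e-12)
  expect_equal(round(halflife_to_rate(364), 4), 0.1143)
  expect_equal(round(halflife_to_rate(55), 4), 0.7562)
  expect_error(halflife_to_rate(0), "positive")
  expect_error(halflife_to_rate(-5), "positive")
})

test_that("plasma decay fitting inverts the generator and flags stability", {
  # noiseless: generator/fitter inverse pair at the ethyl-ester half-life
  d <- gen_invitro_decay(halflife_to_rate(55), noise = noise_model(0, seed = 1))
  fit <- fit_halflife(d)
  expect_false(fit$stable)
  expect_equal(fit$t_half_min, 55, tolerance = 1e-8)
  expect_equal(fit$k_h, halflife_to_rate(55), tolerance = 1e-8)

  # seeded noisy prodrug decay: a 2 h incubation observes less than a
  # quarter of a 364 min half-life, so a single noisy run carries a ~25%
  # sampling error; the estimator must still be unbiased, so the mean over
  # seeded repetitions recovers the truth within 15%
  est <- vapply(1:25, function(i) {
    d2 <- gen_invitro_decay(halflife_to_rate(364),
                            noise = noise_model(10, seed = 200 + i))
    fit_halflife(d2)$t_half_min
  }, 0)
  expect_true(all(is.finite(est)))
  expect_lt(abs(mean(est) - 364) / 364, 0.15)

  # constant series: stable (the desethyl intermediate does not decay)
  d3 <- gen_invitro_decay("stable", noise = noise_model(5, seed = 3))
  expect_true(fit_halflife(d3)$stable)

  expect_error(fit_halflife(data.frame(time_min = 0:5, conc = rep(0, 6))),
               "all-zero")
  expect_error(fit_halflife(data.frame(time_min = c(0, 1, 2), conc = c(1, .5, .2))),
               "4 distinct")
})

test_that("Michaelis-Menten fitting recovers parameters", {
  d <- gen_mm_rates(10, 2, noise = noise_model(0, seed = 1))
  fit <- fit_mm(d)
  expect_equal(fit$vmax, 10, tolerance = 1e-6)
  expect_equal(fit$km_um, 2, tolerance = 1e-6)

  d2 <- gen_mm_rates(8, 1.5, noise = noise_model(10, seed = 11))
  fit2 <- fit_mm(d2)
  expect_lt(abs(fit2$vmax - 8) / 8, 0.2)
  expect_lt(abs(fit2$km_um - 1.5) / 1.5, 0.2)

  # a CYP3A-like design around Km 2 uM keeps the estimate in the 1-3 uM window
  d3 <- gen_mm_rates(5, 2, noise = noise_model(10, seed = 5))
  fit3 <- fit_mm(d3)
  expect_gt(fit3$km_um, 1)
  expect_lt(fit3$km_um, 3)

  expect_error(fit_mm(data.frame(conc_um = c(1, 2, 3), rate = c(1, 2, 3))),
               "4 distinct")
  expect_warning(
    fit_mm(data.frame(conc_um = c(10, 20, 30, 40), rate = 9 * c(10, 20, 30, 40) / (2 + c(10, 20, 30, 40)))),
    "0.2x-5x")
})

test_that("ISEF is the HLM over recombinant-times-abundance ratio", {
  expect_equal(compute_isef(100, 1, 100), 1)
  expect_equal(compute_isef(50, 1, 100), 0.5)
  expect_equal(compute_isef(25, 1, 100), 0.25)  # halving clint_hlm halves ISEF
  expect_error(compute_isef(0, 1, 100), "positive")
})

test_that("intrinsic clearance scaling is exact and homogeneous", {
  # vmax/km = 1 uL/min/mg scaled by MPPGL 40 and liver 1650 g -> 3.96 L/h
  expect_equal(scale_clint_liver(1, 1, mppgl = 40, liver_mass_g = 1650), 3.96)
  expect_equal(scale_clint_liver(0, 1), 0)            # disabled pathway
  expect_equal(scale_clint_liver(1, 1, fu_inc = 0.5), # reciprocal fu scaling
               2 * scale_clint_liver(1, 1, fu_inc = 1))
  expect_equal(scale_clint_bile(273, 120, 1650), 3243.24)
  expect_equal(scale_clint_bile(0), 0)
  # homogeneity of degree 1 in extensive inputs
  expect_equal(scale_clint_liver(1, 1, liver_mass_g = 3300),
               2 * scale_clint_liver(1, 1, liver_mass_g = 1650))
  expect_equal(scale_clint_bile(273, 120, 3300),
               2 * scale_clint_bile(273, 120, 1650))
})

test_that("jejunal permeability correlation behaves as configured", {
  co <- peff_coefficients()
  expect_equal(predict_peff(0, 0), 10^co[["intercept"]] / 1e-4)
  # the monoester descriptors (PSA 137, HBD 3) give a low-permeability value
  expect_equal(predict_peff(137, 3), 0.1297, tolerance = 1e-3)
  expect_lt(predict_peff(137, 4), predict_peff(137, 3))  # decreasing in HBD
  expect_lt(predict_peff(150, 3), predict_peff(137, 3))  # decreasing in PSA
  expect_error(predict_peff(-1, 0), "non-negative")
})

test_that("blood unbound fraction divides plasma binding by B:P", {
  expect_equal(fu_blood(0.227, 0.6), 0.3783, tolerance = 1e-3)
  expect_equal(fu_blood(0.018, 0.6), 0.030, tolerance = 1e-3)
  expect_equal(fu_blood(0.5, 1), 0.5)
})

test_that("pathway constructors enforce their invariants", {
  expect_error(enzyme_pathway("CES1", "liver", 10, 2, isef = 0.5), "isef = 1")
  expect_error(enzyme_pathway("CYP3A4", "gut", -1, 2), "non-negative")
  expect_error(enzyme_pathway("CYP3A4", "gut", 1, 0), "positive")
  expect_error(transporter_pathway(-1), "non-negative")
  expect_error(binding_params(0, 1), "\\(0, 1\\]")
  expect_error(binding_params(0.5, 0), "positive")
  ok <- enzyme_pathway("CYP3A4", "liver", 100, 2, isef = 0.3, product = "DAB",
                       source = "per_pmol")
  expect_s3_class(ok, "enzyme_pathway")
  expect_true(ok$is_cyp)
})
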