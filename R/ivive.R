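# In vitro -> in vivo extrapolation: converting bench measurements (plasma
# stability half-lives, microsomal Michaelis-Menten kinetics, binding,
# permeability descriptors) into the kinetic and scaling parameters the PBPK
# engine consumes.

#' Convert an in vitro half-life to a first-order rate constant
#'
#' Plasma esterase hydrolysis of the prodrug and its ethyl-ester intermediate
#' is concentration independent, so a single half-life fully determines the
#' conversion rate constant used in the systemic model.
#'
#' @param t_half_min Half-life in minutes (> 0).
#' @return First-order rate constant in 1/h.
#' @examples
#' halflife_to_rate(60)   # ln(2) per hour
#' halflife_to_rate(364)  # prodrug plasma hydrolysis
#' @export
halflife_to_rate <- function(t_half_min) {
  assert_positive(t_half_min, "t_half_min")
  log(2) * 60 / t_half_min
}

#' Fit a first-order decay half-life from an in vitro incubation
#'
#' Log-linear regression of concentration on time, pooled over replicates.
#' When the decay slope is not distinguishable from zero (two-sided test at
#' \code{alpha}), the compound is reported as stable over the incubation.
#'
#' @param data Data frame with columns \code{time_min}, \code{conc} (and
#'   optionally \code{replicate}); concentrations in any common unit.
#' @param alpha Significance level for the slope-zero stability test.
#' @return List with \code{stable} (logical), \code{t_half_min},
#'   \code{se_t_half_min}, \code{k_h} (rate in 1/h) and the fitted model.
#' @export
fit_halflife <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data), all(c("time_min", "conc") %in% names(data)))
  if (length(unique(data$time_min)) < 4)
    stop_invalid("at least 4 distinct time points are required")
  if (all(data$conc <= 0)) stop_invalid("all-zero concentration series")
  d <- data[data$conc > 0, , drop = FALSE]
  fit <- stats::lm(log(conc) ~ time_min, data = d)
  sm <- suppressWarnings(summary(fit))$coefficients  # noiseless data fit exactly
  slope <- sm["time_min", "Estimate"]
  p <- sm["time_min", "Pr(>|t|)"]
  if (slope >= 0 || p >= alpha)
    return(list(stable = TRUE, t_half_min = Inf, se_t_half_min = NA_real_,
                k_h = 0, fit = fit))
  k_min <- -slope
  t_half <- log(2) / k_min
  # delta method: t1/2 = ln2/k
  se_t <- log(2) / k_min^2 * sm["time_min", "Std. Error"]
  list(stable = FALSE, t_half_min = t_half, se_t_half_min = se_t,
       k_h = k_min * 60, fit = fit)
}

#' Fit Michaelis-Menten kinetics to a rate-versus-concentration dataset
#'
#' Nonlinear least squares of \eqn{v = V_{max} C / (K_m + C)}. Warns when the
#' concentration design does not span roughly 0.2x-5x the fitted Km, where the
#' two parameters become poorly identifiable.
#'
#' @param data Data frame with columns \code{conc_um} and \code{rate}.
#' @return List with \code{vmax}, \code{km_um}, standard errors and the fit.
#' @export
fit_mm <- function(data) {
  stopifnot(is.data.frame(data), all(c("conc_um", "rate") %in% names(data)))
  if (any(data$conc_um <= 0)) stop_invalid("concentrations must be positive")
  if (length(unique(data$conc_um)) < 4)
    stop_invalid("at least 4 distinct concentrations are required")
  start <- list(vmax = max(data$rate) * 1.2,
                km = stats::median(data$conc_um))
  fit <- tryCatch({
    if (requireNamespace("minpack.lm", quietly = TRUE)) {
      minpack.lm::nlsLM(rate ~ vmax * conc_um / (km + conc_um), data = data,
                        start = start,
                        lower = c(vmax = 0, km = 1e-9))
    } else {
      stats::nls(rate ~ vmax * conc_um / (km + conc_um), data = data,
                 start = start, algorithm = "port",
                 lower = c(vmax = 0, km = 1e-9))
    }
  }, error = function(e) {
    stop_invalid("Michaelis-Menten fit did not converge: ", conditionMessage(e))
  })
  est <- summary(fit)$coefficients
  km <- est["km", "Estimate"]
  if (min(data$conc_um) > 0.2 * km || max(data$conc_um) < 5 * km)
    warning("concentration design spans less than 0.2x-5x the fitted Km; ",
            "parameters may be poorly identified", call. = FALSE)
  list(vmax = est["vmax", "Estimate"], km_um = km,
       se_vmax = est["vmax", "Std. Error"], se_km = est["km", "Std. Error"],
       fit = fit)
}

#' Intersystem extrapolation factor from HLM and recombinant-enzyme data
#'
#' \eqn{ISEF = CL_{int,HLM} / (CL_{int,rCYP} \times abundance)}, scaling
#' recombinant-enzyme intrinsic clearance to the activity seen in tissue
#' microsomes.
#'
#' @param clint_hlm Microsomal intrinsic clearance, uL/min/mg protein.
#' @param clint_rcyp Recombinant-enzyme intrinsic clearance, uL/min/pmol.
#' @param abundance Enzyme abundance in tissue microsomes, pmol/mg protein.
#' @return Dimensionless ISEF.
#' @export
compute_isef <- function(clint_hlm, clint_rcyp, abundance) {
  assert_positive(clint_hlm, "clint_hlm")
  assert_positive(clint_rcyp, "clint_rcyp")
  assert_positive(abundance, "abundance")
  clint_hlm / (clint_rcyp * abundance)
}

#' Scale microsomal kinetics to whole-liver unbound intrinsic clearance
#'
#' @param vmax Vmax, pmol/min/mg microsomal protein.
#' @param km_u Unbound Km, uM.
#' @param isef Intersystem extrapolation factor (1 for HLM-sourced values).
#' @param fu_inc Unbound fraction in the incubation.
#' @param mppgl Microsomal protein per gram liver, mg/g.
#' @param liver_mass_g Liver mass, g.
#' @return Whole-liver unbound intrinsic clearance, L/h.
#' @export
scale_clint_liver <- function(vmax, km_u, isef = 1, fu_inc = 1,
                              mppgl = 40, liver_mass_g = 1650) {
  if (vmax < 0) stop_invalid("vmax must be non-negative")
  assert_positive(km_u, "km_u")
  assert_fraction(fu_inc, "fu_inc")
  assert_positive(mppgl, "mppgl")
  assert_positive(liver_mass_g, "liver_mass_g")
  ul_min_to_l_h(isef * (vmax / km_u) / fu_inc * mppgl * liver_mass_g)
}

#' Scale a per-cell biliary intrinsic clearance to the whole liver
#'
#' @param clint_cell Biliary intrinsic clearance, uL/min/10^6 hepatocytes.
#' @param hepatocellularity 10^6 cells per gram liver.
#' @param liver_mass_g Liver mass, g.
#' @return Whole-liver biliary intrinsic clearance, L/h.
#' @export
scale_clint_bile <- function(clint_cell, hepatocellularity = 120,
                             liver_mass_g = 1650) {
  if (clint_cell < 0) stop_invalid("clint_cell must be non-negative")
  assert_positive(hepatocellularity, "hepatocellularity")
  assert_positive(liver_mass_g, "liver_mass_g")
  ul_min_to_l_h(clint_cell * hepatocellularity * liver_mass_g)
}

#' Coefficients of the human jejunal permeability correlation
#'
#' Published regression of log10 effective jejunal permeability (cm/s) on
#' polar surface area and hydrogen-bond-donor count. Stored as configuration
#' rather than hard-coded inside \code{\link{predict_peff}} so an alternative
#' correlation can be swapped in.
#'
#' @return Named numeric vector \code{c(intercept, psa, hbd)}.
#' @export
peff_coefficients <- function() {
  c(intercept = -2.546, psa = -0.011, hbd = -0.278)
}

#' Predict human effective jejunal permeability from PSA and HBD
#'
#' @param psa Polar surface area, Angstrom^2.
#' @param hbd Hydrogen bond donor count.
#' @param coef Correlation coefficients, see \code{\link{peff_coefficients}}.
#' @return Peff in 1e-4 cm/s.
#' @export
predict_peff <- function(psa, hbd, coef = peff_coefficients()) {
  if (psa < 0 || hbd < 0) stop_invalid("psa and hbd must be non-negative")
  10^(coef[["intercept"]] + coef[["psa"]] * psa + coef[["hbd"]] * hbd) / 1e-4
}

#' Unbound fraction in blood from plasma binding and blood partitioning
#'
#' @param fu_plasma Fraction unbound in plasma, (0, 1].
#' @param bp_ratio Blood-to-plasma concentration ratio, > 0.
#' @return Unbound fraction referenced to whole-blood concentration.
#' @export
fu_blood <- function(fu_plasma, bp_ratio) {
  assert_fraction(fu_plasma, "fu_plasma")
  assert_positive(bp_ratio, "bp_ratio")
  fu_plasma / bp_ratio
}

#' Construct and validate an enzyme pathway
#'
#' @param enzyme One of CYP3A4, CYP3A5, CES1, CES2.
#' @param organ "gut" or "liver".
#' @param vmax Maximum rate. Interpretation depends on \code{source}:
#'   pmol/min/mg microsomal protein (\code{"per_mg"}), pmol/min/pmol enzyme
#'   (\code{"per_pmol"}), or umol/h whole organ (\code{"organ"}).
#' @param km_u Unbound Michaelis constant, uM.
#' @param isef Intersystem extrapolation factor (CYP pathways only).
#' @param fu_inc Unbound fraction in the source incubation.
#' @param product Compound id receiving the metabolic flux, or
#'   \code{"oxidative_sink"} for CYP-mediated oxidation.
#' @param source Scaling basis of \code{vmax}, see above.
#' @return A validated list of class \code{enzyme_pathway}.
#' @export
enzyme_pathway <- function(enzyme, organ, vmax, km_u, isef = 1, fu_inc = 1,
                           product = "oxidative_sink", source = "organ") {
  enzyme <- match.arg(enzyme, c("CYP3A4", "CYP3A5", "CES1", "CES2"))
  organ <- match.arg(organ, c("gut", "liver"))
  source <- match.arg(source, c("organ", "per_mg", "per_pmol"))
  if (vmax < 0) stop_invalid("vmax must be non-negative")
  assert_positive(km_u, "km_u")
  assert_fraction(fu_inc, "fu_inc")
  if (isef < 0) stop_invalid("isef must be non-negative")
  is_ces <- enzyme %in% c("CES1", "CES2")
  if (is_ces && isef != 1) stop_invalid("CES pathways must have isef = 1")
  structure(list(enzyme = enzyme, organ = organ, vmax = vmax, km_u = km_u,
                 isef = isef, fu_inc = fu_inc, product = product,
                 source = source, is_cyp = !is_ces),
            class = "enzyme_pathway")
}

#' Construct and validate the apical efflux transporter pathway
#'
#' @param jmax Whole-gut maximum transport rate, umol/h (distributed over
#'   segments by the physiology's abundance-weight vector).
#' @param km_um Michaelis constant, uM.
#' @return A validated list of class \code{transporter_pathway}.
#' @export
transporter_pathway <- function(jmax, km_um = 2.6) {
  if (jmax < 0) stop_invalid("jmax must be non-negative")
  assert_positive(km_um, "km_um")
  structure(list(transporter = "P-gp", location = "gut_apical",
                 jmax = jmax, km_um = km_um),
            class = "transporter_pathway")
}

#' Construct and validate binding parameters
#'
#' @param fu_plasma Fraction unbound in plasma.
#' @param bp_ratio Blood-to-plasma ratio.
#' @param fu_gut Unbound fraction in the enterocyte (default 1).
#' @return A validated list of class \code{binding_params}.
#' @export
binding_params <- function(fu_plasma, bp_ratio, fu_gut = 1) {
  assert_fraction(fu_plasma, "fu_plasma")
  assert_positive(bp_ratio, "bp_ratio")
  assert_fraction(fu_gut, "fu_gut")
  structure(list(fu_plasma = fu_plasma, bp_ratio = bp_ratio, fu_gut = fu_gut),
            class = "binding_params")
}
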