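# Intestinal absorption primitives: diffusion-layer dissolution,
# supersaturation-triggered precipitation, passive uptake, apical P-gp
# efflux, enterocyte metabolism. All rate functions are vectorized over
# segments; the engine assembles them into the full ODE right-hand side.

#' Dissolution rate coefficient (diffusion-layer / Wang-Flanagan form)
#'
#' Coefficient \eqn{k_d} such that the dissolution flux is
#' \eqn{k_d A^{2/3} (C_s - C)} in umol/h, for a monodisperse powder of
#' initial amount \code{amount0_umol}. Shrinking-sphere geometry makes the
#' flux scale with amount to the 2/3 power; halving the initial particle
#' radius doubles \eqn{k_d}.
#'
#' @param particle_radius_um Initial particle radius, um.
#' @param density_g_ml True density, g/mL.
#' @param mw_g_mol Molecular weight, g/mol.
#' @param amount0_umol Initial solid amount, umol.
#' @param diffusion_cm2_s Aqueous diffusion coefficient, cm^2/s.
#' @param thickness_um Diffusion boundary-layer thickness, um.
#' @return kd in umol^(1/3)/h/uM.
#' @export
dissolution_rate_coef <- function(particle_radius_um, density_g_ml, mw_g_mol,
                                  amount0_umol, diffusion_cm2_s = 5e-6,
                                  thickness_um = 30) {
  assert_positive(particle_radius_um, "particle_radius_um")
  assert_positive(density_g_ml, "density_g_ml")
  if (amount0_umol < 0) stop_invalid("amount0_umol must be non-negative")
  d_cm2_h <- diffusion_cm2_s * 3600
  r0_cm <- particle_radius_um * 1e-4
  h_cm <- thickness_um * 1e-4
  3 * d_cm2_h * 1e-9 * mw_g_mol * amount0_umol^(1 / 3) /
    (density_g_ml * h_cm * r0_cm)
}

#' Dissolution flux of a solid luminal pool
#'
#' @param solid_umol Solid amount (vectorized), umol.
#' @param conc_um Dissolved concentration, uM.
#' @param solubility_um Local solubility, uM.
#' @param kd Rate coefficient from \code{\link{dissolution_rate_coef}}.
#' @return Flux in umol/h, clamped at >= 0 (loss from solution is handled by
#'   the precipitation operation, never by reverse dissolution).
#' @export
dissolution_flux <- function(solid_umol, conc_um, solubility_um, kd) {
  if (any(solid_umol < -1e-9)) stop_invalid("negative solid amount")
  pmax(0, kd * pmax(solid_umol, 0)^(2 / 3) * (solubility_um - conc_um))
}

#' Smooth supersaturation trigger indicator
#'
#' Near-step function of the saturation ratio \code{conc/solubility} around
#' the critical supersaturation ratio; used as the forcing term of the
#' latched per-segment trigger state so the ODE right-hand side stays
#' continuous.
#'
#' @param conc_um Dissolved concentration, uM.
#' @param solubility_um Solubility, uM.
#' @param csr Critical supersaturation ratio.
#' @param sharpness Logistic steepness on the relative ratio scale.
#' @return Indicator in [0, 1].
#' @export
supersaturation_trigger <- function(conc_um, solubility_um, csr,
                                    sharpness = 200) {
  ratio <- conc_um / solubility_um
  stats::plogis(sharpness * (ratio / csr - 1))
}

#' Precipitation flux from a supersaturated luminal solution
#'
#' Zero until the segment's latched trigger has fired (saturation ratio
#' reached the critical supersaturation ratio at least once); thereafter
#' first-order in the excess dissolved concentration with rate \code{prc_h}
#' until the solution relaxes to its solubility.
#'
#' @param conc_um Dissolved concentration, uM (vectorized over segments).
#' @param solubility_um Solubility, uM.
#' @param prc_h Precipitation rate constant, 1/h.
#' @param volume_l Segment fluid volume, L.
#' @param latched Trigger state in [0, 1] (1 = fired).
#' @return Flux removed from solution, umol/h.
#' @export
precipitation_flux <- function(conc_um, solubility_um, prc_h, volume_l,
                               latched) {
  latched * prc_h * pmax(conc_um - solubility_um, 0) * volume_l
}

#' First-order absorption rate constant for a cylindrical gut segment
#'
#' \eqn{k_a = 2 P_{eff} / r} with unit conversion to 1/h.
#'
#' @param peff_1e4_cm_s Effective permeability, 1e-4 cm/s.
#' @param radius_cm Segment radius, cm.
#' @return ka in 1/h.
#' @export
absorption_rate_constant <- function(peff_1e4_cm_s, radius_cm) {
  if (any(peff_1e4_cm_s < 0)) stop_invalid("peff must be non-negative")
  if (any(radius_cm <= 0)) stop_invalid("radius must be positive")
  2 * peff_1e4_cm_s * 1e-4 * 3600 / radius_cm
}

#' Apical P-gp efflux flux for one or more segments
#'
#' Saturable efflux directed enterocyte -> lumen. Competitive inhibition
#' scales the Michaelis constant; the saturation plateau is unaffected.
#'
#' @param conc_u_um Unbound enterocyte concentration, uM (vectorized).
#' @param jmax_umol_h Whole-gut maximum transport rate, umol/h.
#' @param km_um Michaelis constant, uM.
#' @param weight Segmental abundance weight(s), summing to 1 over segments.
#' @param inhibition_factor Competitive factor >= 1 applied to Km.
#' @return Efflux flux per segment, umol/h.
#' @export
pgp_efflux <- function(conc_u_um, jmax_umol_h, km_um, weight = 1,
                       inhibition_factor = 1) {
  if (any(inhibition_factor < 1)) stop_invalid("inhibition_factor must be >= 1")
  cc <- pmax(conc_u_um, 0)
  weight * jmax_umol_h * cc / (km_um * inhibition_factor + cc)
}

#' Saturable enzymatic rate (Michaelis-Menten with activity and inhibition)
#'
#' @param conc_u_um Unbound substrate concentration, uM.
#' @param vmax_umol_h Local maximum rate, umol/h.
#' @param km_u_um Unbound Michaelis constant, uM.
#' @param activity Active enzyme fraction in [0, 1] (mechanism-based
#'   inactivation state; 1 = baseline).
#' @param km_factor Competitive inhibition factor >= 1 applied to Km.
#' @return Rate in umol/h.
#' @export
saturable_rate <- function(conc_u_um, vmax_umol_h, km_u_um, activity = 1,
                           km_factor = 1) {
  cc <- pmax(conc_u_um, 0)
  activity * vmax_umol_h * cc / (km_u_um * km_factor + cc)
}

#' Per-pathway enterocyte metabolic rates across gut segments
#'
#' Distributes each pathway's whole-gut Vmax over segments by the relevant
#' abundance fractions (CYP3A or CES), applies the mechanism-based activity
#' state and competitive Km scaling to CYP pathways (esterases are not
#' inhibited), and evaluates the saturable rate at the local unbound
#' enterocyte concentration.
#'
#' @param conc_u_um Unbound enterocyte concentration per segment, uM.
#' @param pathways List of gut \code{\link{enzyme_pathway}} objects with
#'   organ-level Vmax (umol/h).
#' @param cyp_frac,ces_frac Segmental abundance fractions.
#' @param cyp_activity Active CYP3A fraction in [0, 1].
#' @param cyp_km_factor Competitive factor >= 1 on CYP3A Km.
#' @return Matrix [n_pathways x n_segments] of rates, umol/h, with pathway
#'   products as row names.
#' @export
enterocyte_metabolism <- function(conc_u_um, pathways, cyp_frac, ces_frac,
                                  cyp_activity = 1, cyp_km_factor = 1) {
  if (cyp_activity < 0 || cyp_activity > 1)
    stop_invalid("cyp_activity must be in [0, 1]")
  n <- length(conc_u_um)
  out <- matrix(0, nrow = length(pathways), ncol = n)
  rn <- character(length(pathways))
  for (i in seq_along(pathways)) {
    p <- pathways[[i]]
    frac <- if (p$is_cyp) cyp_frac else ces_frac
    act <- if (p$is_cyp) cyp_activity else 1
    kmf <- if (p$is_cyp) cyp_km_factor else 1
    out[i, ] <- saturable_rate(conc_u_um, p$vmax * frac, p$km_u, act, kmf)
    rn[i] <- p$product
  }
  rownames(out) <- rn
  out
}

#' Fraction absorbed and fraction escaping gut metabolism from a simulation
#'
#' For the dosed parent, \eqn{F_a} is the cumulative net apical transfer into
#' the enterocytes over the dose, and \eqn{F_g} the cumulative basolateral
#' transfer to the portal vein over the total enterocyte input (net apical +
#' in-situ formation). For a gut-formed metabolite \eqn{F_a} is not defined
#' (reported as 1) and \eqn{F_g} is basolateral transfer over amount formed.
#'
#' @param ledger Data frame of cumulative fluxes per compound (rows) with
#'   columns \code{abs_in}, \code{efflux}, \code{ent_formed}, \code{bl_out}.
#' @param dose_umol Named vector of administered doses, umol.
#' @return Data frame with columns \code{compound}, \code{fa}, \code{fg} and
#'   an \code{undefined} flag where nothing entered the enterocytes.
#' @export
first_pass_summary <- function(ledger, dose_umol) {
  res <- data.frame(compound = rownames(ledger), fa = NA_real_,
                    fg = NA_real_, undefined = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ledger))) {
    cid <- rownames(ledger)[i]
    net_apical <- ledger$abs_in[i] - ledger$efflux[i]
    input <- net_apical + ledger$ent_formed[i]
    dosed <- !is.na(dose_umol[cid]) && dose_umol[cid] > 0
    if (dosed) {
      res$fa[i] <- net_apical / dose_umol[cid]
    } else {
      res$fa[i] <- 1
    }
    if (input > 0) {
      res$fg[i] <- ledger$bl_out[i] / input
    } else {
      res$undefined[i] <- TRUE
    }
  }
  res
}
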