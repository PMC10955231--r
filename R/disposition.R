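# Systemic disposition primitives: well-stirred hepatic clearance, plasma
# esterase conversion, hepatic fraction accounting. The compartmental ODE
# blocks themselves are assembled in the engine.

#' Well-stirred hepatic clearance and hepatic availability
#'
#' @param qh_l_h Hepatic blood flow, L/h.
#' @param fu_b Unbound fraction in blood.
#' @param clint_u_l_h Unbound hepatic intrinsic clearance, L/h.
#' @return List with \code{clh} (L/h) and \code{fh} = 1 - CLh/Qh.
#' @export
well_stirred_clh <- function(qh_l_h, fu_b, clint_u_l_h) {
  assert_positive(qh_l_h, "qh_l_h")
  if (fu_b <= 0 || clint_u_l_h < 0)
    stop_invalid("fu_b must be positive and clint_u non-negative")
  clh <- qh_l_h * fu_b * clint_u_l_h / (qh_l_h + fu_b * clint_u_l_h)
  list(clh = clh, fh = 1 - clh / qh_l_h)
}

#' First-order plasma esterase conversion fluxes
#'
#' Concentration-independent hydrolysis in blood: flux = k * amount, applied
#' to the central and portal blood pools of compounds with a configured
#' plasma half-life. Returns per-compound loss fluxes; the engine credits
#' each product compartment with the matching gain.
#'
#' @param amounts_umol Named vector of blood-pool amounts, umol.
#' @param k_h Named vector of conversion rate constants, 1/h (0 for stable
#'   compounds).
#' @return Named vector of conversion fluxes, umol/h.
#' @export
plasma_conversion <- function(amounts_umol, k_h) {
  k_h[names(amounts_umol)] * amounts_umol
}

#' Whole-organ Vmax of a liver pathway, umol/h
#'
#' Applies the in vitro to in vivo scaling chain appropriate to the source
#' basis of the pathway's Vmax: microsomal protein yield for per-mg values,
#' enzyme abundance times ISEF for recombinant-sourced values, or none when
#' the Vmax is already organ-level.
#'
#' @param pathway An \code{\link{enzyme_pathway}} with organ "liver".
#' @param phys A \code{\link{default_physiology}} object.
#' @return Vmax in umol/h for the whole liver.
#' @export
liver_pathway_vmax <- function(pathway, phys) {
  stopifnot(inherits(pathway, "enzyme_pathway"), pathway$organ == "liver")
  pm_min <- switch(pathway$source,
    organ = return(pathway$vmax),
    per_mg = pathway$vmax * pathway$isef / pathway$fu_inc *
      phys$mppgl_mg_g * phys$liver_mass_g,
    per_pmol = pathway$vmax * pathway$isef / pathway$fu_inc *
      phys$liver_cyp3a4_pmol_mg * phys$mppgl_mg_g * phys$liver_mass_g)
  pm_min * 60 / 1e6  # pmol/min -> umol/h
}

#' Whole-gut Vmax of a gut pathway, umol/h
#'
#' Gut CYP pathways on a per-pmol basis scale by the total small-intestinal
#' CYP3A4 abundance and ISEF; organ-level values pass through.
#'
#' @param pathway An \code{\link{enzyme_pathway}} with organ "gut".
#' @param phys A \code{\link{default_physiology}} object.
#' @return Vmax in umol/h for the whole gut wall.
#' @export
gut_pathway_vmax <- function(pathway, phys) {
  stopifnot(inherits(pathway, "enzyme_pathway"), pathway$organ == "gut")
  if (pathway$source == "organ") return(pathway$vmax)
  if (pathway$source == "per_pmol")
    return(pathway$vmax * pathway$isef / pathway$fu_inc *
             phys$gut_cyp3a4_nmol * 1000 * 60 / 1e6)
  stop_invalid("per-mg scaling is not defined for the gut wall; ",
               "supply organ-level or per-pmol Vmax")
}

#' Fraction escaping hepatic extraction from cumulative flux accounting
#'
#' \eqn{F_h} = cumulative hepatic outflow to the systemic circulation over
#' cumulative hepatic input (portal + arterial inflow + in-liver formation).
#' With recirculation this equals one minus the average extraction over all
#' passes.
#'
#' @param ledger Data frame of cumulative fluxes per compound (rows) with
#'   columns \code{liver_in} and \code{liver_out}.
#' @return Data frame with \code{compound}, \code{fh}, \code{undefined}.
#' @export
fh_summary <- function(ledger) {
  res <- data.frame(compound = rownames(ledger), fh = NA_real_,
                    undefined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ledger))) {
    if (ledger$liver_in[i] > 0) {
      res$fh[i] <- ledger$liver_out[i] / ledger$liver_in[i]
    } else {
      res$undefined[i] <- TRUE
    }
  }
  res
}
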