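# System (drug-independent) parameters: gut segment geometry, transit,
# blood flows, enzyme abundances, hepatic scalars. Standard literature
# values; everything is overridable for degenerate test configurations.

#' Default human physiology for the gut and liver
#'
#' Nine luminal segments (stomach, duodenum, two jejunal, four ileal, colon)
#' in the style of multi-segment compartmental absorption-transit models.
#' The stomach neither absorbs nor metabolizes; colonic absorption is
#' disabled for the poorly soluble prodrug by default. Fractional CYP3A and
#' P-gp abundance vectors each sum to 1 over the seven absorptive
#' small-intestinal segments; small-intestinal transit times sum to 3.5 h.
#'
#' @param ... Named overrides for any constant (e.g. \code{qh_l_h = 80}) or
#'   \code{segments} to replace the whole segment table.
#' @return List of class \code{physiology} with a \code{segments} data frame
#'   and scalar constants (units in field names).
#' @export
default_physiology <- function(...) {
  segments <- data.frame(
    name = c("stomach", "duodenum", "jejunum_1", "jejunum_2",
             "ileum_1", "ileum_2", "ileum_3", "ileum_4", "colon"),
    radius_cm = c(10, 1.6, 1.4, 1.3, 1.2, 1.1, 1.0, 0.9, 2.5),
    fluid_volume_ml = c(250, 40, 40, 30, 25, 20, 15, 10, 15),
    transit_time_h = c(0.4, 0.26, 0.95, 0.76, 0.59, 0.43, 0.31, 0.20, 13.5),
    ph = c(1.5, 6.0, 6.2, 6.4, 6.6, 6.9, 7.2, 7.4, 6.8),
    enterocyte_volume_ml = c(0, 25, 60, 60, 50, 40, 35, 30, 0),
    villous_flow_frac = c(0, 0.12, 0.24, 0.20, 0.14, 0.11, 0.10, 0.09, 0),
    cyp3a_frac = c(0, 0.22, 0.28, 0.22, 0.12, 0.08, 0.05, 0.03, 0),
    ces2_frac = c(0, 0.22, 0.28, 0.22, 0.12, 0.08, 0.05, 0.03, 0),
    pgp_weight = c(0, 0.05, 0.10, 0.15, 0.17, 0.17, 0.18, 0.18, 0),
    absorptive = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  phys <- list(
    segments = segments,
    mppgl_mg_g = 40,               # microsomal protein per g liver
    hepatocellularity_1e6_g = 120, # 10^6 cells per g liver
    liver_mass_g = 1650,
    liver_volume_l = 1.65,
    portal_volume_l = 1.0,
    qh_l_h = 97,                   # total hepatic blood flow
    portal_flow_frac = 0.75,       # portal-vein share of hepatic flow
    villous_flow_l_h = 18,         # mucosal blood flow, whole small intestine
    gut_cyp3a4_nmol = 66,          # total small-intestinal CYP3A4
    liver_cyp3a4_pmol_mg = 137,    # hepatic CYP3A4 abundance
    kdeg_cyp3a_gut_h = 0.030,      # enterocyte CYP3A turnover
    kdeg_cyp3a_liver_h = 0.019,    # hepatic CYP3A turnover
    body_weight_kg = 75
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm == "segments") phys$segments <- ov[[nm]] else phys[[nm]] <- ov[[nm]]
  }
  validate_physiology(phys)
}

validate_physiology <- function(phys) {
  seg <- phys$segments
  need <- c("name", "radius_cm", "fluid_volume_ml", "transit_time_h",
            "enterocyte_volume_ml", "villous_flow_frac", "cyp3a_frac",
            "ces2_frac", "pgp_weight", "absorptive")
  miss <- setdiff(need, names(seg))
  if (length(miss))
    stop_invalid("physiology segments lack fields: ", paste(miss, collapse = ", "))
  if (any(seg$transit_time_h <= 0)) stop_invalid("transit times must be positive")
  ab <- seg$absorptive
  for (col in c("cyp3a_frac", "ces2_frac", "pgp_weight", "villous_flow_frac")) {
    s <- sum(seg[[col]][ab])
    if (abs(s - 1) > 1e-6)
      stop_invalid(col, " must sum to 1 over absorptive segments (got ", s, ")")
    if (any(seg[[col]][!ab] != 0))
      stop_invalid(col, " must be zero in non-absorptive segments")
  }
  structure(phys, class = "physiology")
}

#' Serial transit rate constant of a gut segment
#'
#' @param transit_time_h Mean transit (residence) time, h.
#' @return First-order transit rate constant, 1/h.
#' @export
transit_rate <- function(transit_time_h) {
  if (any(transit_time_h <= 0)) stop_invalid("transit_time_h must be positive")
  1 / transit_time_h
}
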