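# Perpetrator (inhibitor) models and interaction machinery: empirical
# one-compartment perpetrator kinetics with gut surrogates, competitive
# inhibition of CYP3A / P-gp, mechanism-based CYP3A inactivation with
# enzyme-turnover dynamics, and DDI outcome ratios.

#' Construct an inhibition term
#'
#' @param target "CYP3A" or "P-gp".
#' @param organ "gut", "liver" or "both" (P-gp is gut-only).
#' @param mechanism "competitive" or "mbi".
#' @param ki_u Unbound competitive inhibition constant, uM.
#' @param kinact Maximum inactivation rate, 1/h (mbi).
#' @param ki_app_u Unbound apparent inactivation constant, uM (mbi).
#' @return List of class \code{inhibition_term}.
#' @export
inhibition_term <- function(target, organ, mechanism, ki_u = NULL,
                            kinact = NULL, ki_app_u = NULL) {
  target <- match.arg(target, c("CYP3A", "P-gp"))
  organ <- match.arg(organ, c("gut", "liver", "both"))
  mechanism <- match.arg(mechanism, c("competitive", "mbi"))
  if (mechanism == "competitive") {
    if (is.null(ki_u) || !is.null(kinact) || !is.null(ki_app_u))
      stop_invalid("competitive terms carry ki_u only")
    assert_positive(ki_u, "ki_u")
  } else {
    if (is.null(kinact) || is.null(ki_app_u) || !is.null(ki_u))
      stop_invalid("mbi terms carry kinact and ki_app_u only")
    assert_positive(kinact, "kinact")
    assert_positive(ki_app_u, "ki_app_u")
    if (target != "CYP3A") stop_invalid("mbi is modeled for CYP3A only")
  }
  structure(list(target = target, organ = organ, mechanism = mechanism,
                 ki_u = ki_u, kinact = kinact, ki_app_u = ki_app_u),
            class = "inhibition_term")
}

#' Construct a perpetrator specification (empirical oral PK)
#'
#' One-compartment first-order-absorption kinetics with superposition over
#' the dosing regimen; gut exposure surrogates are derived from the
#' absorbable luminal amount. An optional circulating metabolite perpetrator
#' is modeled proportional to the parent concentration with its own
#' inhibition terms.
#'
#' @param id Identifier.
#' @param mw_g_mol Molecular weight, g/mol.
#' @param dose_mg Dose per administration.
#' @param n_doses Number of administrations.
#' @param interval_h Dosing interval, h.
#' @param start_h Time of the first dose on the simulation clock, h.
#' @param ka_h Absorption rate constant, 1/h.
#' @param v_f_l Apparent volume V/F, L.
#' @param cl_f_l_h Apparent clearance CL/F, L/h.
#' @param fu_plasma,bp_ratio Plasma binding and blood partitioning.
#' @param interactions List of \code{\link{inhibition_term}}.
#' @param metabolite Optional list \code{list(id, conc_ratio, interactions)}
#'   for a formed metabolite perpetrator.
#' @return List of class \code{perpetrator_spec}.
#' @export
perpetrator_spec <- function(id, mw_g_mol, dose_mg, n_doses = 1,
                             interval_h = 24, start_h = 0,
                             ka_h, v_f_l, cl_f_l_h, fu_plasma, bp_ratio = 1,
                             interactions = list(), metabolite = NULL) {
  assert_positive(mw_g_mol, "mw_g_mol")
  assert_positive(dose_mg, "dose_mg")
  assert_positive(ka_h, "ka_h")
  assert_positive(v_f_l, "v_f_l")
  assert_positive(cl_f_l_h, "cl_f_l_h")
  assert_fraction(fu_plasma, "fu_plasma")
  if (start_h < 0) stop_invalid("regimen times must be non-negative")
  for (tm in interactions) stopifnot(inherits(tm, "inhibition_term"))
  structure(list(id = id, mw_g_mol = mw_g_mol, dose_mg = dose_mg,
                 n_doses = n_doses, interval_h = interval_h, start_h = start_h,
                 ka_h = ka_h, v_f_l = v_f_l, cl_f_l_h = cl_f_l_h,
                 fu_plasma = fu_plasma, bp_ratio = bp_ratio,
                 interactions = interactions, metabolite = metabolite),
            class = "perpetrator_spec")
}

#' Unbound perpetrator exposure at the interaction sites
#'
#' Deterministic closed-form concentration surrogates (vectorized over
#' \code{t}): systemic plasma concentration by superposition of
#' one-compartment oral doses; luminal concentration from the remaining
#' absorbable amount over the small-intestinal fluid volume; enterocyte
#' concentration from the perpetrator's own absorption flux over the villous
#' blood flow; hepatic inlet as systemic plus the absorption flux over the
#' portal blood flow.
#'
#' @param spec \code{\link{perpetrator_spec}}.
#' @param t Time(s) on the simulation clock, h.
#' @param phys A \code{\link{default_physiology}} object.
#' @return List of numeric vectors (uM): \code{sys_u}, \code{portal_u},
#'   \code{lumen}, \code{ent} (gut surrogates are total concentrations; the
#'   inhibition constants acting on them are apparent values).
#' @export
perpetrator_exposure <- function(spec, t, phys) {
  dose_umol <- spec$dose_mg * 1000 / spec$mw_g_mol
  tds <- spec$start_h + (seq_len(spec$n_doses) - 1) * spec$interval_h
  ke <- spec$cl_f_l_h / spec$v_f_l
  ka <- spec$ka_h
  c_sys <- numeric(length(t))
  a_lum <- numeric(length(t))
  for (td in tds) {
    dt <- t - td
    on <- dt > 0
    if (!any(on)) next
    dtp <- dt[on]
    if (abs(ka - ke) < 1e-8) ka <- ka * (1 + 1e-6)
    c_sys[on] <- c_sys[on] + dose_umol / spec$v_f_l * ka / (ka - ke) *
      (exp(-ke * dtp) - exp(-ka * dtp))
    a_lum[on] <- a_lum[on] + dose_umol * exp(-ka * dtp)
  }
  v_lum <- sum(phys$segments$fluid_volume_ml[phys$segments$absorptive]) / 1000
  q_pv <- phys$qh_l_h * phys$portal_flow_frac
  list(sys_u = spec$fu_plasma * c_sys,
       portal_u = spec$fu_plasma * (c_sys + ka * a_lum / q_pv),
       lumen = a_lum / v_lum,
       ent = ka * a_lum / phys$villous_flow_l_h)
}

#' Competitive inhibition factor on a Michaelis constant
#'
#' \eqn{1 + \sum_i I_{u,i}/K_{i,u,i}} over co-present inhibitors (parent
#' plus metabolite).
#'
#' @param i_u Unbound inhibitor concentration(s), uM.
#' @param ki_u Matching inhibition constant(s), uM.
#' @return Multiplier >= 1.
#' @export
competitive_factor <- function(i_u, ki_u) {
  if (any(i_u < 0)) stop_invalid("inhibitor concentrations must be >= 0")
  1 + sum(i_u / ki_u)
}

#' Enzyme-activity turnover under mechanism-based inactivation
#'
#' \eqn{de/dt = k_{deg}(1 - e) - e\, k_{inact} I_u / (K_{I,u} + I_u)}:
#' synthesis restores the active fraction toward 1 while inactivation
#' removes it in proportion to inhibitor occupancy.
#'
#' @param e Active enzyme fraction in [0, 1].
#' @param i_u Unbound inhibitor concentration, uM.
#' @param kinact Maximum inactivation rate, 1/h.
#' @param ki_app_u Apparent unbound inactivation constant, uM.
#' @param kdeg Enzyme degradation (turnover) rate, 1/h.
#' @return de/dt, 1/h.
#' @export
mbi_rhs <- function(e, i_u, kinact, ki_app_u, kdeg) {
  kdeg * (1 - e) - e * kinact * i_u / (ki_app_u + i_u)
}

#' Steady-state active enzyme fraction under constant inhibitor exposure
#'
#' Closed form of \code{\link{mbi_rhs}} at de/dt = 0.
#' @inheritParams mbi_rhs
#' @return e* in (0, 1].
#' @export
mbi_steady_state <- function(i_u, kinact, ki_app_u, kdeg) {
  kdeg / (kdeg + kinact * i_u / (ki_app_u + i_u))
}

#' The calibrated perpetrator set
#'
#' Empirical one-compartment oral models with population-mean flavored PK
#' constants; interaction mechanisms: clarithromycin (CTC) = mechanism-based
#' CYP3A inactivation (gut + liver) plus competitive P-gp; itraconazole
#' (ITZ, with hydroxy-itraconazole as a formed metabolite perpetrator) =
#' competitive CYP3A plus competitive P-gp (Ki 2 and 5 uM); verapamil (VP) =
#' mechanism-based CYP3A plus potent competitive P-gp; single-dose rifampin
#' (RF) = competitive P-gp plus weak competitive CYP3A (no induction on a
#' single dose). All constants not printed in the source tables are
#' calibrated stand-ins.
#'
#' @return Named list of \code{\link{perpetrator_spec}} objects.
#' @export
default_perpetrators <- function() {
  ctc <- perpetrator_spec(
    id = "CTC", mw_g_mol = 747.95,
    dose_mg = 500, n_doses = 10, interval_h = 12, start_h = 0,
    ka_h = 0.5, v_f_l = 250, cl_f_l_h = 40, fu_plasma = 0.3,
    interactions = list(
      inhibition_term("CYP3A", "both", "mbi", kinact = 2.0, ki_app_u = 15), # calibrated
      inhibition_term("CYP3A", "both", "competitive", ki_u = 16),
      inhibition_term("P-gp", "gut", "competitive", ki_u = 35)
    ))
  itz <- perpetrator_spec(
    id = "ITZ", mw_g_mol = 705.63,
    dose_mg = 200, n_doses = 5, interval_h = 24, start_h = 0,
    ka_h = 0.4, v_f_l = 700, cl_f_l_h = 22, fu_plasma = 0.036,
    interactions = list(
      inhibition_term("CYP3A", "both", "competitive", ki_u = 0.04),  # calibrated
      inhibition_term("P-gp", "gut", "competitive", ki_u = 2)  # printed value
    ),
    metabolite = list(
      id = "OH-ITZ", conc_ratio = 1.0,
      interactions = list(
        inhibition_term("CYP3A", "both", "competitive", ki_u = 0.08),  # calibrated
        inhibition_term("P-gp", "gut", "competitive", ki_u = 5)  # printed value
      )))
  vp <- perpetrator_spec(
    id = "VP", mw_g_mol = 454.60,
    dose_mg = 120, n_doses = 1, start_h = 0,
    ka_h = 1.5, v_f_l = 300, cl_f_l_h = 50, fu_plasma = 0.1, bp_ratio = 0.84,
    interactions = list(
      inhibition_term("CYP3A", "both", "mbi", kinact = 3.0, ki_app_u = 3),  # calibrated
      inhibition_term("P-gp", "gut", "competitive", ki_u = 0.1)
    ))
  rf <- perpetrator_spec(
    id = "RF", mw_g_mol = 822.94,
    dose_mg = 600, n_doses = 1, start_h = 0,
    ka_h = 1.0, v_f_l = 60, cl_f_l_h = 12, fu_plasma = 0.2,
    interactions = list(
      inhibition_term("P-gp", "gut", "competitive", ki_u = 1.5),
      inhibition_term("CYP3A", "both", "competitive", ki_u = 6)   # calibrated
    ))
  list(CTC = ctc, ITZ = itz, VP = vp, RF = rf)
}

#' DDI outcome ratios between an inhibited and a control simulation
#'
#' Substrate-aligned noncompartmental ratios for the active metabolite plus
#' the first-pass dissection ratios \eqn{F_a'/F_a}, \eqn{F_g'/F_g} (per
#' compound) and \eqn{F_h'/F_h}.
#'
#' @param control,inhibited \code{pbpk_sim} results with the same substrate
#'   regimen.
#' @param compound Compound whose exposure ratios are reported.
#' @return List with \code{cmax_ratio}, \code{auc_ratio} and a data frame
#'   \code{first_pass} of per-compound ratio columns.
#' @export
ddi_outcome <- function(control, inhibited, compound = "DAB") {
  same <- isTRUE(all.equal(control$substrate$id, inhibited$substrate$id)) &&
    isTRUE(all.equal(control$substrate$dose_mg, inhibited$substrate$dose_mg)) &&
    identical(control$substrate$formulation, inhibited$substrate$formulation) &&
    length(control$substrate$dose_times_h) == length(inhibited$substrate$dose_times_h)
  if (!same)
    stop_invalid("control and inhibited runs have different substrate regimens")
  pc <- substrate_profile(control, compound)
  pi <- substrate_profile(inhibited, compound)
  nc <- nca(pc$time, pc$conc)
  ni <- nca(pi$time, pi$conc)
  fp <- merge(control$summary, inhibited$summary, by = "compound",
              suffixes = c("", "_i"), sort = FALSE)
  out <- data.frame(compound = fp$compound,
                    fa_ratio = fp$fa_i / fp$fa,
                    fg_ratio = fp$fg_i / fp$fg,
                    fh_ratio = fp$fh_i / fp$fh)
  list(cmax_ratio = ni$cmax / nc$cmax,
       auc_ratio = ni$auc_0_inf / nc$auc_0_inf,
       nca_control = nc, nca_inhibited = ni, first_pass = out)
}
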