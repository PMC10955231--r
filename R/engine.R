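# Model assembly and integration. The state vector is laid out as:
# substrate luminal pools (solid, dissolved, precipitated, trigger latch;
# 9 segments), enterocyte amounts (7 absorptive segments x gut-present
# compounds), systemic compartments (portal, liver, central, peripheral x
# compounds), CYP3A activity states (gut, liver), then cumulative flux
# accumulators per compound. Amounts are umol, time is h, volumes L.
# The right-hand side works on integer indices precomputed at build time.

ACC_NAMES <- c("abs_in", "efflux", "ent_formed", "bl_out", "gut_sink",
               "fecal", "liver_in", "liver_out", "liver_formed",
               "liver_ces", "liver_sink", "bile", "renal", "other",
               "plconv_out")

#' Construct a simulation scenario
#'
#' @param dose_mg Substrate dose per administration, mg.
#' @param formulation "solution" (dosed into the gastric dissolved pool,
#'   precipitation enabled) or "solid" (immediate-release solid dosed into
#'   the gastric solid pool).
#' @param dose_times_h Substrate administration times on the simulation
#'   clock, h.
#' @param substrate Compound id of the dosed species.
#' @param perpetrators Character vector of built-in perpetrator ids (see
#'   \code{\link{default_perpetrators}}) and/or a list of
#'   \code{\link{perpetrator_spec}} objects.
#' @param horizon_h Simulation horizon, h.
#' @param dt_out_h Output grid spacing, h.
#' @param dose_segment Luminal segment receiving the dose (default stomach).
#' @param rtol,atol Solver tolerances.
#' @return List of class \code{scenario_spec}.
#' @export
scenario_spec <- function(dose_mg, formulation = c("solution", "solid"),
                          dose_times_h = 0, substrate = "DABE",
                          perpetrators = NULL, horizon_h = NULL,
                          dt_out_h = 0.25, dose_segment = "stomach",
                          rtol = 1e-7, atol = 1e-10) {
  formulation <- match.arg(formulation)
  assert_positive(dose_mg, "dose_mg")
  if (any(dose_times_h < 0)) stop_invalid("dose times must be non-negative")
  if (is.null(horizon_h)) horizon_h <- max(dose_times_h) + 36
  structure(list(dose_mg = dose_mg, formulation = formulation,
                 dose_times_h = sort(dose_times_h), substrate = substrate,
                 perpetrators = perpetrators, horizon_h = horizon_h,
                 dt_out_h = dt_out_h, dose_segment = dose_segment,
                 rtol = rtol, atol = atol),
            class = "scenario_spec")
}

resolve_perpetrators <- function(perpetrators) {
  if (is.null(perpetrators)) return(list())
  builtin <- NULL
  out <- list()
  for (p in perpetrators) {
    if (is.character(p)) {
      if (is.null(builtin)) builtin <- default_perpetrators()
      if (!p %in% names(builtin)) stop_invalid("unknown perpetrator id: ", p)
      out[[length(out) + 1L]] <- builtin[[p]]
    } else if (inherits(p, "perpetrator_spec")) {
      out[[length(out) + 1L]] <- p
    } else stop_invalid("perpetrators must be ids or perpetrator_spec objects")
  }
  out
}

# Detect cycles in the compound conversion graph (gut, liver, plasma edges).
check_routing <- function(compounds) {
  ids <- names(compounds)
  edges <- list()
  for (cid in ids) {
    cp <- compounds[[cid]]
    prods <- c(vapply(cp$gut_pathways, `[[`, "", "product"),
               vapply(cp$liver_pathways, `[[`, "", "product"))
    if (!is.na(cp$plasma_product)) prods <- c(prods, cp$plasma_product)
    prods <- setdiff(unique(prods), "oxidative_sink")
    bad <- setdiff(prods, ids)
    if (length(bad))
      stop_invalid("compound ", cid, " routes to unresolved product(s): ",
                   paste(bad, collapse = ", "))
    edges[[cid]] <- prods
  }
  state <- setNames(rep(0L, length(ids)), ids)  # 0 unseen, 1 active, 2 done
  visit <- function(v) {
    if (state[v] == 1L) stop_invalid("routing cycle detected at compound ", v)
    if (state[v] == 2L) return(invisible())
    state[v] <<- 1L
    for (w in edges[[v]]) visit(w)
    state[v] <<- 2L
  }
  for (v in ids) visit(v)
  invisible(TRUE)
}

#' Assemble compounds, physiology and a scenario into an ODE model
#'
#' Validates the conversion cascade (no cycles, all products resolve),
#' precomputes segmental rate constants and whole-organ pathway capacities,
#' and builds the indexed state map and right-hand-side function.
#'
#' @param compounds Named list of \code{\link{compound_spec}} objects; the
#'   dosed substrate must be among them.
#' @param phys A \code{\link{default_physiology}} object.
#' @param scenario A \code{\link{scenario_spec}}.
#' @return List of class \code{pbpk_model}.
#' @export
build_model <- function(compounds, phys, scenario) {
  stopifnot(inherits(phys, "physiology"), inherits(scenario, "scenario_spec"))
  check_routing(compounds)
  ids <- names(compounds)
  nC <- length(ids)
  sub_id <- scenario$substrate
  if (!sub_id %in% ids) stop_invalid("substrate ", sub_id, " not in compound set")

  seg <- phys$segments
  ab <- which(seg$absorptive)
  nseg <- nrow(seg)
  nab <- length(ab)
  sub <- compounds[[sub_id]]

  # enterocyte-present compounds: the substrate plus every gut metabolic product
  ent_ids <- sub_id
  for (cid in ids) {
    prods <- vapply(compounds[[cid]]$gut_pathways, `[[`, "", "product")
    ent_ids <- union(ent_ids, setdiff(prods, "oxidative_sink"))
  }
  ent_ids <- ids[ids %in% ent_ids]  # keep cascade order
  nE <- length(ent_ids)
  ent_pos <- match(ent_ids, ids)

  # ---- state index map ----
  seg_lab <- seg$name
  nm <- c(paste0("sol.", seg_lab), paste0("dis.", seg_lab),
          paste0("prc.", seg_lab), paste0("lat.", seg_lab))
  for (cid in ent_ids) nm <- c(nm, paste0("ent.", cid, ".", seg_lab[ab]))
  for (cid in ids) nm <- c(nm, paste0(c("pv.", "li.", "ce.", "pe."), cid))
  nm <- c(nm, "e_gut", "e_liver")
  for (cid in ids) nm <- c(nm, paste0("acc.", cid, ".", ACC_NAMES))
  ix <- setNames(seq_along(nm), nm)
  iget <- function(keys) as.integer(unname(ix[keys]))

  i_sol <- iget(paste0("sol.", seg_lab))
  i_dis <- iget(paste0("dis.", seg_lab))
  i_prc <- iget(paste0("prc.", seg_lab))
  i_lat <- iget(paste0("lat.", seg_lab))
  i_ent <- lapply(ent_ids, function(cid) iget(paste0("ent.", cid, ".", seg_lab[ab])))
  names(i_ent) <- ent_ids
  i_sys <- lapply(ids, function(cid) iget(paste0(c("pv.", "li.", "ce.", "pe."), cid)))
  names(i_sys) <- ids
  i_pv <- vapply(i_sys, `[`, 0L, 1L); i_li <- vapply(i_sys, `[`, 0L, 2L)
  i_ce <- vapply(i_sys, `[`, 0L, 3L); i_pe <- vapply(i_sys, `[`, 0L, 4L)
  i_eg <- ix[["e_gut"]]; i_el <- ix[["e_liver"]]
  i_acc <- lapply(ids, function(cid) setNames(iget(paste0("acc.", cid, ".", ACC_NAMES)), ACC_NAMES))
  names(i_acc) <- ids
  i_acc_m <- vapply(i_acc, identity, integer(length(ACC_NAMES)))  # [acc x compound]
  rownames(i_acc_m) <- ACC_NAMES

  # ---- precomputed physiology ----
  kt <- transit_rate(seg$transit_time_h)
  v_lum <- seg$fluid_volume_ml / 1000
  v_ent <- seg$enterocyte_volume_ml[ab] / 1000
  q_villi <- phys$villous_flow_l_h * seg$villous_flow_frac[ab]
  cyp_frac <- seg$cyp3a_frac[ab]
  ces_frac <- seg$ces2_frac[ab]
  pgp_w <- seg$pgp_weight[ab]
  qh <- phys$qh_l_h
  qpv <- qh * phys$portal_flow_frac
  qha <- qh - qpv
  vpv <- phys$portal_volume_l
  vli <- phys$liver_volume_l
  bw <- phys$body_weight_kg
  kdeg_g <- phys$kdeg_cyp3a_gut_h; kdeg_l <- phys$kdeg_cyp3a_liver_h

  # ---- per-compound numeric precomputation (integer-indexed) ----
  fu_b <- vc <- vp <- qq <- k_pl <- renal <- other <- bile <- numeric(nC)
  pl_tgt <- integer(nC)
  fu_gut <- bp <- mw <- numeric(nC)
  for (j in seq_len(nC)) {
    cp <- compounds[[j]]
    fu_b[j] <- fu_blood(cp$binding$fu_plasma, cp$binding$bp_ratio)
    fu_gut[j] <- cp$binding$fu_gut
    bp[j] <- cp$binding$bp_ratio
    mw[j] <- cp$mw_g_mol
    vc[j] <- cp$vss_l_kg * bw * cp$central_fraction
    vp[j] <- cp$vss_l_kg * bw * (1 - cp$central_fraction)
    qq[j] <- cp$q_l_h
    k_pl[j] <- if (is.na(cp$plasma_t_half_min)) 0 else halflife_to_rate(cp$plasma_t_half_min)
    pl_tgt[j] <- if (is.na(cp$plasma_product)) 0L else match(cp$plasma_product, ids)
    renal[j] <- cp$renal_cl_u_l_h
    other[j] <- cp$other_cl_u_l_h
    bile[j] <- scale_clint_bile(cp$bile_clint_ul_min_1e6,
                                phys$hepatocellularity_1e6_g,
                                phys$liver_mass_g)
  }
  # liver pathways flattened: owner, vmax, km, cyp flag, product index (0 sink)
  lp_owner <- integer(0); lp_vmax <- lp_km <- numeric(0)
  lp_cyp <- logical(0); lp_tgt <- integer(0)
  for (j in seq_len(nC)) {
    for (p in compounds[[j]]$liver_pathways) {
      lp_owner <- c(lp_owner, j)
      lp_vmax <- c(lp_vmax, liver_pathway_vmax(p, phys))
      lp_km <- c(lp_km, p$km_u)
      lp_cyp <- c(lp_cyp, p$is_cyp)
      lp_tgt <- c(lp_tgt, if (p$product == "oxidative_sink") 0L else match(p$product, ids))
    }
  }
  # gut pathways per enterocyte compound: segmental Vmax rows precomputed
  gp <- vector("list", nE)
  kbl <- vector("list", nE)
  for (e in seq_len(nE)) {
    j <- ent_pos[e]
    cp <- compounds[[j]]
    pws <- cp$gut_pathways
    vs <- matrix(0, nrow = length(pws), ncol = nab)
    km <- numeric(length(pws)); cyp <- logical(length(pws)); tgt <- integer(length(pws))
    for (k in seq_along(pws)) {
      p <- pws[[k]]
      vmax_org <- gut_pathway_vmax(p, phys)
      vs[k, ] <- vmax_org * (if (p$is_cyp) cyp_frac else ces_frac)
      km[k] <- p$km_u; cyp[k] <- p$is_cyp
      tgt[k] <- if (p$product == "oxidative_sink") 0L else match(p$product, ent_ids)
    }
    gp[[e]] <- list(vs = vs, km = km, cyp = cyp, tgt = tgt, npw = length(pws))
    kbl[[e]] <- q_villi * cp$binding$fu_gut * cp$bl_scalar / v_ent
  }
  has_pgp <- !is.null(sub$pgp)
  pgp_jmax <- if (has_pgp) sub$pgp$jmax else 0
  pgp_km <- if (has_pgp) sub$pgp$km_um else 1
  e_sub <- match(sub_id, ent_ids)

  # substrate luminal constants
  dose_umol <- scenario$dose_mg * 1000 / sub$mw_g_mol
  sol_int <- sub$solubility_mg_ml / sub$mw_g_mol * 1e6      # uM
  sol_gas <- sub$solubility_stomach_mg_ml / sub$mw_g_mol * 1e6
  if (is.na(sol_int)) sol_int <- Inf
  if (is.na(sol_gas)) sol_gas <- sol_int
  sol_seg <- c(sol_gas, rep(sol_int, nseg - 1))
  kd <- if (scenario$formulation == "solid")
    dissolution_rate_coef(sub$particle_radius_um, sub$density_g_ml,
                          sub$mw_g_mol, dose_umol) else 0
  ka_sub <- absorption_rate_constant(sub$peff_1e4_cm_s, seg$radius_cm[ab])
  csr <- sub$csr; prc <- sub$prc_h
  finite_sol <- is.finite(sol_int)

  perps <- resolve_perpetrators(scenario$perpetrators)
  nP <- length(perps)
  # flattened inhibition-term tables (numeric, integer perp index)
  tb <- list(mbi_g = NULL, mbi_l = NULL, cg = NULL, cl = NULL, pg = NULL)
  if (nP) {
    add <- function(tab, rec) rbind(tab, rec)
    for (k in seq_len(nP)) {
      sp <- perps[[k]]
      sets <- list(list(terms = sp$interactions, ratio = 1))
      if (!is.null(sp$metabolite))
        sets <- c(sets, list(list(terms = sp$metabolite$interactions,
                                  ratio = sp$metabolite$conc_ratio)))
      for (s in sets) for (tm in s$terms) {
        if (tm$mechanism == "mbi") {
          rec <- c(k, s$ratio, tm$kinact, tm$ki_app_u)
          if (tm$organ %in% c("gut", "both")) tb$mbi_g <- add(tb$mbi_g, rec)
          if (tm$organ %in% c("liver", "both")) tb$mbi_l <- add(tb$mbi_l, rec)
        } else if (tm$target == "P-gp") {
          tb$pg <- add(tb$pg, c(k, s$ratio, tm$ki_u))
        } else {
          rec <- c(k, s$ratio, tm$ki_u)
          if (tm$organ %in% c("gut", "both")) tb$cg <- add(tb$cg, rec)
          if (tm$organ %in% c("liver", "both")) tb$cl <- add(tb$cl, rec)
        }
      }
    }
  }
  perp_fu <- vapply(perps, `[[`, 0, "fu_plasma")

  n <- length(nm)
  colon <- nseg
  zero_ab <- numeric(nab)
  inv_vp <- ifelse(vp > 0, 1 / vp, 0)
  z0 <- function(x) { x[x < 0] <- 0; x }

  rhs <- function(t, y, parms) {
    names(y) <- NULL
    dy <- numeric(n)

    # ---- perpetrator exposures and inhibition factors ----
    if_cg <- if_cl_ <- if_pg <- 1
    inact_g <- inact_l <- 0
    if (nP) {
      ent_u <- portal_u <- gut_tot <- numeric(nP)
      for (k in seq_len(nP)) {
        e <- perpetrator_exposure(perps[[k]], t, phys)
        ent_u[k] <- perp_fu[k] * e$ent
        portal_u[k] <- e$portal_u
        gut_tot[k] <- e$lumen + e$ent
      }
      if (!is.null(tb$cg))
        if_cg <- 1 + sum(tb$cg[, 2] * ent_u[tb$cg[, 1]] / tb$cg[, 3])
      if (!is.null(tb$cl))
        if_cl_ <- 1 + sum(tb$cl[, 2] * portal_u[tb$cl[, 1]] / tb$cl[, 3])
      if (!is.null(tb$pg))
        if_pg <- 1 + sum(tb$pg[, 2] * gut_tot[tb$pg[, 1]] / tb$pg[, 3])
      if (!is.null(tb$mbi_g)) {
        iu <- tb$mbi_g[, 2] * ent_u[tb$mbi_g[, 1]]
        inact_g <- sum(tb$mbi_g[, 3] * iu / (tb$mbi_g[, 4] + iu))
      }
      if (!is.null(tb$mbi_l)) {
        iu <- tb$mbi_l[, 2] * portal_u[tb$mbi_l[, 1]]
        inact_l <- sum(tb$mbi_l[, 3] * iu / (tb$mbi_l[, 4] + iu))
      }
    }
    e_g <- min(max(y[i_eg], 0), 1); e_l <- min(max(y[i_el], 0), 1)
    dy[i_eg] <- kdeg_g * (1 - e_g) - e_g * inact_g
    dy[i_el] <- kdeg_l * (1 - e_l) - e_l * inact_l

    # ---- substrate lumen ----
    solid <- z0(y[i_sol]); diss <- z0(y[i_dis])
    conc <- diss / v_lum
    fdis <- if (kd > 0) kd * solid^(2 / 3) * z0(sol_seg - conc) else 0
    if (finite_sol) {
      lat <- y[i_lat]; lat[lat < 0] <- 0; lat[lat > 1] <- 1
      trig <- stats::plogis(40 * (conc / (sol_seg * csr) - 1))
      trig[trig < 1e-12] <- 0  # exact zero far below the threshold
      trig[1] <- 0
      dy[i_lat] <- 30 * trig * (1 - lat)
      fprec <- lat * prc * z0(conc - sol_seg) * v_lum
      fprec[1] <- 0
    } else fprec <- 0
    out_s <- kt * solid; out_d <- kt * diss
    abs_f <- ka_sub * diss[ab]
    d_sol <- c(0, out_s[-nseg]) - out_s - fdis
    d_dis <- c(0, out_d[-nseg]) - out_d + fdis - fprec
    d_dis[ab] <- d_dis[ab] - abs_f
    dy[i_prc] <- fprec
    acc_s <- i_acc_m[, match(sub_id, ids)]
    dy[acc_s[6L]] <- out_s[colon] + out_d[colon]   # fecal
    dy[acc_s[1L]] <- sum(abs_f)                    # abs_in

    # ---- enterocytes (cascade order) ----
    form <- matrix(0, nrow = nE, ncol = nab)
    bl_sum <- numeric(nC)
    for (e in seq_len(nE)) {
      j <- ent_pos[e]
      a_ent <- z0(y[i_ent[[e]]])
      cu <- fu_gut[j] * a_ent / v_ent
      g <- gp[[e]]
      met_tot <- zero_ab; sink <- 0
      if (g$npw) for (k in seq_len(g$npw)) {
        act <- if (g$cyp[k]) e_g else 1
        kmf <- if (g$cyp[k]) if_cg else 1
        v <- act * g$vs[k, ] * cu / (g$km[k] * kmf + cu)
        met_tot <- met_tot + v
        if (g$tgt[k] == 0L) sink <- sink + sum(v)
        else form[g$tgt[k], ] <- form[g$tgt[k], ] + v
      }
      eff <- if (e == e_sub && has_pgp)
        pgp_w * pgp_jmax * cu / (pgp_km * if_pg + cu) else zero_ab
      blout <- kbl[[e]] * a_ent
      influx <- if (e == e_sub) abs_f else zero_ab
      dy[i_ent[[e]]] <- influx + form[e, ] - eff - met_tot - blout
      if (e == e_sub) d_dis[ab] <- d_dis[ab] + eff
      bl_sum[j] <- sum(blout)
      acc <- i_acc_m[, j]
      dy[acc[2L]] <- sum(eff)        # efflux
      dy[acc[3L]] <- sum(form[e, ])  # ent_formed
      dy[acc[4L]] <- sum(blout)      # bl_out
      dy[acc[5L]] <- sink            # gut_sink
    }
    dy[i_sol] <- d_sol
    dy[i_dis] <- d_dis

    # ---- systemic (cascade order so conversions feed forward) ----
    apv <- y[i_pv]; ali <- y[i_li]; ac <- y[i_ce]; ap <- y[i_pe]
    cpv <- apv / vpv; cli <- ali / vli; cc <- ac / vc
    cp_ <- ap * inv_vp
    cu_li <- fu_b * z0(cli)
    liver_form <- pv_gain <- ce_gain <- numeric(nC)
    el_tot <- ces_out <- sink_out <- numeric(nC)
    if (length(lp_owner)) for (k in seq_along(lp_owner)) {
      j <- lp_owner[k]
      act <- if (lp_cyp[k]) e_l else 1
      kmf <- if (lp_cyp[k]) if_cl_ else 1
      v <- act * lp_vmax[k] * cu_li[j] / (lp_km[k] * kmf + cu_li[j])
      el_tot[j] <- el_tot[j] + v
      if (lp_tgt[k] == 0L) sink_out[j] <- sink_out[j] + v
      else { liver_form[lp_tgt[k]] <- liver_form[lp_tgt[k]] + v; ces_out[j] <- ces_out[j] + v }
    }
    bile_f <- bile * cu_li
    conv_pv <- k_pl * z0(apv)
    conv_ce <- k_pl * z0(ac)
    for (j in seq_len(nC)) if (pl_tgt[j] > 0L) {
      pv_gain[pl_tgt[j]] <- pv_gain[pl_tgt[j]] + conv_pv[j]
      ce_gain[pl_tgt[j]] <- ce_gain[pl_tgt[j]] + conv_ce[j]
    }
    liv_in <- qpv * cpv + qha * cc + liver_form
    ccl <- z0(cc)
    dy[i_pv] <- qpv * cc - qpv * cpv + bl_sum - conv_pv + pv_gain
    dy[i_li] <- liv_in - qh * cli - el_tot - bile_f
    dy[i_ce] <- qh * cli - qh * cc - qq * (cc - cp_) -
      (renal + other) * fu_b * ccl - conv_ce + ce_gain
    dy[i_pe] <- qq * (cc - cp_)
    # ledger rates use clamped concentrations so the cumulative flux
    # accumulators stay monotone through tolerance-scale negative excursions
    dy[i_acc_m[7L, ]] <- qpv * z0(cpv) + qha * ccl + liver_form  # liver_in
    dy[i_acc_m[8L, ]] <- qh * z0(cli)      # liver_out
    dy[i_acc_m[9L, ]] <- liver_form        # liver_formed
    dy[i_acc_m[10L, ]] <- ces_out          # liver_ces
    dy[i_acc_m[11L, ]] <- sink_out         # liver_sink
    dy[i_acc_m[12L, ]] <- bile_f           # bile
    dy[i_acc_m[13L, ]] <- renal * fu_b * ccl
    dy[i_acc_m[14L, ]] <- other * fu_b * ccl
    dy[i_acc_m[15L, ]] <- conv_pv + conv_ce
    list(dy)
  }

  y0 <- setNames(numeric(n), nm)
  y0[i_eg] <- 1; y0[i_el] <- 1

  dose_var <- if (scenario$formulation == "solid")
    paste0("sol.", scenario$dose_segment) else paste0("dis.", scenario$dose_segment)
  if (!dose_var %in% nm) stop_invalid("unknown dose segment: ", scenario$dose_segment)
  # doses at t = 0 go straight into the initial state; later doses are events
  y0[dose_var] <- dose_umol * sum(scenario$dose_times_h == 0)
  later <- scenario$dose_times_h[scenario$dose_times_h > 0]
  events <- if (length(later))
    data.frame(var = dose_var, time = later, value = dose_umol,
               method = "add", stringsAsFactors = FALSE)
  else NULL

  structure(list(
    compounds = compounds, phys = phys, scenario = scenario,
    ids = ids, ent_ids = ent_ids, sub_id = sub_id,
    ix = ix, i_sys = i_sys, i_acc = i_acc, i_ent = i_ent,
    i_sol = i_sol, i_dis = i_dis, i_prc = i_prc, i_lat = i_lat,
    vc = setNames(vc, ids), bp = setNames(bp, ids), mw = setNames(mw, ids),
    rhs = rhs, y0 = y0, events = events,
    dose_umol = dose_umol, n_states = n, perps = perps
  ), class = "pbpk_model")
}

#' Integrate an assembled PBPK model
#'
#' Stiff-solver integration (lsoda) with instantaneous dose events, plasma
#' concentration output in ng/mL, a cumulative flux ledger, first-pass
#' summaries and a whole-system mass-balance audit.
#'
#' @param model A \code{\link{build_model}} result.
#' @param times Optional output grid, h (default: scenario grid).
#' @return List of class \code{pbpk_sim}: \code{times}, \code{plasma}
#'   (matrix, ng/mL per compound), \code{states}, \code{ledger},
#'   \code{summary} (Fa/Fg/Fh), \code{mass_balance_residual},
#'   \code{substrate} (regimen echo).
#' @export
simulate_model <- function(model, times = NULL) {
  sc <- model$scenario
  if (is.null(times))
    times <- seq(0, sc$horizon_h, by = sc$dt_out_h)
  times <- sort(unique(c(times, sc$dose_times_h)))
  ev <- if (!is.null(model$events)) list(data = model$events) else NULL
  # sparse-Jacobian stiff solver: the coupling structure is highly sparse
  # (transit chain, segment-local metabolism, lumped systemic compartments)
  out <- deSolve::lsodes(model$y0, times, func = function(t, y, p) model$rhs(t, y, p),
                         parms = NULL, rtol = sc$rtol, atol = sc$atol,
                         sparsetype = "sparseint", events = ev,
                         maxsteps = 50000)
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop("solver failure at t = ", max(out[, 1]), call. = FALSE)
  st <- out[, -1, drop = FALSE]
  tt <- out[, 1]

  ids <- model$ids
  plasma <- matrix(0, nrow = length(tt), ncol = length(ids),
                   dimnames = list(NULL, ids))
  for (cid in ids) {
    cc_blood <- st[, model$i_sys[[cid]][3]] / model$vc[cid]   # uM blood
    plasma[, cid] <- pmax(cc_blood, 0) / model$bp[cid] * model$mw[cid]  # ng/mL
  }

  led <- t(vapply(ids, function(cid) st[nrow(st), model$i_acc[[cid]]],
                  numeric(length(ACC_NAMES))))
  ledger <- as.data.frame(led)
  names(ledger) <- ACC_NAMES
  rownames(ledger) <- ids

  # mass balance: all amounts plus terminal sinks must equal dose-to-date
  amount_cols <- c(model$i_sol, model$i_dis, model$i_prc,
                   unlist(model$i_ent, use.names = FALSE),
                   unlist(model$i_sys, use.names = FALSE))
  sink_cols <- unlist(lapply(ids, function(cid)
    model$i_acc[[cid]][c("gut_sink", "fecal", "liver_sink", "bile",
                         "renal", "other")]), use.names = FALSE)
  total <- rowSums(st[, amount_cols, drop = FALSE]) +
    rowSums(st[, sink_cols, drop = FALSE])
  # doses at t = 0 live in the initial state (counted from t >= 0); event
  # doses apply after the output at their own time (counted strictly after)
  t0_doses <- sum(sc$dose_times_h == 0)
  later <- sc$dose_times_h[sc$dose_times_h > 0]
  dosed <- vapply(tt, function(x)
    model$dose_umol * (t0_doses + sum(later < x)), 0)
  denom <- max(model$dose_umol * length(sc$dose_times_h), .Machine$double.eps)
  residual <- max(abs(total - dosed)) / denom

  doses <- setNames(rep(0, length(ids)), ids)
  doses[model$sub_id] <- model$dose_umol * length(sc$dose_times_h)
  fp <- first_pass_summary(ledger, doses)
  fh <- fh_summary(ledger)
  summary <- merge(fp, fh, by = "compound", sort = FALSE)

  structure(list(times = tt, plasma = plasma, states = st, ledger = ledger,
                 summary = summary, mass_balance_residual = residual,
                 substrate = list(id = model$sub_id, dose_mg = sc$dose_mg,
                                  formulation = sc$formulation,
                                  dose_times_h = sc$dose_times_h),
                 e_gut = st[, model$ix[["e_gut"]]],
                 e_liver = st[, model$ix[["e_liver"]]]),
            class = "pbpk_sim")
}

#' Build and simulate in one call
#'
#' @param compounds,phys,scenario As for \code{\link{build_model}}.
#' @param times Optional output grid.
#' @return A \code{pbpk_sim}.
#' @export
simulate_scenario <- function(compounds = default_compounds(),
                              phys = default_physiology(),
                              scenario, times = NULL) {
  simulate_model(build_model(compounds, phys, scenario), times = times)
}

#' Substrate-dose-aligned concentration profile
#'
#' @param sim A \code{pbpk_sim}.
#' @param compound Compound id.
#' @return Data frame \code{time} (h since last substrate dose), \code{conc}
#'   (ng/mL).
#' @export
substrate_profile <- function(sim, compound = "DAB") {
  t0 <- max(sim$substrate$dose_times_h)
  keep <- sim$times >= t0
  data.frame(time = sim$times[keep] - t0, conc = sim$plasma[keep, compound])
}

#' Population simulation with log-normal parameter variability
#'
#' Per-subject multiplicative log-normal factors are applied to parameter
#' groups (shared across compounds within a subject), the model is rebuilt
#' and integrated, and pooled percentile bands are returned. A convenience
#' approximation of between-subject variability, not a covariate-based
#' virtual population.
#'
#' @param compounds,phys,scenario As for \code{\link{build_model}}.
#' @param cv_map Named numeric of percent CVs; names among
#'   \code{"clearance"} (liver/bile/renal/other pathway capacities),
#'   \code{"vss"}, \code{"gut_vmax"}, \code{"peff"}.
#' @param n_subjects Subjects per trial.
#' @param n_trials Number of trials.
#' @param seed Mandatory RNG seed.
#' @param compound Compound whose plasma profile is banded.
#' @return List with \code{times}, \code{profiles} (subjects x times),
#'   \code{median}, \code{lower}, \code{upper} (5th/95th percentiles),
#'   \code{trial} index.
#' @export
simulate_population <- function(compounds = default_compounds(),
                                phys = default_physiology(), scenario,
                                cv_map = c(clearance = 30, vss = 20),
                                n_subjects = 10, n_trials = 10, seed,
                                compound = "DAB") {
  if (missing(seed)) stop_invalid("a seed is mandatory for population runs")
  set.seed(seed)
  ntot <- n_subjects * n_trials
  base <- simulate_scenario(compounds, phys, scenario)
  profiles <- matrix(NA_real_, nrow = ntot, ncol = length(base$times))
  draw <- function(cv) if (is.na(cv) || cv <= 0) 1 else
    exp(stats::rnorm(1, -cv_to_sdlog(cv)^2 / 2, cv_to_sdlog(cv)))
  for (i in seq_len(ntot)) {
    cps <- compounds
    f_cl <- draw(cv_map["clearance"]); f_v <- draw(cv_map["vss"])
    f_gv <- draw(cv_map["gut_vmax"]); f_pe <- draw(cv_map["peff"])
    for (cid in names(cps)) {
      cp <- cps[[cid]]
      cp$renal_cl_u_l_h <- cp$renal_cl_u_l_h * f_cl
      cp$other_cl_u_l_h <- cp$other_cl_u_l_h * f_cl
      cp$bile_clint_ul_min_1e6 <- cp$bile_clint_ul_min_1e6 * f_cl
      cp$liver_pathways <- lapply(cp$liver_pathways, function(p) {
        p$vmax <- p$vmax * f_cl; p })
      cp$gut_pathways <- lapply(cp$gut_pathways, function(p) {
        p$vmax <- p$vmax * f_gv; p })
      cp$vss_l_kg <- cp$vss_l_kg * f_v
      cp$peff_1e4_cm_s <- cp$peff_1e4_cm_s * f_pe
      cps[[cid]] <- cp
    }
    sim <- simulate_scenario(cps, phys, scenario)
    profiles[i, ] <- sim$plasma[, compound]
  }
  list(times = base$times, profiles = profiles,
       median = apply(profiles, 2, stats::median),
       lower = apply(profiles, 2, stats::quantile, 0.05),
       upper = apply(profiles, 2, stats::quantile, 0.95),
       trial = rep(seq_len(n_trials), each = n_subjects))
}
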