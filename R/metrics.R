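# Noncompartmental analysis and model-evaluation statistics: Guest DDI
# acceptance limits, geometric mean fold error, CV/n-based success bounds,
# dose-linearity diagnostics and visual-predictive-check coverage.

#' Noncompartmental metrics of a concentration-time profile
#'
#' Linear-up/log-down trapezoidal AUC; terminal slope from a log-linear
#' regression over the tail (the window after Cmax with the best adjusted
#' fit, at least 3 points); AUC extrapolated to infinity as Clast/lambda_z.
#'
#' @param time Time since dose, h.
#' @param conc Concentration (any unit).
#' @param min_tail Minimum number of tail points for the lambda_z fit.
#' @return List of class \code{pk_metrics}: \code{cmax}, \code{tmax},
#'   \code{auc_0_t}, \code{auc_0_inf}, \code{lambda_z},
#'   \code{extrapolated_fraction}, \code{flag} (character, "" when clean).
#' @export
nca <- function(time, conc, min_tail = 3) {
  stopifnot(length(time) == length(conc), !is.unsorted(time))
  conc <- pmax(conc, 0)
  if (all(conc == 0))
    return(structure(list(cmax = 0, tmax = NA_real_, auc_0_t = 0,
                          auc_0_inf = 0, lambda_z = NA_real_,
                          extrapolated_fraction = NA_real_,
                          flag = "all-zero profile"), class = "pk_metrics"))
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- time[imax]
  # linear-up / log-down trapezoid
  auc <- 0
  for (i in seq_len(length(time) - 1)) {
    dt <- time[i + 1] - time[i]
    c1 <- conc[i]; c2 <- conc[i + 1]
    auc <- auc + if (c2 < c1 && c2 > 0) dt * (c1 - c2) / log(c1 / c2)
    else dt * (c1 + c2) / 2
  }
  # terminal slope: best adjusted-R2 window over the post-Cmax tail
  tail_idx <- which(seq_along(time) > imax & conc > 0)
  lambda <- NA_real_; flag <- ""
  if (length(tail_idx) >= min_tail) {
    best <- -Inf
    for (k in min_tail:length(tail_idx)) {
      idx <- utils::tail(tail_idx, k)
      ft <- stats::lm(log(conc[idx]) ~ time[idx])
      sl <- unname(stats::coef(ft)[2])
      if (!is.finite(sl) || sl >= 0) next
      # noiseless profiles fit perfectly; silence the summary caveat
      r2 <- suppressWarnings(summary(ft)$r.squared)
      adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
      if (adj > best + 1e-10) { best <- adj; lambda <- -sl }
    }
  }
  if (is.na(lambda)) {
    flag <- "lambda_z not estimable"
    auc_inf <- auc; extf <- NA_real_
  } else {
    clast <- conc[max(which(conc > 0))]
    auc_inf <- auc + clast / lambda
    extf <- 1 - auc / auc_inf
    if (extf >= 0.2) flag <- "extrapolated fraction >= 20%"
  }
  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc,
                 auc_0_inf = auc_inf, lambda_z = lambda,
                 extrapolated_fraction = extf, flag = flag),
            class = "pk_metrics")
}

#' Guest acceptance limits for a DDI ratio
#'
#' The acceptance window narrows toward unity for small observed ratios:
#' \eqn{L = (\delta + 2(R_{obs}-1))/R_{obs}} with limits
#' \eqn{(R_{obs}/L,\; R_{obs} L)}. Ratios below 1 are evaluated on the
#' reciprocal and mapped back, preserving log-scale symmetry
#' (lower x upper = Robs^2).
#'
#' @param robs Observed ratio, > 0.
#' @param delta Baseline variability factor (default 1).
#' @return List of class \code{guest_limits}: \code{robs}, \code{lower},
#'   \code{upper}, \code{delta}.
#' @export
guest_limits <- function(robs, delta = 1) {
  assert_positive(robs, "robs")
  if (delta < 1) stop_invalid("delta must be >= 1")
  r <- max(robs, 1 / robs)
  l <- (delta + 2 * (r - 1)) / r
  structure(list(robs = robs, lower = robs / l, upper = robs * l,
                 delta = delta), class = "guest_limits")
}

#' Is a simulated DDI ratio within the Guest acceptance window?
#'
#' @param rsim Simulated ratio.
#' @param robs Observed ratio.
#' @param delta Baseline variability factor.
#' @return Logical.
#' @export
guest_pass <- function(rsim, robs, delta = 1) {
  gl <- guest_limits(robs, delta)
  rsim >= gl$lower & rsim <= gl$upper
}

#' Geometric mean fold error of simulated versus observed values
#'
#' Signed variant (as conventionally printed alongside PBPK qualification
#' tables): \eqn{10^{\mathrm{mean}(\log_{10}(sim/obs))}}, which can fall
#' below 1 when predictions run low on average. The absolute variant
#' (\code{signed = FALSE}) uses \eqn{|\log_{10}|} and is always >= 1.
#'
#' @param observed,simulated Positive numeric vectors of equal length.
#' @param signed Use the signed (default) or absolute-value variant.
#' @return List of class \code{gmfe}: \code{value}, \code{n_pairs},
#'   \code{signed}.
#' @export
gmfe <- function(observed, simulated, signed = TRUE) {
  if (length(observed) != length(simulated) || length(observed) < 1)
    stop_invalid("observed and simulated must be equal-length, non-empty")
  if (any(observed <= 0) || any(simulated <= 0))
    stop_invalid("all values must be positive")
  lg <- log10(simulated / observed)
  if (!signed) lg <- abs(lg)
  structure(list(value = 10^mean(lg), n_pairs = length(lg), signed = signed),
            class = "gmfe")
}

#' Success bounds for a PK parameter from its observed mean and CV
#'
#' Bounds of a two-sided confidence interval on the (log-normal) mean:
#' \eqn{\sigma_{\log} = \sqrt{\ln(1 + (cv/100)^2)}} and
#' \eqn{bounds = \bar{x}\,e^{\mp z \sigma_{\log}/\sqrt{n}}} with z at the
#' stated confidence. When the study size is unknown the bounds fall back to
#' the twofold window.
#'
#' @param geo_mean Observed (geometric) mean.
#' @param cv_percent Observed percent coefficient of variation (NA when not
#'   reported).
#' @param n_subjects Study size (NA when not reported).
#' @param confidence Two-sided confidence level (default 99.998%).
#' @return List with \code{lower}, \code{upper}, \code{twofold_fallback}.
#' @export
success_bounds <- function(geo_mean, cv_percent = NA, n_subjects = NA,
                           confidence = 0.99998) {
  assert_positive(geo_mean, "geo_mean")
  if (is.na(cv_percent) || is.na(n_subjects)) {
    return(list(lower = geo_mean / 2, upper = geo_mean * 2,
                twofold_fallback = TRUE))
  }
  assert_positive(cv_percent, "cv_percent")
  if (n_subjects < 2) stop_invalid("n_subjects must be >= 2")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  half <- z * cv_to_sdlog(cv_percent) / sqrt(n_subjects)
  list(lower = geo_mean * exp(-half), upper = geo_mean * exp(half),
       twofold_fallback = FALSE)
}

#' Dose-normalized exposure ratios and deviation from proportionality
#'
#' @param dose Vector of doses.
#' @param auc Matching exposure values.
#' @param ref_dose Reference dose defining proportionality.
#' @return Data frame with \code{dose}, \code{auc}, \code{ratio}
#'   ((AUC/d)/(AUC_ref/ref)) and \code{deviation_factor} (1/ratio for
#'   sub-proportional doses).
#' @export
dose_linearity <- function(dose, auc, ref_dose) {
  stopifnot(length(dose) == length(auc), length(dose) >= 2)
  iref <- which(dose == ref_dose)
  if (length(iref) != 1) stop_invalid("ref_dose must match exactly one dose")
  norm_ref <- auc[iref] / dose[iref]
  ratio <- (auc / dose) / norm_ref
  data.frame(dose = dose, auc = auc, ratio = ratio,
             deviation_factor = 1 / ratio)
}

#' Visual-predictive-check coverage of observations by a percentile band
#'
#' @param obs_time,obs_conc Observed points.
#' @param band_time,band_lower,band_upper Simulated percentile band
#'   (interpolated linearly at the observation times).
#' @return List with \code{coverage} (fraction inside) and
#'   \code{excursions} (data frame of points outside the band).
#' @export
vpc_coverage <- function(obs_time, obs_conc, band_time, band_lower,
                         band_upper) {
  lo <- stats::approx(band_time, band_lower, xout = obs_time, rule = 2)$y
  hi <- stats::approx(band_time, band_upper, xout = obs_time, rule = 2)$y
  inside <- obs_conc >= lo & obs_conc <= hi
  list(coverage = mean(inside),
       excursions = data.frame(time = obs_time, conc = obs_conc,
                               lower = lo, upper = hi)[!inside, ])
}

#' Printed qualification tables of the dabigatran PBPK evaluation
#'
#' Observed and simulated DAB plasma PK parameters (single/multiple dosing
#' across the microdose-to-therapeutic range) and DDI ratios with dual
#' CYP3A/P-gp inhibitors, as printed in the published evaluation; inputs to
#' the evaluation statistics (GMFE, Guest windows, success bounds).
#'
#' @return List of two data frames: \code{pk} (columns \code{set},
#'   \code{role}, \code{dose_mg}, \code{metric}, \code{observed},
#'   \code{simulated}) and \code{ddi} (\code{set}, \code{role},
#'   \code{dose_mg}, \code{perpetrator}, \code{metric}, \code{observed},
#'   \code{simulated}).
#' @export
qualification_tables <- function() {
  pk <- rbind(
    data.frame(set = "1",     role = "training",      dose_mg = 0.375, metric = "cmax", observed = 0.17, simulated = 0.15),
    data.frame(set = "1",     role = "training",      dose_mg = 0.375, metric = "auc",  observed = 1.44, simulated = 1.44),
    data.frame(set = "2",     role = "training",      dose_mg = 300,   metric = "cmax", observed = 174,  simulated = 166),
    data.frame(set = "2",     role = "training",      dose_mg = 300,   metric = "auc",  observed = 1220, simulated = 1181),
    data.frame(set = "3",     role = "training",      dose_mg = 200,   metric = "cmax", observed = 145,  simulated = 151),
    data.frame(set = "3",     role = "training",      dose_mg = 200,   metric = "auc",  observed = 930,  simulated = 1166),
    data.frame(set = "4_sd",  role = "qualification", dose_mg = 400,   metric = "cmax", observed = 281,  simulated = 249),
    data.frame(set = "4_sd",  role = "qualification", dose_mg = 400,   metric = "auc",  observed = 1254, simulated = 1128),
    data.frame(set = "4_md",  role = "qualification", dose_mg = 400,   metric = "cmax", observed = 662,  simulated = 334),
    data.frame(set = "4_md",  role = "qualification", dose_mg = 400,   metric = "auc",  observed = 5071, simulated = 2805),
    data.frame(set = "5",     role = "qualification", dose_mg = 150,   metric = "cmax", observed = 107,  simulated = 124),
    data.frame(set = "5",     role = "qualification", dose_mg = 150,   metric = "auc",  observed = 937,  simulated = 965),
    data.frame(set = "6",     role = "qualification", dose_mg = 0.75,  metric = "cmax", observed = 0.38, simulated = 0.33),
    data.frame(set = "6",     role = "qualification", dose_mg = 0.75,  metric = "auc",  observed = 3.11, simulated = 3.10),
    data.frame(set = "9",     role = "qualification", dose_mg = 300,   metric = "cmax", observed = 83,   simulated = 170),
    data.frame(set = "9",     role = "qualification", dose_mg = 300,   metric = "auc",  observed = 547,  simulated = 1239),
    data.frame(set = "10_11", role = "qualification", dose_mg = 150,   metric = "cmax", observed = 63,   simulated = 105),
    data.frame(set = "10_11", role = "qualification", dose_mg = 150,   metric = "auc",  observed = 536,  simulated = 793))
  ddi <- rbind(
    data.frame(set = "1",  role = "training",      dose_mg = 0.375, perpetrator = "CTC", metric = "cmax_ratio", observed = 4.57, simulated = 4.46),
    data.frame(set = "1",  role = "training",      dose_mg = 0.375, perpetrator = "CTC", metric = "auc_ratio",  observed = 4.02, simulated = 4.64),
    data.frame(set = "2",  role = "training",      dose_mg = 300,   perpetrator = "CTC", metric = "cmax_ratio", observed = 1.60, simulated = 1.61),
    data.frame(set = "2",  role = "training",      dose_mg = 300,   perpetrator = "CTC", metric = "auc_ratio",  observed = 1.49, simulated = 1.97),
    data.frame(set = "6",  role = "qualification", dose_mg = 0.75,  perpetrator = "RF",  metric = "cmax_ratio", observed = 1.86, simulated = 2.16),
    data.frame(set = "6",  role = "qualification", dose_mg = 0.75,  perpetrator = "RF",  metric = "auc_ratio",  observed = 2.22, simulated = 1.94),
    data.frame(set = "7",  role = "qualification", dose_mg = 0.375, perpetrator = "ITZ", metric = "cmax_ratio", observed = 6.42, simulated = 4.82),
    data.frame(set = "7",  role = "qualification", dose_mg = 0.375, perpetrator = "ITZ", metric = "auc_ratio",  observed = 6.92, simulated = 5.12),
    data.frame(set = "8",  role = "qualification", dose_mg = 0.375, perpetrator = "RF",  metric = "cmax_ratio", observed = 1.78, simulated = 2.16),
    data.frame(set = "8",  role = "qualification", dose_mg = 0.375, perpetrator = "RF",  metric = "auc_ratio",  observed = 2.32, simulated = 1.94),
    data.frame(set = "9",  role = "qualification", dose_mg = 300,   perpetrator = "CTC", metric = "cmax_ratio", observed = 1.71, simulated = 1.61),
    data.frame(set = "9",  role = "qualification", dose_mg = 300,   perpetrator = "CTC", metric = "auc_ratio",  observed = 1.97, simulated = 1.97),
    data.frame(set = "10", role = "qualification", dose_mg = 150,   perpetrator = "VP",  metric = "cmax_ratio", observed = 2.15, simulated = 1.55),
    data.frame(set = "10", role = "qualification", dose_mg = 150,   perpetrator = "VP",  metric = "auc_ratio",  observed = 1.98, simulated = 1.88),
    data.frame(set = "11", role = "qualification", dose_mg = 150,   perpetrator = "VP",  metric = "cmax_ratio", observed = 2.70, simulated = 1.74),
    data.frame(set = "11", role = "qualification", dose_mg = 150,   perpetrator = "VP",  metric = "auc_ratio",  observed = 2.37, simulated = 2.07))
  list(pk = pk, ddi = ddi)
}
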