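# Seeded synthetic-data generators: in vitro plasma-decay incubations,
# Michaelis-Menten rate-versus-concentration designs, and sparse noisy
# plasma observations from a known ground-truth simulation. Every generator
# is bit-reproducible from its seed; zero-noise generation composed with the
# corresponding fitter recovers the truth.

#' Multiplicative log-normal noise model
#'
#' @param cv_percent Percent coefficient of variation (>= 0).
#' @param seed Mandatory RNG seed.
#' @param lloq Lower limit of quantification for reported concentrations
#'   (ng/mL); values below are censored.
#' @return List of class \code{noise_model}.
#' @export
noise_model <- function(cv_percent, seed, lloq = 0.01) {
  if (cv_percent < 0) stop_invalid("cv_percent must be >= 0")
  if (missing(seed)) stop_invalid("a seed is mandatory")
  structure(list(kind = "lognormal", cv_percent = cv_percent, seed = seed,
                 lloq = lloq), class = "noise_model")
}

apply_noise <- function(x, noise, stream = 0L) {
  if (noise$cv_percent <= 0) return(x)
  set.seed(noise$seed + stream)
  sdl <- cv_to_sdlog(noise$cv_percent)
  x * exp(stats::rnorm(length(x), 0, sdl))
}

#' Generate an in vitro plasma-decay incubation dataset
#'
#' First-order decay \eqn{C(t) = C_0 e^{-kt}} (or a constant series for a
#' stable compound) with multiplicative log-normal error; replicate-wise
#' RNG streams derive deterministically from the master seed.
#'
#' @param k_h Decay rate constant in 1/h, or the string \code{"stable"}.
#' @param times_min Sampling times, minutes (default 0-120 min design).
#' @param c0_um Initial concentration, uM.
#' @param n_replicates Number of replicates.
#' @param noise A \code{\link{noise_model}}.
#' @return Data frame \code{time_min}, \code{conc}, \code{replicate}.
#' @export
gen_invitro_decay <- function(k_h, times_min = seq(0, 120, by = 15),
                              c0_um = 1, n_replicates = 3, noise) {
  stopifnot(inherits(noise, "noise_model"))
  k_min <- if (identical(k_h, "stable")) 0 else {
    assert_positive(k_h, "k_h"); k_h / 60
  }
  out <- lapply(seq_len(n_replicates), function(r) {
    mu <- c0_um * exp(-k_min * times_min)
    data.frame(time_min = times_min,
               conc = apply_noise(mu, noise, stream = r),
               replicate = r)
  })
  do.call(rbind, out)
}

#' Generate a Michaelis-Menten rate-versus-concentration dataset
#'
#' @param vmax,km_um True parameters.
#' @param conc_um Substrate concentration design, uM.
#' @param n_replicates Number of replicates.
#' @param noise A \code{\link{noise_model}}.
#' @return Data frame \code{conc_um}, \code{rate}, \code{replicate}.
#' @export
gen_mm_rates <- function(vmax, km_um, conc_um = c(0.3, 0.6, 1, 2, 5, 10, 20, 30),
                         n_replicates = 2, noise) {
  stopifnot(inherits(noise, "noise_model"))
  assert_positive(vmax, "vmax"); assert_positive(km_um, "km_um")
  if (any(conc_um <= 0)) stop_invalid("concentrations must be positive")
  out <- lapply(seq_len(n_replicates), function(r) {
    mu <- vmax * conc_um / (km_um + conc_um)
    data.frame(conc_um = conc_um,
               rate = apply_noise(mu, noise, stream = 100L + r),
               replicate = r)
  })
  do.call(rbind, out)
}

#' Generate sparse noisy plasma observations from a ground-truth simulation
#'
#' Simulates the scenario under known (optionally overridden) parameters,
#' samples the profile at the requested times, applies multiplicative
#' log-normal error and LLOQ censoring, and returns the tidy observation
#' table the estimation module consumes.
#'
#' @param scenario A \code{\link{scenario_spec}}.
#' @param truth_overrides Compound-field overrides defining the truth (see
#'   \code{\link{default_compounds}}).
#' @param sampling_times_h Observation times since the (last) substrate
#'   dose, h.
#' @param noise A \code{\link{noise_model}}.
#' @param compound Observed compound.
#' @param phys Physiology.
#' @return Data frame \code{time_h}, \code{compound}, \code{conc_ng_per_ml},
#'   \code{censored}; censored rows keep the LLOQ flag but an NA value.
#' @export
gen_pk_observations <- function(scenario, truth_overrides = NULL,
                                sampling_times_h, noise, compound = "DAB",
                                phys = default_physiology()) {
  stopifnot(inherits(noise, "noise_model"))
  cps <- default_compounds(overrides = truth_overrides)
  sim <- simulate_scenario(cps, phys, scenario)
  prof <- substrate_profile(sim, compound)
  mu <- stats::approx(prof$time, prof$conc, xout = sampling_times_h)$y
  obs <- apply_noise(mu, noise, stream = 1000L)
  cens <- obs < noise$lloq
  if (all(cens)) stop_invalid("all samples fall below the LLOQ")
  data.frame(time_h = sampling_times_h, compound = compound,
             conc_ng_per_ml = ifelse(cens, NA_real_, obs),
             censored = cens)
}
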