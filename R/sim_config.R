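#' Simulator configuration
#'
#' Assembles and validates the full parameter set of the coupled
#' forcing-and-bloom simulator. Defaults describe a Northwestern
#' Mediterranean-like regime: a seasonal net-heat-flux (NHF) cycle turning
#' positive in mid-March (day-of-year 74), one-composite-step wind bursts
#' that are much more frequent in winter than in summer, strong negative
#' coupling between storm wind stress and NHF, and a slab mixed-layer
#' phytoplankton model whose winter dynamics are set by storm dilution and
#' calm-spell light exposure and whose spring decay is set by grazing and
#' nutrient drawdown.
#'
#' @param n_years simulated years.
#' @param start_year first calendar year (sets the date axis only).
#' @param steps_per_year 8-day composite windows per year (46).
#' @param seed integer RNG seed; required for reproducible runs.
#' @param nhf_amplitude amplitude of the seasonal NHF sine, W m-2.
#' @param nhf_zero_doy day-of-year at which the seasonal NHF cycle crosses
#'   zero upward (mid-March).
#' @param storm_prob_winter,storm_prob_summer per-step storm probability at
#'   the winter peak and summer minimum of the storm season.
#' @param storm_peak_doy day-of-year of maximum storm frequency (mid-Feb,
#'   when deep convection events peak).
#' @param storm_ws_mean mean wind-stress anomaly of a storm, N m-2
#'   (lognormal).
#' @param storm_ws_sdlog lognormal log-scale spread of storm magnitude.
#' @param ws_base background wind stress, N m-2.
#' @param ws_noise_sd lognormal sd of calm-weather wind-stress jitter.
#' @param nhf_ws_coupling loss of NHF per unit storm wind-stress anomaly,
#'   W m-2 per N m-2 (latent + sensible response to wind bursts).
#' @param nhf_noise_sd Gaussian NHF noise, W m-2.
#' @param h_min,h_max mixed-layer depth bounds, m.
#' @param mix_light_coeff metres of actively mixing layer per W m-2 of
#'   effective surface cooling.
#' @param mix_memory_weight weight of instantaneous NHF (vs its low-pass)
#'   in the mixing-depth target; the low-pass term represents convective
#'   preconditioning.
#' @param mix_memory_timescale e-folding of the NHF low-pass, days.
#' @param deepen_timescale e-folding of mixed-layer deepening towards its
#'   target, days (storm deepening is fast).
#' @param restrat_timescale e-folding of restratification towards the
#'   target, days.
#' @param mu_max maximum phytoplankton growth rate, day-1.
#' @param light_halfsat half-saturation irradiance for growth, W m-2.
#' @param attenuation light attenuation of seawater, m-1.
#' @param i0_mean,i0_amp annual mean and amplitude of daily-mean surface
#'   irradiance, W m-2 (cosine with maximum at the June solstice).
#' @param loss_base background linear loss, day-1.
#' @param loss_grazing grazing loss at unit grazing pressure, day-1.
#' @param grazing_halfsat chlorophyll scale of the grazing response,
#'   mg Chl m-3.
#' @param grazing_rise_timescale,grazing_decay_timescale e-folding of the
#'   lagged grazing pressure when food increases / decreases, days.
#' @param deep_chl chlorophyll of entrained deep water, mg Chl m-3.
#' @param nutrient_halfsat half-saturation of the (normalised, deep value
#'   1) nutrient pool.
#' @param nutrient_uptake_coeff nutrient drawn down per unit production,
#'   (mg Chl m-3)-1 day-1 scale.
#' @param nutrient_recharge_timescale recharge e-folding towards the deep
#'   value at full mixed-layer depth, days.
#' @param chl_floor lower bound on chlorophyll, mg Chl m-3.
#' @param obs_noise_sd lognormal sd of multiplicative observation noise on
#'   SChl.
#' @param n_lat,n_lon grid size.
#' @param lat0,lon0,dlat,dlon grid origin (degrees) and spacing.
#' @param mu_max_scale per-pixel multiplicative scaling of `mu_max`:
#'   either a `n_lat x n_lon` matrix or a length-2 range expanded into a
#'   longitude gradient (emulating the onshore-offshore productivity
#'   gradient that delimits the bloom region).
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_forcing()], [simulate_dataset()], [step_slab()]
#' @export
sim_config <- function(n_years = 20,
                       start_year = 1998,
                       steps_per_year = 46,
                       seed = 42,
                       nhf_amplitude = 200,
                       nhf_zero_doy = 74,
                       storm_prob_winter = 0.25,
                       storm_prob_summer = 0.05,
                       storm_peak_doy = 46,
                       storm_ws_mean = 0.15,
                       storm_ws_sdlog = 0.6,
                       ws_base = 0.05,
                       ws_noise_sd = 0.4,
                       nhf_ws_coupling = 800,
                       nhf_noise_sd = 15,
                       h_min = 15,
                       h_max = 500,
                       mix_light_coeff = 0.45,
                       mix_memory_weight = 0.6,
                       mix_memory_timescale = 40,
                       deepen_timescale = 2,
                       restrat_timescale = 10,
                       mu_max = 0.8,
                       light_halfsat = 30,
                       attenuation = 0.08,
                       i0_mean = 180,
                       i0_amp = 70,
                       loss_base = 0.1,
                       loss_grazing = 0.5,
                       grazing_halfsat = 1.5,
                       grazing_rise_timescale = 8,
                       grazing_decay_timescale = 15,
                       deep_chl = 0.05,
                       nutrient_halfsat = 0.2,
                       nutrient_uptake_coeff = 0.05,
                       nutrient_recharge_timescale = 3,
                       chl_floor = 0.01,
                       obs_noise_sd = 0.1,
                       n_lat = 1L,
                       n_lon = 1L,
                       lat0 = 41.5, lon0 = 4.0,
                       dlat = 0.125, dlon = 0.125,
                       mu_max_scale = NULL) {
  cfg <- as.list(environment())
  if (!is.numeric(n_years) || n_years < 1)
    stop("n_years must be a positive integer")
  if (steps_per_year * 8 > 368) stop("steps_per_year * 8 must be <= 368")
  probs <- c(storm_prob_winter, storm_prob_summer)
  if (any(probs < 0 | probs > 1)) stop("storm probabilities must be in [0, 1]")
  if (h_min >= h_max) stop("h_min must be < h_max")
  pos <- c("nhf_amplitude", "storm_ws_mean", "ws_base", "mu_max",
           "light_halfsat", "attenuation", "loss_base", "loss_grazing",
           "grazing_halfsat", "deep_chl", "chl_floor", "i0_mean")
  for (nm in pos) if (cfg[[nm]] < 0) stop(nm, " must be non-negative")
  if (is.null(mu_max_scale)) mu_max_scale <- c(0.4, 1.15)
  if (is.matrix(mu_max_scale)) {
    if (!all(dim(mu_max_scale) == c(n_lat, n_lon)))
      stop("mu_max_scale matrix must be n_lat x n_lon")
  } else if (length(mu_max_scale) == 2) {
    grad <- if (n_lon > 1) seq(mu_max_scale[1], mu_max_scale[2],
                               length.out = n_lon) else mean(mu_max_scale)
    mu_max_scale <- matrix(grad, n_lat, n_lon, byrow = TRUE)
  } else if (length(mu_max_scale) == 1) {
    mu_max_scale <- matrix(mu_max_scale, n_lat, n_lon)
  } else stop("mu_max_scale must be a matrix, a range, or a scalar")
  if (any(mu_max_scale < 0)) stop("mu_max_scale must be non-negative")
  cfg$mu_max_scale <- mu_max_scale
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d year(s) from %d, %d x %d grid, ",
                     "seed %d\n"),
              x$n_years, x$start_year, x$n_lat, x$n_lon, x$seed))
  invisible(x)
}

#' Seasonal daily-mean surface irradiance
#'
#' Cosine annual cycle peaking at the June solstice (day 172).
#'
#' @param doy day of year (1-366).
#' @param config a [sim_config()].
#' @return Irradiance, W m-2.
#' @export
surface_irradiance <- function(doy, config) {
  config$i0_mean + config$i0_amp * cos(2 * pi * (doy - 172) / 365.25)
}

#' Read a simulator configuration from a YAML file
#'
#' The file holds any subset of [sim_config()] arguments by name; unnamed
#' parameters keep their defaults. A `seed` entry is required.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed)) stop("config file must set 'seed'")
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
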