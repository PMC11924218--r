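# Seeded synthetic-data generators: every input the pipeline consumes can be
# produced with known ground truth, so each stage is testable without
# external downloads. These are statistical stand-ins, not physical
# simulations: no meteorology, seasonality or emission physics.

#' Synthetic-data configuration
#'
#' Bundles the ground-truth CNT parameters and the sizes/noise levels of all
#' generators. Defaults emulate a desk-scale version of the study setup: a
#' ~100-droplet-scale assay design with a three-step dilution ladder, a
#' 24 x 12-cell globe at 6-hourly resolution over 30 days, and
#' lognormally-noised observations (sigma = ln 3, the order of scatter of
#' field INP measurements).
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param true_params ground-truth [cnt_params()] driving assay simulation.
#' @param n_droplets droplets per assay.
#' @param droplet_volume droplet volume \[L\] (1 uL default).
#' @param dilutions dilution ladder for [simulate_dilution_series()].
#' @param cooling_rate cooling ramp \[K s^-1\] (1 K/min default); its
#'   reciprocal is the natural effective nucleation time per 1-K bin.
#' @param grid_shape `c(nlat, nlon)` of the synthetic globe.
#' @param n_timesteps,timestep_hours length and spacing of the field record.
#' @param obs_noise_sigma lognormal observation noise (log-space sd).
#' @param n_observations number of synthetic observation records.
#' @param temperature_grid assay temperature grid \[K\].
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       true_params = hsz25_params(),
                       n_droplets = 300, droplet_volume = 1e-6,
                       dilutions = c(1, 10, 100),
                       cooling_rate = 1 / 60,
                       grid_shape = c(12, 24),
                       n_timesteps = 120, timestep_hours = 6,
                       obs_noise_sigma = log(3), n_observations = 500,
                       temperature_grid = default_temperature_grid()) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n_droplets > 0,
            cooling_rate > 0, all(dilutions >= 1), length(grid_shape) == 2,
            n_timesteps > 0, obs_noise_sigma >= 0, n_observations >= 0)
  .check_grid(temperature_grid)
  structure(list(seed = as.integer(seed), true_params = true_params,
                 n_droplets = n_droplets, droplet_volume = droplet_volume,
                 dilutions = dilutions, cooling_rate = cooling_rate,
                 grid_shape = grid_shape, n_timesteps = n_timesteps,
                 timestep_hours = timestep_hours,
                 obs_noise_sigma = obs_noise_sigma,
                 n_observations = n_observations,
                 temperature_grid = temperature_grid),
            class = "sim_config")
}

# Core assay simulator (no seeding; callers control the RNG stream).
# Per droplet: site count k ~ Poisson(n_max c V / dilution); each site draws
# theta from the truncated normal; a site's freezing temperature is sampled
# by inverse transform from the forward model's activation CDF along the
# cooling ramp, G(T) = 1 - exp(-j(T, theta) a_site delta_t) (equivalently,
# per grid step the site nucleates with the increment of that cumulative
# hazard). The droplet freezes with its warmest-freezing site; droplets
# whose sites never nucleate in the grid stay liquid (right-censored).
.simulate_assay_core <- function(params, thermo, c_basis, droplet_volume,
                                 dilution, n_droplets, grid,
                                 sample_id = "sim", treatment = "none") {
  lam <- params$n_max * c_basis * droplet_volume / dilution
  k <- rpois(n_droplets, lam)
  K <- sum(k)
  if (K == 0)
    return(freezing_assay(sample_id, droplet_volume, dilution,
                          numeric(0), n_droplets, treatment))
  mu <- params$mu_theta; sigma <- params$sigma_theta
  plo <- pnorm(-mu / sigma); phi <- pnorm((pi - mu) / sigma)
  theta <- mu + sigma * qnorm(runif(K, plo, phi))

  # hazard H(T_s, theta) = j a delta_t, cumulative (monotone) along cooling
  dgkt <- dg_hom(thermo, grid) / (.kB * grid)
  lnAat <- log(a_kin(thermo, grid) * params$a_site * params$delta_t)
  c1 <- df_diff(thermo, grid) / (.kB * grid)
  f_th <- compatibility_factor(theta)
  # steps x sites matrix of log-hazards
  lnH <- matrix(lnAat - c1, length(grid), K) -
    ifelse(is.finite(dgkt), dgkt, Inf) %o% f_th
  H <- exp(lnH)
  for (s in seq_len(nrow(H))[-1])       # enforce cumulative monotone hazard
    H[s, ] <- pmax(H[s, ], H[s - 1, ])
  E <- rexp(K)
  # first grid step where the cumulative hazard exceeds the site's
  # exponential threshold; NA if the site never activates in the grid
  n_below <- colSums(H < E[col(H)])
  site_step <- ifelse(n_below < length(grid), n_below + 1L, NA_integer_)
  droplet <- rep.int(seq_len(n_droplets), k)
  first <- tapply(site_step, droplet, function(s)
    if (all(is.na(s))) NA_integer_ else min(s, na.rm = TRUE))
  frozen_steps <- first[!is.na(first)]
  freezing_assay(sample_id, droplet_volume, dilution,
                 grid[frozen_steps], n_droplets, treatment)
}

#' Simulate a droplet freezing assay
#'
#' Forward simulation of the assay under the configured ground-truth CNT
#' parameters; exactly reproducible under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param chemistry [sample_chemistry()] row for the simulated sample (its
#'   `c_tccho` drives the site budget when the truth is on the c_tccho
#'   basis).
#' @param dilution dilution factor for this assay.
#' @param thermo a [thermo_profile()].
#' @param sample_id sample identifier.
#' @param seed RNG seed (default `config$seed`).
#' @param inm_survival fraction of INMs surviving a pre-assay treatment
#'   (e.g. 0.02 for a filtration removing 98 %); scales the site budget.
#' @param treatment treatment label recorded on the assay.
#' @return a [freezing_assay()].
#' @export
simulate_assay <- function(config, chemistry, dilution = 1,
                           thermo = thermo_profile(), sample_id = NULL,
                           seed = config$seed, inm_survival = 1,
                           treatment = "none") {
  stopifnot(inherits(config, "sim_config"), inm_survival >= 0,
            inm_survival <= 1)
  if (!is.null(seed)) set.seed(seed)
  sample_id <- sample_id %||% chemistry$sample_id[1]
  conc <- .basis_concentration(chemistry, sample_id, "c_tccho")
  p <- config$true_params
  p_eff <- cnt_params(p$mu_theta, p$sigma_theta,
                      max(p$n_max * inm_survival, .Machine$double.xmin),
                      p$a_site, p$delta_t, p$basis)
  .simulate_assay_core(p_eff, thermo, conc, config$droplet_volume,
                       dilution, config$n_droplets,
                       config$temperature_grid, sample_id, treatment)
}

#' @rdname simulate_assay
#' @return `simulate_dilution_series()`: list of assays, one per
#'   `config$dilutions` entry (distinct derived seeds).
#' @export
simulate_dilution_series <- function(config, chemistry,
                                     thermo = thermo_profile(),
                                     sample_id = NULL, seed = config$seed) {
  lapply(seq_along(config$dilutions), function(i)
    simulate_assay(config, chemistry, dilution = config$dilutions[i],
                   thermo = thermo, sample_id = sample_id,
                   seed = seed + i - 1L))
}

# smooth AR(1) log-multiplier time series, one per cell
.ar1_lognoise <- function(n_cell, n_time, rho = 0.8, sd_log = 0.4) {
  x <- matrix(rnorm(n_cell * n_time), n_cell, n_time)
  for (t in seq_len(n_time)[-1])
    x[, t] <- rho * x[, t - 1] + sqrt(1 - rho^2) * x[, t]
  exp(sd_log * x - sd_log^2 / 2)
}

#' Generate synthetic gridded aerosol fields
#'
#' Seeded statistical stand-in for a chemistry-transport model's lowermost
#' layer: sea salt elevated over ocean cells with a storm-belt latitude
#' profile; dust as plumes decaying (1/e scale 2000 km) from land source
#' cells, hemispherically asymmetric with stronger northern sources; smooth
#' lognormal AR(1) variability in time; mode number concentrations derived
#' from the masses through the mode geometry (so surface-area inversion is
#' exact by construction).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return an [aerosol_fields()].
#' @export
generate_fields <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed + 1000L)
  nlat <- config$grid_shape[1]; nlon <- config$grid_shape[2]
  lat <- seq(-90 + 90 / nlat, 90 - 90 / nlat, length.out = nlat)
  lon <- seq(-180 + 180 / nlon, 180 - 180 / nlon, length.out = nlon)
  nt <- config$n_timesteps
  time <- seq(0, by = config$timestep_hours, length.out = nt)
  cells <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
  n_cell <- nrow(cells)

  # synthetic continents: land within a radius of seeded centres, biased
  # to the northern hemisphere
  centres <- data.frame(
    lat = c(runif(3, 10, 65), runif(1, -60, -15)),
    lon = runif(4, -180, 180),
    radius_km = runif(4, 2200, 4200))
  land <- rep(FALSE, n_cell)
  for (s in seq_len(nrow(centres)))
    land <- land | .haversine_km(centres$lat[s], centres$lon[s],
                                 cells$lat, cells$lon) < centres$radius_km[s]
  ocean <- matrix(!land, nlat, nlon)

  # sea salt mass [kg m^-3]: storm-belt latitude profile over ocean
  belt <- 0.4 + 0.6 * exp(-((abs(cells$lat) - 50) / 18)^2)
  ss_base <- 2e-9 * belt * as.vector(ocean)
  ss_t <- .ar1_lognoise(n_cell, nt, rho = 0.85, sd_log = 0.35)
  ss <- array(ss_base * ss_t, c(nlat, nlon, nt))

  # dust mass: plumes from land sources, mostly northern
  n_src_n <- 2; n_src_s <- 1
  land_cells <- which(land)
  north_land <- land_cells[cells$lat[land_cells] > 5]
  south_land <- land_cells[cells$lat[land_cells] < -5]
  pick <- function(pool, n, fallback)
    if (length(pool) >= n) sample(pool, n) else fallback
  src_n <- pick(north_land, n_src_n, land_cells[seq_len(
    min(n_src_n, length(land_cells)))])
  src_s <- pick(south_land, n_src_s, integer(0))
  dust_base <- rep(1e-13, n_cell)
  for (s in src_n)
    dust_base <- dust_base + 1e-8 *
      exp(-.haversine_km(cells$lat[s], cells$lon[s],
                         cells$lat, cells$lon) / 2000)
  for (s in src_s)
    dust_base <- dust_base + 3e-10 *
      exp(-.haversine_km(cells$lat[s], cells$lon[s],
                         cells$lat, cells$lon) / 2000)
  dust_t <- .ar1_lognoise(n_cell, nt, rho = 0.7, sd_log = 0.7)
  dust <- array(dust_base * dust_t, c(nlat, nlon, nt))

  modes <- default_modes()
  num_from_mass <- function(mass, d_g, mode)
    mass / (pi / 6 * mode$density * d_g^3 * exp(4.5 * log(mode$sigma_g)^2))
  vars <- list(
    seasalt_mass_accu = ss * 0.08,
    seasalt_mass_coarse = ss * 0.92,
    dust_mass_accu = dust * 0.15,
    dust_mass_coarse = dust * 0.85)
  vars$num_seasalt_accu <- num_from_mass(vars$seasalt_mass_accu, 0.2e-6,
                                         modes$seasalt_accu)
  vars$num_seasalt_coarse <- num_from_mass(vars$seasalt_mass_coarse, 2e-6,
                                           modes$seasalt_coarse)
  vars$num_dust_accu <- num_from_mass(vars$dust_mass_accu, 0.3e-6,
                                      modes$dust_accu)
  vars$num_dust_coarse <- num_from_mass(vars$dust_mass_coarse, 2e-6,
                                        modes$dust_coarse)
  aerosol_fields(lat, lon, time, vars, ocean, modes)
}

#' Generate synthetic INP observation records
#'
#' Samples ocean cells and evaluated activation temperatures (uniformly over
#' the scenario temperatures inside the window - observations land exactly
#' on evaluated temperatures so that noise-free records reproduce the model
#' truth), takes the chosen model variant as truth, and perturbs it with
#' lognormal noise `exp(N(0, obs_noise_sigma))`.
#'
#' @param inpf an [inp_fields()] supplying the truth.
#' @param config a [sim_config()] (noise level, record count).
#' @param truth model variant used as truth: `"n15_hsz25"`, `"n15"` or
#'   `"n15_m18"`.
#' @param t_window window \[K\] from which activation temperatures are
#'   drawn.
#' @param seed RNG seed (default `config$seed`).
#' @return an `"inp_observations"` data frame (5 synthetic campaigns
#'   assigned by latitude band).
#' @export
generate_observations <- function(inpf, config, truth = "n15_hsz25",
                                  t_window = celsius_to_kelvin(c(-20, -15)),
                                  seed = config$seed) {
  stopifnot(inherits(inpf, "inp_fields"))
  truth <- match.arg(truth, c("n15_hsz25", "n15", "n15_m18"))
  if (!is.null(seed)) set.seed(seed + 2000L)
  temps <- inpf$temperatures
  temps <- temps[temps >= min(t_window) - 1e-9 &
                 temps <= max(t_window) + 1e-9]
  if (length(temps) == 0)
    stop("no evaluated activation temperatures inside the window")
  ocean_idx <- which(inpf$land_sea_mask, arr.ind = TRUE)
  n <- config$n_observations
  pick_cell <- ocean_idx[sample.int(nrow(ocean_idx), n, replace = TRUE), ,
                         drop = FALSE]
  t_pick <- temps[sample.int(length(temps), n, replace = TRUE)]
  k <- match(t_pick, inpf$temperatures)
  base <- switch(truth,
    n15 = inpf$dust,
    n15_hsz25 = inpf$dust + inpf$poly,
    n15_m18 = {
      if (is.null(inpf$m18)) stop("inp fields lack the M18 scheme")
      inpf$dust + inpf$m18
    })
  tru <- base[cbind(pick_cell[, 1], pick_cell[, 2], k)]
  noise <- if (config$obs_noise_sigma > 0)
    exp(rnorm(n, 0, config$obs_noise_sigma)) else rep(1, n)
  lat <- inpf$lat[pick_cell[, 1]]
  campaign <- paste0("SYN-", cut(lat, c(-91, -45, -10, 10, 45, 91),
                                 labels = c("SO", "STS", "TR", "STN", "AR")))
  observation_records(
    campaign = campaign, lat = lat, lon = inpf$lon[pick_cell[, 2]],
    time = sample(seq_len(config$n_timesteps), n, replace = TRUE),
    activation_temperature = t_pick, inp_conc = tru * noise)
}

#' Run the full synthetic end-to-end pipeline
#'
#' simulate assays -> reduce to spectra -> fit the CNT model -> generate
#' aerosol fields -> apply the three INP parametrizations -> generate
#' observations -> evaluate. Deterministic under a fixed seed.
#'
#' @param seed integer seed.
#' @param config a [sim_config()]; its seed is overridden by `seed`.
#' @param scenario an [inp_scenario()].
#' @param thermo a [thermo_profile()].
#' @return list with elements `config`, `chemistry`, `assays`, `spectra`,
#'   `fit`, `fields`, `inp`, `observations`, `evaluation`, `share_minus15`
#'   (share map at the warmest evaluated temperature), `share_by_temp`
#'   (ocean-mean share per activation temperature).
#' @export
run_demo_pipeline <- function(seed = 1L, config = NULL,
                              scenario = inp_scenario(),
                              thermo = thermo_profile()) {
  config <- config %||% sim_config(seed = seed)
  chemistry <- sample_chemistry("sim-organism", c_tccho = 1e-3, toc = 2.5e-3)
  assays <- simulate_dilution_series(config, chemistry, thermo)
  spectra <- lapply(assays, assay_spectrum, chemistry = chemistry,
                    basis = "c_tccho",
                    temperature_grid = config$temperature_grid)
  fit <- cnt_fit(assays, chemistry, basis = "c_tccho", thermo = thermo,
                 temperature_grid = config$temperature_grid,
                 seed = config$seed)
  fields <- generate_fields(config)
  inp <- inp_fields(fields, scenario, hsz25 = fit$params, thermo = thermo)
  observations <- generate_observations(inp, config)
  evaluation <- evaluate_inp(observations, inp)
  ocean <- inp$land_sea_mask
  share_by_temp <- vapply(inp$temperatures, function(T) {
    s <- polysaccharide_share(inp, T)
    mean(s[ocean], na.rm = TRUE)
  }, numeric(1))
  names(share_by_temp) <- sprintf("%.0fC", kelvin_to_celsius(
    inp$temperatures))
  list(config = config, chemistry = chemistry, assays = assays,
       spectra = spectra, fit = fit, fields = fields, inp = inp,
       observations = observations, evaluation = evaluation,
       share_minus15 = polysaccharide_share(inp, inp$temperatures[1]),
       share_by_temp = share_by_temp)
}
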