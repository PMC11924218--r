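# Gridded application: hold hourly (or coarser) aerosol fields, derive
# polysaccharide mass, apply the three INP parametrizations per time step,
# average over the record, and map the polysaccharide share of the INP
# population. Only the lowermost model layer is represented.

.field_vars <- c("seasalt_mass_accu", "seasalt_mass_coarse",
                 "dust_mass_accu", "dust_mass_coarse",
                 "num_seasalt_accu", "num_seasalt_coarse",
                 "num_dust_accu", "num_dust_coarse")

#' Gridded aerosol fields
#'
#' Container for lowermost-layer aerosol fields on a regular lat/lon grid:
#' per-mode sea salt and mineral dust mass \[kg m^-3\], mode number
#' concentrations \[m^-3\], and a land/sea mask. Arrays are
#' `(lat, lon, time)`.
#'
#' @param lat,lon cell-centre coordinates \[deg\], ascending.
#' @param time time stamps (numeric hours or POSIXct).
#' @param vars named list of arrays `(nlat, nlon, ntime)`; required names:
#'   `seasalt_mass_accu`, `seasalt_mass_coarse`, `dust_mass_accu`,
#'   `dust_mass_coarse`, `num_seasalt_accu`, `num_seasalt_coarse`,
#'   `num_dust_accu`, `num_dust_coarse`.
#' @param land_sea_mask logical `(nlat, nlon)` matrix, `TRUE` = ocean.
#' @param modes list of [mode_spec()]s, defaults [default_modes()].
#' @return object of class `"aerosol_fields"`.
#' @export
aerosol_fields <- function(lat, lon, time, vars, land_sea_mask,
                           modes = default_modes()) {
  miss <- setdiff(.field_vars, names(vars))
  if (length(miss))
    stop("missing field variable(s): ", paste(miss, collapse = ", "))
  dims <- c(length(lat), length(lon), length(time))
  for (v in .field_vars) {
    a <- vars[[v]]
    if (!identical(dim(a), as.integer(dims)))
      stop(sprintf("variable '%s' has inconsistent shape", v))
    if (any(a < 0, na.rm = TRUE))
      stop(sprintf("variable '%s' has negative values", v))
  }
  stopifnot(is.logical(land_sea_mask),
            identical(dim(land_sea_mask), as.integer(dims[1:2])))
  structure(list(lat = lat, lon = lon, time = time, vars = vars,
                 land_sea_mask = land_sea_mask, modes = modes),
            class = "aerosol_fields")
}

#' @export
print.aerosol_fields <- function(x, ...) {
  cat(sprintf(
    "Aerosol fields: %d x %d grid, %d time steps, %.0f%% ocean\n",
    length(x$lat), length(x$lon), length(x$time),
    100 * mean(x$land_sea_mask)))
  invisible(x)
}

#' Scenario configuration for the polysaccharide INP application
#'
#' Polysaccharide mass fractions of sea salt per mode (defaults 0.5 % of the
#' soluble accumulation mode and 0.1 % of the coarse mode, with 0.05 % /
#' 0.5 % in both modes as lower and upper bound scenarios), the
#' polysaccharide-to-carbon conversion, and the activation temperatures at
#' which INP fields are evaluated.
#'
#' @param poly_fraction_accumulation,poly_fraction_coarse polysaccharide
#'   mass fraction of the sea salt mass per mode, in `[0, 1]`.
#' @param carbon_fraction carbon mass fraction of polysaccharide.
#' @param temperatures activation temperatures \[K\].
#' @param tag free-text scenario tag carried into reports.
#' @return object of class `"inp_scenario"`.
#' @export
inp_scenario <- function(poly_fraction_accumulation = 0.005,
                         poly_fraction_coarse = 0.001,
                         carbon_fraction = 0.40,
                         temperatures =
                           celsius_to_kelvin(c(-15, -17, -19, -21, -23, -25)),
                         tag = "default") {
  stopifnot(poly_fraction_accumulation >= 0,
            poly_fraction_accumulation <= 1,
            poly_fraction_coarse >= 0, poly_fraction_coarse <= 1)
  structure(list(poly_fraction_accumulation = poly_fraction_accumulation,
                 poly_fraction_coarse = poly_fraction_coarse,
                 carbon_fraction = carbon_fraction,
                 temperatures = sort(temperatures, decreasing = TRUE),
                 tag = tag),
            class = "inp_scenario")
}

#' @rdname inp_scenario
#' @param bound `"low"` (0.05 % both modes) or `"high"` (0.5 % both modes).
#' @export
scenario_bounds <- function(bound = c("low", "high"), ...) {
  bound <- match.arg(bound)
  f <- if (bound == "low") 0.0005 else 0.005
  inp_scenario(poly_fraction_accumulation = f, poly_fraction_coarse = f,
               tag = paste0("bound_", bound), ...)
}

#' Gridded polysaccharide mass per mode
#'
#' Sea salt mass times the per-mode polysaccharide fraction; co-emission
#' with sea salt is implicit in the mass-fraction formulation.
#'
#' @param fields an [aerosol_fields()].
#' @param scenario an [inp_scenario()].
#' @return list of arrays `accu`, `coarse` \[kg m^-3\].
#' @export
polysaccharide_mass_field <- function(fields, scenario) {
  stopifnot(inherits(fields, "aerosol_fields"),
            inherits(scenario, "inp_scenario"))
  list(accu = fields$vars$seasalt_mass_accu *
         scenario$poly_fraction_accumulation,
       coarse = fields$vars$seasalt_mass_coarse *
         scenario$poly_fraction_coarse)
}

#' Time-mean gridded INP concentrations per scheme
#'
#' Applies, per time step and grid cell, the dust surface scheme (N15-style)
#' to dust surface area, the polysaccharide scheme (HSZ25-style) to
#' polysaccharide mass, and optionally the sea-spray surface scheme (M18) to
#' sea salt surface area, then averages over the record per cell and
#' activation temperature. Sea-salt-derived INP (polysaccharide and M18) are
#' zero over land; dust INP is kept everywhere.
#'
#' @param fields an [aerosol_fields()].
#' @param scenario an [inp_scenario()].
#' @param hsz25 fitted [cnt_params()] on the c_tccho basis.
#' @param n15,m18 [n15_profile()] / [m18_profile()] (set `m18 = NULL` to
#'   skip the comparison scheme).
#' @param thermo a [thermo_profile()].
#' @return object of class `"inp_fields"`: arrays `dust`, `poly`, `m18`
#'   (each `(nlat, nlon, n_temperature)` \[per litre air\]) plus grid
#'   metadata.
#' @export
inp_fields <- function(fields, scenario = inp_scenario(),
                       hsz25 = hsz25_params(), n15 = n15_profile(),
                       m18 = m18_profile(), thermo = thermo_profile()) {
  stopifnot(inherits(fields, "aerosol_fields"),
            inherits(scenario, "inp_scenario"))
  temps <- scenario$temperatures
  v <- fields$vars
  modes <- fields$modes

  s_dust <- mode_surface_area(v$dust_mass_accu, v$num_dust_accu,
                              modes$dust_accu) +
    mode_surface_area(v$dust_mass_coarse, v$num_dust_coarse,
                      modes$dust_coarse)
  s_salt <- mode_surface_area(v$seasalt_mass_accu, v$num_seasalt_accu,
                              modes$seasalt_accu) +
    mode_surface_area(v$seasalt_mass_coarse, v$num_seasalt_coarse,
                      modes$seasalt_coarse)
  poly <- polysaccharide_mass_field(fields, scenario)
  poly_mass <- poly$accu + poly$coarse

  ocean <- fields$land_sea_mask
  nlat <- length(fields$lat); nlon <- length(fields$lon)
  nT <- length(temps)
  dims <- c(nlat, nlon, nT)
  dust_out <- array(0, dims); poly_out <- array(0, dims)
  m18_out <- if (is.null(m18)) NULL else array(0, dims)

  # site densities are scalar in T, so the per-time-step application and
  # time averaging reduce to n_s(T) x time-mean(proxy); proxies are averaged
  # once and each scheme applied per activation temperature
  mean_t <- function(a) apply(a, c(1, 2), mean)
  s_dust_m <- mean_t(s_dust)
  s_salt_m <- mean_t(s_salt) * ocean   # sea-salt INP masked over land
  poly_m <- mean_t(poly_mass) * ocean

  n_m_poly <- hsz25$n_max *
    site_activation_probability(temps, hsz25, thermo)
  n_s_dust <- surface_site_density(n15, temps, thermo)
  for (k in seq_len(nT)) {
    dust_out[, , k] <- s_dust_m * n_s_dust[k] / 1000
    poly_out[, , k] <- poly_m * 1000 * scenario$carbon_fraction *
      n_m_poly[k] / 1000
    if (!is.null(m18))
      m18_out[, , k] <- s_salt_m *
        surface_site_density(m18, temps[k], thermo) / 1000
  }
  structure(list(lat = fields$lat, lon = fields$lon,
                 temperatures = temps, dust = dust_out, poly = poly_out,
                 m18 = m18_out, land_sea_mask = ocean,
                 scenario = scenario),
            class = "inp_fields")
}

#' @export
print.inp_fields <- function(x, ...) {
  cat(sprintf(
    "Time-mean INP fields: %d x %d grid, %d activation temperatures (%s C)\n",
    length(x$lat), length(x$lon), length(x$temperatures),
    paste(round(kelvin_to_celsius(x$temperatures), 1), collapse = ", ")))
  cat(sprintf("  scenario: %s (poly fractions %.2g%% accu / %.2g%% coarse)\n",
              x$scenario$tag, 100 * x$scenario$poly_fraction_accumulation,
              100 * x$scenario$poly_fraction_coarse))
  invisible(x)
}

#' Polysaccharide share of the modeled INP population
#'
#' `100 * poly / (poly + dust)` per grid cell at one activation temperature;
#' cells where both schemes give zero are masked (`NA`).
#'
#' @param inpf an [inp_fields()].
#' @param T activation temperature \[K\] (must be one of the evaluated
#'   temperatures).
#' @return `(nlat, nlon)` matrix of percent shares.
#' @export
polysaccharide_share <- function(inpf, T) {
  stopifnot(inherits(inpf, "inp_fields"))
  k <- match(TRUE, abs(inpf$temperatures - T) < 1e-6)
  if (is.na(k)) stop("T is not one of the evaluated activation temperatures")
  dust <- inpf$dust[, , k]
  poly <- inpf$poly[, , k]
  tot <- dust + poly
  share <- 100 * poly / tot
  share[tot == 0] <- NA_real_
  share
}

# ---- plain-text gridded interchange --------------------------------------

#' Read/write aerosol fields as long-format CSV
#'
#' Plain-text interchange dialect for the gridded fields: one row per
#' (variable, lat, lon, time) with columns `var`, `lat`, `lon`, `time`,
#' `value`; the land/sea mask travels as variable `"ocean_mask"` at the
#' first time stamp. `write_aerosol_csv()` and `read_aerosol_csv()` are
#' exact inverses.
#'
#' @param fields an [aerosol_fields()].
#' @param path CSV path.
#' @return `read_aerosol_csv()` returns an [aerosol_fields()];
#'   `write_aerosol_csv()` returns `path` invisibly.
#' @export
write_aerosol_csv <- function(fields, path) {
  stopifnot(inherits(fields, "aerosol_fields"))
  grid <- expand.grid(lat = fields$lat, lon = fields$lon,
                      time = fields$time, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(.field_vars, function(v)
    data.frame(var = v, grid, value = as.vector(fields$vars[[v]])))
  mask_rows <- data.frame(var = "ocean_mask",
                          expand.grid(lat = fields$lat, lon = fields$lon,
                                      KEEP.OUT.ATTRS = FALSE),
                          time = fields$time[1],
                          value = as.numeric(fields$land_sea_mask))
  write.csv(rbind(do.call(rbind, rows), mask_rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aerosol_csv
#' @export
read_aerosol_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  time <- sort(unique(df$time[df$var != "ocean_mask"]))
  dims <- c(length(lat), length(lon), length(time))
  vars <- lapply(.field_vars, function(v) {
    g <- df[df$var == v, ]
    a <- array(NA_real_, dims)
    a[cbind(match(g$lat, lat), match(g$lon, lon), match(g$time, time))] <-
      g$value
    a
  })
  names(vars) <- .field_vars
  m <- df[df$var == "ocean_mask", ]
  mask <- matrix(FALSE, dims[1], dims[2])
  mask[cbind(match(m$lat, lat), match(m$lon, lon))] <- m$value > 0.5
  aerosol_fields(lat, lon, time, vars, mask)
}

#' Write time-mean INP fields to CSV
#'
#' One row per (scheme, activation temperature, cell): `scheme`, `temp_C`,
#' `lat`, `lon`, `inp_per_L`.
#'
#' @param inpf an [inp_fields()].
#' @param path CSV path.
#' @export
write_inp_csv <- function(inpf, path) {
  stopifnot(inherits(inpf, "inp_fields"))
  grid <- expand.grid(lat = inpf$lat, lon = inpf$lon,
                      temp_K = inpf$temperatures, KEEP.OUT.ATTRS = FALSE)
  schemes <- c(dust = "N15", poly = "HSZ25", m18 = "M18")
  rows <- lapply(names(schemes), function(s) {
    if (is.null(inpf[[s]])) return(NULL)
    data.frame(scheme = schemes[[s]],
               temp_C = kelvin_to_celsius(grid$temp_K),
               lat = grid$lat, lon = grid$lon,
               inp_per_L = as.vector(inpf[[s]]))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.inp_fields <- function(x, T = x$temperatures[1], ...) {
  share <- polysaccharide_share(x, T)
  image(x$lon, x$lat, t(share), col = hcl.colors(24, "viridis"),
        xlab = "lon", ylab = "lat",
        main = sprintf("polysaccharide INP share [%%] at %.1f C",
                       kelvin_to_celsius(T)), ...)
  invisible(x)
}
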