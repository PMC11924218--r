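# Model-vs-observation evaluation: pair INP observation records with the
# nearest grid cell and nearest evaluated activation temperature, compute
# factor-of-N agreement fractions per model variant, and the fraction of the
# factor-of-10 improvement explained by the polysaccharide scheme.

#' Construct/validate INP observation records
#'
#' @param campaign campaign labels.
#' @param lat,lon coordinates \[deg\].
#' @param time time stamps (any comparable type).
#' @param activation_temperature activation temperature \[K\], < 273.15.
#' @param inp_conc observed INP concentration \[per litre air\], >= 0.
#' @param marine_flag logical, predominantly marine air mass.
#' @return data frame of class `"inp_observations"`.
#' @export
observation_records <- function(campaign, lat, lon, time,
                                activation_temperature, inp_conc,
                                marine_flag = TRUE) {
  stopifnot(all(inp_conc >= 0), all(activation_temperature < 273.15),
            all(abs(lat) <= 90))
  df <- data.frame(campaign = as.character(campaign), lat = lat, lon = lon,
                   time = time,
                   activation_temperature = activation_temperature,
                   inp_conc = inp_conc, marine_flag = marine_flag,
                   stringsAsFactors = FALSE)
  class(df) <- c("inp_observations", "data.frame")
  df
}

#' Read INP observations from CSV
#'
#' Columns: `campaign`, `lat`, `lon`, `time_iso`, `activation_temp_C`,
#' `inp_per_L`, `marine_flag`.
#'
#' @param path CSV path.
#' @return an `"inp_observations"` data frame.
#' @export
read_observations_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  observation_records(df$campaign, df$lat, df$lon, df$time_iso,
                      celsius_to_kelvin(df$activation_temp_C),
                      df$inp_per_L,
                      if (is.null(df$marine_flag)) TRUE
                      else as.logical(df$marine_flag))
}

#' @rdname read_observations_csv
#' @param obs an `"inp_observations"` data frame.
#' @export
write_observations_csv <- function(obs, path) {
  out <- data.frame(campaign = obs$campaign, lat = obs$lat, lon = obs$lon,
                    time_iso = obs$time,
                    activation_temp_C =
                      kelvin_to_celsius(obs$activation_temperature),
                    inp_per_L = obs$inp_conc,
                    marine_flag = obs$marine_flag)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# great-circle distance [km] between one point and vectors of points
.haversine_km <- function(lat1, lon1, lat2, lon2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Pair observations with time-mean model INP values
#'
#' Each observation whose activation temperature lies in the window is
#' paired with the model value at the great-circle-nearest grid cell and the
#' nearest evaluated activation temperature (within `t_match_tol`, else
#' skipped). Annual/time-mean model values are deliberately compared with
#' instantaneous observations: in remote marine regions the proxies'
#' short-term variability averages out.
#'
#' @param obs an `"inp_observations"` data frame.
#' @param inpf an [inp_fields()] (with the M18 comparison scheme for the
#'   three-variant evaluation).
#' @param t_window temperature window \[K\], `c(cold, warm)`; default the
#'   -20 to -15 C band.
#' @param t_match_tol maximum |T_obs - T_model| \[K\] for a pair.
#' @return data frame of pairs with model variants `n15`, `n15_hsz25` and
#'   (if available) `n15_m18`; skipped-record counts in attributes
#'   `n_outside_window` and `n_no_temperature_match`.
#' @export
match_pairs <- function(obs, inpf,
                        t_window = celsius_to_kelvin(c(-20, -15)),
                        t_match_tol = 0.5) {
  stopifnot(inherits(inpf, "inp_fields"), length(t_window) == 2)
  t_window <- sort(t_window)
  in_win <- obs$activation_temperature >= t_window[1] - 1e-9 &
    obs$activation_temperature <= t_window[2] + 1e-9
  kept <- obs[in_win, , drop = FALSE]
  n_outside <- sum(!in_win)

  if (nrow(kept) == 0) {
    out <- data.frame(campaign = character(), lat = numeric(),
                      lon = numeric(), activation_temperature = numeric(),
                      observed = numeric(), n15 = numeric(),
                      n15_hsz25 = numeric(), n15_m18 = numeric(),
                      cell_lat = numeric(), cell_lon = numeric(),
                      model_temp = numeric())
    attr(out, "n_outside_window") <- n_outside
    attr(out, "n_no_temperature_match") <- 0L
    return(out)
  }

  cells <- expand.grid(i = seq_along(inpf$lat), j = seq_along(inpf$lon),
                       KEEP.OUT.ATTRS = FALSE)
  cell_lat <- inpf$lat[cells$i]; cell_lon <- inpf$lon[cells$j]

  rows <- vector("list", nrow(kept))
  n_no_t <- 0L
  for (r in seq_len(nrow(kept))) {
    dt <- abs(inpf$temperatures - kept$activation_temperature[r])
    k <- which.min(dt)
    if (dt[k] > t_match_tol + 1e-9) { n_no_t <- n_no_t + 1L; next }
    d <- .haversine_km(kept$lat[r], kept$lon[r], cell_lat, cell_lon)
    c_idx <- which.min(d)
    i <- cells$i[c_idx]; j <- cells$j[c_idx]
    rows[[r]] <- data.frame(
      campaign = kept$campaign[r], lat = kept$lat[r], lon = kept$lon[r],
      activation_temperature = kept$activation_temperature[r],
      observed = kept$inp_conc[r],
      n15 = inpf$dust[i, j, k],
      n15_hsz25 = inpf$dust[i, j, k] + inpf$poly[i, j, k],
      n15_m18 = if (is.null(inpf$m18)) NA_real_
                else inpf$dust[i, j, k] + inpf$m18[i, j, k],
      cell_lat = inpf$lat[i], cell_lon = inpf$lon[j],
      model_temp = inpf$temperatures[k])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "n_outside_window") <- n_outside
  attr(out, "n_no_temperature_match") <- n_no_t
  out
}

#' Factor-of-N agreement fraction
#'
#' Fraction of (observed, modeled) pairs whose symmetric ratio
#' `max(m/o, o/m)` is at most `factor` (a ratio exactly equal to the factor
#' counts as within). Pairs with a zero on either side are excluded from the
#' ratio and counted separately: the metric is undefined at zero.
#'
#' @param observed,modeled positive concentration vectors of equal length.
#' @param factor agreement factor (> 1), e.g. 2 or 10.
#' @return fraction in `[0, 1]` (NA if no usable pairs, with a warning);
#'   attributes `n_used` and `n_excluded`.
#' @export
fac_fraction <- function(observed, modeled, factor) {
  stopifnot(length(observed) == length(modeled), factor > 1)
  ok <- is.finite(observed) & is.finite(modeled) &
    observed > 0 & modeled > 0
  n_excluded <- sum(!ok)
  if (!any(ok)) {
    warning("no pairs with positive observed and modeled values")
    return(structure(NA_real_, n_used = 0L, n_excluded = n_excluded))
  }
  ratio <- pmax(modeled[ok] / observed[ok], observed[ok] / modeled[ok])
  structure(mean(ratio <= factor * (1 + 1e-12)),
            n_used = sum(ok), n_excluded = n_excluded)
}

#' Fraction of improved factor-of-10 agreement explained by polysaccharides
#'
#' `F = (FAC10_N15+HSZ25 - FAC10_N15) / (FAC10_N15+M18 - FAC10_N15)`: how
#' much of the agreement gained by adding the sea-spray surface scheme (M18)
#' on top of dust-only is recovered when the added marine INPs are instead
#' attributed to polysaccharides alone. May exceed 1.
#'
#' @param fac10_n15 factor-of-10 fraction, dust-only variant.
#' @param fac10_n15_m18 dust + sea-spray-surface variant.
#' @param fac10_n15_hsz25 dust + polysaccharide variant.
#' @return dimensionless fraction; `NA` with a warning when the M18 variant
#'   added no agreement (denominator <= 0).
#' @export
improvement_fraction <- function(fac10_n15, fac10_n15_m18,
                                 fac10_n15_hsz25) {
  stopifnot(all(c(fac10_n15, fac10_n15_m18, fac10_n15_hsz25) >= 0),
            all(c(fac10_n15, fac10_n15_m18, fac10_n15_hsz25) <= 1))
  den <- fac10_n15_m18 - fac10_n15
  if (den <= 0) {
    warning("M18 variant added no factor-of-10 agreement; ",
            "improvement fraction undefined")
    return(NA_real_)
  }
  (fac10_n15_hsz25 - fac10_n15) / den
}

#' Evaluate modeled INP fields against observations
#'
#' Runs [match_pairs()], computes FAC2/FAC10 per model variant and the
#' improvement fraction, optionally stratified by campaign.
#'
#' @inheritParams match_pairs
#' @param factors agreement factors to evaluate.
#' @param by_campaign also compute per-campaign FAC10 tables.
#' @return object of class `"inp_eval"` with `n_pairs`, `fac` (matrix
#'   variant x factor), `improvement_fraction`, `window`, `scenario_tag`,
#'   `pairs`.
#' @export
evaluate_inp <- function(obs, inpf,
                         t_window = celsius_to_kelvin(c(-20, -15)),
                         factors = c(2, 10), by_campaign = FALSE) {
  pairs <- match_pairs(obs, inpf, t_window)
  variants <- c("n15", "n15_hsz25", "n15_m18")
  variants <- variants[variants %in% names(pairs)]
  if (!is.null(pairs$n15_m18) && all(is.na(pairs$n15_m18)))
    variants <- setdiff(variants, "n15_m18")
  fac <- matrix(NA_real_, length(variants), length(factors),
                dimnames = list(variants, paste0("fac", factors)))
  if (nrow(pairs) > 0)
    for (v in variants) for (fi in seq_along(factors))
      fac[v, fi] <- as.numeric(
        fac_fraction(pairs$observed, pairs[[v]], factors[fi]))
  impr <- if (all(c("n15", "n15_m18", "n15_hsz25") %in% variants) &&
              10 %in% factors && nrow(pairs) > 0) {
    tryCatch(improvement_fraction(fac["n15", "fac10"],
                                  fac["n15_m18", "fac10"],
                                  fac["n15_hsz25", "fac10"]),
             warning = function(w) NA_real_)
  } else NA_real_
  by_c <- NULL
  if (by_campaign && nrow(pairs) > 0) {
    by_c <- do.call(rbind, lapply(split(pairs, pairs$campaign), function(g)
      data.frame(campaign = g$campaign[1], n = nrow(g),
                 fac10_n15 = as.numeric(
                   fac_fraction(g$observed, g$n15, 10)),
                 fac10_n15_hsz25 = as.numeric(
                   fac_fraction(g$observed, g$n15_hsz25, 10)))))
  }
  structure(list(n_pairs = nrow(pairs), fac = fac,
                 improvement_fraction = impr, window = t_window,
                 scenario_tag = inpf$scenario$tag, pairs = pairs,
                 by_campaign = by_c,
                 n_outside_window = attr(pairs, "n_outside_window"),
                 n_no_temperature_match =
                   attr(pairs, "n_no_temperature_match")),
            class = "inp_eval")
}

#' @export
print.inp_eval <- function(x, ...) {
  cat(sprintf(
    "INP evaluation: %d pairs in window %.1f..%.1f C (scenario %s)\n",
    x$n_pairs, kelvin_to_celsius(x$window[1]),
    kelvin_to_celsius(x$window[2]), x$scenario_tag))
  cat(sprintf("  skipped: %d outside window, %d without temperature match\n",
              x$n_outside_window, x$n_no_temperature_match))
  print(round(x$fac, 3))
  if (!is.na(x$improvement_fraction))
    cat(sprintf(
      "  fraction of FAC10 improvement explained by polysaccharides: %.2f\n",
      x$improvement_fraction))
  invisible(x)
}
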