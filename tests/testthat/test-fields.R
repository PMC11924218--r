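# Gridded application: polysaccharide mass fields, time-mean INP fields,
# share maps, and the plain-text interchange format.

small_fields <- function(seed = 5, nlat = 6, nlon = 8, nt = 10) {
  cfg <- sim_config(seed = seed, grid_shape = c(nlat, nlon),
                    n_timesteps = nt)
  generate_fields(cfg)
}

test_that("polysaccharide mass is sea salt mass times the mode fraction", {
  fl <- small_fields()
  sc <- inp_scenario()
  pm <- polysaccharide_mass_field(fl, sc)
  expect_equal(pm$accu, fl$vars$seasalt_mass_accu * 0.005)
  expect_equal(pm$coarse, fl$vars$seasalt_mass_coarse * 0.001)
  # 1e-9 kg/m3 at 0.5 % -> 5e-12 kg/m3
  expect_equal(0.005 * 1e-9, 5e-12)
  sc0 <- inp_scenario(poly_fraction_accumulation = 0,
                      poly_fraction_coarse = 0)
  pm0 <- polysaccharide_mass_field(fl, sc0)
  expect_true(all(pm0$accu == 0) && all(pm0$coarse == 0))
  expect_error(inp_scenario(poly_fraction_accumulation = 1.2), "<= 1")
  # bound scenarios order the mass fields monotonically
  hi <- polysaccharide_mass_field(fl, scenario_bounds("high"))
  lo <- polysaccharide_mass_field(fl, scenario_bounds("low"))
  expect_true(all(hi$accu >= lo$accu) && all(hi$coarse >= lo$coarse))
})

test_that("INP fields: zero aerosol gives zero INP, schemes are additive,
           and constant fields commute with time averaging", {
  fl <- small_fields()
  zero <- fl
  for (v in names(zero$vars)) zero$vars[[v]][] <- 0
  inp0 <- inp_fields(zero, inp_scenario(), thermo = th_fix)
  expect_true(all(inp0$dust == 0) && all(inp0$poly == 0) &&
                all(inp0$m18 == 0))

  # dust-only field: total INP equals the dust scheme exactly
  dust_only <- fl
  for (v in grep("seasalt", names(fl$vars), value = TRUE))
    dust_only$vars[[v]][] <- 0
  inp_d <- inp_fields(dust_only, inp_scenario(), thermo = th_fix)
  expect_true(all(inp_d$poly == 0) && all(inp_d$m18 == 0))
  expect_true(any(inp_d$dust > 0))

  # constant-in-time fields: the time mean equals the instantaneous value
  const <- fl
  for (v in names(const$vars))
    const$vars[[v]] <- array(const$vars[[v]][, , 1],
                             dim = dim(const$vars[[v]]))
  inp_c <- inp_fields(const, inp_scenario(), thermo = th_fix)
  one_step <- const
  one_step$vars <- lapply(const$vars, function(a) a[, , 1, drop = FALSE])
  one_step$time <- const$time[1]
  inp_1 <- inp_fields(aerosol_fields(one_step$lat, one_step$lon,
                                     one_step$time, one_step$vars,
                                     one_step$land_sea_mask),
                      inp_scenario(), thermo = th_fix)
  expect_equal(inp_c$dust, inp_1$dust, tolerance = 1e-12)
  expect_equal(inp_c$poly, inp_1$poly, tolerance = 1e-12)
})

test_that("sea-salt INP linearity and land masking", {
  fl <- small_fields()
  scaled <- fl
  for (v in c("seasalt_mass_accu", "seasalt_mass_coarse"))
    scaled$vars[[v]] <- 3 * scaled$vars[[v]]
  inp1 <- inp_fields(fl, inp_scenario(), thermo = th_fix)
  inp3 <- inp_fields(scaled, inp_scenario(), thermo = th_fix)
  expect_equal(inp3$poly, 3 * inp1$poly, tolerance = 1e-12)
  # sea-salt-derived INP vanishes over land; dust is kept everywhere
  land <- !fl$land_sea_mask
  if (any(land)) {
    for (k in seq_along(inp1$temperatures)) {
      expect_true(all(inp1$poly[, , k][land] == 0))
      expect_true(all(inp1$m18[, , k][land] == 0))
    }
    expect_true(any(inp1$dust[, , length(inp1$temperatures)][land] > 0))
  }
})

test_that("polysaccharide share map: limits, masking, and the dust
           takeover towards cold temperatures", {
  fl <- small_fields()
  inp <- inp_fields(fl, inp_scenario(), thermo = th_fix)
  share <- polysaccharide_share(inp, inp$temperatures[1])
  expect_true(all(share[!is.na(share)] >= 0 & share[!is.na(share)] <= 100))
  # dust = 0, poly > 0 -> 100 %; poly = dust -> 50 %
  inp_m <- inp
  inp_m$dust[] <- 0
  s100 <- polysaccharide_share(inp_m, inp$temperatures[1])
  ocean <- inp$land_sea_mask
  expect_true(all(abs(s100[ocean][!is.na(s100[ocean])] - 100) < 1e-9))
  inp_eq <- inp
  inp_eq$dust <- inp_eq$poly
  s50 <- polysaccharide_share(inp_eq, inp$temperatures[1])
  expect_true(all(abs(s50[ocean][!is.na(s50[ocean])] - 50) < 1e-9))
  # both zero -> masked
  expect_true(all(is.na(polysaccharide_share(inp0 <- local({
    x <- inp; x$dust[] <- 0; x$poly[] <- 0; x
  }), inp$temperatures[1]))))
  # ocean-mean share declines monotonically with cooling: the dust scheme
  # keeps growing where the polysaccharide scheme saturates
  sh <- vapply(inp$temperatures, function(T)
    mean(polysaccharide_share(inp, T)[ocean], na.rm = TRUE), numeric(1))
  expect_true(all(diff(sh) <= 1e-9))
  expect_error(polysaccharide_share(inp, 300), "evaluated")
})

test_that("aerosol and INP CSV round-trips are exact", {
  fl <- small_fields(seed = 9, nlat = 4, nlon = 5, nt = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_aerosol_csv(fl, tmp)
  back <- read_aerosol_csv(tmp)
  expect_equal(back$lat, fl$lat)
  expect_equal(back$land_sea_mask, fl$land_sea_mask)
  for (v in names(fl$vars))
    expect_equal(back$vars[[v]], fl$vars[[v]], tolerance = 1e-12)
  inp <- inp_fields(fl, inp_scenario(), thermo = th_fix)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_inp_csv(inp, tmp2)
  df <- read.csv(tmp2)
  expect_setequal(unique(df$scheme), c("N15", "HSZ25", "M18"))
  expect_equal(nrow(df), 3 * length(fl$lat) * length(fl$lon) *
                 length(inp$temperatures))
  d1 <- df[df$scheme == "N15" &
             abs(df$temp_C - kelvin_to_celsius(inp$temperatures[1])) <
               1e-9, ]
  expect_equal(sort(d1$inp_per_L), sort(as.vector(inp$dust[, , 1])))
})

test_that("aerosol field container validates shapes and signs", {
  fl <- small_fields(seed = 2, nlat = 3, nlon = 4, nt = 2)
  bad <- fl$vars
  bad$dust_mass_accu <- bad$dust_mass_accu[, , 1, drop = FALSE]
  expect_error(aerosol_fields(fl$lat, fl$lon, fl$time, bad,
                              fl$land_sea_mask), "inconsistent shape")
  bad2 <- fl$vars
  bad2$dust_mass_accu[1, 1, 1] <- -1
  expect_error(aerosol_fields(fl$lat, fl$lon, fl$time, bad2,
                              fl$land_sea_mask), "negative")
  expect_error(aerosol_fields(fl$lat, fl$lon, fl$time,
                              fl$vars[-1], fl$land_sea_mask), "missing")
})
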