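# Model-observation matching, factor-of-N metrics and the improvement
# fraction.

eval_fixture <- function(seed = 13) {
  cfg <- sim_config(seed = seed, grid_shape = c(6, 8), n_timesteps = 8,
                    n_observations = 60)
  fl <- generate_fields(cfg)
  list(cfg = cfg, fl = fl,
       inp = inp_fields(fl, inp_scenario(), thermo = th_fix))
}

test_that("fac_fraction agrees with a brute-force per-pair oracle and is
           symmetric and monotone in the factor", {
  set.seed(17)
  for (rep in 1:5) {
    obs <- 10^runif(200, -4, 0)
    mod <- obs * 10^rnorm(200, 0, 0.8)
    for (fac in c(2, 10)) {
      got <- as.numeric(fac_fraction(obs, mod, fac))
      # oracle: loop every pair explicitly
      within <- logical(200)
      for (i in 1:200)
        within[i] <- max(mod[i] / obs[i], obs[i] / mod[i]) <= fac
      expect_identical(got, mean(within))
      expect_identical(got, as.numeric(fac_fraction(mod, obs, fac)))
    }
    expect_lte(as.numeric(fac_fraction(obs, mod, 2)),
               as.numeric(fac_fraction(obs, mod, 10)))
  }
})

test_that("fac_fraction counts boundary ratios as within and excludes
           zeros", {
  expect_equal(as.numeric(fac_fraction(1, 10, 10)), 1)
  expect_equal(as.numeric(fac_fraction(1, 11, 10)), 0)
  expect_equal(as.numeric(fac_fraction(c(1, 1), c(1, 1), 2)), 1)
  out <- fac_fraction(c(1, 0, 2), c(1, 5, 0), 2)
  expect_equal(as.numeric(out), 1)
  expect_equal(attr(out, "n_used"), 1L)
  expect_equal(attr(out, "n_excluded"), 2L)
  expect_warning(fac_fraction(0, 1, 2), "no pairs")
})

test_that("improvement fraction implements its defining arithmetic", {
  expect_equal(improvement_fraction(0.37, 0.60, 0.52),
               (0.52 - 0.37) / (0.60 - 0.37))
  expect_equal(improvement_fraction(0.37, 0.60, 0.52), 0.652,
               tolerance = 1e-3)
  expect_equal(improvement_fraction(0.3, 0.6, 0.6), 1.0)
  expect_equal(improvement_fraction(0.3, 0.6, 0.3), 0.0)
  # may exceed 1 when polysaccharides outperform the sea-spray scheme
  expect_gt(improvement_fraction(0.3, 0.5, 0.55), 1)
  expect_warning(f <- improvement_fraction(0.5, 0.5, 0.6), "undefined")
  expect_true(is.na(f))
})

test_that("nearest-cell matching agrees with brute-force great-circle
           minimisation", {
  skip_if_not_installed("geosphere")
  fx <- eval_fixture()
  inp <- fx$inp
  set.seed(19)
  n <- 100
  obs <- observation_records(
    campaign = "rnd", lat = runif(n, -88, 88), lon = runif(n, -180, 180),
    time = seq_len(n),
    activation_temperature = celsius_to_kelvin(runif(n, -20, -15)),
    inp_conc = rep(1, n))
  pairs <- match_pairs(obs, inp)
  cells <- expand.grid(lat = inp$lat, lon = inp$lon,
                       KEEP.OUT.ATTRS = FALSE)
  for (r in seq_len(nrow(pairs))) {
    d <- geosphere::distHaversine(cbind(pairs$lon[r], pairs$lat[r]),
                                  cbind(cells$lon, cells$lat))
    best <- which.min(d)
    expect_equal(c(pairs$cell_lat[r], pairs$cell_lon[r]),
                 c(cells$lat[best], cells$lon[best]))
  }
})

test_that("temperature matching honours the window and the 0.5 K
           tolerance", {
  fx <- eval_fixture()
  inp <- fx$inp
  obs <- observation_records(
    campaign = c("a", "a", "a"),
    lat = c(0, 0, 0), lon = c(10, 10, 10), time = 1:3,
    activation_temperature = celsius_to_kelvin(c(-15.2, -16.2, -12)),
    inp_conc = c(1, 1, 1))
  pairs <- match_pairs(obs, inp)
  # -15.2 matches the -15 level; -16.2 is > 0.5 K from both -15 and -17;
  # -12 is outside the window
  expect_equal(nrow(pairs), 1)
  expect_equal(kelvin_to_celsius(pairs$model_temp), -15, tolerance = 1e-9)
  expect_equal(attr(pairs, "n_outside_window"), 1L)
  expect_equal(attr(pairs, "n_no_temperature_match"), 1L)
  # observation exactly at a cell centre and evaluated temperature pairs
  # with that cell
  obs2 <- observation_records("b", inp$lat[3], inp$lon[4], 1,
                              inp$temperatures[2], 1)
  p2 <- match_pairs(obs2, inp)
  expect_equal(c(p2$cell_lat, p2$cell_lon), c(inp$lat[3], inp$lon[4]))
  expect_equal(p2$model_temp, inp$temperatures[2])
  # empty observation set
  p0 <- match_pairs(obs2[0, ], inp)
  expect_equal(nrow(p0), 0)
})

test_that("evaluation closure: observations copied from model truth give
           perfect agreement and a unit improvement fraction", {
  fx <- eval_fixture()
  cfg0 <- fx$cfg
  cfg0$obs_noise_sigma <- 0
  obs <- generate_observations(fx$inp, cfg0, truth = "n15_hsz25")
  ev <- evaluate_inp(obs, fx$inp)
  expect_equal(unname(ev$fac["n15_hsz25", "fac2"]), 1)
  expect_equal(unname(ev$fac["n15_hsz25", "fac10"]), 1)
  expect_true(ev$fac["n15", "fac2"] <= ev$fac["n15", "fac10"])
  # if the M18 variant coincided with the HSZ25 variant, F would be exactly
  # 1; emulate by overwriting the m18 field with the poly field
  inp_same <- fx$inp
  inp_same$m18 <- inp_same$poly
  ev2 <- evaluate_inp(obs, inp_same)
  expect_equal(ev2$improvement_fraction, 1.0)
  # and if HSZ25 added nothing at all, F = 0
  inp_nopoly <- fx$inp
  inp_nopoly$poly[] <- 0
  ev3 <- evaluate_inp(obs, inp_nopoly)
  if (!is.na(ev3$improvement_fraction))
    expect_equal(ev3$improvement_fraction, 0.0)
})

test_that("per-campaign stratification and report printing work", {
  fx <- eval_fixture()
  obs <- generate_observations(fx$inp, fx$cfg)
  ev <- evaluate_inp(obs, fx$inp, by_campaign = TRUE)
  expect_s3_class(ev, "inp_eval")
  expect_equal(ev$n_pairs, nrow(ev$pairs))
  expect_true(!is.null(ev$by_campaign))
  expect_equal(sum(ev$by_campaign$n), ev$n_pairs)
  expect_output(print(ev), "INP evaluation")
})

test_that("observation CSV round-trip preserves records", {
  fx <- eval_fixture()
  obs <- generate_observations(fx$inp, fx$cfg)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_observations_csv(obs, tmp)
  back <- read_observations_csv(tmp)
  expect_equal(back$inp_conc, obs$inp_conc, tolerance = 1e-12)
  expect_equal(back$activation_temperature, obs$activation_temperature,
               tolerance = 1e-9)
  expect_equal(back$campaign, obs$campaign)
})
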