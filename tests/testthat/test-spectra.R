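# Assay reduction: frozen fractions, Vali cumulative spectra, normalisation
# and treatment comparisons.

test_that("frozen fraction counts droplets frozen at or above each grid T", {
  grid <- default_temperature_grid(263.15, 253.15, 1)
  # none frozen / all frozen above the warmest grid point / half frozen
  a0 <- mk_assay(numeric(0), 30)
  expect_equal(frozen_fraction_curve(a0, grid)$frozen_fraction,
               rep(0, length(grid)))
  a1 <- mk_assay(rep(270, 30), 30)
  expect_equal(frozen_fraction_curve(a1, grid)$frozen_fraction,
               rep(1, length(grid)))
  a2 <- mk_assay(c(rep(260.15, 5), rep(240, 2)), 10)
  ff <- frozen_fraction_curve(a2, grid)
  # droplet freezing exactly at a grid T counts as frozen at that T
  expect_equal(ff$frozen_fraction[ff$temp_K == 260.15], 0.5)
  expect_equal(ff$frozen_fraction[ff$temp_K == 261.15], 0)
  # below-grid freezes are not counted anywhere in the grid
  expect_equal(max(ff$frozen_fraction), 0.5)
})

test_that("grid validation rejects empty and non-descending grids", {
  a <- mk_assay(c(260), 10)
  expect_error(frozen_fraction_curve(a, numeric(0)), "empty")
  expect_error(frozen_fraction_curve(a, c(250, 260)), "descending")
  expect_error(default_temperature_grid(250, 260), "t_warm > t_cold")
})

test_that("assay constructor enforces its invariants", {
  expect_error(freezing_assay("x", 1e-6, 1, rep(250, 5), 3), "more freezing")
  expect_error(freezing_assay("x", 1e-6, 1, 274, 10), "below 273.15")
  expect_error(freezing_assay("x", 1e-6, 0.5, 250, 10), "dilution_factor")
  expect_error(freezing_assay("x", -1e-6, 1, 250, 10), "droplet_volume")
  expect_error(sample_chemistry("x", c_tccho = 2, toc = 1), "exceeds toc")
})

test_that("Vali transform, censoring and inversion are exact", {
  grid <- c(262.15, 260.15, 258.15)
  # f = 1 - e^-1 at 1 uL, dilution 1 -> exactly 1e6 INM/L
  n_tot <- 10000
  k <- round((1 - exp(-1)) * n_tot)
  a <- mk_assay(rep(260.15, k), n_tot)
  sp <- cumulative_inm_concentration(frozen_fraction_curve(a, grid))
  expect_equal(sp$n_inm_per_L[1], 0)
  expect_equal(sp$n_inm_per_L[2], -log(1 - k / n_tot) * 1e6)
  expect_equal(sp$n_inm_per_L[2] / 1e6, 1, tolerance = 1e-3)
  expect_false(any(sp$censored))
  # inversion: f = 1 - exp(-n V / dilution) recovers the input fraction
  f_back <- -expm1(-sp$n_inm_per_L * 1e-6)
  expect_equal(f_back, sp$frozen_fraction, tolerance = 1e-12)
  # dilution scaling enters linearly
  a10 <- mk_assay(rep(260.15, k), n_tot, dil = 10)
  sp10 <- cumulative_inm_concentration(frozen_fraction_curve(a10, grid))
  expect_equal(sp10$n_inm_per_L[2], 10 * sp$n_inm_per_L[2])
  # full freezing is censored, finite, and flagged
  af <- mk_assay(rep(270, 10), 10)
  spf <- cumulative_inm_concentration(frozen_fraction_curve(af, grid))
  expect_true(all(spf$censored))
  expect_true(all(is.finite(spf$n_inm_per_L)))
  expect_equal(spf$n_inm_per_L[1], -log(1 - 9.5 / 10) * 1e6)
  # monotone: cumulative concentration nondecreasing with cooling
  expect_true(all(diff(sp$n_inm_per_L) >= 0))
})

test_that("confidence bounds bracket the estimate and are Clopper-Pearson", {
  grid <- default_temperature_grid(263.15, 253.15, 1)
  set.seed(4)
  a <- mk_assay(runif(40, 254, 262), 100)
  sp <- cumulative_inm_concentration(frozen_fraction_curve(a, grid))
  ok <- !sp$censored
  expect_true(all(sp$ci_low[ok] <= sp$n_inm_per_L[ok] + 1e-9))
  expect_true(all(sp$ci_high[ok] >= sp$n_inm_per_L[ok] - 1e-9))
  # spot-check the underlying interval against binom.test
  k <- sp$n_frozen[5]
  bt <- binom.test(k, 100)$conf.int
  cp <- clopper_pearson(k, 100)
  expect_equal(unname(cp[1, ]), c(bt[1], bt[2]), tolerance = 1e-10)
})

test_that("Poisson Monte-Carlo oracle matches the cumulative estimate", {
  # 10,000 droplets each holding Poisson(0.5) INMs all active at T:
  # the estimated concentration must agree with lambda/V within the
  # transformed 95% binomial interval
  set.seed(11)
  lam <- 0.5; V <- 1e-6
  frozen <- rpois(10000, lam) > 0
  grid <- c(262.15, 258.15)
  a <- mk_assay(rep(258.15, sum(frozen)), 10000, V = V)
  sp <- cumulative_inm_concentration(frozen_fraction_curve(a, grid))
  expect_gt(lam / V, sp$ci_low[2])
  expect_lt(lam / V, sp$ci_high[2])
})

test_that("normalisation divides by the basis concentration", {
  grid <- c(262.15, 260.15)
  a <- mk_assay(rep(261, 500), 1000)
  sp <- cumulative_inm_concentration(frozen_fraction_curve(a, grid))
  spn <- normalize_spectrum(sp, chem_fix, "c_tccho")
  expect_equal(spn$n_m, sp$n_inm_per_L / 1e-3)
  expect_identical(attr(spn, "normalization_basis"), "c_tccho")
  # per_volume is the identity
  expect_identical(normalize_spectrum(sp, chem_fix, "per_volume"), sp)
  # missing / zero basis errors name the sample
  chem0 <- sample_chemistry("s1", c_tccho = 0)
  expect_error(normalize_spectrum(sp, chem0, "c_tccho"), "s1")
  expect_error(normalize_spectrum(sp, chem_fix, "dry_mass"), "dry_mass")
  expect_error(
    normalize_spectrum(sp, sample_chemistry("other", 1), "c_tccho"),
    "no chemistry record")
})

test_that("treatment reduction is percent loss with propagated interval", {
  grid <- c(262.15, 260.15)
  ref <- cumulative_inm_concentration(
    frozen_fraction_curve(mk_assay(rep(261, 500), 1000), grid))
  same <- cumulative_inm_concentration(
    frozen_fraction_curve(mk_assay(rep(261, 500), 1000), grid))
  expect_equal(treatment_reduction(ref, same, 260.15)$estimate, 0)
  # a 99% reduction by construction: n_treated = n_ref / 100
  f_ref <- 0.5
  n_ref <- -log(1 - f_ref) * 1e6
  f_tr <- -expm1(-n_ref / 100 * 1e-6)
  tr <- cumulative_inm_concentration(
    frozen_fraction_curve(mk_assay(rep(261, round(f_tr * 1e5)), 1e5), grid))
  red <- treatment_reduction(ref, tr, 260.15)
  expect_equal(red$estimate, 99, tolerance = 0.01)
  expect_true(red$ci[1] < 99 && red$ci[2] > 99)
  # zero reference is flagged undefined
  ref0 <- cumulative_inm_concentration(
    frozen_fraction_curve(mk_assay(numeric(0), 100), grid))
  expect_true(treatment_reduction(ref0, tr, 260.15)$flagged)
})

test_that("simulated 98% filtration is recovered within the interval", {
  cfg <- sim_config(seed = 21, n_droplets = 1000,
                    true_params = cnt_params(1.75, 0.3, 1e11))
  ref_a <- simulate_assay(cfg, chem_fix, dilution = 1, seed = 21)
  trt_a <- simulate_assay(cfg, chem_fix, dilution = 1, seed = 22,
                          inm_survival = 0.02,
                          treatment = "filtered_0.2um")
  grid <- cfg$temperature_grid
  ref <- cumulative_inm_concentration(frozen_fraction_curve(ref_a, grid))
  trt <- cumulative_inm_concentration(frozen_fraction_curve(trt_a, grid))
  T0 <- 257.15  # -16 C: reference fraction mid-range
  red <- treatment_reduction(ref, trt, T0)
  expect_equal(red$estimate, 98, tolerance = 0.03)
  expect_true(red$ci[1] < 98 && 98 < red$ci[2])
})

test_that("background subtraction works in n-space and floors at zero", {
  grid <- c(262.15, 260.15)
  sp <- cumulative_inm_concentration(
    frozen_fraction_curve(mk_assay(rep(261, 500), 1000), grid))
  bg <- cumulative_inm_concentration(
    frozen_fraction_curve(mk_assay(rep(261, 600), 1000), grid))
  out <- subtract_background(sp, bg)
  expect_equal(out$n_inm_per_L, rep(0, 2))  # background above sample
  out2 <- subtract_background(bg, sp)
  expect_equal(out2$n_inm_per_L,
               bg$n_inm_per_L - sp$n_inm_per_L)
})

test_that("dilution series give consistent concentration estimates", {
  cfg <- sim_config(seed = 31, n_droplets = 500)
  a1 <- simulate_assay(cfg, chem_fix, dilution = 1, seed = 31)
  a10 <- simulate_assay(cfg, chem_fix, dilution = 10, seed = 32)
  grid <- cfg$temperature_grid
  s1 <- cumulative_inm_concentration(frozen_fraction_curve(a1, grid))
  s10 <- cumulative_inm_concentration(frozen_fraction_curve(a10, grid))
  # at a temperature where both assays resolve the spectrum, the joint
  # confidence intervals must overlap
  T0 <- 256.15
  i <- match(T0, grid)
  expect_false(s1$censored[i] || s10$censored[i])
  lo <- pmax(s1$ci_low[i], s10$ci_low[i])
  hi <- pmin(s1$ci_high[i], s10$ci_high[i])
  expect_lt(lo, hi)
})

test_that("assay and chemistry CSV round-trips preserve the data", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    sample_id = "org1",
    droplet_id = 1:6,
    droplet_volume_uL = 1,
    dilution_factor = 10,
    freeze_temp_C = c(-12.5, -14, NA, -20, NA, -9.25),
    treatment = "none",
    background_id = "bg1")
  write.csv(df, tmp, row.names = FALSE)
  assays <- read_assay_csv(tmp)
  expect_length(assays, 1)
  a <- assays[[1]]
  expect_equal(a$n_droplets_total, 6L)
  expect_equal(sort(a$freezing_temperatures),
               sort(celsius_to_kelvin(c(-12.5, -14, -20, -9.25))))
  expect_equal(a$droplet_volume, 1e-6)
  expect_equal(a$dilution_factor, 10)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "org1", c_tccho_gC_per_L = 2e-3,
                       toc_gC_per_L = 5e-3), tmp2, row.names = FALSE)
  chem <- read_chemistry_csv(tmp2)
  expect_equal(chem$c_tccho, 2e-3)

  # spectrum export carries basis and censoring metadata
  sp <- assay_spectrum(a, chem, "c_tccho",
                       default_temperature_grid(step = 1))
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, tmp3)
  back <- read.csv(tmp3)
  expect_equal(nrow(back), length(default_temperature_grid(step = 1)))
  expect_true(all(back$basis == "c_tccho"))
  expect_equal(back$n_m, sp$n_m)
})
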