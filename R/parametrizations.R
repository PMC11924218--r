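# INP parametrizations and the aerosol-mode geometry feeding them:
#  - HSZ25-style: polysaccharide (carbohydrate-carbon) mass x fitted CNT
#    site density,
#  - N15-style: mineral dust surface area x CNT surface site density,
#  - M18: sea-spray surface area x exponential surface site density.

#' Lognormal aerosol mode specification
#'
#' Geometric standard deviation and particle density of one aerosol mode.
#' Defaults (see [default_modes()]): sigma_g 1.59 accumulation / 2.0 coarse,
#' densities 2200 kg m^-3 (sea salt) and 2650 kg m^-3 (dust) - declared
#' assumptions standing in for the driving transport model's unreprinted
#' mode definitions, all configurable.
#'
#' @param name one of `"soluble_accumulation"`, `"soluble_coarse"`,
#'   `"insoluble_accumulation"`, `"insoluble_coarse"`.
#' @param sigma_g geometric standard deviation (> 1).
#' @param density particle density \[kg m^-3\].
#' @return object of class `"mode_spec"`.
#' @export
mode_spec <- function(name = c("soluble_accumulation", "soluble_coarse",
                               "insoluble_accumulation", "insoluble_coarse"),
                      sigma_g, density) {
  name <- match.arg(name)
  stopifnot(sigma_g > 1, density > 0)
  structure(list(name = name, sigma_g = sigma_g, density = density),
            class = "mode_spec")
}

#' @rdname mode_spec
#' @export
default_modes <- function() {
  list(
    seasalt_accu = mode_spec("soluble_accumulation", 1.59, 2200),
    seasalt_coarse = mode_spec("soluble_coarse", 2.0, 2200),
    dust_accu = mode_spec("insoluble_accumulation", 1.59, 2650),
    dust_coarse = mode_spec("insoluble_coarse", 2.0, 2650))
}

#' Surface area concentration of a lognormal mode
#'
#' From mass and number concentration, assuming a lognormal size
#' distribution: the median diameter is
#' `d_g = (6 M / (pi rho N))^(1/3) exp(-1.5 ln^2 sigma_g)` and the surface
#' area concentration `S = N pi d_g^2 exp(2 ln^2 sigma_g)`. Returns 0 where
#' mass or number is 0.
#'
#' @param mass_conc mode mass concentration \[kg m^-3 air\], vectorised.
#' @param number_conc mode number concentration \[m^-3 air\].
#' @param mode a [mode_spec()].
#' @return surface area concentration \[m^2 per m^3 air\].
#' @export
mode_surface_area <- function(mass_conc, number_conc, mode) {
  stopifnot(inherits(mode, "mode_spec"))
  if (any(mass_conc < 0, na.rm = TRUE) || any(number_conc < 0, na.rm = TRUE))
    stop("mass and number concentrations must be nonnegative")
  ln2s <- log(mode$sigma_g)^2
  out <- mass_conc * 0
  ok <- mass_conc > 0 & number_conc > 0
  d_g <- (6 * mass_conc[ok] / (pi * mode$density * number_conc[ok]))^(1 / 3) *
    exp(-1.5 * ln2s)
  out[ok] <- number_conc[ok] * pi * d_g^2 * exp(2 * ln2s)
  out
}

#' Surface site density schemes (N15, M18)
#'
#' Named, versioned coefficient profiles mapping temperature to an ice
#' nucleation surface site density `n_s(T)` \[m^-2\].
#'
#' `n15_profile()` is a CNT/contact-angle scheme for mineral dust evaluated
#' through the same machinery as the polysaccharide model but on an area
#' basis. The original published coefficients are not reprinted here; the
#' shipped defaults (`"n15.synthetic.v1"`) are synthetic representative
#' values chosen to reproduce widely reported desert-dust site-density
#' magnitudes (~1e4 m^-2 at -15 C rising towards ~1e10 m^-2 at -30 C), and
#' every coefficient is configurable.
#'
#' `m18_profile()` is the published sea-spray scheme of McCluskey et al.
#' (2018): `n_s(T) = exp(a Tc + b)` with `a = -0.545`, `b = 1.0125` (`Tc` in
#' Celsius), validity -26 to -5 C. It is unbounded in its raw form, so
#' evaluation outside validity errors unless clamping is requested
#' explicitly.
#'
#' @param mu_theta,sigma_theta,n_s_max,a_site,delta_t CNT parameters of the
#'   dust scheme (area basis).
#' @param t_range validity range \[K\].
#' @param a,b exponential coefficients of the M18 scheme.
#' @return object of class `"surface_param"`.
#' @references Niedermeier, D. et al. (2015) Geophys. Res. Lett. 42,
#'   8758-8766. McCluskey, C. S. et al. (2018) Geophys. Res. Lett. 45,
#'   11989-11997.
#' @export
n15_profile <- function(mu_theta = 2.38, sigma_theta = 0.24, n_s_max = 1e12,
                        a_site = 1e-14, delta_t = 60,
                        t_range = c(233.15, 272.15)) {
  structure(list(scheme = "N15", version = "n15.synthetic.v1",
                 type = "cnt",
                 params = cnt_params(mu_theta, sigma_theta, n_s_max,
                                     a_site, delta_t, basis = "per_m2"),
                 t_range = t_range),
            class = "surface_param")
}

#' @rdname n15_profile
#' @export
m18_profile <- function(a = -0.545, b = 1.0125,
                        t_range = celsius_to_kelvin(c(-26, -5))) {
  structure(list(scheme = "M18", version = "m18.v1", type = "exponential",
                 a = a, b = b, t_range = t_range),
            class = "surface_param")
}

#' @export
print.surface_param <- function(x, ...) {
  cat(sprintf("Surface site density scheme %s (%s), validity %.1f..%.1f C\n",
              x$scheme, x$version, kelvin_to_celsius(x$t_range[1]),
              kelvin_to_celsius(x$t_range[2])))
  if (x$type == "cnt") print(x$params)
  else cat(sprintf("  n_s(T) = exp(%g Tc %+g) m^-2\n", x$a, x$b))
  invisible(x)
}

.check_scheme_range <- function(profile, T, extrapolation) {
  out_of_range <- T < profile$t_range[1] - 1e-9 |
    T > profile$t_range[2] + 1e-9
  if (any(out_of_range)) {
    if (extrapolation == "error")
      stop(sprintf(
        "temperature outside %s validity [%.2f, %.2f] K (no extrapolation)",
        profile$scheme, profile$t_range[1], profile$t_range[2]))
    T <- pmin(pmax(T, profile$t_range[1]), profile$t_range[2])
  }
  T
}

#' Evaluate a surface site density scheme
#'
#' @param profile a [n15_profile()] or [m18_profile()].
#' @param T temperature \[K\], vectorised.
#' @param thermo thermo profile (CNT schemes only).
#' @param extrapolation `"error"` (default: refuse temperatures outside the
#'   scheme validity) or `"clamp"` (evaluate at the nearest validity edge).
#' @return site density `n_s(T)` \[m^-2\].
#' @export
surface_site_density <- function(profile, T, thermo = thermo_profile(),
                                 extrapolation = c("error", "clamp")) {
  stopifnot(inherits(profile, "surface_param"))
  extrapolation <- match.arg(extrapolation)
  T <- .check_scheme_range(profile, T, extrapolation)
  if (profile$type == "cnt") {
    profile$params$n_max *
      site_activation_probability(T, profile$params, thermo)
  } else {
    exp(profile$a * kelvin_to_celsius(T) + profile$b)
  }
}

#' INP concentration from an aerosol surface-area proxy
#'
#' `N_INP(T) = S n_s(T)`, converted to per litre of air.
#'
#' @inheritParams surface_site_density
#' @param surface_area_conc aerosol surface area concentration
#'   \[m^2 per m^3 air\], vectorised.
#' @return INP concentration \[per litre air\].
#' @export
surface_inp <- function(T, surface_area_conc, profile,
                        thermo = thermo_profile(),
                        extrapolation = c("error", "clamp")) {
  if (any(surface_area_conc < 0, na.rm = TRUE))
    stop("surface area concentration must be nonnegative")
  n_s <- surface_site_density(profile, T, thermo, extrapolation)
  surface_area_conc * n_s / 1000
}

#' INP concentration from polysaccharide mass (HSZ25-style)
#'
#' Converts airborne polysaccharide mass to carbohydrate-carbon mass with
#' `carbon_fraction`, multiplies by the fitted site density
#' `n_m,C-TCCHO(T)`, and converts to per litre of air. The default
#' `carbon_fraction = 0.40` (glucan-like CH2O stoichiometry ~0.44, rounded
#' conservatively) is an assumption surfaced in all outputs, because the
#' polysaccharide-mass to carbohydrate-carbon conversion is not fixed by the
#' parametrization itself.
#'
#' @param T temperature \[K\], vectorised.
#' @param polysaccharide_mass_conc airborne polysaccharide mass
#'   \[kg per m^3 air\], vectorised (recycled against `T`).
#' @param params fitted [cnt_params()] on the `"c_tccho"` basis.
#' @param thermo a [thermo_profile()].
#' @param carbon_fraction carbon mass fraction of polysaccharide.
#' @return INP concentration \[per litre air\].
#' @export
hsz25_inp <- function(T, polysaccharide_mass_conc, params = hsz25_params(),
                      thermo = thermo_profile(), carbon_fraction = 0.40) {
  stopifnot(inherits(params, "cnt_params"))
  if (params$basis != "c_tccho")
    stop("basis mismatch: carbon_fraction conversion requires params on ",
         "the 'c_tccho' basis, got '", params$basis, "'")
  stopifnot(carbon_fraction > 0, carbon_fraction <= 1)
  if (any(polysaccharide_mass_conc < 0, na.rm = TRUE))
    stop("polysaccharide mass must be nonnegative")
  n_m <- params$n_max * site_activation_probability(T, params, thermo)
  m_c <- carbon_fraction * polysaccharide_mass_conc * 1000  # kg -> g C
  m_c * n_m / 1000
}
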