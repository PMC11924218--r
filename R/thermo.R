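# Thermodynamic ingredients of the heterogeneous CNT nucleation rate.
#
# The profile bundles, as a named versioned set, everything j_het needs:
#   sigma_iw(T)  ice-water interfacial energy            [J m^-2]
#   delta_mu(T)  water-ice chemical potential difference [J / molecule]
#   df_diff(T)   diffusion activation energy             [J]
#   a_kin(T)     kinetic prefactor                       [m^-2 s^-1]
# delta_mu uses the Murphy & Koop (2005) saturation vapour pressures over
# supercooled water and ice; df_diff is the Vogel-Fulcher-Tammann activation
# energy of water self-diffusion (E = 892 K, T0 = 118 K, Zobrist-type);
# sigma_iw is linear in T. Any internally consistent set works for fitting
# because (mu_theta, sigma_theta, n_max) absorb overall scale; the profile is
# pinned and reported so fits are reproducible.

.kB <- 1.380649e-23      # Boltzmann constant [J/K]
.h_planck <- 6.62607015e-34
.N_Avogadro <- 6.02214076e23
.M_water <- 18.01528e-3  # [kg/mol]

#' Thermodynamic profile for CNT nucleation rates
#'
#' Constructs the named, versioned coefficient set used by [j_het()] and the
#' site-density model. The default profile `"mkz.v1"` combines Murphy & Koop
#' (2005) vapour pressures (chemical potential difference), a
#' Vogel-Fulcher-Tammann diffusion activation energy, a linear ice-water
#' interfacial energy, and a `kT/h` kinetic prefactor over a monolayer site
#' density.
#'
#' @param name profile name tag stored with every fit.
#' @param t_range validity range \[K\]; evaluation outside errors.
#' @param sigma0 ice-water interfacial energy at 273.15 K \[J m^-2\].
#' @param dsigma_dT linear temperature slope of `sigma_iw` \[J m^-2 K^-1\].
#' @param vft_E,vft_T0 VFT parameters of water self-diffusion \[K\].
#' @param n_mono areal molecule density entering the prefactor \[m^-2\].
#' @param rho_ice ice density \[kg m^-3\] (volume per molecule in ice).
#' @return object of class `"thermo_profile"`.
#' @references Murphy, D. M. and Koop, T. (2005) Q. J. R. Meteorol. Soc. 131,
#'   1539-1565. Zobrist, B. et al. (2007) J. Phys. Chem. C 111, 2149-2155.
#' @export
#' @examples
#' th <- thermo_profile()
#' delta_mu(th, 253.15)  # positive under supercooling
thermo_profile <- function(name = "mkz.v1",
                           t_range = c(233.15, 272.15),
                           sigma0 = 0.0289, dsigma_dT = 2.5e-4,
                           vft_E = 892, vft_T0 = 118,
                           n_mono = 1e19, rho_ice = 916.7) {
  stopifnot(length(t_range) == 2L, t_range[1] < t_range[2],
            sigma0 > 0, vft_E > 0, vft_T0 > 0, n_mono > 0, rho_ice > 0)
  structure(list(name = name, t_range = t_range,
                 sigma0 = sigma0, dsigma_dT = dsigma_dT,
                 vft_E = vft_E, vft_T0 = vft_T0,
                 n_mono = n_mono, rho_ice = rho_ice),
            class = "thermo_profile")
}

#' @export
print.thermo_profile <- function(x, ...) {
  cat("CNT thermodynamic profile '", x$name, "'\n", sep = "")
  cat(sprintf("  validity: %.2f .. %.2f K (%.1f .. %.1f C)\n",
              x$t_range[1], x$t_range[2],
              kelvin_to_celsius(x$t_range[1]), kelvin_to_celsius(x$t_range[2])))
  cat(sprintf("  sigma_iw(T) = %.4g %+.3g (T - 273.15) J m^-2\n",
              x$sigma0, x$dsigma_dT))
  cat(sprintf("  VFT diffusion: E = %g K, T0 = %g K\n", x$vft_E, x$vft_T0))
  cat(sprintf("  prefactor: (kB T / h) * %.3g m^-2\n", x$n_mono))
  invisible(x)
}

.assert_thermo <- function(thermo) {
  if (!inherits(thermo, "thermo_profile"))
    stop("'thermo' must be a thermo_profile object")
  invisible(thermo)
}

.assert_t_range <- function(thermo, T) {
  if (any(T < thermo$t_range[1] - 1e-9 | T > thermo$t_range[2] + 1e-9))
    stop(sprintf(
      "temperature outside thermo profile validity range [%.2f, %.2f] K",
      thermo$t_range[1], thermo$t_range[2]))
  invisible(T)
}

# Murphy & Koop (2005): saturation vapour pressure [Pa], eq. (7) over ice
.ln_p_ice <- function(T) 9.550426 - 5723.265 / T + 3.53068 * log(T) -
  0.00728332 * T

# Murphy & Koop (2005): eq. (10) over (supercooled) liquid water
.ln_p_liq <- function(T) {
  54.842763 - 6763.22 / T - 4.210 * log(T) + 0.000367 * T +
    tanh(0.0415 * (T - 218.8)) *
      (53.878 - 1331.22 / T - 9.44523 * log(T) + 0.014025 * T)
}

#' Evaluate thermodynamic profile components
#'
#' `sigma_iw`: ice-water interfacial energy \[J m^-2\]; `delta_mu`: chemical
#' potential difference between supercooled water and ice per molecule \[J\]
#' (0 at/above melting); `df_diff`: diffusion activation energy \[J\];
#' `a_kin`: kinetic prefactor \[m^-2 s^-1\]; `v_ice_molecule`: volume per
#' molecule in ice \[m^3\]; `dg_hom`: homogeneous nucleation energy barrier
#' \[J\] (`Inf` when there is no supercooling).
#'
#' @param thermo a [thermo_profile()].
#' @param T temperature \[K\], vectorised. Range-checked against the profile.
#' @return numeric vector (or scalar for `v_ice_molecule`).
#' @export
sigma_iw <- function(thermo, T) {
  .assert_thermo(thermo); .assert_t_range(thermo, T)
  s <- thermo$sigma0 + thermo$dsigma_dT * (T - 273.15)
  if (any(s <= 0)) stop("sigma_iw must stay positive over the validity range")
  s
}

#' @rdname sigma_iw
#' @export
delta_mu <- function(thermo, T) {
  .assert_thermo(thermo); .assert_t_range(thermo, T)
  pmax(0, .kB * T * (.ln_p_liq(T) - .ln_p_ice(T)))
}

#' @rdname sigma_iw
#' @export
df_diff <- function(thermo, T) {
  .assert_thermo(thermo); .assert_t_range(thermo, T)
  .kB * thermo$vft_E * T^2 / (T - thermo$vft_T0)^2
}

#' @rdname sigma_iw
#' @export
a_kin <- function(thermo, T) {
  .assert_thermo(thermo); .assert_t_range(thermo, T)
  (.kB * T / .h_planck) * thermo$n_mono
}

#' @rdname sigma_iw
#' @export
v_ice_molecule <- function(thermo) {
  .assert_thermo(thermo)
  .M_water / (thermo$rho_ice * .N_Avogadro)
}

#' @rdname sigma_iw
#' @export
dg_hom <- function(thermo, T) {
  dmu <- delta_mu(thermo, T)
  sig <- sigma_iw(thermo, T)
  v <- v_ice_molecule(thermo)
  out <- rep(Inf, length(T))
  ok <- dmu > 0
  out[ok] <- (16 * pi / 3) * sig[ok]^3 * v^2 / dmu[ok]^2
  out
}

#' Homogeneous ice nucleation rate per site area
#'
#' The contact-angle model's homogeneous limit (`theta = pi`, compatibility
#' factor 1): `A_kin(T) * exp(-(dF_diff + dG_hom) / kB T)`.
#'
#' @inheritParams sigma_iw
#' @return rate \[m^-2 s^-1\]; 0 when there is no supercooling.
#' @export
j_hom <- function(T, thermo = thermo_profile()) {
  dg <- dg_hom(thermo, T)
  expo <- -(df_diff(thermo, T) + dg) / (.kB * T)
  ifelse(is.finite(dg), a_kin(thermo, T) * exp(expo), 0)
}
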