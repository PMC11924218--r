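# Shared fixtures and independent oracles for the test suite.

th_fix <- thermo_profile()
chem_fix <- sample_chemistry("s1", c_tccho = 1e-3, toc = 2.5e-3)

# Independent brute-force evaluation of the site activation probability:
# composite Simpson on 1e5 + 1 uniform nodes over (0, pi], completely
# separate from the package's panelled Gauss-Legendre path.
simpson_p_site <- function(T1, mu, sigma, a_site = 1e-14, delta_t = 60,
                           thermo = th_fix, n = 100001) {
  x <- seq(0, pi, length.out = n)
  h <- x[2] - x[1]
  Z <- pnorm((pi - mu) / sigma) - pnorm(-mu / sigma)
  g <- -expm1(-j_het(T1, x, thermo) * a_site * delta_t)
  f <- dnorm(x, mu, sigma) * g / Z
  w <- rep(c(4, 2), length.out = n - 2)
  (h / 3) * (f[1] + f[n] + sum(w * f[2:(n - 1)]))
}

# quick assay builder with explicit freezing temperatures (kelvin)
mk_assay <- function(temps, n_total, V = 1e-6, dil = 1, id = "s1",
                     treatment = "none") {
  freezing_assay(id, V, dil, temps, n_total, treatment)
}

# coarse grid for cheaper fits in unit tests
coarse_grid <- default_temperature_grid(step = 1)
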