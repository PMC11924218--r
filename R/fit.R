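# Maximum-likelihood estimation of CNT contact-angle parameters from
# droplet freezing assays. This is the package's central model-fitting
# interface, in the classic R idiom: cnt_fit() returns a classed object with
# print/summary/coef/logLik/predict/plot/simulate/residuals methods.

# Bin one assay's freezing temperatures onto the grid.
# Returns per-increment freeze counts d (length = grid) and the number of
# droplets still liquid at the cold end (right-censored, includes droplets
# that froze below the grid).
.bin_assay <- function(assay, grid) {
  cum_k <- vapply(grid, function(T) sum(assay$freezing_temperatures >= T),
                  numeric(1))
  d <- diff(c(0, cum_k))
  list(d = d,
       n_surv = assay$n_droplets_total - cum_k[length(cum_k)],
       n_total = assay$n_droplets_total,
       scale = assay$droplet_volume / assay$dilution_factor)
}

# Exact interval-censored log-likelihood: droplets freeze in grid increments
# with probability F(T_s) - F(T_{s-1}) and survive the whole ramp with
# probability exp(-lambda_end). Equivalent to the product of conditional
# per-bin binomials of the observed frozen counts.
.cnt_nll <- function(par, bins, conc, grid, a_site, delta_t, thermo,
                     n_nodes = 64) {
  mu <- par[1]
  sigma <- exp(par[2])
  n_max <- 10^par[3]
  if (!is.finite(mu) || mu < 0.02 || mu > pi - 0.02 ||
      !is.finite(sigma) || sigma > 2 || sigma < 1e-5 ||
      !is.finite(n_max)) return(1e10)
  p <- tryCatch(
    .p_site_curve(grid, mu, sigma, a_site, delta_t, thermo, n_nodes),
    error = function(e) NULL)
  if (is.null(p)) return(1e10)
  n_m <- n_max * p
  ll <- 0
  for (b in bins) {
    lam <- n_m * conc * b$scale
    F <- -expm1(-lam)
    q <- pmax(diff(c(0, F)), 0)
    if (any(b$d > 0 & q <= 0)) return(1e10)
    pos <- b$d > 0
    ll <- ll + sum(b$d[pos] * log(q[pos])) - b$n_surv * lam[length(lam)]
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Empirical log10 site-density guess from the most informative bins.
.nmax_guess <- function(bins, conc, grid) {
  best <- -Inf
  for (b in bins) {
    cum <- cumsum(b$d)
    f <- cum / b$n_total
    f_eff <- ifelse(f >= 1, (cum - 0.5) / pmax(cum, 1), f)
    n_emp <- -log1p(-pmin(f_eff, 1 - 1e-12)) / b$scale / conc
    ok <- is.finite(n_emp) & n_emp > 0
    if (any(ok)) best <- max(best, max(n_emp[ok]))
  }
  if (!is.finite(best)) stop("spectrum uninformative: no frozen droplets")
  log10(best)
}

#' Fit the CNT contact-angle model to freezing assays
#'
#' Maximises the exact interval-censored binomial likelihood of the observed
#' per-bin frozen counts under the forward model
#' [predict_frozen_fraction()], over `(mu_theta, log sigma_theta,
#' log10 n_max)` (unconstrained transforms enforce positivity). A documented
#' multi-start grid (`mu_theta` in 1.2, 1.6, 2.0, 2.4 rad crossed with
#' seed-jittered `log10 n_max` guesses from the empirical spectrum) guards
#' against the likelihood's multi-modality in `(mu, sigma)`; the best
#' converged start is returned.
#'
#' All assays passed in are treated as replicates/dilution series of one
#' sample sharing a single basis concentration, so dilution series are fitted
#' jointly.
#'
#' @param assays a [freezing_assay()] or list of them (one sample).
#' @param chemistry [sample_chemistry()] table; required unless
#'   `basis = "per_volume"`.
#' @param basis normalisation basis of the fitted `n_max`.
#' @param thermo a [thermo_profile()].
#' @param temperature_grid descending grid \[K\] used for binning and model
#'   evaluation.
#' @param a_site,delta_t pinned per-site area \[m^2\] and effective
#'   nucleation time \[s\] (reported with the fit; they trade off against
#'   `mu_theta`/`n_max`).
#' @param n_boot parametric bootstrap replicates for parameter
#'   uncertainties (0 = skip; 200 is the recommended production setting).
#' @param seed RNG seed controlling start jitter and the bootstrap.
#' @param control passed to [stats::optim()] (Nelder-Mead).
#' @return object of class `"cnt_fit"`.
#' @seealso [site_density_curve()], [ensemble_spread()]
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 7, n_droplets = 120, dilutions = c(1, 10))
#' chem <- sample_chemistry("demo", c_tccho = 1e-3)
#' assays <- simulate_dilution_series(cfg, chem)
#' fit <- cnt_fit(assays, chem, seed = 7)
#' coef(fit)
#' }
cnt_fit <- function(assays, chemistry = NULL,
                    basis = c("c_tccho", "toc", "dry_mass", "per_volume"),
                    thermo = thermo_profile(),
                    temperature_grid = default_temperature_grid(),
                    a_site = 1e-14, delta_t = 60,
                    n_boot = 0, seed = NULL, control = list()) {
  basis <- match.arg(basis)
  if (inherits(assays, "freezing_assay")) assays <- list(assays)
  stopifnot(length(assays) >= 1,
            all(vapply(assays, inherits, TRUE, "freezing_assay")))
  .check_grid(temperature_grid)
  sample_id <- assays[[1]]$sample_id

  n_frozen <- sum(vapply(assays, function(a)
    sum(a$freezing_temperatures >= min(temperature_grid)), numeric(1)))
  n_warm <- sum(vapply(assays, function(a)
    sum(a$freezing_temperatures >= max(temperature_grid)), numeric(1)))
  n_total <- sum(vapply(assays, function(a) a$n_droplets_total, numeric(1)))
  # degenerate only when nothing froze inside the grid or everything had
  # already frozen at the warmest grid point: no transition to fit
  if (n_frozen == 0 || n_warm == n_total)
    stop("spectrum uninformative: need at least one frozen and one ",
         "unfrozen droplet across the grid")

  conc <- if (basis == "per_volume") 1
          else .basis_concentration(chemistry, sample_id, basis)
  bins <- lapply(assays, .bin_assay, grid = temperature_grid)

  if (!is.null(seed)) set.seed(seed)
  g <- .nmax_guess(bins, conc, temperature_grid)
  mu_starts <- c(1.2, 1.6, 2.0, 2.4)
  starts <- expand.grid(mu = mu_starts, lg = c(g, g + 0.5))
  starts$mu <- starts$mu + rnorm(nrow(starts), 0, 0.05)
  starts$lg <- starts$lg + rnorm(nrow(starts), 0, 0.15)

  # two stages: cheap exploration from every start, then a fine polish of
  # the best candidate at full quadrature accuracy
  ctrl1 <- list(maxit = 250, reltol = 1e-7)
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      optim(c(starts$mu[i], log(0.2), starts$lg[i]), .cnt_nll,
            bins = bins, conc = conc, grid = temperature_grid,
            a_site = a_site, delta_t = delta_t, thermo = thermo,
            n_nodes = 32, method = "Nelder-Mead", control = ctrl1),
      error = function(e) list(value = Inf, convergence = 99))
  }
  vals <- vapply(fits, function(f) f$value, numeric(1))
  if (all(!is.finite(vals) | vals >= 1e10))
    stop("optimizer failed from every start")
  ctrl2 <- utils::modifyList(list(maxit = 800, reltol = 1e-12), control)
  best <- optim(fits[[which.min(vals)]]$par, .cnt_nll,
                bins = bins, conc = conc, grid = temperature_grid,
                a_site = a_site, delta_t = delta_t, thermo = thermo,
                method = "Nelder-Mead", control = ctrl2)
  converged <- best$convergence == 0

  par <- best$par
  params <- cnt_params(par[1], exp(par[2]), 10^par[3],
                       a_site = a_site, delta_t = delta_t, basis = basis)
  obj <- structure(list(
    params = params,
    coefficients = c(mu_theta = par[1], sigma_theta = exp(par[2]),
                     log10_n_max = par[3]),
    logLik = -best$value,
    n_assays = length(assays),
    n_droplets = n_total,
    n_frozen = n_frozen,
    basis = basis,
    basis_concentration = conc,
    thermo = thermo,
    temperature_grid = temperature_grid,
    bins = bins,
    assay_design = lapply(assays, function(a)
      list(droplet_volume = a$droplet_volume,
           dilution_factor = a$dilution_factor,
           n_droplets = a$n_droplets_total)),
    converged = converged,
    n_starts = nrow(starts),
    sample_id = sample_id,
    boot = NULL,
    call = match.call()), class = "cnt_fit")

  if (n_boot > 0) obj <- .cnt_boot(obj, n_boot, seed)
  obj
}

# Parametric bootstrap: resimulate the fitted design from the fitted
# parameters and refit from the fitted optimum (single start).
.cnt_boot <- function(fit, n_boot, seed = NULL) {
  if (!is.null(seed)) set.seed(seed + 1L)
  par0 <- c(fit$coefficients["mu_theta"],
            log(fit$coefficients["sigma_theta"]),
            fit$coefficients["log10_n_max"])
  grid <- fit$temperature_grid
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, names(fit$coefficients)))
  for (b in seq_len(n_boot)) {
    bins <- lapply(fit$assay_design, function(dsn) {
      a <- .simulate_assay_core(fit$params, fit$thermo,
                                c_basis = fit$basis_concentration,
                                droplet_volume = dsn$droplet_volume,
                                dilution = dsn$dilution_factor,
                                n_droplets = dsn$n_droplets,
                                grid = grid, sample_id = fit$sample_id)
      .bin_assay(a, grid)
    })
    opt <- tryCatch(
      optim(par0, .cnt_nll, bins = bins, conc = fit$basis_concentration,
            grid = grid, a_site = fit$params$a_site,
            delta_t = fit$params$delta_t, thermo = fit$thermo,
            method = "Nelder-Mead",
            control = list(maxit = 400, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value < 1e10)
      reps[b, ] <- c(opt$par[1], exp(opt$par[2]), opt$par[3])
  }
  fit$boot <- reps[complete.cases(reps), , drop = FALSE]
  fit
}

#' @export
print.cnt_fit <- function(x, ...) {
  cat("CNT contact-angle fit to freezing spectra\n")
  cat(sprintf("  sample: %s  (%d assays, %d droplets, %d frozen in grid)\n",
              x$sample_id, x$n_assays, x$n_droplets, x$n_frozen))
  cat(sprintf("  basis: %s   logLik: %.2f   converged: %s\n",
              x$basis, x$logLik, x$converged))
  print(x$params)
  invisible(x)
}

#' @export
coef.cnt_fit <- function(object, ...) object$coefficients

#' @export
logLik.cnt_fit <- function(object, ...) {
  structure(object$logLik, df = 3, nobs = object$n_droplets,
            class = "logLik")
}

#' @export
summary.cnt_fit <- function(object, ...) {
  se <- if (!is.null(object$boot) && nrow(object$boot) > 1)
    apply(object$boot, 2, sd) else rep(NA_real_, 3)
  structure(list(fit = object,
                 table = cbind(estimate = object$coefficients, se = se)),
            class = "summary.cnt_fit")
}

#' @export
print.summary.cnt_fit <- function(x, ...) {
  print(x$fit)
  cat("Parameter uncertainties (parametric bootstrap):\n")
  print(round(x$table, 4))
  if (all(is.na(x$table[, "se"])))
    cat("  (run cnt_fit(..., n_boot = 200) for bootstrap uncertainties)\n")
  invisible(x)
}

#' @export
vcov.cnt_fit <- function(object, ...) {
  if (is.null(object$boot) || nrow(object$boot) < 2)
    stop("no bootstrap replicates stored; refit with n_boot > 0")
  cov(object$boot)
}

#' @export
confint.cnt_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$boot) || nrow(object$boot) < 2)
    stop("no bootstrap replicates stored; refit with n_boot > 0")
  a <- (1 - level) / 2
  t(apply(object$boot, 2, quantile, probs = c(a, 1 - a)))
}

#' Predict from a fitted CNT model
#'
#' @param object a `"cnt_fit"`.
#' @param temperatures temperatures \[K\] (descending for curves).
#' @param type `"site_density"` (n_m per gram basis), `"activation"`
#'   (per-site probability) or `"frozen_fraction"`.
#' @param droplet_volume,dilution assay design for
#'   `type = "frozen_fraction"`; defaults to the first fitted assay.
#' @param ... unused.
#' @return data frame of predictions.
#' @export
predict.cnt_fit <- function(object, temperatures = object$temperature_grid,
                            type = c("site_density", "activation",
                                     "frozen_fraction"),
                            droplet_volume = NULL, dilution = NULL, ...) {
  type <- match.arg(type)
  temperatures <- sort(unique(temperatures), decreasing = TRUE)
  if (type == "site_density")
    return(site_density_curve(object$params, object$thermo, temperatures))
  if (type == "activation") {
    p <- site_activation_probability(temperatures, object$params,
                                     object$thermo)
    return(data.frame(temp_K = temperatures,
                      temp_C = kelvin_to_celsius(temperatures), p_site = p))
  }
  dsn <- object$assay_design[[1]]
  predict_frozen_fraction(object$params, object$thermo,
                          c_basis = object$basis_concentration,
                          droplet_volume = droplet_volume %||%
                            dsn$droplet_volume,
                          dilution = dilution %||% dsn$dilution_factor,
                          temperature_grid = temperatures)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate assays from a fitted CNT model
#'
#' Parametric simulation of the fitted assay design (same droplet numbers,
#' volumes and dilutions) from the fitted parameters.
#'
#' @param object a `"cnt_fit"`.
#' @param nsim number of replicate assay sets.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of length `nsim`; each element a list of
#'   [freezing_assay()] objects matching the fitted design.
#' @export
simulate.cnt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simplify = FALSE,
    lapply(object$assay_design, function(dsn)
      .simulate_assay_core(object$params, object$thermo,
                           c_basis = object$basis_concentration,
                           droplet_volume = dsn$droplet_volume,
                           dilution = dsn$dilution_factor,
                           n_droplets = dsn$n_droplets,
                           grid = object$temperature_grid,
                           sample_id = object$sample_id)))
}

#' Per-bin deviance residuals of a CNT fit
#'
#' Signed square-root deviance contributions of the observed per-increment
#' freeze counts (plus the final survival bin) under the fitted model,
#' concatenated over assays.
#'
#' @param object a `"cnt_fit"`.
#' @param ... unused.
#' @return numeric vector.
#' @export
residuals.cnt_fit <- function(object, ...) {
  p <- site_activation_probability(object$temperature_grid, object$params,
                                   object$thermo)
  n_m <- object$params$n_max * p
  out <- numeric(0)
  for (b in object$bins) {
    lam <- n_m * object$basis_concentration * b$scale
    F <- -expm1(-lam)
    q <- pmax(diff(c(0, F)), 1e-300)
    surv <- exp(-lam[length(lam)])
    probs <- c(q, surv)
    d <- c(b$d, b$n_surv)
    e <- b$n_total * probs
    dev <- 2 * (ifelse(d > 0, d * log(d / e), 0) - (d - e))
    out <- c(out, sign(d - e) * sqrt(pmax(dev, 0)))
  }
  out
}

#' Plot a CNT fit against its empirical spectrum
#'
#' Empirical site densities (Vali transform of each assay, censored bins
#' dropped) with the fitted `n_m(T)` curve, on a log axis.
#'
#' @param x a `"cnt_fit"`.
#' @param ... passed to [plot()].
#' @export
plot.cnt_fit <- function(x, ...) {
  curve_df <- predict(x, type = "site_density")
  grid <- x$temperature_grid
  pts_t <- numeric(0); pts_n <- numeric(0)
  for (b in x$bins) {
    cum <- cumsum(b$d)
    f <- cum / b$n_total
    ok <- f > 0 & f < 1
    n_emp <- -log1p(-f[ok]) / b$scale / x$basis_concentration
    pts_t <- c(pts_t, kelvin_to_celsius(grid[ok]))
    pts_n <- c(pts_n, n_emp)
  }
  ok <- is.finite(pts_n) & pts_n > 0
  yl <- range(c(pts_n[ok], curve_df$n_m[curve_df$n_m > 0]))
  plot(pts_t[ok], pts_n[ok], log = "y", xlab = "temperature [C]",
       ylab = sprintf("n_m [per g %s]", x$basis), pch = 19, ylim = yl, ...)
  lines(curve_df$temp_C, pmax(curve_df$n_m, yl[1] * 1e-3), col = 2, lwd = 2)
  legend("bottomleft", c("empirical", "CNT fit"), pch = c(19, NA),
         lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Order-of-magnitude spread of fitted site densities
#'
#' `log10(max / min)` of the fitted `n_m(T)` across an ensemble of fits at a
#' common temperature: the quantity that collapses from about three orders
#' (per volume) to about one (per carbohydrate carbon) when INM activity is
#' carried by a shared chemical component.
#'
#' @param fits list of `"cnt_fit"` objects on a common basis.
#' @param T temperature \[K\].
#' @return spread in orders of magnitude (log10).
#' @export
ensemble_spread <- function(fits, T) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, TRUE, "cnt_fit")))
  bases <- vapply(fits, function(f) f$basis, character(1))
  if (length(unique(bases)) != 1)
    stop("fits must share a normalisation basis")
  n_m <- vapply(fits, function(f)
    predict(f, temperatures = T, type = "site_density")$n_m, numeric(1))
  if (any(n_m <= 0)) {
    warning("excluding fit(s) with zero site density at T")
    n_m <- n_m[n_m > 0]
  }
  if (length(n_m) < 2) stop("fewer than two usable fits at T")
  log10(max(n_m) / min(n_m))
}
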