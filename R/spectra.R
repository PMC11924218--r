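# Droplet freezing assay reduction: frozen-fraction curves, cumulative
# Vali-type INM concentration spectra with exact binomial confidence bounds,
# chemical normalisation to site densities, and treatment comparisons.

.treatments <- c("none", "filtered_0.2um", "heated_95C_1h",
                 "filtered_then_heated", "acid_hydrolysis", "cacl2",
                 "cacl2_then_filtered")

#' Droplet freezing assay record
#'
#' One cooling-ramp assay: the freezing temperatures of the droplets that
#' froze (kelvin; droplets that stayed liquid are simply absent), droplet
#' volume, dilution factor, and treatment metadata.
#'
#' @param sample_id sample identifier.
#' @param droplet_volume droplet volume \[L\], > 0.
#' @param dilution_factor factor (>= 1) by which the original sample was
#'   diluted before dispensing.
#' @param freezing_temperatures temperatures \[K\] at which droplets froze,
#'   one per frozen droplet; all < 273.15 K.
#' @param n_droplets_total total droplets dispensed (>= number frozen).
#' @param treatment one of `"none"`, `"filtered_0.2um"`, `"heated_95C_1h"`,
#'   `"filtered_then_heated"`, `"acid_hydrolysis"`, `"cacl2"`,
#'   `"cacl2_then_filtered"`.
#' @param background_id optional identifier of a paired pure-water assay.
#' @return object of class `"freezing_assay"`.
#' @export
freezing_assay <- function(sample_id, droplet_volume, dilution_factor,
                           freezing_temperatures, n_droplets_total,
                           treatment = "none", background_id = NA_character_) {
  .scalar_pos(droplet_volume, "droplet_volume")
  stopifnot(is.numeric(dilution_factor), length(dilution_factor) == 1L,
            dilution_factor >= 1)
  stopifnot(is.numeric(n_droplets_total), n_droplets_total >= 1)
  freezing_temperatures <- as.numeric(freezing_temperatures)
  if (length(freezing_temperatures) > n_droplets_total)
    stop("more freezing temperatures than droplets")
  if (length(freezing_temperatures) &&
      any(freezing_temperatures >= 273.15))
    stop("freezing temperatures must be below 273.15 K")
  treatment <- match.arg(treatment, .treatments)
  structure(list(sample_id = as.character(sample_id),
                 droplet_volume = droplet_volume,
                 dilution_factor = dilution_factor,
                 freezing_temperatures = freezing_temperatures,
                 n_droplets_total = as.integer(n_droplets_total),
                 treatment = treatment,
                 background_id = background_id),
            class = "freezing_assay")
}

#' @export
print.freezing_assay <- function(x, ...) {
  cat(sprintf(
    "Freezing assay '%s': %d/%d droplets frozen, V = %.3g L, dilution %g, treatment %s\n",
    x$sample_id, length(x$freezing_temperatures), x$n_droplets_total,
    x$droplet_volume, x$dilution_factor, x$treatment))
  invisible(x)
}

#' Per-sample chemical concentrations
#'
#' Carbohydrate carbon (C-TCCHO), total organic carbon and dry mass per litre
#' of sample; these are measured inputs, never modelled here.
#'
#' @param sample_id sample identifier(s).
#' @param c_tccho carbohydrate carbon mass concentration \[g C / L\].
#' @param toc total organic carbon \[g C / L\] (optional, `NA` allowed).
#' @param dry_mass dry mass \[g / L\] (optional).
#' @return data frame of class `"sample_chemistry"`.
#' @export
sample_chemistry <- function(sample_id, c_tccho, toc = NA_real_,
                             dry_mass = NA_real_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   c_tccho = c_tccho, toc = toc, dry_mass = dry_mass,
                   stringsAsFactors = FALSE)
  if (any(df$c_tccho < 0, na.rm = TRUE) || any(df$toc < 0, na.rm = TRUE) ||
      any(df$dry_mass < 0, na.rm = TRUE))
    stop("chemical concentrations must be nonnegative")
  bad <- !is.na(df$c_tccho) & !is.na(df$toc) & df$c_tccho > df$toc
  if (any(bad))
    stop("c_tccho exceeds toc for sample(s): ",
         paste(df$sample_id[bad], collapse = ", "))
  class(df) <- c("sample_chemistry", "data.frame")
  df
}

#' Frozen-fraction curve of an assay
#'
#' Counts, at each grid temperature `T`, the droplets already frozen by the
#' time the cooling ramp reaches `T` (a droplet freezing exactly at `T`
#' counts as frozen at `T`) and divides by the number dispensed.
#'
#' @param assay a [freezing_assay()].
#' @param temperature_grid strictly descending temperatures \[K\].
#' @return data frame of class `"inm_spectrum"` with columns `temp_K`,
#'   `temp_C`, `n_frozen`, `n_total`, `frozen_fraction`; assay metadata kept
#'   as attributes.
#' @export
frozen_fraction_curve <- function(assay,
                                  temperature_grid =
                                    default_temperature_grid()) {
  stopifnot(inherits(assay, "freezing_assay"))
  .check_grid(temperature_grid)
  k <- vapply(temperature_grid,
              function(T) sum(assay$freezing_temperatures >= T), numeric(1))
  out <- data.frame(temp_K = temperature_grid,
                    temp_C = kelvin_to_celsius(temperature_grid),
                    n_frozen = as.integer(k),
                    n_total = assay$n_droplets_total,
                    frozen_fraction = k / assay$n_droplets_total)
  attr(out, "sample_id") <- assay$sample_id
  attr(out, "droplet_volume") <- assay$droplet_volume
  attr(out, "dilution_factor") <- assay$dilution_factor
  attr(out, "treatment") <- assay$treatment
  attr(out, "normalization_basis") <- "per_volume"
  class(out) <- c("inm_spectrum", "data.frame")
  out
}

#' Cumulative INM concentration spectrum
#'
#' Vali transform of a frozen-fraction curve:
#' `n(T) = -ln(1 - f(T)) / V * dilution` \[INM per litre of original
#' sample\], with Clopper-Pearson bounds on `f` pushed through the same
#' transform. Grid points where every droplet froze (`f = 1`) cannot give a
#' finite cumulative value; they are flagged `censored` and reported as the
#' lower bound obtained from `f = (k - 0.5)/k`.
#'
#' @param spectrum output of [frozen_fraction_curve()].
#' @param conf_level confidence level for the binomial bounds.
#' @return the spectrum with columns `n_inm_per_L`, `ci_low`, `ci_high`,
#'   `censored` added.
#' @export
cumulative_inm_concentration <- function(spectrum, conf_level = 0.95) {
  stopifnot(inherits(spectrum, "inm_spectrum"))
  f <- spectrum$frozen_fraction
  if (any(f < 0 | f > 1)) stop("frozen fractions must lie in [0, 1]")
  V <- attr(spectrum, "droplet_volume")
  dil <- attr(spectrum, "dilution_factor")
  k <- spectrum$n_frozen
  n <- spectrum$n_total
  censored <- f >= 1
  f_eff <- ifelse(censored, (k - 0.5) / k, f)
  ci <- clopper_pearson(k, n, conf_level)
  # upper CP bound can be 1 (when k = n); the transformed upper bound is then
  # unbounded and reported Inf, consistent with the censoring flag
  to_n <- function(ff) -log1p(-pmin(ff, 1)) / V * dil
  spectrum$n_inm_per_L <- to_n(f_eff)
  spectrum$ci_low <- to_n(ci[, "lower"])
  spectrum$ci_high <- to_n(ci[, "upper"])
  spectrum$censored <- censored
  spectrum
}

#' Normalise a spectrum to a chemical basis
#'
#' Divides the cumulative INM concentration by the sample's basis
#' concentration, giving the INM number site density `n_m` \[INM per gram of
#' basis\] (e.g. `n_m,C-TCCHO` per gram carbohydrate carbon). With
#' `basis = "per_volume"` the spectrum is returned unchanged.
#'
#' @param spectrum output of [cumulative_inm_concentration()].
#' @param chemistry a [sample_chemistry()] table containing the spectrum's
#'   sample.
#' @param basis `"c_tccho"`, `"toc"`, `"dry_mass"` or `"per_volume"`.
#' @return the spectrum with `n_m`, `n_m_ci_low`, `n_m_ci_high` added and the
#'   `normalization_basis` attribute set.
#' @export
normalize_spectrum <- function(spectrum, chemistry = NULL,
                               basis = c("c_tccho", "toc", "dry_mass",
                                         "per_volume")) {
  stopifnot(inherits(spectrum, "inm_spectrum"))
  basis <- match.arg(basis)
  if (basis == "per_volume") return(spectrum)
  if (is.null(spectrum$n_inm_per_L))
    stop("run cumulative_inm_concentration() first")
  id <- attr(spectrum, "sample_id")
  conc <- .basis_concentration(chemistry, id, basis)
  spectrum$n_m <- spectrum$n_inm_per_L / conc
  if (!is.null(spectrum$ci_low)) {
    spectrum$n_m_ci_low <- spectrum$ci_low / conc
    spectrum$n_m_ci_high <- spectrum$ci_high / conc
  }
  attr(spectrum, "normalization_basis") <- basis
  attr(spectrum, "basis_concentration") <- conc
  spectrum
}

.basis_concentration <- function(chemistry, sample_id, basis) {
  if (is.null(chemistry)) stop("chemistry table required for basis ", basis)
  row <- chemistry[chemistry$sample_id == sample_id, , drop = FALSE]
  if (nrow(row) == 0)
    stop("no chemistry record for sample '", sample_id, "'")
  conc <- row[[basis]][1]
  if (is.na(conc) || conc <= 0)
    stop(sprintf("basis '%s' concentration missing or zero for sample '%s'",
                 basis, sample_id))
  conc
}

#' Percent reduction of INM concentration by a treatment
#'
#' `100 (1 - n_treated(T) / n_reference(T))` at a shared grid temperature,
#' with a propagated confidence interval from the two spectra's binomial
#' bounds (ratio of interval endpoints; conservative). Negative values mean
#' enhancement.
#'
#' @param reference,treated spectra from [cumulative_inm_concentration()]
#'   sharing a grid that contains `T`.
#' @param T temperature \[K\] at which to compare.
#' @return list with `estimate` (percent), `ci` (length 2), `flagged`
#'   (`TRUE` when the reference concentration is zero or a bound is
#'   unbounded).
#' @export
treatment_reduction <- function(reference, treated, T) {
  stopifnot(inherits(reference, "inm_spectrum"),
            inherits(treated, "inm_spectrum"))
  ir <- match(TRUE, abs(reference$temp_K - T) < 1e-9)
  it <- match(TRUE, abs(treated$temp_K - T) < 1e-9)
  if (is.na(ir) || is.na(it))
    stop("both spectra must contain grid temperature T")
  n_r <- reference$n_inm_per_L[ir]
  n_t <- treated$n_inm_per_L[it]
  if (!is.finite(n_r) || n_r <= 0)
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                flagged = TRUE))
  est <- 100 * (1 - n_t / n_r)
  lo <- 100 * (1 - treated$ci_high[it] / reference$ci_low[ir])
  hi <- 100 * (1 - treated$ci_low[it] / reference$ci_high[ir])
  flag <- !is.finite(lo) || !is.finite(hi)
  list(estimate = est, ci = c(lo, hi), flagged = flag)
}

#' Subtract a paired pure-water background spectrum
#'
#' Subtracts the background's cumulative INM concentration in n-space,
#' floored at zero. Off by default in the pipeline: the assay literature
#' reports sample signals relative to background without prescribing
#' subtraction, so this is an explicit opt-in.
#'
#' @param spectrum,background spectra from [cumulative_inm_concentration()]
#'   on the same grid.
#' @return `spectrum` with `n_inm_per_L` (and bounds) background-corrected.
#' @export
subtract_background <- function(spectrum, background) {
  stopifnot(inherits(spectrum, "inm_spectrum"),
            inherits(background, "inm_spectrum"))
  if (!isTRUE(all.equal(spectrum$temp_K, background$temp_K)))
    stop("spectrum and background must share a temperature grid")
  b <- background$n_inm_per_L
  spectrum$n_inm_per_L <- pmax(0, spectrum$n_inm_per_L - b)
  if (!is.null(spectrum$ci_low)) {
    spectrum$ci_low <- pmax(0, spectrum$ci_low - b)
    spectrum$ci_high <- pmax(0, spectrum$ci_high - b)
  }
  spectrum
}

#' One-call assay reduction
#'
#' Chains [frozen_fraction_curve()], [cumulative_inm_concentration()] and
#' [normalize_spectrum()].
#'
#' @inheritParams frozen_fraction_curve
#' @inheritParams normalize_spectrum
#' @param conf_level binomial confidence level.
#' @return an `"inm_spectrum"` data frame.
#' @export
assay_spectrum <- function(assay, chemistry = NULL, basis = "per_volume",
                           temperature_grid = default_temperature_grid(),
                           conf_level = 0.95) {
  sp <- frozen_fraction_curve(assay, temperature_grid)
  sp <- cumulative_inm_concentration(sp, conf_level)
  normalize_spectrum(sp, chemistry, basis)
}

# ---- CSV interfaces -------------------------------------------------------

#' Read droplet freezing assays from CSV
#'
#' Expected columns: `sample_id`, `droplet_id`, `droplet_volume_uL`,
#' `dilution_factor`, `freeze_temp_C` (empty for droplets that never froze),
#' `treatment`, `background_id`. One assay is built per unique
#' (`sample_id`, `treatment`, `dilution_factor`) combination.
#'
#' @param path CSV file path.
#' @return named list of [freezing_assay()] objects.
#' @export
read_assay_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "droplet_id", "droplet_volume_uL",
            "dilution_factor", "freeze_temp_C")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("assay CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(df$treatment)) df$treatment <- "none"
  if (is.null(df$background_id)) df$background_id <- NA_character_
  key <- interaction(df$sample_id, df$treatment, df$dilution_factor,
                     drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    temps <- suppressWarnings(as.numeric(g$freeze_temp_C))
    temps <- temps[!is.na(temps)]
    freezing_assay(sample_id = g$sample_id[1],
                   droplet_volume = g$droplet_volume_uL[1] * 1e-6,
                   dilution_factor = g$dilution_factor[1],
                   freezing_temperatures = celsius_to_kelvin(temps),
                   n_droplets_total = nrow(g),
                   treatment = g$treatment[1],
                   background_id = g$background_id[1])
  })
  names(out) <- levels(key)
  out
}

#' Read sample chemistry from CSV
#'
#' Expected columns: `sample_id`, `c_tccho_gC_per_L`, `toc_gC_per_L`,
#' `dry_mass_g_per_L` (the latter two optional).
#'
#' @param path CSV file path.
#' @return a [sample_chemistry()] table.
#' @export
read_chemistry_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "c_tccho_gC_per_L") %in% names(df)))
    stop("chemistry CSV needs sample_id and c_tccho_gC_per_L")
  sample_chemistry(df$sample_id, df$c_tccho_gC_per_L,
                   toc = if (is.null(df$toc_gC_per_L)) NA_real_
                         else df$toc_gC_per_L,
                   dry_mass = if (is.null(df$dry_mass_g_per_L)) NA_real_
                              else df$dry_mass_g_per_L)
}

#' Write spectra to CSV
#'
#' Emits one row per grid temperature with Celsius temperatures and the
#' basis/censoring metadata: `sample_id`, `temp_C`, `frozen_fraction`,
#' `n_inm_per_L`, `ci_low`, `ci_high`, `n_m`, `basis`, `censored_flag`.
#'
#' @param spectra an `"inm_spectrum"` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectra, path) {
  if (inherits(spectra, "inm_spectrum")) spectra <- list(spectra)
  rows <- lapply(spectra, function(sp) {
    data.frame(sample_id = attr(sp, "sample_id"),
               temp_C = sp$temp_C,
               frozen_fraction = sp$frozen_fraction,
               n_inm_per_L = if (is.null(sp$n_inm_per_L)) NA_real_
                             else sp$n_inm_per_L,
               ci_low = if (is.null(sp$ci_low)) NA_real_ else sp$ci_low,
               ci_high = if (is.null(sp$ci_high)) NA_real_ else sp$ci_high,
               n_m = if (is.null(sp$n_m)) NA_real_ else sp$n_m,
               basis = attr(sp, "normalization_basis"),
               censored_flag = if (is.null(sp$censored)) FALSE
                               else sp$censored)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.inm_spectrum <- function(x, y_col = c("n_inm_per_L", "frozen_fraction",
                                           "n_m"), ...) {
  y_col <- match.arg(y_col)
  yv <- x[[y_col]]
  ok <- is.finite(yv) & yv > 0
  logy <- if (y_col == "frozen_fraction") "" else "y"
  plot(x$temp_C[ok], yv[ok], log = logy, xlab = "temperature [C]",
       ylab = y_col, pch = 19, ...)
  invisible(x)
}
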