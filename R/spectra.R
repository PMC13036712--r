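# TD-DFT excitation tables to UV-vis spectra: Gaussian band broadening on a
# wavenumber grid, unit conversions, oscillator-strength/dipole relations,
# snapshot-ensemble statistics, and Beer-Lambert absorptivity fits.

#' Electronic excitation table
#'
#' @param position Band positions; interpreted per `unit` and stored as
#'   wavenumbers (cm^-1).
#' @param f Oscillator strengths (dimensionless, >= 0).
#' @param unit Unit of `position`: `"cm-1"`, `"nm"` or `"eV"`.
#' @param label Optional snapshot identifier.
#' @return An `excitation_table` data frame (columns `nu_cm1`, `f`).
#' @export
excitation_table <- function(position, f, unit = c("cm-1", "nm", "eV"),
                             label = NULL) {
  unit <- match.arg(unit)
  stopifnot(length(position) == length(f))
  if (length(position) == 0) stop("excitation_table: at least one excitation required")
  if (any(!is.finite(position)) || any(position <= 0)) {
    stop("excitation_table: positions must be positive")
  }
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("excitation_table: oscillator strengths must be non-negative")
  }
  nu <- convert_position(position, unit, "cm-1")
  structure(data.frame(nu_cm1 = nu, f = f),
            label = label, class = c("excitation_table", "data.frame"))
}

#' Convert a spectral position between nm, cm^-1 and eV
#'
#' Uses the exact reciprocal relation nu'(cm^-1) = 1e7 / lambda(nm) and the
#' photon-energy relation E(eV) = 1239.842 / lambda(nm).
#'
#' @param value Positive position value(s).
#' @param from_unit,to_unit One of `"nm"`, `"cm-1"`, `"eV"`.
#' @return Converted value(s).
#' @examples
#' convert_position(334, "nm", "cm-1")  # 29940.12
#' @export
convert_position <- function(value, from_unit, to_unit) {
  units <- c("nm", "cm-1", "eV")
  from_unit <- match.arg(from_unit, units)
  to_unit <- match.arg(to_unit, units)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("convert_position: values must be positive")
  }
  nm <- switch(from_unit,
    nm = value,
    `cm-1` = 1e7 / value,
    eV = .EV_NM / value)
  switch(to_unit,
    nm = nm,
    `cm-1` = 1e7 / nm,
    eV = .EV_NM / nm)
}

#' Gaussian absorption band of one electronic transition
#'
#' Molar absorptivity contributed at wavenumber `nu` by a transition at
#' `nu_if` with oscillator strength `f`, broadened to a full width at half
#' maximum `fwhm`:
#' \deqn{\epsilon(\nu) = \frac{2.175\times 10^8}{\Delta\nu_{1/2}} f
#'   \exp\left(-2.772\,\frac{(\nu-\nu_{i\to f})^2}{\Delta\nu_{1/2}^2}\right).}
#' The literal constants 2.175e8 and 2.772 (= 4 ln 2 to three significant
#' figures) are used as is, matching the standard convolution convention.
#'
#' @param nu Evaluation wavenumber(s) (cm^-1).
#' @param nu_if Transition wavenumber (cm^-1).
#' @param f Oscillator strength.
#' @param fwhm Full width at half maximum (cm^-1), > 0.
#' @return Molar absorptivity (M^-1 cm^-1).
#' @export
band_epsilon <- function(nu, nu_if, f, fwhm) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("band_epsilon: fwhm must be positive")
  if (any(f < 0)) stop("band_epsilon: f must be non-negative")
  (2.175e8 / fwhm) * f * exp(-2.772 * (nu - nu_if)^2 / fwhm^2)
}

#' Convolute an excitation table into a UV-vis spectrum
#'
#' Pointwise sum of [band_epsilon()] over all excitations on a wavenumber
#' grid. Warns when the grid does not cover every band by at least 5 FWHM on
#' both sides.
#'
#' @param table An [excitation_table()].
#' @param grid Strictly increasing wavenumber grid (cm^-1); default
#'   10,000-50,000 cm^-1 at 10 cm^-1 spacing.
#' @param fwhm Band FWHM (cm^-1), default 3000.
#' @return A `spectrum_uv` data frame with columns `nu_cm1`, `epsilon` and
#'   attribute `fwhm`.
#' @export
convolve_spectrum <- function(table, grid = seq(10000, 50000, by = 10),
                              fwhm = 3000) {
  stopifnot(inherits(table, "excitation_table"))
  if (nrow(table) == 0) stop("convolve_spectrum: empty excitation table")
  if (any(diff(grid) <= 0)) stop("convolve_spectrum: grid must be strictly increasing")
  if (!is.finite(fwhm) || fwhm <= 0) stop("convolve_spectrum: fwhm must be positive")
  if (min(table$nu_cm1) - 5 * fwhm < min(grid) ||
      max(table$nu_cm1) + 5 * fwhm > max(grid)) {
    warning("convolve_spectrum: grid does not cover all bands +/- 5 FWHM; ",
            "band tails are truncated")
  }
  eps <- rep(0, length(grid))
  for (i in seq_len(nrow(table))) {
    eps <- eps + band_epsilon(grid, table$nu_cm1[i], table$f[i], fwhm)
  }
  structure(data.frame(nu_cm1 = grid, epsilon = eps),
            fwhm = fwhm, label = attr(table, "label"),
            class = c("spectrum_uv", "data.frame"))
}

#' Transition dipole moment from oscillator strength
#'
#' Length-gauge atomic-unit identity \eqn{f = (2/3)\,\Delta E\,|M|^2} with
#' the excitation energy in hartree, inverted for the dipole magnitude.
#'
#' @param f Oscillator strength (>= 0).
#' @param position Transition position, in the unit given by `unit`.
#' @param unit Unit of `position` (default `"cm-1"`).
#' @return |M| in atomic units (e a0).
#' @examples
#' dipole_from_f(0.47, 334, "nm")  # about 2.273 a.u.
#' @export
dipole_from_f <- function(f, position, unit = c("cm-1", "nm", "eV")) {
  unit <- match.arg(unit)
  if (any(f < 0)) stop("dipole_from_f: f must be non-negative")
  nu <- convert_position(position, unit, "cm-1")
  dE_hartree <- nu / .HARTREE_CM1
  sqrt(3 * f / (2 * dE_hartree))
}

#' Oscillator strength from a transition dipole
#'
#' Inverse of [dipole_from_f()]: \eqn{f = (2/3)\Delta E |M|^2}.
#'
#' @param M_au Dipole magnitude (atomic units).
#' @param position Transition position.
#' @param unit Unit of `position`.
#' @return Oscillator strength.
#' @export
f_from_dipole <- function(M_au, position, unit = c("cm-1", "nm", "eV")) {
  unit <- match.arg(unit)
  nu <- convert_position(position, unit, "cm-1")
  (2 / 3) * (nu / .HARTREE_CM1) * M_au^2
}

#' Ensemble statistics of a band over thermal snapshots
#'
#' For each snapshot table, the band inside `band_window` is convolved and
#' its absorption maximum located; the function reports the population mean
#' and standard deviation of the per-snapshot maxima (in nm) and the range
#' of oscillator strengths of the excitations inside the window.
#'
#' @param tables List of [excitation_table()] objects (>= 2).
#' @param band_window Length-2 nm window selecting one band per snapshot.
#' @param fwhm Broadening FWHM (cm^-1).
#' @param grid_step Wavenumber grid step (cm^-1) for locating the maximum.
#' @return List with `lambda_max_nm` (per snapshot), `mean_nm`, `sd_nm`
#'   (population), `f_range`.
#' @export
ensemble_stats <- function(tables, band_window, fwhm = 3000, grid_step = 1) {
  stopifnot(is.list(tables), length(tables) >= 2, length(band_window) == 2)
  lo_nm <- min(band_window); hi_nm <- max(band_window)
  nu_lo <- 1e7 / hi_nm; nu_hi <- 1e7 / lo_nm
  lam <- numeric(length(tables))
  f_all <- c()
  for (i in seq_along(tables)) {
    tab <- tables[[i]]
    stopifnot(inherits(tab, "excitation_table"))
    sel <- tab$nu_cm1 >= nu_lo & tab$nu_cm1 <= nu_hi
    if (!any(sel)) {
      lbl <- attr(tab, "label")
      stop(sprintf("ensemble_stats: no excitation in window for snapshot %s",
                   if (is.null(lbl)) as.character(i) else lbl))
    }
    sub <- excitation_table(tab$nu_cm1[sel], tab$f[sel], unit = "cm-1")
    grid <- seq(nu_lo, nu_hi, by = grid_step)
    # the window is deliberately narrow: only the in-window maximum is used
    sp <- suppressWarnings(convolve_spectrum(sub, grid = grid, fwhm = fwhm))
    lam[i] <- 1e7 / sp$nu_cm1[which.max(sp$epsilon)]
    f_all <- c(f_all, tab$f[sel])
  }
  n <- length(lam)
  m <- mean(lam)
  list(lambda_max_nm = lam,
       mean_nm = m,
       sd_nm = sqrt(sum((lam - m)^2) / n),
       f_range = range(f_all))
}

#' Beer-Lambert molar absorptivity from a dilution series
#'
#' Zero-intercept least-squares slope of absorbance versus concentration,
#' divided by the optical path length.
#'
#' @param conc Concentrations (M), >= 3 values, not all zero.
#' @param absorbance Absorbances at the analytical wavelength.
#' @param path_cm Optical path (cm), default 1.
#' @return Molar absorptivity epsilon (M^-1 cm^-1).
#' @export
molar_absorptivity <- function(conc, absorbance, path_cm = 1) {
  stopifnot(length(conc) == length(absorbance), length(conc) >= 3)
  if (!is.finite(path_cm) || path_cm <= 0) {
    stop("molar_absorptivity: path must be positive")
  }
  if (all(conc == 0)) stop("molar_absorptivity: all concentrations are zero")
  (sum(conc * absorbance) / sum(conc^2)) / path_cm
}

#' Integrate a spectrum and recover the total oscillator strength
#'
#' Trapezoidal integral of epsilon over wavenumber, converted back to a
#' total oscillator strength through the Gaussian area identity
#' (area = 1.0645 * peak * FWHM for each band).
#'
#' @param spectrum A `spectrum_uv` (from [convolve_spectrum()]).
#' @return List with `integral` (M^-1 cm^-2) and `f_total`.
#' @export
integrate_spectrum <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum_uv"))
  nu <- spectrum$nu_cm1; eps <- spectrum$epsilon
  area <- sum(diff(nu) * (eps[-1] + eps[-length(eps)]) / 2)
  list(integral = area, f_total = area / (2.175e8 * 1.0645))
}
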