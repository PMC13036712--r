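# Seeded generators for every input the analysis consumes: titration and
# IDA series, TCSPC decay traces, thermally jittered excitation ensembles,
# and solvation-shell trajectories. Each is a pure function of
# (parameters, seed); the caller's RNG state is left untouched.
#
# Defaults mirror the study regimes the package targets: association
# constants near 5e5 M^-1, ~1 uM indicator, a 0-90 uM host sweep, an
# 8-1500 uM competitor sweep, and a 3000 cm^-1 broadening width.

#' Generate a 1:1 host-titration series
#'
#' Sweeps total host at fixed indicator, computes the exact 1:1 equilibrium
#' signal and applies multiplicative Gaussian noise:
#' `signal = predict_signal(...) * (1 + N(0, noise_sd))`.
#'
#' @param K Association constant (M^-1), > 0.
#' @param H_totals Host totals (M), >= 4 values.
#' @param I_total Indicator total (M).
#' @param signal_params `c(I_free_coeff, I_complex_coeff)` intensity per M.
#' @param noise_sd Relative noise standard deviation (0 = noiseless).
#' @param seed Integer seed (mandatory).
#' @return A [titration_series()] with mode `"host_titration"`.
#' @export
gen_titration <- function(K, H_totals = c(0, 1, 2, 3, 4, 5, 6, 8, 10, 12,
                                          15, 20, 25, 30, 40, 50, 60, 75,
                                          90) * 1e-6,
                          I_total = 1.16e-6,
                          signal_params = c(2.1e6, 9.8e6),
                          noise_sd = 0, seed) {
  if (!is.finite(K) || K <= 0) stop("gen_titration: K must be positive")
  if (length(H_totals) < 4 || any(H_totals < 0)) {
    stop("gen_titration: need >= 4 non-negative host totals")
  }
  if (missing(seed)) stop("gen_titration: a seed is required")
  mu <- vapply(H_totals, function(h)
    predict_signal(solve_1to1(h, I_total, K), signal_params), numeric(1))
  sig <- .with_seed(seed, mu * (1 + stats::rnorm(length(mu), 0, noise_sd)))
  titration_series(H_total = H_totals, I_total = I_total, G_total = 0,
                   signal = sig, mode = "host_titration")
}

#' Generate a competitive indicator-displacement series
#'
#' Sweeps total competitor at fixed host and indicator through the exact
#' competitive equilibrium; noise as in [gen_titration()]. With the complex
#' brighter than the free indicator and no noise the signal is monotone
#' non-increasing in the competitor total.
#'
#' @param K1 Host-indicator association constant (M^-1).
#' @param K2 Host-competitor association constant (M^-1); 0 gives a flat
#'   series.
#' @param H_total,I_total Fixed totals (M).
#' @param G_totals Competitor totals (M), >= 4 values.
#' @inheritParams gen_titration
#' @return A [titration_series()] with mode `"competitor_titration"`.
#' @export
gen_ida <- function(K1 = 4.54e5, K2 = 5.5e5, H_total = 10e-6,
                    I_total = 1e-6,
                    G_totals = exp(seq(log(8e-6), log(1500e-6),
                                       length.out = 16)),
                    signal_params = c(2.1e6, 9.8e6), noise_sd = 0, seed) {
  if (!is.finite(K1) || K1 <= 0) stop("gen_ida: K1 must be positive")
  if (!is.finite(K2) || K2 < 0) stop("gen_ida: K2 must be non-negative")
  if (length(G_totals) < 4 || any(G_totals < 0)) {
    stop("gen_ida: need >= 4 non-negative competitor totals")
  }
  if (missing(seed)) stop("gen_ida: a seed is required")
  mu <- vapply(G_totals, function(g) {
    st <- solve_competitive(equilibrium_system(H_total, I_total, g, K1,
                                               max(K2, 1e-30)))
    predict_signal(st, signal_params)
  }, numeric(1))
  sig <- .with_seed(seed, mu * (1 + stats::rnorm(length(mu), 0, noise_sd)))
  titration_series(H_total = H_total, I_total = I_total, G_total = G_totals,
                   signal = sig, mode = "competitor_titration")
}

#' Generate a TCSPC decay trace with IRF smearing
#'
#' Builds the expected decay as the reconvolution of a multi-exponential
#' law (amplitudes set from the requested fractional intensities) with a
#' Gaussian IRF, scales it to the requested peak counts, and draws Poisson
#' counts per bin. The (noise-free) IRF histogram is included in the trace.
#'
#' @param lifetimes Component lifetimes (ns).
#' @param fractions Fractional intensities (sum to 1).
#' @param irf_fwhm IRF full width at half maximum (ns).
#' @param peak_counts Expected counts in the peak bin (default 10000).
#' @param bin_width Bin width (ns).
#' @param n_bins Number of bins.
#' @param background Expected background counts per bin (default 0).
#' @param seed Integer seed.
#' @param expectation If TRUE, return the expected (noise-free) counts
#'   instead of Poisson draws.
#' @return A [decay_trace()]; the generating `multi_exp_model` is attached
#'   as attribute `"model"`.
#' @export
gen_decay <- function(lifetimes, fractions, irf_fwhm = 0.2,
                      peak_counts = 10000, bin_width = 0.02, n_bins = 2048,
                      background = 0, seed, expectation = FALSE) {
  stopifnot(length(lifetimes) == length(fractions))
  if (any(lifetimes <= 0)) stop("gen_decay: lifetimes must be positive")
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0)) {
    stop("gen_decay: fractions must be non-negative and sum to 1")
  }
  if (missing(seed)) stop("gen_decay: a seed is required")
  edges <- seq(0, by = bin_width, length.out = n_bins + 1)
  t_centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  # Gaussian IRF centered early in the window
  sigma <- irf_fwhm / (2 * sqrt(2 * log(2)))
  t0 <- max(10 * sigma, 20 * bin_width)
  irf_shape <- exp(-(t_centers - t0)^2 / (2 * sigma^2))
  irf_counts <- round(irf_shape / max(irf_shape) * peak_counts)
  # amplitudes from fractional intensities: a_i proportional to f_i / tau_i
  a_raw <- fractions / lifetimes
  model <- multi_exp_model(a_raw, lifetimes, shift = 0, background = 0)
  mu <- reconvolve(model, irf_counts, edges)
  scale <- peak_counts / max(mu)
  mu <- mu * scale + background
  model <- multi_exp_model(model$amplitudes * scale, model$lifetimes,
                           shift = 0, background = background)
  counts <- if (expectation) mu else .with_seed(seed, stats::rpois(n_bins, mu))
  tr <- decay_trace(edges, counts, irf_counts)
  attr(tr, "model") <- model
  tr
}

#' Generate a thermally jittered excitation ensemble
#'
#' Adds Gaussian jitter to band positions (in the wavelength domain, where
#' thermal solvation shifts are approximately normal) and to oscillator
#' strengths (floored at 0), producing one table per snapshot.
#'
#' @param base_table An [excitation_table()].
#' @param sigma_lambda Position jitter s.d. (nm).
#' @param sigma_f Oscillator-strength jitter s.d.
#' @param n_snapshots Number of snapshots (>= 1).
#' @param seed Integer seed.
#' @return List of `excitation_table` objects labeled `snap<i>`.
#' @export
gen_excitation_ensemble <- function(base_table, sigma_lambda = 6,
                                    sigma_f = 0, n_snapshots = 10, seed) {
  stopifnot(inherits(base_table, "excitation_table"))
  if (sigma_lambda < 0 || sigma_f < 0) stop("gen_excitation_ensemble: sigmas must be >= 0")
  if (n_snapshots < 1) stop("gen_excitation_ensemble: n_snapshots must be >= 1")
  if (missing(seed)) stop("gen_excitation_ensemble: a seed is required")
  lam0 <- 1e7 / base_table$nu_cm1
  f0 <- base_table$f
  .with_seed(seed, {
    lapply(seq_len(n_snapshots), function(i) {
      lam <- lam0 + stats::rnorm(length(lam0), 0, sigma_lambda)
      if (any(lam <= 0)) stop("gen_excitation_ensemble: jitter produced non-positive wavelength")
      f <- pmax(f0 + stats::rnorm(length(f0), 0, sigma_f), 0)
      excitation_table(lam, f, unit = "nm", label = sprintf("snap%d", i))
    })
  })
}

# Unit vector at polar angle theta (deg) from +x, random azimuth.
.dir_at_angle <- function(theta_deg) {
  th <- theta_deg * pi / 180
  phi <- stats::runif(1, 0, 2 * pi)
  c(cos(th), sin(th) * cos(phi), sin(th) * sin(phi))
}

#' Generate solvation frames with a planted first shell
#'
#' Builds a trajectory around a fixed two-atom solute donor site (heavy
#' atom `"SD"` at the box center with its hydrogen `"SH"` along +x).
#' `planted_shell` waters are placed at prescribed acceptor-donor distances
#' and acceptor-donor-hydrogen angles (so hydrogen-bond-satisfying and
#' -violating geometries can be planted exactly); the remaining waters are
#' uniform with overlap rejection and are kept outside `exclusion_radius`
#' of the solute. Water labels are `"OW"`, `"HW"`, `"HW"`.
#'
#' @param n_waters Total number of waters (planted + random).
#' @param box Box lengths (Angstrom).
#' @param planted_shell Data frame with columns `distance` (Angstrom) and
#'   `angle` (degrees, acceptor-donor-hydrogen at the solute donor), one
#'   row per planted water; NULL for none.
#' @param n_frames Number of frames (planted geometry fixed; random waters
#'   redrawn each frame).
#' @param seed Integer seed.
#' @param min_separation Minimum O-O separation (Angstrom, default 2.5).
#' @param exclusion_radius Random waters are kept at least this far from
#'   the solute center (Angstrom, default 4).
#' @return A [trajectory()]; planted water indices (into the water list)
#'   are attached as attribute `"planted"`.
#' @export
gen_solvation_frames <- function(n_waters, box = c(25, 25, 25),
                                 planted_shell = NULL, n_frames = 1, seed,
                                 min_separation = 2.5,
                                 exclusion_radius = 4) {
  if (missing(seed)) stop("gen_solvation_frames: a seed is required")
  n_planted <- if (is.null(planted_shell)) 0 else nrow(planted_shell)
  if (n_planted > n_waters) stop("gen_solvation_frames: more planted waters than n_waters")
  # crude packing feasibility check
  if (min_separation > 0 &&
      n_waters * 4 / 3 * pi * (min_separation / 2)^3 > 0.65 * prod(box)) {
    stop("gen_solvation_frames: box cannot accommodate n_waters at the requested separation")
  }
  center <- box / 2
  d_oh <- 0.9572
  solute <- rbind(SD = center, SH = center + c(d_oh, 0, 0))

  .with_seed(seed, {
    make_water <- function(O, toward = NULL) {
      # hydrogens ~104.5 deg apart, oriented along `toward` (or random)
      axis <- if (is.null(toward)) .dir_at_angle(stats::runif(1, 0, 180)) else toward
      axis <- axis / sqrt(sum(axis^2))
      ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- ref - sum(ref * axis) * axis
      perp <- perp / sqrt(sum(perp^2))
      half <- 104.52 / 2 * pi / 180
      H1 <- O + d_oh * (cos(half) * axis + sin(half) * perp)
      H2 <- O + d_oh * (cos(half) * axis - sin(half) * perp)
      rbind(O, H1, H2)
    }
    planted_oxy <- NULL
    if (n_planted > 0) {
      planted_oxy <- t(vapply(seq_len(n_planted), function(i) {
        center + planted_shell$distance[i] * .dir_at_angle(planted_shell$angle[i])
      }, numeric(3)))
    }
    frames <- lapply(seq_len(n_frames), function(fi) {
      oxy <- matrix(NA_real_, n_waters, 3)
      if (n_planted > 0) oxy[seq_len(n_planted), ] <- planted_oxy
      placed <- n_planted
      tries <- 0
      while (placed < n_waters) {
        cand <- stats::runif(3) * box
        d_sol <- sqrt(sum(.min_image(cand - center, box)^2))
        ok <- d_sol >= exclusion_radius
        if (ok && placed > 0) {
          d <- .min_image(sweep(oxy[seq_len(placed), , drop = FALSE], 2, cand, `-`), box)
          ok <- min(sqrt(rowSums(d^2))) >= min_separation
        }
        if (ok) {
          placed <- placed + 1
          oxy[placed, ] <- cand
        }
        tries <- tries + 1
        if (tries > 20000 * n_waters) {
          stop("gen_solvation_frames: packing failed; box too small")
        }
      }
      coords <- solute
      labels <- c("SD", "SH")
      for (w in seq_len(n_waters)) {
        toward <- if (w <= n_planted) {
          v <- oxy[w, ] - center
          v / sqrt(sum(v^2))  # hydrogens point away from the solute
        } else NULL
        coords <- rbind(coords, make_water(oxy[w, ], toward = toward))
        labels <- c(labels, "OW", "HW", "HW")
      }
      dimnames(coords) <- NULL
      list(labels = labels, coords = coords)
    })
    tr <- trajectory(frames, box)
    attr(tr, "planted") <- seq_len(n_planted)
    tr
  })
}
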