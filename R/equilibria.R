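# Host-guest equilibrium models: 1:1 association and competitive
# indicator displacement, solved by exact mass balance.

#' Gas constant in kcal mol-1 K-1
#' @keywords internal
.R_KCAL <- 1.98720425e-3

#' Solve the 1:1 host-guest equilibrium
#'
#' Computes the equilibrium speciation of a single host H binding a single
#' indicator (guest) I with association constant `K1`, by the quadratic
#' mass-balance equation: the complex concentration is the smaller root of
#' \deqn{x^2 - (H_T + I_T + 1/K_1)x + H_T I_T = 0.}
#' The smaller root is the only one satisfying both mass balances with
#' non-negative free concentrations.
#'
#' @param H_total Total host concentration (M).
#' @param I_total Total indicator concentration (M).
#' @param K1 Association constant (M^-1). `K1 = Inf` is accepted and returns
#'   the stoichiometric limit `HI = min(H_total, I_total)`; `K1 = 0` returns
#'   no binding.
#' @return A `species_state` list with components `free_H`, `free_I`,
#'   `free_G`, `HI`, `HG` (all M; `free_G` and `HG` are 0 here).
#' @examples
#' solve_1to1(1e-5, 1e-5, 1e5)$HI  # 3.8197e-6 M
#' @export
solve_1to1 <- function(H_total, I_total, K1) {
  stopifnot(length(H_total) == 1L, length(I_total) == 1L, length(K1) == 1L)
  if (is.na(H_total) || is.na(I_total) || is.na(K1) ||
      H_total < 0 || I_total < 0 || K1 < 0) {
    stop("solve_1to1: H_total, I_total and K1 must be finite and non-negative")
  }
  if (K1 == 0 || H_total == 0 || I_total == 0) {
    HI <- 0
  } else if (is.infinite(K1)) {
    HI <- min(H_total, I_total)
  } else {
    b <- H_total + I_total + 1 / K1
    disc <- b^2 - 4 * H_total * I_total
    # smaller root in the cancellation-free form 2c / (b + sqrt(disc))
    HI <- 2 * H_total * I_total / (b + sqrt(max(disc, 0)))
    HI <- min(HI, H_total, I_total)
  }
  species_state(free_H = H_total - HI, free_I = I_total - HI,
                free_G = 0, HI = HI, HG = 0)
}

#' Construct a species state
#'
#' Container for the equilibrium concentrations of the five species of the
#' competitive system (free host, free indicator, free competitor, and the
#' two binary complexes). All concentrations in molar.
#'
#' @param free_H,free_I,free_G,HI,HG Molar concentrations.
#' @return An object of class `species_state`.
#' @export
species_state <- function(free_H, free_I, free_G = 0, HI = 0, HG = 0) {
  structure(list(free_H = free_H, free_I = free_I, free_G = free_G,
                 HI = HI, HG = HG),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat("Equilibrium species (M):\n")
  cat(sprintf("  free H: %.6g   free I: %.6g   free G: %.6g\n",
              x$free_H, x$free_I, x$free_G))
  cat(sprintf("  HI:     %.6g   HG:     %.6g\n", x$HI, x$HG))
  invisible(x)
}

#' Define a competitive (indicator displacement) equilibrium system
#'
#' @param H_total Total host concentration (M).
#' @param I_total Total indicator concentration (M).
#' @param G_total Total competitor concentration (M); 0 reduces to the 1:1
#'   system.
#' @param K1 Host-indicator association constant (M^-1).
#' @param K2 Host-competitor association constant (M^-1).
#' @return An object of class `equilibrium_system`.
#' @export
equilibrium_system <- function(H_total, I_total, G_total, K1, K2) {
  vals <- c(H_total = H_total, I_total = I_total, G_total = G_total,
            K1 = K1, K2 = K2)
  if (any(is.na(vals)) || any(vals < 0)) {
    stop("equilibrium_system: all concentrations and constants must be non-negative")
  }
  structure(as.list(vals), class = "equilibrium_system")
}

#' Solve the competitive indicator-displacement equilibrium
#'
#' Solves the coupled equilibria H + I <-> HI (K1) and H + G <-> HG (K2)
#' under the three mass balances for host, indicator and competitor. The
#' problem reduces to a single monotone scalar equation in the free host
#' concentration h:
#' \deqn{h (1 + K_1 I_T/(1 + K_1 h) + K_2 G_T/(1 + K_2 h)) = H_T,}
#' which has exactly one root in [0, H_T]; it is bracketed and then polished
#' by Newton iterations to near machine precision.
#'
#' @param system An [equilibrium_system()].
#' @param tol Relative tolerance on the mass-balance residuals.
#' @return A `species_state`.
#' @export
solve_competitive <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "equilibrium_system"))
  H <- system$H_total; I <- system$I_total; G <- system$G_total
  K1 <- system$K1; K2 <- system$K2
  if (H == 0) {
    return(species_state(0, I, G, 0, 0))
  }
  if (K1 == 0 && K2 == 0) {
    return(species_state(H, I, G, 0, 0))
  }
  # residual of the host mass balance as a function of free host h
  f <- function(h) h * (1 + K1 * I / (1 + K1 * h) + K2 * G / (1 + K2 * h)) - H
  fp <- function(h) 1 + K1 * I / (1 + K1 * h)^2 + K2 * G / (1 + K2 * h)^2
  lo <- 0; hi <- H
  # f(0) = -H < 0, f(H) >= 0: bisection to a coarse bracket
  for (it in seq_len(200)) {
    mid <- 0.5 * (lo + hi)
    if (f(mid) < 0) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-6 * H) break
  }
  h <- 0.5 * (lo + hi)
  # Newton polish (f is smooth, increasing and convex-free of traps here)
  for (it in seq_len(60)) {
    step <- f(h) / fp(h)
    h_new <- h - step
    if (h_new <= 0) h_new <- h / 2
    if (h_new >= H) h_new <- 0.5 * (h + H)
    h <- h_new
    if (abs(step) <= 1e-16 * max(h, H * 1e-12)) break
  }
  free_I <- I / (1 + K1 * h)
  free_G <- G / (1 + K2 * h)
  st <- species_state(free_H = h, free_I = free_I, free_G = free_G,
                      HI = K1 * h * free_I, HG = K2 * h * free_G)
  res <- abs(st$free_H + st$HI + st$HG - H) / max(H, .Machine$double.xmin)
  if (res > max(tol, 1e-10)) {
    stop(sprintf("solve_competitive: mass balance residual %.3g exceeds tolerance", res))
  }
  st
}

#' Predict the spectroscopic signal of a species state
#'
#' Linear response model: the measured intensity is a linear combination of
#' the free indicator and the host-indicator complex (the free dye retains
#' residual emission; the complex is typically brighter).
#'
#' @param state A `species_state`.
#' @param signal_params Numeric length-2 vector `c(I_free_coeff,
#'   I_complex_coeff)`, intensity per molar.
#' @return Predicted intensity (arbitrary units).
#' @export
predict_signal <- function(state, signal_params) {
  stopifnot(inherits(state, "species_state"), length(signal_params) == 2L)
  if (any(!is.finite(signal_params))) {
    stop("predict_signal: signal coefficients must be finite")
  }
  signal_params[[1]] * state$free_I + signal_params[[2]] * state$HI
}

#' Assemble a titration series
#'
#' @param H_total,I_total,G_total Numeric vectors (recycled) of total
#'   concentrations (M).
#' @param signal Measured intensities (arbitrary units).
#' @param mode `"host_titration"` (host swept against fixed indicator, 1:1
#'   fit) or `"competitor_titration"` (competitor swept, IDA fit).
#' @return A `titration_series` data frame with attribute `mode`.
#' @export
titration_series <- function(H_total, I_total, G_total = 0, signal,
                             mode = c("host_titration", "competitor_titration")) {
  mode <- match.arg(mode)
  df <- data.frame(H_total = H_total, I_total = I_total,
                   G_total = G_total, signal = signal)
  if (any(df$H_total < 0 | df$I_total < 0 | df$G_total < 0)) {
    stop("titration_series: totals must be non-negative")
  }
  structure(df, mode = mode, class = c("titration_series", "data.frame"))
}

# Given the solved HI/free_I vectors, profile out the linear signal
# coefficients by (optionally restricted) linear least squares.
.signal_lsq <- function(free_I, HI, signal, signal_model) {
  X <- switch(signal_model,
    linear = cbind(free_I, HI),
    `complex-only` = cbind(HI))
  fit <- stats::lm.fit(X, signal)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  fitted <- as.numeric(X %*% coefs)
  if (signal_model == "complex-only") coefs <- c(0, coefs)
  list(coefs = unname(coefs), fitted = fitted,
       rss = sum((signal - fitted)^2))
}

.solved_1to1_series <- function(series, K) {
  states <- lapply(seq_len(nrow(series)), function(i)
    solve_1to1(series$H_total[i], series$I_total[i], K))
  list(free_I = vapply(states, `[[`, numeric(1), "free_I"),
       HI = vapply(states, `[[`, numeric(1), "HI"))
}

.solved_ida_series <- function(series, K1, K2) {
  states <- lapply(seq_len(nrow(series)), function(i)
    solve_competitive(equilibrium_system(series$H_total[i], series$I_total[i],
                                         series$G_total[i], K1, K2)))
  list(free_I = vapply(states, `[[`, numeric(1), "free_I"),
       HI = vapply(states, `[[`, numeric(1), "HI"))
}

# Profile residual sum of squares as a function of log10 K, for either model.
.profile_rss <- function(series, logK, solver, signal_model) {
  sol <- solver(10^logK)
  .signal_lsq(sol$free_I, sol$HI, series$signal, signal_model)$rss
}

# Grid + local refinement minimizer over log10 K. Multi-start is implicit in
# the coarse grid, which covers the full physically plausible range.
.optimize_logK <- function(series, solver, signal_model,
                           grid = seq(0, 12, by = 0.1)) {
  rss <- vapply(grid, function(lk) .profile_rss(series, lk, solver, signal_model),
                numeric(1))
  lk0 <- grid[which.min(rss)]
  opt <- stats::optimize(function(lk) .profile_rss(series, lk, solver, signal_model),
                         lower = lk0 - 0.15, upper = lk0 + 0.15, tol = 1e-10)
  opt$minimum
}

.check_identifiable <- function(series) {
  s <- series$signal
  span <- diff(range(s))
  if (!is.finite(span) || span <= 1e-9 * max(abs(s), 1e-300)) {
    stop("binding fit: signal is flat across the titration; ",
         "the binding constant is not identifiable")
  }
}

.new_binding_fit <- function(K_hat, coefs, residual_norm, K_interval,
                             n_boot, seed, model, K_boot) {
  structure(list(K_hat = K_hat,
                 signal_params = c(I_free_coeff = coefs[1],
                                   I_complex_coeff = coefs[2]),
                 residual_norm = residual_norm,
                 K_interval = K_interval,
                 n_boot = n_boot, seed = seed, model = model,
                 K_boot = K_boot),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("%s binding fit\n", if (x$model == "1:1") "1:1 host-guest"
              else "competitive IDA"))
  cat(sprintf("  K = %.4g M^-1  [%.4g, %.4g] (bootstrap %d, seed %d)\n",
              x$K_hat, x$K_interval[1], x$K_interval[2], x$n_boot, x$seed))
  cat(sprintf("  signal coefficients: free %.4g, complex %.4g (per M)\n",
              x$signal_params[1], x$signal_params[2]))
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' Fit the 1:1 binding constant from a host titration
#'
#' Least-squares fit of `log10 K1` with the two signal coefficients profiled
#' out linearly at each candidate K (variable projection). Uncertainty by
#' residual bootstrap: residuals are resampled with replacement, added back
#' to the fitted curve, and the fit repeated; the interval is the 2.5/97.5
#' percentile of the bootstrap K distribution.
#'
#' @param series A `titration_series` with mode `"host_titration"` and at
#'   least 4 points.
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Integer seed for the bootstrap (mandatory, recorded in the
#'   result).
#' @param signal_model `"linear"` (free indicator plus complex both emit) or
#'   `"complex-only"`.
#' @return A `binding_fit` with elements `K_hat`, `signal_params`,
#'   `residual_norm`, `K_interval`, `n_boot`, `seed`.
#' @export
fit_1to1 <- function(series, n_boot = 500, seed,
                     signal_model = c("linear", "complex-only")) {
  signal_model <- match.arg(signal_model)
  stopifnot(inherits(series, "titration_series"))
  if (attr(series, "mode") != "host_titration") {
    stop("fit_1to1: series mode must be 'host_titration'")
  }
  if (nrow(series) < 4) stop("fit_1to1: need at least 4 titration points")
  if (missing(seed)) stop("fit_1to1: a seed is required")
  .check_identifiable(series)

  solver <- function(K) .solved_1to1_series(series, K)
  fit_once <- function(sig, grid) {
    ser <- series; ser$signal <- sig
    lk <- .optimize_logK(ser, solver, signal_model, grid = grid)
    sol <- solver(10^lk)
    ls <- .signal_lsq(sol$free_I, sol$HI, sig, signal_model)
    list(K = 10^lk, coefs = ls$coefs, fitted = ls$fitted, rss = ls$rss)
  }
  main <- fit_once(series$signal, grid = seq(0, 12, by = 0.1))
  resid <- series$signal - main$fitted

  if (n_boot == 0) {
    return(.new_binding_fit(main$K, main$coefs, sqrt(main$rss),
                            c(main$K, main$K), 0L, seed, "1:1", numeric(0)))
  }
  K_boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      y_star <- main$fitted + sample(resid, length(resid), replace = TRUE)
      lk0 <- log10(main$K)
      fit_once(y_star, grid = seq(max(0, lk0 - 2), min(12, lk0 + 2), by = 0.1))$K
    }, numeric(1))
  })
  ki <- unname(stats::quantile(K_boot, c(0.025, 0.975), type = 7))
  ki <- c(min(ki[1], main$K), max(ki[2], main$K))
  .new_binding_fit(main$K, main$coefs, sqrt(main$rss), ki, n_boot, seed,
                   "1:1", K_boot)
}

#' Fit the competitor binding constant from an IDA titration
#'
#' Fits `log10 K2` for the competitor from a competitor-sweep series, with
#' the indicator constant `K1_fixed` held at its independently determined
#' value, through the exact competitive equilibrium solver. Signal
#' coefficients are profiled out linearly; bootstrap as in [fit_1to1()].
#'
#' @param series A `titration_series` with mode `"competitor_titration"`.
#' @param K1_fixed Host-indicator association constant (M^-1), from a prior
#'   1:1 fit.
#' @inheritParams fit_1to1
#' @return A `binding_fit` for K2.
#' @export
fit_ida <- function(series, K1_fixed, n_boot = 500, seed,
                    signal_model = c("linear", "complex-only")) {
  signal_model <- match.arg(signal_model)
  stopifnot(inherits(series, "titration_series"))
  if (attr(series, "mode") != "competitor_titration") {
    stop("fit_ida: series mode must be 'competitor_titration'")
  }
  if (nrow(series) < 4) stop("fit_ida: need at least 4 titration points")
  if (missing(seed)) stop("fit_ida: a seed is required")
  if (!is.finite(K1_fixed) || K1_fixed <= 0) {
    stop("fit_ida: K1_fixed must be positive")
  }
  .check_identifiable(series)
  # the competitor sweep must actually displace the indicator
  hi_range <- range(.solved_ida_series(series, K1_fixed, 1e9)$HI)
  sol0 <- .solved_ida_series(series, K1_fixed, 0)$HI

  solver <- function(K2) .solved_ida_series(series, K1_fixed, K2)
  fit_once <- function(sig, grid) {
    ser <- series; ser$signal <- sig
    lk <- .optimize_logK(ser, solver, signal_model, grid = grid)
    sol <- solver(10^lk)
    ls <- .signal_lsq(sol$free_I, sol$HI, sig, signal_model)
    list(K = 10^lk, coefs = ls$coefs, fitted = ls$fitted, rss = ls$rss)
  }
  main <- fit_once(series$signal, grid = seq(0, 12, by = 0.1))
  sol_hat <- solver(main$K)
  if (diff(range(sol_hat$HI)) < 1e-3 * max(sol_hat$HI, 1e-300)) {
    stop("fit_ida: competitor range leaves the complex essentially unchanged; ",
         "K2 is not identifiable")
  }
  resid <- series$signal - main$fitted

  K_boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      y_star <- main$fitted + sample(resid, length(resid), replace = TRUE)
      lk0 <- log10(main$K)
      fit_once(y_star, grid = seq(max(0, lk0 - 2), min(12, lk0 + 2), by = 0.1))$K
    }, numeric(1))
  })
  ki <- unname(stats::quantile(K_boot, c(0.025, 0.975), type = 7))
  ki <- c(min(ki[1], main$K), max(ki[2], main$K))
  .new_binding_fit(main$K, main$coefs, sqrt(main$rss), ki, n_boot, seed,
                   "IDA", K_boot)
}

#' Standard free energy from an association constant
#'
#' \eqn{\Delta G = -RT \ln K} with R = 1.98720425e-3 kcal/(mol K).
#'
#' @param K Association constant (M^-1), > 0.
#' @param T_K Temperature (K), > 0.
#' @return Free energy (kcal/mol).
#' @examples
#' gibbs_from_k(4.54e5, 298)  # about -7.71 kcal/mol
#' @export
gibbs_from_k <- function(K, T_K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("gibbs_from_k: K must be positive")
  if (any(!is.finite(T_K)) || any(T_K <= 0)) stop("gibbs_from_k: T must be positive")
  -.R_KCAL * T_K * log(K)
}

#' Thermodynamic bookkeeping: free energy from enthalpy and entropy terms
#'
#' \eqn{\Delta G = \Delta H - T\Delta S}, with the entropic contribution
#' supplied already multiplied by temperature.
#'
#' @param dH Enthalpy change (kcal/mol).
#' @param TdS Entropy term T*dS (kcal/mol).
#' @return dG (kcal/mol).
#' @examples
#' thermo_consistency(-9.9, -2.7)  # -7.2
#' @export
thermo_consistency <- function(dH, TdS) {
  if (any(!is.finite(c(dH, TdS)))) stop("thermo_consistency: inputs must be finite")
  dH - TdS
}
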