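# Photophysics: relative quantum yield by the reference-slope method and
# fluorescence lifetime extraction by iterative reconvolution with a
# measured instrument response function (IRF).

#' Quantum-yield input record
#'
#' Slopes of integrated emission intensity versus absorbance for the sample
#' and for a reference fluorophore of known quantum yield, plus solvent
#' refractive indices.
#'
#' @param gradient_sample,gradient_ref Slopes (intensity per absorbance
#'   unit), both > 0.
#' @param phi_ref Reference quantum yield in (0, 1].
#' @param n_sample,n_ref Refractive indices (defaults equal: same-solvent
#'   comparison).
#' @return An object of class `qy_input`.
#' @export
qy_input <- function(gradient_sample, gradient_ref, phi_ref,
                     n_sample = 1.333, n_ref = 1.333) {
  if (!is.finite(gradient_sample) || gradient_sample <= 0 ||
      !is.finite(gradient_ref) || gradient_ref <= 0) {
    stop("qy_input: gradients must be positive")
  }
  if (!is.finite(phi_ref) || phi_ref <= 0 || phi_ref > 1) {
    stop("qy_input: phi_ref must lie in (0, 1]")
  }
  structure(list(gradient_sample = gradient_sample,
                 gradient_ref = gradient_ref, phi_ref = phi_ref,
                 n_sample = n_sample, n_ref = n_ref),
            class = "qy_input")
}

#' Relative fluorescence quantum yield
#'
#' Reference-slope method:
#' \deqn{\phi = \phi_{ref} \frac{grad_{sample}}{grad_{ref}}
#'   \frac{n_{sample}^2}{n_{ref}^2}.}
#' A warning is raised (and the value returned unclipped) if the result
#' exceeds 1.
#'
#' @param qy A [qy_input()].
#' @return Quantum yield (dimensionless).
#' @examples
#' quantum_yield(qy_input(1, 1, 0.55))  # 0.55
#' @export
quantum_yield <- function(qy) {
  stopifnot(inherits(qy, "qy_input"))
  phi <- qy$phi_ref * (qy$gradient_sample / qy$gradient_ref) *
    (qy$n_sample^2 / qy$n_ref^2)
  if (phi > 1) warning(sprintf("quantum yield %.3f exceeds 1; check inputs", phi))
  phi
}

#' Slope of integrated intensity versus absorbance
#'
#' Least-squares slope of the dilution series used as input to the
#' quantum-yield determination; by default forced through the origin (zero
#' absorbance emits nothing).
#'
#' @param absorbance,intensity Paired measurements, length >= 2.
#' @param through_origin Force a zero intercept (default TRUE).
#' @return The slope (intensity per absorbance unit).
#' @export
qy_gradient <- function(absorbance, intensity, through_origin = TRUE) {
  stopifnot(length(absorbance) == length(intensity), length(absorbance) >= 2)
  if (through_origin) {
    sum(absorbance * intensity) / sum(absorbance^2)
  } else {
    unname(stats::coef(stats::lm(intensity ~ absorbance))[2])
  }
}

#' Multi-exponential decay model
#'
#' @param amplitudes Non-negative pre-exponential amplitudes (counts).
#' @param lifetimes Lifetimes tau_i (ns), > 0; stored in increasing order
#'   (amplitudes reordered along).
#' @param shift IRF time offset (ns), applied by linear interpolation.
#' @param background Constant background (counts per bin).
#' @return An object of class `multi_exp_model`.
#' @export
multi_exp_model <- function(amplitudes, lifetimes, shift = 0, background = 0) {
  stopifnot(length(amplitudes) == length(lifetimes), length(lifetimes) >= 1)
  if (any(!is.finite(lifetimes)) || any(lifetimes <= 0)) {
    stop("multi_exp_model: lifetimes must be positive")
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0)) {
    stop("multi_exp_model: amplitudes must be non-negative")
  }
  ord <- order(lifetimes)
  structure(list(amplitudes = amplitudes[ord], lifetimes = lifetimes[ord],
                 shift = shift, background = background),
            class = "multi_exp_model")
}

#' Decay trace container
#'
#' @param bin_edges Bin edges (ns), equal width, length = n_bins + 1.
#' @param counts Photon counts per bin (non-negative).
#' @param irf_counts IRF histogram on the same bins.
#' @return An object of class `decay_trace`.
#' @export
decay_trace <- function(bin_edges, counts, irf_counts) {
  n <- length(counts)
  stopifnot(length(bin_edges) == n + 1, length(irf_counts) == n)
  widths <- diff(bin_edges)
  if (diff(range(widths)) > 1e-9 * mean(widths)) {
    stop("decay_trace: bins must have equal width")
  }
  if (any(counts < 0) || any(irf_counts < 0)) {
    stop("decay_trace: counts must be non-negative")
  }
  if (sum(counts) <= 0) stop("decay_trace: total counts must be positive")
  structure(list(bin_edges = bin_edges, counts = counts,
                 irf_counts = irf_counts),
            class = "decay_trace")
}

# Shift a histogram by a continuous offset (in bins) using circular linear
# interpolation, then normalize to unit sum.
.shift_kernel <- function(irf, shift_bins) {
  n <- length(irf)
  k <- floor(shift_bins)
  w <- shift_bins - k
  idx0 <- ((seq_len(n) - 1 - k) %% n) + 1
  idx1 <- ((seq_len(n) - 2 - k) %% n) + 1
  out <- (1 - w) * irf[idx0] + w * irf[idx1]
  s <- sum(out)
  if (s <= 0) stop("IRF kernel has zero mass")
  out / s
}

#' Reconvolve a decay model with an IRF
#'
#' Computes the expected counts per bin as the periodic discrete convolution
#' of the multi-exponential decay law sampled at bin centers with the
#' unit-normalized (and shift-interpolated) IRF, plus a constant background.
#' Periodic convolution mirrors the repetitive excitation of TCSPC
#' acquisition and conserves total model intensity exactly under a
#' normalized kernel.
#'
#' @param model A [multi_exp_model()].
#' @param irf IRF histogram (non-negative, same length as the bin count).
#' @param bin_edges Bin edges (ns).
#' @return Expected counts per bin.
#' @export
reconvolve <- function(model, irf, bin_edges) {
  stopifnot(inherits(model, "multi_exp_model"))
  n <- length(irf)
  stopifnot(length(bin_edges) == n + 1)
  if (any(irf < 0)) stop("reconvolve: IRF must be non-negative")
  dt <- diff(bin_edges)[1]
  t <- (bin_edges[-(n + 1)] + bin_edges[-1]) / 2 - bin_edges[1]
  decay <- rep(0, n)
  for (i in seq_along(model$lifetimes)) {
    decay <- decay + model$amplitudes[i] * exp(-t / model$lifetimes[i])
  }
  kern <- .shift_kernel(irf, model$shift / dt)
  conv <- Re(stats::fft(stats::fft(decay) * stats::fft(kern), inverse = TRUE)) / n
  pmax(conv, 0) + model$background
}

#' Fractional intensities of a multi-exponential model
#'
#' The steady-state contribution of each component:
#' \eqn{f_i = a_i \tau_i / \sum_j a_j \tau_j}, in percent.
#'
#' @param amplitudes,lifetimes Model arrays (equal length).
#' @return Percent contributions summing to 100.
#' @examples
#' fractional_intensity(c(1, 1), c(1, 3))  # 25, 75
#' @export
fractional_intensity <- function(amplitudes, lifetimes) {
  stopifnot(length(amplitudes) == length(lifetimes))
  w <- amplitudes * lifetimes
  if (sum(w) <= 0) stop("fractional_intensity: all amplitudes are zero")
  100 * w / sum(w)
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("Reconvolution fit, %d component(s)\n", length(x$model$lifetimes)))
  for (i in seq_along(x$model$lifetimes)) {
    cat(sprintf("  tau_%d = %.4g ns   amplitude %.4g   f = %.1f%%\n",
                i, x$model$lifetimes[i], x$model$amplitudes[i],
                x$fractional_intensity[i]))
  }
  cat(sprintf("  IRF shift %.4g ns, background %.4g counts/bin\n",
              x$model$shift, x$model$background))
  cat(sprintf("  reduced chi-square: %.4g\n", x$chisq_reduced))
  invisible(x)
}

#' Fit fluorescence lifetimes by iterative reconvolution
#'
#' Fits a 1-3 component multi-exponential decay convolved with the measured
#' IRF to a TCSPC histogram. Lifetimes (log-parameterized) and the IRF shift
#' are optimized by Levenberg-Marquardt; amplitudes and background enter
#' linearly and are profiled out at each step by weighted least squares.
#' The default objective is Poisson-weighted least squares with weights
#' 1/max(counts, 1); a Poisson maximum-likelihood objective is available
#' via `objective = "mle"`.
#'
#' @param trace A [decay_trace()].
#' @param n_components Number of exponential components (1, 2 or 3).
#' @param seed Integer seed for randomized multi-start initialization.
#' @param objective `"wls"` (default) or `"mle"`.
#' @param fit_shift Fit the IRF shift (default TRUE).
#' @return A `lifetime_fit` with elements `model` (a `multi_exp_model`),
#'   `fractional_intensity` (percent), `chisq_reduced`, `fitted`.
#' @export
fit_reconvolution <- function(trace, n_components = 1, seed,
                              objective = c("wls", "mle"), fit_shift = TRUE) {
  objective <- match.arg(objective)
  stopifnot(inherits(trace, "decay_trace"))
  if (!n_components %in% 1:3) stop("fit_reconvolution: n_components must be 1, 2 or 3")
  if (missing(seed)) stop("fit_reconvolution: a seed is required")
  y <- trace$counts
  n <- length(y)
  edges <- trace$bin_edges
  dt <- diff(edges)[1]
  irf <- trace$irf_counts
  w <- 1 / pmax(y, 1)

  basis_at <- function(log_tau, shift) {
    t <- (edges[-(n + 1)] + edges[-1]) / 2 - edges[1]
    kern <- .shift_kernel(irf, shift / dt)
    Fk <- stats::fft(kern)
    B <- vapply(log_tau, function(lt) {
      d <- exp(-t / exp(lt))
      pmax(Re(stats::fft(stats::fft(d) * Fk, inverse = TRUE)) / n, 0)
    }, numeric(n))
    cbind(B, bg = 1)
  }
  lin_solve <- function(X) {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    # amplitudes and background are physical counts: clamp to >= 0 and
    # re-solve on the active set if needed
    if (any(beta < 0)) {
      keep <- beta >= 0
      beta[] <- 0
      if (any(keep)) {
        f2 <- stats::lm.wfit(X[, keep, drop = FALSE], y, w)
        b2 <- f2$coefficients; b2[is.na(b2)] <- 0
        beta[keep] <- pmax(b2, 0)
      }
    }
    beta
  }
  resid_fun <- function(theta) {
    k <- n_components
    log_tau <- theta[seq_len(k)]
    shift <- if (fit_shift) theta[k + 1] else 0
    X <- basis_at(log_tau, shift)
    beta <- lin_solve(X)
    mu <- as.numeric(X %*% beta)
    (mu - y) * sqrt(w)
  }

  t_span <- edges[n + 1] - edges[1]
  base_tau <- exp(seq(log(max(2 * dt, t_span / 200)), log(t_span / 4),
                      length.out = n_components + 2))[1 + seq_len(n_components)]
  starts <- .with_seed(seed, {
    c(list(log(base_tau)),
      lapply(1:3, function(i) log(base_tau) + stats::rnorm(n_components, 0, 0.5)))
  })

  best <- NULL
  for (st in starts) {
    theta0 <- if (fit_shift) c(st, 0) else st
    fit <- try(minpack.lm::nls.lm(par = theta0, fn = resid_fun,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("fit_reconvolution: optimizer failed to converge")

  theta <- best$fit$par
  log_tau <- theta[seq_len(n_components)]
  shift <- if (fit_shift) theta[n_components + 1] else 0
  X <- basis_at(log_tau, shift)
  beta <- lin_solve(X)

  if (objective == "mle") {
    # refine by direct Poisson negative log-likelihood over all parameters
    nll <- function(p) {
      lt <- p[seq_len(n_components)]
      sh <- if (fit_shift) p[n_components + 1] else 0
      la <- p[(n_components + fit_shift) + seq_len(n_components)]
      lb <- p[length(p)]
      Xm <- basis_at(lt, sh)
      mu <- as.numeric(Xm %*% c(exp(la), exp(lb)))
      mu <- pmax(mu, 1e-12)
      sum(mu - y * log(mu))
    }
    p0 <- c(log_tau, if (fit_shift) shift, log(pmax(beta[seq_len(n_components)], 1e-8)),
            log(max(beta[n_components + 1], 1e-8)))
    opt <- stats::optim(p0, nll, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    log_tau <- opt$par[seq_len(n_components)]
    shift <- if (fit_shift) opt$par[n_components + 1] else 0
    X <- basis_at(log_tau, shift)
    beta <- c(exp(opt$par[(n_components + fit_shift) + seq_len(n_components)]),
              exp(opt$par[length(opt$par)]))
  }

  amps <- unname(beta[seq_len(n_components)])
  bg <- unname(beta[n_components + 1])
  mu <- as.numeric(X %*% beta)
  n_par <- n_components * 2 + 1 + as.integer(fit_shift)
  chisq <- sum((mu - y)^2 * w) / (n - n_par)

  if (n_components > 1) {
    # flag near-degenerate components
    taus <- sort(exp(log_tau))
    if (any(taus[-1] / taus[-length(taus)] < 1.15) || any(amps == 0)) {
      warning("fit_reconvolution: components are nearly degenerate; ",
              "consider fewer components")
    }
  }
  model <- multi_exp_model(amps, exp(log_tau), shift = shift, background = bg)
  structure(list(model = model,
                 fractional_intensity = fractional_intensity(
                   model$amplitudes, model$lifetimes),
                 chisq_reduced = chisq,
                 fitted = mu,
                 seed = seed,
                 objective = objective),
            class = "lifetime_fit")
}
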