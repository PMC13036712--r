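# Minimal Gaussian-primitive wavefunction models: the electron-density
# source for the QTAIM and NCI machinery. Basis functions are contracted
# s-type Gaussians; molecular orbitals are linear combinations with
# occupation numbers (single-determinant case).

#' Construct a Gaussian-primitive wavefunction model
#'
#' @param centers Numeric n x 3 matrix of nuclear coordinates (bohr).
#' @param Z Integer atomic numbers (length n), used only for export.
#' @param basis List of basis functions; each is
#'   `list(center = <index>, alpha = <exponents>, coeff = <contraction
#'   coefficients>)`. Primitives are individually normalized s-Gaussians
#'   `(2a/pi)^(3/4) exp(-a r^2)`.
#' @param mo_coefficients nbasis x nmo matrix of MO coefficients.
#' @param occupations Occupation numbers (length nmo, >= 0); their sum is
#'   the electron count.
#' @param normalize If TRUE (default), rescale each MO to unit analytic
#'   norm.
#' @return An object of class `wavefunction_model`.
#' @export
wavefunction_model <- function(centers, Z = NULL, basis, mo_coefficients,
                               occupations, normalize = TRUE) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 3)
  if (is.null(Z)) Z <- rep(1L, nrow(centers))
  stopifnot(length(Z) == nrow(centers))
  mo_coefficients <- as.matrix(mo_coefficients)
  stopifnot(nrow(mo_coefficients) == length(basis),
            ncol(mo_coefficients) == length(occupations))
  if (any(occupations < 0)) stop("wavefunction_model: occupations must be >= 0")
  for (b in basis) {
    stopifnot(b$center >= 1, b$center <= nrow(centers),
              length(b$alpha) == length(b$coeff), all(b$alpha > 0))
  }
  model <- structure(list(centers = centers, Z = as.integer(Z), basis = basis,
                          mo_coefficients = mo_coefficients,
                          occupations = occupations),
                     class = "wavefunction_model")
  if (normalize) {
    S <- .overlap_matrix(model)
    for (i in seq_along(occupations)) {
      c_i <- model$mo_coefficients[, i]
      nrm <- sqrt(as.numeric(t(c_i) %*% S %*% c_i))
      if (nrm > 0) model$mo_coefficients[, i] <- c_i / nrm
    }
  }
  model
}

#' @export
print.wavefunction_model <- function(x, ...) {
  cat(sprintf("Gaussian-primitive wavefunction: %d center(s), %d basis function(s), %d MO(s), %.3g electrons\n",
              nrow(x$centers), length(x$basis), length(x$occupations),
              sum(x$occupations)))
  invisible(x)
}

#' Electron count of a model
#' @param model A `wavefunction_model`.
#' @return Sum of occupation numbers.
#' @export
electron_count <- function(model) sum(model$occupations)

# Analytic overlap matrix of the contracted s-Gaussian basis.
.overlap_matrix <- function(model) {
  nb <- length(model$basis)
  S <- matrix(0, nb, nb)
  for (p in seq_len(nb)) for (q in seq_len(p)) {
    bp <- model$basis[[p]]; bq <- model$basis[[q]]
    d2 <- sum((model$centers[bp$center, ] - model$centers[bq$center, ])^2)
    s <- 0
    for (ip in seq_along(bp$alpha)) for (iq in seq_along(bq$alpha)) {
      a <- bp$alpha[ip]; b <- bq$alpha[iq]
      s <- s + bp$coeff[ip] * bq$coeff[iq] *
        (4 * a * b / (a + b)^2)^0.75 * exp(-a * b / (a + b) * d2)
    }
    S[p, q] <- S[q, p] <- s
  }
  S
}

#' Analytic MO norms
#'
#' @param model A `wavefunction_model`.
#' @return Vector of MO norms (should be 1 after construction).
#' @export
mo_norms <- function(model) {
  S <- .overlap_matrix(model)
  vapply(seq_along(model$occupations), function(i) {
    c_i <- model$mo_coefficients[, i]
    sqrt(as.numeric(t(c_i) %*% S %*% c_i))
  }, numeric(1))
}

# Batch evaluation of basis functions, their gradients and Hessians at a
# set of points. Returns chi (m x nb), dchi (list x/y/z of m x nb), and the
# six independent Hessian components (m x nb each).
.basis_batch <- function(model, P) {
  P <- matrix(P, ncol = 3)
  m <- nrow(P); nb <- length(model$basis)
  chi <- matrix(0, m, nb)
  dx <- dy <- dz <- matrix(0, m, nb)
  hxx <- hyy <- hzz <- hxy <- hxz <- hyz <- matrix(0, m, nb)
  for (k in seq_len(nb)) {
    b <- model$basis[[k]]
    R <- model$centers[b$center, ]
    rx <- P[, 1] - R[1]; ry <- P[, 2] - R[2]; rz <- P[, 3] - R[3]
    r2 <- rx^2 + ry^2 + rz^2
    for (p in seq_along(b$alpha)) {
      a <- b$alpha[p]
      g <- b$coeff[p] * (2 * a / pi)^0.75 * exp(-a * r2)
      chi[, k] <- chi[, k] + g
      dx[, k] <- dx[, k] - 2 * a * rx * g
      dy[, k] <- dy[, k] - 2 * a * ry * g
      dz[, k] <- dz[, k] - 2 * a * rz * g
      hxx[, k] <- hxx[, k] + (4 * a^2 * rx^2 - 2 * a) * g
      hyy[, k] <- hyy[, k] + (4 * a^2 * ry^2 - 2 * a) * g
      hzz[, k] <- hzz[, k] + (4 * a^2 * rz^2 - 2 * a) * g
      hxy[, k] <- hxy[, k] + 4 * a^2 * rx * ry * g
      hxz[, k] <- hxz[, k] + 4 * a^2 * rx * rz * g
      hyz[, k] <- hyz[, k] + 4 * a^2 * ry * rz * g
    }
  }
  list(chi = chi, dx = dx, dy = dy, dz = dz,
       hxx = hxx, hyy = hyy, hzz = hzz, hxy = hxy, hxz = hxz, hyz = hyz)
}

# Density, gradient, Hessian components and kinetic energy density at a
# batch of points. All quantities in atomic units.
.field_batch <- function(model, P) {
  P <- matrix(P, ncol = 3)
  B <- .basis_batch(model, P)
  C <- model$mo_coefficients
  occ <- model$occupations
  phi <- B$chi %*% C
  px <- B$dx %*% C; py <- B$dy %*% C; pz <- B$dz %*% C
  pxx <- B$hxx %*% C; pyy <- B$hyy %*% C; pzz <- B$hzz %*% C
  pxy <- B$hxy %*% C; pxz <- B$hxz %*% C; pyz <- B$hyz %*% C
  wphi <- sweep(phi, 2, occ, `*`)
  rho <- rowSums(wphi * phi)
  gx <- 2 * rowSums(wphi * px)
  gy <- 2 * rowSums(wphi * py)
  gz <- 2 * rowSums(wphi * pz)
  wx <- sweep(px, 2, occ, `*`); wy <- sweep(py, 2, occ, `*`)
  wz <- sweep(pz, 2, occ, `*`)
  Hxx <- 2 * (rowSums(wx * px) + rowSums(wphi * pxx))
  Hyy <- 2 * (rowSums(wy * py) + rowSums(wphi * pyy))
  Hzz <- 2 * (rowSums(wz * pz) + rowSums(wphi * pzz))
  Hxy <- 2 * (rowSums(wx * py) + rowSums(wphi * pxy))
  Hxz <- 2 * (rowSums(wx * pz) + rowSums(wphi * pxz))
  Hyz <- 2 * (rowSums(wy * pz) + rowSums(wphi * pyz))
  G <- 0.5 * (rowSums(wx * px) + rowSums(wy * py) + rowSums(wz * pz))
  list(rho = rho, gx = gx, gy = gy, gz = gz,
       hxx = Hxx, hyy = Hyy, hzz = Hzz, hxy = Hxy, hxz = Hxz, hyz = Hyz,
       G = G)
}

# Vectorized eigenvalues of symmetric 3x3 matrices given by component
# vectors; returns a 3-column matrix sorted ascending per row.
.sym3_eigenvalues <- function(a11, a22, a33, a12, a13, a23) {
  m <- length(a11)
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- matrix(0, m, 3)
  diag_case <- p <= .Machine$double.eps * pmax(abs(q), 1)
  if (any(diag_case)) {
    idx <- which(diag_case)
    out[idx, ] <- t(apply(cbind(a11[idx], a22[idx], a33[idx]), 1, sort))
  }
  idx <- which(!diag_case)
  if (length(idx)) {
    b11 <- (a11[idx] - q[idx]) / p[idx]
    b22 <- (a22[idx] - q[idx]) / p[idx]
    b33 <- (a33[idx] - q[idx]) / p[idx]
    b12 <- a12[idx] / p[idx]; b13 <- a13[idx] / p[idx]; b23 <- a23[idx] / p[idx]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[idx] + 2 * p[idx] * cos(phi)
    e3 <- q[idx] + 2 * p[idx] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[idx] - e1 - e3
    ev <- cbind(e3, e2, e1)  # already ascending: e3 <= e2 <= e1
    out[idx, ] <- ev
  }
  out
}

#' Evaluate QTAIM local descriptors at a point
#'
#' Computes, analytically from the Gaussian-primitive model: the electron
#' density rho, its gradient and Hessian, the positive-definite kinetic
#' energy density `G = 1/2 sum_i eta_i |grad phi_i|^2`, the potential
#' energy density by the local virial relation `V = 1/4 lap(rho) - 2G`, the
#' total energy density `H = G + V`, the reduced density gradient `s`, and
#' the middle Hessian eigenvalue `lambda2`.
#'
#' @param model A [wavefunction_model()].
#' @param point Numeric length-3 position (bohr).
#' @return An object of class `field_point` with components `rho`, `grad`,
#'   `hessian`, `laplacian`, `G`, `V`, `H`, `s`, `lambda`, `lambda2`.
#' @export
eval_field <- function(model, point) {
  stopifnot(inherits(model, "wavefunction_model"), length(point) == 3)
  fb <- .field_batch(model, matrix(point, 1, 3))
  hess <- matrix(c(fb$hxx, fb$hxy, fb$hxz,
                   fb$hxy, fb$hyy, fb$hyz,
                   fb$hxz, fb$hyz, fb$hzz), 3, 3)
  lap <- fb$hxx + fb$hyy + fb$hzz
  V <- 0.25 * lap - 2 * fb$G
  grad <- c(fb$gx, fb$gy, fb$gz)
  gn <- sqrt(sum(grad^2))
  lam <- sort(eigen(hess, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(rho = fb$rho, grad = grad, hessian = hess,
                 laplacian = lap, G = fb$G, V = V, H = fb$G + V,
                 s = if (fb$rho > 0) rdg(fb$rho, gn) else Inf,
                 lambda = lam, lambda2 = lam[2]),
            class = "field_point")
}

#' @export
print.field_point <- function(x, ...) {
  cat(sprintf("rho = %.6g e/a0^3, |grad| = %.3g, lap = %.4g\n",
              x$rho, sqrt(sum(x$grad^2)), x$laplacian))
  cat(sprintf("G = %.4g, V = %.4g, H = %.4g hartree/a0^3, s = %.4g, lambda2 = %.4g\n",
              x$G, x$V, x$H, x$s, x$lambda2))
  invisible(x)
}

#' Numerical electron count by quadrature
#'
#' Midpoint-rule integral of the density over a cubic grid enclosing the
#' model; used to validate models against their nominal electron count.
#'
#' @param model A `wavefunction_model`.
#' @param padding Box padding beyond the centers (bohr).
#' @param spacing Grid spacing (bohr).
#' @return Approximate integral of rho.
#' @export
integrate_density <- function(model, padding = 7, spacing = 0.25) {
  lo <- apply(model$centers, 2, min) - padding
  hi <- apply(model$centers, 2, max) + padding
  xs <- seq(lo[1] + spacing / 2, hi[1], by = spacing)
  ys <- seq(lo[2] + spacing / 2, hi[2], by = spacing)
  zs <- seq(lo[3] + spacing / 2, hi[3], by = spacing)
  total <- 0
  # slab-wise to bound memory
  for (z in zs) {
    P <- cbind(rep(xs, times = length(ys)),
               rep(ys, each = length(xs)), z)
    total <- total + sum(.field_batch(model, P)$rho)
  }
  total * spacing^3
}

# ---- packaged model builders -------------------------------------------

#' Single-center model: one normalized s-Gaussian orbital
#'
#' @param alpha Exponent (bohr^-2).
#' @param occupation Occupation number (default 2).
#' @return A `wavefunction_model`.
#' @export
wfn_single_center <- function(alpha = 1, occupation = 2) {
  wavefunction_model(centers = matrix(0, 1, 3), Z = 1L,
                     basis = list(list(center = 1L, alpha = alpha, coeff = 1)),
                     mo_coefficients = matrix(1, 1, 1),
                     occupations = occupation)
}

#' Symmetric two-center model
#'
#' Two identical s-Gaussian orbitals on the z axis; its single bond critical
#' point lies at the exact midpoint by symmetry.
#'
#' @param alpha Exponent.
#' @param separation Internuclear distance (bohr).
#' @param occupation Occupation per orbital.
#' @return A `wavefunction_model`.
#' @export
wfn_symmetric_dimer <- function(alpha = 1, separation = 2, occupation = 2) {
  centers <- rbind(c(0, 0, 0), c(0, 0, separation))
  wavefunction_model(centers = centers, Z = c(1L, 1L),
                     basis = list(list(center = 1L, alpha = alpha, coeff = 1),
                                  list(center = 2L, alpha = alpha, coeff = 1)),
                     mo_coefficients = diag(2),
                     occupations = c(occupation, occupation))
}

#' Asymmetric two-center model
#'
#' Different exponents on the two centers; the bond critical point is pulled
#' toward the more diffuse center.
#'
#' @param alpha Length-2 exponents.
#' @param separation Internuclear distance (bohr).
#' @param occupation Occupation per orbital.
#' @return A `wavefunction_model`.
#' @export
wfn_asymmetric_dimer <- function(alpha = c(1, 0.5), separation = 3,
                                 occupation = 2) {
  centers <- rbind(c(0, 0, 0), c(0, 0, separation))
  wavefunction_model(centers = centers, Z = c(1L, 1L),
                     basis = list(list(center = 1L, alpha = alpha[1], coeff = 1),
                                  list(center = 2L, alpha = alpha[2], coeff = 1)),
                     mo_coefficients = diag(2),
                     occupations = c(occupation, occupation))
}

#' Noncovalent dimer model
#'
#' Two closed-shell fragments at van der Waals-like separation: the
#' intermolecular critical point shows the closed-shell signature (positive
#' Laplacian, positive total energy density, -G/V > 1) with a density in the
#' hydrogen-bond range (rho <= 0.0208 e/a0^3). This is a synthetic model
#' density, not a DFT wavefunction.
#'
#' @param separation Intermolecular distance (bohr).
#' @return A `wavefunction_model`.
#' @export
wfn_noncovalent_dimer <- function(separation = 3.1) {
  centers <- rbind(c(0, 0, 0), c(0, 0, separation))
  wavefunction_model(centers = centers, Z = c(8L, 8L),
                     basis = list(list(center = 1L, alpha = c(1.6, 0.9),
                                       coeff = c(0.5, 0.6)),
                                  list(center = 2L, alpha = c(1.6, 0.9),
                                       coeff = c(0.5, 0.6))),
                     mo_coefficients = diag(2),
                     occupations = c(2, 2))
}
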