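# QTAIM topology: reduced density gradient, bond-critical-point search and
# classification, the linear binding-energy estimator, and NCI grids.

#' Reduced density gradient
#'
#' \deqn{s = \frac{|\nabla\rho|}{2(3\pi^2)^{1/3}\rho^{4/3}}.}
#'
#' @param rho Electron density (e/a0^3), > 0.
#' @param grad_norm Norm of the density gradient (e/a0^4), >= 0.
#' @return Dimensionless s.
#' @examples
#' rho0 <- 1 / pi                       # hydrogenic density at the nucleus
#' rdg(rho0, 2 * rho0)                  # 0.4734
#' @export
rdg <- function(rho, grad_norm) {
  if (any(rho <= 0)) stop("rdg: rho must be positive")
  grad_norm / (2 * (3 * pi^2)^(1 / 3) * rho^(4 / 3))
}

#' Locate bond critical points
#'
#' Newton search on the density gradient seeded from the midpoint of each
#' requested atom pair, with step damping when a step increases |grad|.
#' Converged points (|grad| < `grad_tol`) are deduplicated (merge distance
#' 1e-4 bohr) and assigned a (rank, signature) from the Hessian eigenvalues
#' with zero-threshold 1e-10. Pairs whose search does not converge are
#' reported absent, not as errors.
#'
#' @param model A [wavefunction_model()].
#' @param atom_pairs Two-column matrix of center indices, or `"all"` for
#'   every pair.
#' @param grad_tol Gradient norm tolerance (default 1e-10).
#' @param max_iter Maximum Newton iterations per seed (default 100).
#' @return List of `critical_point` objects; each has `position`, `rank`,
#'   `signature`, `field` (a `field_point`), `atoms`, `degenerate`.
#' @export
find_bcps <- function(model, atom_pairs = "all", grad_tol = 1e-10,
                      max_iter = 100) {
  stopifnot(inherits(model, "wavefunction_model"))
  n <- nrow(model$centers)
  if (identical(atom_pairs, "all")) {
    if (n < 2) return(list())
    atom_pairs <- t(utils::combn(n, 2))
  }
  atom_pairs <- matrix(as.integer(atom_pairs), ncol = 2)
  found <- list()
  for (r in seq_len(nrow(atom_pairs))) {
    i <- atom_pairs[r, 1]; j <- atom_pairs[r, 2]
    x <- (model$centers[i, ] + model$centers[j, ]) / 2
    fp <- eval_field(model, x)
    gn <- sqrt(sum(fp$grad^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      if (gn < grad_tol) { ok <- TRUE; break }
      step <- tryCatch(-solve(fp$hessian, fp$grad), error = function(e) NULL)
      if (is.null(step)) break
      # damp when the full step overshoots (gradient norm grows)
      lambda <- 1
      repeat {
        x_new <- x + lambda * step
        fp_new <- eval_field(model, x_new)
        gn_new <- sqrt(sum(fp_new$grad^2))
        if (gn_new < gn || lambda < 1e-4) break
        lambda <- lambda * 0.5
      }
      x <- x_new; fp <- fp_new; gn <- gn_new
    }
    if (!(ok || gn < grad_tol)) next
    lam <- fp$lambda
    nz <- abs(lam) > 1e-10
    cp <- structure(list(position = x,
                         rank = sum(nz),
                         signature = sum(sign(lam[nz])),
                         field = fp,
                         atoms = c(i, j),
                         degenerate = any(!nz)),
                    class = "critical_point")
    dup <- FALSE
    for (prev in found) {
      if (sqrt(sum((prev$position - x)^2)) < 1e-4) { dup <- TRUE; break }
    }
    if (!dup) found[[length(found) + 1]] <- cp
  }
  found
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("(%d,%+d) critical point between atoms %d-%d at (%.4f, %.4f, %.4f) bohr%s\n",
              x$rank, x$signature, x$atoms[1], x$atoms[2],
              x$position[1], x$position[2], x$position[3],
              if (x$degenerate) " [degenerate Hessian]" else ""))
  print(x$field)
  invisible(x)
}

#' Classify a bond critical point as noncovalent or shared
#'
#' Closed-shell (noncovalent) interactions show a positive Laplacian, a
#' positive total energy density and a kinetic/potential ratio -G/V greater
#' than one at the (3,-1) critical point; everything else is classified as
#' a shared (covalent-type) interaction.
#'
#' @param cp A `critical_point` with signature (3,-1).
#' @return `"noncovalent"` or `"shared"`.
#' @export
classify_interaction <- function(cp) {
  stopifnot(inherits(cp, "critical_point"))
  if (!(cp$rank == 3 && cp$signature == -1)) {
    stop("classify_interaction: requires a (3,-1) critical point")
  }
  f <- cp$field
  if (f$laplacian > 0 && f$H > 0 && (-f$G / f$V) > 1) "noncovalent" else "shared"
}

#' Hydrogen-bond energy from the critical-point density
#'
#' Linear estimator \eqn{B_E(\mathrm{kcal/mol}) = -223.08\,\rho_{BCP} +
#' 0.7423}, calibrated for hydrogen-bond critical-point densities; a
#' warning is issued outside the calibration range [0.002, 0.04] e/a0^3.
#'
#' @param rho_bcp Electron density at the bond critical point (e/a0^3).
#' @return Estimated interaction energy (kcal/mol; negative = attractive).
#' @examples
#' be_from_rho(0.0208)  # -3.90 kcal/mol
#' be_from_rho(0.0114)  # -1.80 kcal/mol
#' @export
be_from_rho <- function(rho_bcp) {
  if (any(!is.finite(rho_bcp)) || any(rho_bcp < 0)) {
    stop("be_from_rho: rho must be non-negative")
  }
  if (any(rho_bcp < 0.002 | rho_bcp > 0.04)) {
    warning("be_from_rho: density outside the H-bond calibration range [0.002, 0.04] e/a0^3")
  }
  -223.08 * rho_bcp + 0.7423
}

#' NCI grid: reduced density gradient and signed density
#'
#' Evaluates `s(r)` and `sign(lambda2) * rho(r)` on a regular grid; voxels
#' with `rho > rho_max` are masked (set NA in `s`), and the signed density
#' exported for coloring is clamped to `color_range`.
#'
#' @param model A [wavefunction_model()].
#' @param box Either `"auto"` (centers padded by `padding`) or a
#'   2 x 3 matrix `rbind(lower, upper)` in bohr.
#' @param spacing Voxel edge (bohr).
#' @param rho_max Density mask threshold (e/a0^3), default 0.05.
#' @param color_range Clamp range for the exported signed density, default
#'   c(-0.05, 0.01).
#' @param padding Padding for `box = "auto"` (bohr).
#' @return An `nci_grid` list: axis vectors `x`, `y`, `z`, 3D arrays `s`,
#'   `signed_rho` (unclamped), `color` (clamped), `rho`, and the call
#'   parameters.
#' @export
nci_grid <- function(model, box = "auto", spacing = 0.25, rho_max = 0.05,
                     color_range = c(-0.05, 0.01), padding = 4) {
  stopifnot(inherits(model, "wavefunction_model"))
  if (!is.finite(spacing) || spacing <= 0) stop("nci_grid: spacing must be positive")
  if (identical(box, "auto")) {
    lo <- apply(model$centers, 2, min) - padding
    hi <- apply(model$centers, 2, max) + padding
  } else {
    box <- as.matrix(box)
    stopifnot(nrow(box) == 2, ncol(box) == 3)
    lo <- box[1, ]; hi <- box[2, ]
  }
  if (any(hi <= lo)) stop("nci_grid: empty box")
  xs <- seq(lo[1], hi[1], by = spacing)
  ys <- seq(lo[2], hi[2], by = spacing)
  zs <- seq(lo[3], hi[3], by = spacing)
  dims <- c(length(xs), length(ys), length(zs))
  s_arr <- array(NA_real_, dims)
  sr_arr <- array(0, dims)
  rho_arr <- array(0, dims)
  # evaluate z-slab by z-slab
  for (k in seq_along(zs)) {
    P <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), zs[k])
    fb <- .field_batch(model, P)
    gn <- sqrt(fb$gx^2 + fb$gy^2 + fb$gz^2)
    lam <- .sym3_eigenvalues(fb$hxx, fb$hyy, fb$hzz, fb$hxy, fb$hxz, fb$hyz)
    lambda2 <- lam[, 2]
    s_vals <- ifelse(fb$rho > 0, gn / (2 * (3 * pi^2)^(1 / 3) * fb$rho^(4 / 3)), Inf)
    sr <- sign(lambda2) * fb$rho
    s_vals[fb$rho > rho_max] <- NA_real_
    s_arr[, , k] <- matrix(s_vals, dims[1], dims[2])
    sr_arr[, , k] <- matrix(sr, dims[1], dims[2])
    rho_arr[, , k] <- matrix(fb$rho, dims[1], dims[2])
  }
  color <- pmin(pmax(sr_arr, color_range[1]), color_range[2])
  structure(list(x = xs, y = ys, z = zs, s = s_arr, signed_rho = sr_arr,
                 color = color, rho = rho_arr, spacing = spacing,
                 rho_max = rho_max, color_range = color_range),
            class = "nci_grid")
}

#' Critical-point report as a data frame
#'
#' Tabulates positions and QTAIM descriptors of a critical-point list in
#' the columns conventionally reported for intermolecular contacts (rho,
#' Laplacian, G, V, H, -G/V, classification, estimated H-bond energy).
#'
#' @param cps List of `critical_point` objects (from [find_bcps()]).
#' @return A data frame, one row per critical point.
#' @export
cp_report <- function(cps) {
  if (length(cps) == 0) {
    return(data.frame(atom_i = integer(), atom_j = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      rank = integer(), signature = integer(),
                      rho = numeric(), laplacian = numeric(), G = numeric(),
                      V = numeric(), H = numeric(), mGV = numeric(),
                      class = character(), BE_kcal = numeric()))
  }
  do.call(rbind, lapply(cps, function(cp) {
    f <- cp$field
    cls <- if (cp$rank == 3 && cp$signature == -1) classify_interaction(cp)
           else NA_character_
    be <- if (identical(cls, "noncovalent"))
      suppressWarnings(be_from_rho(f$rho)) else NA_real_
    data.frame(atom_i = cp$atoms[1], atom_j = cp$atoms[2],
               x = cp$position[1], y = cp$position[2], z = cp$position[3],
               rank = cp$rank, signature = cp$signature,
               rho = f$rho, laplacian = f$laplacian, G = f$G, V = f$V,
               H = f$H, mGV = -f$G / f$V, class = cls, BE_kcal = be)
  }))
}
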