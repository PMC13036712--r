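# Trajectory-based solvation statistics: radial distribution functions,
# first-shell coordination, geometric hydrogen-bond selection, nanodroplet
# extraction and occupancy maps. Orthorhombic boxes, minimum-image
# convention throughout.

.MASS_O <- 15.999
.MASS_H <- 1.008

#' Trajectory container
#'
#' @param frames List of frames; each frame is `list(labels = <character>,
#'   coords = <n x 3 matrix, Angstrom>)`.
#' @param box Orthorhombic box lengths c(lx, ly, lz) (Angstrom).
#' @param timestep Optional time between frames (ps), metadata only.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, box, timestep = NA_real_) {
  stopifnot(is.list(frames), length(frames) >= 1, length(box) == 3)
  if (any(!is.finite(box)) || any(box <= 0)) {
    stop("trajectory: box lengths must be positive")
  }
  n0 <- nrow(frames[[1]]$coords)
  for (fr in frames) {
    stopifnot(is.matrix(fr$coords), ncol(fr$coords) == 3,
              length(fr$labels) == nrow(fr$coords))
    if (nrow(fr$coords) != n0) stop("trajectory: atom count varies across frames")
    if (any(!is.finite(fr$coords))) stop("trajectory: non-finite coordinates")
  }
  structure(list(frames = frames, box = box, timestep = timestep),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frame(s), %d atoms, box %.2f x %.2f x %.2f A\n",
              length(x$frames), nrow(x$frames[[1]]$coords),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

# Minimum-image displacement vectors (rows) for an orthorhombic box.
.min_image <- function(d, box) {
  d <- matrix(d, ncol = 3)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# Resolve a selection (labels or indices) against a frame's labels.
.resolve_sel <- function(labels, selection) {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1 | idx > length(labels))) stop("selection index out of range")
    idx
  } else {
    idx <- which(labels %in% selection)
    if (length(idx) == 0) stop("selection matches no atoms")
    idx
  }
}

#' Radial distribution function between two selections
#'
#' Standard minimum-image pair-distance histogram normalized by the
#' ideal-gas expectation `n_B/V * 4/3 pi (r2^3 - r1^3)` per reference atom,
#' averaged over frames. Identical atom indices are excluded from pairing.
#'
#' @param traj A [trajectory()].
#' @param selection_A,selection_B Atom labels (character) or indices
#'   (numeric) for the reference and distributed species.
#' @param r_max Histogram range (Angstrom), must be less than half the
#'   smallest box length.
#' @param bin_width Bin width (Angstrom).
#' @return An `rdf_result` with `r_centers`, `g`, `counts` (mean pair count
#'   per frame per bin), and normalization metadata.
#' @export
rdf <- function(traj, selection_A, selection_B, r_max = NULL, bin_width = 0.05) {
  stopifnot(inherits(traj, "trajectory"))
  box <- traj$box
  if (is.null(r_max)) r_max <- min(box) / 2 * 0.999
  if (r_max >= min(box) / 2) {
    stop("rdf: r_max must be smaller than half the smallest box length")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1
  counts <- rep(0, nb)
  n_frames <- length(traj$frames)
  nA <- nB <- NULL
  for (fr in traj$frames) {
    iA <- .resolve_sel(fr$labels, selection_A)
    iB <- .resolve_sel(fr$labels, selection_B)
    nA <- length(iA); nB <- length(iB)
    for (a in iA) {
      jb <- setdiff(iB, a)
      if (!length(jb)) next
      d <- .min_image(sweep(fr$coords[jb, , drop = FALSE], 2,
                            fr$coords[a, ], `-`), box)
      r <- sqrt(rowSums(d^2))
      r <- r[r < edges[nb + 1]]
      if (length(r)) {
        h <- graphics::hist(r, breaks = edges, plot = FALSE)
        counts <- counts + h$counts
      }
    }
  }
  counts <- counts / n_frames
  V <- prod(box)
  dens_B <- nB / V
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (nA * dens_B * shell_vol)
  structure(list(r_centers = (edges[-1] + edges[-(nb + 1)]) / 2,
                 g = g, counts = counts, edges = edges,
                 n_A = nA, n_B = nB, density_B = dens_B,
                 n_frames = n_frames),
            class = "rdf_result")
}

#' First solvation shell of an RDF
#'
#' Locates the first interior local maximum of g(r) and the following local
#' minimum (on a 3-point moving average by default, to suppress bin noise)
#' and integrates the coordination number up to that minimum:
#' \deqn{N = 4\pi\rho_B \int_0^{r_{min}} g(r) r^2 dr,}
#' evaluated with exact spherical-shell volumes so that the integral equals
#' the mean pair count within the shell.
#'
#' @param rdf_res An `rdf_result` from [rdf()].
#' @param number_density_B Number density of species B (A^-3); defaults to
#'   the value recorded in the RDF.
#' @param smooth Use the 3-point moving average for extrema detection
#'   (default TRUE); the integration always uses the raw histogram.
#' @return List with `r_max`, `r_min` (Angstrom) and `coordination`.
#' @export
first_shell <- function(rdf_res, number_density_B = NULL, smooth = TRUE) {
  stopifnot(inherits(rdf_res, "rdf_result"))
  g <- rdf_res$g
  if (is.null(number_density_B)) number_density_B <- rdf_res$density_B
  gs <- if (smooth && length(g) >= 3) {
    stats::filter(g, rep(1 / 3, 3), sides = 2)
  } else g
  gs[is.na(gs)] <- g[is.na(gs)]
  n <- length(gs)
  i_max <- NA_integer_
  for (i in 2:(n - 1)) {
    if (gs[i] > gs[i - 1] && gs[i] >= gs[i + 1] && gs[i] > 0) { i_max <- i; break }
  }
  if (is.na(i_max)) stop("first_shell: g(r) has no interior maximum")
  i_min <- NA_integer_
  for (i in (i_max + 1):(n - 1)) {
    if (gs[i] <= gs[i - 1] && gs[i] < gs[i + 1]) { i_min <- i; break }
  }
  if (is.na(i_min)) {
    # monotone tail after the peak: take the global minimum after the peak
    i_min <- i_max + which.min(gs[(i_max + 1):n])
  }
  edges <- rdf_res$edges
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  # rho_B * sum g_i Vshell_i is the shell-volume-exact form of
  # 4 pi rho_B int g r^2 dr; it equals the mean pair count within r_min
  coord <- number_density_B * sum(g[seq_len(i_min)] * shell_vol[seq_len(i_min)])
  list(r_max = rdf_res$r_centers[i_max],
       r_min = rdf_res$r_centers[i_min],
       coordination = coord)
}

#' Geometric hydrogen-bond criteria
#'
#' @param max_angle Maximum acceptor-donor-hydrogen angle (degrees,
#'   default 30): the angle at the donor between the donor-to-acceptor and
#'   donor-to-hydrogen directions, so small values mean a near-linear
#'   D-H...A arrangement.
#' @param max_distance Maximum heavy-atom (acceptor-donor) distance
#'   (Angstrom, default 3.5).
#' @param vertex Angle convention: `"donor"` (default, as above) or
#'   `"hydrogen"` (deviation of the D-H...A angle at the hydrogen from
#'   linearity).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_angle = 30, max_distance = 3.5,
                           vertex = c("donor", "hydrogen")) {
  vertex <- match.arg(vertex)
  if (!is.finite(max_angle) || max_angle <= 0 || max_angle > 180) {
    stop("hbond_criteria: max_angle must be in (0, 180]")
  }
  if (!is.finite(max_distance) || max_distance <= 0) {
    stop("hbond_criteria: max_distance must be positive")
  }
  structure(list(max_angle = max_angle, max_distance = max_distance,
                 vertex = vertex),
            class = "hbond_criteria")
}

#' Select hydrogen-bonded triples in one frame
#'
#' Applies the geometric criteria (acceptor-donor distance and
#' acceptor-donor-hydrogen angle) to every combination of a donor-hydrogen
#' pair with an acceptor, using minimum-image distances.
#'
#' @param frame A frame (`list(labels, coords)`).
#' @param donors Integer indices of donor heavy atoms; each entry is paired
#'   with the hydrogen at the same position of `hydrogens`.
#' @param hydrogens Integer indices of the covalently bound hydrogens,
#'   parallel to `donors`.
#' @param acceptors Integer indices of acceptor heavy atoms.
#' @param criteria An [hbond_criteria()].
#' @param box Box lengths (Angstrom); if NULL, no periodic wrapping.
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle`.
#' @export
hbond_partners <- function(frame, donors, hydrogens, acceptors,
                           criteria = hbond_criteria(), box = NULL) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  if (length(donors) != length(hydrogens)) {
    stop("hbond_partners: every hydrogen must be mapped to a donor ",
         "(donors and hydrogens must have equal length)")
  }
  X <- frame$coords
  n <- nrow(X)
  if (any(c(donors, hydrogens, acceptors) < 1) ||
      any(c(donors, hydrogens, acceptors) > n)) {
    stop("hbond_partners: atom index out of range")
  }
  disp <- function(to, from) {
    d <- matrix(X[to, ] - X[from, ], ncol = 3)
    if (!is.null(box)) d <- .min_image(d, box)
    d
  }
  out <- list()
  for (k in seq_along(donors)) {
    d_i <- donors[k]; h_i <- hydrogens[k]
    v_dh <- disp(h_i, d_i)
    for (a_i in acceptors) {
      if (a_i == d_i || a_i == h_i) next
      v_da <- disp(a_i, d_i)
      dist <- sqrt(sum(v_da^2))
      if (dist > criteria$max_distance) next
      cosang <- sum(v_da * v_dh) / (dist * sqrt(sum(v_dh^2)))
      ang_donor <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ang <- if (criteria$vertex == "donor") {
        ang_donor
      } else {
        v_hd <- -v_dh
        v_ha <- disp(a_i, h_i)
        theta <- acos(pmin(pmax(sum(v_hd * v_ha) /
          (sqrt(sum(v_hd^2)) * sqrt(sum(v_ha^2))), -1), 1)) * 180 / pi
        180 - theta
      }
      if (ang <= criteria$max_angle) {
        out[[length(out) + 1]] <- data.frame(
          donor = d_i, hydrogen = h_i, acceptor = a_i,
          distance = dist, angle = ang)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  }
  do.call(rbind, out)
}

#' Extract a solvation nanodroplet and tag QM/MM waters
#'
#' Retains every water whose center of mass (masses O 15.999, H 1.008) lies
#' within `radius` of the unweighted geometric center of the solute; among
#' the retained waters, those hydrogen-bonded to the solute (either
#' direction, per `criteria`) are tagged `qm`, the rest `mm`. The two sets
#' partition the retained set.
#'
#' @param frame A frame (`list(labels, coords)`).
#' @param solute_idx Indices of solute atoms.
#' @param water_groups List of integer triples `c(O, H1, H2)` per water.
#' @param radius Retention radius (Angstrom), default 20.
#' @param criteria An [hbond_criteria()].
#' @param solute_acceptors Solute acceptor heavy-atom indices.
#' @param solute_donor_pairs Two-column matrix (donor, hydrogen) of solute
#'   donor sites.
#' @param box Optional box lengths for minimum-image distances.
#' @return List with integer vectors `qm`, `mm` (positions in
#'   `water_groups`), and `retained` (their union).
#' @export
extract_nanodroplet <- function(frame, solute_idx, water_groups, radius = 20,
                                criteria = hbond_criteria(),
                                solute_acceptors = integer(),
                                solute_donor_pairs = NULL, box = NULL) {
  stopifnot(length(solute_idx) >= 1)
  X <- frame$coords
  center <- colMeans(X[solute_idx, , drop = FALSE])
  masses <- c(.MASS_O, .MASS_H, .MASS_H)
  retained <- integer()
  for (w in seq_along(water_groups)) {
    gi <- water_groups[[w]]
    stopifnot(length(gi) == 3)
    com <- colSums(X[gi, , drop = FALSE] * masses) / sum(masses)
    d <- com - center
    if (!is.null(box)) d <- .min_image(d, box)
    if (sqrt(sum(d^2)) <= radius) retained <- c(retained, w)
  }
  qm <- integer()
  for (w in retained) {
    gi <- water_groups[[w]]
    # water as donor toward solute acceptors
    hb1 <- if (length(solute_acceptors)) {
      hbond_partners(frame, donors = rep(gi[1], 2), hydrogens = gi[2:3],
                     acceptors = solute_acceptors, criteria = criteria,
                     box = box)
    } else NULL
    # solute donors toward the water oxygen
    hb2 <- if (!is.null(solute_donor_pairs) && nrow(solute_donor_pairs)) {
      hbond_partners(frame, donors = solute_donor_pairs[, 1],
                     hydrogens = solute_donor_pairs[, 2],
                     acceptors = gi[1], criteria = criteria, box = box)
    } else NULL
    if ((!is.null(hb1) && nrow(hb1)) || (!is.null(hb2) && nrow(hb2))) {
      qm <- c(qm, w)
    }
  }
  list(qm = qm, mm = setdiff(retained, qm), retained = retained)
}

#' 3D occupancy map of selected atoms
#'
#' Counts atom positions per voxel over all frames, after wrapping into the
#' primary box image. Optionally recenters each frame so the geometric
#' center of `center_on` sits at the box center before counting.
#'
#' @param traj A [trajectory()].
#' @param selection Labels or indices of the atoms to count.
#' @param voxel Voxel edge (Angstrom), > 0.
#' @param center_on Optional labels/indices defining the alignment center.
#' @return An `occupancy_grid`: 3D `counts` array, axis center vectors
#'   `x`, `y`, `z`, and `voxel`.
#' @export
occupancy_map <- function(traj, selection, voxel, center_on = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.finite(voxel) || voxel <= 0) stop("occupancy_map: voxel must be positive")
  box <- traj$box
  dims <- pmax(ceiling(box / voxel), 1)
  counts <- array(0L, dims)
  for (fr in traj$frames) {
    idx <- .resolve_sel(fr$labels, selection)
    X <- fr$coords[idx, , drop = FALSE]
    if (!is.null(center_on)) {
      cidx <- .resolve_sel(fr$labels, center_on)
      ctr <- colMeans(fr$coords[cidx, , drop = FALSE])
      X <- sweep(X, 2, ctr - box / 2, `-`)
    }
    for (k in 1:3) X[, k] <- X[, k] %% box[k]
    iv <- pmin(floor(sweep(X, 2, voxel, `/`)) + 1L,
               matrix(dims, nrow(X), 3, byrow = TRUE))
    for (r in seq_len(nrow(iv))) {
      counts[iv[r, 1], iv[r, 2], iv[r, 3]] <- counts[iv[r, 1], iv[r, 2], iv[r, 3]] + 1L
    }
  }
  structure(list(counts = counts,
                 x = (seq_len(dims[1]) - 0.5) * voxel,
                 y = (seq_len(dims[2]) - 0.5) * voxel,
                 z = (seq_len(dims[3]) - 0.5) * voxel,
                 voxel = voxel),
            class = "occupancy_grid")
}
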