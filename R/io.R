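# Readers and writers for the plain-text formats the package consumes and
# emits. Readers validate and reject malformed input rather than coerce.

#' Read a titration CSV
#'
#' Expected columns: `host_total_M`, `indicator_total_M`,
#' `competitor_total_M`, `signal` (header required; `#` comment lines
#' allowed). A `# units: uM` directive line, or `units = "uM"`, declares
#' micromolar concentrations, which are converted to molar.
#'
#' @param path File path.
#' @param units `"M"` (default) or `"uM"`; overridden by a units directive
#'   in the file.
#' @param mode Titration mode passed to [titration_series()]; by default
#'   inferred: competitor sweep if `competitor_total_M` varies, else host
#'   sweep.
#' @return A [titration_series()].
#' @export
read_titration <- function(path, units = c("M", "uM"), mode = NULL) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("read_titration: file not found: ", path)
  raw <- readLines(path)
  directive <- grep("^#\\s*units:", raw, value = TRUE)
  if (length(directive)) {
    u <- trimws(sub("^#\\s*units:\\s*", "", directive[1]))
    if (!u %in% c("M", "uM")) stop("read_titration: unknown units directive: ", u)
    units <- u
  }
  df <- utils::read.csv(text = raw, comment.char = "#",
                        stringsAsFactors = FALSE)
  required <- c("host_total_M", "indicator_total_M", "competitor_total_M",
                "signal")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("read_titration: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in required) {
    if (!is.numeric(df[[col]])) {
      stop("read_titration: column ", col, " is not numeric")
    }
  }
  conc_cols <- required[1:3]
  for (col in conc_cols) {
    bad <- which(df[[col]] < 0)
    if (length(bad)) {
      stop("read_titration: negative concentration in column ", col,
           " at row ", bad[1])
    }
  }
  scale <- if (units == "uM") 1e-6 else 1
  if (is.null(mode)) {
    mode <- if (length(unique(df$competitor_total_M)) > 1) {
      "competitor_titration"
    } else "host_titration"
  }
  titration_series(H_total = df$host_total_M * scale,
                   I_total = df$indicator_total_M * scale,
                   G_total = df$competitor_total_M * scale,
                   signal = df$signal, mode = mode)
}

#' Write a titration series as CSV
#'
#' @param series A [titration_series()].
#' @param path Output path.
#' @export
write_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: M", sprintf("# mode: %s", attr(series, "mode"))), con)
  utils::write.csv(
    data.frame(host_total_M = series$H_total,
               indicator_total_M = series$I_total,
               competitor_total_M = series$G_total,
               signal = series$signal),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TCSPC decay (and IRF) from two-column text
#'
#' Whitespace-separated columns: time (ns) and counts; `#` comments
#' allowed. Times are bin centers on an equal-width grid.
#'
#' @param decay_path Path to the decay histogram.
#' @param irf_path Path to the IRF histogram on the same bins.
#' @return A [decay_trace()].
#' @export
read_decay <- function(decay_path, irf_path) {
  rd <- function(p) {
    if (!file.exists(p)) stop("read_decay: file not found: ", p)
    df <- utils::read.table(p, comment.char = "#", col.names = c("t", "counts"))
    if (any(!is.finite(df$t)) || any(!is.finite(df$counts))) {
      stop("read_decay: non-numeric data in ", p)
    }
    df
  }
  d <- rd(decay_path); i <- rd(irf_path)
  if (nrow(d) != nrow(i) || max(abs(d$t - i$t)) > 1e-9 * diff(range(d$t))) {
    stop("read_decay: decay and IRF are not on the same bins")
  }
  dt <- diff(d$t)
  if (diff(range(dt)) > 1e-6 * mean(dt)) stop("read_decay: bins are not equal width")
  edges <- c(d$t - dt[1] / 2, d$t[nrow(d)] + dt[1] / 2)
  decay_trace(edges, d$counts, i$counts)
}

#' Write a decay trace to two-column text files
#'
#' @param trace A [decay_trace()].
#' @param decay_path,irf_path Output paths.
#' @export
write_decay <- function(trace, decay_path, irf_path) {
  stopifnot(inherits(trace, "decay_trace"))
  n <- length(trace$counts)
  t <- (trace$bin_edges[-1] + trace$bin_edges[-(n + 1)]) / 2
  utils::write.table(data.frame(t, trace$counts), decay_path,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(t, trace$irf_counts), irf_path,
                     row.names = FALSE, col.names = FALSE)
  invisible(decay_path)
}

#' Read an excitation table from TSV
#'
#' Tab-separated columns `position`, `unit` (`nm`, `cm-1` or `eV`) and `f`;
#' `#` comments allowed. Mixed units per row are honored.
#'
#' @param path File path.
#' @param label Snapshot label (default: file base name).
#' @return An [excitation_table()].
#' @export
read_excitations <- function(path, label = NULL) {
  if (!file.exists(path)) stop("read_excitations: file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  required <- c("position", "unit", "f")
  if (!all(required %in% names(df))) {
    stop("read_excitations: required columns: position, unit, f")
  }
  bad <- setdiff(unique(df$unit), c("nm", "cm-1", "eV"))
  if (length(bad)) stop("read_excitations: unknown unit(s): ",
                        paste(bad, collapse = ", "))
  nu <- mapply(function(p, u) convert_position(p, u, "cm-1"),
               df$position, df$unit)
  excitation_table(nu, df$f, unit = "cm-1",
                   label = if (is.null(label)) basename(path) else label)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks (atom count line, comment line, then
#' `label x y z` rows, Angstrom). The comment line of each frame must carry
#' the orthorhombic box as `box <lx> <ly> <lz>`.
#'
#' @param path File path.
#' @return A [trajectory()].
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop("read_xyz_trajectory: file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  box <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("read_xyz_trajectory: expected atom count at line ", i)
    comment <- lines[i + 1]
    m <- regmatches(comment,
                    regexec("box\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)",
                            comment))[[1]]
    if (length(m) != 4) {
      stop("read_xyz_trajectory: frame comment must contain 'box lx ly lz'")
    }
    this_box <- as.numeric(m[2:4])
    if (is.null(box)) box <- this_box
    rows <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    labels <- vapply(parts, `[[`, character(1), 1)
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(coords))) {
      stop("read_xyz_trajectory: non-numeric coordinates in frame starting at line ", i)
    }
    frames[[length(frames) + 1]] <- list(labels = labels, coords = coords)
    i <- i + 2 + n
  }
  trajectory(frames, box)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in traj$frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("box %.6f %.6f %.6f", traj$box[1], traj$box[2],
                       traj$box[3]), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", fr$labels,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Write a 3D grid as a Gaussian cube file
#'
#' Standard cube layout: two comment lines; atom count and grid origin;
#' three axis lines (voxel count and step vector); one line per atom
#' (Z, charge, coordinates); values with the last (z) axis fastest.
#' Internally the cube is always written in bohr; `input_unit = "angstrom"`
#' converts origin/voxel/atom coordinates and, per the cube convention,
#' marks the conversion by negating the axis voxel counts.
#'
#' @param grid 3D numeric array (nx x ny x nz).
#' @param origin Grid origin (length 3).
#' @param voxel Voxel steps: length 3 (orthogonal) in the input unit.
#' @param atoms Data frame with columns `Z`, `x`, `y`, `z` (may have zero
#'   rows).
#' @param path Output path.
#' @param input_unit `"bohr"` (default) or `"angstrom"`.
#' @return The path, invisibly.
#' @export
write_cube <- function(grid, origin, voxel, atoms = NULL, path,
                       input_unit = c("bohr", "angstrom")) {
  input_unit <- match.arg(input_unit)
  if (length(dim(grid)) != 3) stop("write_cube: grid must be a 3D array")
  stopifnot(length(origin) == 3, length(voxel) == 3)
  if (is.null(atoms)) atoms <- data.frame(Z = integer(), x = numeric(),
                                          y = numeric(), z = numeric())
  if (!all(c("Z", "x", "y", "z") %in% names(atoms))) {
    stop("write_cube: atoms needs columns Z, x, y, z")
  }
  conv <- if (input_unit == "angstrom") 1 / .BOHR_A else 1
  axis_sign <- if (input_unit == "angstrom") -1 else 1
  dims <- dim(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("supraspec scalar field", "cube format: z fastest"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nrow(atoms),
                     origin[1] * conv, origin[2] * conv, origin[3] * conv), con)
  steps <- diag(voxel * conv, 3)
  for (k in 1:3) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", axis_sign * dims[k],
                       steps[k, 1], steps[k, 2], steps[k, 3]), con)
  }
  for (r in seq_len(nrow(atoms))) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", atoms$Z[r],
                       as.numeric(atoms$Z[r]), atoms$x[r] * conv,
                       atoms$y[r] * conv, atoms$z[r] * conv), con)
  }
  vals <- numeric(0)
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    vals <- c(vals, grid[ix, iy, ])
  }
  lines <- vapply(split(vals, ceiling(seq_along(vals) / 6)),
                  function(v) paste(sprintf("%13.5E", v), collapse = ""),
                  character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path File path.
#' @return List with `grid` (3D array), `origin`, `voxel`, `atoms`,
#'   `unit` (`"bohr"`; negative axis counts, meaning Angstrom-authored
#'   axes, are normalized to positive with the values already in bohr).
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("read_cube: file not found: ", path)
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- num(lines[3])
  natoms <- as.integer(hdr[1])
  origin <- hdr[2:4]
  ax <- lapply(4:6, function(i) num(lines[i]))
  dims <- abs(vapply(ax, function(a) as.integer(a[1]), integer(1)))
  voxel <- vapply(seq_along(ax), function(k) ax[[k]][k + 1], numeric(1))
  atoms <- if (natoms > 0) {
    do.call(rbind, lapply(seq_len(natoms), function(r) {
      a <- num(lines[6 + r])
      data.frame(Z = as.integer(a[1]), x = a[3], y = a[4], z = a[5])
    }))
  } else data.frame(Z = integer(), x = numeric(), y = numeric(), z = numeric())
  vals <- unlist(lapply(lines[(7 + natoms):length(lines)], num), use.names = FALSE)
  if (length(vals) != prod(dims)) stop("read_cube: value count does not match grid")
  grid <- array(0, dims)
  p <- 1
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    grid[ix, iy, ] <- vals[p:(p + dims[3] - 1)]
    p <- p + dims[3]
  }
  list(grid = grid, origin = origin, voxel = voxel, atoms = atoms,
       unit = "bohr")
}

#' Write an NCI grid as a pair of cube files
#'
#' Exports the reduced density gradient and the clamped signed density of
#' an [nci_grid()] for standard NCI visualizers (masked voxels are written
#' as a large RDG value, 100, so they fall outside any isovalue).
#'
#' @param nci An `nci_grid`.
#' @param model The `wavefunction_model` (for the atom block).
#' @param s_path,color_path Output paths.
#' @export
write_nci_cubes <- function(nci, model, s_path, color_path) {
  stopifnot(inherits(nci, "nci_grid"), inherits(model, "wavefunction_model"))
  atoms <- data.frame(Z = model$Z, x = model$centers[, 1],
                      y = model$centers[, 2], z = model$centers[, 3])
  s_out <- nci$s
  s_out[!is.finite(s_out)] <- 100
  origin <- c(nci$x[1], nci$y[1], nci$z[1])
  voxel <- rep(nci$spacing, 3)
  write_cube(s_out, origin, voxel, atoms, s_path)
  write_cube(nci$color, origin, voxel, atoms, color_path)
  invisible(c(s_path, color_path))
}

#' Write an occupancy grid as a cube file
#'
#' @param occ An `occupancy_grid` from [occupancy_map()].
#' @param path Output path.
#' @export
write_occupancy_cube <- function(occ, path) {
  stopifnot(inherits(occ, "occupancy_grid"))
  origin <- c(occ$x[1], occ$y[1], occ$z[1]) - occ$voxel / 2
  write_cube(occ$counts, origin, rep(occ$voxel, 3),
             atoms = NULL, path = path, input_unit = "angstrom")
}

#' Read a Gaussian-primitive wavefunction model from keyed text
#'
#' Format (one key per line, `#` comments allowed):
#' \preformatted{
#' natoms 2
#' atom 8 0.0 0.0 0.0        # Z x y z (bohr)
#' nbasis 2
#' basis 1 2                  # center index, number of primitives
#' prim 1.6 0.5               # exponent, contraction coefficient
#' prim 0.9 0.6
#' nmo 2
#' mo 2.0 1.0 0.0             # occupation, then nbasis coefficients
#' }
#'
#' @param path File path.
#' @return A [wavefunction_model()].
#' @export
read_wfn <- function(path) {
  if (!file.exists(path)) stop("read_wfn: file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  key <- vapply(toks, `[[`, character(1), 1)
  i <- 1
  expect <- function(k) {
    if (key[i] != k) stop(sprintf("read_wfn: expected '%s' at entry %d, got '%s'",
                                  k, i, key[i]))
  }
  expect("natoms"); nat <- as.integer(toks[[i]][2]); i <- i + 1
  centers <- matrix(0, nat, 3); Z <- integer(nat)
  for (a in seq_len(nat)) {
    expect("atom")
    Z[a] <- as.integer(toks[[i]][2])
    centers[a, ] <- as.numeric(toks[[i]][3:5])
    i <- i + 1
  }
  expect("nbasis"); nb <- as.integer(toks[[i]][2]); i <- i + 1
  basis <- vector("list", nb)
  for (b in seq_len(nb)) {
    expect("basis")
    ctr <- as.integer(toks[[i]][2]); np <- as.integer(toks[[i]][3]); i <- i + 1
    alpha <- numeric(np); coeff <- numeric(np)
    for (p in seq_len(np)) {
      expect("prim")
      alpha[p] <- as.numeric(toks[[i]][2]); coeff[p] <- as.numeric(toks[[i]][3])
      i <- i + 1
    }
    basis[[b]] <- list(center = ctr, alpha = alpha, coeff = coeff)
  }
  expect("nmo"); nmo <- as.integer(toks[[i]][2]); i <- i + 1
  occ <- numeric(nmo); C <- matrix(0, nb, nmo)
  for (m in seq_len(nmo)) {
    expect("mo")
    v <- as.numeric(toks[[i]][-1])
    if (length(v) != nb + 1) stop("read_wfn: mo line needs occupation + nbasis coefficients")
    occ[m] <- v[1]; C[, m] <- v[-1]
    i <- i + 1
  }
  wavefunction_model(centers, Z, basis, C, occ)
}

#' Write a wavefunction model to keyed text
#'
#' @param model A [wavefunction_model()].
#' @param path Output path.
#' @export
write_wfn <- function(model, path) {
  stopifnot(inherits(model, "wavefunction_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("natoms %d", nrow(model$centers)), con)
  for (a in seq_len(nrow(model$centers))) {
    writeLines(sprintf("atom %d %.12g %.12g %.12g", model$Z[a],
                       model$centers[a, 1], model$centers[a, 2],
                       model$centers[a, 3]), con)
  }
  writeLines(sprintf("nbasis %d", length(model$basis)), con)
  for (b in model$basis) {
    writeLines(sprintf("basis %d %d", b$center, length(b$alpha)), con)
    for (p in seq_along(b$alpha)) {
      writeLines(sprintf("prim %.12g %.12g", b$alpha[p], b$coeff[p]), con)
    }
  }
  nmo <- length(model$occupations)
  writeLines(sprintf("nmo %d", nmo), con)
  for (m in seq_len(nmo)) {
    writeLines(paste("mo", format(model$occupations[m], digits = 12),
                     paste(format(model$mo_coefficients[, m], digits = 12),
                           collapse = " ")), con)
  }
  invisible(path)
}
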