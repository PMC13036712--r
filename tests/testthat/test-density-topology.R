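test_that("field evaluation matches analytic values for a single s orbital", {
  m <- wfn_single_center(alpha = 1, occupation = 2)
  f0 <- eval_field(m, c(0, 0, 0))
  expect_equal(f0$rho, 2 * (2 / pi)^1.5, tolerance = 1e-12)
  expect_equal(f0$G, 0, tolerance = 1e-14)       # centered s orbital: flat at center
  expect_equal(sqrt(sum(f0$grad^2)), 0, tolerance = 1e-12)
  expect_equal(f0$H, f0$G + f0$V)
  expect_equal(f0$V, 0.25 * f0$laplacian - 2 * f0$G, tolerance = 1e-14)
})

test_that("analytic derivatives agree with finite differences", {
  models <- list(wfn_single_center(), wfn_asymmetric_dimer(),
                 wfn_noncovalent_dimer())
  set.seed(404)
  worst_g <- 0; worst_l <- 0; worst_v <- 0
  for (m in models) {
    for (r in seq_len(30)) {
      p <- runif(3, -1.5, 3.5)
      f <- eval_field(m, p)
      if (f$rho < 1e-8) next
      g_fd <- fd_density_gradient(m, p)
      l_fd <- fd_density_laplacian(m, p)
      scale_g <- max(sqrt(sum(g_fd^2)), 1e-8)
      worst_g <- max(worst_g, sqrt(sum((f$grad - g_fd)^2)) / scale_g)
      worst_l <- max(worst_l, abs(f$laplacian - l_fd) / max(abs(l_fd), 1e-8))
      # virial decomposition against the finite-difference Laplacian
      worst_v <- max(worst_v, abs(f$V - (0.25 * l_fd - 2 * f$G)) /
                       max(abs(f$V), 1e-8))
    }
  }
  expect_lt(worst_g, 1e-6)
  expect_lt(worst_l, 1e-6)
  expect_lt(worst_v, 1e-6)
})

test_that("orbitals are normalized and quadrature recovers the electron count", {
  for (m in list(wfn_single_center(), wfn_symmetric_dimer(),
                 wfn_noncovalent_dimer())) {
    expect_equal(mo_norms(m), rep(1, length(m$occupations)), tolerance = 1e-8)
    expect_equal(integrate_density(m), electron_count(m),
                 tolerance = 1e-3)
  }
})

test_that("reduced density gradient has its closed-form values", {
  expect_equal(rdg(0.3, 0), 0)
  # hydrogenic density rho = exp(-2r)/pi at the nucleus: s = (3 pi^2)^(-1/3) rho^(-1/3)
  rho0 <- 1 / pi
  expect_equal(rdg(rho0, 2 * rho0), 0.4734, tolerance = 1e-4)
  expect_equal(rdg(rho0, 2 * rho0), (3 * pi^2)^(-1 / 3) * rho0^(-1 / 3))
  expect_error(rdg(0, 1), "positive")
  # homogeneity: rho -> c rho with grad -> c^(4/3) grad leaves s unchanged
  set.seed(9)
  for (i in 1:20) {
    rho <- runif(1, 1e-4, 1); gn <- runif(1, 0, 1); c0 <- runif(1, 0.1, 10)
    expect_equal(rdg(c0 * rho, c0^(4 / 3) * gn), rdg(rho, gn),
                 tolerance = 1e-12)
  }
})

test_that("the symmetric dimer has one (3,-1) point at the exact midpoint", {
  m <- wfn_symmetric_dimer(alpha = 1, separation = 2)
  cps <- find_bcps(m)
  expect_length(cps, 1)
  cp <- cps[[1]]
  expect_equal(cp$rank, 3)
  expect_equal(cp$signature, -1)
  expect_lt(sqrt(sum((cp$position - c(0, 0, 1))^2)), 1e-6)
  lam <- cp$field$lambda
  expect_true(lam[1] <= lam[2] && lam[2] < 0 && lam[3] > 0)
  expect_lt(sign(lam[2]) * cp$field$rho, 0)
})

test_that("a single center yields no bond critical point", {
  expect_length(find_bcps(wfn_single_center()), 0)
})

test_that("the asymmetric dimer BCP matches a brute-force grid scan", {
  m <- wfn_asymmetric_dimer(alpha = c(1, 0.5), separation = 3)
  cps <- find_bcps(m)
  expect_length(cps, 1)
  # dense scan of |grad rho| along the internuclear axis
  zs <- seq(0.2, 2.8, by = 1e-3)
  gn <- vapply(zs, function(z) {
    sqrt(sum(eval_field(m, c(0, 0, z))$grad^2))
  }, numeric(1))
  z_scan <- zs[which.min(gn)]
  expect_lt(abs(cps[[1]]$position[3] - z_scan), 1e-3)
  expect_equal(cps[[1]]$position[1:2], c(0, 0), tolerance = 1e-8)
})

test_that("interaction classification follows the closed-shell criteria", {
  # compact symmetric dimer: shared-type (H < 0 at the BCP)
  shared_cp <- find_bcps(wfn_symmetric_dimer(alpha = 1, separation = 2))[[1]]
  expect_lt(shared_cp$field$H, 0)
  expect_equal(classify_interaction(shared_cp), "shared")
  # packaged noncovalent dimer: closed-shell pattern within the H-bond
  # density envelope
  nc_cps <- find_bcps(wfn_noncovalent_dimer())
  expect_gte(length(nc_cps), 1)
  for (cp in nc_cps) {
    expect_equal(classify_interaction(cp), "noncovalent")
    expect_gt(cp$field$laplacian, 0)
    expect_gt(cp$field$H, 0)
    expect_gt(-cp$field$G / cp$field$V, 1)
    expect_lte(cp$field$rho, 0.0208)
  }
  bad <- shared_cp; bad$signature <- 3
  expect_error(classify_interaction(bad), "3,-1")
})

test_that("the linear estimator maps BCP density to H-bond energy", {
  expect_equal(be_from_rho(0.0208), -223.08 * 0.0208 + 0.7423)
  expect_equal(round(be_from_rho(0.0208), 1), -3.9)
  expect_equal(round(be_from_rho(0.0114), 1), -1.8)
  expect_warning(b0 <- be_from_rho(0), "calibration")
  expect_equal(b0, 0.7423)
  expect_error(be_from_rho(-0.01), "non-negative")
})

test_that("NCI grids are pointwise and consistent with the BCP search", {
  # symmetric noncovalent dimer: its BCP density sits inside the NCI window
  m <- wfn_noncovalent_dimer()
  z_bcp <- find_bcps(m)[[1]]$position[3]
  g <- nci_grid(m, box = rbind(c(-1.5, -1.5, -1.5), c(1.5, 1.5, 4.6)),
                spacing = 0.25)
  # minimum of s along the internuclear axis sits at the BCP within a voxel
  ix <- which.min(abs(g$x - 0)); iy <- which.min(abs(g$y - 0))
  s_axis <- g$s[ix, iy, ]
  z_min <- g$z[which.min(s_axis)]
  expect_lt(abs(z_min - z_bcp), g$spacing + 1e-9)
  # s is a pointwise field: refining the grid does not change shared points
  g2 <- nci_grid(m, box = rbind(c(-1.5, -1.5, -1.5), c(1.5, 1.5, 4.6)),
                 spacing = 0.125)
  shared_z <- intersect(round(g$z, 9), round(g2$z, 9))
  iz1 <- match(shared_z, round(g$z, 9)); iz2 <- match(shared_z, round(g2$z, 9))
  ix2 <- which.min(abs(g2$x - 0)); iy2 <- which.min(abs(g2$y - 0))
  expect_equal(g$s[ix, iy, iz1], g2$s[ix2, iy2, iz2], tolerance = 1e-12)
  # masking: no rdg value where the density exceeds rho_max
  expect_true(all(is.na(g$s[g$rho > g$rho_max])))
  # color clamped to the export range
  expect_true(all(g$color >= g$color_range[1] - 1e-15 &
                  g$color <= g$color_range[2] + 1e-15))
})

test_that("an isolated atom shows no low-s low-rho interaction region", {
  g <- nci_grid(wfn_single_center(), box = rbind(c(-3, -3, -3), c(3, 3, 3)),
                spacing = 0.25)
  sel <- !is.na(g$s) & g$rho > 1e-3
  expect_gt(min(g$s[sel]), 0.6)
})

test_that("packaged wavefunction fixtures load and round-trip", {
  fx <- system.file("extdata", package = "supraspec")
  nc_file <- read_wfn(file.path(fx, "noncovalent_dimer_synthetic.wfn"))
  nc_code <- wfn_noncovalent_dimer()
  expect_equal(nc_file$centers, nc_code$centers)
  expect_equal(nc_file$mo_coefficients, nc_code$mo_coefficients,
               tolerance = 1e-10)
  p <- c(0.3, -0.2, 1.4)
  expect_equal(eval_field(nc_file, p)$rho, eval_field(nc_code, p)$rho,
               tolerance = 1e-10)
  tmp <- tempfile(fileext = ".wfn")
  write_wfn(nc_code, tmp)
  again <- read_wfn(tmp)
  expect_equal(again$mo_coefficients, nc_code$mo_coefficients,
               tolerance = 1e-10)
})
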