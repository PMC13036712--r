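# Small hand-built frames plus planted-geometry trajectories from
# gen_solvation_frames.

frame_pair <- function(dist = 3.0, box = c(20, 20, 20)) {
  list(labels = c("A", "B"),
       coords = rbind(c(5, 5, 5), c(5 + dist, 5, 5)))
}

test_that("a single fixed pair puts all RDF mass in one bin", {
  tr <- trajectory(list(frame_pair(3.0)), box = c(20, 20, 20))
  r <- rdf(tr, "A", "B", r_max = 6, bin_width = 0.1)
  hit <- which(r$counts > 0)
  expect_length(hit, 1)
  expect_true(r$edges[hit] < 3.0 + 1e-12 && 3.0 <= r$edges[hit + 1] + 1e-12)
  expect_equal(sum(r$counts), 1)
})

test_that("an ideal gas has g near 1 beyond contact", {
  tr <- gen_solvation_frames(n_waters = 300, box = c(20, 20, 20),
                             n_frames = 40, seed = 77,
                             min_separation = 0, exclusion_radius = 0)
  r <- rdf(tr, "OW", "OW", r_max = 8, bin_width = 0.2)
  far <- r$r_centers > 2
  expect_lt(max(abs(r$g[far] - 1)), 0.05)
  # total-count conservation: sum of histogram = mean pair count in range
  d_all <- 0
  for (fr in tr$frames) {
    O <- fr$coords[fr$labels == "OW", ]
    for (a in seq_len(nrow(O))) {
      d <- supraspec:::.min_image(sweep(O[-a, , drop = FALSE], 2, O[a, ], `-`),
                                  tr$box)
      d_all <- d_all + sum(sqrt(rowSums(d^2)) < max(r$edges))
    }
  }
  expect_equal(sum(r$counts), d_all / length(tr$frames))
})

test_that("RDF normalization is conserved under bin-width changes", {
  tr <- gen_solvation_frames(n_waters = 150, box = c(18, 18, 18),
                             n_frames = 6, seed = 78,
                             min_separation = 0, exclusion_radius = 0)
  r1 <- rdf(tr, "OW", "OW", r_max = 8, bin_width = 0.1)
  r2 <- rdf(tr, "OW", "OW", r_max = 8, bin_width = 0.2)
  integ <- function(r, lo, hi) {
    sel <- r$r_centers >= lo & r$r_centers < hi
    sum(r$g[sel] * r$r_centers[sel]^2 * diff(r$edges)[sel])
  }
  expect_equal(integ(r1, 2, 6), integ(r2, 2, 6), tolerance = 0.01)
})

test_that("planted first-shell waters give their exact coordination number", {
  tr <- gen_solvation_frames(
    n_waters = 40, box = c(24, 24, 24),
    planted_shell = data.frame(distance = c(1.9, 2.0), angle = c(10, 20)),
    n_frames = 3, seed = 79)
  r <- rdf(tr, "SD", "OW", r_max = 8, bin_width = 0.1)
  sh <- first_shell(r)
  expect_equal(sh$coordination, 2, tolerance = 0.05)
  expect_gt(sh$r_max, 1.7); expect_lt(sh$r_max, 2.2)
  expect_error(first_shell(rdf(trajectory(list(frame_pair(10)), c(30, 30, 30)),
                               "A", "B", r_max = 4, bin_width = 0.5)),
               "maximum")
})

test_that("first-shell geometry scales with coordinates; coordination does not", {
  tr <- gen_solvation_frames(
    n_waters = 30, box = c(24, 24, 24),
    planted_shell = data.frame(distance = c(1.9, 2.0), angle = c(10, 20)),
    n_frames = 1, seed = 80)
  c0 <- 1.5
  scaled_frames <- lapply(tr$frames, function(fr)
    list(labels = fr$labels, coords = fr$coords * c0))
  tr_s <- trajectory(scaled_frames, tr$box * c0)
  sh <- first_shell(rdf(tr, "SD", "OW", r_max = 8, bin_width = 0.1))
  sh_s <- first_shell(rdf(tr_s, "SD", "OW", r_max = 8 * c0,
                          bin_width = 0.1 * c0))
  expect_equal(sh_s$r_max, sh$r_max * c0, tolerance = 1e-9)
  expect_equal(sh_s$r_min, sh$r_min * c0, tolerance = 1e-9)
  expect_equal(sh_s$coordination, sh$coordination, tolerance = 1e-9)
})

test_that("hydrogen-bond selection applies the distance and angle cutoffs", {
  # donor O at origin with H along +x; acceptor placed on the x axis
  mk <- function(d_acc, angle_deg) {
    th <- angle_deg * pi / 180
    list(labels = c("OD", "HD", "OA"),
         coords = rbind(c(0, 0, 0), c(0.96, 0, 0),
                        d_acc * c(cos(th), sin(th), 0)))
  }
  crit <- hbond_criteria()   # 30 degrees, 3.5 A
  expect_equal(nrow(hbond_partners(mk(2.8, 0), 1, 2, 3, crit)), 1)
  expect_equal(nrow(hbond_partners(mk(3.6, 0), 1, 2, 3, crit)), 0)
  expect_equal(nrow(hbond_partners(mk(2.8, 40), 1, 2, 3, crit)), 0)
  hb <- hbond_partners(mk(3.2, 25), 1, 2, 3, crit)
  expect_equal(hb$distance, 3.2, tolerance = 1e-9)
  expect_equal(hb$angle, 25, tolerance = 1e-9)
  expect_error(hbond_partners(mk(2.8, 0), 1, c(2, 2), 3, crit), "mapped")
})

test_that("hydrogen-bond selection is invariant under rigid motion", {
  fr <- list(labels = c("OD", "HD", "OA", "OB"),
             coords = rbind(c(0, 0, 0), c(0.96, 0, 0), c(2.9, 0.4, 0.2),
                            c(1.5, 2.9, 0)))
  set.seed(5)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0),
              c(0, 0, 1))
  shift <- c(3.2, -1.1, 0.7)
  fr2 <- list(labels = fr$labels,
              coords = sweep(fr$coords %*% t(Rz %*% Rx), 2, shift, `+`))
  hb1 <- hbond_partners(fr, 1, 2, c(3, 4))
  hb2 <- hbond_partners(fr2, 1, 2, c(3, 4))
  expect_equal(hb1$acceptor, hb2$acceptor)
  expect_equal(hb1$distance, hb2$distance, tolerance = 1e-9)
  expect_equal(hb1$angle, hb2$angle, tolerance = 1e-9)
})

test_that("planted H-bonded waters are selected exactly", {
  tr <- gen_solvation_frames(
    n_waters = 50, box = c(30, 30, 30),
    planted_shell = data.frame(distance = c(2.8, 3.0, 3.2, 2.8, 2.9),
                               angle = c(5, 15, 25, 40, 60)),
    n_frames = 1, seed = 81)
  fr <- tr$frames[[1]]
  sd_i <- which(fr$labels == "SD"); sh_i <- which(fr$labels == "SH")
  ow_i <- which(fr$labels == "OW")
  hb <- hbond_partners(fr, sd_i, sh_i, ow_i, hbond_criteria(), box = tr$box)
  expect_equal(nrow(hb), 3)
  # the three selected are the first three planted waters
  expect_setequal(hb$acceptor, ow_i[1:3])
})

test_that("nanodroplet extraction partitions retained waters into qm and mm", {
  # hand-built: solute donor at the center; three waters at controlled radii
  box <- c(50, 50, 50); ctr <- box / 2
  water_at <- function(p) rbind(p, p + c(0.96, 0, 0), p + c(-0.24, 0.93, 0))
  coords <- rbind(ctr, ctr + c(0.96, 0, 0),
                  water_at(ctr + c(2.9, 0.2, 0)),     # H-bonded, inside
                  water_at(ctr + c(19.9, 0, 0)),      # inside, not H-bonded
                  water_at(ctr + c(20.5, 0, 0)))      # outside
  labels <- c("SD", "SH", rep(c("OW", "HW", "HW"), 3))
  fr <- list(labels = labels, coords = coords)
  groups <- list(3:5, 6:8, 9:11)
  res <- extract_nanodroplet(fr, solute_idx = 1:2, water_groups = groups,
                             radius = 20,
                             solute_donor_pairs = cbind(1L, 2L), box = box)
  expect_setequal(res$retained, c(1, 2))
  expect_equal(res$qm, 1)
  expect_equal(res$mm, 2)
  expect_length(intersect(res$qm, res$mm), 0)
  expect_setequal(c(res$qm, res$mm), res$retained)
})

test_that("planted frames give the expected qm set", {
  tr <- gen_solvation_frames(
    n_waters = 50, box = c(30, 30, 30),
    planted_shell = data.frame(distance = c(2.8, 3.0, 3.2, 2.8, 2.9),
                               angle = c(5, 15, 25, 40, 60)),
    n_frames = 1, seed = 82)
  fr <- tr$frames[[1]]
  n_w <- sum(fr$labels == "OW")
  groups <- lapply(seq_len(n_w), function(w) 2 + (w - 1) * 3 + 1:3)
  res <- extract_nanodroplet(fr, solute_idx = 1:2, water_groups = groups,
                             radius = 14, solute_donor_pairs = cbind(1L, 2L),
                             box = tr$box)
  expect_setequal(res$qm, 1:3)
  expect_setequal(c(res$qm, res$mm), res$retained)
})

test_that("occupancy maps count positions and add over selections", {
  box <- c(10, 10, 10)
  frames <- lapply(1:4, function(i)
    list(labels = c("X", "Y"), coords = rbind(c(2.3, 5.1, 7.7),
                                              c(8.1, 1.2, 3.3))))
  tr <- trajectory(frames, box)
  occ_x <- occupancy_map(tr, "X", voxel = 1)
  expect_equal(sum(occ_x$counts), 4)
  expect_equal(max(occ_x$counts), 4)          # static atom: one voxel
  occ_y <- occupancy_map(tr, "Y", voxel = 1)
  occ_xy <- occupancy_map(tr, c("X", "Y"), voxel = 1)
  expect_equal(occ_xy$counts, occ_x$counts + occ_y$counts)
  expect_equal(sum(occ_xy$counts), 2 * 4)     # n_selected x n_frames
})

test_that("a jittered cloud peaks at its planted center", {
  set.seed(6)
  ctr <- c(6, 6, 6)
  frames <- lapply(1:60, function(i)
    list(labels = "P",
         coords = matrix(ctr + rnorm(3, 0, 0.3), 1, 3)))
  tr <- trajectory(frames, c(12, 12, 12))
  occ <- occupancy_map(tr, "P", voxel = 1)
  peak <- which(occ$counts == max(occ$counts), arr.ind = TRUE)[1, ]
  peak_center <- c(occ$x[peak[1]], occ$y[peak[2]], occ$z[peak[3]])
  expect_lt(max(abs(peak_center - ctr)), 1 + 1e-9)
})

test_that("rdf validates its range against the box", {
  tr <- trajectory(list(frame_pair(3)), box = c(10, 10, 10))
  expect_error(rdf(tr, "A", "B", r_max = 6), "half the smallest")
})
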