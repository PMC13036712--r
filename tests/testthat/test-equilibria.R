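test_that("solve_1to1 reproduces closed-form and limiting cases", {
  expect_equal(solve_1to1(0, 1e-5, 1e5)$HI, 0)
  # quadratic formula: b = 3e-5, disc = 5e-10
  expect_equal(solve_1to1(1e-5, 1e-5, 1e5)$HI,
               (3e-5 - sqrt(5e-10)) / 2, tolerance = 1e-12)
  expect_equal(solve_1to1(1e-5, 1e-5, 1e5)$HI, 3.8196601e-6, tolerance = 1e-7)
  # stoichiometric limit
  expect_equal(solve_1to1(2e-5, 1e-5, Inf)$HI, 1e-5)
  # no binding
  expect_equal(solve_1to1(1e-5, 1e-5, 0)$HI, 0)
  expect_error(solve_1to1(-1e-5, 1e-5, 1e5), "non-negative")
})

test_that("solve_1to1 satisfies mass balance and matches bisection oracle", {
  set.seed(101)
  n <- 10000
  H <- 10^runif(n, -8, -2)
  I <- 10^runif(n, -8, -2)
  K <- 10^runif(n, 1, 9)
  HI <- vapply(seq_len(n), function(i) solve_1to1(H[i], I[i], K[i])$HI,
               numeric(1))
  HI_oracle <- oracle_1to1_bisect(H, I, K)
  expect_lt(max(abs(HI - HI_oracle) / pmax(HI_oracle, 1e-300)), 1e-10)
  st <- solve_1to1(H[1], I[1], K[1])
  expect_equal(st$free_H + st$HI, H[1], tolerance = 1e-12)
  expect_equal(st$free_I + st$HI, I[1], tolerance = 1e-12)
})

test_that("solve_competitive matches the fixed-point oracle and obeys mass balance", {
  # spec'd reference case
  st <- solve_competitive(equilibrium_system(1e-5, 1e-6, 1e-4, 4.54e5, 5.5e5))
  or <- oracle_competitive_fixed_point(1e-5, 1e-6, 1e-4, 4.54e5, 5.5e5)
  for (f in c("free_H", "free_I", "free_G", "HI", "HG")) {
    expect_equal(st[[f]], or[[f]], tolerance = 1e-10)
  }
  # random draws: all five defining equations to 1e-10 relative
  set.seed(202)
  worst <- 0
  for (r in seq_len(1000)) {
    H <- 10^runif(1, -7, -3); I <- 10^runif(1, -7, -3)
    G <- 10^runif(1, -7, -3)
    K1 <- 10^runif(1, 2, 7); K2 <- 10^runif(1, 2, 7)
    st <- solve_competitive(equilibrium_system(H, I, G, K1, K2))
    worst <- max(worst,
                 abs(st$free_H + st$HI + st$HG - H) / H,
                 abs(st$free_I + st$HI - I) / I,
                 abs(st$free_G + st$HG - G) / G,
                 abs(st$HI / (st$free_H * st$free_I) - K1) / K1,
                 abs(st$HG / (st$free_H * st$free_G) - K2) / K2)
  }
  expect_lt(worst, 1e-10)
})

test_that("solve_competitive reduces to 1:1 without an effective competitor", {
  st0 <- solve_competitive(equilibrium_system(1e-5, 2e-6, 0, 3e5, 1e5))
  ref <- solve_1to1(1e-5, 2e-6, 3e5)
  expect_equal(st0$HI, ref$HI, tolerance = 1e-12)
  # inert competitor
  st1 <- solve_competitive(equilibrium_system(1e-5, 2e-6, 1e-3, 3e5, 1e-30))
  expect_equal(st1$HI, ref$HI, tolerance = 1e-6)
})

test_that("bound indicator is displaced monotonically by competitor amount and strength", {
  G_grid <- seq(0, 2e-3, length.out = 25)
  HI_G <- vapply(G_grid, function(g)
    solve_competitive(equilibrium_system(1e-5, 1e-6, g, 4.54e5, 5.5e5))$HI,
    numeric(1))
  expect_true(all(diff(HI_G) <= 1e-18))
  K2_grid <- 10^seq(2, 8, length.out = 25)
  HI_K <- vapply(K2_grid, function(k2)
    solve_competitive(equilibrium_system(1e-5, 1e-6, 1e-4, 4.54e5, k2))$HI,
    numeric(1))
  expect_true(all(diff(HI_K) <= 1e-18))
})

test_that("predict_signal is the linear response of free and bound indicator", {
  expect_equal(predict_signal(species_state(0, 0, 0, 0, 0), c(1e6, 1e7)), 0)
  expect_equal(predict_signal(species_state(0, 0, 0, 1e-6, 0), c(0, 1e6)), 1)
  # generator/predictor round trip at the generating parameters
  ser <- gen_titration(K = 4.54e5, noise_sd = 0, seed = 7)
  mu <- vapply(seq_len(nrow(ser)), function(i)
    predict_signal(solve_1to1(ser$H_total[i], ser$I_total[i], 4.54e5),
                   c(2.1e6, 9.8e6)), numeric(1))
  expect_equal(ser$signal, mu)
})

test_that("fit_1to1 recovers the generating constant", {
  ser <- gen_titration(K = 4.54e5, noise_sd = 0, seed = 11)
  fit <- fit_1to1(ser, n_boot = 0, seed = 1)
  expect_lt(abs(fit$K_hat - 4.54e5) / 4.54e5, 0.001)
  # 1% multiplicative noise: within 5%
  ser_n <- gen_titration(K = 4.54e5, noise_sd = 0.01, seed = 12)
  fit_n <- fit_1to1(ser_n, n_boot = 100, seed = 2)
  expect_lt(abs(fit_n$K_hat - 4.54e5) / 4.54e5, 0.05)
  expect_true(fit_n$K_interval[1] <= fit_n$K_hat &&
              fit_n$K_hat <= fit_n$K_interval[2])
  expect_identical(fit_n$seed, 2)
})

test_that("fit_1to1 rejects uninformative series", {
  flat <- titration_series(H_total = seq(0, 9e-5, length.out = 6),
                           I_total = 1e-6, signal = rep(5, 6),
                           mode = "host_titration")
  expect_error(fit_1to1(flat, n_boot = 0, seed = 1), "identifiable")
  short <- titration_series(H_total = c(0, 1e-5, 2e-5), I_total = 1e-6,
                            signal = c(1, 2, 3), mode = "host_titration")
  expect_error(fit_1to1(short, n_boot = 0, seed = 1), "4")
})

test_that("fit_ida recovers K2 with K1 held fixed", {
  ser <- gen_ida(K1 = 4.54e5, K2 = 5.5e5, noise_sd = 0, seed = 21)
  fit <- fit_ida(ser, K1_fixed = 4.54e5, n_boot = 0, seed = 1)
  expect_lt(abs(fit$K_hat - 5.5e5) / 5.5e5, 0.005)
  # seeded 2% noise: within 10%
  ser_n <- gen_ida(K1 = 4.54e5, K2 = 5.5e5, noise_sd = 0.02, seed = 22)
  fit_n <- fit_ida(ser_n, K1_fixed = 4.54e5, n_boot = 50, seed = 3)
  expect_lt(abs(fit_n$K_hat - 5.5e5) / 5.5e5, 0.10)
  expect_true(fit_n$K_interval[1] <= fit_n$K_hat &&
              fit_n$K_hat <= fit_n$K_interval[2])
  expect_error(fit_ida(ser, K1_fixed = -1, n_boot = 0, seed = 1), "positive")
})

test_that("fit_ida flags a competitor sweep that does not displace", {
  # competitor range so narrow that the complex is essentially constant
  G <- 1e-4 * (1 + c(0, 1e-4, 2e-4, 3e-4, 4e-4))
  ser <- gen_ida(K1 = 4.54e5, K2 = 5.5e5, G_totals = G, noise_sd = 0,
                 seed = 31)
  expect_error(fit_ida(ser, K1_fixed = 4.54e5, n_boot = 0, seed = 1),
               "identifiable")
})

test_that("thermodynamic bookkeeping follows dG = -RT ln K and dG = dH - TdS", {
  expect_equal(gibbs_from_k(1, 298), 0)
  expect_equal(gibbs_from_k(4.54e5, 298), -7.71, tolerance = 1e-3)
  # inverse round trip
  dG <- gibbs_from_k(4.54e5, 298)
  expect_equal(exp(-dG / (1.98720425e-3 * 298)), 4.54e5, tolerance = 1e-12)
  expect_error(gibbs_from_k(0, 298), "positive")
  # -RT ln K decreasing in K
  Ks <- 10^seq(0, 9, length.out = 20)
  expect_true(all(diff(gibbs_from_k(Ks, 298)) < 0))
  expect_equal(thermo_consistency(-9.9, -2.7), -7.2)
  expect_equal(thermo_consistency(0, 0), 0)
  expect_equal(thermo_consistency(-5, 3), -8)
})
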