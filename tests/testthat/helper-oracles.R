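# Independent brute-force oracles used to cross-check the closed-form /
# Newton solvers. These deliberately share no code with the implementation.

# Vectorized bisection for the 1:1 complex concentration: root of
# K (H - x)(I - x) - x = 0 on [0, min(H, I)].
oracle_1to1_bisect <- function(H, I, K, n_iter = 120) {
  lo <- rep(0, length(H))
  hi <- pmin(H, I)
  g <- function(x) K * (H - x) * (I - x) - x
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

# Damped fixed-point iteration on the free concentrations of the
# competitive system.
oracle_competitive_fixed_point <- function(H, I, G, K1, K2,
                                           damping = 0.3,
                                           max_iter = 200000,
                                           tol = 1e-15) {
  h <- H; i <- I; g <- G
  for (it in seq_len(max_iter)) {
    h_new <- H / (1 + K1 * i + K2 * g)
    i_new <- I / (1 + K1 * h)
    g_new <- G / (1 + K2 * h)
    h_next <- (1 - damping) * h + damping * h_new
    i_next <- (1 - damping) * i + damping * i_new
    g_next <- (1 - damping) * g + damping * g_new
    delta <- max(abs(h_next - h) / max(h, 1e-300),
                 abs(i_next - i) / max(i, 1e-300),
                 abs(g_next - g) / max(g, 1e-300))
    h <- h_next; i <- i_next; g <- g_next
    if (delta < tol) break
  }
  list(free_H = h, free_I = i, free_G = g,
       HI = K1 * h * i, HG = K2 * h * g, iterations = it)
}

# Finite-difference density derivatives from rho alone (central, step in
# bohr); independent check of the analytic gradient/Hessian.
fd_density_gradient <- function(model, point, step = 1e-4) {
  rho_at <- function(p) eval_field(model, p)$rho
  vapply(1:3, function(k) {
    e <- rep(0, 3); e[k] <- step
    (rho_at(point + e) - rho_at(point - e)) / (2 * step)
  }, numeric(1))
}

fd_density_laplacian <- function(model, point, step = 1e-4) {
  rho_at <- function(p) eval_field(model, p)$rho
  r0 <- rho_at(point)
  sum(vapply(1:3, function(k) {
    e <- rep(0, 3); e[k] <- step
    (rho_at(point + e) - 2 * r0 + rho_at(point - e)) / step^2
  }, numeric(1)))
}
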