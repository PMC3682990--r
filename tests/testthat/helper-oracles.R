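# Independent oracles used across the suite. These never call the code
# paths they check: the grid search evaluates the SSE surface directly,
# and the cascade oracle solves the linearized system by matrix
# exponential (Matrix::expm), not by the package's ODE integrator.

hill_curve <- function(G, sigma, alpha, gamma) {
  sigma * G^gamma / (alpha^gamma + G^gamma)
}

# Coarse grid search for the least-squares Hill fit; an upper bound on
# the attainable SSE that the optimizer must beat or match.
grid_search_sse <- function(data,
                            sigma_grid = seq(80, 160, by = 2),
                            alpha_grid = seq(6, 14, by = 0.2),
                            gamma_grid = seq(1, 6, by = 0.1)) {
  G <- data$glucose_mM
  r <- data$rate_pM_per_min
  best <- Inf
  for (s in sigma_grid) for (a in alpha_grid) for (g in gamma_grid) {
    v <- sum((r - hill_curve(G, s, a, g))^2)
    if (v < best) best <- v
  }
  best
}

# Analytic solution of the linear cascade (q = q_hat = 0) from the zero
# state under constant secretion s: x' = A x + b, x(t) = A^{-1}(e^{At}-I)b.
cascade_matrix <- function(params) {
  rbind(c(-params$p, 0, 0, 0),
        c(3 * params$p, -params$p_hat, 0, 0),
        c(0, 2 * params$p_hat, -(params$c + params$d_i), 0),
        c(0, 0, params$k, -params$d_i))
}

cascade_state <- function(t, params, s) {
  A <- cascade_matrix(params)
  b <- c(s / 6, 0, 0, 0)
  E <- as.matrix(Matrix::expm(A * t))
  x <- solve(A, (E %*% b) - b)
  stats::setNames(as.numeric(x), c("h", "d", "m", "Ip"))
}

# First time Ip(t) reaches fraction * Ip* in the linear cascade.
cascade_time_to_fraction <- function(params, s, fraction, t_upper = 500) {
  A <- cascade_matrix(params)
  b <- c(s / 6, 0, 0, 0)
  Ip_star <- solve(-A, b)[4]
  f <- function(t) cascade_state(t, params, s)[["Ip"]] - fraction * Ip_star
  stats::uniroot(f, c(1e-6, t_upper), tol = 1e-10)$root
}

# Small hand-built parameter set that avoids the packaged-table fit.
toy_params <- function(q = 1.6e-15, q_hat = 1e-7,
                       hill = hill_params(100, 9, 3)) {
  d_i <- log(2) / 6
  kinetic_params(p = 0.5, q = q, p_hat = 1.0, q_hat = q_hat,
                 d_i = d_i, c = 0.5 - d_i, k = 3 * d_i, hill = hill)
}

equilibrium_state <- function(params, glucose) {
  eq <- islet_equilibrium(params, glucose)
  islet_state(h = eq$h_pM, d = eq$d_pM, m = eq$m_pM, Ip = eq$Ip_pM)
}
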