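test_that("the right-hand side vanishes at the closed-form equilibrium", {
  params <- toy_params()
  for (G in c(0, 2, 7, 16.5, 25)) {
    deriv <- islet_rhs(equilibrium_state(params, G), G, params)
    expect_equal(unname(deriv), rep(0, 4), tolerance = 1e-10)
  }
})

test_that("the empty islet at zero glucose is inert, and secretion enters as hexamer", {
  params <- toy_params()
  expect_equal(unname(islet_rhs(islet_state(), 0, params)), rep(0, 4))
  d7 <- islet_rhs(islet_state(), 7, params)
  s7 <- hill_rate(7, params$hill)
  expect_equal(d7[["h"]], s7 / 6)
  expect_equal(unname(d7[c("d", "m", "Ip")]), rep(0, 3))
  expect_error(islet_rhs(c(h = -1, d = 0, m = 0, Ip = 0), 7, params),
               "nonnegative")
})

test_that("kinetic parameter invariants are enforced", {
  h <- hill_params(100, 9, 3)
  expect_error(kinetic_params(0.5, 0, 0.4, 0, 0.1, 0.4, 0.3, h), "p_hat")
  expect_error(kinetic_params(0.5, -1, 1, 0, 0.1, 0.4, 0.3, h), "nonnegative")
  expect_error(kinetic_params(0.5, 0, 1, 0, -0.1, 0.4, 0.3, h), "positive")
})

test_that("equilibrium follows the closed form and is monotone in glucose", {
  params <- toy_params()
  g <- c(0, 2, 4, 7, 10, 16.5, 25)
  eq <- islet_equilibrium(params, g)
  s <- hill_rate(g, params$hill)
  m <- s / (params$c + params$d_i)
  expect_equal(eq$m_pM, m)
  expect_equal(eq$Ip_pM, (params$k / params$d_i) * m)
  expect_equal(eq$d_pM, s / (2 * params$p_hat) + params$q_hat * m^2)
  expect_equal(eq$h_pM, s / (6 * params$p) + params$q * eq$d_pM^3)
  expect_equal(unlist(eq[1, -1]), rep(0, 5), ignore_attr = TRUE) # s(0) = 0
  for (col in c("h_pM", "d_pM", "m_pM", "Ip_pM", "total_monomer_pM")) {
    expect_true(all(diff(eq[[col]]) >= 0))
  }
  # aggregation corrections are negligible at islet concentrations
  eq7 <- islet_equilibrium(params, 7)
  expect_lt(params$q * eq7$d_pM^3, 1e-10)
  expect_lt(params$q_hat * eq7$m_pM^2, 1e-3)
  expect_lt(max(params$q * eq$d_pM^3), 1e-9)
  expect_lt(max(params$q_hat * eq$m_pM^2), 1e-2)
})

test_that("new-to-peripheral ratio is d_i/k, glucose independent, consistent with the equilibrium", {
  params <- toy_params()
  expect_equal(new_to_peripheral_ratio(params), 1 / 3, tolerance = 1e-12)
  for (G in c(2, 5, 20)) {
    eq <- islet_equilibrium(params, G)
    expect_equal(eq$m_pM / eq$Ip_pM, new_to_peripheral_ratio(params))
  }
  sym <- kinetic_params(p = 0.5, q = 0, p_hat = 1, q_hat = 0,
                        d_i = 0.2, c = 0.3, k = 0.2,
                        hill = hill_params(100, 9, 3))
  expect_equal(new_to_peripheral_ratio(sym), 1)
  expect_equal(total_intra_islet_monomer(params, 0), 0)
})

test_that("equilibrium monomer pools are invariant to the oligomer kinetics", {
  base <- toy_params()
  eq0 <- islet_equilibrium(base, 7)
  tenfold <- kinetic_params(p = base$p * 10, q = base$q * 10,
                            p_hat = base$p_hat * 10, q_hat = base$q_hat * 10,
                            d_i = base$d_i, c = base$c, k = base$k,
                            hill = base$hill)
  eq1 <- islet_equilibrium(tenfold, 7)
  expect_equal(eq1$m_pM, eq0$m_pM)
  expect_equal(eq1$Ip_pM, eq0$Ip_pM)
  # the aggregated pools are NOT invariant
  expect_false(isTRUE(all.equal(eq1$h_pM, eq0$h_pM)))
  expect_false(isTRUE(all.equal(eq1$d_pM, eq0$d_pM)))
})

test_that("simulation is stationary at equilibrium and converges from the empty islet", {
  params <- toy_params()
  init <- equilibrium_state(params, 10)
  tr <- simulate_clamp(params, 10, t_end = 60, dt_out = 1, init = init)
  for (col in c("h_pM", "d_pM", "m_pM", "Ip_pM")) {
    expect_equal(tr[[col]], rep(tr[[col]][1], nrow(tr)), tolerance = 1e-6)
  }
  tr0 <- simulate_clamp(params, 10, t_end = 600, dt_out = 1)
  eq <- islet_equilibrium(params, 10)
  terminal <- tr0[nrow(tr0), c("h_pM", "d_pM", "m_pM", "Ip_pM")]
  expect_equal(unlist(terminal),
               unlist(eq[, c("h_pM", "d_pM", "m_pM", "Ip_pM")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("with no aggregation the trace matches the analytic linear cascade", {
  params <- toy_params(q = 0, q_hat = 0)
  s <- hill_rate(10, params$hill)
  tr <- simulate_clamp(params, 10, t_end = 120, dt_out = 10)
  for (i in seq_len(nrow(tr))[-1]) {
    exact <- cascade_state(tr$time_min[i], params, s)
    expect_equal(unlist(tr[i, c("h_pM", "d_pM", "m_pM", "Ip_pM")]),
                 exact, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("normalized peripheral response is glucose independent in the linear regime", {
  params <- toy_params(q = 0, q_hat = 0)
  profiles <- purrr::map(c(5, 10, 15), function(G) {
    tr <- simulate_clamp(params, G, t_end = 120, dt_out = 1)
    tr$Ip_pM / islet_equilibrium(params, G)$Ip_pM
  })
  expect_equal(profiles[[1]], profiles[[2]], tolerance = 1e-6)
  expect_equal(profiles[[2]], profiles[[3]], tolerance = 1e-6)
})

test_that("time_to_fraction matches the multi-exponential oracle and handles edge cases", {
  params <- toy_params(q = 0, q_hat = 0)
  s <- hill_rate(10, params$hill)
  tr <- simulate_clamp(params, 10, t_end = 120, dt_out = 0.05)
  Ip_star <- islet_equilibrium(params, 10)$Ip_pM
  t90 <- time_to_fraction(tr, "Ip_pM", 0.9, Ip_star)
  t50 <- time_to_fraction(tr, "Ip_pM", 0.5, Ip_star)
  expect_equal(t90, cascade_time_to_fraction(params, s, 0.9), tolerance = 1e-3)
  expect_equal(t50, cascade_time_to_fraction(params, s, 0.5), tolerance = 1e-3)
  # constant trace at the reference is settled at t = 0
  const <- simulate_clamp(params, 10, t_end = 10, dt_out = 1,
                          init = equilibrium_state(params, 10))
  expect_equal(time_to_fraction(const, "Ip_pM", 0.9, Ip_star), 0)
  # never crosses -> sentinel
  short <- simulate_clamp(params, 10, t_end = 2, dt_out = 0.5)
  expect_true(is.na(time_to_fraction(short, "Ip_pM", 0.99, Ip_star)))
})

test_that("trajectories from random states stay nonnegative, bounded, and converge", {
  params <- toy_params()
  states <- gen_initial_states(25, upper_bound = 1e4, seed = 7L)
  eq <- islet_equilibrium(params, 12)
  eq_vec <- unlist(eq[, c("h_pM", "d_pM", "m_pM", "Ip_pM")])
  bound <- 10 * (1e4 + max(eq_vec))
  for (i in seq_len(nrow(states))) {
    init <- islet_state(states$h[i], states$d[i], states$m[i], states$Ip[i])
    tr <- simulate_clamp(params, 12, t_end = 1000, dt_out = 10, init = init)
    vals <- as.matrix(tr[, c("h_pM", "d_pM", "m_pM", "Ip_pM")])
    expect_gt(min(vals), -1e-9)
    expect_lt(max(vals), bound)
    expect_equal(unname(vals[nrow(vals), ]), unname(eq_vec), tolerance = 1e-3)
  }
})
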