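# Independent oracles and random-case generators shared across tests.

# the three benchmark parameter sets, spelled out rather than taken from
# printed_scenarios() so fixture tests stay independent of the generator
fix1 <- function() game_params(V = 1, L = 0.2, C = 0.1, alpha = 1.05,
                               beta = 0.5, gamma = 2)
fix2 <- function() game_params(V = 1, L = 0.2, C = 0.1, alpha = 1.1,
                               beta = 0.5, gamma = 2.5)
fix3 <- function() game_params(V = 1, L = 0.2, C = 0.1, alpha = 1.1,
                               beta = 0.5, gamma = 1.1)

# fetch one (user, government) pair from a payoff_matrix object
payoff_cell_test <- function(pm, share, disclose) {
  i <- which(pm$cells$share == share & pm$cells$disclose == disclose)
  c(pm$cells$user[i], pm$cells$government[i])
}

# random valid parameter set (no regime constraint)
random_params <- function() {
  game_params(V = runif(1, 0.2, 3), L = runif(1, 0.02, 1),
              C = runif(1, 0.02, 1), alpha = runif(1, 1.001, 2),
              beta = runif(1, 0.05, 0.95), gamma = runif(1, 1.001, 4))
}

# generic replicator form built from expected payoffs: an independent
# derivation of the vector field, used to cross-check the closed forms
rhs_from_payoffs <- function(p, state) {
  ep <- expected_payoffs(p, state)
  c(state[1] * (ep$user_share - ep$user_average),
    state[2] * (ep$gov_disclose - ep$gov_average))
}

# central finite-difference Jacobian of replicator_rhs
fd_jacobian <- function(p, state, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    hi <- state; lo <- state
    hi[j] <- min(1, state[j] + h); lo[j] <- max(0, state[j] - h)
    J[, j] <- (replicator_rhs(p, hi) - replicator_rhs(p, lo)) /
      (hi[j] - lo[j])
  }
  J
}

# fixed-step forward-Euler integrator of the replicator system
euler_trajectory <- function(p, init, t_end, h = 1e-3) {
  s <- as.numeric(init)
  n <- round(t_end / h)
  for (i in seq_len(n)) {
    d <- replicator_rhs(p, s)
    s <- pmin(pmax(s + h * unname(d), 0), 1)
  }
  s
}
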