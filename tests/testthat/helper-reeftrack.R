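# Shared fixtures and independent oracles for the test suite.

# minimal 3-receiver layout for solver unit tests
triangle_layout <- function() {
  array_layout(
    receivers = data.frame(id = c("A", "B", "C"),
                           x = c(0, 1000, 0), y = c(0, 0, 1000), depth = 30),
    structures = data.frame(id = "R01", kind = "reef", x = 100, y = 100,
                            scour = FALSE)
  )
}

square_layout <- function(side = 1000) {
  array_layout(
    receivers = data.frame(id = c("A", "B", "C", "D"),
                           x = c(0, side, side, 0),
                           y = c(0, 0, side, side), depth = 30),
    structures = data.frame(id = "R01", kind = "reef", x = side / 2,
                            y = side / 2, scour = FALSE)
  )
}

# exact detection group for a source at (sx, sy) with zero noise
exact_group <- function(layout, sx, sy, c0 = 1500, t0 = 0) {
  r <- layout$receivers
  d <- sqrt((sx - r$x)^2 + (sy - r$y)^2)
  data.frame(receiver_id = r$id, time_sync = t0 + d / c0)
}

# TDOA Jacobian at a point, for direct HPE evaluation
tdoa_jacobian <- function(p, rx, ry, c0 = 1500) {
  d <- sqrt((p[1] - rx)^2 + (p[2] - ry)^2)
  ux <- (p[1] - rx) / d
  uy <- (p[2] - ry) / d
  cbind(-(ux[-1] - ux[1]) / c0, -(uy[-1] - uy[1]) / c0)
}

# brute-force HMM likelihood by full path enumeration (independent oracle)
brute_force_loglik <- function(spec, par, data) {
  K <- spec$n_states
  T_ <- nrow(data)
  X <- reeftrack:::build_design(spec, data)
  dens <- reeftrack:::emission_density(spec, par, data)
  A <- reeftrack:::transition_array(spec, par, X)
  delta <- reeftrack:::hmm_delta(spec, par, colMeans(X))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- delta[paths[r, 1]] * dens[1, paths[r, 1]]
    for (t in seq_len(T_)[-1]) {
      p <- p * A[paths[r, t - 1], paths[r, t], t] * dens[t, paths[r, t]]
    }
    tot <- tot + p
  }
  log(tot)
}

# brute-force most probable path and its log-probability
brute_force_viterbi <- function(spec, par, data) {
  K <- spec$n_states
  T_ <- nrow(data)
  X <- reeftrack:::build_design(spec, data)
  dens <- reeftrack:::emission_density(spec, par, data)
  A <- reeftrack:::transition_array(spec, par, X)
  delta <- reeftrack:::hmm_delta(spec, par, colMeans(X))
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- apply(paths, 1, function(p) {
    v <- log(delta[p[1]]) + log(dens[1, p[1]])
    for (t in seq_len(T_)[-1]) {
      v <- v + log(A[p[t - 1], p[t], t]) + log(dens[t, p[t]])
    }
    v
  })
  list(path = paths[which.max(lp), ], logp = max(lp))
}

path_logprob <- function(spec, par, data, path) {
  X <- reeftrack:::build_design(spec, data)
  dens <- reeftrack:::emission_density(spec, par, data)
  A <- reeftrack:::transition_array(spec, par, X)
  delta <- reeftrack:::hmm_delta(spec, par, colMeans(X))
  v <- log(delta[path[1]]) + log(dens[1, path[1]])
  for (t in seq_along(path)[-1]) {
    v <- v + log(A[path[t - 1], path[t], t]) + log(dens[t, path[t]])
  }
  v
}

# a small, well-separated 3-state Gamma/Gamma parameter set used by several
# recovery tests (step in metres per 10 min, VeDBA in m s^-2)
behaviour_truth_par <- function() {
  list(
    emission = list(
      step = list(mean = c(1, 3, 30), sd = c(1, 2.5, 20),
                  zero = c(0.4, 0.1, 0.02)),
      vedba = list(mean = c(0.05, 0.25, 0.45), sd = c(0.03, 0.12, 0.25))
    ),
    beta = matrix(log(0.04), 1, 6)
  )
}

behaviour_spec <- function(transition = ~1) {
  hmm_spec(3,
           streams = list(step = list(family = "gamma", zero_inflated = TRUE),
                          vedba = list(family = "gamma")),
           transition = transition)
}
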