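test_that("forward log-likelihood matches brute-force enumeration", {
  set.seed(3)
  # mixed streams with zero inflation, missing values and a covariate
  spec <- hmm_spec(3,
                   streams = list(s = list(family = "gamma",
                                           zero_inflated = TRUE),
                                  v = list(family = "gamma"),
                                  b = list(family = "bernoulli")),
                   transition = ~z)
  par <- list(
    emission = list(
      s = list(mean = c(1, 5, 30), sd = c(1, 4, 20),
               zero = c(0.3, 0.1, 0.05)),
      v = list(mean = c(0.05, 0.25, 0.45), sd = c(0.03, 0.12, 0.25)),
      b = list(prob = c(0.1, 0.5, 0.9))),
    beta = matrix(rnorm(12, -2, 0.5), 2, 6))
  dat <- data.frame(s = c(0, rgamma(5, 2, 1)), v = rgamma(6, 2, 10),
                    b = rbinom(6, 1, 0.5), z = rnorm(6))
  dat$s[3] <- NA; dat$v[5] <- NA
  expect_equal(forward_loglik(spec, par, dat),
               brute_force_loglik(spec, par, dat), tolerance = 1e-10)

  # K = 4, homogeneous chain, T = 7
  spec4 <- hmm_spec(4, streams = list(s = list(family = "gamma")))
  par4 <- list(emission = list(s = list(mean = c(1, 3, 9, 27),
                                        sd = c(1, 2, 5, 10))),
               beta = matrix(rnorm(12, -1.5, 0.4), 1, 12))
  d4 <- data.frame(s = rgamma(7, 2, 0.5))
  expect_equal(forward_loglik(spec4, par4, d4),
               brute_force_loglik(spec4, par4, d4), tolerance = 1e-10)

  # K = 2, T = 5 bernoulli only
  spec2 <- hmm_spec(2, streams = list(b = list(family = "bernoulli")))
  par2 <- list(emission = list(b = list(prob = c(0.2, 0.9))),
               beta = matrix(c(-1, -2), 1, 2))
  d2 <- data.frame(b = c(0, 1, 1, NA, 0))
  expect_equal(forward_loglik(spec2, par2, d2),
               brute_force_loglik(spec2, par2, d2), tolerance = 1e-10)
})

test_that("degenerate cases: K = 1 and all-missing data", {
  spec1 <- hmm_spec(1, streams = list(s = list(family = "gamma")))
  par1 <- list(emission = list(s = list(mean = 2, sd = 1)),
               beta = matrix(0, 1, 0))
  d <- data.frame(s = rgamma(20, 4, 2))
  gs <- gamma_shape_scale(2, 1)
  expect_equal(forward_loglik(spec1, par1, d),
               sum(dgamma(d$s, shape = gs$shape, scale = gs$scale,
                          log = TRUE)),
               tolerance = 1e-10)
  spec2 <- hmm_spec(2, streams = list(s = list(family = "gamma")))
  par2 <- list(emission = list(s = list(mean = c(1, 5), sd = c(1, 3))),
               beta = matrix(-1, 1, 2))
  dm <- data.frame(s = rep(NA_real_, 10))
  expect_equal(forward_loglik(spec2, par2, dm), 0, tolerance = 1e-12)
})

test_that("viterbi equals brute-force enumeration and handles ties", {
  set.seed(4)
  spec4 <- hmm_spec(4, streams = list(s = list(family = "gamma")))
  par4 <- list(emission = list(s = list(mean = c(1, 3, 9, 27),
                                        sd = c(1, 2, 5, 10))),
               beta = matrix(rnorm(12, -1.5, 0.4), 1, 12))
  d4 <- data.frame(s = rgamma(7, 2, 0.5))
  fit <- list(spec = spec4, par = par4)
  vit <- viterbi_decode(fit, d4)
  oracle <- brute_force_viterbi(spec4, par4, d4)
  expect_equal(path_logprob(spec4, par4, d4, vit), oracle$logp,
               tolerance = 1e-10)

  # near-degenerate, well-separated emissions: per-bin nearest state
  spec3 <- hmm_spec(3, streams = list(s = list(family = "gamma")))
  par3 <- list(emission = list(s = list(mean = c(1, 10, 100),
                                        sd = c(0.05, 0.5, 5))),
               beta = matrix(0, 1, 6))
  d3 <- data.frame(s = c(1, 100, 10, 1, 100))
  expect_equal(viterbi_decode(list(spec = spec3, par = par3), d3),
               c(1L, 3L, 2L, 1L, 3L))

  # absorbing chain with fixed start: constant path
  parA <- list(emission = list(s = list(mean = c(1, 1), sd = c(1, 1))),
               beta = matrix(-60, 1, 2), delta = c(1, 0))
  specA <- hmm_spec(2, streams = list(s = list(family = "gamma")))
  dA <- data.frame(s = rgamma(10, 2, 1))
  expect_equal(viterbi_decode(list(spec = specA, par = parA), dA),
               rep(1L, 10))
})

test_that("viterbi path beats random paths", {
  set.seed(6)
  spec <- behaviour_spec()
  par <- behaviour_truth_par()
  d <- simulate_hmm(spec, par, n_seq = 1, len = 50, seed = 2)
  vit <- viterbi_decode(list(spec = spec, par = par), d)
  lp_vit <- path_logprob(spec, par, d, vit)
  for (r in seq_len(200)) {
    rp <- sample.int(3, 50, replace = TRUE)
    expect_gte(lp_vit, path_logprob(spec, par, d, rp))
  }
})

test_that("transition rows sum to one at arbitrary covariate values", {
  set.seed(7)
  spec <- hmm_spec(4, streams = list(s = list(family = "gamma")),
                   transition = ~z1 + z2)
  par <- list(emission = list(s = list(mean = 1:4, sd = rep(1, 4))),
              beta = matrix(rnorm(36), 3, 12))
  X <- cbind(1, matrix(rnorm(100), 50, 2))
  A <- reeftrack:::transition_array(spec, par, X)
  sums <- apply(A, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(A > 0))
})

test_that("gamma mean/sd and shape/scale conversions round-trip", {
  set.seed(8)
  mu <- runif(20, 0.01, 100); sg <- runif(20, 0.01, 50)
  gs <- gamma_shape_scale(mu, sg)
  back <- gamma_mean_sd(gs$shape, gs$scale)
  expect_equal(back$mean, mu, tolerance = 1e-12)
  expect_equal(back$sd, sg, tolerance = 1e-12)
})

test_that("one-state fit reduces to a single Gamma estimate", {
  set.seed(9)
  spec <- hmm_spec(1, streams = list(s = list(family = "gamma")))
  d <- data.frame(s = rgamma(2000, shape = 4, scale = 0.5))
  fit <- fit_hmm(spec, d, nstarts = 1)
  # oracle: direct single-Gamma ML on the same data
  nll <- function(w) -sum(dgamma(d$s, shape = exp(w[1]), scale = exp(w[2]),
                                 log = TRUE))
  o <- optim(c(log(4), log(0.5)), nll, method = "BFGS")
  est <- gamma_mean_sd(exp(o$par[1]), exp(o$par[2]))
  expect_equal(fit$par$emission$s$mean, est$mean, tolerance = 1e-3)
  expect_equal(fit$par$emission$s$sd, est$sd, tolerance = 1e-3)
  expect_equal(fit$logL, -o$value, tolerance = 1e-6)
})

test_that("parameters of a 3-state model are recovered from simulation", {
  spec <- behaviour_spec()
  par <- behaviour_truth_par()
  sim <- simulate_hmm(spec, par, n_seq = 5, len = 300, seed = 11)
  fit <- fit_hmm(spec, sim, sequence = "id", par0 = par, nstarts = 1)
  perm <- order(fit$par$emission$step$mean)
  expect_equal(fit$par$emission$step$mean[perm],
               par$emission$step$mean, tolerance = 0.15)
  expect_equal(fit$par$emission$vedba$mean[perm],
               par$emission$vedba$mean, tolerance = 0.15)
  dec <- viterbi_decode(fit, sim, sequence = "id")
  acc <- mean(match(dec, perm) == sim$state)
  expect_gt(acc, 0.9)
  # refit from the truth reaches at least the same optimum as moment starts
  fit2 <- fit_hmm(spec, sim, sequence = "id", nstarts = 2, seed = 2)
  expect_lt(abs(fit$logL - fit2$logL), 1)
})

test_that("AIC ranking follows the formula with stable tie order", {
  f1 <- structure(list(npar = 5, logL = -100, AIC = 2 * 5 - 2 * -100,
                       n_obs = 50), class = "fitted_hmm")
  expect_equal(f1$AIC, 210)
  f2 <- structure(list(npar = 8, logL = -100, AIC = 216, n_obs = 50),
                  class = "fitted_hmm")
  tab <- rank_models(list(a = f1, dup = f1, b = f2))
  expect_equal(tab$model, c("a", "dup", "b"))
  expect_equal(tab$dAIC, c(0, 0, 6))
  f3 <- structure(list(npar = 2, logL = -1, AIC = 6, n_obs = 49),
                  class = "fitted_hmm")
  expect_error(rank_models(list(f1, f3)), "different observation sets")
})

test_that("state permutation preserves the likelihood", {
  set.seed(12)
  spec <- behaviour_spec(transition = ~z)
  par <- behaviour_truth_par()
  par$beta <- matrix(rnorm(12, -2, 0.3), 2, 6)
  d <- simulate_hmm(spec, par, n_seq = 2, len = 40,
                    covariates = data.frame(z = rnorm(80)), seed = 3)
  ll <- forward_loglik(spec, par, d, sequence = "id")
  fit <- structure(list(spec = spec, par = par), class = "fitted_hmm")
  fp <- permute_states(fit, c(3, 1, 2))
  expect_equal(forward_loglik(spec, fp$par, d, sequence = "id"), ll,
               tolerance = 1e-9)
})
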