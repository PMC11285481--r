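test_that("default layout satisfies the deployment geometry", {
  lay <- default_layout()
  expect_equal(nrow(lay$receivers), 16)
  expect_false(anyDuplicated(lay$receivers$id) > 0)
  d <- as.matrix(dist(lay$receivers[, c("x", "y")]))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_true(all(nn >= 200 & nn <= 250))
  expect_equal(sum(lay$structures$kind == "reef"), 4)
  expect_equal(sum(lay$structures$kind == "turbine"), 1)
})

test_that("tracks are deterministic under a fixed seed", {
  lay <- default_layout()
  a <- simulate_tracks(lay, n_fish = 2, duration = 0.2, seed = 9)
  b <- simulate_tracks(lay, n_fish = 2, duration = 0.2, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_tracks(lay, n_fish = 2, duration = 0.2, seed = 10)
  expect_false(identical(a$x, c_$x))
})

test_that("absorbing hiding state pins fish within 2 m of the home reef", {
  lay <- default_layout()
  P <- diag(3)
  dimnames(P) <- list(c("hiding", "local", "transit"),
                      c("hiding", "local", "transit"))
  tr <- simulate_tracks(lay, transition_matrix = P, n_fish = 3,
                        duration = 0.5, seed = 1, start_regime = "hiding")
  homes <- attr(tr, "homes")
  for (tg in unique(tr$tag_id)) {
    home <- lay$structures[lay$structures$id ==
                             homes$home[homes$tag_id == tg], ]
    tt <- tr[tr$tag_id == tg, ]
    expect_true(all(tt$regime == "hiding"))
    expect_true(all(sqrt((tt$x - home$x)^2 + (tt$y - home$y)^2) <= 2 + 1e-9))
  }
})

test_that("regime occupancy matches the chain's stationary distribution", {
  lay <- default_layout()
  P <- default_transition_matrix()
  # oracle: stationary distribution by eigen-decomposition
  e <- eigen(t(P))
  pi_ <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_ <- pi_ / sum(pi_)
  tr <- simulate_tracks(lay, transition_matrix = P, n_fish = 10,
                        duration = 10, seed = 7)
  occ <- table(factor(tr$regime, levels = rownames(P)))
  n <- sum(occ)
  for (k in seq_len(3)) {
    # 99% binomial bounds are optimistic for a correlated chain; allow the
    # effective sample size of ~n/expected dwell to widen them
    ess <- n / 300
    half <- qnorm(0.995) * sqrt(pi_[k] * (1 - pi_[k]) / ess)
    expect_lt(abs(occ[k] / n - pi_[k]), half + 0.02)
  }
  expect_equal(markov_stationary(P), pi_, tolerance = 1e-12)
})

test_that("transit steps exceed local steps by construction", {
  lay <- default_layout()
  tr <- simulate_tracks(lay, n_fish = 4, duration = 2, seed = 3)
  tr <- data.table::as.data.table(tr)
  tr[, step := c(NA, sqrt(diff(x)^2 + diff(y)^2)), by = "tag_id"]
  ms <- tapply(tr$step, tr$regime, mean, na.rm = TRUE)
  expect_gt(ms[["transit"]], ms[["local"]])
  expect_gt(ms[["local"]], ms[["hiding"]])
})

test_that("inter-transmission delays are uniform on [delay_min, delay_max]", {
  lay <- default_layout()
  tr <- simulate_tracks(lay, n_fish = 2, duration = 5, seed = 5)
  det <- simulate_detections(tr, lay, seed = 6)
  tx <- det$transmissions
  gaps <- unlist(tapply(tx$time, tx$tag_id, diff))
  expect_gte(length(gaps), 1e4)
  expect_true(all(gaps >= 50 & gaps <= 100))
  ks <- suppressWarnings(ks.test(gaps, "punif", 50, 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("detection probability is logistic in distance", {
  lay <- array_layout(
    receivers = data.frame(id = "A", x = 0, y = 0, depth = 30),
    structures = data.frame(id = "R01", kind = "reef", x = 300, y = 0,
                            scour = FALSE))
  # fish pinned at d50 via an absorbing hiding regime with detectability 1
  reg <- default_regimes(hiding_detectability = 1)
  P <- diag(3)
  dimnames(P) <- list(reg$name, reg$name)
  tr <- simulate_tracks(lay, reg, P, n_fish = 1, duration = 3, seed = 2,
                        start_regime = "hiding")
  det <- simulate_detections(tr, lay, regimes = reg,
                             detection_model = c(d50 = 300, slope = 60),
                             seed = 3)
  frac <- nrow(det$detections) / nrow(det$transmissions)
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("detection fraction is non-increasing in distance", {
  lay <- array_layout(
    receivers = data.frame(id = "A", x = 0, y = 0, depth = 30),
    structures = data.frame(id = "R01", kind = "reef", x = 0, y = 0,
                            scour = FALSE))
  reg <- default_regimes(hiding_detectability = 1)
  P <- diag(3); dimnames(P) <- list(reg$name, reg$name)
  fracs <- sapply(c(100, 250, 400, 600), function(dd) {
    l2 <- lay
    l2$structures$x <- dd
    tr <- simulate_tracks(l2, reg, P, n_fish = 1, duration = 2, seed = 2,
                          start_regime = "hiding")
    det <- simulate_detections(tr, l2, regimes = reg, seed = 3)
    nrow(det$detections) / nrow(det$transmissions)
  })
  expect_true(all(diff(fracs) < 0))
})

test_that("hiding occlusion lowers per-bin unique receiver counts", {
  lay <- default_layout()
  reg <- default_regimes()          # hiding detectability 0.02
  tr <- simulate_tracks(lay, reg, n_fish = 3, duration = 5, seed = 8)
  det <- simulate_detections(tr, lay, regimes = reg, seed = 9)
  d <- data.table::as.data.table(det$detections)
  d[, bin := floor(time_local / 600)]
  counts <- d[, list(nrec = length(unique(receiver_id))),
              by = c("tag_id", "bin")]
  trd <- data.table::as.data.table(tr)
  trd[, bin := floor(time / 600)]
  regime_bin <- trd[, list(hiding = mean(regime == "hiding") > 0.5),
                    by = c("tag_id", "bin")]
  m <- merge(regime_bin, counts, by = c("tag_id", "bin"), all.x = TRUE)
  m[is.na(nrec), nrec := 0]
  expect_gt(sum(m$hiding), 100)   # enough hiding bins to compare
  expect_lt(mean(m$nrec[m$hiding]), mean(m$nrec[!m$hiding]) / 2)
})

test_that("regime-conditional VeDBA matches the configured Gamma moments", {
  lay <- default_layout()
  reg <- default_regimes()
  tr <- simulate_tracks(lay, reg, n_fish = 5, duration = 5, seed = 4)
  for (k in seq_len(nrow(reg))) {
    v <- tr$vedba[tr$regime == reg$name[k]]
    n <- length(v)
    se_mean <- reg$vedba_sd[k] / sqrt(n)
    expect_lt(abs(mean(v) - reg$vedba_mean[k]), 3 * se_mean)
    # sd standard error approx sd/sqrt(2n) for near-normal; Gamma is skewed,
    # allow 5 of those
    expect_lt(abs(sd(v) - reg$vedba_sd[k]),
              5 * reg$vedba_sd[k] / sqrt(2 * n))
  }
})

test_that("environment series: periodicity, season and determinism", {
  env0 <- simulate_environment(3, seed = 1, current_noise = 0, sst_noise = 0)
  period_bins <- 12.42 * 3600 / 600
  # rectified sinusoid repeats every tidal period (non-integer bin count, so
  # compare via the generating function)
  tt <- env0$time
  expect_equal(env0$current, 0.6 * abs(sin(2 * pi * tt / (12.42 * 3600))),
               tolerance = 1e-12)
  yr <- simulate_environment(365, seed = 2, start_doy = 1)
  imax <- which.max(yr$sst)
  doy_max <- 1 + yr$time[imax] / 86400
  expect_gt(doy_max, 365 / 4)        # summer half of the series
  expect_lt(doy_max, 3 * 365 / 4)
  a <- simulate_environment(2, seed = 3)
  b <- simulate_environment(2, seed = 3)
  expect_identical(a, b)
})

test_that("identical seeds give identical detection output", {
  lay <- default_layout()
  tr <- simulate_tracks(lay, n_fish = 1, duration = 0.5, seed = 1)
  a <- simulate_detections(tr, lay, seed = 11)
  b <- simulate_detections(tr, lay, seed = 11)
  expect_identical(as.data.frame(a$detections), as.data.frame(b$detections))
  expect_identical(as.data.frame(a$sync), as.data.frame(b$sync))
})
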