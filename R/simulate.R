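#' Simulate regime-switching fish tracks around the array
#'
#' Generates ground-truthed tracks at a fixed `dt` time step. Each fish is
#' assigned a home reef (cycled over the reefs in `layout`). The latent
#' movement regime follows a first-order Markov chain with per-step
#' `transition_matrix`; positions follow the regime's movement rule:
#' \describe{
#'   \item{hiding}{pinned inside the reef structure, within 2 m of the home
#'     reef;}
#'   \item{local}{mean-reverting walk around the home reef (pull-back rate
#'     `attraction` per second);}
#'   \item{transit}{directed walk towards a randomly chosen other structure
#'     or an exit point beyond the array edge.}
#' }
#' VeDBA is drawn per step from the regime's Gamma distribution
#' (parametrized by mean and sd).
#'
#' @param layout an [array_layout()].
#' @param regimes data.frame as returned by [default_regimes()]; rows are
#'   matched to `transition_matrix` by `name`.
#' @param transition_matrix row-stochastic K x K matrix with dimnames equal
#'   to the regime names; applied once per `dt`.
#' @param n_fish number of animals.
#' @param duration days of track per animal.
#' @param seed integer seed; identical seeds give identical output.
#' @param dt time step, s (default 60).
#' @param start_regime regime name to start every fish in, or `NULL` to draw
#'   the start from the chain's stationary distribution.
#' @return data.table with columns `tag_id`, `time` (s, strictly increasing
#'   per tag), `x`, `y` (m), `regime`, `vedba` (m s^-2), `depth` (m).
#'   Attribute `"homes"` maps `tag_id` to the home reef id.
#' @export
simulate_tracks <- function(layout, regimes = default_regimes(),
                            transition_matrix = default_transition_matrix(),
                            n_fish = 10, duration = 30, seed = 1,
                            dt = 60, start_regime = NULL) {
  stopifnot(inherits(layout, "array_layout"), n_fish >= 1, duration > 0)
  K <- nrow(transition_matrix)
  if (is.null(rownames(transition_matrix)) ||
      !setequal(rownames(transition_matrix), regimes$name)) {
    stop("transition_matrix dimnames must match regime names")
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-8)) {
    stop("transition_matrix rows must be non-negative and sum to 1")
  }
  transition_matrix <- transition_matrix[regimes$name, regimes$name]
  set.seed(seed)

  reefs <- layout$structures[layout$structures$kind == "reef", , drop = FALSE]
  if (nrow(reefs) == 0) stop("layout has no reefs to serve as home sites")
  exits <- array_exit_points(layout)
  targets <- rbind(layout$structures[, c("x", "y")], exits)

  n_steps <- ceiling(duration * 86400 / dt)
  start_idx <- if (is.null(start_regime)) NULL else match(start_regime, regimes$name)
  if (!is.null(start_regime) && is.na(start_idx)) stop("unknown start_regime")
  statio <- markov_stationary(transition_matrix)

  out <- vector("list", n_fish)
  homes <- character(n_fish)
  for (f in seq_len(n_fish)) {
    home_row <- reefs[((f - 1) %% nrow(reefs)) + 1, ]
    homes[f] <- home_row$id
    home <- c(home_row$x, home_row$y)

    s <- integer(n_steps)
    s[1] <- if (is.null(start_idx)) sample.int(K, 1, prob = statio) else start_idx
    u <- stats::runif(n_steps)
    cums <- apply(transition_matrix, 1, cumsum)   # K x K, column = from-state
    for (t in 2:n_steps) {
      s[t] <- findInterval(u[t], cums[, s[t - 1]], left.open = TRUE) + 1L
    }

    x <- y <- numeric(n_steps)
    pos <- home
    target <- NULL
    for (t in seq_len(n_steps)) {
      rg <- regimes[s[t], ]
      if (rg$name == "hiding") {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- 2 * sqrt(stats::runif(1))
        pos <- home + rad * c(cos(ang), sin(ang))
        target <- NULL
      } else if (rg$name == "transit") {
        if (is.null(target)) {
          repeat {
            j <- sample.int(nrow(targets), 1)
            target <- as.numeric(targets[j, ])
            if (sum((target - pos)^2) > 50^2) break
          }
        }
        dir <- target - pos
        nd <- sqrt(sum(dir^2))
        if (nd < 30) target <- NULL else {
          pos <- pos + rg$step_scale * dir / nd +
            stats::rnorm(2, 0, rg$step_scale / 4)
        }
      } else {
        pos <- pos + rg$attraction * dt * (home - pos) +
          stats::rnorm(2, 0, rg$step_scale / sqrt(2))
        target <- NULL
      }
      x[t] <- pos[1]; y[t] <- pos[2]
    }
    shp <- regimes$vedba_mean[s]^2 / regimes$vedba_sd[s]^2
    scl <- regimes$vedba_sd[s]^2 / regimes$vedba_mean[s]
    vedba <- stats::rgamma(n_steps, shape = shp, scale = scl)
    depth <- pmax(1, 28 + stats::rnorm(n_steps, 0, 0.5))
    out[[f]] <- data.table::data.table(
      tag_id = sprintf("F%02d", f),
      time = (seq_len(n_steps) - 1) * dt,
      x = x, y = y, regime = regimes$name[s], vedba = vedba, depth = depth
    )
  }
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "homes",
                      data.frame(tag_id = sprintf("F%02d", seq_len(n_fish)),
                                 home = homes, stringsAsFactors = FALSE))
  res[]
}

# Exit points 300 m beyond the four array corners.
array_exit_points <- function(layout) {
  r <- layout$receivers
  m <- 300
  data.frame(x = c(min(r$x) - m, max(r$x) + m, max(r$x) + m, min(r$x) - m),
             y = c(min(r$y) - m, min(r$y) - m, max(r$y) + m, max(r$y) + m))
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to
#' sum to 1.
#'
#' @param P row-stochastic K x K matrix.
#' @return numeric vector of length K.
#' @export
markov_stationary <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Identity and randomized receiver clock models
#'
#' Linear clock model per receiver: `local = true * (1 + drift) + offset`.
#' `identity_clocks()` gives perfectly synchronized clocks;
#' `random_clocks()` draws offsets and drift rates (drift ~ N(0, 1e-5) by
#' default).
#'
#' @param layout an [array_layout()].
#' @param seed integer seed.
#' @param offset_sd sd of the initial clock offsets, s.
#' @param drift_sd sd of the drift rates, s/s.
#' @return data.frame with columns `receiver_id`, `offset`, `drift`.
#' @export
identity_clocks <- function(layout) {
  data.frame(receiver_id = layout$receivers$id, offset = 0, drift = 0,
             stringsAsFactors = FALSE)
}

#' @rdname identity_clocks
#' @export
random_clocks <- function(layout, seed = 1, offset_sd = 0.1, drift_sd = 1e-5) {
  set.seed(seed)
  n <- nrow(layout$receivers)
  data.frame(receiver_id = layout$receivers$id,
             offset = stats::rnorm(n, 0, offset_sd),
             drift = stats::rnorm(n, 0, drift_sd),
             stringsAsFactors = FALSE)
}

#' Simulate acoustic detections (animal transmissions and sync pings)
#'
#' Each tag transmits with a uniform random delay in
#' `[delay_min, delay_max]` s, alternating pressure and acceleration
#' payloads. A transmission at distance `d` from a receiver is detected
#' independently with probability
#' `plogis((d50 - d) / slope) * detectability(regime)`, optionally damped by
#' a logistic network-load factor in the number of active tags. Arrival time
#' at a receiver is emission time + `d / sound_speed` + Gaussian timing noise,
#' then mapped through the receiver's linear clock model. Every receiver also
#' emits sync pings on a fixed staggered schedule, heard by its neighbours
#' (and itself), which makes clock correction testable.
#'
#' @param truth track table from [simulate_tracks()].
#' @param layout an [array_layout()].
#' @param tag a [tag_config()].
#' @param regimes regime table (for detectability multipliers); default
#'   matches [default_regimes()].
#' @param detection_model named vector `c(d50 = , slope = )`, metres: `d50` is
#'   the 50% detection distance.
#' @param clock_models data.frame `receiver_id, offset, drift`; default
#'   identity clocks.
#' @param timing_sd arrival-time noise sd, s.
#' @param sound_speed m/s.
#' @param seed integer seed.
#' @param sync_interval sync ping period per receiver, s.
#' @param load optional network-load damping, named vector
#'   `c(midpoint = 15, slope = 3)` in units of active tags; `NULL` (default)
#'   disables it.
#' @return list with data.tables `detections` (columns `receiver_id`,
#'   `tag_id`, `time_local`, `sensor`, `value`), `sync` (same columns plus
#'   `emitter`), and `transmissions` (ground truth per emission: `tag_id`,
#'   `time`, `x`, `y`, `regime`, `sensor`, `value`).
#' @export
simulate_detections <- function(truth, layout, tag = tag_config(),
                                regimes = default_regimes(),
                                detection_model = c(d50 = 300, slope = 60),
                                clock_models = NULL, timing_sd = 1e-4,
                                sound_speed = 1500, seed = 1,
                                sync_interval = 600, load = NULL) {
  stopifnot(inherits(layout, "array_layout"),
            detection_model[["d50"]] > 0, sound_speed > 0)
  if (is.null(clock_models)) clock_models <- identity_clocks(layout)
  set.seed(seed)
  truth <- data.table::as.data.table(truth)
  rec <- layout$receivers
  d50 <- detection_model[["d50"]]; slope <- detection_model[["slope"]]

  load_factor <- 1
  if (!is.null(load)) {
    n_tags <- length(unique(truth$tag_id))
    load_factor <- 1 / (1 + exp((n_tags - load[["midpoint"]]) / load[["slope"]]))
  }

  # --- transmission schedule per tag ------------------------------------
  tx_list <- list()
  for (tg in unique(truth$tag_id)) {
    tr <- truth[truth$tag_id == tg]
    t0 <- tr$time[1]; t1 <- tr$time[nrow(tr)]
    n_max <- ceiling((t1 - t0) / tag$delay_min) + 2
    delays <- stats::runif(n_max, tag$delay_min, tag$delay_max)
    times <- t0 + cumsum(delays)
    times <- times[times <= t1]
    if (!length(times)) next
    ix <- findInterval(times, tr$time)
    # linear interpolation of position within the step
    ix2 <- pmin(ix + 1L, nrow(tr))
    w <- (times - tr$time[ix]) / pmax(tr$time[ix2] - tr$time[ix], 1)
    sens <- rep_len(c("pressure", "acceleration"), length(times))
    tx_list[[tg]] <- data.table::data.table(
      tag_id = tg, time = times,
      x = tr$x[ix] * (1 - w) + tr$x[ix2] * w,
      y = tr$y[ix] * (1 - w) + tr$y[ix2] * w,
      regime = tr$regime[ix], sensor = sens,
      value = ifelse(sens == "pressure", tr$depth[ix], tr$vedba[ix])
    )
  }
  tx <- data.table::rbindlist(tx_list)
  det_mult <- regimes$detectability[match(tx$regime, regimes$name)]

  # --- per-receiver detection draws -------------------------------------
  det_list <- vector("list", nrow(rec))
  for (r in seq_len(nrow(rec))) {
    d <- sqrt((tx$x - rec$x[r])^2 + (tx$y - rec$y[r])^2)
    p <- stats::plogis((d50 - d) / slope) * det_mult * load_factor
    hit <- stats::runif(nrow(tx)) < p
    if (!any(hit)) next
    arr <- tx$time[hit] + d[hit] / sound_speed +
      stats::rnorm(sum(hit), 0, timing_sd)
    cm <- clock_models[clock_models$receiver_id == rec$id[r], ]
    det_list[[r]] <- data.table::data.table(
      receiver_id = rec$id[r], tag_id = tx$tag_id[hit],
      time_local = arr * (1 + cm$drift) + cm$offset,
      sensor = tx$sensor[hit], value = tx$value[hit]
    )
  }
  detections <- data.table::rbindlist(det_list)
  if (nrow(detections)) data.table::setorder(detections, time_local)

  # --- sync pings --------------------------------------------------------
  t0 <- min(truth$time); t1 <- max(truth$time)
  sync_list <- list()
  for (e in seq_len(nrow(rec))) {
    etimes <- seq(t0 + (e - 1) * sync_interval / nrow(rec), t1,
                  by = sync_interval)
    for (r in seq_len(nrow(rec))) {
      d <- sqrt((rec$x[e] - rec$x[r])^2 + (rec$y[e] - rec$y[r])^2)
      p <- stats::plogis((d50 - d) / slope)
      hit <- stats::runif(length(etimes)) < p
      if (!any(hit)) next
      arr <- etimes[hit] + d / sound_speed +
        stats::rnorm(sum(hit), 0, timing_sd)
      cm <- clock_models[clock_models$receiver_id == rec$id[r], ]
      sync_list[[length(sync_list) + 1L]] <- data.table::data.table(
        receiver_id = rec$id[r], tag_id = paste0("sync-", rec$id[e]),
        time_local = arr * (1 + cm$drift) + cm$offset,
        sensor = "sync", value = NA_real_, emitter = rec$id[e]
      )
    }
  }
  sync <- data.table::rbindlist(sync_list)
  if (nrow(sync)) data.table::setorder(sync, time_local)
  list(detections = detections, sync = sync, transmissions = tx)
}

#' Simulate the environmental series (tidal current and SST)
#'
#' Current speed is a rectified tidal sinusoid with the principal lunar
#' semidiurnal period (12.42 h) plus truncated Gaussian noise; sea-surface
#' temperature is a seasonal sinusoid peaking in early August (day of year
#' 215) plus noise. The series stands in for a nearby weather station.
#'
#' @param duration days.
#' @param seed integer seed.
#' @param dt sampling interval, s (default 600).
#' @param start_doy day of year at `time = 0`.
#' @param current_amp tidal current amplitude, m/s.
#' @param current_noise,sst_noise noise sd (0 gives the exact sinusoids).
#' @param sst_mean,sst_amp seasonal SST mean and amplitude, degrees C.
#' @return data.table with columns `time` (s), `current` (m/s, >= 0),
#'   `sst` (degrees C).
#' @export
simulate_environment <- function(duration, seed = 1, dt = 600, start_doy = 1,
                                 current_amp = 0.6, current_noise = 0.05,
                                 sst_mean = 12, sst_amp = 5, sst_noise = 0.3) {
  stopifnot(duration > 0)
  set.seed(seed)
  tt <- seq(0, duration * 86400, by = dt)
  tidal_period <- 12.42 * 3600
  current <- pmax(0, current_amp * abs(sin(2 * pi * tt / tidal_period)) +
                    stats::rnorm(length(tt), 0, current_noise))
  doy <- start_doy + tt / 86400
  sst <- sst_mean + sst_amp * cos(2 * pi * (doy - 215) / 365.25) +
    stats::rnorm(length(tt), 0, sst_noise)
  data.table::data.table(time = tt, current = current, sst = sst)
}
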