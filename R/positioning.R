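#' Synchronize receiver clocks from sync-ping detections
#'
#' Each receiver carries a linear clock (`local = true * (1 + drift) +
#' offset`). Sync pings emitted by the receivers themselves are heard across
#' the array; for a pair of receivers hearing the same ping, the difference of
#' local arrival times equals the known travel-time difference plus the
#' relative clock offset and a term linear in time (relative drift). Per
#' receiver, (offset, drift) relative to the `reference` receiver are
#' estimated by least squares over shared pings. Receivers that never share
#' enough pings with the reference are corrected transitively through an
#' already-synchronized neighbour (breadth-first from the reference); a
#' receiver with no sync path at all is flagged unusable.
#'
#' @param sync_detections sync detection table (`receiver_id`, `tag_id`,
#'   `time_local`); sync tag ids must be `"sync-<receiver id>"` so the
#'   emitter position is known.
#' @param layout an [array_layout()].
#' @param reference receiver id whose clock defines synchronized time
#'   (default: first receiver).
#' @param sound_speed m/s.
#' @param min_shared minimum shared pings required to fit a pair (default 10).
#' @return data.frame of class `clock_models`: `receiver_id`, `offset`,
#'   `drift`, `resid_sd` (s), `n_obs`, `ok`, plus attribute `"reference"`.
#' @export
synchronize_clocks <- function(sync_detections, layout, reference = NULL,
                               sound_speed = 1500, min_shared = 10) {
  rec <- layout$receivers
  if (is.null(reference)) reference <- rec$id[1]
  stopifnot(reference %in% rec$id)
  sd_ <- data.table::as.data.table(sync_detections)
  sd_$emitter <- sub("^sync-", "", sd_$tag_id)
  sd_ <- sd_[sd_$emitter %in% rec$id & sd_$receiver_id %in% rec$id]

  # group detections of the same ping: per emitter, arrivals within a short
  # coincidence window (clock offsets are << the sync interval)
  diag_len <- sqrt(diff(range(rec$x))^2 + diff(range(rec$y))^2)
  win <- diag_len / sound_speed + 5
  data.table::setorder(sd_, emitter, time_local)
  sd_[, ping := cumsum(c(1, diff(time_local) > win)), by = "emitter"]
  sd_[, ping_id := paste(emitter, ping, sep = "_")]

  dist_m <- as.matrix(stats::dist(rec[, c("x", "y")]))
  dimnames(dist_m) <- list(rec$id, rec$id)

  fit_pair <- function(r, base) {
    # observations shared between receiver r and an already-solved base
    a <- sd_[sd_$receiver_id == r, c("ping_id", "time_local", "emitter")]
    b <- sd_[sd_$receiver_id == base, c("ping_id", "time_local")]
    m <- merge(a, b, by = "ping_id", suffixes = c("_r", "_b"))
    if (nrow(m) < min_shared) return(NULL)
    dd <- (dist_m[cbind(m$emitter, r)] - dist_m[cbind(m$emitter, base)]) /
      sound_speed
    yv <- m$time_local_r - m$time_local_b - dd
    fit <- stats::lm.fit(cbind(1, m$time_local_b), yv)
    list(offset = fit$coefficients[1], drift = fit$coefficients[2],
         resid_sd = stats::sd(fit$residuals), n = nrow(m))
  }

  res <- data.frame(receiver_id = rec$id, offset = NA_real_,
                    drift = NA_real_, resid_sd = NA_real_, n_obs = 0L,
                    ok = FALSE, stringsAsFactors = FALSE)
  res[res$receiver_id == reference,
      c("offset", "drift", "resid_sd", "n_obs", "ok")] <-
    list(0, 0, 0, 0L, TRUE)

  solved <- reference
  queue <- reference
  while (length(queue)) {
    base <- queue[1]; queue <- queue[-1]
    bi <- which(res$receiver_id == base)
    for (r in setdiff(rec$id, solved)) {
      f <- fit_pair(r, base)
      if (is.null(f)) next
      # compose the pairwise fit with the base receiver's own model
      a_rel <- 1 + f$drift
      offset <- a_rel * res$offset[bi] + f$offset
      drift <- a_rel * (1 + res$drift[bi]) - 1
      ri <- which(res$receiver_id == r)
      res[ri, c("offset", "drift", "resid_sd", "n_obs", "ok")] <-
        list(unname(offset), unname(drift), f$resid_sd, f$n, TRUE)
      solved <- c(solved, r)
      queue <- c(queue, r)
    }
  }
  attr(res, "reference") <- reference
  class(res) <- c("clock_models", "data.frame")
  res
}

#' Map local receiver timestamps to synchronized time
#'
#' @param clocks a `clock_models` table (or any data.frame with
#'   `receiver_id`, `offset`, `drift`).
#' @param receiver_id receiver of each timestamp.
#' @param time_local local timestamps, s.
#' @return synchronized times on the reference clock, s (NA for receivers
#'   without a usable clock model).
#' @export
correct_time <- function(clocks, receiver_id, time_local) {
  i <- match(receiver_id, clocks$receiver_id)
  ok <- !is.na(i) & clocks$ok[i]
  out <- rep(NA_real_, length(time_local))
  out[ok] <- (time_local[ok] - clocks$offset[i[ok]]) /
    (1 + clocks$drift[i[ok]])
  out
}

#' Group synchronized detections into candidate transmissions
#'
#' Detections of one tag are grouped greedily in time order: a detection
#' joins the current group while it lies within the coincidence window of the
#' group's first arrival; otherwise it starts a new group. The default window
#' is 1.5 x (array diagonal / sound speed), the maximum arrival-time spread a
#' single transmission can produce plus margin.
#'
#' @param detections detection table (`receiver_id`, `tag_id`, `time_local`).
#' @param layout an [array_layout()].
#' @param clocks `clock_models` from [synchronize_clocks()].
#' @param sound_speed m/s.
#' @param window coincidence window, s (default from the array diagonal).
#' @return data.table of detections with added `time_sync` and integer
#'   `group` (unique per tag x transmission); detections from unusable
#'   receivers are dropped.
#' @export
group_detections <- function(detections, layout, clocks, sound_speed = 1500,
                             window = NULL) {
  rec <- layout$receivers
  if (is.null(window)) {
    diag_len <- sqrt(diff(range(rec$x))^2 + diff(range(rec$y))^2)
    window <- 1.5 * diag_len / sound_speed
  }
  d <- data.table::as.data.table(detections)
  d[, time_sync := correct_time(clocks, receiver_id, time_local)]
  d <- d[!is.na(time_sync)]
  data.table::setorder(d, tag_id, time_sync)
  d[, group := {
    g <- integer(.N); cur <- 1L; start <- time_sync[1]
    for (k in seq_len(.N)) {
      if (time_sync[k] - start > window) { cur <- cur + 1L; start <- time_sync[k] }
      g[k] <- cur
    }
    g
  }, by = "tag_id"]
  d[, group := as.integer(factor(paste(tag_id, group)))]
  d[]
}

#' Solve one transmission position by TDOA least squares
#'
#' Gauss-Newton minimization of pairwise time-difference-of-arrival
#' residuals (all receivers against the first), with Levenberg damping on
#' steps that increase the residual sum of squares. Initialized at the
#' centroid of the detecting receivers; convergence when the position step is
#' below `tol` metres. At least three receivers are required for a
#' two-dimensional fix.
#'
#' @param group data.frame of detections of one transmission: `receiver_id`,
#'   `time_sync` (one row per receiver; duplicates keep the earliest).
#' @param layout an [array_layout()].
#' @param sound_speed m/s.
#' @param timing_sd assumed arrival-noise sd, s (enters the HPE definition,
#'   which is invariant to it).
#' @param max_iter,tol solver controls.
#' @return list with `ok`; on success `x`, `y`, `time` (estimated emission
#'   time), `hpe`, `n_receivers`, `resid_rms` (m); on failure `reason`
#'   (`"insufficient_receivers"` or `"no_convergence"`).
#' @export
solve_position <- function(group, layout, sound_speed = 1500,
                           timing_sd = 1e-4, max_iter = 50, tol = 1e-6) {
  g <- data.table::as.data.table(group)
  data.table::setorder(g, time_sync)
  g <- g[!duplicated(g$receiver_id)]
  if (nrow(g) < 3) {
    return(list(ok = FALSE, reason = "insufficient_receivers",
                n_receivers = nrow(g)))
  }
  rec <- layout$receivers
  ri <- match(g$receiver_id, rec$id)
  rx <- rec$x[ri]; ry <- rec$y[ri]; tt <- g$time_sync
  c0 <- sound_speed

  resid_fn <- function(p) {
    d <- sqrt((p[1] - rx)^2 + (p[2] - ry)^2)
    (tt[-1] - tt[1]) - (d[-1] - d[1]) / c0
  }
  jac_fn <- function(p) {
    d <- pmax(sqrt((p[1] - rx)^2 + (p[2] - ry)^2), 1e-9)
    ux <- (p[1] - rx) / d; uy <- (p[2] - ry) / d
    cbind(-(ux[-1] - ux[1]) / c0, -(uy[-1] - uy[1]) / c0)
  }

  gauss_newton <- function(p) {
    r <- resid_fn(p); rss <- sum(r^2)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      J <- jac_fn(p)
      A <- crossprod(J)
      ok_step <- FALSE
      for (k in 0:8) {
        damp <- if (k > 0) 10^(k - 5) * max(diag(A)) else 0
        delta <- tryCatch(-solve(A + damp * diag(2), crossprod(J, r)),
                          error = function(e) NULL)
        if (is.null(delta)) next
        p_new <- p + as.numeric(delta)
        r_new <- resid_fn(p_new); rss_new <- sum(r_new^2)
        if (is.finite(rss_new) && rss_new <= rss + 1e-18) {
          ok_step <- TRUE; break
        }
      }
      if (!ok_step) break
      step <- sqrt(sum((p_new - p)^2))
      p <- p_new; r <- r_new; rss <- rss_new
      if (step < tol) { converged <- TRUE; break }
    }
    list(p = p, r = r, rss = rss, converged = converged)
  }

  sol <- gauss_newton(c(mean(rx), mean(ry)))
  # residuals above the noise floor flag a wrong local minimum: retry from
  # each receiver and keep the best fit
  floor_rms <- 3 * timing_sd + 1e-12
  if (sqrt(sol$rss / length(sol$r)) > floor_rms) {
    for (s in seq_along(rx)) {
      alt <- gauss_newton(c(rx[s], ry[s]))
      if (alt$rss < sol$rss) sol <- alt
      if (sqrt(sol$rss / length(sol$r)) <= floor_rms) break
    }
  }
  p <- sol$p; r <- sol$r; rss <- sol$rss
  if (!sol$converged && sqrt(rss) / length(r) > 1e-3) {
    return(list(ok = FALSE, reason = "no_convergence", n_receivers = nrow(g)))
  }
  J <- jac_fn(p)
  d <- sqrt((p[1] - rx)^2 + (p[2] - ry)^2)
  list(ok = TRUE, x = p[1], y = p[2],
       time = mean(tt - d / c0),
       hpe = compute_hpe(J, sound_speed = c0, timing_sd = timing_sd,
                         receivers = cbind(rx, ry)),
       n_receivers = nrow(g),
       resid_rms = c0 * sqrt(mean(r^2)))
}

#' Horizontal position error of a linearized TDOA fix
#'
#' `HPE = sqrt(trace(cov(x, y))) / (sound_speed * timing_sd)` with
#' `cov = timing_sd^2 (J'J)^-1` from the linearized least squares, so the
#' timing noise scale cancels and HPE is a dimensionless, geometry-only
#' quality indicator (a dilution-of-precision measure). It is specific to one
#' network set-up and not comparable across configurations. Degenerate
#' (collinear-receiver) geometry yields `Inf`, which any quantile filter
#' removes first.
#'
#' @param J (n-1) x 2 Jacobian of the TDOA residuals (s/m) at the solution.
#' @param sound_speed m/s.
#' @param timing_sd arrival-noise sd, s (cancels; kept for the definition).
#' @param receivers optional n x 2 matrix of detecting-receiver coordinates;
#'   a collinear set (which leaves a mirror ambiguity) forces the sentinel.
#' @return non-negative scalar, `Inf` for singular geometry.
#' @export
compute_hpe <- function(J, sound_speed = 1500, timing_sd = 1e-4,
                        receivers = NULL) {
  if (!is.null(receivers)) {
    ctr <- scale(as.matrix(receivers), scale = FALSE)
    sv <- svd(ctr, nu = 0, nv = 0)$d
    if (length(sv) < 2 || sv[2] < 1e-9 * max(sv[1], 1)) return(Inf)
  }
  A <- crossprod(J)
  if (!all(is.finite(A)) || abs(det(A)) < 1e-30 ||
      rcond(A) < .Machine$double.eps) {
    return(Inf)
  }
  covm <- timing_sd^2 * solve(A)
  sqrt(sum(diag(covm))) / (sound_speed * timing_sd)
}

#' Solve all grouped detections into positions
#'
#' @param grouped output of [group_detections()].
#' @param layout an [array_layout()].
#' @inheritParams solve_position
#' @return data.table of positions: `tag_id`, `time`, `x`, `y`, `hpe`,
#'   `n_receivers`, `resid_rms`, plus the per-group mean of any sensor
#'   payloads (`depth`, `vedba`) when present.
#' @export
solve_positions <- function(grouped, layout, sound_speed = 1500,
                            timing_sd = 1e-4) {
  g <- data.table::as.data.table(grouped)
  has_sensor <- all(c("sensor", "value") %in% names(g))
  out <- g[, {
    fx <- solve_position(.SD, layout, sound_speed, timing_sd)
    if (isTRUE(fx$ok)) {
      row <- list(time = fx$time, x = fx$x, y = fx$y, hpe = fx$hpe,
                  n_receivers = fx$n_receivers, resid_rms = fx$resid_rms)
      if (has_sensor) {
        row$depth <- mean(value[sensor == "pressure"])
        row$vedba <- mean(value[sensor == "acceleration"])
      }
      row
    } else NULL
  }, by = c("tag_id", "group")]
  out[, group := NULL]
  data.table::setorder(out, tag_id, time)
  out[]
}

#' Filter positions by the upper HPE quantile
#'
#' Removes positions whose HPE is strictly greater than the empirical
#' `(1 - quantile)` percentile under the nearest-rank convention (the sorted
#' value at index `ceiling((1 - quantile) * N)`), i.e. the highest-HPE tail
#' is filtered out (default the highest 2%). With all-tied HPE values the
#' strict inequality retains everything; the operation is idempotent.
#'
#' @param positions position table with an `hpe` column.
#' @param quantile fraction to remove from the top (default 0.02).
#' @param by_tag logical; apply the filter per tag instead of globally
#'   (default global).
#' @return the retained positions (same class as the input).
#' @export
filter_hpe <- function(positions, quantile = 0.02, by_tag = FALSE) {
  stopifnot(quantile >= 0, quantile < 1, nrow(positions) >= 1)
  thr_keep <- function(h) {
    s <- sort(h)
    thr <- s[ceiling((1 - quantile) * length(s))]
    h <= thr
  }
  if (by_tag) {
    d <- data.table::as.data.table(positions)
    d[, .keep := thr_keep(hpe), by = "tag_id"]
    out <- d[.keep == TRUE]
    out[, .keep := NULL]
    return(out[])
  }
  positions[thr_keep(positions$hpe), ]
}

#' Screen tracks for tag loss or death
#'
#' A tag whose positions stay within `radius` metres of their window
#' centroid AND whose mean VeDBA stays below `vedba_floor` for at least
#' `window` consecutive days is considered lost or dead from the start of
#' that window; both the spatial and the activity condition are required, so
#' a stationary but active animal (e.g. hiding) is never screened out.
#'
#' @param positions position table (`tag_id`, `time` s, `x`, `y`).
#' @param vedba table (`tag_id`, `time`, `vedba`) of activity readings.
#' @param window days (default 7).
#' @param radius m (default 5).
#' @param vedba_floor m s^-2 (default 0.02).
#' @return data.frame `tag_id`, `truncate_at` (s; NA when no screening
#'   applies).
#' @export
screen_tag_loss <- function(positions, vedba, window = 7, radius = 5,
                            vedba_floor = 0.02) {
  p <- data.table::as.data.table(positions)
  v <- data.table::as.data.table(vedba)
  tags <- unique(p$tag_id)
  out <- data.frame(tag_id = tags, truncate_at = NA_real_,
                    stringsAsFactors = FALSE)
  for (tg in tags) {
    pt <- p[p$tag_id == tg]
    vt <- v[v$tag_id == tg]
    if (nrow(pt) == 0) next
    days <- sort(unique(floor(pt$time / 86400)))
    for (d0 in days) {
      t0 <- d0 * 86400; t1 <- t0 + window * 86400
      pw <- pt[pt$time >= t0 & pt$time < t1]
      if (nrow(pw) < 2 || max(pw$time) - min(pw$time) < (window - 1) * 86400)
        next
      cx <- mean(pw$x); cy <- mean(pw$y)
      if (max(sqrt((pw$x - cx)^2 + (pw$y - cy)^2)) > radius) next
      vw <- vt[vt$time >= t0 & vt$time < t1]
      if (nrow(vw) == 0 || mean(vw$vedba) >= vedba_floor) next
      out$truncate_at[out$tag_id == tg] <- t0
      break
    }
  }
  out
}

#' Full positioning pipeline: sync, group, solve, filter
#'
#' @param detections animal detection table from the simulator or a field
#'   export.
#' @param sync_detections sync-ping detections.
#' @param layout an [array_layout()].
#' @param reference reference receiver id.
#' @param sound_speed m/s.
#' @param timing_sd assumed arrival-noise sd, s.
#' @param hpe_quantile top HPE fraction to drop (default 0.02).
#' @return list with `positions` (filtered), `positions_raw`, `clocks`.
#' @export
estimate_positions <- function(detections, sync_detections, layout,
                               reference = NULL, sound_speed = 1500,
                               timing_sd = 1e-4, hpe_quantile = 0.02) {
  clocks <- synchronize_clocks(sync_detections, layout, reference,
                               sound_speed)
  grouped <- group_detections(detections, layout, clocks, sound_speed)
  raw <- solve_positions(grouped, layout, sound_speed, timing_sd)
  list(positions = filter_hpe(raw, hpe_quantile), positions_raw = raw,
       clocks = clocks)
}
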