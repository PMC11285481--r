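#' Build 10-min behavioural bins (step length, VeDBA, covariates)
#'
#' Positions are grouped per animal into 10-min intervals; each bin carries
#' the mean of its positions, the step length to the previous bin (Euclidean
#' distance between consecutive bin mean positions, missing when either bin
#' has no position), and the mean of in-bin acceleration payloads (VeDBA,
#' missing when the bin only saw pressure payloads). Covariates joined at
#' the bin midpoint: current speed and SST (linearly interpolated from the
#' environmental series; a series not covering the bin range is a hard
#' error), day of year and hour of day (also as sine/cosine pairs for use on
#' transition logits), individual tag extent (0 at release, 1 at departure =
#' last detection) and distance to the closest reef (interpolated where the
#' bin has no position).
#'
#' @param positions HPE-filtered positions (`tag_id`, `time`, `x`, `y`,
#'   optionally `vedba` from acceleration payloads).
#' @param env environmental series (`time`, `current`, `sst`).
#' @param layout an [array_layout()].
#' @param epoch POSIXct of study time 0 (UTC).
#' @param bin bin length, s (default 600).
#' @return data.table: `tag_id`, `bin_start`, `x`, `y`, `step`, `vedba`,
#'   `current`, `sst`, `doy`, `hour`, `doy_sin`, `doy_cos`, `hour_sin`,
#'   `hour_cos`, `extent`, `reef_dist`.
#' @export
build_behaviour_bins <- function(positions, env, layout, epoch, bin = 600) {
  p <- data.table::as.data.table(positions)
  if (!"vedba" %in% names(p)) p$vedba <- NA_real_
  e <- data.table::as.data.table(env)

  out <- list()
  for (tg in unique(p$tag_id)) {
    pt <- p[p$tag_id == tg]
    t0 <- floor(min(pt$time) / bin) * bin
    t1 <- floor(max(pt$time) / bin) * bin
    starts <- seq(t0, t1, by = bin)
    ib <- findInterval(pt$time, starts)
    bd <- data.table::data.table(tag_id = tg, bin_start = starts)
    agg <- pt[, list(mx = mean(x), my = mean(y),
                     mv = mean(vedba, na.rm = TRUE)),
              by = list(ib = ib)]
    bd$x <- bd$y <- bd$vedba <- NA_real_
    bd$x[agg$ib] <- agg$mx
    bd$y[agg$ib] <- agg$my
    bd$vedba[agg$ib] <- ifelse(is.nan(agg$mv), NA_real_, agg$mv)
    # step to the previous bin; missing when either bin is empty
    bd$step <- c(NA_real_, sqrt(diff(bd$x)^2 + diff(bd$y)^2))
    # tag extent: linear in elapsed time between release and departure
    bd$extent <- if (length(starts) > 1) {
      (starts - t0) / (t1 - t0)
    } else 0
    cs_x <- bd$x; cs_y <- bd$y
    obs <- which(!is.na(cs_x))
    if (length(obs) >= 2) {
      cs_x <- stats::approx(starts[obs], cs_x[obs], xout = starts,
                            rule = 2)$y
      cs_y <- stats::approx(starts[obs], cs_y[obs], xout = starts,
                            rule = 2)$y
    } else {
      cs_x[] <- cs_x[obs[1]]; cs_y[] <- cs_y[obs[1]]
    }
    bd$reef_dist <- closest_structure(cs_x, cs_y, layout$structures,
                                      kind = "reef")$dist
    out[[tg]] <- bd
  }
  b <- data.table::rbindlist(out)

  mid <- b$bin_start + bin / 2
  if (min(mid) < min(e$time) || max(mid) > max(e$time)) {
    stop(sprintf(paste0("environmental series [%.0f, %.0f] s does not ",
                        "cover the bin range [%.0f, %.0f] s"),
                 min(e$time), max(e$time), min(mid), max(mid)))
  }
  b$current <- stats::approx(e$time, e$current, xout = mid)$y
  b$sst <- stats::approx(e$time, e$sst, xout = mid)$y
  abs_t <- as.numeric(epoch) + mid
  pt_ <- as.POSIXct(abs_t, origin = "1970-01-01", tz = "UTC")
  b$doy <- as.integer(format(pt_, "%j"))
  b$hour <- (abs_t %% 86400) / 3600
  b$doy_sin <- sin(2 * pi * b$doy / 365.25)
  b$doy_cos <- cos(2 * pi * b$doy / 365.25)
  b$hour_sin <- sin(2 * pi * b$hour / 24)
  b$hour_cos <- cos(2 * pi * b$hour / 24)
  b[]
}

# covariate name -> design terms (periodic covariates as sin/cos pairs)
behaviour_cov_terms <- function(covs) {
  unlist(lapply(covs, function(v) switch(v,
    doy = c("doy_sin", "doy_cos"),
    hour = c("hour_sin", "hour_cos"),
    v)))
}

#' Fit the 3-state behavioural HMM with AIC covariate selection
#'
#' A 3-state HMM on `step` (zero-inflated Gamma, so identical consecutive
#' positions are legal) and `vedba` (Gamma), with animal id always on the
#' transition logits and candidate environmental/individual covariates
#' selected by AIC. The default search is forward selection from the
#' id-only base over `pool`, with the full covariate set always fitted too.
#' States are relabelled post-fit to the conventional order: BS3 has the
#' largest step mean (transit); of the two local states, BS1 has the lower
#' VeDBA mean (locally inactive) and BS2 the higher (locally active).
#'
#' @param bins output of [build_behaviour_bins()].
#' @param pool candidate covariates (default `current`, `sst`, `doy`,
#'   `hour`, `extent`, `reef_dist`).
#' @param search `"forward"` (default), `"full_only"` or `"none"`
#'   (id-only model).
#' @param nstarts optimizer restarts for the base fit (later fits start
#'   from the base solution).
#' @param seed integer seed.
#' @param strict_labels error (rather than warn and fall back to step-mean
#'   ordering) when the fitted step means cannot be separated into two local
#'   states and a transit state.
#' @param control optimizer control.
#' @return list: `fit` (best model, relabelled), `aic_table`, `bins`
#'   (with `state` in `BS1..BS3`), `models` (all fitted models), `perm`.
#' @export
fit_behaviour_hmm <- function(bins,
                              pool = c("current", "sst", "doy", "hour",
                                       "extent", "reef_dist"),
                              search = c("forward", "full_only", "none"),
                              nstarts = 3, seed = 1, strict_labels = FALSE,
                              control = list(maxit = 2000, reltol = 1e-8)) {
  search <- match.arg(search)
  bins <- data.table::as.data.table(bins)
  bins$id <- factor(bins$tag_id)
  multi_animal <- nlevels(bins$id) >= 2
  base_rhs <- if (multi_animal) "id" else "1"

  make_spec <- function(covs) {
    rhs <- c(base_rhs, behaviour_cov_terms(covs))
    hmm_spec(3,
             streams = list(step = list(family = "gamma",
                                        zero_inflated = TRUE),
                            vedba = list(family = "gamma")),
             transition = stats::as.formula(paste("~",
                                                  paste(rhs, collapse = "+"))))
  }

  fits <- list()
  base <- fit_hmm(make_spec(character(0)), bins, sequence = "tag_id",
                  nstarts = nstarts, seed = seed, control = control)
  fits[["id"]] <- base

  refit <- function(covs, name) {
    spec <- make_spec(covs)
    X <- build_design(spec, bins)
    par0 <- base$par
    beta0 <- matrix(0, ncol(X), ncol(par0$beta))
    rownames(beta0) <- colnames(X)
    common <- intersect(colnames(X), base$design)
    beta0[common, ] <- par0$beta[match(common, base$design), ]
    par0$beta <- beta0
    fits[[name]] <<- fit_hmm(spec, bins, sequence = "tag_id", par0 = par0,
                             nstarts = 1, seed = seed, control = control)
  }

  if (search == "forward" && length(pool)) {
    chosen <- character(0)
    cur_aic <- base$AIC
    repeat {
      remaining <- setdiff(pool, chosen)
      if (!length(remaining)) break
      cand_names <- vapply(remaining, function(v)
        paste(c("id", chosen, v), collapse = "+"), "")
      for (i in seq_along(remaining)) {
        refit(c(chosen, remaining[i]), cand_names[i])
      }
      aics <- vapply(cand_names, function(n) fits[[n]]$AIC, numeric(1))
      if (min(aics) < cur_aic - 1e-9) {
        chosen <- c(chosen, remaining[which.min(aics)])
        cur_aic <- min(aics)
      } else break
    }
  }
  if (search %in% c("forward", "full_only") && length(pool)) {
    full_name <- paste(c("id", pool), collapse = "+")
    if (is.null(fits[[full_name]])) refit(pool, full_name)
  }

  tab <- rank_models(fits)
  best <- fits[[tab$model[1]]]

  sm <- best$par$emission$step$mean
  vm <- best$par$emission$vedba$mean
  o <- order(sm)
  local_pair <- o[1:2]
  if (sm[o[3]] <= 1.05 * sm[o[2]]) {
    msg <- paste0("state relabelling ambiguous: step means ",
                  paste(signif(sm, 3), collapse = ", "))
    if (strict_labels) stop(msg)
    warning(msg, "; falling back to step-mean ordering")
    perm <- o
  } else {
    perm <- c(local_pair[order(vm[local_pair])], o[3])
  }
  best <- permute_states(best, perm)
  states <- viterbi_decode(best, bins, sequence = "tag_id")
  bins$state <- paste0("BS", states)
  list(fit = best, aic_table = tab, bins = bins[], models = fits,
       perm = perm)
}

#' Per-state spatial density maps of decoded behavioural states
#'
#' One normalized two-dimensional kernel density per decoded state over the
#' bin mean positions. States with fewer than `min_bins` positioned bins are
#' omitted with a warning.
#'
#' @param decoded_bins `bins` element from [fit_behaviour_hmm()] (needs
#'   `x`, `y`, `state`).
#' @param h kernel sd, m (default 15).
#' @param grid_step grid resolution, m (default 5).
#' @param min_bins minimum positioned bins per state (default 10).
#' @return named list of `ud_grid` objects, one per retained state.
#' @export
map_states <- function(decoded_bins, h = 15, grid_step = 5, min_bins = 10) {
  b <- data.table::as.data.table(decoded_bins)
  b <- b[!is.na(x) & !is.na(y)]
  out <- list()
  for (st in sort(unique(b$state))) {
    bs <- b[b$state == st]
    if (nrow(bs) < min_bins) {
      warning("state ", st, " has fewer than ", min_bins,
              " positioned bins; density omitted")
      next
    }
    out[[st]] <- fit_ud(bs$x, bs$y, h = h, grid_step = grid_step)
  }
  out
}
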