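#' Build 10-min hiding data streams from detections and positions
#'
#' For each animal and 10-min interval between its first and last detection,
#' derives the three streams the hiding model uses:
#' \describe{
#'   \item{dist}{mean over in-bin positions of the distance to the closest
#'     reef; for bins without a position the value is linearly interpolated
#'     in time between the nearest non-missing bins (nearest-value extension
#'     at the ends) and flagged `interpolated`;}
#'   \item{nrec}{number of unique receiver ids detecting the animal in the
#'     bin (0 allowed);}
#'   \item{pos}{binary, 1 when at least one successfully solved position
#'     falls in the bin.}
#' }
#' Bins with zero detections are retained (they carry interpolated distance,
#' `nrec = 0`, `pos = 0`): the "not at reef, no positioning" state needs
#' them. Animals without a single position are excluded with a warning.
#'
#' @param detections detection table (`tag_id`, `receiver_id`, `time_local`
#'   or `time_sync`).
#' @param positions HPE-filtered position table (`tag_id`, `time`, `x`, `y`).
#' @param layout an [array_layout()] (reef coordinates).
#' @param bin bin length, s (default 600).
#' @return data.table: `tag_id`, `bin_start`, `dist`, `interpolated`,
#'   `nrec`, `pos`.
#' @export
build_hiding_bins <- function(detections, positions, layout, bin = 600) {
  d <- data.table::as.data.table(detections)
  tcol <- if ("time_sync" %in% names(d)) "time_sync" else "time_local"
  p <- data.table::as.data.table(positions)
  cs <- closest_structure(p$x, p$y, layout$structures, kind = "reef")
  p[, reef_dist := cs$dist]

  out <- list()
  for (tg in unique(d$tag_id)) {
    dt_ <- d[d$tag_id == tg]
    pt <- p[p$tag_id == tg]
    if (nrow(pt) == 0) {
      warning("animal ", tg, " has no positions; excluded from hiding bins")
      next
    }
    t0 <- floor(min(dt_[[tcol]]) / bin) * bin
    t1 <- floor(max(dt_[[tcol]]) / bin) * bin
    starts <- seq(t0, t1, by = bin)
    bd <- data.table::data.table(tag_id = tg, bin_start = starts)
    ib_d <- findInterval(dt_[[tcol]], starts)
    bd$nrec <- 0L
    cnt <- dt_[, list(n = length(unique(receiver_id))),
               by = list(ib = ib_d)]
    bd$nrec[cnt$ib] <- cnt$n
    ib_p <- findInterval(pt$time, starts)
    keep <- ib_p >= 1 & ib_p <= length(starts)
    md <- tapply(pt$reef_dist[keep], ib_p[keep], mean)
    bd$dist <- NA_real_
    bd$dist[as.integer(names(md))] <- as.numeric(md)
    bd$pos <- as.numeric(!is.na(bd$dist))
    bd$interpolated <- is.na(bd$dist)
    if (anyNA(bd$dist)) {
      obs <- which(!is.na(bd$dist))
      bd$dist <- stats::approx(starts[obs], bd$dist[obs], xout = starts,
                               rule = 2)$y
    }
    out[[tg]] <- bd
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("tag_id", "bin_start", "dist",
                                 "interpolated", "nrec", "pos"))
  res[]
}

#' Fit the 4-state hiding HMM and decode the bins
#'
#' Streams: `dist` (Gamma), `nrec` (zero-inflated Gamma) and `pos`
#' (Bernoulli). The four states are: HS1 at reef without positioning
#' (hiding inside the pipes), HS2 at reef with positioning, HS3 away from
#' the reefs with positioning, HS4 away without positioning.
#' Initial values encode those semantics (small vs large distance means,
#' positioning probability near 0 vs near 1); after fitting, states are
#' relabelled to the semantic pattern: the two smallest fitted distance
#' means are "at reef" and within each distance pair the Bernoulli
#' positioning probability separates hidden from visible. The fit fails with
#' a diagnostic error when the fitted distance means are too close to
#' support the at-reef / not-at-reef split.
#'
#' @param bins output of [build_hiding_bins()].
#' @param nstarts optimizer restarts (default 3).
#' @param seed integer seed.
#' @param control optimizer control (see [fit_hmm()]).
#' @return list: `fit` (relabelled `fitted_hmm`), `bins` (input plus
#'   `state` in `HS1..HS4`), `perm` (old index of each new state),
#'   `occupancy` (state proportions).
#' @export
fit_hiding_hmm <- function(bins, nstarts = 3, seed = 1,
                           control = list(maxit = 2000, reltol = 1e-8)) {
  bins <- data.table::as.data.table(bins)
  spec <- hmm_spec(
    4,
    streams = list(dist = list(family = "gamma"),
                   nrec = list(family = "gamma", zero_inflated = TRUE),
                   pos = list(family = "bernoulli"))
  )
  near <- stats::quantile(bins$dist, 0.2)
  far <- stats::quantile(bins$dist, 0.8)
  near <- max(near, 1); far <- max(far, near * 3)
  nr_pos <- bins$nrec[bins$nrec > 0]
  nr_lo <- max(stats::quantile(nr_pos, 0.25), 0.5)
  nr_hi <- max(stats::quantile(nr_pos, 0.75), nr_lo + 1)
  par0 <- list(
    emission = list(
      dist = list(mean = c(near, near, far, far),
                  sd = c(near, near, far, far) / 1.5),
      nrec = list(mean = c(nr_lo, nr_hi, nr_hi, nr_lo),
                  sd = c(nr_lo, nr_hi, nr_hi, nr_lo) / 1.5,
                  zero = c(0.6, 0.05, 0.05, 0.6)),
      pos = list(prob = c(0.05, 0.95, 0.95, 0.05))
    ),
    beta = matrix(log(0.05), 1, 12)
  )
  fit <- fit_hmm(spec, bins, sequence = "tag_id", par0 = par0,
                 nstarts = nstarts, seed = seed, control = control)

  dm <- fit$par$emission$dist$mean
  pp <- fit$par$emission$pos$prob
  o <- order(dm)
  near_pair <- o[1:2]; far_pair <- o[3:4]
  thr <- sqrt(dm[o[2]] * dm[o[3]])  # geometric midpoint of the two groups
  if (!(all(dm[near_pair] < thr) && all(dm[far_pair] > thr))) {
    stop("state relabelling failed: fitted distance means do not separate ",
         "an at-reef from a not-at-reef group (",
         paste(signif(dm, 3), collapse = ", "), ")")
  }
  perm <- c(near_pair[order(pp[near_pair])][1],   # HS1: at reef, no fix
            near_pair[order(pp[near_pair])][2],   # HS2: at reef, fix
            far_pair[order(pp[far_pair], decreasing = TRUE)][1],  # HS3
            far_pair[order(pp[far_pair], decreasing = TRUE)][2])  # HS4
  fit <- permute_states(fit, perm)
  states_old <- viterbi_decode(fit, bins, sequence = "tag_id")
  labels <- paste0("HS", states_old)
  bins$state <- labels
  list(fit = fit, bins = bins[], perm = perm,
       occupancy = prop.table(table(factor(labels,
                                           levels = paste0("HS", 1:4)))))
}

#' Daily hiding proportion with model covariates
#'
#' Per animal and date: the proportion of 10-min bins decoded as HS1, with
#' the covariates of the daily additive model attached — the reef the animal
#' was most associated with that day (modal closest reef of its positions),
#' mean daily current speed, day of year, and the number of distinct animals
#' detected anywhere in the array that day.
#'
#' @param decoded_bins `bins` element from [fit_hiding_hmm()].
#' @param positions position table (`tag_id`, `time`, `x`, `y`).
#' @param env environment table from [simulate_environment()] (or with the
#'   same columns).
#' @param layout an [array_layout()].
#' @param epoch POSIXct of study time 0 (UTC).
#' @return data.table: `id`, `date`, `n_bins`, `n_hs1`, `prop`, `reef`,
#'   `current`, `doy`, `n_ids`.
#' @export
daily_hiding <- function(decoded_bins, positions, env, layout, epoch) {
  b <- data.table::as.data.table(decoded_bins)
  b[, date := as.Date(as.POSIXct(as.numeric(epoch) + bin_start,
                                 origin = "1970-01-01", tz = "UTC"))]
  daily <- b[, list(n_bins = .N, n_hs1 = sum(state == "HS1")),
             by = c("tag_id", "date")]
  daily[, prop := n_hs1 / n_bins]

  nid <- b[, list(n_ids = length(unique(tag_id))), by = "date"]
  daily <- merge(daily, nid, by = "date")

  p <- data.table::as.data.table(positions)
  cs <- closest_structure(p$x, p$y, layout$structures, kind = "reef")
  p[, reef := cs$id]
  p[, date := as.Date(as.POSIXct(as.numeric(epoch) + time,
                                 origin = "1970-01-01", tz = "UTC"))]
  modal <- p[, list(reef = names(which.max(table(reef)))),
             by = c("tag_id", "date")]
  daily <- merge(daily, modal, by = c("tag_id", "date"), all.x = TRUE)
  daily[is.na(reef), reef := "other"]

  e <- data.table::as.data.table(env)
  e[, date := as.Date(as.POSIXct(as.numeric(epoch) + time,
                                 origin = "1970-01-01", tz = "UTC"))]
  ecur <- e[, list(current = mean(current)), by = "date"]
  daily <- merge(daily, ecur, by = "date", all.x = TRUE)
  daily[, doy := as.integer(format(date, "%j"))]
  data.table::setnames(daily, "tag_id", "id")
  data.table::setorder(daily, id, date)
  daily[]
}

#' Penalized additive model of the daily hiding proportion
#'
#' Binomial-family GAM with per-day bin counts as weights. Terms: animal id
#' as a ridge-penalized random intercept, reef as categorical, and penalized
#' spline smooths of current speed (k = 9), day of year (k = 9) and daily
#' number of animals detected (k = 5); smoothing parameters by REML. Terms
#' whose covariate is constant (or a factor with a single level) are dropped
#' with a warning; smooth basis dimensions are capped by the number of
#' distinct covariate values.
#'
#' @param daily output of [daily_hiding()] (columns `prop`, `n_bins`, `id`,
#'   `reef`, `current`, `doy`, `n_ids`).
#' @param k_current,k_doy,k_nids smooth basis dimensions (defaults 9, 9, 5).
#' @return list of class `hiding_gam`: `fit` (a [mgcv::gam()] object),
#'   `terms` (character), `dropped` (character).
#' @export
fit_hiding_gam <- function(daily, k_current = 9, k_doy = 9, k_nids = 5) {
  d <- as.data.frame(daily)
  stopifnot(nrow(d) >= 30)
  d$id <- factor(d$id)
  d$reef <- factor(d$reef)
  terms <- character(0); dropped <- character(0)

  add_smooth <- function(var, k) {
    nu <- length(unique(d[[var]]))
    if (nu < 3) {
      dropped <<- c(dropped, var)
      warning("covariate '", var, "' is (nearly) constant; term dropped")
      return(invisible(NULL))
    }
    terms <<- c(terms, sprintf("s(%s, k = %d)", var, min(k, nu - 1)))
  }
  if (nlevels(d$id) >= 2) {
    terms <- c(terms, "s(id, bs = 're')")
  } else dropped <- c(dropped, "id")
  if (nlevels(d$reef) >= 2) {
    terms <- c(terms, "reef")
  } else dropped <- c(dropped, "reef")
  add_smooth("current", k_current)
  add_smooth("doy", k_doy)
  add_smooth("n_ids", k_nids)
  if (!length(terms)) stop("no usable covariates")
  form <- stats::as.formula(paste("prop ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, family = stats::binomial(), weights = n_bins,
                   data = d, method = "REML")
  structure(list(fit = fit, terms = terms, dropped = dropped, data = d),
            class = "hiding_gam")
}

#' Partial effect of one covariate of the hiding GAM
#'
#' Evaluates the fitted smooth of `term` over a grid spanning the observed
#' covariate range, holding everything else fixed (link-scale term
#' contribution, as mgcv reports it), with standard errors and the
#' response-scale effect around the model intercept.
#'
#' @param object a `hiding_gam`.
#' @param term covariate name (`"current"`, `"doy"` or `"n_ids"`).
#' @param n grid size.
#' @return data.frame: `value`, `effect` (link scale, centred), `se`,
#'   `response` (inverse-link of intercept + effect).
#' @export
partial_effect <- function(object, term, n = 100) {
  stopifnot(inherits(object, "hiding_gam"))
  d <- object$data
  if (!term %in% names(d)) stop("unknown covariate: ", term)
  grid <- data.frame(value = seq(min(d[[term]]), max(d[[term]]),
                                 length.out = n))
  nd <- d[rep(1, n), , drop = FALSE]
  nd[[term]] <- grid$value
  for (v in c("current", "doy", "n_ids")) {
    if (v != term && v %in% names(nd)) nd[[v]] <- stats::median(d[[v]])
  }
  pr <- mgcv::predict.gam(object$fit, newdata = nd, type = "terms",
                          se.fit = TRUE)
  col <- grep(paste0("\\(", term), colnames(pr$fit))
  if (!length(col)) col <- which(colnames(pr$fit) == term)
  eff <- rowSums(pr$fit[, col, drop = FALSE])
  se <- sqrt(rowSums(pr$se.fit[, col, drop = FALSE]^2))
  icpt <- stats::coef(object$fit)[["(Intercept)"]]
  data.frame(value = grid$value, effect = eff, se = se,
             response = stats::plogis(icpt + eff))
}
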