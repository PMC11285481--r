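#' Fixed-bandwidth Gaussian kernel utilization distribution
#'
#' Bivariate product-Gaussian kernel density with a fixed smoothing factor
#' `h` (the kernel standard deviation, metres) on a regular grid padded at
#' least `4 h` beyond the data extent, then renormalized so the discrete
#' density integrates to one. A fixed `h` standardizes the estimate across
#' animals and days; `h = 6` m is the package default.
#'
#' @param x,y position coordinates, m (>= 6 points required).
#' @param h kernel sd, m.
#' @param grid_step grid resolution, m.
#' @param pad grid padding beyond the data range, m (default `4 * h`).
#' @return object of class `ud_grid`: `gx`, `gy` (cell-centre coordinates),
#'   `z` (density matrix, rows = gx), `cell_area`, `h`, `n`.
#' @export
fit_ud <- function(x, y, h = 6, grid_step = 1, pad = 4 * h) {
  stopifnot(length(x) == length(y), h > 0, grid_step > 0)
  if (length(x) < 6) stop("at least 6 positions are required to fit a UD")
  gx <- seq(floor((min(x) - pad) / grid_step) * grid_step,
            ceiling((max(x) + pad) / grid_step) * grid_step, by = grid_step)
  gy <- seq(floor((min(y) - pad) / grid_step) * grid_step,
            ceiling((max(y) + pad) / grid_step) * grid_step, by = grid_step)
  dx <- outer(gx, x, function(a, b) stats::dnorm(a - b, sd = h))
  dy <- outer(gy, y, function(a, b) stats::dnorm(a - b, sd = h))
  z <- (dx %*% t(dy)) / length(x)
  cell_area <- grid_step^2
  z <- z / (sum(z) * cell_area)
  structure(list(gx = gx, gy = gy, z = z, cell_area = cell_area, h = h,
                 n = length(x)),
            class = "ud_grid")
}

#' Extract the UD95 isopleth (smallest region holding 95% of the UD)
#'
#' Cells are ranked by density; the threshold is the density of the last cell
#' needed to accumulate at least `level` of the total mass, and the home
#' range is the super-level set at that threshold. Its mass therefore lies in
#' `[level, level + one cell's mass)`. Disjoint components are labelled by
#' 4-neighbour connectivity; the centroid (and any structure association)
#' uses the largest-mass component, while containment tests use all
#' components. Polygon outlines are traced by contouring at the threshold.
#'
#' @param ud a `ud_grid` from [fit_ud()].
#' @param level mass level (default 0.95).
#' @return object of class `ud_iso`: `threshold`, `mass`, `cells` (logical
#'   matrix), `comp` (integer component labels, 0 outside), `largest_comp`,
#'   `area` (m^2, all components), `centroid` (largest component),
#'   `polygons` (list of data.frames `x`,`y`), plus grid metadata.
#' @export
extract_ud95 <- function(ud, level = 0.95) {
  stopifnot(inherits(ud, "ud_grid"), level > 0, level < 1)
  mass <- ud$z * ud$cell_area
  ord <- order(ud$z, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level)[1]
  threshold <- ud$z[ord[k]]
  cells <- ud$z >= threshold
  comp <- label_components(cells)
  comp_mass <- tapply(mass[cells], comp[cells], sum)
  largest <- as.integer(names(comp_mass)[which.max(comp_mass)])
  sel <- comp == largest
  w <- mass[sel] / sum(mass[sel])
  idx <- which(sel, arr.ind = TRUE)
  centroid <- c(x = sum(ud$gx[idx[, 1]] * w), y = sum(ud$gy[idx[, 2]] * w))
  polys <- grDevices::contourLines(ud$gx, ud$gy, ud$z, levels = threshold)
  polys <- lapply(polys, function(p) data.frame(x = p$x, y = p$y))
  structure(list(threshold = threshold, mass = sum(mass[cells]),
                 cells = cells, comp = comp, largest_comp = largest,
                 n_components = length(comp_mass),
                 area = sum(cells) * ud$cell_area,
                 centroid = centroid, polygons = polys,
                 gx = ud$gx, gy = ud$gy, cell_area = ud$cell_area),
            class = "ud_iso")
}

# 4-connectivity component labelling on a logical matrix (flood fill)
label_components <- function(cells) {
  nr <- nrow(cells); nc <- ncol(cells)
  comp <- matrix(0L, nr, nc)
  lab <- 0L
  todo <- which(cells & comp == 0L)
  while (length(todo)) {
    lab <- lab + 1L
    queue <- todo[1]
    comp[queue] <- lab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      i <- (cur - 1L) %% nr + 1L
      j <- (cur - 1L) %/% nr + 1L
      for (d in 1:4) {
        ii <- i + c(-1L, 1L, 0L, 0L)[d]
        jj <- j + c(0L, 0L, -1L, 1L)[d]
        okn <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
        nb <- (jj[okn] - 1L) * nr + ii[okn]
        nb <- nb[cells[nb] & comp[nb] == 0L]
        if (length(nb)) { comp[nb] <- lab; queue <- c(queue, nb) }
      }
      queue <- unique(queue)
    }
    todo <- which(cells & comp == 0L)
  }
  comp
}

#' Test containment of points in a UD95 region
#'
#' Points are mapped to their nearest grid cell; a point is inside when that
#' cell belongs to the super-level set (any component).
#'
#' @param iso a `ud_iso` from [extract_ud95()].
#' @param x,y point coordinates, m.
#' @return logical vector.
#' @export
ud_contains <- function(iso, x, y) {
  step_x <- iso$gx[2] - iso$gx[1]; step_y <- iso$gy[2] - iso$gy[1]
  ix <- round((x - iso$gx[1]) / step_x) + 1
  iy <- round((y - iso$gy[1]) / step_y) + 1
  ok <- ix >= 1 & ix <= length(iso$gx) & iy >= 1 & iy <= length(iso$gy)
  out <- logical(length(x))
  out[ok] <- iso$cells[cbind(ix[ok], iy[ok])]
  out
}

#' Home-range polygon acceptance filters
#'
#' A daily diel home range is kept only when it is (i) derived from at least
#' `min_positions` positions and (ii) the time extent of the positions that
#' fall inside the polygon exceeds `min_extent_h` hours.
#'
#' @param times position timestamps, s.
#' @param inside logical, position inside the UD95 region.
#' @param min_positions minimum positions (default 6).
#' @param min_extent_h minimum in-polygon time extent, h (default 2).
#' @return list: `accepted`, `n_positions`, `n_inside`, `extent_h`.
#' @export
qualify_polygon <- function(times, inside, min_positions = 6,
                            min_extent_h = 2) {
  n <- length(times)
  n_in <- sum(inside)
  extent_h <- if (n_in > 0) diff(range(times[inside])) / 3600 else 0
  list(accepted = n >= min_positions && extent_h > min_extent_h,
       n_positions = n, n_inside = n_in, extent_h = extent_h)
}

#' Associate a home-range centroid with a structure
#'
#' The polygon centroid is associated with the nearest structure when its
#' distance is strictly less than `max_dist` metres (default 30 m), else
#' `"other"`. Distance ties are broken by the lexicographically smaller
#' structure id.
#'
#' @param centroid `c(x, y)` m.
#' @param structures structure table from an `array_layout`.
#' @param max_dist association radius, m.
#' @return structure id or `"other"`.
#' @export
associate_structure <- function(centroid, structures, max_dist = 30) {
  d <- sqrt((structures$x - centroid[1])^2 + (structures$y - centroid[2])^2)
  o <- order(d, structures$id)
  if (d[o[1]] < max_dist) structures$id[o[1]] else "other"
}

#' Site fidelity to a home-range polygon
#'
#' Of the `n` positions in a period (animal x date x diel), `n_inside` fall
#' inside the home-range polygon; fidelity is `n_inside / n`, bounded in
#' `[0, 1]` and equal to 1 exactly when every position is inside.
#'
#' @param n total positions in the period (> 0).
#' @param n_inside positions inside the polygon (0 <= n_inside <= n).
#' @return fidelity in `[0, 1]`.
#' @export
fidelity <- function(n, n_inside) {
  stopifnot(n > 0, n_inside >= 0, n_inside <= n)
  n_inside / n
}

#' Daily diel-split home ranges with association and fidelity
#'
#' For every (animal, date, diel period) with at least 6 positions, fits the
#' fixed-bandwidth UD, extracts the UD95 region, applies the acceptance
#' filters, associates the centroid with a structure and computes fidelity.
#'
#' @param positions table `tag_id`, `time` (s since epoch start), `x`, `y`.
#' @param layout an [array_layout()] (structures + diel anchor).
#' @param epoch POSIXct of study time 0 (UTC).
#' @param h kernel sd, m (default 6).
#' @param grid_step grid resolution, m (default 1).
#' @param max_dist association radius, m (default 30).
#' @return data.table, one row per fitted polygon: `animal`, `date`, `diel`,
#'   `n_positions`, `n_inside`, `extent_h`, `area`, `centroid_x`,
#'   `centroid_y`, `n_components`, `structure`, `fidelity`, `accepted`.
#' @export
home_ranges <- function(positions, layout, epoch, h = 6, grid_step = 1,
                        max_dist = 30) {
  p <- data.table::as.data.table(positions)
  dl <- split_diel(p$time, layout$origin, epoch)
  p[, `:=`(diel = dl$diel, date = dl$date)]
  out <- p[, {
    if (.N >= 6) {
      ud <- fit_ud(x, y, h = h, grid_step = grid_step)
      iso <- extract_ud95(ud)
      inside <- ud_contains(iso, x, y)
      q <- qualify_polygon(time, inside)
      list(n_positions = q$n_positions, n_inside = q$n_inside,
           extent_h = q$extent_h, area = iso$area,
           centroid_x = iso$centroid[["x"]],
           centroid_y = iso$centroid[["y"]],
           n_components = iso$n_components,
           structure = associate_structure(iso$centroid, layout$structures,
                                           max_dist),
           fidelity = fidelity(q$n_positions, q$n_inside),
           accepted = q$accepted)
    } else NULL
  }, by = c("tag_id", "date", "diel")]
  data.table::setnames(out, "tag_id", "animal")
  data.table::setorder(out, animal, date, diel)
  out[]
}

#' Residency and per-structure use summary
#'
#' Residency is the elapsed time (days) from release to the last detection of
#' the animal in the array; it is flagged censored when within
#' `censor_margin` days of the nominal battery life (the tag, not the animal,
#' likely expired). Per-structure use counts the distinct dates on which the
#' animal had at least one accepted home-range polygon associated with that
#' structure.
#'
#' @param detections detection table (`tag_id`, `time_local` or `time`).
#' @param releases data.frame `tag_id`, `release_time` (s).
#' @param polygons optional output of [home_ranges()] for structure-day
#'   counts.
#' @param battery_life days (default 278).
#' @param censor_margin days (default 5).
#' @return list: `summary` (per animal: `residency_days`, `censored`,
#'   `last_detection`), `structure_days` (animal x structure day counts, or
#'   NULL).
#' @export
residency <- function(detections, releases, polygons = NULL,
                      battery_life = 278, censor_margin = 5) {
  d <- data.table::as.data.table(detections)
  tcol <- if ("time" %in% names(d)) "time" else "time_local"
  last <- d[, list(last_detection = max(get(tcol))), by = "tag_id"]
  s <- merge(data.table::as.data.table(releases), last, by = "tag_id",
             all.x = TRUE)
  s[, residency_days := pmax(0, (last_detection - release_time) / 86400)]
  s[is.na(residency_days), residency_days := 0]
  s[, censored := residency_days >= battery_life - censor_margin]
  sd_tab <- NULL
  if (!is.null(polygons)) {
    pg <- data.table::as.data.table(polygons)
    pg <- pg[accepted == TRUE & structure != "other"]
    sd_tab <- pg[, list(days = length(unique(date))),
                 by = c("animal", "structure")]
  }
  list(summary = s[], structure_days = sd_tab)
}
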