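#' Receiver array and structure layout
#'
#' Container for the geometry of an acoustic positioning study: receiver
#' stations, seabed structures (artificial reefs, a turbine monopile), and a
#' geographic anchor used only for solar (diel) computations. All planar
#' coordinates are local metres (ENU), anchored at the array centre.
#'
#' @param receivers data.frame with columns `id`, `x`, `y`, `depth` (metres).
#' @param structures data.frame with columns `id`, `kind` (one of `"reef"`,
#'   `"turbine"`, `"other"`), `x`, `y`, and logical `scour`.
#' @param origin numeric `c(lat, lon)` in decimal degrees; geographic anchor
#'   for day/night classification.
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(receivers, structures, origin = c(51.70, 3.05)) {
  receivers <- as.data.frame(receivers)
  structures <- as.data.frame(structures)
  stopifnot(
    all(c("id", "x", "y", "depth") %in% names(receivers)),
    all(c("id", "kind", "x", "y", "scour") %in% names(structures)),
    length(origin) == 2
  )
  if (anyDuplicated(receivers$id)) stop("receiver ids must be unique")
  if (!all(structures$kind %in% c("reef", "turbine", "other"))) {
    stop("structure kind must be reef, turbine or other")
  }
  structure(
    list(receivers = receivers, structures = structures,
         origin = as.numeric(origin)),
    class = "array_layout"
  )
}

#' Default study layout: 4 x 4 receiver grid around 4 reefs and a monopile
#'
#' Sixteen receivers on a square 4 x 4 grid with `spacing` metres between
#' neighbours (default 225 m, within the deployed 200-250 m range), centred on
#' a turbine monopile, with four artificial reefs placed on the NW/NE/SE/SW
#' diagonals at `reef_dist` metres from the monopile. Scour protection flags
#' are set on the monopile and the two southernmost reefs.
#'
#' @param spacing receiver grid spacing, m.
#' @param reef_dist reef distance from the central monopile, m.
#' @param depth nominal water depth, m.
#' @param origin geographic anchor `c(lat, lon)`.
#' @return An `array_layout`.
#' @export
default_layout <- function(spacing = 225, reef_dist = 280, depth = 30,
                           origin = c(51.70, 3.05)) {
  g <- seq(-1.5, 1.5, by = 1) * spacing
  rec <- expand.grid(ix = 1:4, iy = 1:4)
  receivers <- data.frame(
    id = sprintf("S%02d", seq_len(16)),
    x = g[rec$ix], y = g[rec$iy], depth = depth
  )
  dd <- reef_dist / sqrt(2)
  structures <- data.frame(
    id = c("R01", "R02", "R03", "R04", "L08"),
    kind = c(rep("reef", 4), "turbine"),
    x = c(-dd, dd, dd, -dd, 0),
    y = c(dd, dd, -dd, -dd, 0),
    scour = c(FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  array_layout(receivers, structures, origin)
}

#' Transmitter configuration
#'
#' @param delay_min,delay_max bounds of the uniform random delay between
#'   transmissions, s (default 50-100 s).
#' @param vedba_window averaging window of the acceleration sensor, s
#'   (default 37 s).
#' @param battery_life nominal battery life, days (default 278).
#' @return An object of class `tag_config`.
#' @export
tag_config <- function(delay_min = 50, delay_max = 100, vedba_window = 37,
                       battery_life = 278) {
  stopifnot(delay_min > 0, delay_min < delay_max, vedba_window > 0,
            battery_life > 0)
  structure(list(delay_min = delay_min, delay_max = delay_max,
                 vedba_window = vedba_window, battery_life = battery_life),
            class = "tag_config")
}

#' Movement regime definitions
#'
#' A regime couples a movement rule with an activity (VeDBA) distribution and
#' an acoustic detectability multiplier. `hiding` pins the animal inside the
#' reef structure (positions within 2 m of the home reef) with near-total
#' signal occlusion; `local` is a mean-reverting walk around the home reef;
#' `transit` is a directed walk towards another structure or the array edge.
#'
#' @param name regime name.
#' @param attraction pull-back rate towards the home reef, 1/s (local regime).
#' @param step_scale typical displacement per time step, m.
#' @param vedba_mean,vedba_sd Gamma mean and sd of VeDBA in the regime,
#'   m s^-2.
#' @param detectability multiplicative factor in `[0, 1]` on per-receiver
#'   detection probability.
#' @return A one-row data.frame.
#' @export
movement_regime <- function(name, attraction, step_scale, vedba_mean,
                            vedba_sd, detectability) {
  stopifnot(step_scale >= 0, vedba_mean > 0, vedba_sd > 0,
            detectability >= 0, detectability <= 1)
  data.frame(name = name, attraction = attraction, step_scale = step_scale,
             vedba_mean = vedba_mean, vedba_sd = vedba_sd,
             detectability = detectability, stringsAsFactors = FALSE)
}

#' Default hiding / local / transit regime set
#'
#' Defaults chosen to be separable in step length and VeDBA, as the
#' behavioural-state analysis assumes: hiding is immobile, weakly detectable
#' (multiplier 0.02) and low-activity; local is a slow mean-reverting walk;
#' transit has the largest steps.
#'
#' @param hiding_detectability signal-occlusion multiplier inside the pipes.
#' @return data.frame of three regimes (rows: hiding, local, transit).
#' @export
default_regimes <- function(hiding_detectability = 0.02) {
  rbind(
    movement_regime("hiding", attraction = 0, step_scale = 0.3,
                    vedba_mean = 0.05, vedba_sd = 0.03,
                    detectability = hiding_detectability),
    movement_regime("local", attraction = 2e-3, step_scale = 3,
                    vedba_mean = 0.25, vedba_sd = 0.12, detectability = 1),
    movement_regime("transit", attraction = 0, step_scale = 30,
                    vedba_mean = 0.45, vedba_sd = 0.25, detectability = 1)
  )
}

#' Default per-step regime transition matrix
#'
#' Row-stochastic 3 x 3 matrix over (hiding, local, transit) applied at every
#' 60 s simulation step. Dwell times are long relative to the 10-min analysis
#' bins so decoded states are well defined at bin scale.
#'
#' @return 3 x 3 matrix with dimnames.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    0.995, 0.005, 0.000,
    0.004, 0.993, 0.003,
    0.000, 0.010, 0.990
  ), 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("hiding", "local", "transit"),
                      c("hiding", "local", "transit"))
  m
}

#' Distance from points to the closest structure of a given kind
#'
#' @param x,y point coordinates, m.
#' @param structures structure table from an `array_layout`.
#' @param kind structure kinds to consider (default reefs only).
#' @return list with `dist` (m) and `id` (closest structure id) per point.
#' @export
closest_structure <- function(x, y, structures, kind = "reef") {
  s <- structures[structures$kind %in% kind, , drop = FALSE]
  if (nrow(s) == 0) stop("no structures of kind ", paste(kind, collapse = ","))
  d <- outer(x, s$x, "-")^2 + outer(y, s$y, "-")^2
  j <- max.col(-d, ties.method = "first")
  list(dist = sqrt(d[cbind(seq_along(x), j)]), id = s$id[j])
}
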