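# Stimulus models: a planar directional light gradient (projector from one
# side of the arena) and a triangular temporal light ramp with plateaus
# (LEDs from above), plus the navigational compass and its heading bins.

#' Arena geometry
#'
#' @param width_cm,height_cm arena side lengths in cm. Default is the
#'   24.5 x 24.5 cm behavioral plate.
#' @return list with class `"arena"`.
#' @export
arena <- function(width_cm = 24.5, height_cm = 24.5) {
  stopifnot(is.numeric(width_cm), width_cm > 0, is.numeric(height_cm), height_cm > 0)
  structure(list(width_cm = width_cm, height_cm = height_cm), class = "arena")
}

#' Directional light field
#'
#' A planar gradient: intensity is maximal at the arena edge nearest the
#' light source and decreases linearly with distance from that edge,
#' clipped at zero.
#'
#' @param edge_intensity intensity in uW/cm2 at the light-side edge
#'   (default 4331, the projector assay value).
#' @param gradient decrease in uW/cm2 per cm of distance from the
#'   light-side edge (default 103).
#' @param light_angle_deg direction (degrees, arena frame) of the unit
#'   vector pointing from the arena toward the light source. Default 0:
#'   light beyond the +x edge.
#' @param arena an [arena()] object.
#' @return object of class `"directional_field"`.
#' @export
directional_field <- function(edge_intensity = 4331, gradient = 103,
                              light_angle_deg = 0, arena = larvatax::arena()) {
  stopifnot(edge_intensity >= 0, gradient >= 0, is.finite(light_angle_deg))
  u <- c(cos(light_angle_deg * pi / 180), sin(light_angle_deg * pi / 180))
  corners <- rbind(c(0, 0), c(arena$width_cm, 0),
                   c(0, arena$height_cm), c(arena$width_cm, arena$height_cm))
  structure(list(edge_intensity = edge_intensity, gradient = gradient,
                 light_angle_deg = wrap_deg(light_angle_deg), u = u,
                 edge_proj = max(corners %*% u), arena = arena),
            class = "directional_field")
}

# Intensity without the arena-bounds check; used by the simulator where
# midline points may poke marginally past a wall.
field_intensity_raw <- function(field, x, y) {
  d <- field$edge_proj - (x * field$u[1] + y * field$u[2])
  pmax(0, field$edge_intensity - field$gradient * d)
}

#' Light intensity of a directional field at an arena position
#'
#' @param field a [directional_field()].
#' @param x,y position in cm (arena frame, origin at one corner).
#' @return intensity in uW/cm2, floored at 0.
#' @export
directional_intensity <- function(field, x, y) {
  stopifnot(inherits(field, "directional_field"))
  tol <- 1e-9
  ok <- x >= -tol & x <= field$arena$width_cm + tol &
    y >= -tol & y <= field$arena$height_cm + tol
  if (any(!ok | is.na(ok)))
    stop("position outside arena bounds")
  field_intensity_raw(field, x, y)
}

#' Intensity change per second sensed while running straight toward the light
#'
#' @param field a [directional_field()].
#' @param speed_cm_per_min crawling speed in cm/min (>= 0).
#' @return sensed rate of intensity change in uW/cm2 per second.
#' @export
sensed_rate_of_change <- function(field, speed_cm_per_min) {
  stopifnot(inherits(field, "directional_field"))
  if (any(speed_cm_per_min < 0)) stop("speed must be non-negative")
  speed_cm_per_min / 60 * field$gradient
}

#' Triangular temporal light ramp
#'
#' Piecewise-linear intensity: a linear ramp of duration `t_ramp`, a
#' constant plateau of duration `t_hold`, the opposite ramp, and the
#' opposite plateau, repeated `n_cycles` times. The integrals of intensity
#' over the up and down segments are identical by construction.
#'
#' @param i_max peak intensity in uW/cm2 (default 380).
#' @param t_ramp duration of each linear segment in s (default 25.5).
#' @param t_hold duration of each constant plateau in s (default 4.5).
#' @param n_cycles number of cycles (default 11, i.e. an 11-min protocol).
#' @param exclusion_margin seconds trimmed on each side of the plateaus
#'   when labeling analysis phases (default 1).
#' @param phase_order `"up_first"` (ramp starts at 0 and rises) or
#'   `"down_first"` (starts at `i_max` and falls).
#' @return object of class `"temporal_ramp"`.
#' @export
temporal_ramp <- function(i_max = 380, t_ramp = 25.5, t_hold = 4.5,
                          n_cycles = 11, exclusion_margin = 1,
                          phase_order = c("up_first", "down_first")) {
  phase_order <- match.arg(phase_order)
  stopifnot(i_max > 0, t_ramp > 0, t_hold >= 0, n_cycles >= 1,
            exclusion_margin >= 0, 2 * exclusion_margin < t_ramp)
  structure(list(i_max = i_max, t_ramp = t_ramp, t_hold = t_hold,
                 n_cycles = as.integer(n_cycles),
                 exclusion_margin = exclusion_margin,
                 phase_order = phase_order,
                 period = 2 * (t_ramp + t_hold)),
            class = "temporal_ramp")
}

ramp_total_duration <- function(ramp) ramp$n_cycles * ramp$period

# phase position within one cycle, vectorized; no bounds check
ramp_eval <- function(ramp, t) {
  tau <- t %% ramp$period
  tr <- ramp$t_ramp; th <- ramp$t_hold; im <- ramp$i_max
  if (ramp$phase_order == "up_first") {
    i <- ifelse(tau < tr, im * tau / tr,
         ifelse(tau < tr + th, im,
         ifelse(tau < 2 * tr + th, im * (1 - (tau - tr - th) / tr), 0)))
    s <- ifelse(tau < tr, im / tr,
         ifelse(tau < tr + th, 0,
         ifelse(tau < 2 * tr + th, -im / tr, 0)))
  } else {
    i <- ifelse(tau < tr, im * (1 - tau / tr),
         ifelse(tau < tr + th, 0,
         ifelse(tau < 2 * tr + th, im * (tau - tr - th) / tr, im)))
    s <- ifelse(tau < tr, -im / tr,
         ifelse(tau < tr + th, 0,
         ifelse(tau < 2 * tr + th, im / tr, 0)))
  }
  list(intensity = i, slope = s, tau = tau)
}

#' Intensity of a temporal ramp at time t
#'
#' @param ramp a [temporal_ramp()].
#' @param t time in seconds since protocol start; must lie within
#'   `[0, n_cycles * period)`.
#' @return intensity in uW/cm2.
#' @export
temporal_intensity <- function(ramp, t) {
  stopifnot(inherits(ramp, "temporal_ramp"))
  if (any(is.na(t)) || any(t < 0) || any(t >= ramp_total_duration(ramp) + 1e-9))
    stop("time outside the stimulation protocol")
  ramp_eval(ramp, t)$intensity
}

#' Slope of a temporal ramp at time t (uW/cm2 per s; 0 on plateaus)
#' @inheritParams temporal_intensity
#' @export
temporal_slope <- function(ramp, t) {
  stopifnot(inherits(ramp, "temporal_ramp"))
  ramp_eval(ramp, t)$slope
}

#' Analysis phase of a temporal ramp at time t
#'
#' Plateaus dilated by `exclusion_margin` on each side (cyclically, so the
#' first seconds of a linear segment following a plateau are trimmed too)
#' are labeled `excluded`; remaining time is labeled by ramp slope sign.
#' Each cycle thus contributes exactly `t_ramp - 2 * exclusion_margin`
#' seconds of `increase` and the same of `decrease`.
#'
#' @inheritParams temporal_intensity
#' @return character vector in `c("increase", "decrease", "excluded")`.
#' @export
phase_of <- function(ramp, t) {
  stopifnot(inherits(ramp, "temporal_ramp"))
  if (any(is.na(t)) || any(t < 0) || any(t >= ramp_total_duration(ramp) + 1e-9))
    stop("time outside the stimulation protocol")
  e <- ramp_eval(ramp, t)
  tau <- e$tau
  tr <- ramp$t_ramp; th <- ramp$t_hold; m <- ramp$exclusion_margin
  in_first <- tau > m & tau < tr - m
  in_second <- tau > tr + th + m & tau < 2 * tr + th - m
  lab <- rep("excluded", length(tau))
  if (ramp$phase_order == "up_first") {
    lab[in_first] <- "increase"; lab[in_second] <- "decrease"
  } else {
    lab[in_first] <- "decrease"; lab[in_second] <- "increase"
  }
  lab
}

#' Convert an arena heading to the navigational compass
#'
#' Compass convention: heading toward the light source is 0 degrees, away
#' is 180; counterclockwise (the animal's left) is positive, so at +90 the
#' animal's right body half faces the light.
#'
#' @param heading numeric vector of arena headings in degrees (use
#'   [vector_to_compass()] for x/y heading vectors).
#' @param field a [directional_field()] (its `light_angle_deg` defines 0),
#'   or a bare numeric light angle in degrees.
#' @return compass angle(s) in (-180, 180].
#' @export
to_compass <- function(heading, field = 0) {
  light <- if (inherits(field, "directional_field")) field$light_angle_deg else field
  wrap_deg(heading - light)
}

#' Compass angle of a heading vector
#'
#' @param dx,dy components of a nonzero heading vector (arena frame).
#' @param field as in [to_compass()].
#' @export
vector_to_compass <- function(dx, dy, field = 0) {
  if (any(dx == 0 & dy == 0)) stop("zero vector has undefined heading")
  to_compass(atan2(dy, dx) * 180 / pi, field)
}

#' Four-bin compass partition
#'
#' Bins of 90 degrees: `toward` = \[-45, 45), `plus90` = \[45, 135),
#' `away` = \[135, 180\] u (-180, -135), `minus90` = \[-135, -45).
#' Boundaries are half-open, closed on the clockwise edge of each bin, so
#' that the bins deterministically partition (-180, 180].
#'
#' @param theta compass angles in degrees.
#' @return factor with levels `toward`, `plus90`, `away`, `minus90`.
#' @export
bin4 <- function(theta) {
  theta <- wrap_deg(theta)
  lab <- ifelse(theta >= -45 & theta < 45, "toward",
         ifelse(theta >= 45 & theta < 135, "plus90",
         ifelse(theta >= -135 & theta < -45, "minus90", "away")))
  factor(lab, levels = c("toward", "plus90", "away", "minus90"))
}

#' Two-bin (half-disk) compass partition
#'
#' `positive_half` = (0, 180], `negative_half` = (-180, 0]; 0 degrees falls
#' in the negative half by the same closed-clockwise-edge rule as [bin4()].
#'
#' @param theta compass angles in degrees.
#' @return factor with levels `positive_half`, `negative_half`.
#' @export
bin2 <- function(theta) {
  theta <- wrap_deg(theta)
  factor(ifelse(theta > 0, "positive_half", "negative_half"),
         levels = c("positive_half", "negative_half"))
}

#' Read / write a stimulus configuration (JSON)
#'
#' The config has a `type` field (`"directional"` or `"temporal"`) plus the
#' corresponding constructor arguments.
#'
#' @param stimulus a [directional_field()] or [temporal_ramp()].
#' @param path file path.
#' @return `read_stimulus_config` returns the reconstructed stimulus object.
#' @export
write_stimulus_config <- function(stimulus, path) {
  cfg <- if (inherits(stimulus, "directional_field")) {
    list(type = "directional",
         edge_intensity = stimulus$edge_intensity,
         gradient = stimulus$gradient,
         light_angle_deg = stimulus$light_angle_deg,
         arena_width_cm = stimulus$arena$width_cm,
         arena_height_cm = stimulus$arena$height_cm)
  } else if (inherits(stimulus, "temporal_ramp")) {
    list(type = "temporal", i_max = stimulus$i_max, t_ramp = stimulus$t_ramp,
         t_hold = stimulus$t_hold, n_cycles = stimulus$n_cycles,
         exclusion_margin = stimulus$exclusion_margin,
         phase_order = stimulus$phase_order)
  } else stop("unsupported stimulus object")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_config
#' @export
read_stimulus_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$type)) stop("stimulus config lacks a 'type' field")
  if (cfg$type == "directional") {
    directional_field(edge_intensity = cfg$edge_intensity,
                      gradient = cfg$gradient,
                      light_angle_deg = cfg$light_angle_deg,
                      arena = arena(cfg$arena_width_cm %||% 24.5,
                                    cfg$arena_height_cm %||% 24.5))
  } else if (cfg$type == "temporal") {
    temporal_ramp(i_max = cfg$i_max, t_ramp = cfg$t_ramp, t_hold = cfg$t_hold,
                  n_cycles = cfg$n_cycles,
                  exclusion_margin = cfg$exclusion_margin %||% 1,
                  phase_order = cfg$phase_order %||% "up_first")
  } else stop("unknown stimulus type: ", cfg$type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
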