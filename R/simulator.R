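# Agent-based larval phototaxis simulator. Each agent alternates runs and
# reorientations; two separable sensory channels drive the behavioral
# biases: a temporal (klinotaxis) channel comparing intensity at head-sweep
# start vs peak, and a spatial (tropotaxis) channel comparing left vs right
# eye input. Eye ablation states expose the one-eyed phenotypes.

#' Agent behavioral parameters
#'
#' All biases act through a single darker-is-preferred sign convention: a
#' head sweep sensing an intensity decrease is more likely accepted, the
#' first sweep is biased toward the darker eye, and runs curve toward the
#' darker side.
#'
#' @param p_accept_dec,p_accept_inc probability that a head sweep sensing
#'   an intensity decrease / increase is accepted (temporal channel).
#' @param turn_rate_dec,turn_rate_inc baseline run-termination hazards
#'   (events/min) while sensing intensity decrease / increase.
#' @param sweep_amp_mean,sweep_amp_sd head sweep amplitude (deg), normal,
#'   floored at `sweep_amp_floor`.
#' @param sweep_amp_floor minimum drawn amplitude (deg); kept above the
#'   20-degree detection threshold.
#' @param extra_turn_gain additional accepted-sweep amplitude (deg) when
#'   accepting under intensity increase (bigger turns in the bright phase).
#' @param spatial_dir_gain logistic slope (per uW/cm2) of the first-sweep
#'   side bias on the right-minus-left eye intensity difference.
#' @param steer_gain run curvature (deg/s) per unit normalized
#'   right-minus-left eye difference (steering toward the darker side).
#' @param run_speed_cm_per_min forward crawling speed (default 4).
#' @param eye_state which eyes are functional: `"both"`, `"left_only"`,
#'   `"right_only"`, `"none"`.
#' @param eye_acceptance_halfwidth directional half-width (deg) of each
#'   eye's raised-cosine acceptance profile.
#' @param eye_forward_offset_deg forward tilt of the eye axes: eyes point
#'   at heading +/- (90 - offset) degrees.
#' @param sweep_rise_s,sweep_return_s durations of the half-cosine head
#'   excursion and its return.
#' @param rebound_logit logit bias of the next sweep away from a just
#'   rejected side.
#' @param turn_speed_frac forward speed during reorientations as a
#'   fraction of run speed.
#' @param run_refractory_s minimum run duration before the termination
#'   hazard applies (default 1.5, comfortably above the analyzers 1 s
#'   minimum run).
#' @param p_pause probability that a run ends in a pause instead of a turn.
#' @param pause_dur_s range (min, max) of pause durations.
#' @param heading_noise_deg heading diffusion during runs (deg per sqrt s).
#' @param jitter_cm isotropic measurement noise added to every emitted
#'   midline point (cm).
#' @return list with class `"agent_params"`.
#' @export
agent_params <- function(p_accept_dec = 0.65, p_accept_inc = 0.45,
                         turn_rate_dec = 2, turn_rate_inc = 3,
                         sweep_amp_mean = 40, sweep_amp_sd = 10,
                         sweep_amp_floor = 25, extra_turn_gain = 15,
                         spatial_dir_gain = 1e-3, steer_gain = 6,
                         run_speed_cm_per_min = 4,
                         eye_state = c("both", "left_only", "right_only", "none"),
                         eye_acceptance_halfwidth = 90,
                         eye_forward_offset_deg = 45,
                         sweep_rise_s = 1.4, sweep_return_s = 0.7,
                         rebound_logit = 1.4, turn_speed_frac = 0.05,
                         run_refractory_s = 1.5,
                         p_pause = 0.05, pause_dur_s = c(1, 2),
                         heading_noise_deg = 4, jitter_cm = 0.001) {
  eye_state <- match.arg(eye_state)
  stopifnot(p_accept_dec >= 0, p_accept_dec <= 1,
            p_accept_inc >= 0, p_accept_inc <= 1,
            turn_rate_dec >= 0, turn_rate_inc >= 0,
            sweep_amp_mean > 0, sweep_amp_sd >= 0,
            sweep_amp_floor > 0, run_speed_cm_per_min > 0,
            eye_acceptance_halfwidth > 0, sweep_rise_s > 0,
            sweep_return_s > 0, turn_speed_frac >= 0,
            p_pause >= 0, p_pause <= 1, heading_noise_deg >= 0,
            jitter_cm >= 0)
  structure(as.list(environment()), class = "agent_params")
}

#' Simulation configuration
#'
#' @param n_agents animals per experiment (default 30).
#' @param duration_s experiment duration in s (default 660, i.e. 11 min).
#' @param fps frames per second of the emitted trajectories (default 13).
#' @param seed RNG seed; the run is bit-reproducible given the seed.
#' @param stimulus a [directional_field()], [temporal_ramp()] or `NULL`
#'   (darkness).
#' @param arena an [arena()].
#' @param midline_points midline samples per frame (default 5).
#' @param body_length_cm larval body length (default 0.4).
#' @param n_experiments number of replicate experiments for
#'   [simulate_experiments()].
#' @return list with class `"sim_config"`.
#' @export
sim_config <- function(n_agents = 30, duration_s = 660, fps = 13, seed = 1L,
                       stimulus = NULL, arena = larvatax::arena(),
                       midline_points = 5, body_length_cm = 0.4,
                       n_experiments = 1L) {
  stopifnot(n_agents >= 0, duration_s > 0, fps > 0, midline_points >= 3,
            body_length_cm > 0, n_experiments >= 1)
  structure(list(n_agents = as.integer(n_agents), duration_s = duration_s,
                 fps = fps, seed = as.integer(seed), stimulus = stimulus,
                 arena = arena, midline_points = as.integer(midline_points),
                 body_length_cm = body_length_cm,
                 n_experiments = as.integer(n_experiments)),
            class = "sim_config")
}

# ---- sensing -------------------------------------------------------------

eye_weight <- function(axis_deg, light_angle_deg, halfwidth) {
  d <- abs(wrap_deg(axis_deg - light_angle_deg))
  ang <- pmin(d * 90 / halfwidth, 90)
  pmax(0, cos(ang * pi / 180))
}

#' Light intensity received by one eye
#'
#' For a directional field, the intensity at the animal's position scaled
#' by a raised-cosine directional acceptance about the eye's outward axis
#' (heading +/- (90 - forward offset)); for a temporal stimulus both eyes
#' receive the full momentary intensity. An ablated eye returns 0.
#'
#' @param stimulus a [directional_field()], [temporal_ramp()] or `NULL`.
#' @param t time in s (temporal stimuli).
#' @param x,y position (cm).
#' @param heading_deg body heading (arena frame, deg).
#' @param side `"left"` or `"right"`.
#' @param params an [agent_params()].
#' @return intensity in uW/cm2 (vectorized over agents).
#' @export
eye_intensity <- function(stimulus, t, x, y, heading_deg, side, params) {
  n <- max(length(x), length(heading_deg))
  ablated <- switch(params$eye_state,
                    both = FALSE,
                    left_only = side == "right",
                    right_only = side == "left",
                    none = TRUE)
  if (ablated || is.null(stimulus)) return(rep(0, n))
  if (inherits(stimulus, "temporal_ramp")) {
    tt <- pmin(pmax(t, 0), ramp_total_duration(stimulus) - 1e-9)
    return(rep(ramp_eval(stimulus, tt)$intensity, n))
  }
  sgn <- if (side == "left") 1 else -1
  axis <- heading_deg + sgn * (90 - params$eye_forward_offset_deg)
  field_intensity_raw(stimulus, x, y) *
    eye_weight(axis, stimulus$light_angle_deg, params$eye_acceptance_halfwidth)
}

# summed input over both eyes for a given head direction
sensed_intensity <- function(stimulus, t, x, y, head_dir, params) {
  eye_intensity(stimulus, t, x, y, head_dir, "left", params) +
    eye_intensity(stimulus, t, x, y, head_dir, "right", params)
}

# ---- stepping ------------------------------------------------------------

# internal vectorized state container
new_sim_state <- function(n, config) {
  r <- 2
  cx <- config$arena$width_cm / 2; cy <- config$arena$height_cm / 2
  ang <- stats::runif(n, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(n))
  list(x = cx + rad * cos(ang), y = cy + rad * sin(ang),
       heading = stats::runif(n, -180, 180),
       mode = rep(0L, n), head_angle = rep(0, n),
       run_t = rep(0, n), run_start_t = rep(0, n),
       run_heading_start = numeric(n), phase_t = rep(0, n),
       amp = rep(0, n), side = rep(0, n), ord = rep(0L, n),
       I0 = rep(0, n), reo_start_t = rep(NA_real_, n),
       prior_heading = rep(NA_real_, n), pause_left = rep(0, n))
}

reflect_walls <- function(S, arena) {
  W <- arena$width_cm; H <- arena$height_cm
  i <- S$x < 0; S$x[i] <- -S$x[i]; S$heading[i] <- wrap_deg(180 - S$heading[i])
  i <- S$x > W; S$x[i] <- 2 * W - S$x[i]; S$heading[i] <- wrap_deg(180 - S$heading[i])
  i <- S$y < 0; S$y[i] <- -S$y[i]; S$heading[i] <- wrap_deg(-S$heading[i])
  i <- S$y > H; S$y[i] <- 2 * H - S$y[i]; S$heading[i] <- wrap_deg(-S$heading[i])
  S
}

# time (s after sweep start) at which the half-cosine rise crosses `level`
rise_crossing <- function(amp, level, T) {
  frac <- pmin(pmax(1 - 2 * level / amp, -1), 1)
  T / pi * acos(frac)
}
# time (s after return start) at which the return drops below `level`
return_crossing <- function(amp, level, T) {
  frac <- pmin(pmax(2 * level / amp - 1, -1), 1)
  T / pi * acos(frac)
}

#' Advance one agent state by dt
#'
#' Single-agent wrapper around the vectorized stepping engine used by
#' [simulate_experiment()]; mainly useful for inspecting the model.
#'
#' @param state list as returned by a previous call or by the internal
#'   initializer (fields x, y, heading, mode, ...).
#' @param stimulus stimulus object or `NULL`.
#' @param params an [agent_params()].
#' @param config a [sim_config()].
#' @param t current time (s).
#' @param dt time step (s), > 0.
#' @return updated state list (with an `events` attribute listing any
#'   transitions that occurred).
#' @export
step_agent <- function(state, stimulus, params, config, t, dt) {
  if (dt <= 0) stop("dt must be positive")
  S <- lapply(state, function(v) v)
  res <- sim_step(S, stimulus, params, config, t, dt)
  out <- res$S
  attr(out, "events") <- res$events
  out
}

# the engine: advances all agents from t to t + dt; returns S plus event rows
sim_step <- function(S, stimulus, params, config, t, dt) {
  n <- length(S$x)
  ev <- list(runs = NULL, sweeps = NULL, reos = NULL)
  bend_start <- 20
  v_run <- params$run_speed_cm_per_min / 60
  t_new <- t + dt

  # eye inputs at the current body heading
  L <- eye_intensity(stimulus, t, S$x, S$y, S$heading, "left", params)
  R <- eye_intensity(stimulus, t, S$x, S$y, S$heading, "right", params)
  ssum <- L + R
  ndiff <- ifelse(ssum > 1e-12, (R - L) / ssum, 0)

  draw_sweep <- function(idx, first, rejected_side = NULL) {
    # side: logistic bias toward the darker eye; rejected side disfavored
    logit <- params$spatial_dir_gain * (R[idx] - L[idx])
    if (!is.null(rejected_side)) logit <- logit - params$rebound_logit * rejected_side
    p_left <- stats::plogis(logit)
    S$side[idx] <<- ifelse(stats::runif(length(idx)) < p_left, 1, -1)
    S$amp[idx] <<- pmax(params$sweep_amp_floor,
                        stats::rnorm(length(idx), params$sweep_amp_mean,
                                     params$sweep_amp_sd))
    S$ord[idx] <<- if (first) 1L else S$ord[idx] + 1L
    S$I0[idx] <<- sensed_intensity(stimulus, t_new, S$x[idx], S$y[idx],
                                   S$heading[idx], params)
    S$phase_t[idx] <<- 0
    S$mode[idx] <<- 1L
    S$sweep_t0[idx] <<- t_new
  }
  if (is.null(S$sweep_t0)) S$sweep_t0 <- rep(NA_real_, n)

  # --- run mode ---
  run <- which(S$mode == 0L)
  if (length(run)) {
    S$heading[run] <- wrap_deg(
      S$heading[run] + params$steer_gain * ndiff[run] * dt +
        stats::rnorm(length(run), 0, params$heading_noise_deg * sqrt(dt)))
    S$x[run] <- S$x[run] + v_run * dt * cos(S$heading[run] * pi / 180)
    S$y[run] <- S$y[run] + v_run * dt * sin(S$heading[run] * pi / 180)
    S$run_t[run] <- S$run_t[run] + dt
    # sensed dI/dt sign during the run
    sgn <- rep(0, length(run))
    if (!is.null(stimulus) && params$eye_state != "none") {
      if (inherits(stimulus, "temporal_ramp")) {
        tt <- min(t, ramp_total_duration(stimulus) - 1e-9)
        sgn <- rep(sign(ramp_eval(stimulus, tt)$slope), length(run))
      } else {
        theta <- to_compass(S$heading[run], stimulus)
        sgn <- sign(cos(theta * pi / 180))
      }
    }
    rate <- ifelse(sgn > 0, params$turn_rate_inc,
            ifelse(sgn < 0, params$turn_rate_dec,
                   (params$turn_rate_inc + params$turn_rate_dec) / 2))
    p_stop <- ifelse(S$run_t[run] >= params$run_refractory_s,
                     1 - exp(-rate / 60 * dt), 0)
    stop_i <- run[stats::runif(length(run)) < p_stop]
    if (length(stop_i)) {
      ev$runs <- data.frame(agent = stop_i, t_start = S$run_start_t[stop_i],
                            t_end = t_new,
                            heading_start = S$run_heading_start[stop_i],
                            heading_end = S$heading[stop_i])
      S$prior_heading[stop_i] <- S$heading[stop_i]
      S$reo_start_t[stop_i] <- t_new
      pz <- stats::runif(length(stop_i)) < params$p_pause
      pidx <- stop_i[pz]; tidx <- stop_i[!pz]
      if (length(pidx)) {
        S$mode[pidx] <- 3L
        S$pause_left[pidx] <- stats::runif(length(pidx), params$pause_dur_s[1],
                                           params$pause_dur_s[2])
      }
      if (length(tidx)) draw_sweep(tidx, first = TRUE)
    }
  }

  # --- head sweep rise ---
  rise <- which(S$mode == 1L)
  if (length(rise)) {
    slow <- v_run * params$turn_speed_frac * dt
    S$x[rise] <- S$x[rise] + slow * cos(S$heading[rise] * pi / 180)
    S$y[rise] <- S$y[rise] + slow * sin(S$heading[rise] * pi / 180)
    S$phase_t[rise] <- S$phase_t[rise] + dt
    frac <- pmin(S$phase_t[rise] / params$sweep_rise_s, 1)
    S$head_angle[rise] <- S$side[rise] * S$amp[rise] * (1 - cos(pi * frac)) / 2
    done <- rise[S$phase_t[rise] >= params$sweep_rise_s - 1e-9]
    if (length(done)) {
      I1 <- sensed_intensity(stimulus, t_new, S$x[done], S$y[done],
                             S$heading[done] + S$head_angle[done], params)
      dI <- I1 - S$I0[done]
      p_acc <- ifelse(dI < 0, params$p_accept_dec,
               ifelse(dI > 0, params$p_accept_inc,
                      (params$p_accept_dec + params$p_accept_inc) / 2))
      acc <- stats::runif(length(done)) < p_acc
      cross <- rise_crossing(S$amp[done], bend_start, params$sweep_rise_s)
      a_i <- done[acc]; r_i <- done[!acc]
      if (length(a_i)) {
        ai <- match(a_i, done)
        extra <- ifelse(dI[ai] > 0, params$extra_turn_gain, 0)
        new_heading <- wrap_deg(S$heading[a_i] + S$side[a_i] *
                                  (S$amp[a_i] + extra))
        ev$sweeps <- rbind(ev$sweeps, data.frame(
          agent = a_i, reo_t = S$reo_start_t[a_i], ordinal = S$ord[a_i],
          t_start = S$sweep_t0[a_i] + cross[ai], t_end = t_new,
          side = ifelse(S$side[a_i] > 0, "left", "right"),
          amp = S$amp[a_i], outcome = "accepted"))
        ev$reos <- rbind(ev$reos, data.frame(
          agent = a_i, t_start = S$reo_start_t[a_i], t_end = t_new,
          kind = "turn", prior_heading = S$prior_heading[a_i],
          new_heading = new_heading, n_sweeps = S$ord[a_i]))
        S$heading[a_i] <- new_heading
        S$head_angle[a_i] <- 0
        S$mode[a_i] <- 0L
        S$run_t[a_i] <- 0
        S$run_start_t[a_i] <- t_new
        S$run_heading_start[a_i] <- new_heading
        S$ord[a_i] <- 0L
      }
      if (length(r_i)) {
        ri <- match(r_i, done)
        back <- return_crossing(S$amp[r_i], 10, params$sweep_return_s)
        ev$sweeps <- rbind(ev$sweeps, data.frame(
          agent = r_i, reo_t = S$reo_start_t[r_i], ordinal = S$ord[r_i],
          t_start = S$sweep_t0[r_i] + cross[ri], t_end = t_new + back,
          side = ifelse(S$side[r_i] > 0, "left", "right"),
          amp = S$amp[r_i], outcome = "rejected"))
        S$mode[r_i] <- 2L
        S$phase_t[r_i] <- 0
      }
    }
  }

  # --- head sweep return ---
  ret <- which(S$mode == 2L)
  if (length(ret)) {
    slow <- v_run * params$turn_speed_frac * dt
    S$x[ret] <- S$x[ret] + slow * cos(S$heading[ret] * pi / 180)
    S$y[ret] <- S$y[ret] + slow * sin(S$heading[ret] * pi / 180)
    S$phase_t[ret] <- S$phase_t[ret] + dt
    frac <- pmin(S$phase_t[ret] / params$sweep_return_s, 1)
    S$head_angle[ret] <- S$side[ret] * S$amp[ret] * (1 + cos(pi * frac)) / 2
    done <- ret[S$phase_t[ret] >= params$sweep_return_s - 1e-9]
    if (length(done)) {
      S$head_angle[done] <- 0
      draw_sweep(done, first = FALSE, rejected_side = S$side[done])
    }
  }

  # --- pause ---
  pau <- which(S$mode == 3L)
  if (length(pau)) {
    S$pause_left[pau] <- S$pause_left[pau] - dt
    done <- pau[S$pause_left[pau] <= 0]
    if (length(done)) {
      ev$reos <- rbind(ev$reos, data.frame(
        agent = done, t_start = S$reo_start_t[done], t_end = t_new,
        kind = "pause", prior_heading = S$prior_heading[done],
        new_heading = S$heading[done], n_sweeps = 0L))
      S$mode[done] <- 0L
      S$run_t[done] <- 0
      S$run_start_t[done] <- t_new
      S$run_heading_start[done] <- S$heading[done]
    }
  }

  S <- reflect_walls(S, config$arena)
  list(S = S, events = ev)
}

#' Emit a midline from an agent state
#'
#' Two-segment body: the posterior segment lies along the body axis, the
#' anterior segment is deflected by the current head angle; `midline_points`
#' samples are spread tail to head over `body_length_cm`. By construction
#' the segmentation's body bend angle of the emitted midline reproduces the
#' head angle.
#'
#' @param x,y body center position (cm).
#' @param heading_deg body axis direction (deg).
#' @param head_angle_deg head deflection (deg, left positive).
#' @param config a [sim_config()].
#' @return numeric matrix `midline_points` x 2, tail to head.
#' @export
synthesize_midline <- function(x, y, heading_deg, head_angle_deg, config) {
  if (config$body_length_cm <= 0) stop("degenerate geometry: zero body length")
  np <- config$midline_points
  half <- config$body_length_cm / 2
  h <- c(cos(heading_deg * pi / 180), sin(heading_deg * pi / 180))
  aa <- (heading_deg + head_angle_deg) * pi / 180
  a <- c(cos(aa), sin(aa))
  n_post <- ceiling(np / 2)          # tail..center inclusive
  n_ant <- np - n_post               # center..head exclusive of center
  post_f <- seq(-1, 0, length.out = n_post)
  ant_f <- seq(0, 1, length.out = n_ant + 1)[-1]
  pts <- rbind(
    cbind(x + post_f * half * h[1], y + post_f * half * h[2]),
    cbind(x + ant_f * half * a[1], y + ant_f * half * a[2]))
  # centroid anchored at (x, y); see the emission loop in
  # simulate_experiment for the rationale
  sweep(pts, 2, colMeans(pts) - c(x, y))
}

#' Simulate one experiment
#'
#' Runs `n_agents` independent agents for `duration_s` at `fps`, emitting
#' the midline trajectory table and a ground-truth event log that is
#' frame-consistent with it. Agents reaching a wall are reflected; tracks
#' are never truncated.
#'
#' @param config a [sim_config()].
#' @param params an [agent_params()].
#' @return list with `tracks` (data.frame: t_s, track_id, x1..yN),
#'   `log` (lists `runs`, `sweeps`, `reorientations`), `config`, `params`.
#' @export
simulate_experiment <- function(config, params = agent_params()) {
  n <- config$n_agents
  dt <- 1 / config$fps
  nf <- round(config$duration_s * config$fps)
  set.seed(config$seed)
  if (n == 0) {
    return(list(tracks = empty_tracks(config$midline_points),
                log = list(runs = empty_gt_runs(), sweeps = empty_gt_sweeps(),
                           reorientations = empty_gt_reos()),
                config = config, params = params))
  }
  S <- new_sim_state(n, config)
  S$run_heading_start <- S$heading
  S$sweep_t0 <- rep(NA_real_, n)
  np <- config$midline_points
  coords <- matrix(NA_real_, nrow = nf * n, ncol = 2 * np)
  runs_acc <- list(); sweeps_acc <- list(); reos_acc <- list()
  half <- config$body_length_cm / 2
  n_post <- ceiling(np / 2)
  post_f <- seq(-1, 0, length.out = n_post)
  ant_f <- seq(0, 1, length.out = np - n_post + 1)[-1]
  fracs <- c(post_f, ant_f)
  is_ant <- c(rep(FALSE, n_post), rep(TRUE, np - n_post))
  # rows of `coords` are frame-major within agent: (agent-1)*nf + frame
  agent_off <- (seq_len(n) - 1L) * nf

  for (k in 1:nf) {
    if (k > 1) {
      t <- (k - 2) * dt
      res <- sim_step(S, config$stimulus, params, config, t, dt)
      S <- res$S
      if (!is.null(res$events$runs)) runs_acc[[length(runs_acc) + 1]] <- res$events$runs
      if (!is.null(res$events$sweeps)) sweeps_acc[[length(sweeps_acc) + 1]] <- res$events$sweeps
      if (!is.null(res$events$reos)) reos_acc[[length(reos_acc) + 1]] <- res$events$reos
    }
    rows <- agent_off + k
    hrad <- S$heading * pi / 180
    arad <- (S$heading + S$head_angle) * pi / 180
    ch <- cos(hrad); sh <- sin(hrad); ca <- cos(arad); sa <- sin(arad)
    # anchor the emitted centroid at the agent position: bending
    # redistributes the midline around the centroid instead of the body
    # center, so centroid speed reflects locomotion only
    sum_post <- sum(fracs[!is_ant]); sum_ant <- sum(fracs[is_ant])
    offx <- (half / np) * (sum_post * ch + sum_ant * ca)
    offy <- (half / np) * (sum_post * sh + sum_ant * sa)
    for (j in seq_len(np)) {
      if (is_ant[j]) {
        coords[rows, 2 * j - 1] <- S$x - offx + fracs[j] * half * ca
        coords[rows, 2 * j] <- S$y - offy + fracs[j] * half * sa
      } else {
        coords[rows, 2 * j - 1] <- S$x - offx + fracs[j] * half * ch
        coords[rows, 2 * j] <- S$y - offy + fracs[j] * half * sh
      }
    }
  }
  t_last <- (nf - 1) * dt

  # close open events at the end of the recording
  open_run <- which(S$mode == 0L)
  if (length(open_run))
    runs_acc[[length(runs_acc) + 1]] <- data.frame(
      agent = open_run, t_start = S$run_start_t[open_run], t_end = t_last,
      heading_start = S$run_heading_start[open_run],
      heading_end = S$heading[open_run])
  open_sweep <- which(S$mode == 1L)
  if (length(open_sweep))
    sweeps_acc[[length(sweeps_acc) + 1]] <- data.frame(
      agent = open_sweep, reo_t = S$reo_start_t[open_sweep],
      ordinal = S$ord[open_sweep],
      t_start = S$sweep_t0[open_sweep] +
        rise_crossing(S$amp[open_sweep], 20, params$sweep_rise_s),
      t_end = t_last,
      side = ifelse(S$side[open_sweep] > 0, "left", "right"),
      amp = S$amp[open_sweep], outcome = "truncated")
  open_reo <- which(S$mode %in% c(1L, 2L, 3L))
  if (length(open_reo))
    reos_acc[[length(reos_acc) + 1]] <- data.frame(
      agent = open_reo, t_start = S$reo_start_t[open_reo], t_end = t_last,
      kind = ifelse(S$mode[open_reo] == 3L, "pause", "turn"),
      prior_heading = S$prior_heading[open_reo], new_heading = NA_real_,
      n_sweeps = S$ord[open_reo])

  runs <- if (length(runs_acc)) do.call(rbind, runs_acc) else empty_gt_runs()
  sweeps <- if (length(sweeps_acc)) do.call(rbind, sweeps_acc) else empty_gt_sweeps()
  reos <- if (length(reos_acc)) do.call(rbind, reos_acc) else empty_gt_reos()
  if (nrow(sweeps)) {
    sweeps$t_start <- pmin(sweeps$t_start, t_last)
    sweeps$t_end <- pmin(sweeps$t_end, t_last)
    sweeps <- sweeps[order(sweeps$agent, sweeps$t_start), ]
    rownames(sweeps) <- NULL
  }
  if (nrow(runs)) {
    runs <- runs[order(runs$agent, runs$t_start), ]; rownames(runs) <- NULL
  }
  if (nrow(reos)) {
    reos <- reos[order(reos$agent, reos$t_start), ]; rownames(reos) <- NULL
  }

  # measurement noise, then flatten to the track table
  if (params$jitter_cm > 0)
    coords <- coords + stats::rnorm(length(coords), 0, params$jitter_cm)
  tracks <- data.frame(
    t_s = rep(seq(0, by = dt, length.out = nf), times = n),
    track_id = rep(seq_len(n), each = nf))
  for (j in seq_len(2 * np)) {
    nm <- if (j %% 2 == 1) paste0("x", (j + 1) / 2) else paste0("y", j / 2)
    tracks[[nm]] <- coords[, j]
  }
  list(tracks = tracks,
       log = list(runs = runs, sweeps = sweeps, reorientations = reos),
       config = config, params = params)
}

empty_tracks <- function(np) {
  out <- data.frame(t_s = numeric(), track_id = integer())
  for (j in seq_len(np)) {
    out[[paste0("x", j)]] <- numeric(); out[[paste0("y", j)]] <- numeric()
  }
  out
}
empty_gt_runs <- function() data.frame(
  agent = integer(), t_start = numeric(), t_end = numeric(),
  heading_start = numeric(), heading_end = numeric())
empty_gt_sweeps <- function() data.frame(
  agent = integer(), reo_t = numeric(), ordinal = integer(),
  t_start = numeric(), t_end = numeric(), side = character(),
  amp = numeric(), outcome = character())
empty_gt_reos <- function() data.frame(
  agent = integer(), t_start = numeric(), t_end = numeric(),
  kind = character(), prior_heading = numeric(), new_heading = numeric(),
  n_sweeps = integer())

#' Simulate replicate experiments
#'
#' Runs `config$n_experiments` experiments with seeds `seed + 0 ... + (m-1)`.
#'
#' @param config a [sim_config()].
#' @param params an [agent_params()].
#' @return list of [simulate_experiment()] results.
#' @export
simulate_experiments <- function(config, params = agent_params()) {
  lapply(seq_len(config$n_experiments), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    cfg$n_experiments <- 1L
    simulate_experiment(cfg, params)
  })
}
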