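# Fixture builders: all synthetic, generated in code at test time.

# straight constant-speed track with a collinear midline
straight_track <- function(track_id = 1, heading_deg = 0, speed_cm_s = 0.1,
                           dur_s = 120, t0 = 0, fps = 13, start = c(5, 12),
                           np = 5, body_cm = 0.4) {
  nf <- round(dur_s * fps) + 1
  tt <- t0 + (seq_len(nf) - 1) / fps
  h <- c(cos(heading_deg * pi / 180), sin(heading_deg * pi / 180))
  cx <- start[1] + speed_cm_s * (tt - t0) * h[1]
  cy <- start[2] + speed_cm_s * (tt - t0) * h[2]
  fr <- seq(-0.5, 0.5, length.out = np) * body_cm
  out <- data.frame(t_s = tt, track_id = track_id)
  for (j in seq_len(np)) {
    out[[paste0("x", j)]] <- cx + fr[j] * h[1]
    out[[paste0("y", j)]] <- cy + fr[j] * h[2]
  }
  out
}

# track with run -> (optional pause) -> two head sweeps (left rejected,
# right accepted) -> run, built from explicit kinematics
handmade_turn_track <- function(fps = 13, speed = 0.1, heading1 = 0,
                                amp = 45, heading2 = -45, pause_s = 0,
                                t0 = 0, start = c(5, 12)) {
  cfg <- larvatax::sim_config(n_agents = 1, body_length_cm = 0.4)
  dt <- 1 / fps
  rows <- list(); tt <- t0; pos <- start
  emit <- function(heading, head_angle) {
    m <- larvatax::synthesize_midline(pos[1], pos[2], heading, head_angle, cfg)
    row <- data.frame(t_s = tt, track_id = 1L)
    for (j in 1:5) { row[[paste0("x", j)]] <- m[j, 1]; row[[paste0("y", j)]] <- m[j, 2] }
    rows[[length(rows) + 1]] <<- row
    tt <<- tt + dt
  }
  h1 <- c(cos(heading1 * pi / 180), sin(heading1 * pi / 180))
  for (k in 1:round(40 * fps)) { emit(heading1, 0); pos <- pos + speed * dt * h1 }
  for (k in seq_len(round(pause_s * fps))) emit(heading1, 0)
  sweep_prof <- function(side) {
    Tr <- 1.4; Tb <- 0.7
    up <- amp * (1 - cos(pi * seq(dt, Tr, by = dt) / Tr)) / 2
    down <- amp * (1 + cos(pi * seq(dt, Tb, by = dt) / Tb)) / 2
    side * c(up, down)
  }
  for (a in sweep_prof(+1)) emit(heading1, a)           # left, comes back: rejected
  Tr <- 1.4
  for (a in amp * (1 - cos(pi * seq(dt, Tr, by = dt) / Tr)) / 2)
    emit(heading1, -a)                                   # right, accepted at peak
  h2 <- c(cos(heading2 * pi / 180), sin(heading2 * pi / 180))
  for (k in 1:round(40 * fps)) { emit(heading2, 0); pos <- pos + speed * dt * h2 }
  do.call(rbind, rows)
}

# minimal fake segmentation object for metric arithmetic tests
fake_seg <- function(events = NULL, sweeps = NULL, tracks = NULL) {
  structure(list(events = events, sweeps = sweeps, tracks = tracks),
            class = "larva_segmentation")
}

clean_params <- function(...) {
  larvatax::agent_params(sweep_amp_mean = 50, sweep_amp_sd = 8,
                         heading_noise_deg = 0, jitter_cm = 0,
                         turn_speed_frac = 0, ...)
}

# match ground-truth events against detected ones (within `frames` frames)
match_rate <- function(gt, det, id_gt = "agent", frames = 2, fps = 13,
                       check = NULL) {
  tol <- frames / fps + 1e-9
  matched <- 0; agree <- 0
  for (i in seq_len(nrow(gt))) {
    cand <- det[det$track_id == gt[[id_gt]][i] &
                  abs(det$t_start - gt$t_start[i]) <= tol &
                  abs(det$t_end - gt$t_end[i]) <= tol, , drop = FALSE]
    if (nrow(cand) >= 1) {
      matched <- matched + 1
      if (!is.null(check) && all(vapply(names(check), function(col)
        cand[[check[[col]]]][1] == gt[[col]][i], logical(1))))
        agree <- agree + 1
    }
  }
  list(n = nrow(gt), matched = matched, agree = agree)
}
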