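# Navigational parameters computed from segmented events plus a stimulus.

#' Binomial standard error of a percentage
#'
#' `sqrt(p * (100 - p)) / sqrt(n)` with `p` in percent.
#'
#' @param p percentage in \[0, 100\].
#' @param n total number of events.
#' @return SEM in percentage points.
#' @export
binary_sem <- function(p, n) sqrt(p * (100 - p)) / sqrt(n)

#' Binary choice rate with binomial SEM
#'
#' @param k count of events in the focal category.
#' @param n total events (`k <= n`).
#' @param label optional name of the focal category.
#' @return list of class `"binary_rate"` with `k`, `n`, `p` (percent) and
#'   `sem` (percentage points).
#' @export
binary_rate <- function(k, n, label = NULL) {
  stopifnot(k >= 0, n >= k)
  p <- if (n > 0) 100 * k / n else NA_real_
  structure(list(k = k, n = n, p = p,
                 sem = if (n > 0) binary_sem(p, n) else NA_real_,
                 label = label),
            class = "binary_rate")
}

#' @export
print.binary_rate <- function(x, ...) {
  cat(sprintf("%s: %d of %d (%.1f%% +/- %.2f)\n",
              if (is.null(x$label)) "rate" else x$label,
              x$k, x$n, x$p, x$sem))
  invisible(x)
}

#' Navigation index
#'
#' Mean centroid velocity component toward the light divided by the mean
#' run speed, pooled over all run frames: +1 if all movement is straight
#' toward the light, -1 straight away, 0 unbiased. Only frames inside
#' detected runs contribute.
#'
#' @param seg a `"larva_segmentation"` from [segment_experiment()] (must
#'   retain its `tracks`).
#' @param field a [directional_field()] defining the light axis.
#' @return dimensionless index in \[-1, 1\].
#' @export
navigation_index <- function(seg, field) {
  runs <- seg$events[seg$events$type == "run", , drop = FALSE]
  if (nrow(runs) == 0) stop("no runs to compute a navigation index from")
  u <- field$u
  vx_all <- numeric(0); sp_all <- numeric(0)
  for (id in unique(runs$track_id)) {
    tr <- seg$tracks[seg$tracks$track_id == id, , drop = FALSE]
    cen <- track_centroid(tr)
    dts <- diff(tr$t_s)
    rr <- runs[runs$track_id == id, , drop = FALSE]
    for (k in seq_len(nrow(rr))) {
      i0 <- rr$i_start[k]; i1 <- rr$i_end[k]
      if (i1 <= i0) next
      sx <- diff(cen[i0:i1, 1]); sy <- diff(cen[i0:i1, 2])
      dt <- dts[i0:(i1 - 1)]
      vx_all <- c(vx_all, (sx * u[1] + sy * u[2]) / dt)
      sp_all <- c(sp_all, sqrt(sx^2 + sy^2) / dt)
    }
  }
  ms <- mean(sp_all)
  if (!is.finite(ms) || ms == 0) stop("mean run speed is zero; index undefined")
  mean(vx_all) / ms
}

#' First head sweep direction relative to the light
#'
#' Classifies first head sweeps as directed away from or toward the light.
#' In `"perpendicular"` mode only sweeps following a heading in the +90 or
#' -90 compass bin count (heading +90: a left sweep is away; heading -90:
#' a right sweep is away). In `"half_disk"` mode the prior heading is
#' binned into half disks: from the positive half a left sweep is away,
#' from the negative half a right sweep is away.
#'
#' @param seg a `"larva_segmentation"`.
#' @param field a [directional_field()].
#' @param bin_mode `"perpendicular"` or `"half_disk"`.
#' @return list with `rate` (a [binary_rate()] of away sweeps) and
#'   `skipped` (events whose prior heading fell outside admissible bins or
#'   was unknown).
#' @export
first_sweep_direction <- function(seg, field,
                                  bin_mode = c("perpendicular", "half_disk")) {
  bin_mode <- match.arg(bin_mode)
  fs <- seg$sweeps[seg$sweeps$ordinal == 1L, , drop = FALSE]
  total <- nrow(fs)
  fs <- fs[!is.na(fs$heading_before), , drop = FALSE]
  theta <- to_compass(fs$heading_before, field)
  left <- fs$side == "left"
  if (bin_mode == "perpendicular") {
    b <- bin4(theta)
    use <- b %in% c("plus90", "minus90")
    away <- ifelse(b == "plus90", left, !left)
  } else {
    b <- bin2(theta)
    use <- rep(TRUE, length(theta))
    away <- ifelse(b == "positive_half", left, !left)
  }
  k <- sum(away[use]); n <- sum(use)
  list(rate = binary_rate(k, n, "first sweeps away from light"),
       skipped = total - n)
}

#' Turn direction relative to the light
#'
#' Turn sense is the sign of the wrapped compass heading change across the
#' reorientation. With `prior_bin = "perpendicular"`, turns following a
#' +90 heading count counterclockwise as away and clockwise as toward (the
#' -90 bin is inverted); the pooled away rate is returned. With
#' `prior_bin = "toward"`, turns following a heading in the toward bin are
#' reported as left vs right counts (`k` = left).
#'
#' @param seg a `"larva_segmentation"`.
#' @param field a [directional_field()].
#' @param prior_bin `"perpendicular"` or `"toward"`.
#' @return list with `rate` (a [binary_rate()]) and `skipped` (turns with
#'   inadmissible prior bin, unknown headings, or zero net heading change).
#' @export
turn_direction <- function(seg, field, prior_bin = c("perpendicular", "toward")) {
  prior_bin <- match.arg(prior_bin)
  turns <- seg$events[seg$events$type == "turn", , drop = FALSE]
  total <- nrow(turns)
  turns <- turns[!is.na(turns$prior_heading) & !is.na(turns$new_heading), ,
                 drop = FALSE]
  d <- wrap_deg(turns$new_heading - turns$prior_heading)
  turns <- turns[d != 0, , drop = FALSE]
  d <- d[d != 0]
  theta <- to_compass(turns$prior_heading, field)
  b <- bin4(theta)
  if (prior_bin == "perpendicular") {
    use <- b %in% c("plus90", "minus90")
    away <- ifelse(b == "plus90", d > 0, d < 0)
    k <- sum(away[use]); n <- sum(use)
    label <- "turns away from light"
  } else {
    use <- b == "toward"
    k <- sum(d[use] > 0); n <- sum(use)
    label <- "turns to the left"
  }
  list(rate = binary_rate(k, n, label), skipped = total - n)
}

#' Heading change within a run (left positive)
#'
#' Wrapped signed difference between the end and start heading of each
#' run, in (-180, 180]; positive values are heading changes to the left.
#'
#' @param runs data.frame of run events (columns `start_heading`,
#'   `end_heading`).
#' @return numeric vector of heading changes in degrees.
#' @export
run_heading_change <- function(runs) {
  wrap_deg(runs$end_heading - runs$start_heading)
}

#' Mean steering within runs
#'
#' Spatial variant (`by = "bin"`): runs whose circular-mean compass
#' heading lies in the +90 / -90 bins are pooled per bin; with
#' `combine_away = TRUE` the -90 bin is sign-flipped before pooling so the
#' combined value is positive for steering away from the light. `"toward"`
#' restricts to the toward bin (signed, left positive). Temporal variant
#' (`by = "phase"`): runs are assigned to ramp phases by their start time
#' and the mean absolute heading change is reported per phase.
#'
#' @param seg a `"larva_segmentation"`.
#' @param stimulus a [directional_field()] (for `by = "bin"`/`"toward"`)
#'   or [temporal_ramp()] (for `by = "phase"`).
#' @param by `"bin"`, `"toward"` or `"phase"`.
#' @param combine_away pool the two perpendicular bins away-positive?
#' @param wall_margin_cm spatial modes only: runs whose centroid comes
#'   within this distance of an arena wall are excluded, because specular
#'   wall reflections flip the heading mid-run and masquerade as steering
#'   (set 0 to disable).
#' @return for `"bin"`: list with per-bin means, `n`s and (optionally)
#'   `combined`; for `"toward"`: list with `mean`, `n`; for `"phase"`:
#'   list with per-phase mean absolute steering and `n`s.
#' @export
mean_steering <- function(seg, stimulus, by = c("bin", "toward", "phase"),
                          combine_away = TRUE, wall_margin_cm = 0.5) {
  by <- match.arg(by)
  runs <- seg$events[seg$events$type == "run", , drop = FALSE]
  chg <- run_heading_change(runs)
  ok <- !is.na(chg) & !is.na(runs$mean_heading)
  if (by != "phase" && wall_margin_cm > 0 &&
      inherits(stimulus, "directional_field") && !is.null(seg$tracks))
    ok <- ok & run_wall_clear(seg, stimulus$arena,
                              wall_margin_cm)[seg$events$type == "run"]
  runs <- runs[ok, , drop = FALSE]; chg <- chg[ok]
  if (by == "phase") {
    stopifnot(inherits(stimulus, "temporal_ramp"))
    ph <- phase_of(stimulus, pmin(runs$t_start,
                                  ramp_total_duration(stimulus) - 1e-6))
    list(increase = mean(abs(chg[ph == "increase"])),
         n_increase = sum(ph == "increase"),
         decrease = mean(abs(chg[ph == "decrease"])),
         n_decrease = sum(ph == "decrease"))
  } else {
    b <- bin4(to_compass(runs$mean_heading, stimulus))
    if (by == "toward")
      return(list(mean = mean(chg[b == "toward"]), n = sum(b == "toward")))
    plus <- chg[b == "plus90"]; minus <- chg[b == "minus90"]
    out <- list(plus90 = mean(plus), n_plus90 = length(plus),
                minus90 = mean(minus), n_minus90 = length(minus))
    if (combine_away) {
      pooled <- c(plus, -minus)
      out$combined <- mean(pooled)
      out$n_combined <- length(pooled)
    }
    out
  }
}

#' First head sweep acceptance rate per ramp phase
#'
#' First sweeps are assigned to `increase` / `decrease` phases by their
#' start time via [phase_of()]; sweeps in excluded windows and sweeps cut
#' off by track truncation are dropped. The accepted fraction is returned
#' per phase as a [binary_rate()].
#'
#' @param seg a `"larva_segmentation"`.
#' @param ramp a [temporal_ramp()].
#' @return list with `increase` and `decrease` [binary_rate()]s and the
#'   number of `excluded` sweeps.
#' @export
acceptance_rate <- function(seg, ramp) {
  fs <- seg$sweeps[seg$sweeps$ordinal == 1L &
                     seg$sweeps$outcome %in% c("accepted", "rejected"), ,
                   drop = FALSE]
  tmax <- ramp_total_duration(ramp) - 1e-6
  ph <- phase_of(ramp, pmin(fs$t_start, tmax))
  rate_for <- function(p) {
    sel <- ph == p
    binary_rate(sum(fs$outcome[sel] == "accepted"), sum(sel),
                paste("accepted first sweeps,", p))
  }
  list(increase = rate_for("increase"), decrease = rate_for("decrease"),
       excluded = sum(ph == "excluded"))
}

#' Turn sizes and the per-experiment turn size delta
#'
#' Turn size is the absolute wrapped difference between the heading before
#' a turn and the new run start heading after it, in \[0, 180\]. The delta
#' is mean turn size in the light-increase phase minus the light-decrease
#' phase (turns assigned to phases by their start time).
#'
#' @param seg a `"larva_segmentation"`.
#' @param ramp optional [temporal_ramp()]; when given, per-phase means and
#'   the delta are included.
#' @return list with `sizes` (per-turn data.frame) and, with a ramp,
#'   `mean_increase`, `mean_decrease`, `delta` and counts.
#' @export
turn_size <- function(seg, ramp = NULL) {
  turns <- seg$events[seg$events$type == "turn" &
                        !is.na(seg$events$prior_heading) &
                        !is.na(seg$events$new_heading), , drop = FALSE]
  sizes <- abs(wrap_deg(turns$new_heading - turns$prior_heading))
  out <- list(sizes = data.frame(t_start = turns$t_start, size_deg = sizes))
  if (!is.null(ramp)) {
    ph <- phase_of(ramp, pmin(turns$t_start, ramp_total_duration(ramp) - 1e-6))
    out$mean_increase <- mean(sizes[ph == "increase"])
    out$mean_decrease <- mean(sizes[ph == "decrease"])
    out$n_increase <- sum(ph == "increase")
    out$n_decrease <- sum(ph == "decrease")
    out$delta <- out$mean_increase - out$mean_decrease
  }
  out
}

#' Turn rate per phase (turns per minute per animal)
#'
#' Turns are counted per ramp phase (by start time) and divided by the
#' animal-minutes spent in that phase: the integral over phase time of the
#' number of concurrently active tracks, in minutes. The delta is
#' rate(increase) minus rate(decrease).
#'
#' @param seg a `"larva_segmentation"` (its retained `tracks` define track
#'   activity windows).
#' @param ramp a [temporal_ramp()].
#' @param grid_dt time step (s) for the phase-time integration.
#' @return list with `increase`, `decrease` (turns/min/animal), `delta`
#'   and the per-phase animal-minutes.
#' @export
turn_rate <- function(seg, ramp, grid_dt = 0.1) {
  turns <- seg$events[seg$events$type == "turn", , drop = FALSE]
  tmax_p <- ramp_total_duration(ramp) - 1e-6
  ph_t <- phase_of(ramp, pmin(turns$t_start, tmax_p))
  windows <- do.call(rbind, lapply(split(seg$tracks$t_s, seg$tracks$track_id),
                                   range))
  if (is.null(windows) || nrow(windows) == 0)
    stop("no tracks available for turn-rate normalization")
  t0 <- min(windows[, 1]); t1 <- min(max(windows[, 2]), tmax_p)
  grid <- seq(t0, t1, by = grid_dt)
  ph_g <- phase_of(ramp, grid)
  n_active <- vapply(grid, function(g)
    sum(windows[, 1] <= g & windows[, 2] >= g), numeric(1))
  mins <- function(p) sum(n_active[ph_g == p]) * grid_dt / 60
  am_inc <- mins("increase"); am_dec <- mins("decrease")
  rate_inc <- if (am_inc > 0) sum(ph_t == "increase") / am_inc else NA_real_
  rate_dec <- if (am_dec > 0) sum(ph_t == "decrease") / am_dec else NA_real_
  list(increase = rate_inc, decrease = rate_dec, delta = rate_inc - rate_dec,
       animal_min_increase = am_inc, animal_min_decrease = am_dec)
}

#' Head sweep sizes by outcome
#'
#' Sweep size is the absolute wrapped difference between the heading
#' before the sweep and the maximal heading reached during it. Means are
#' reported separately for accepted and rejected sweeps (all ordinals;
#' truncated sweeps excluded).
#'
#' @param seg a `"larva_segmentation"`.
#' @return list with `accepted`, `rejected` mean sizes (deg) and counts.
#' @export
head_sweep_size <- function(seg) {
  sw <- seg$sweeps[seg$sweeps$outcome %in% c("accepted", "rejected") &
                     !is.na(seg$sweeps$heading_before) &
                     !is.na(seg$sweeps$max_heading), , drop = FALSE]
  sz <- abs(wrap_deg(sw$max_heading - sw$heading_before))
  list(accepted = mean(sz[sw$outcome == "accepted"]),
       n_accepted = sum(sw$outcome == "accepted"),
       rejected = mean(sz[sw$outcome == "rejected"]),
       n_rejected = sum(sw$outcome == "rejected"))
}

#' Mean run speed of an experiment
#'
#' Each run's path length divided by its duration, averaged over runs.
#'
#' @param seg a `"larva_segmentation"`.
#' @return mean run speed in cm/s.
#' @export
run_speed <- function(seg) {
  runs <- seg$events[seg$events$type == "run" & seg$events$duration_s > 0, ,
                     drop = FALSE]
  if (nrow(runs) == 0) return(NA_real_)
  mean(runs$path_cm / runs$duration_s)
}

#' Per-experiment metrics report
#'
#' Computes every navigational parameter applicable to the given stimulus
#' for a list of segmented experiments; continuous metrics are aggregated
#' per experiment first, grand means across experiments second.
#'
#' @param segs list of `"larva_segmentation"` objects (one per experiment).
#' @param stimulus a [directional_field()], [temporal_ramp()], or `NULL`
#'   (stimulus-free metrics only).
#' @param achiral_mirror logical vector, one per experiment: mirror that
#'   experiment about the light axis before pooling (used to merge left-
#'   and right-ablated groups into an achiral dataset). Mirroring negates
#'   all signed headings/sides.
#' @return object of class `"metrics_report"`: list with `per_experiment`
#'   data.frame, pooled `binary` rates, and `grand` means.
#' @export
metrics_report <- function(segs, stimulus = NULL, achiral_mirror = NULL) {
  if (inherits(segs, "larva_segmentation")) segs <- list(segs)
  if (!is.null(achiral_mirror)) {
    stopifnot(length(achiral_mirror) == length(segs))
    segs <- Map(function(s, m) if (m) mirror_segmentation(s, stimulus) else s,
                segs, achiral_mirror)
  }
  is_dir <- inherits(stimulus, "directional_field")
  is_tmp <- inherits(stimulus, "temporal_ramp")
  per <- lapply(seq_along(segs), function(i) {
    s <- segs[[i]]
    row <- data.frame(experiment = i,
                      n_tracks = length(unique(s$events$track_id)),
                      n_runs = sum(s$events$type == "run"),
                      n_turns = sum(s$events$type == "turn"),
                      n_pauses = sum(s$events$type == "pause"),
                      run_speed_cm_s = run_speed(s))
    hs <- head_sweep_size(s)
    row$sweep_size_accepted <- hs$accepted
    row$sweep_size_rejected <- hs$rejected
    if (is_dir) {
      row$navigation_index <- tryCatch(navigation_index(s, stimulus),
                                       error = function(e) NA_real_)
      st <- mean_steering(s, stimulus, by = "bin")
      row$steering_away_deg <- st$combined
    }
    if (is_tmp) {
      ts <- turn_size(s, stimulus)
      row$turn_size_increase <- ts$mean_increase
      row$turn_size_decrease <- ts$mean_decrease
      row$turn_size_delta <- ts$delta
      tr <- turn_rate(s, stimulus)
      row$turn_rate_increase <- tr$increase
      row$turn_rate_decrease <- tr$decrease
      row$turn_rate_delta <- tr$delta
      st <- mean_steering(s, stimulus, by = "phase")
      row$abs_steering_increase <- st$increase
      row$abs_steering_decrease <- st$decrease
    }
    row
  })
  per <- do.call(rbind, per)
  binary <- list()
  if (is_dir) {
    pool <- pool_segmentations(segs)
    binary$first_sweep_away <- first_sweep_direction(pool, stimulus)$rate
    binary$turn_away <- turn_direction(pool, stimulus)$rate
  }
  if (is_tmp) {
    pool <- pool_segmentations(segs)
    acc <- acceptance_rate(pool, stimulus)
    binary$acceptance_increase <- acc$increase
    binary$acceptance_decrease <- acc$decrease
  }
  grand <- colMeans(per[setdiff(names(per), "experiment")], na.rm = TRUE)
  structure(list(per_experiment = per, binary = binary, grand = as.list(grand),
                 stimulus = stimulus),
            class = "metrics_report")
}

# concatenate events/sweeps/tracks of several experiments, namespacing ids
pool_segmentations <- function(segs) {
  ev <- list(); sw <- list(); trk <- list()
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    e <- s$events; w <- s$sweeps; tk <- s$tracks
    if (nrow(e)) { e$track_id <- paste0(i, ":", e$track_id); ev[[i]] <- e }
    if (nrow(w)) { w$track_id <- paste0(i, ":", w$track_id); sw[[i]] <- w }
    if (!is.null(tk) && nrow(tk)) {
      tk$track_id <- paste0(i, ":", tk$track_id); trk[[i]] <- tk
    }
  }
  structure(list(events = do.call(rbind, ev), sweeps = do.call(rbind, sw),
                 tracks = if (length(trk)) do.call(rbind, trk) else NULL),
            class = "larva_segmentation")
}

# mirror a segmentation about the light axis: compass angles negate, so
# arena headings reflect about the light angle; sweep sides swap.
mirror_segmentation <- function(seg, stimulus) {
  light <- if (inherits(stimulus, "directional_field"))
    stimulus$light_angle_deg else 0
  refl <- function(h) wrap_deg(2 * light - h)
  for (col in c("start_heading", "end_heading", "mean_heading",
                "prior_heading", "new_heading"))
    seg$events[[col]] <- refl(seg$events[[col]])
  if (nrow(seg$sweeps)) {
    for (col in c("heading_before", "max_heading"))
      seg$sweeps[[col]] <- refl(seg$sweeps[[col]])
    seg$sweeps$side <- ifelse(seg$sweeps$side == "left", "right", "left")
  }
  if (!is.null(seg$tracks) && nrow(seg$tracks)) {
    u <- c(cos(light * pi / 180), sin(light * pi / 180))
    np <- n_midline_points(seg$tracks)
    for (j in seq_len(np)) {
      x <- seg$tracks[[paste0("x", j)]]; y <- seg$tracks[[paste0("y", j)]]
      # reflect (x, y) about the line through the arena center along u
      cx <- mean(range(x)); cy <- mean(range(y))
      px <- x - cx; py <- y - cy
      par_ <- px * u[1] + py * u[2]
      perp <- -px * u[2] + py * u[1]
      seg$tracks[[paste0("x", j)]] <- cx + par_ * u[1] + perp * u[2]
      seg$tracks[[paste0("y", j)]] <- cy + par_ * u[2] - perp * u[1]
    }
  }
  seg
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report:", nrow(x$per_experiment), "experiment(s)\n")
  for (nm in names(x$binary)) print(x$binary[[nm]])
  g <- x$grand
  for (nm in names(g))
    if (is.finite(g[[nm]])) cat(sprintf("  %-24s %.4g\n", nm, g[[nm]]))
  invisible(x)
}


# TRUE for run events whose centroid path stays at least `margin` from
# every arena wall (other event types get TRUE)
run_wall_clear <- function(seg, arena, margin) {
  ev <- seg$events
  out <- rep(TRUE, nrow(ev))
  for (id in unique(ev$track_id)) {
    tr <- seg$tracks[seg$tracks$track_id == id, , drop = FALSE]
    if (nrow(tr) == 0) next
    cen <- track_centroid(tr)
    d <- pmin(cen[, 1], arena$width_cm - cen[, 1],
              cen[, 2], arena$height_cm - cen[, 2])
    sel <- which(ev$track_id == id & ev$type == "run")
    for (i in sel)
      out[i] <- min(d[ev$i_start[i]:ev$i_end[i]]) >= margin
  }
  out
}
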