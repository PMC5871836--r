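# Segmentation of midline trajectories into runs, reorientations (turns
# with head sweeps) and pauses.
#
# Tracks are data.frames with one row per frame: columns t_s, track_id,
# then x1,y1,...,xN,yN midline coordinates (cm) ordered tail -> head.

#' Segmentation parameters
#'
#' @param bend_start_deg body-bend angle (deg) flagging head-sweep
#'   initiation (default 20).
#' @param bend_end_deg body-bend angle below which a head sweep ends
#'   (default 10); must be smaller than `bend_start_deg`.
#' @param min_run_s minimum run duration in s (default 1).
#' @param min_track_len_cm minimum track path length in cm (default 0.5).
#' @param min_track_dur_s minimum track duration in s (default 30).
#' @param discard_initial_s acclimatization time removed from the start of
#'   every experiment (default 60).
#' @param window_s window used both for run endpoint headings and for the
#'   "immediately before and after a reorientation" speed samples of the
#'   per-animal threshold (default 0.5).
#' @param thr_scale multiplier on the median centroid speed giving the
#'   provisional speed threshold (default 0.5).
#' @param thr_scale2 multiplier on the mean before/after-reorientation
#   speed in the iterative refinement (default 0.8).
#' @param max_iter maximum refinement iterations (default 3).
#' @param speed_smooth_frames moving-average window (frames) applied to the
#'   centroid speed before thresholding (default 5).
#' @return list with class `"segmentation_params"`.
#' @export
segmentation_params <- function(bend_start_deg = 20, bend_end_deg = 10,
                                min_run_s = 1, min_track_len_cm = 0.5,
                                min_track_dur_s = 30, discard_initial_s = 60,
                                window_s = 0.5, thr_scale = 0.5,
                                thr_scale2 = 0.8, max_iter = 3,
                                speed_smooth_frames = 5) {
  stopifnot(bend_end_deg < bend_start_deg, bend_start_deg > 0,
            bend_end_deg > 0, min_run_s > 0, min_track_len_cm > 0,
            min_track_dur_s > 0, discard_initial_s >= 0, window_s > 0,
            thr_scale > 0, thr_scale2 > 0, max_iter >= 1,
            speed_smooth_frames >= 1)
  structure(as.list(environment()), class = "segmentation_params")
}

# ---- track geometry ------------------------------------------------------

n_midline_points <- function(track) {
  nm <- names(track)
  sum(grepl("^x[0-9]+$", nm))
}

midline_matrices <- function(track) {
  np <- n_midline_points(track)
  if (np < 3) stop("a track needs at least 3 midline points")
  list(X = as.matrix(track[paste0("x", seq_len(np))]),
       Y = as.matrix(track[paste0("y", seq_len(np))]),
       np = np)
}

track_centroid <- function(track) {
  m <- midline_matrices(track)
  cbind(rowMeans(m$X), rowMeans(m$Y))
}

track_fps <- function(track) {
  dt <- stats::median(diff(track$t_s))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer frame period")
  1 / dt
}

# Total-least-squares direction (radians) of each row's points, oriented
# tail -> head (sign fixed by the first-to-last point chord).
tls_direction <- function(X, Y) {
  mx <- rowMeans(X); my <- rowMeans(Y)
  sxx <- rowMeans(X * X) - mx^2
  syy <- rowMeans(Y * Y) - my^2
  sxy <- rowMeans(X * Y) - mx * my
  phi <- 0.5 * atan2(2 * sxy, sxx - syy)
  ex <- X[, ncol(X)] - X[, 1]
  ey <- Y[, ncol(Y)] - Y[, 1]
  flip <- (cos(phi) * ex + sin(phi) * ey) < 0
  phi[flip] <- phi[flip] + pi
  degenerate <- (sxx + syy) < 1e-16
  phi[degenerate] <- NA_real_
  phi
}

# Per-frame body-bend angles from midline matrices. The midline is split at
# the middle sample (odd counts share the vertex); each half gets a
# total-least-squares line, oriented tail -> head. Returns the signed angle
# (deg, head deflected to the animal's left positive) between the two
# half directions, plus the oriented anterior-half direction.
bend_angles <- function(X, Y) {
  np <- ncol(X)
  post <- seq_len(ceiling(np / 2))
  ant <- seq.int(floor(np / 2) + if (np %% 2 == 1) 0L else 1L, np)
  if (np %% 2 == 1) ant <- seq.int((np + 1) / 2, np)
  phi_p <- tls_direction(X[, post, drop = FALSE], Y[, post, drop = FALSE])
  phi_a <- tls_direction(X[, ant, drop = FALSE], Y[, ant, drop = FALSE])
  signed <- wrap_deg((phi_a - phi_p) * 180 / pi)
  list(signed = signed, phi_ant_deg = wrap_deg(phi_a * 180 / pi),
       phi_post_deg = wrap_deg(phi_p * 180 / pi))
}

#' Body bend angle of a single midline
#'
#' The absolute angle between the total-least-squares line fits of the
#' anterior and posterior halves of the midline (split at the middle
#' sample), in degrees. The signed version is positive when the head is
#' deflected to the animal's left.
#'
#' @param midline numeric matrix with >= 3 rows, columns x and y, ordered
#'   tail to head.
#' @param signed return the signed angle? (default FALSE)
#' @return angle in degrees; absolute value in \[0, 180).
#' @export
body_bend_angle <- function(midline, signed = FALSE) {
  midline <- as.matrix(midline)
  if (nrow(midline) < 3) stop("a midline needs at least 3 points")
  X <- matrix(midline[, 1], nrow = 1)
  Y <- matrix(midline[, 2], nrow = 1)
  b <- bend_angles(X, Y)
  if (is.na(b$signed)) stop("degenerate midline: points are coincident")
  if (signed) b$signed else abs(b$signed)
}

#' Smoothed centroid speed of a track
#'
#' Frame-to-frame centroid displacement divided by the frame period,
#' smoothed with a centered moving average.
#'
#' @param track a track data.frame.
#' @param params a [segmentation_params()].
#' @return numeric vector, one speed (cm/s) per frame.
#' @export
track_speed <- function(track, params = segmentation_params()) {
  cen <- track_centroid(track)
  n <- nrow(cen)
  if (n < 2) return(rep(0, n))
  dt <- diff(track$t_s)
  v <- sqrt(diff(cen[, 1])^2 + diff(cen[, 2])^2) / dt
  v <- c(v, v[n - 1])
  k <- params$speed_smooth_frames
  if (k > 1 && n > k) {
    pad <- (k - 1) %/% 2
    vp <- c(rep(v[1], pad), v, rep(v[n], k - 1 - pad))
    v <- as.numeric(stats::filter(vp, rep(1 / k, k), sides = 2))
    v <- v[(pad + 1):(pad + n)]
  }
  v
}

# ---- segmentation core ---------------------------------------------------

# rle helper: maximal TRUE intervals as (start, end) frame indices
true_intervals <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Segment one track into runs, turns and pauses
#'
#' Runs are maximal intervals with body aligned (|bend| below
#' `bend_start_deg`) and smoothed centroid speed at or above `threshold`,
#' lasting at least `min_run_s`; shorter aligned-and-fast stretches are
#' merged into the surrounding reorientation. Within reorientations, head
#' sweeps are detected with hysteresis on the signed bend angle: a sweep
#' starts when |bend| exceeds `bend_start_deg` and ends when |bend| drops
#' below `bend_end_deg`, the head swings to the other side of the body, or
#' a run starts. The last sweep of a turn that is followed by a run is
#' labeled `accepted`; all other sweeps are `rejected`, except a final
#' sweep cut off by the end of the track, labeled `truncated` and excluded
#' from acceptance counts.
#'
#' @param track a track data.frame (single `track_id`).
#' @param params a [segmentation_params()].
#' @param threshold per-animal run/turn speed threshold (cm/s); computed
#'   with [estimate_speed_threshold()] when `NULL`.
#' @return list of class `"larva_segmentation"` with data.frames `events`
#'   (runs/turns/pauses) and `sweeps`.
#' @export
segment_track <- function(track, params = segmentation_params(),
                          threshold = NULL) {
  if (nrow(track) == 0)
    return(structure(list(events = empty_events(), sweeps = empty_sweeps(),
                          threshold = NA_real_), class = "larva_segmentation"))
  if (is.null(threshold))
    threshold <- estimate_speed_threshold(track, params)
  m <- midline_matrices(track)
  b <- bend_angles(m$X, m$Y)
  sb <- b$signed
  ab <- abs(sb)
  speed <- track_speed(track, params)
  fps <- track_fps(track)
  n <- nrow(track)
  tt <- track$t_s

  run_frame <- !is.na(sb) & ab < params$bend_start_deg & speed >= threshold
  ri <- true_intervals(run_frame)
  if (nrow(ri) > 0) {
    dur <- (ri[, "end"] - ri[, "start"]) / fps
    keep <- dur >= params$min_run_s - 1e-9
    for (j in which(!keep)) run_frame[ri[j, 1]:ri[j, 2]] <- FALSE
    ri <- ri[keep, , drop = FALSE]
  }
  reo_i <- true_intervals(!run_frame)

  cen <- track_centroid(track)
  w <- max(1L, round(params$window_s * fps))
  head_of <- function(i0, i1) {
    # net displacement direction over up to w frames from i0 forward
    j <- min(i0 + w, i1)
    dx <- cen[j, 1] - cen[i0, 1]; dy <- cen[j, 2] - cen[i0, 2]
    if (dx == 0 && dy == 0) return(NA_real_)
    atan2(dy, dx) * 180 / pi
  }
  tail_heading <- function(i0, i1) {
    j <- max(i1 - w, i0)
    dx <- cen[i1, 1] - cen[j, 1]; dy <- cen[i1, 2] - cen[j, 2]
    if (dx == 0 && dy == 0) return(NA_real_)
    atan2(dy, dx) * 180 / pi
  }

  runs <- NULL
  if (nrow(ri) > 0) {
    runs <- data.frame(
      type = "run", i_start = ri[, "start"], i_end = ri[, "end"],
      t_start = tt[ri[, "start"]], t_end = tt[ri[, "end"]])
    runs$start_heading <- mapply(head_of, runs$i_start, runs$i_end)
    runs$end_heading <- mapply(tail_heading, runs$i_start, runs$i_end)
    runs$mean_heading <- vapply(seq_len(nrow(runs)), function(k) {
      i0 <- runs$i_start[k]; i1 <- runs$i_end[k]
      if (i1 == i0) return(runs$start_heading[k])
      steps <- cbind(diff(cen[i0:i1, 1]), diff(cen[i0:i1, 2]))
      nz <- steps[, 1] != 0 | steps[, 2] != 0
      circ_mean_deg(atan2(steps[nz, 2], steps[nz, 1]) * 180 / pi)
    }, numeric(1))
    runs$path_cm <- vapply(seq_len(nrow(runs)), function(k) {
      i0 <- runs$i_start[k]; i1 <- runs$i_end[k]
      if (i1 == i0) return(0)
      sum(sqrt(diff(cen[i0:i1, 1])^2 + diff(cen[i0:i1, 2])^2))
    }, numeric(1))
    runs$duration_s <- runs$t_end - runs$t_start
    runs$mean_speed <- ifelse(runs$duration_s > 0, runs$path_cm / runs$duration_s, 0)
  }

  # sweep detection within each reorientation interval
  sweeps_list <- list()
  reos <- NULL
  if (nrow(reo_i) > 0) {
    reos <- data.frame(type = NA_character_, i_start = reo_i[, "start"],
                       i_end = reo_i[, "end"], t_start = tt[reo_i[, "start"]],
                       t_end = tt[reo_i[, "end"]])
    for (k in seq_len(nrow(reos))) {
      i0 <- reos$i_start[k]; i1 <- reos$i_end[k]
      in_sweep <- FALSE
      s_start <- NA_integer_; s_side <- 0; s_max <- 0; s_peak <- NA_integer_
      ord <- 0L
      close_sweep <- function(jend) {
        sweeps_list[[length(sweeps_list) + 1L]] <<- data.frame(
          reo_index = k, ordinal = ord, i_start = s_start, i_end = jend,
          t_start = tt[s_start], t_end = tt[jend],
          side = if (s_side > 0) "left" else "right",
          max_bend_deg = s_max, i_peak = s_peak)
      }
      for (j in i0:i1) {
        bj <- sb[j]
        if (is.na(bj)) next
        if (!in_sweep) {
          if (abs(bj) > params$bend_start_deg) {
            in_sweep <- TRUE; ord <- ord + 1L
            s_start <- j; s_side <- sign(bj); s_max <- abs(bj); s_peak <- j
          }
        } else {
          if (abs(bj) < params$bend_end_deg) {
            close_sweep(j); in_sweep <- FALSE
          } else if (sign(bj) != s_side) {
            close_sweep(max(j - 1L, s_start)); in_sweep <- FALSE
            if (abs(bj) > params$bend_start_deg) {
              in_sweep <- TRUE; ord <- ord + 1L
              s_start <- j; s_side <- sign(bj); s_max <- abs(bj); s_peak <- j
            }
          } else if (abs(bj) > s_max) {
            s_max <- abs(bj); s_peak <- j
          }
        }
      }
      if (in_sweep) close_sweep(i1)
      reos$type[k] <- if (ord > 0) "turn" else "pause"
    }
  }

  events <- rbind(
    if (!is.null(runs)) runs[c("type", "i_start", "i_end", "t_start", "t_end",
                               "start_heading", "end_heading", "mean_heading",
                               "path_cm", "duration_s", "mean_speed")],
    if (!is.null(reos)) {
      reos$start_heading <- NA_real_; reos$end_heading <- NA_real_
      reos$mean_heading <- NA_real_; reos$path_cm <- NA_real_
      reos$duration_s <- reos$t_end - reos$t_start
      reos$mean_speed <- NA_real_
      reos[c("type", "i_start", "i_end", "t_start", "t_end", "start_heading",
             "end_heading", "mean_heading", "path_cm", "duration_s",
             "mean_speed")]
    })
  events <- events[order(events$i_start), ]
  rownames(events) <- NULL
  events$event_id <- seq_len(nrow(events))

  # prior / new headings for reorientations from flanking runs
  events$prior_heading <- NA_real_
  events$new_heading <- NA_real_
  is_reo <- events$type %in% c("turn", "pause")
  for (e in which(is_reo)) {
    if (e > 1 && events$type[e - 1] == "run")
      events$prior_heading[e] <- events$end_heading[e - 1]
    if (e < nrow(events) && events$type[e + 1] == "run")
      events$new_heading[e] <- events$start_heading[e + 1]
  }

  sweeps <- if (length(sweeps_list)) do.call(rbind, sweeps_list) else empty_sweeps()
  if (nrow(sweeps) > 0) {
    # map reo_index (order within reos) to event ids
    reo_event_ids <- events$event_id[is_reo]
    reo_order <- order(events$i_start[is_reo])
    sweeps$event_id <- reo_event_ids[reo_order][sweeps$reo_index]
    sweeps$reo_index <- NULL
    ev_row <- match(sweeps$event_id, events$event_id)
    sweeps$heading_before <- events$prior_heading[ev_row]
    sweeps$max_heading <- b$phi_ant_deg[sweeps$i_peak]
    # outcome: last sweep of a reorientation followed by a run is accepted
    followed <- !is.na(events$new_heading[ev_row]) |
      vapply(ev_row, function(r) r < nrow(events) && events$type[r + 1] == "run",
             logical(1))
    sweeps$outcome <- "rejected"
    for (ev in unique(sweeps$event_id)) {
      idx <- which(sweeps$event_id == ev)
      last <- idx[which.max(sweeps$ordinal[idx])]
      r <- match(ev, events$event_id)
      if (r < nrow(events) && events$type[r + 1] == "run") {
        sweeps$outcome[last] <- "accepted"
      } else {
        sweeps$outcome[last] <- "truncated"
      }
    }
    sweeps <- sweeps[order(sweeps$i_start), ]
    rownames(sweeps) <- NULL
    sweeps$sweep_id <- seq_len(nrow(sweeps))
  }
  events$n_sweeps <- 0L
  if (nrow(sweeps) > 0) {
    cnt <- table(sweeps$event_id)
    events$n_sweeps[match(as.integer(names(cnt)), events$event_id)] <-
      as.integer(cnt)
  }
  structure(list(events = events, sweeps = sweeps, threshold = threshold),
            class = "larva_segmentation")
}

empty_events <- function() {
  data.frame(type = character(), i_start = integer(), i_end = integer(),
             t_start = numeric(), t_end = numeric(),
             start_heading = numeric(), end_heading = numeric(),
             mean_heading = numeric(), path_cm = numeric(),
             duration_s = numeric(), mean_speed = numeric(),
             event_id = integer(), prior_heading = numeric(),
             new_heading = numeric(), n_sweeps = integer())
}

empty_sweeps <- function() {
  data.frame(ordinal = integer(), i_start = integer(), i_end = integer(),
             t_start = numeric(), t_end = numeric(), side = character(),
             max_bend_deg = numeric(), i_peak = integer(),
             event_id = integer(), heading_before = numeric(),
             max_heading = numeric(), outcome = character(),
             sweep_id = integer())
}

#' Per-animal run/turn speed threshold
#'
#' Iterative scheme: the provisional threshold is `thr_scale` times the
#' median smoothed centroid speed; the track is segmented with it and the
#' threshold re-estimated as `thr_scale2` times the mean speed in the
#' `window_s` immediately before and after each detected reorientation;
#' repeated up to `max_iter` times. Falls back to the provisional value
#' with a warning when no reorientation is found.
#'
#' @inheritParams segment_track
#' @return threshold speed in cm/s.
#' @export
estimate_speed_threshold <- function(track, params = segmentation_params()) {
  speed <- track_speed(track, params)
  thr0 <- params$thr_scale * stats::median(speed)
  thr <- thr0
  fps <- track_fps(track)
  w <- max(1L, round(params$window_s * fps))
  n <- nrow(track)
  for (iter in seq_len(params$max_iter)) {
    seg <- segment_track(track, params, threshold = thr)
    reo <- seg$events[seg$events$type %in% c("turn", "pause"), , drop = FALSE]
    if (nrow(reo) == 0) {
      if (iter == 1) {
        warning("no reorientations found; using provisional speed threshold")
        return(thr0)
      }
      return(thr)
    }
    idx <- unique(unlist(lapply(seq_len(nrow(reo)), function(k) {
      c(seq.int(max(1L, reo$i_start[k] - w), max(1L, reo$i_start[k] - 1L)),
        seq.int(min(n, reo$i_end[k] + 1L), min(n, reo$i_end[k] + w)))
    })))
    idx <- setdiff(idx, unlist(lapply(seq_len(nrow(reo)), function(k)
      reo$i_start[k]:reo$i_end[k])))
    if (length(idx) == 0) return(thr)
    thr_new <- params$thr_scale2 * mean(speed[idx])
    if (abs(thr_new - thr) < 1e-8) return(thr_new)
    thr <- thr_new
  }
  thr
}

#' Filter tracks by the acclimatization window and track minima
#'
#' Removes all frames before `discard_initial_s` (experiment time base),
#' then drops tracks with path length below `min_track_len_cm` or duration
#' below `min_track_dur_s`.
#'
#' @param tracks data.frame of one or more tracks (column `track_id`).
#' @param params a [segmentation_params()].
#' @return filtered tracks data.frame.
#' @export
filter_tracks <- function(tracks, params = segmentation_params()) {
  tracks <- tracks[tracks$t_s >= params$discard_initial_s, , drop = FALSE]
  if (nrow(tracks) == 0) return(tracks)
  keep <- vapply(split(seq_len(nrow(tracks)), tracks$track_id), function(ix) {
    tr <- tracks[ix, , drop = FALSE]
    dur <- max(tr$t_s) - min(tr$t_s)
    if (dur < params$min_track_dur_s) return(FALSE)
    cen <- track_centroid(tr)
    path <- sum(sqrt(diff(cen[, 1])^2 + diff(cen[, 2])^2))
    path >= params$min_track_len_cm
  }, logical(1))
  ids_keep <- names(keep)[keep]
  out <- tracks[as.character(tracks$track_id) %in% ids_keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment all tracks of an experiment
#'
#' Applies [filter_tracks()], estimates a per-animal speed threshold and
#' segments each surviving track; results are concatenated with a
#' `track_id` column.
#'
#' @param tracks multi-track data.frame.
#' @param params a [segmentation_params()].
#' @return `"larva_segmentation"` object with pooled `events` and `sweeps`
#'   tables (each carrying `track_id`) and a named `thresholds` vector.
#' @export
segment_experiment <- function(tracks, params = segmentation_params()) {
  tracks <- filter_tracks(tracks, params)
  ids <- unique(tracks$track_id)
  ev <- list(); sw <- list(); thr <- numeric(0)
  for (id in ids) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    th <- suppressWarnings(estimate_speed_threshold(tr, params))
    seg <- segment_track(tr, params, threshold = th)
    if (nrow(seg$events)) { seg$events$track_id <- id; ev[[length(ev) + 1]] <- seg$events }
    if (nrow(seg$sweeps)) { seg$sweeps$track_id <- id; sw[[length(sw) + 1]] <- seg$sweeps }
    thr[as.character(id)] <- th
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    cbind(empty_events(), data.frame(track_id = character()))
  sweeps <- if (length(sw)) do.call(rbind, sw) else
    cbind(empty_sweeps(), data.frame(track_id = character()))
  structure(list(events = events, sweeps = sweeps, thresholds = thr,
                 params = params, tracks = tracks),
            class = "larva_segmentation")
}
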