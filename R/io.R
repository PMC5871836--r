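# File formats and end-to-end orchestration.
#
# Trajectory dialect: '#'-prefixed header (format version, fps, midline
# point count, units) followed by a tab-separated table with columns
# t_s, track_id, x1, y1, ..., xN, yN. Units are cm/s throughout.

TRACKS_FORMAT <- "larvatax-tracks v1"

#' Write a track table
#'
#' @param tracks track data.frame (`t_s`, `track_id`, `x1..yN`).
#' @param path output file.
#' @param fps frames per second recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, fps = 13) {
  np <- n_midline_points(tracks)
  header <- c(paste("#", TRACKS_FORMAT),
              paste("# fps:", fps),
              paste("# midline_points:", np),
              "# units: cm")
  writeLines(header, path)
  suppressWarnings(data.table::fwrite(tracks, path, sep = "\t", append = TRUE,
                                      col.names = TRUE))
  invisible(path)
}

#' Read a track table
#'
#' Validates the dialect header, column count, coordinate finiteness and
#' per-track time monotonicity; malformed content is reported with the
#' offending line number.
#'
#' @param path input file.
#' @param expected_fps optional fps to validate the header against.
#' @return track data.frame with attributes `fps` and `midline_points`.
#' @export
read_tracks <- function(path, expected_fps = NULL) {
  head_lines <- readLines(path, n = 4)
  if (length(head_lines) < 4 || !grepl(TRACKS_FORMAT, head_lines[1], fixed = TRUE))
    stop("missing or unrecognized tracks header in ", path)
  fps <- as.numeric(sub("# fps:", "", head_lines[2], fixed = TRUE))
  np <- as.integer(sub("# midline_points:", "", head_lines[3], fixed = TRUE))
  if (!is.finite(fps) || is.na(np)) stop("malformed tracks header in ", path)
  if (!grepl("units: cm", head_lines[4]))
    stop("tracks file must declare units = cm (line 4)")
  if (!is.null(expected_fps) && abs(fps - expected_fps) > 1e-6)
    stop("fps mismatch: file declares ", fps, ", expected ", expected_fps)
  tr <- as.data.frame(data.table::fread(path, skip = 4, sep = "\t",
                                        header = TRUE))
  if (nrow(tr) == 0) {
    out <- empty_tracks(np)
    attr(out, "fps") <- fps; attr(out, "midline_points") <- np
    return(out)
  }
  want <- c("t_s", "track_id",
            as.vector(rbind(paste0("x", 1:np), paste0("y", 1:np))))
  if (!identical(names(tr), want))
    stop("unexpected columns; expected ", paste(want, collapse = ", "))
  num_cols <- setdiff(want, "track_id")
  bad <- which(!stats::complete.cases(tr[num_cols]) |
                 !apply(is.finite(as.matrix(tr[num_cols])), 1, all))
  if (length(bad))
    stop("non-finite coordinates at line ", bad[1] + 5L, " of ", path)
  for (id in unique(tr$track_id)) {
    tt <- tr$t_s[tr$track_id == id]
    if (any(diff(tt) <= 0)) {
      row <- which(tr$track_id == id)[which(diff(tt) <= 0)[1] + 1L]
      stop("non-monotone time for track ", id, " at line ", row + 5L)
    }
  }
  attr(tr, "fps") <- fps
  attr(tr, "midline_points") <- np
  tr
}

#' Write / read segmented events
#'
#' Events and sweeps are written as two tab-separated tables.
#'
#' @param seg a `"larva_segmentation"`.
#' @param dir output directory (files `events.tsv`, `sweeps.tsv`).
#' @return the directory (write) or a `"larva_segmentation"` (read),
#'   without the tracks.
#' @export
write_events <- function(seg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(seg$events, file.path(dir, "events.tsv"), sep = "\t")
  data.table::fwrite(seg$sweeps, file.path(dir, "sweeps.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_events
#' @export
read_events <- function(dir) {
  structure(list(
    events = as.data.frame(data.table::fread(file.path(dir, "events.tsv"))),
    sweeps = as.data.frame(data.table::fread(file.path(dir, "sweeps.tsv"))),
    tracks = NULL), class = "larva_segmentation")
}

#' Experiment bundle
#'
#' Groups the inputs of one analysis: per-experiment track tables, the
#' stimulus, segmentation parameters and free-text metadata.
#'
#' @param tracks a track data.frame or list of them (one per experiment).
#' @param stimulus a stimulus object or `NULL`.
#' @param params a [segmentation_params()].
#' @param meta named list of metadata (id, condition, genotype, ...).
#' @return list of class `"experiment_bundle"`.
#' @export
experiment_bundle <- function(tracks, stimulus = NULL,
                              params = segmentation_params(), meta = list()) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  structure(list(tracks = tracks, stimulus = stimulus, params = params,
                 meta = meta), class = "experiment_bundle")
}

#' Run the full analysis pipeline on a bundle
#'
#' filter -> per-animal speed threshold -> segmentation -> metrics ->
#' statistical battery, logging event counts per stage. Deterministic
#' given its inputs. Without a stimulus, spatial/temporal metrics are
#' skipped with a warning and speed/size metrics are still produced.
#'
#' @param bundle an [experiment_bundle()].
#' @param achiral_mirror passed to [metrics_report()].
#' @param bin_mode passed to [first_sweep_direction()].
#' @param verbose print per-stage event counts?
#' @return list with `segmentations`, `report` (a metrics_report), and
#'   `stats` (data.frame from [stats_table()], or NULL).
#' @export
run_pipeline <- function(bundle, achiral_mirror = NULL,
                         bin_mode = "perpendicular", verbose = TRUE) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  say <- function(...) if (verbose) message(sprintf(...))
  segs <- lapply(seq_along(bundle$tracks), function(i) {
    seg <- segment_experiment(bundle$tracks[[i]], bundle$params)
    say("experiment %d: %d tracks kept, %d runs, %d turns, %d pauses, %d sweeps",
        i, length(unique(seg$events$track_id)),
        sum(seg$events$type == "run"), sum(seg$events$type == "turn"),
        sum(seg$events$type == "pause"), nrow(seg$sweeps))
    seg
  })
  if (all(vapply(segs, function(s) nrow(s$events) == 0, logical(1))))
    stop("no events left after filtering")
  if (is.null(bundle$stimulus))
    warning("bundle has no stimulus: spatial and temporal metrics skipped")
  report <- metrics_report(segs, bundle$stimulus, achiral_mirror)
  stats_df <- pipeline_stats(segs, report, bundle$stimulus, bin_mode)
  list(segmentations = segs, report = report, stats = stats_df)
}

# the statistical battery matching the stimulus type, BH-adjusted
pipeline_stats <- function(segs, report, stimulus, bin_mode = "perpendicular") {
  res <- list()
  per <- report$per_experiment
  if (inherits(stimulus, "directional_field")) {
    pool <- pool_segmentations(segs)
    fs <- first_sweep_direction(pool, stimulus,
                                if (bin_mode == "half_disk") "half_disk"
                                else "perpendicular")
    res[["first sweep direction vs chance"]] <-
      exact_binomial(fs$rate$k, fs$rate$n)
    td <- turn_direction(pool, stimulus)
    res[["turn direction vs chance"]] <- exact_binomial(td$rate$k, td$rate$n)
    if (nrow(per) >= 2) {
      ni <- per$navigation_index
      if (sum(!is.na(ni)) >= 2 && stats::sd(ni, na.rm = TRUE) > 0)
        res[["navigation index vs 0"]] <- one_sample_t(ni)
      stv <- per$steering_away_deg
      if (sum(!is.na(stv)) >= 2 && stats::sd(stv, na.rm = TRUE) > 0)
        res[["steering away vs 0"]] <- one_sample_t(stv)
    }
  } else if (inherits(stimulus, "temporal_ramp")) {
    pool <- pool_segmentations(segs)
    acc <- acceptance_rate(pool, stimulus)
    tab <- rbind(c(acc$increase$k, acc$increase$n - acc$increase$k),
                 c(acc$decrease$k, acc$decrease$n - acc$decrease$k))
    res[["acceptance increase vs decrease"]] <- fisher_exact_2x2(tab)
    if (nrow(per) >= 2) {
      res[["turn size increase vs decrease"]] <- tryCatch(
        two_sample_t(per$turn_size_increase, per$turn_size_decrease),
        error = function(e) NULL)
      res[["turn rate increase vs decrease"]] <- tryCatch(
        two_sample_t(per$turn_rate_increase, per$turn_rate_decrease),
        error = function(e) NULL)
    }
    res <- Filter(Negate(is.null), res)
  }
  if (length(res) == 0) return(NULL)
  stats_table(res)
}

#' Write a metrics report
#'
#' A human-readable key/value summary plus a machine-readable delimited
#' table (one row per experiment, metric and stratum).
#'
#' @param report a `"metrics_report"`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per <- report$per_experiment
  long <- do.call(rbind, lapply(setdiff(names(per), "experiment"), function(m)
    data.frame(experiment = per$experiment, metric = m, value = per[[m]])))
  for (nm in names(report$binary)) {
    b <- report$binary[[nm]]
    long <- rbind(long,
                  data.frame(experiment = NA, metric = paste0(nm, ".k"), value = b$k),
                  data.frame(experiment = NA, metric = paste0(nm, ".n"), value = b$n),
                  data.frame(experiment = NA, metric = paste0(nm, ".pct"), value = b$p),
                  data.frame(experiment = NA, metric = paste0(nm, ".sem"), value = b$sem))
  }
  data.table::fwrite(long, file.path(dir, "metrics.tsv"), sep = "\t")
  con <- file(file.path(dir, "metrics.txt"), "w")
  on.exit(close(con))
  writeLines("# larvatax metrics report", con)
  for (nm in names(report$binary)) {
    b <- report$binary[[nm]]
    writeLines(sprintf("%s: %d (%d) = %.1f%% +/- %.2f", nm, b$k, b$n, b$p, b$sem),
               con)
  }
  for (nm in names(report$grand))
    if (is.finite(report$grand[[nm]]))
      writeLines(sprintf("%s: %.5g", nm, report$grand[[nm]]), con)
  invisible(dir)
}
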