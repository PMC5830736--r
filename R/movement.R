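## Trajectory metrics for singer tracks: linear interpolation onto a regular
## grid, separation distances between two singers, meander ratio (path
## tortuosity over 5-min bins), and the spatial null distribution built by
## superimposing the tracks of solo singers pairwise.

.one_singer <- function(trk, singer_id = NULL) {
  if (!is.null(singer_id)) trk <- trk[trk$singer_id == singer_id, , drop = FALSE]
  ids <- unique(trk$singer_id)
  if (length(ids) != 1)
    stop_validation("expected a track for exactly one singer, got %d", length(ids))
  trk[order(trk$time_s), , drop = FALSE]
}

# Nearest covered time within tolerance; localization dropouts (surfacings,
# moves out of the array) can leave a track slightly short of a window
# endpoint, so the nearest covered time within `tol_s` stands in for it.
.covered_time <- function(trk, t, tol_s, what = "endpoint") {
  t0 <- min(trk$time_s)
  t1 <- max(trk$time_s)
  if (t >= t0 && t <= t1) return(t)
  if (t < t0 && t0 - t <= tol_s) return(t0)
  if (t > t1 && t - t1 <= tol_s) return(t1)
  stop_validation("track for singer '%s' does not cover %s %.0f s (span %.0f-%.0f s, tolerance %.0f s)",
                  trk$singer_id[1], what, t, t0, t1, tol_s)
}

.position_at <- function(trk, t) {
  c(x = approx(trk$time_s, trk$x_m, xout = t)$y,
    y = approx(trk$time_s, trk$y_m, xout = t)$y)
}

#' Linearly interpolate a track onto a regular time grid
#'
#' Positions are interpolated piecewise-linearly at `grid_interval_s` steps
#' over the track's observed span (no extrapolation beyond the first and
#' last fix).
#'
#' @param trk Track data.frame for one singer (see [validate_track()]).
#' @param grid_interval_s Grid step in seconds (default 150 s, the nominal
#'   localization cadence of 2.5 min).
#' @return A track data.frame on the regular grid.
#' @export
interpolate_track <- function(trk, grid_interval_s = 150) {
  trk <- .one_singer(validate_track(trk))
  if (nrow(trk) < 2)
    stop_validation("interpolation requires at least 2 track samples")
  grid <- seq(min(trk$time_s), max(trk$time_s), by = grid_interval_s)
  data.frame(
    singer_id = trk$singer_id[1],
    time_s = grid,
    x_m = approx(trk$time_s, trk$x_m, xout = grid)$y,
    y_m = approx(trk$time_s, trk$y_m, xout = grid)$y,
    stringsAsFactors = FALSE
  )
}

#' Separation distance between two singers at a time point
#'
#' Euclidean distance between the (linearly interpolated) positions of two
#' singers at time `t_s`, which must lie within both tracks' spans.
#'
#' @param track_a,track_b Single-singer track data.frames.
#' @param t_s Time in seconds.
#' @return Distance in meters.
#' @export
separation <- function(track_a, track_b, t_s) {
  a <- .one_singer(validate_track(track_a))
  b <- .one_singer(validate_track(track_b))
  for (trk in list(a, b))
    if (t_s < min(trk$time_s) || t_s > max(trk$time_s))
      stop_validation("time %.0f s outside the span of singer '%s'",
                      t_s, trk$singer_id[1])
  pa <- .position_at(a, t_s)
  pb <- .position_at(b, t_s)
  sqrt(sum((pa - pb)^2))
}

#' Separation statistics of a singer dyad over a window
#'
#' Starting separation, ending separation, and change in distance
#' (`delta_m = end - start`; negative means the singers approached) over
#' the window `[window_start_s, window_end_s]`. If a track does not cover a
#' window endpoint, the nearest covered time within `tol_s` is used; larger
#' gaps are an error naming the singer and endpoint.
#'
#' @param track_a,track_b Single-singer track data.frames.
#' @param window_start_s,window_end_s Window endpoints in seconds.
#' @param tol_s Endpoint coverage tolerance in seconds.
#' @return A data.frame row: `id_a`, `id_b`, `start_sep_m`, `end_sep_m`,
#'   `delta_m`.
#' @export
dyad_spatial <- function(track_a, track_b, window_start_s, window_end_s,
                         tol_s = 300) {
  a <- .one_singer(validate_track(track_a))
  b <- .one_singer(validate_track(track_b))
  pa0 <- .position_at(a, .covered_time(a, window_start_s, tol_s, "window start"))
  pb0 <- .position_at(b, .covered_time(b, window_start_s, tol_s, "window start"))
  pa1 <- .position_at(a, .covered_time(a, window_end_s, tol_s, "window end"))
  pb1 <- .position_at(b, .covered_time(b, window_end_s, tol_s, "window end"))
  start_sep <- sqrt(sum((pa0 - pb0)^2))
  end_sep <- sqrt(sum((pa1 - pb1)^2))
  data.frame(
    id_a = a$singer_id[1], id_b = b$singer_id[1],
    start_sep_m = start_sep, end_sep_m = end_sep,
    delta_m = end_sep - start_sep, stringsAsFactors = FALSE
  )
}

#' Meander ratio of a singer over a window
#'
#' Path length divided by chord (straight-line) distance over a window,
#' with the path summed over positions at sequential `bin_s` boundaries
#' (default 5-min bins, which damps position jitter from oversampled
#' tracks). A singer travelling in a straight line scores 1; a milling
#' singer scores much more than 1. When the chord is shorter than
#' `chord_eps_m` (default 1 m — far below acoustic localization error) the
#' ratio is numerically meaningless and reported as undefined (`NA`).
#'
#' @param trk Single-singer track data.frame.
#' @param window_start_s,window_end_s Window endpoints in seconds.
#' @param bin_s Bin length in seconds.
#' @param chord_eps_m Minimum chord for a defined ratio.
#' @param tol_s Endpoint coverage tolerance in seconds (as in
#'   [dyad_spatial()]).
#' @return A list of class `meander_result`: `singer_id`, `path_m`,
#'   `chord_m`, `ratio` (`NA_real_` when undefined).
#' @export
meander_ratio <- function(trk, window_start_s, window_end_s, bin_s = 300,
                          chord_eps_m = 1, tol_s = 300) {
  trk <- .one_singer(validate_track(trk))
  if (window_end_s - window_start_s < bin_s)
    stop_validation("window (%.0f s) shorter than one bin (%.0f s)",
                    window_end_s - window_start_s, bin_s)
  ws <- .covered_time(trk, window_start_s, tol_s, "window start")
  we <- .covered_time(trk, window_end_s, tol_s, "window end")
  bounds <- seq(ws, we, by = bin_s)
  if (bounds[length(bounds)] < we) bounds <- c(bounds, we)
  xs <- approx(trk$time_s, trk$x_m, xout = bounds)$y
  ys <- approx(trk$time_s, trk$y_m, xout = bounds)$y
  steps <- sqrt(diff(xs)^2 + diff(ys)^2)
  path <- sum(steps)
  chord <- sqrt((xs[length(xs)] - xs[1])^2 + (ys[length(ys)] - ys[1])^2)
  structure(list(
    singer_id = trk$singer_id[1],
    path_m = path, chord_m = chord,
    ratio = if (chord >= chord_eps_m) path / chord else NA_real_
  ), class = "meander_result")
}

#' @export
print.meander_result <- function(x, ...) {
  cat(sprintf("Meander: singer '%s', path %.0f m / chord %.0f m = %s\n",
              x$singer_id, x$path_m, x$chord_m,
              if (is.na(x$ratio)) "undefined (chord below threshold)"
              else sprintf("%.2f", x$ratio)))
  invisible(x)
}

#' Spatial null distribution from solo singers superimposed pairwise
#'
#' Solo singers recorded at non-overlapping times could not have been
#' interacting, so superimposing their tracks in time as though they had
#' sung simultaneously yields a null for dyad separation statistics. Every
#' unordered pair of solo singers contributes one start separation, end
#' separation, and change in distance, computed from the singers' start and
#' end positions; `n` singers give `choose(n, 2)` pairs (18 give 153).
#'
#' @param endpoints Data.frame with columns `singer_id`, `start_x_m`,
#'   `start_y_m`, `end_x_m`, `end_y_m`, one row per solo singer (see
#'   [read_solo_endpoints()]).
#' @return A data.frame of [dyad_spatial()]-shaped rows with attributes
#'   `n_singers` and `n_pairs`.
#' @export
solo_pairwise_null <- function(endpoints) {
  need <- c("singer_id", "start_x_m", "start_y_m", "end_x_m", "end_y_m")
  miss <- setdiff(need, names(endpoints))
  if (length(miss))
    stop_validation("endpoints missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(endpoints$singer_id))
    stop_validation("duplicate singer_id in endpoints")
  n <- nrow(endpoints)
  if (n < 2) stop_validation("at least 2 solo singers required")
  cmb <- combn(n, 2)
  i <- cmb[1, ]
  j <- cmb[2, ]
  start_sep <- sqrt((endpoints$start_x_m[i] - endpoints$start_x_m[j])^2 +
                    (endpoints$start_y_m[i] - endpoints$start_y_m[j])^2)
  end_sep <- sqrt((endpoints$end_x_m[i] - endpoints$end_x_m[j])^2 +
                  (endpoints$end_y_m[i] - endpoints$end_y_m[j])^2)
  out <- data.frame(
    id_a = endpoints$singer_id[i], id_b = endpoints$singer_id[j],
    start_sep_m = start_sep, end_sep_m = end_sep,
    delta_m = end_sep - start_sep, stringsAsFactors = FALSE
  )
  attr(out, "n_singers") <- n
  attr(out, "n_pairs") <- nrow(out)
  out
}
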