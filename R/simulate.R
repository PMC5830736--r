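## Synthetic humpback song and movement generators. These emulate the
## statistical structure the analysis assumes — cyclical eventual-variety
## phrase sequences drawn from a shared repertoire of about ten phrase
## types, and singer tracks ranging from near-stationary milling to
## directed travel — so every stage of the pipeline is testable without
## acoustic recordings.

#' Song generator parameters
#'
#' Song is modeled as an eventual-variety Markov sequence: the singer
#' repeats the current phrase type, and at each phrase boundary switches to
#' a new type with probability `switch_prob` (repetition counts are thus
#' geometric, and the expected switching rate equals `switch_prob`, which
#' gives a clean parameter-recovery target). With `cycle_order = TRUE`
#' switches advance cyclically through the repertoire, reproducing the
#' similar theme order shared by singers in a population. Phrase durations
#' are truncated-normal with a 3-s floor, keeping the sequence continuous;
#' occasional surfacing gaps interrupt it.
#'
#' @param repertoire Ordered character vector of phrase types (default 10
#'   types, the most present in a population-wide song at one time).
#' @param phrase_dur_mean_s,phrase_dur_sd_s Phrase duration distribution in
#'   seconds (defaults 15 and 4).
#' @param switch_prob Per-phrase probability of switching type; the
#'   expected switching rate.
#' @param cycle_order If `TRUE`, switches go to the next repertoire type in
#'   cyclic order; otherwise to a uniformly drawn different type.
#' @param gap_prob Per-phrase probability that a surfacing gap follows.
#' @param gap_dur_s Gap duration in seconds.
#' @param seed Optional integer seed (generators draw from the current RNG
#'   stream when `NULL`, so composite simulations stay reproducible under a
#'   single outer seed).
#' @return An object of class `song_gen_params`.
#' @export
song_gen_params <- function(repertoire = sprintf("T%02d", 1:10),
                            phrase_dur_mean_s = 15, phrase_dur_sd_s = 4,
                            switch_prob = 0.15, cycle_order = TRUE,
                            gap_prob = 0.02, gap_dur_s = 20, seed = NULL) {
  if (length(unique(repertoire)) < 2)
    stop_validation("repertoire must contain at least 2 phrase types")
  if (phrase_dur_mean_s <= 0 || phrase_dur_sd_s < 0)
    stop_validation("phrase durations must be positive")
  if (switch_prob <= 0 || switch_prob >= 1)
    stop_validation("switch_prob must be in (0, 1)")
  if (gap_prob < 0 || gap_prob > 1) stop_validation("gap_prob must be in [0, 1]")
  structure(list(repertoire = unique(repertoire),
                 phrase_dur_mean_s = phrase_dur_mean_s,
                 phrase_dur_sd_s = phrase_dur_sd_s,
                 switch_prob = switch_prob, cycle_order = cycle_order,
                 gap_prob = gap_prob, gap_dur_s = gap_dur_s, seed = seed),
            class = "song_gen_params")
}

# One phrase duration, truncated-normal with a 3-s floor.
.phrase_dur <- function(params) {
  max(3, rnorm(1, params$phrase_dur_mean_s, params$phrase_dur_sd_s))
}

# Advance the repertoire index on a switch.
.next_type <- function(params, idx) {
  k <- length(params$repertoire)
  if (params$cycle_order) idx %% k + 1
  else sample(setdiff(seq_len(k), idx), 1)
}

# Core song loop shared by the plain and coupled generators. `pick_type(t,
# idx)` returns the repertoire index to sing at a phrase starting at t.
.simulate_song_loop <- function(params, span_s, singer_id, start_s, pick_type) {
  end_total <- start_s + span_s
  k <- length(params$repertoire)
  idx <- if (params$cycle_order) 1L else sample(k, 1)
  begin <- numeric(0); ende <- numeric(0); type <- character(0)
  t <- start_s
  while (t < end_total) {
    idx <- pick_type(t, idx)
    dur <- .phrase_dur(params)
    e <- min(t + dur, end_total)
    if (e - t >= 1) {
      begin <- c(begin, t); ende <- c(ende, e)
      type <- c(type, params$repertoire[idx])
    }
    t <- t + dur
    if (runif(1) < params$gap_prob) t <- t + params$gap_dur_s
    if (runif(1) < params$switch_prob) idx <- .next_type(params, idx)
  }
  validate_annotations(data.frame(
    singer_id = singer_id, begin_s = round(begin, 3), end_s = round(ende, 3),
    phrase_type = type, stringsAsFactors = FALSE
  ))
}

#' Simulate one singer's song
#'
#' Generates phrase annotations tiling `[start_s, start_s + span_s)` (up to
#' sampled surfacing gaps) under the eventual-variety model of
#' [song_gen_params()].
#'
#' @param params A [song_gen_params()].
#' @param span_s Length of the simulated bout in seconds.
#' @param singer_id Singer label for the annotations.
#' @param start_s Start time of the bout.
#' @return A validated annotation data.frame.
#' @export
simulate_song <- function(params, span_s, singer_id = "S1", start_s = 0) {
  if (span_s <= 0) stop_validation("span_s must be positive")
  if (!is.null(params$seed)) set.seed(params$seed)
  # pick_type keeps the already-advanced Markov state
  .simulate_song_loop(params, span_s, singer_id, start_s,
                      function(t, idx) idx)
}

#' Track generator parameters
#'
#' Tracks are correlated random walks: constant speed, heading perturbed at
#' each step by a normal turn. `turn_sd_rad = 0` gives straight-line travel
#' (meander ratio 1); large values give milling. An optional attraction
#' point biases the heading toward a target, emulating one singer
#' approaching another.
#'
#' @param start_xy Numeric length-2 start position in meters.
#' @param speed_mps Speed in m/s (default 1.0, a typical slow swim).
#' @param turn_sd_rad Turning-angle standard deviation per step, radians.
#' @param target_xy Optional length-2 attraction point in meters.
#' @param target_weight Blend weight in \[0, 1\] pulling the heading toward
#'   the target bearing each step.
#' @param step_s Step length in seconds (default 60).
#' @param heading_rad Optional initial heading; drawn uniformly (or aimed
#'   at the target) when `NULL`.
#' @param seed Optional integer seed.
#' @return An object of class `track_gen_params`.
#' @export
track_gen_params <- function(start_xy = c(0, 0), speed_mps = 1.0,
                             turn_sd_rad = 0.3, target_xy = NULL,
                             target_weight = 0.2, step_s = 60,
                             heading_rad = NULL, seed = NULL) {
  if (speed_mps < 0) stop_validation("speed_mps must be >= 0")
  if (step_s <= 0) stop_validation("step_s must be positive")
  if (turn_sd_rad < 0) stop_validation("turn_sd_rad must be >= 0")
  if (target_weight < 0 || target_weight > 1)
    stop_validation("target_weight must be in [0, 1]")
  structure(list(start_xy = start_xy, speed_mps = speed_mps,
                 turn_sd_rad = turn_sd_rad, target_xy = target_xy,
                 target_weight = target_weight, step_s = step_s,
                 heading_rad = heading_rad, seed = seed),
            class = "track_gen_params")
}

#' Simulate a singer track
#'
#' Correlated random walk per [track_gen_params()], sampled every `step_s`
#' seconds over `[start_s, start_s + span_s]`.
#'
#' @param params A [track_gen_params()].
#' @param span_s Track span in seconds (at least two steps).
#' @param singer_id Singer label.
#' @param start_s Start time.
#' @return A validated track data.frame.
#' @export
simulate_track <- function(params, span_s, singer_id = "S1", start_s = 0) {
  if (span_s < 2 * params$step_s)
    stop_validation("span_s must cover at least two steps")
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- floor(span_s / params$step_s)
  x <- numeric(n + 1); y <- numeric(n + 1)
  x[1] <- params$start_xy[1]; y[1] <- params$start_xy[2]
  heading <- params$heading_rad %||% {
    if (!is.null(params$target_xy))
      atan2(params$target_xy[2] - y[1], params$target_xy[1] - x[1])
    else runif(1, 0, 2 * pi)
  }
  step_len <- params$speed_mps * params$step_s
  for (i in seq_len(n)) {
    heading <- heading + rnorm(1, 0, params$turn_sd_rad)
    if (!is.null(params$target_xy)) {
      bearing <- atan2(params$target_xy[2] - y[i], params$target_xy[1] - x[i])
      # shortest signed angular difference, blended toward the target
      dh <- atan2(sin(bearing - heading), cos(bearing - heading))
      heading <- heading + params$target_weight * dh
    }
    x[i + 1] <- x[i] + step_len * cos(heading)
    y[i + 1] <- y[i] + step_len * sin(heading)
  }
  validate_track(data.frame(
    singer_id = singer_id,
    time_s = start_s + (0:n) * params$step_s,
    x_m = x, y_m = y, stringsAsFactors = FALSE
  ))
}

#' Dyad generator parameters
#'
#' Everything needed to simulate one focal/second pair: song parameters for
#' each singer, the matching coupling, movement parameters, and an optional
#' quit rule. `coupling_m` is the probability that, at each of his phrase
#' starts, the second singer adopts the focal singer's concurrent phrase
#' type (he finishes his current phrase first, as an eventual-variety
#' singer must): 0 gives two independent cyclical songs, 1 makes the second
#' singer copy the focal whenever the focal is audible.
#'
#' @param focal,second [song_gen_params()] for the two singers.
#' @param coupling_m Matching coupling probability in \[0, 1\].
#' @param focal_track,second_track [track_gen_params()] for the two singers.
#' @param quit_rule Optional list `list(threshold_m =, who =)`: when the
#'   separation first drops below `threshold_m` during the DURING period,
#'   the singer named by `who` (`"second"` or `"focal"`) stops singing and
#'   his annotations are truncated there.
#' @param seed Optional integer seed for the whole dyad simulation.
#' @return An object of class `dyad_gen_params`.
#' @export
dyad_gen_params <- function(focal = song_gen_params(),
                            second = song_gen_params(),
                            coupling_m = 0,
                            focal_track = track_gen_params(),
                            second_track = track_gen_params(start_xy = c(3000, 0)),
                            quit_rule = NULL, seed = NULL) {
  if (coupling_m < 0 || coupling_m > 1)
    stop_validation("coupling_m must be in [0, 1]")
  if (!is.null(quit_rule)) {
    if (is.null(quit_rule$threshold_m) || quit_rule$threshold_m <= 0)
      stop_validation("quit_rule$threshold_m must be positive")
    quit_rule$who <- quit_rule$who %||% "second"
    if (!quit_rule$who %in% c("focal", "second"))
      stop_validation("quit_rule$who must be 'focal' or 'second'")
  }
  structure(list(focal = focal, second = second, coupling_m = coupling_m,
                 focal_track = focal_track, second_track = second_track,
                 quit_rule = quit_rule, seed = seed),
            class = "dyad_gen_params")
}

# Phrase type the focal singer produces at time t, or NA in a gap.
.focal_type_at <- function(focal_ann, t) {
  idx <- findInterval(t, focal_ann$begin_s)
  if (idx > 0 && t < focal_ann$end_s[idx]) focal_ann$phrase_type[idx]
  else NA_character_
}

# Truncate a singer's annotations at time t_quit.
.truncate_song <- function(ann, t_quit) {
  ann <- ann[ann$begin_s < t_quit, , drop = FALSE]
  ann$end_s <- pmin(ann$end_s, t_quit)
  ann <- ann[ann$end_s - ann$begin_s >= 1, , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Simulate a focal/second singer dyad
#'
#' The focal singer sings from the start of the BEFORE period through the
#' end of the DURING period; the second singer starts at `scenario$onset_s`.
#' At each second-singer phrase start, with probability `coupling_m` he
#' adopts the focal's concurrent phrase type (if the focal is audible),
#' otherwise his own Markov process continues. Tracks are generated for
#' both singers; if a quit rule is set, the nominated singer's annotations
#' are truncated at the first DURING time the separation falls below the
#' threshold.
#'
#' @param params A [dyad_gen_params()].
#' @param scenario A [dyad_scenario()]; its `seed` is used when
#'   `params$seed` is `NULL`.
#' @return A list with `annotations` (both singers), `tracks` (both
#'   singers), `quit_time_s` (`NA` if nobody quit), and the `scenario`.
#' @export
simulate_dyad <- function(params, scenario) {
  set.seed(params$seed %||% scenario$seed)
  onset <- scenario$onset_s
  before_start <- onset - scenario$before_len_s
  d_end <- onset + scenario$during_len_s
  if (before_start < 0)
    stop_validation("scenario implies a negative before start; increase onset_s")

  # focal song and the coupled second song (draws stay on the outer stream)
  focal_p <- params$focal; focal_p$seed <- NULL
  second_p <- params$second; second_p$seed <- NULL
  focal_ann <- .simulate_song_loop(focal_p, d_end - before_start,
                                   scenario$focal_id, before_start,
                                   function(t, idx) idx)
  repertoire <- params$second$repertoire
  second_ann <- .simulate_song_loop(
    second_p, scenario$during_len_s, scenario$second_id, onset,
    function(t, idx) {
      if (params$coupling_m > 0 && runif(1) < params$coupling_m) {
        ft <- .focal_type_at(focal_ann, t)
        if (!is.na(ft) && ft %in% repertoire) return(match(ft, repertoire))
      }
      idx
    }
  )

  ft_p <- params$focal_track; ft_p$seed <- NULL
  st_p <- params$second_track; st_p$seed <- NULL
  focal_trk <- simulate_track(ft_p, d_end - before_start,
                              scenario$focal_id, before_start)
  second_trk <- simulate_track(st_p, scenario$during_len_s,
                               scenario$second_id, onset)

  quit_time <- NA_real_
  if (!is.null(params$quit_rule)) {
    probe <- seq(onset, d_end, by = min(ft_p$step_s, st_p$step_s))
    seps <- vapply(probe, function(t) separation(focal_trk, second_trk, t),
                   numeric(1))
    hit <- which(seps < params$quit_rule$threshold_m)
    if (length(hit)) {
      quit_time <- probe[hit[1]]
      if (params$quit_rule$who == "second")
        second_ann <- .truncate_song(second_ann, quit_time)
      else
        focal_ann <- .truncate_song(focal_ann, quit_time)
    }
  }

  list(annotations = rbind(focal_ann, second_ann),
       tracks = rbind(focal_trk, second_trk),
       quit_time_s = quit_time, scenario = scenario)
}

#' Simulate a population of solo singers
#'
#' Independent tracks for `n` solo singers, start positions scattered
#' uniformly over a rectangular array footprint (default 6 km x 3 km, a
#' typical nearshore hydrophone-array coverage), returning their start and
#' end positions — the synthetic analogue of a solo-singer endpoint table
#' for building the spatial null.
#'
#' @param n Number of solo singers (at least 2).
#' @param params A [track_gen_params()] template (its `start_xy` and `seed`
#'   are overridden per singer).
#' @param span_s Track span in seconds (default 2700, one 45-min period).
#' @param seed Integer seed.
#' @param footprint_m Numeric length-2 extent of the start-position
#'   scatter, meters.
#' @return An endpoint data.frame (see [read_solo_endpoints()]) with the
#'   full tracks attached as attribute `"tracks"`.
#' @export
simulate_solo_population <- function(n, params = track_gen_params(),
                                     span_s = 2700, seed = 1,
                                     footprint_m = c(6000, 3000)) {
  if (n < 2) stop_validation("at least 2 solo singers required")
  set.seed(seed)
  rows <- vector("list", n)
  tracks <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- NULL
    p$start_xy <- c(runif(1, -footprint_m[1] / 2, footprint_m[1] / 2),
                    runif(1, -footprint_m[2] / 2, footprint_m[2] / 2))
    id <- sprintf("solo%02d", i)
    trk <- simulate_track(p, span_s, singer_id = id)
    tracks[[i]] <- trk
    rows[[i]] <- data.frame(
      singer_id = id,
      start_x_m = trk$x_m[1], start_y_m = trk$y_m[1],
      end_x_m = trk$x_m[nrow(trk)], end_y_m = trk$y_m[nrow(trk)],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "tracks") <- do.call(rbind, tracks)
  out
}
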