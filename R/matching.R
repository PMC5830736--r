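## Phrase-type overlap ("song matching") between two simultaneous singers,
## tested against a Monte Carlo time-shift null. Humpback song is continuous
## and cyclical and all males in a population share the phrase repertoire,
## so some overlap is expected by chance; the null distribution quantifies
## how much, by repeatedly restarting the second singer's sequence at a
## random time and re-measuring the overlap.

#' Sample the phrase-type grid of one singer
#'
#' Which phrase type a singer is producing at each point of a fixed-interval
#' grid (default every 8 s) spanning a window. Grid point `t` takes the
#' phrase type of the annotation covering it (`begin_s <= t < end_s`), or
#' `NA` where the singer is silent (surfacing, or not yet singing).
#'
#' @param ann Validated annotations.
#' @param singer_id Which singer.
#' @param window_start_s,window_end_s Window span; the grid is anchored at
#'   `window_start_s` and has `floor(span / interval_s)` points.
#' @param interval_s Sampling interval in seconds.
#' @return A character vector of phrase types (with `NA` gaps) carrying
#'   attributes `grid_start_s` and `interval_s`.
#' @export
sample_phrase_grid <- function(ann, singer_id, window_start_s, window_end_s,
                               interval_s = 8) {
  if (interval_s <= 0) stop_validation("interval_s must be positive")
  n <- floor((window_end_s - window_start_s) / interval_s)
  t <- window_start_s + (seq_len(n) - 1) * interval_s
  s <- ann[ann$singer_id == singer_id, ]
  s <- s[order(s$begin_s), ]
  labels <- rep(NA_character_, n)
  if (nrow(s) > 0 && n > 0) {
    idx <- findInterval(t, s$begin_s)
    hit <- idx > 0
    hit[hit] <- t[hit] < s$end_s[idx[hit]]
    labels[hit] <- s$phrase_type[idx[hit]]
  }
  structure(labels, grid_start_s = window_start_s, interval_s = interval_s)
}

#' Proportion of co-sampled grid points with matching phrase types
#'
#' Grid points where both singers are audible (neither label is `NA`) are
#' the co-samples; the overlap is the fraction of co-samples at which both
#' singers produce the same phrase type. Reported as a proportion rather
#' than a raw count because time-shifted sequences cover the grid unevenly.
#'
#' @param a,b Grids from [sample_phrase_grid()] on the same grid (same
#'   start, interval and length).
#' @return A list with `proportion` (`NA_real_` when there are no
#'   co-samples) and `n_co_samples`.
#' @export
overlap_proportion <- function(a, b) {
  if (length(a) != length(b) ||
      !isTRUE(all.equal(attr(a, "grid_start_s"), attr(b, "grid_start_s"))) ||
      !isTRUE(all.equal(attr(a, "interval_s"), attr(b, "interval_s"))))
    stop_validation("overlap_proportion requires two series on the same grid")
  co <- !is.na(a) & !is.na(b)
  n_co <- sum(co)
  if (n_co == 0) return(list(proportion = NA_real_, n_co_samples = 0L))
  list(proportion = sum(a[co] == b[co]) / n_co, n_co_samples = n_co)
}

#' Translate a singer's whole song sequence to a new start time
#'
#' Every phrase is shifted by the same offset so that the first phrase
#' begins at `new_start_s`; internal gaps, phrase durations, and the order
#' of phrase types are preserved exactly.
#'
#' @param ann Validated annotations.
#' @param singer_id Which singer's sequence to shift.
#' @param new_start_s Target begin time of the singer's first phrase.
#' @return The singer's annotations, shifted (other singers' rows are not
#'   returned).
#' @export
shift_sequence <- function(ann, singer_id, new_start_s) {
  s <- ann[ann$singer_id == singer_id, , drop = FALSE]
  if (nrow(s) == 0)
    stop_validation("no annotations for singer '%s'", singer_id)
  delta <- new_start_s - min(s$begin_s)
  s$begin_s <- s$begin_s + delta
  s$end_s <- s$end_s + delta
  rownames(s) <- NULL
  s
}

#' Monte Carlo time-shift test of phrase-type overlap
#'
#' Measures the observed overlap between the focal and second singers on an
#' 8-s phrase-type grid over the DURING period, then builds a null
#' distribution by repeatedly (`mc_reps` times) drawing a new start time for
#' the second singer uniformly within the BEFORE period, shifting his entire
#' sequence there (phrase order and timing preserved), and re-measuring the
#' overlap on the same grid. The null is what overlap would look like if the
#' two song sequences were completely independent of one another.
#'
#' P-values use the add-one permutation convention,
#' `p_right = (1 + #\{null >= observed\}) / (1 + reps used)` (and `<=` for
#' `p_left`), so they are never exactly zero. Both tails are reported:
#' a large `p_right` with a small `p_left` indicates matching *avoidance*.
#'
#' A shifted replicate whose sequence barely overlaps the DURING window
#' yields an unstable proportion; replicates with fewer co-samples than
#' `min_co_frac` of the grid length are redrawn (up to `max_redraw` times),
#' after which the replicate is recorded as missing and excluded.
#'
#' @param focal_ann,second_ann Validated annotations for the two singers
#'   (each may contain other singers' rows; only the scenario's ids are
#'   used).
#' @param scenario A [dyad_scenario()]; supplies the window geometry, grid
#'   interval, replicate count and seed.
#' @param before_start_s Start of the BEFORE period, from which null start
#'   times are drawn; defaults to `onset_s - before_len_s`.
#' @param min_co_frac Minimum co-sample fraction for a valid replicate.
#' @param max_redraw Redraw attempts per replicate.
#' @return An object of class `mc_overlap_test`: `observed_overlap`,
#'   `null_overlaps` (length `mc_reps`, `NA` for failed replicates),
#'   `mean_expected_overlap`, `p_right`, `p_left`, `n_co_samples`,
#'   `n_reps_used`, `seed`.
#' @export
mc_overlap_test <- function(focal_ann, second_ann, scenario,
                            before_start_s = scenario$onset_s - scenario$before_len_s,
                            min_co_frac = 0.25, max_redraw = 10) {
  onset <- scenario$onset_s
  ws <- onset
  we <- onset + scenario$during_len_s
  if (before_start_s >= onset)
    stop_validation("before_start_s must precede onset_s")

  ga <- sample_phrase_grid(focal_ann, scenario$focal_id, ws, we,
                           scenario$grid_interval_s)
  gb <- sample_phrase_grid(second_ann, scenario$second_id, ws, we,
                           scenario$grid_interval_s)
  obs <- overlap_proportion(ga, gb)
  if (is.na(obs$proportion))
    stop_degenerate("no co-samples in the DURING window for dyad %s/%s",
                    scenario$focal_id, scenario$second_id)

  second_only <- second_ann[second_ann$singer_id == scenario$second_id, ,
                            drop = FALSE]
  min_co <- min_co_frac * length(ga)
  set.seed(scenario$seed)
  null_overlaps <- rep(NA_real_, scenario$mc_reps)
  for (r in seq_len(scenario$mc_reps)) {
    for (attempt in seq_len(max_redraw)) {
      new_start <- runif(1, before_start_s, onset)
      shifted <- shift_sequence(second_only, scenario$second_id, new_start)
      gs <- sample_phrase_grid(shifted, scenario$second_id, ws, we,
                               scenario$grid_interval_s)
      ov <- overlap_proportion(ga, gs)
      if (ov$n_co_samples >= min_co) {
        null_overlaps[r] <- ov$proportion
        break
      }
    }
  }
  used <- !is.na(null_overlaps)
  n_used <- sum(used)
  if (n_used == 0)
    stop_degenerate("no valid Monte Carlo replicate achieved the minimum co-sample coverage")
  p_right <- (1 + sum(null_overlaps[used] >= obs$proportion)) / (1 + n_used)
  p_left <- (1 + sum(null_overlaps[used] <= obs$proportion)) / (1 + n_used)

  structure(list(
    observed_overlap = obs$proportion,
    null_overlaps = null_overlaps,
    mean_expected_overlap = mean(null_overlaps[used]),
    p_right = p_right, p_left = p_left,
    n_co_samples = obs$n_co_samples,
    n_reps_used = n_used,
    seed = scenario$seed
  ), class = "mc_overlap_test")
}

#' @export
print.mc_overlap_test <- function(x, ...) {
  cat(sprintf("Phrase-type overlap test (%d/%d Monte Carlo replicates used, seed %d)\n",
              x$n_reps_used, length(x$null_overlaps), x$seed))
  cat(sprintf("  observed overlap %.3f vs mean expected %.3f (%d co-samples)\n",
              x$observed_overlap, x$mean_expected_overlap, x$n_co_samples))
  cat(sprintf("  p (right tail, matching) = %.3f; p (left tail, avoidance) = %.3f\n",
              x$p_right, x$p_left))
  invisible(x)
}
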