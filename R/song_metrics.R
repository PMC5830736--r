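## Song-pattern metrics: analysis-window segmentation, phrase-type switching
## rate, and relative song evenness (normalized Shannon entropy), computed
## per 15-min window and averaged per period.

#' Segment the BEFORE and DURING periods into analysis windows
#'
#' DURING windows tile forward from the second singer's onset in
#' `window_len_s` steps, up to `during_len_s` of coverage. BEFORE windows
#' tile backward from the onset, limited both by `before_len_s` and by when
#' the focal singer actually started (`actual_before_start_s`). A leading
#' partial BEFORE window is kept only if it is at least two thirds of
#' `window_len_s` long, so that windows stay comparable; focal singers are
#' not always alone for the full nominal period before the second singer
#' starts, so BEFORE periods shorter than the nominal length are common.
#'
#' @param scenario A [dyad_scenario()].
#' @param actual_before_start_s When the focal singer's analyzable solo song
#'   actually begins (seconds; must precede `onset_s`).
#' @return A data.frame with columns `period` (`"BEFORE"`/`"DURING"`),
#'   `index` (ordinal within period, earliest first), `start_s`, `end_s`.
#' @export
segment_windows <- function(scenario, actual_before_start_s = scenario$onset_s - scenario$before_len_s) {
  onset <- scenario$onset_s
  wl <- scenario$window_len_s
  if (actual_before_start_s >= onset)
    stop_validation("actual_before_start_s must precede onset_s")

  n_during <- floor(scenario$during_len_s / wl)
  during <- data.frame(
    period = "DURING", index = seq_len(n_during),
    start_s = onset + (seq_len(n_during) - 1) * wl,
    end_s = onset + seq_len(n_during) * wl,
    stringsAsFactors = FALSE
  )

  earliest <- max(actual_before_start_s, onset - scenario$before_len_s)
  full_starts <- rev(seq(onset - wl, by = -wl,
                         length.out = floor((onset - earliest) / wl)))
  starts <- full_starts
  ends <- full_starts + wl
  # leading partial window, kept only if >= 2/3 of the window length
  lead <- if (length(full_starts)) full_starts[1] else onset
  if (lead - earliest >= (2 / 3) * wl) {
    starts <- c(earliest, starts)
    ends <- c(lead, ends)
  }
  if (length(starts) == 0)
    stop_validation("insufficient before period: %.0f s available, %.0f s needed",
                    onset - earliest, (2 / 3) * wl)
  before <- data.frame(
    period = "BEFORE", index = seq_along(starts),
    start_s = starts, end_s = ends, stringsAsFactors = FALSE
  )
  rbind(before, during)
}

#' Extract the ordered phrase-type sequence inside a window
#'
#' A phrase belongs to the window whose half-open span `[start_s, end_s)`
#' contains its midpoint — an unambiguous assignment that treats window
#' boundaries symmetrically.
#'
#' @param ann Validated annotations (see [validate_annotations()]).
#' @param singer_id Which singer.
#' @param start_s,end_s Window span in seconds.
#' @return Character vector of phrase types in time order (possibly empty).
#' @export
phrase_sequence_in_window <- function(ann, singer_id, start_s, end_s) {
  s <- ann[ann$singer_id == singer_id, ]
  mid <- (s$begin_s + s$end_s) / 2
  s <- s[mid >= start_s & mid < end_s, ]
  s$phrase_type[order(s$begin_s)]
}

#' Phrase-type switching rate
#'
#' The number of transitions from one phrase type to another divided by one
#' less than the number of phrases: `SR = Tn / (Pn - 1)`, in \[0, 1\]. A
#' singer repeating one phrase type scores 0; one switching at every phrase
#' scores 1.
#'
#' @param sequence Character vector of phrase types in time order.
#' @return The switching rate, or `NA_real_` when fewer than two phrases
#'   make the metric undefined (such windows are excluded from period
#'   averages).
#' @export
switching_rate <- function(sequence) {
  n <- length(sequence)
  if (n < 2) return(NA_real_)
  sum(sequence[-1] != sequence[-n]) / (n - 1)
}

#' Relative song evenness
#'
#' Normalized Shannon entropy of phrase-type proportions over a singer's
#' repertoire: `J' = -sum(p_i * log(p_i)) / log(k)`, where `p_i` is the
#' proportion of phrases of type `i` and `k` the repertoire size, with
#' `0 * log(0) := 0`. The log base cancels; the natural log is used. J' is
#' 1 when every repertoire type is equally represented and 0 when a single
#' type carries all the phrases.
#'
#' Because song changes over time, the repertoire should contain only the
#' phrase types present in the individual's song at the time of recording —
#' in practice the union of types he sang over his analyzed span (see
#' [repertoire_of()]).
#'
#' @param sequence Non-empty character vector of phrase types.
#' @param repertoire Character vector of the singer's phrase types; every
#'   sequence element must be in it.
#' @return J' in \[0, 1\], or `NA_real_` when the repertoire has fewer than
#'   two types (undefined metric).
#' @export
song_evenness <- function(sequence, repertoire) {
  repertoire <- unique(repertoire)
  k <- length(repertoire)
  if (length(sequence) == 0)
    stop_validation("song_evenness requires a non-empty sequence")
  outside <- setdiff(unique(sequence), repertoire)
  if (length(outside))
    stop_validation("phrase type(s) outside repertoire: %s",
                    paste(outside, collapse = ", "))
  if (k < 2) return(NA_real_)
  p <- as.numeric(table(factor(sequence, levels = repertoire))) / length(sequence)
  terms <- ifelse(p > 0, p * log(p), 0)
  -sum(terms) / log(k)
}

#' The observed repertoire of a singer
#'
#' The set of phrase types a singer produced across his analyzed span; used
#' as `k` in [song_evenness()]. For a focal singer the span is BEFORE plus
#' DURING; for a second singer, DURING only.
#'
#' @param ann Validated annotations.
#' @param singer_id Which singer.
#' @param start_s,end_s Optional span limits (midpoint rule, as in
#'   [phrase_sequence_in_window()]); defaults to the singer's full record.
#' @return Sorted character vector of phrase types.
#' @export
repertoire_of <- function(ann, singer_id, start_s = -Inf, end_s = Inf) {
  sort(unique(phrase_sequence_in_window(ann, singer_id, start_s, end_s)))
}

#' Per-window song-pattern metrics
#'
#' @param ann Validated annotations.
#' @param singer_id Which singer.
#' @param windows A window data.frame from [segment_windows()] (possibly
#'   filtered to one period).
#' @param repertoire The singer's repertoire (see [repertoire_of()]).
#' @return A data.frame with one row per window: `singer_id`, `period`,
#'   `index`, `n_phrases`, `n_transitions`, `switching_rate`, `evenness`,
#'   `k`. Metrics are `NA` where undefined (fewer than 2 phrases for SR;
#'   empty window for J').
#' @export
window_metrics <- function(ann, singer_id, windows, repertoire) {
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    seq_i <- phrase_sequence_in_window(ann, singer_id, w$start_s, w$end_s)
    n <- length(seq_i)
    data.frame(
      singer_id = singer_id, period = w$period, index = w$index,
      n_phrases = n,
      n_transitions = if (n >= 2) sum(seq_i[-1] != seq_i[-n]) else NA_integer_,
      switching_rate = switching_rate(seq_i),
      evenness = if (n > 0) song_evenness(seq_i, repertoire) else NA_real_,
      k = length(unique(repertoire)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Period-level song-pattern metrics
#'
#' Window metrics averaged over one period (BEFORE or DURING). Windows where
#' a metric is undefined are recorded but excluded from its mean.
#'
#' @inheritParams window_metrics
#' @param period `"BEFORE"` or `"DURING"`; `windows` is filtered to it.
#' @return A list of class `period_metrics`: `singer_id`, `period`,
#'   `mean_switching_rate`, `mean_evenness`, `windows` (the per-window
#'   data.frame).
#' @export
period_metrics <- function(ann, singer_id, windows, repertoire,
                           period = c("BEFORE", "DURING")) {
  period <- match.arg(period)
  w <- windows[windows$period == period, , drop = FALSE]
  if (nrow(w) == 0) stop_validation("no %s windows supplied", period)
  wm <- window_metrics(ann, singer_id, w, repertoire)
  if (all(is.na(wm$switching_rate)) && all(is.na(wm$evenness)))
    stop_degenerate("all %s windows undefined for singer '%s'", period, singer_id)
  mean_def <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  structure(list(
    singer_id = singer_id, period = period,
    mean_switching_rate = mean_def(wm$switching_rate),
    mean_evenness = mean_def(wm$evenness),
    windows = wm
  ), class = "period_metrics")
}

#' @export
print.period_metrics <- function(x, ...) {
  cat(sprintf("Singer '%s', %s period (%d windows): mean SR = %.3f, mean J' = %.3f\n",
              x$singer_id, x$period, nrow(x$windows),
              x$mean_switching_rate, x$mean_evenness))
  invisible(x)
}
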