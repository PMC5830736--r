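# Small fixture builders shared across the test files.

# A tiny hand-written annotation table: one singer, phrases A, A, B.
tiny_annotations <- function(singer = "F") {
  data.frame(
    singer_id = singer,
    begin_s = c(0, 12, 24),
    end_s = c(12, 24, 40),
    phrase_type = c("A", "A", "B"),
    stringsAsFactors = FALSE
  )
}

# Random millisecond-resolution annotations for round-trip tests: n phrases
# per singer, contiguous with small random gaps.
random_annotations <- function(n, singers = "F", types = LETTERS[1:6]) {
  rows <- lapply(singers, function(id) {
    dur <- round(runif(n, 5, 25), 3)
    gap <- round(ifelse(runif(n) < 0.1, runif(n, 5, 30), 0), 3)
    begin <- cumsum(c(0, (dur + gap)[-n]))
    data.frame(singer_id = id, begin_s = round(begin, 3),
               end_s = round(begin + dur, 3),
               phrase_type = sample(types, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  validate_annotations(do.call(rbind, rows))
}

# A straight-line track at constant speed.
straight_track <- function(id = "S1", n = 10, step_s = 300, speed = 1,
                           heading = 0.3, start = c(0, 0)) {
  t <- (0:n) * step_s
  data.frame(singer_id = id, time_s = t,
             x_m = start[1] + speed * t * cos(heading),
             y_m = start[2] + speed * t * sin(heading),
             stringsAsFactors = FALSE)
}

# Build a grid series by hand (for overlap oracle tests).
grid_series <- function(labels, start = 0, interval = 8) {
  structure(labels, grid_start_s = start, interval_s = interval)
}

# Default small scenario used throughout.
test_scenario <- function(seed = 1, mc_reps = 100, ...) {
  dyad_scenario("F", "S", onset_s = 2700, mc_reps = mc_reps, seed = seed, ...)
}
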