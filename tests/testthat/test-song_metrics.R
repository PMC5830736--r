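test_that("windows tile the BEFORE and DURING periods per the segmentation rule", {
  sc <- test_scenario()

  # full 45-min solo period: three 15-min windows each side of the onset
  w <- segment_windows(sc, 0)
  expect_equal(w$start_s[w$period == "BEFORE"], c(0, 900, 1800))
  expect_equal(w$start_s[w$period == "DURING"], c(2700, 3600, 4500))
  expect_equal(w$end_s - w$start_s, rep(900, 6))

  # focal only solo from 582 s (35.3 min before onset): two full BEFORE
  # windows; the leading 318-s remnant is below the 600-s threshold
  w2 <- segment_windows(sc, 582)
  wb <- w2[w2$period == "BEFORE", ]
  expect_equal(wb$start_s, c(900, 1800))

  # a leading partial window >= 2/3 of the window length is kept
  w3 <- segment_windows(sc, 250)
  expect_equal(w3$start_s[w3$period == "BEFORE"], c(250, 900, 1800))
  expect_equal(w3$end_s[w3$period == "BEFORE"][1], 900)

  # window length equal to the period length gives exactly one DURING window
  sc1 <- dyad_scenario("F", "S", onset_s = 2700, window_len_s = 2700)
  w4 <- segment_windows(sc1, 0)
  expect_equal(sum(w4$period == "DURING"), 1)

  expect_error(segment_windows(sc, 2650), "insufficient before period")
})

test_that("phrases are assigned to windows by their midpoint", {
  # midpoint 905 falls outside [0, 900); midpoint 895 inside
  p1 <- data.frame(singer_id = "F", begin_s = 890, end_s = 920,
                   phrase_type = "A", stringsAsFactors = FALSE)
  p2 <- data.frame(singer_id = "F", begin_s = 880, end_s = 910,
                   phrase_type = "B", stringsAsFactors = FALSE)
  expect_equal(phrase_sequence_in_window(p1, "F", 0, 900), character(0))
  expect_equal(phrase_sequence_in_window(p1, "F", 900, 1800), "A")
  expect_equal(phrase_sequence_in_window(p2, "F", 0, 900), "B")

  # every phrase lands in exactly one window of a tiling (brute force)
  set.seed(5)
  rand <- random_annotations(50)
  tiles <- seq(0, ceiling(max(rand$end_s) / 300) * 300, by = 300)
  counts <- sum(vapply(seq_len(length(tiles) - 1), function(i)
    length(phrase_sequence_in_window(rand, "F", tiles[i], tiles[i + 1])),
    numeric(1)))
  expect_equal(counts, nrow(rand))
})

test_that("switching rate counts adjacent transitions over Pn - 1", {
  expect_equal(switching_rate(c("A", "A", "A", "B", "B", "C")), 0.4)
  expect_equal(switching_rate(rep("A", 4)), 0)
  expect_equal(switching_rate(c("A", "B", "C", "D")), 1)
  expect_true(is.na(switching_rate("A")))

  # brute-force oracle over random sequences, plus relabeling invariance
  set.seed(31)
  for (i in 1:50) {
    s <- sample(LETTERS[1:4], sample(2:40, 1), replace = TRUE)
    brute <- sum(vapply(seq_len(length(s) - 1),
                        function(j) s[j] != s[j + 1], logical(1)))
    expect_equal(switching_rate(s), brute / (length(s) - 1))
    relab <- setNames(sample(letters[1:4]), LETTERS[1:4])
    expect_equal(switching_rate(unname(relab[s])), switching_rate(s))
  }
})

test_that("song evenness is normalized Shannon entropy over the repertoire", {
  expect_equal(song_evenness(rep(c("A", "B"), each = 5), c("A", "B")), 1)
  expect_lt(abs(song_evenness(c(rep("A", 9), "B"), c("A", "B")) - 0.4690),
            1e-3)
  expect_equal(song_evenness(rep("A", 10), c("A", "B")), 0)

  # unused repertoire types count in k and lower J'
  expect_lt(song_evenness(rep(c("A", "B"), 5), c("A", "B", "C")), 1)

  # undefined for k < 2; error for a type outside the repertoire
  expect_true(is.na(song_evenness(rep("A", 3), "A")))
  expect_error(song_evenness(c("A", "Z"), c("A", "B")), "outside repertoire")
  expect_error(song_evenness(character(0), c("A", "B")), "non-empty")

  # label-permutation invariance and the majorization property: moving
  # mass from a rarer to a more common category strictly lowers J'
  set.seed(8)
  for (i in 1:20) {
    counts <- sample(1:20, 4)
    s <- rep(LETTERS[1:4], counts)
    perm <- sample(LETTERS[1:4])
    s2 <- setNames(perm, LETTERS[1:4])[s]
    expect_equal(song_evenness(unname(s2), perm), song_evenness(s, LETTERS[1:4]))
    lo <- which.min(counts); hi <- which.max(counts)
    if (counts[lo] > 1 && lo != hi) {
      counts2 <- counts; counts2[lo] <- counts2[lo] - 1
      counts2[hi] <- counts2[hi] + 1
      expect_lt(song_evenness(rep(LETTERS[1:4], counts2), LETTERS[1:4]),
                song_evenness(s, LETTERS[1:4]))
    }
  }
})

test_that("period metrics average defined windows only", {
  sc <- test_scenario()
  w <- segment_windows(sc, 0)

  # three BEFORE windows engineered to SR 0.1, 0.1, 0.4
  mk <- function(start, seqs) {
    n <- length(seqs)
    data.frame(singer_id = "F", begin_s = start + (0:(n - 1)) * 20,
               end_s = start + (1:n) * 20, phrase_type = seqs,
               stringsAsFactors = FALSE)
  }
  s01 <- c(rep("A", 6), rep("B", 5))                                # 1/10
  s03 <- c(rep("A", 3), rep("B", 3), rep("C", 3), rep("D", 2))      # 3/10
  ann <- validate_annotations(rbind(mk(0, s01), mk(900, s01), mk(1800, s03)))
  pm <- period_metrics(ann, "F", w, c("A", "B", "C", "D"), "BEFORE")
  expect_equal(pm$mean_switching_rate, mean(c(0.1, 0.1, 0.3)))

  # a single defined window carries the period mean
  ann1 <- validate_annotations(mk(0, s01))
  pm1 <- period_metrics(ann1, "F", w, c("A", "B"), "BEFORE")
  expect_equal(pm1$mean_switching_rate, 0.1)
  expect_equal(sum(!is.na(pm1$windows$switching_rate)), 1)

  # all windows empty is degenerate
  expect_error(period_metrics(ann1, "F", w, c("A", "B"), "DURING"),
               class = "songdyad_degenerate_error")
})

test_that("generated songs recover the target switching rate per period", {
  sc <- test_scenario()
  w <- segment_windows(sc, 0)
  wb <- w[w$period == "BEFORE", ]
  set.seed(99)
  # ~80 phrases per 15-min window needs ~11 s phrases; target SR 0.15
  p <- song_gen_params(phrase_dur_mean_s = 11, phrase_dur_sd_s = 2,
                       switch_prob = 0.15, gap_prob = 0)
  ann <- simulate_song(p, 2700, singer_id = "F")
  pm <- period_metrics(ann, "F", wb, p$repertoire)
  expect_lt(abs(pm$mean_switching_rate - 0.15), 0.05)
})
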