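test_that("simulated songs satisfy the annotation invariants and the switching model", {
  p <- song_gen_params(seed = 17)
  ann <- simulate_song(p, 2700)
  expect_true(all(ann$end_s > ann$begin_s))
  expect_true(all(nzchar(ann$phrase_type)))
  expect_true(all(ann$phrase_type %in% p$repertoire))
  # non-overlapping by construction (validate_annotations would error)
  expect_silent(validate_annotations(ann))

  # bit-reproducible under a fixed seed; different under another
  expect_identical(simulate_song(p, 2700), ann)
  expect_false(identical(simulate_song(song_gen_params(seed = 18), 2700), ann))

  # near-degenerate switching probabilities force SR toward the extremes
  hi <- simulate_song(song_gen_params(switch_prob = 0.999, gap_prob = 0,
                                      seed = 4), 2700)
  expect_gt(switching_rate(hi$phrase_type), 0.99)
  lo <- simulate_song(song_gen_params(switch_prob = 1e-6, gap_prob = 0,
                                      seed = 4), 2700)
  expect_equal(switching_rate(lo$phrase_type), 0)
  expect_equal(length(unique(lo$phrase_type)), 1)
})

test_that("realized switching rate converges to the switch probability", {
  set.seed(50)
  sr <- vapply(1:50, function(i) {
    ann <- simulate_song(song_gen_params(switch_prob = 0.15, gap_prob = 0),
                         2700)
    switching_rate(ann$phrase_type)
  }, numeric(1))
  expect_lt(abs(mean(sr) - 0.15), 0.03)

  # evenness of a cyclical singer rises with the switching probability
  set.seed(51)
  j_of <- function(sp) {
    p <- song_gen_params(switch_prob = sp, gap_prob = 0)
    mean(vapply(1:10, function(i)
      song_evenness(simulate_song(p, 2700)$phrase_type, p$repertoire),
      numeric(1)))
  }
  j <- vapply(c(0.05, 0.15, 0.4), j_of, numeric(1))
  expect_true(all(diff(j) > 0))
})

test_that("simulated tracks follow the correlated-random-walk contract", {
  # zero turning and no target: straight line, meander ratio 1
  st <- simulate_track(track_gen_params(turn_sd_rad = 0, seed = 1), 2700)
  expect_equal(meander_ratio(st, 0, 2700)$ratio, 1)

  # zero speed: stationary, meander undefined
  z <- simulate_track(track_gen_params(speed_mps = 0, seed = 1), 2700)
  expect_true(is.na(meander_ratio(z, 0, 2700)$ratio))

  # heavy turning: strongly meandering paths
  set.seed(52)
  med <- stats::median(vapply(1:50, function(i) {
    trk <- simulate_track(track_gen_params(turn_sd_rad = 1.5), 2700)
    meander_ratio(trk, 0, 2700)$ratio
  }, numeric(1)), na.rm = TRUE)
  expect_gt(med, 2)

  # target attraction closes the distance to the target
  tw <- simulate_track(track_gen_params(start_xy = c(0, 0), turn_sd_rad = 0.2,
                                        target_xy = c(2000, 0),
                                        target_weight = 0.5, seed = 3), 2700)
  d0 <- sqrt(sum((c(tw$x_m[1], tw$y_m[1]) - c(2000, 0))^2))
  d1 <- sqrt(sum((c(tw$x_m[nrow(tw)], tw$y_m[nrow(tw)]) - c(2000, 0))^2))
  expect_lt(d1, d0)

  expect_identical(simulate_track(track_gen_params(seed = 5), 2700),
                   simulate_track(track_gen_params(seed = 5), 2700))
  expect_error(simulate_track(track_gen_params(step_s = 60), 60),
               "two steps")
})

test_that("dyad simulation honors onset, coupling and the quit rule", {
  sc <- test_scenario(seed = 30)
  sim <- simulate_dyad(dyad_gen_params(coupling_m = 0), sc)
  sec <- sim$annotations[sim$annotations$singer_id == "S", ]
  foc <- sim$annotations[sim$annotations$singer_id == "F", ]
  expect_gte(min(sec$begin_s), sc$onset_s)
  expect_equal(min(foc$begin_s), 0)
  expect_true(is.na(sim$quit_time_s))

  # identical seeds give identical dyads
  expect_identical(simulate_dyad(dyad_gen_params(coupling_m = 0), sc), sim)

  # full coupling with no gaps: the second singer's grid labels equal the
  # focal's almost everywhere he is audible
  sc2 <- test_scenario(seed = 31)
  simc <- simulate_dyad(dyad_gen_params(
    coupling_m = 1,
    focal = song_gen_params(gap_prob = 0),
    second = song_gen_params(gap_prob = 0)), sc2)
  ga <- sample_phrase_grid(simc$annotations, "F", 2700, 5400, 8)
  gb <- sample_phrase_grid(simc$annotations, "S", 2700, 5400, 8)
  expect_gt(overlap_proportion(ga, gb)$proportion, 0.8)

  # approaching tracks with a quit rule truncate the second singer's song
  # at the first sub-threshold separation
  sc3 <- test_scenario(seed = 32)
  simq <- simulate_dyad(dyad_gen_params(
    coupling_m = 0,
    focal_track = track_gen_params(speed_mps = 0, start_xy = c(0, 0)),
    second_track = track_gen_params(start_xy = c(3000, 0),
                                    target_xy = c(0, 0), target_weight = 1,
                                    turn_sd_rad = 0.05),
    quit_rule = list(threshold_m = 1000, who = "second")), sc3)
  expect_false(is.na(simq$quit_time_s))
  tf <- simq$tracks[simq$tracks$singer_id == "F", ]
  ts <- simq$tracks[simq$tracks$singer_id == "S", ]
  expect_lt(separation(tf, ts, simq$quit_time_s), 1000)
  sq <- simq$annotations[simq$annotations$singer_id == "S", ]
  expect_lte(max(sq$end_s), simq$quit_time_s)
})

test_that("solo populations scatter starts over the array footprint reproducibly", {
  ep <- simulate_solo_population(18, seed = 8)
  expect_equal(nrow(ep), 18)
  expect_true(all(abs(ep$start_x_m) <= 3000))
  expect_true(all(abs(ep$start_y_m) <= 1500))
  expect_identical(simulate_solo_population(18, seed = 8), ep)
  expect_false(identical(simulate_solo_population(18, seed = 9)$start_x_m,
                         ep$start_x_m))
  expect_error(simulate_solo_population(1, seed = 1), "at least 2")
})
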