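test_that("track interpolation is linear, clipped, and idempotent", {
  trk <- data.frame(singer_id = "A", time_s = c(0, 300),
                    x_m = c(0, 300), y_m = c(0, 0))
  gi <- interpolate_track(trk, 150)
  expect_equal(gi$x_m, c(0, 150, 300))
  expect_equal(gi$y_m, c(0, 0, 0))

  # grid equal to the sample times reproduces the samples
  st <- straight_track(n = 5, step_s = 150)
  expect_equal(interpolate_track(st, 150), st, ignore_attr = TRUE)

  # interpolated points lie on the original segments (geometric oracle)
  set.seed(14)
  rough <- simulate_track(track_gen_params(turn_sd_rad = 1), 3000)
  gi2 <- interpolate_track(rough, 100)
  seg_dist <- vapply(seq_len(nrow(gi2)), function(i) {
    t <- gi2$time_s[i]
    k <- findInterval(t, rough$time_s, rightmost.closed = TRUE)
    p0 <- c(rough$x_m[k], rough$y_m[k]); p1 <- c(rough$x_m[k + 1], rough$y_m[k + 1])
    u <- (t - rough$time_s[k]) / diff(rough$time_s[k + (0:1)])
    sqrt(sum((p0 + u * (p1 - p0) - c(gi2$x_m[i], gi2$y_m[i]))^2))
  }, numeric(1))
  expect_lt(max(seg_dist), 1e-8)

  # idempotent on its own grid; single-sample tracks are an error
  expect_equal(interpolate_track(gi2, 100), gi2)
  expect_error(interpolate_track(trk[1, ], 100), "at least 2")
})

test_that("separation is the Euclidean distance between interpolated positions", {
  a <- data.frame(singer_id = "A", time_s = c(0, 100), x_m = 0, y_m = 0)
  b <- data.frame(singer_id = "B", time_s = c(0, 100), x_m = 3, y_m = 4)
  expect_equal(separation(a, b, 50), 5)
  expect_equal(separation(a, a, 50), 0)
  expect_error(separation(a, b, 200), "outside the span")

  # brute-force oracle at random times on random tracks
  set.seed(20)
  ta <- simulate_track(track_gen_params(turn_sd_rad = 0.8), 3000, "A")
  tb <- simulate_track(track_gen_params(turn_sd_rad = 0.8,
                                        start_xy = c(500, -200)), 3000, "B")
  for (t in runif(20, 0, 3000)) {
    pa <- c(approx(ta$time_s, ta$x_m, t)$y, approx(ta$time_s, ta$y_m, t)$y)
    pb <- c(approx(tb$time_s, tb$x_m, t)$y, approx(tb$time_s, tb$y_m, t)$y)
    expect_equal(separation(ta, tb, t), sqrt(sum((pa - pb)^2)))
  }
})

test_that("dyad separation statistics are symmetric and signed correctly", {
  # stationary pair: delta 0
  a <- data.frame(singer_id = "A", time_s = c(0, 2700), x_m = 0, y_m = 0)
  b <- data.frame(singer_id = "B", time_s = c(0, 2700), x_m = 1000, y_m = 0)
  sp <- dyad_spatial(a, b, 0, 2700)
  expect_equal(sp$delta_m, 0)

  # approach from 2000 m to 500 m: delta -1500
  b2 <- data.frame(singer_id = "B", time_s = c(0, 2700),
                   x_m = c(2000, 500), y_m = 0)
  sp2 <- dyad_spatial(a, b2, 0, 2700)
  expect_equal(sp2$start_sep_m, 2000)
  expect_equal(sp2$end_sep_m, 500)
  expect_equal(sp2$delta_m, -1500)

  # symmetric swap keeps the separation fields identical; argument order
  # only relabels the ids
  sp3 <- dyad_spatial(b2, a, 0, 2700)
  expect_equal(sp3[, c("start_sep_m", "end_sep_m", "delta_m")],
               sp2[, c("start_sep_m", "end_sep_m", "delta_m")])

  # endpoint within tolerance uses the nearest covered time; beyond errors
  short <- data.frame(singer_id = "B", time_s = c(100, 2600),
                      x_m = c(2000, 500), y_m = 0)
  expect_equal(dyad_spatial(a, short, 0, 2700)$delta_m, -1500)
  far <- data.frame(singer_id = "B", time_s = c(700, 2600),
                    x_m = c(2000, 500), y_m = 0)
  expect_error(dyad_spatial(a, far, 0, 2700), "singer 'B'.*window start")
})

test_that("meander ratio is path over chord at 5-min bin boundaries", {
  # straight-line constant-speed track: exactly 1
  st <- straight_track(n = 9, step_s = 300)
  m <- meander_ratio(st, 0, 2700)
  expect_equal(m$ratio, 1)

  # L-shaped path: boundary positions (0,0) -> (300,0) -> (300,400)
  lt <- data.frame(singer_id = "L", time_s = c(0, 300, 600),
                   x_m = c(0, 300, 300), y_m = c(0, 0, 400))
  ml <- meander_ratio(lt, 0, 600, bin_s = 300)
  expect_equal(ml$path_m, 700)
  expect_equal(ml$chord_m, 500)
  expect_equal(ml$ratio, 1.4)

  # returning to the start (chord below the 1-m threshold): undefined
  loop <- data.frame(singer_id = "O", time_s = c(0, 300, 600),
                     x_m = c(0, 400, 0), y_m = c(0, 300, 0))
  expect_true(is.na(meander_ratio(loop, 0, 600, bin_s = 300)$ratio))

  # path >= chord over random tracks (triangle inequality)
  set.seed(44)
  for (i in 1:10) {
    trk <- simulate_track(track_gen_params(turn_sd_rad = runif(1, 0, 1.5)), 2700)
    mm <- meander_ratio(trk, 0, 2700)
    expect_gte(mm$path_m, mm$chord_m - 1e-9)
    if (!is.na(mm$ratio)) expect_gte(mm$ratio, 1 - 1e-12)
  }

  expect_error(meander_ratio(st, 0, 200), "shorter than one bin")
})

test_that("the solo pairwise null enumerates all C(n,2) superimposed pairs", {
  ep18 <- simulate_solo_population(18, seed = 2)
  np <- solo_pairwise_null(ep18)
  expect_equal(nrow(np), 153)
  expect_equal(attr(np, "n_pairs"), 153)

  ep2 <- simulate_solo_population(2, seed = 2)
  expect_equal(nrow(solo_pairwise_null(ep2)), 1)

  # brute-force oracle for the pair means on 5 singers
  ep5 <- simulate_solo_population(5, seed = 9)
  np5 <- solo_pairwise_null(ep5)
  expect_equal(nrow(np5), 10)
  brute <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    s <- sqrt((ep5$start_x_m[i] - ep5$start_x_m[j])^2 +
              (ep5$start_y_m[i] - ep5$start_y_m[j])^2)
    e <- sqrt((ep5$end_x_m[i] - ep5$end_x_m[j])^2 +
              (ep5$end_y_m[i] - ep5$end_y_m[j])^2)
    brute <- rbind(brute, c(s, e, e - s))
  }
  expect_equal(np5$start_sep_m, brute[, 1])
  expect_equal(np5$end_sep_m, brute[, 2])
  expect_equal(mean(np5$delta_m), mean(brute[, 3]))

  # stationary population: all deltas zero
  eps <- simulate_solo_population(4, track_gen_params(speed_mps = 0), seed = 1)
  expect_true(all(solo_pairwise_null(eps)$delta_m == 0))

  ep_dup <- ep5; ep_dup$singer_id[2] <- ep_dup$singer_id[1]
  expect_error(solo_pairwise_null(ep_dup), "duplicate")
})
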