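## Study orchestration: run every analysis stage over a set of dyads plus a
## solo-singer population, applying the per-dyad exclusion rules, and emit
## the report tables (song-pattern means and paired tests; per-dyad matching
## results; spatial observed-vs-null comparisons; the quit analysis; meander
## ratios and their tests).

#' Classify the outcome of a dyad's DURING period
#'
#' A singer "quit" if his last annotation ends more than `tol_s` (default
#' 120 s) before the end of the DURING window — the tolerance separates a
#' final surfacing gap from actual song cessation. When both singers quit,
#' the earlier quitter names the outcome.
#'
#' @param focal_ann,second_ann Validated annotations.
#' @param scenario A [dyad_scenario()].
#' @param tol_s Cessation tolerance in seconds.
#' @return One of `"both_continued"`, `"focal_quit"`, `"second_quit"`.
#' @export
classify_dyad_outcome <- function(focal_ann, second_ann, scenario, tol_s = 120) {
  d_end <- scenario$onset_s + scenario$during_len_s
  last_of <- function(ann, id) {
    e <- ann$end_s[ann$singer_id == id]
    if (length(e) == 0) -Inf else max(e)
  }
  last_f <- last_of(focal_ann, scenario$focal_id)
  last_s <- last_of(second_ann, scenario$second_id)
  f_quit <- last_f < d_end - tol_s
  s_quit <- last_s < d_end - tol_s
  if (f_quit && s_quit) return(if (last_f <= last_s) "focal_quit" else "second_quit")
  if (f_quit) return("focal_quit")
  if (s_quit) return("second_quit")
  "both_continued"
}

# Record an exclusion row.
.exclusion <- function(dyad_id, analysis, reason) {
  data.frame(dyad_id = dyad_id, analysis = analysis, reason = reason,
             stringsAsFactors = FALSE)
}

# NA-safe wrapper: run a test, return NA result on degenerate input.
.try_test <- function(expr) {
  tryCatch(expr, songdyad_degenerate_error = function(e) NULL)
}

.test_row <- function(comparison, res) {
  if (is.null(res))
    return(data.frame(comparison = comparison, test = NA_character_,
                      statistic = NA_real_, n = NA_integer_,
                      p_two = NA_real_, p_one = NA_real_,
                      stringsAsFactors = FALSE))
  data.frame(comparison = comparison, test = res$test_name,
             statistic = res$statistic, n = res$n[1],
             p_two = res$p_two, p_one = res$p_one,
             stringsAsFactors = FALSE)
}

#' Run the full dyad-interaction study
#'
#' Executes every analysis stage for a set of dyads and a solo-singer
#' endpoint table, applying the exclusion rules (a focal singer who quits
#' before half of the DURING period excludes the dyad from song-pattern and
#' matching analyses but not from the spatial tables; a second singer who
#' quits before half of DURING excludes the dyad from matching only, since
#' the time-shift null cannot decorrelate so short a sequence; dyads
#' flagged `poor_quality` have their second singer excluded from
#' song-pattern and matching analyses). Every input dyad appears either in
#' each applicable
#' table or in the exclusion table with a reason. The run is a pure
#' function of its inputs and the scenario seeds.
#'
#' @param dyads A named list; each element a list with `scenario` (a
#'   [dyad_scenario()]), `annotations`, `tracks`, and optionally
#'   `before_start_s` (defaults to `onset_s - before_len_s`) and flags
#'   `poor_quality` (logical).
#' @param solo_endpoints Solo-singer endpoint data.frame (see
#'   [read_solo_endpoints()]); `NULL` skips the spatial null comparisons.
#' @param out_dir Optional directory; when given, all tables are written as
#'   TSV plus a JSON run manifest.
#' @param quit_tol_s Cessation tolerance passed to
#'   [classify_dyad_outcome()].
#' @return An object of class `study_report`: `song_windows`, `table1`,
#'   `song_tests`, `table2`, `spatial`, `spatial_tests`, `quit_analysis`,
#'   `meander`, `meander_tests`, `null_pairs`, `exclusions`.
#' @export
run_study <- function(dyads, solo_endpoints = NULL, out_dir = NULL,
                      quit_tol_s = 120) {
  if (length(dyads) < 1) stop_validation("at least one dyad required")
  if (is.null(names(dyads)) || any(!nzchar(names(dyads))))
    names(dyads) <- sprintf("dyad%02d", seq_along(dyads))

  excl <- list()
  song_rows <- list(); win_rows <- list(); match_rows <- list()
  spat_rows <- list(); meander_rows <- list(); outcome_rows <- list()

  for (id in names(dyads)) {
    d <- dyads[[id]]
    sc <- d$scenario
    ann <- validate_annotations(d$annotations)
    trk <- validate_track(d$tracks)
    before_start <- d$before_start_s %||% (sc$onset_s - sc$before_len_s)
    outcome <- classify_dyad_outcome(ann, ann, sc, tol_s = quit_tol_s)

    # how much of DURING did each singer cover?
    d_end <- sc$onset_s + sc$during_len_s
    sung_frac <- function(sid) {
      e <- ann$end_s[ann$singer_id == sid]
      if (length(e) == 0) 0 else (max(e) - sc$onset_s) / sc$during_len_s
    }
    focal_early_quit <- outcome == "focal_quit" && sung_frac(sc$focal_id) < 0.5
    # a second singer covering less than half of DURING leaves the time-shift
    # null too few admissible start times to decorrelate the cycle phase, so
    # such dyads are excluded from matching (not from song patterns)
    second_early_quit <- sung_frac(sc$second_id) < 0.5
    poor <- isTRUE(d$poor_quality)

    outcome_rows[[id]] <- data.frame(dyad_id = id, outcome = outcome,
                                     stringsAsFactors = FALSE)

    ## --- song-pattern metrics -------------------------------------------
    if (focal_early_quit) {
      excl[[length(excl) + 1]] <-
        .exclusion(id, "song_pattern", "focal quit before 50% of DURING")
      excl[[length(excl) + 1]] <-
        .exclusion(id, "matching", "focal quit before 50% of DURING")
    } else {
      windows <- segment_windows(sc, before_start)
      rep_focal <- repertoire_of(ann, sc$focal_id)
      rep_second <- repertoire_of(ann, sc$second_id, sc$onset_s, d_end)
      pm <- function(sid, repertoire, period) {
        tryCatch(period_metrics(ann, sid, windows, repertoire, period),
                 songdyad_degenerate_error = function(e) NULL,
                 songdyad_validation_error = function(e) NULL)
      }
      fb <- pm(sc$focal_id, rep_focal, "BEFORE")
      fd <- pm(sc$focal_id, rep_focal, "DURING")
      sd_ <- if (poor) NULL else pm(sc$second_id, rep_second, "DURING")
      if (poor)
        excl[[length(excl) + 1]] <-
          .exclusion(id, "song_pattern_second", "poor recording quality")
      row <- data.frame(
        dyad_id = id,
        focal_sr_before = if (is.null(fb)) NA_real_ else fb$mean_switching_rate,
        focal_sr_during = if (is.null(fd)) NA_real_ else fd$mean_switching_rate,
        second_sr_during = if (is.null(sd_)) NA_real_ else sd_$mean_switching_rate,
        focal_j_before = if (is.null(fb)) NA_real_ else fb$mean_evenness,
        focal_j_during = if (is.null(fd)) NA_real_ else fd$mean_evenness,
        second_j_during = if (is.null(sd_)) NA_real_ else sd_$mean_evenness,
        stringsAsFactors = FALSE
      )
      song_rows[[id]] <- row
      wins <- list()
      if (!is.null(fb)) wins <- c(wins, list(fb$windows))
      if (!is.null(fd)) wins <- c(wins, list(fd$windows))
      if (!is.null(sd_)) wins <- c(wins, list(sd_$windows))
      if (length(wins)) {
        w <- do.call(rbind, wins)
        w <- cbind(dyad_id = id, w)
        win_rows[[id]] <- w
      }

      ## --- matching -----------------------------------------------------
      if (poor) {
        excl[[length(excl) + 1]] <-
          .exclusion(id, "matching", "poor recording quality")
      } else if (second_early_quit) {
        excl[[length(excl) + 1]] <-
          .exclusion(id, "matching", "second singer quit before 50% of DURING")
      } else {
        mt <- tryCatch(
          mc_overlap_test(ann, ann, sc, before_start_s = before_start),
          songdyad_degenerate_error = function(e) NULL,
          songdyad_validation_error = function(e) NULL)
        if (is.null(mt)) {
          excl[[length(excl) + 1]] <-
            .exclusion(id, "matching", "no co-sampled DURING coverage")
        } else {
          match_rows[[id]] <- data.frame(
            dyad_id = id,
            mean_expected_overlap = mt$mean_expected_overlap,
            observed_overlap = mt$observed_overlap,
            p_right = mt$p_right, p_left = mt$p_left,
            n_reps_used = mt$n_reps_used, seed = mt$seed,
            stringsAsFactors = FALSE
          )
        }
      }
    }

    ## --- movement -------------------------------------------------------
    tf <- trk[trk$singer_id == sc$focal_id, ]
    ts <- trk[trk$singer_id == sc$second_id, ]
    sp <- tryCatch(dyad_spatial(tf, ts, sc$onset_s, d_end),
                   songdyad_validation_error = function(e) NULL)
    if (is.null(sp)) {
      excl[[length(excl) + 1]] <-
        .exclusion(id, "spatial", "track does not cover the DURING window")
    } else {
      spat_rows[[id]] <- cbind(dyad_id = id, sp,
                               outcome = outcome, stringsAsFactors = FALSE)
    }
    mr <- function(t, ws, we, sid, period) {
      m <- tryCatch(meander_ratio(t, ws, we),
                    songdyad_validation_error = function(e) NULL)
      if (is.null(m)) return(NULL)
      data.frame(dyad_id = id, singer_id = sid, period = period,
                 path_m = m$path_m, chord_m = m$chord_m, ratio = m$ratio,
                 stringsAsFactors = FALSE)
    }
    meander_rows[[paste0(id, "_fb")]] <-
      mr(tf, before_start, sc$onset_s, sc$focal_id, "BEFORE")
    meander_rows[[paste0(id, "_fd")]] <-
      mr(tf, sc$onset_s, d_end, sc$focal_id, "DURING")
    meander_rows[[paste0(id, "_sd")]] <-
      mr(ts, sc$onset_s, d_end, sc$second_id, "DURING")
  }

  table1 <- do.call(rbind, song_rows)
  song_windows <- do.call(rbind, win_rows)
  table2 <- do.call(rbind, match_rows)
  spatial <- do.call(rbind, spat_rows)
  meander <- do.call(rbind, meander_rows)
  rownames(table1) <- rownames(table2) <- rownames(spatial) <- NULL
  if (!is.null(meander)) rownames(meander) <- NULL

  ## --- pooled song-pattern tests (arcsine-transformed proportions) ------
  song_tests <- NULL
  if (!is.null(table1)) {
    cc <- function(x, y) {
      ok <- !is.na(x) & !is.na(y)
      list(x = x[ok], y = y[ok])
    }
    tests <- list()
    p1 <- cc(table1$focal_sr_before, table1$focal_sr_during)
    tests[["focal SR: BEFORE vs DURING"]] <- if (length(p1$x) >= 3)
      .try_test(paired_t(arcsine_sqrt(p1$x), arcsine_sqrt(p1$y), "less"))
    p2 <- cc(table1$focal_j_before, table1$focal_j_during)
    tests[["focal J': BEFORE vs DURING"]] <- if (length(p2$x) >= 3)
      .try_test(paired_t(arcsine_sqrt(p2$x), arcsine_sqrt(p2$y), "less"))
    p3 <- cc(table1$focal_sr_during, table1$second_sr_during)
    tests[["focal vs second SR: DURING"]] <- if (length(p3$x) >= 3)
      .try_test(paired_t(arcsine_sqrt(p3$x), arcsine_sqrt(p3$y), "greater"))
    p4 <- cc(table1$focal_j_during, table1$second_j_during)
    tests[["focal vs second J': DURING"]] <- if (length(p4$x) >= 3)
      .try_test(paired_t(arcsine_sqrt(p4$x), arcsine_sqrt(p4$y), "greater"))
    song_tests <- do.call(rbind, lapply(names(tests), function(nm)
      .test_row(nm, tests[[nm]])))
  }

  ## --- spatial null comparisons ------------------------------------------
  null_pairs <- NULL
  spatial_tests <- NULL
  if (!is.null(solo_endpoints) && !is.null(spatial)) {
    null_pairs <- solo_pairwise_null(solo_endpoints)
    spatial_tests <- rbind(
      .test_row("start separation: observed vs null",
                .try_test(ks_two_sample(spatial$start_sep_m, null_pairs$start_sep_m))),
      .test_row("end separation: observed vs null",
                .try_test(ks_two_sample(spatial$end_sep_m, null_pairs$end_sep_m))),
      .test_row("change in distance: observed vs null",
                .try_test(ks_two_sample(spatial$delta_m, null_pairs$delta_m)))
    )
  }

  ## --- quit analysis -----------------------------------------------------
  quit_analysis <- NULL
  if (!is.null(spatial)) {
    quit <- spatial$outcome != "both_continued"
    res <- if (sum(quit) >= 1 && sum(!quit) >= 1 && nrow(spatial) >= 4)
      .try_test(mann_whitney_u(spatial$delta_m[quit], spatial$delta_m[!quit],
                               "less"))
    quit_analysis <- list(
      groups = data.frame(
        group = c("one_quit", "both_continued"),
        n = c(sum(quit), sum(!quit)),
        mean_delta_m = c(mean(spatial$delta_m[quit]),
                         mean(spatial$delta_m[!quit])),
        stringsAsFactors = FALSE
      ),
      test = .test_row("change in distance: one quit vs both continued", res)
    )
  }

  ## --- meander tests -----------------------------------------------------
  meander_tests <- NULL
  if (!is.null(meander)) {
    fb <- meander[meander$period == "BEFORE", c("dyad_id", "ratio")]
    fid <- vapply(names(dyads), function(i) dyads[[i]]$scenario$focal_id,
                  character(1))
    fd <- meander[meander$period == "DURING" &
                    meander$singer_id == fid[meander$dyad_id], ,
                  drop = FALSE][, c("dyad_id", "ratio")]
    m1 <- merge(fb, fd, by = "dyad_id", suffixes = c("_before", "_during"))
    m1 <- m1[!is.na(m1$ratio_before) & !is.na(m1$ratio_during), ]
    w_res <- if (nrow(m1) >= 5)
      .try_test(wilcoxon_signed_rank(m1$ratio_before, m1$ratio_during, "less"))
    sec <- meander[meander$period == "DURING" &
                     meander$singer_id != fid[meander$dyad_id], , drop = FALSE]
    u_res <- if (nrow(fd) >= 2 && nrow(sec) >= 2)
      .try_test(mann_whitney_u(fd$ratio[!is.na(fd$ratio)],
                               sec$ratio[!is.na(sec$ratio)], "greater"))
    meander_tests <- rbind(
      .test_row("focal meander: BEFORE vs DURING", w_res),
      .test_row("meander DURING: focal vs second", u_res)
    )
  }

  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(dyad_id = character(0), analysis = character(0),
               reason = character(0), stringsAsFactors = FALSE)

  report <- structure(list(
    song_windows = song_windows, table1 = table1, song_tests = song_tests,
    table2 = table2, spatial = spatial, spatial_tests = spatial_tests,
    quit_analysis = quit_analysis, meander = meander,
    meander_tests = meander_tests, null_pairs = null_pairs,
    outcomes = do.call(rbind, outcome_rows),
    exclusions = exclusions
  ), class = "study_report")

  if (!is.null(out_dir)) write_study_report(report, dyads, out_dir)
  report
}

#' Write a study report to disk
#'
#' Emits every report table as TSV plus a JSON run manifest (dyad ids,
#' seeds, parameters, exclusions), so that a run can be audited and
#' regenerated.
#'
#' @param report A `study_report` from [run_study()].
#' @param dyads The dyad list the report was computed from.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, dyads, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$song_windows, "song_windows")
  wt(report$table1, "table1_song_patterns")
  wt(report$song_tests, "song_tests")
  wt(report$table2, "table2_matching")
  wt(report$spatial, "spatial_observed")
  wt(report$null_pairs, "spatial_null_pairs")
  wt(report$spatial_tests, "spatial_tests")
  wt(report$meander, "meander")
  wt(report$meander_tests, "meander_tests")
  wt(report$outcomes, "outcomes")
  wt(report$exclusions, "exclusions")
  if (!is.null(report$quit_analysis)) {
    wt(report$quit_analysis$groups, "quit_groups")
    wt(report$quit_analysis$test, "quit_test")
  }
  manifest <- list(
    n_dyads = length(dyads),
    dyads = lapply(dyads, function(d) list(
      focal_id = d$scenario$focal_id, second_id = d$scenario$second_id,
      onset_s = d$scenario$onset_s, mc_reps = d$scenario$mc_reps,
      seed = d$scenario$seed,
      poor_quality = isTRUE(d$poor_quality)
    )),
    exclusions = report$exclusions
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Singer-dyad study report\n")
  if (!is.null(x$table1))
    cat(sprintf("  song patterns: %d dyads\n", nrow(x$table1)))
  if (!is.null(x$table2))
    cat(sprintf("  matching: %d dyads analyzed\n", nrow(x$table2)))
  if (!is.null(x$spatial))
    cat(sprintf("  spatial: %d dyads (%s)\n", nrow(x$spatial),
                paste(sprintf("%s=%d", names(table(x$spatial$outcome)),
                              as.integer(table(x$spatial$outcome))),
                      collapse = ", ")))
  if (!is.null(x$null_pairs))
    cat(sprintf("  spatial null: %d pairs from %d solo singers\n",
                attr(x$null_pairs, "n_pairs"), attr(x$null_pairs, "n_singers")))
  if (nrow(x$exclusions))
    cat(sprintf("  exclusions: %d (see $exclusions)\n", nrow(x$exclusions)))
  invisible(x)
}
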