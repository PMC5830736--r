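#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study population.
#
# Eleven focal/second dyads plus eighteen solo singers, mirroring the shape
# of a passive-acoustic singer-interaction study: most dyads keep singing
# through the 45-min DURING period, two dyads countersing with strong
# phrase-type coupling, three dyads involve a close approach under a quit
# rule (one of them with the focal singer quitting early enough to be
# excluded from the song-pattern analyses), and two dyads carry a
# poor-recording-quality flag for their second singer. All files are
# written as plain text under results/data/.

suppressMessages(library(songdyad))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
base_seed <- 42

dyad_specs <- data.frame(
  id = sprintf("dyad%02d", 1:11),
  coupling = c(0, 0, 0.9, 0, 0, 0.9, 0, 0, 0, 0, 0),
  quit_who = c(rep("", 8), "second", "focal", "second"),
  poor_quality = c(FALSE, FALSE, FALSE, TRUE, TRUE, rep(FALSE, 6)),
  # one dyad with a BEFORE period of only ~35 min
  before_start_s = c(582, rep(0, 10)),
  stringsAsFactors = FALSE
)

for (i in seq_len(nrow(dyad_specs))) {
  sp <- dyad_specs[i, ]
  sc <- dyad_scenario(sprintf("F%02d", i), sprintf("S%02d", i),
                      onset_s = 2700, mc_reps = 1000, seed = base_seed + i)
  quit_rule <- NULL
  second_track <- track_gen_params(start_xy = c(2200 + 400 * i, 300 * (i - 6)),
                                   turn_sd_rad = 0.25)
  focal_track <- track_gen_params(turn_sd_rad = 1.0, speed_mps = 0.6)
  if (nzchar(sp$quit_who)) {
    # an approaching second singer and a near-stationary focal; the
    # focal-quit dyad starts close and approaches fast, so the focal stops
    # within the first few minutes of the DURING period
    quit_rule <- list(threshold_m = 1000, who = sp$quit_who)
    focal_track <- track_gen_params(turn_sd_rad = 1.2, speed_mps = 0.2)
    second_track <- track_gen_params(
      start_xy = if (sp$quit_who == "focal") c(1400, 200) else c(2600, 300),
      target_xy = c(0, 0), target_weight = 1, turn_sd_rad = 0.05,
      speed_mps = if (sp$quit_who == "focal") 3 else 1.2)
  }
  dp <- dyad_gen_params(coupling_m = sp$coupling,
                        focal_track = focal_track,
                        second_track = second_track,
                        quit_rule = quit_rule)
  sim <- simulate_dyad(dp, sc)
  write_phrase_table(sim$annotations, file.path(out, paste0(sp$id, "_phrases.tsv")))
  write_track(sim$tracks, file.path(out, paste0(sp$id, "_tracks.csv")))
  yaml::write_yaml(unclass(sc), file.path(out, paste0(sp$id, "_scenario.yaml")))
  cat(sprintf("%s: %d phrases, quit at %s\n", sp$id, nrow(sim$annotations),
              if (is.na(sim$quit_time_s)) "never"
              else sprintf("%.0f s", sim$quit_time_s)))
}

write.table(dyad_specs, file.path(out, "dyads.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

solo <- simulate_solo_population(18, track_gen_params(turn_sd_rad = 0.6,
                                                      speed_mps = 0.8),
                                 span_s = 2700, seed = base_seed)
write_solo_endpoints(solo, file.path(out, "solo_endpoints.csv"))
cat(sprintf("18 solo singers written (%d pairwise combinations available)\n",
            choose(18, 2)))
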