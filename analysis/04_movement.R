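#!/usr/bin/env Rscript
# Stage 4: movement analyses.
#
# Observed separation statistics for each dyad over the DURING window,
# compared (K-S) against the null distribution built from all pairwise
# superpositions of the 18 solo singers; the quit analysis (change in
# distance vs whether one singer stopped); and meander ratios with their
# paired and two-sample tests.

suppressMessages(library(songdyad))
source("analysis/_load_study.R")
study <- load_study()

null_pairs <- solo_pairwise_null(study$solo)
cat(sprintf("Spatial null: %d pairs; mean start %.0f m, end %.0f m, delta %.0f m\n",
            nrow(null_pairs), mean(null_pairs$start_sep_m),
            mean(null_pairs$end_sep_m), mean(null_pairs$delta_m)))

spat <- list(); meander <- list()
for (id in names(study$dyads)) {
  d <- study$dyads[[id]]
  sc <- d$scenario
  d_end <- sc$onset_s + sc$during_len_s
  tf <- d$tracks[d$tracks$singer_id == sc$focal_id, ]
  ts <- d$tracks[d$tracks$singer_id == sc$second_id, ]
  sp <- dyad_spatial(tf, ts, sc$onset_s, d_end)
  outcome <- classify_dyad_outcome(d$annotations, d$annotations, sc)
  spat[[id]] <- cbind(dyad_id = id, sp, outcome = outcome)
  add <- function(trk, ws, we, period) {
    m <- meander_ratio(trk, ws, we)
    data.frame(dyad_id = id, singer_id = m$singer_id, period = period,
               path_m = m$path_m, chord_m = m$chord_m, ratio = m$ratio)
  }
  meander[[id]] <- rbind(add(tf, sc$onset_s - sc$before_len_s, sc$onset_s, "BEFORE"),
                         add(tf, sc$onset_s, d_end, "DURING"),
                         add(ts, sc$onset_s, d_end, "DURING"))
}
spat <- do.call(rbind, spat); rownames(spat) <- NULL
meander <- do.call(rbind, meander); rownames(meander) <- NULL
dir.create("results", showWarnings = FALSE)
write.table(spat, "results/spatial_observed.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(null_pairs, "results/spatial_null_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(meander, "results/meander.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nObserved vs null (two-sample K-S):\n  start separation: ")
print(ks_two_sample(spat$start_sep_m, null_pairs$start_sep_m))
cat("  end separation:   ")
print(ks_two_sample(spat$end_sep_m, null_pairs$end_sep_m))
cat("  change:           ")
print(ks_two_sample(spat$delta_m, null_pairs$delta_m))

quit <- spat$outcome != "both_continued"
cat(sprintf("\nQuit analysis: %d dyads with a quitter (mean delta %.0f m) vs %d continuing (mean delta %.0f m)\n",
            sum(quit), mean(spat$delta_m[quit]),
            sum(!quit), mean(spat$delta_m[!quit])))
print(mann_whitney_u(spat$delta_m[quit], spat$delta_m[!quit], "less"))

is_focal <- grepl("^F", meander$singer_id)
fb <- meander$ratio[meander$period == "BEFORE"]
fd <- meander$ratio[meander$period == "DURING" & is_focal]
sd_ <- meander$ratio[meander$period == "DURING" & !is_focal]
cat(sprintf("\nMeander ratios: focal %.2f (BEFORE) -> %.2f (DURING); second %.2f\n",
            mean(fb, na.rm = TRUE), mean(fd, na.rm = TRUE),
            mean(sd_, na.rm = TRUE)))
ok <- !is.na(fb) & !is.na(fd)
cat("  focal BEFORE vs DURING: ")
print(wilcoxon_signed_rank(fb[ok], fd[ok], "less"))
cat("  focal vs second (DURING): ")
print(mann_whitney_u(fd[!is.na(fd)], sd_[!is.na(sd_)], "greater"))
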