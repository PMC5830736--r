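#!/usr/bin/env Rscript
# Stage 5: full orchestrated report.
#
# Runs every stage through run_study(), which also applies the exclusion
# rules (early focal quit, poor recording quality) and writes the report
# tables plus a JSON run manifest under results/report/.

suppressMessages(library(songdyad))
source("analysis/_load_study.R")
study <- load_study()

report <- run_study(study$dyads, study$solo, out_dir = "results/report")
print(report)

cat("\nSong-pattern tests:\n")
print(report$song_tests, row.names = FALSE)
cat("\nSpatial tests:\n")
print(report$spatial_tests, row.names = FALSE)
cat("\nQuit analysis:\n")
print(report$quit_analysis$groups, row.names = FALSE)
print(report$quit_analysis$test, row.names = FALSE)
cat("\nMeander tests:\n")
print(report$meander_tests, row.names = FALSE)
cat("\nExclusions:\n")
print(report$exclusions, row.names = FALSE)
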