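# Shared loader for stages 2-5: rebuild the dyad list from the files that
# stage 1 wrote. Sourced, not run, by the numbered scripts.

load_study <- function(data_dir = "results/data") {
  specs <- read.delim(file.path(data_dir, "dyads.tsv"),
                      stringsAsFactors = FALSE)
  dyads <- list()
  for (i in seq_len(nrow(specs))) {
    id <- specs$id[i]
    dyads[[id]] <- list(
      scenario = load_scenario(file.path(data_dir, paste0(id, "_scenario.yaml"))),
      annotations = read_phrase_table(file.path(data_dir, paste0(id, "_phrases.tsv"))),
      tracks = read_track(file.path(data_dir, paste0(id, "_tracks.csv"))),
      before_start_s = specs$before_start_s[i],
      poor_quality = specs$poor_quality[i]
    )
  }
  list(dyads = dyads,
       solo = read_solo_endpoints(file.path(data_dir, "solo_endpoints.csv")))
}
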