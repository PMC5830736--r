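## Reading and writing the three on-disk formats: phrase annotation tables
## (TSV, with a Raven selection-table dialect accepted on read), singer track
## files (CSV), and dyad scenario configs (YAML or JSON).

# Column aliases accepted on read for phrase tables.  The canonical schema is
# singer_id / begin_s / end_s / phrase_type; Raven selection tables use
# "Begin Time (s)" / "End Time (s)" plus a named annotation column.
.phrase_aliases <- list(
  singer_id   = c("singer_id", "Singer", "singer"),
  begin_s     = c("begin_s", "Begin Time (s)", "Begin Time (S)"),
  end_s       = c("end_s", "End Time (s)", "End Time (S)"),
  phrase_type = c("phrase_type", "Phrase Type", "Annotation", "Tags")
)

.match_column <- function(nm, canonical) {
  hits <- which(nm %in% .phrase_aliases[[canonical]])
  if (length(hits) == 0)
    stop_validation("phrase table is missing required column '%s'", canonical)
  hits[1]
}

#' Read a phrase annotation table
#'
#' Reads a tab-separated table of phrase-level song annotations, one row per
#' sung phrase. The canonical header is `singer_id`, `begin_s`, `end_s`,
#' `phrase_type`; Raven selection-table headers (`Begin Time (s)`,
#' `End Time (s)`, plus a `Singer` and an `Annotation`/`Phrase Type` column)
#' are mapped onto it. Times are seconds from the recording start.
#'
#' Rows are validated (end after begin, non-empty phrase type, no overlapping
#' phrases from the same singer — humpback song is a non-overlapping sequence
#' of phrases) and returned sorted by singer and begin time. No row is ever
#' silently dropped: the row count out equals the row count in, or an error
#' is raised naming the offending row.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `singer_id`, `begin_s`, `end_s`,
#'   `phrase_type`, sorted by `(singer_id, begin_s)`.
#' @seealso [write_phrase_table()]
#' @export
read_phrase_table <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  nm <- names(raw)
  ann <- data.frame(
    singer_id   = as.character(raw[[.match_column(nm, "singer_id")]]),
    begin_s     = as.numeric(raw[[.match_column(nm, "begin_s")]]),
    end_s       = as.numeric(raw[[.match_column(nm, "end_s")]]),
    phrase_type = as.character(raw[[.match_column(nm, "phrase_type")]]),
    stringsAsFactors = FALSE
  )
  validate_annotations(ann)
}

#' Validate a phrase annotation data.frame
#'
#' Checks the invariants of phrase annotations (see [read_phrase_table()])
#' and returns the data sorted by `(singer_id, begin_s)`.
#'
#' @param ann A data.frame with columns `singer_id`, `begin_s`, `end_s`,
#'   `phrase_type`.
#' @return The validated, sorted data.frame.
#' @export
validate_annotations <- function(ann) {
  need <- c("singer_id", "begin_s", "end_s", "phrase_type")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop_validation("annotations are missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (nrow(ann) == 0) return(ann[, need])
  if (anyNA(ann$begin_s) || anyNA(ann$end_s))
    stop_validation("non-numeric begin/end time in annotations")
  bad <- which(ann$end_s <= ann$begin_s)
  if (length(bad))
    stop_validation("end_s <= begin_s at row %d", bad[1])
  if (any(ann$begin_s < 0))
    stop_validation("negative begin_s at row %d", which(ann$begin_s < 0)[1])
  empty <- which(!nzchar(ann$phrase_type) | is.na(ann$phrase_type))
  if (length(empty))
    stop_validation("empty phrase_type at row %d", empty[1])
  ann <- ann[order(ann$singer_id, ann$begin_s), need, drop = FALSE]
  rownames(ann) <- NULL
  # same-singer overlap is an error, never auto-repaired
  for (id in unique(ann$singer_id)) {
    s <- ann[ann$singer_id == id, ]
    if (nrow(s) > 1 && any(s$begin_s[-1] < s$end_s[-nrow(s)] - 1e-9))
      stop_validation("overlapping phrases for singer '%s'", id)
  }
  ann
}

#' Write a phrase annotation table
#'
#' Writes annotations as canonical UTF-8 TSV, times formatted to millisecond
#' precision (channel synchronization in passive acoustic arrays is on the
#' order of a millisecond, so nothing finer is meaningful). The output is
#' readable by [read_phrase_table()] and round-trips exactly for
#' millisecond-resolution times.
#'
#' @param ann A valid annotation data.frame.
#' @param path Output path.
#' @export
write_phrase_table <- function(ann, path) {
  ann <- validate_annotations(ann)
  out <- data.frame(
    singer_id   = ann$singer_id,
    begin_s     = sprintf("%.3f", ann$begin_s),
    end_s       = sprintf("%.3f", ann$end_s),
    phrase_type = ann$phrase_type,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a singer track file
#'
#' Reads time-ordered planar positions, CSV with header
#' `singer_id,time_s,x_m,y_m`. Coordinates are meters in a local projection
#' (e.g. meters from the center of a hydrophone array). Duplicate timestamps
#' for one singer are rejected; rows are returned sorted by singer and time.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `singer_id`, `time_s`, `x_m`, `y_m`.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  trk <- read.csv(path, stringsAsFactors = FALSE)
  validate_track(trk)
}

#' Validate a singer track data.frame
#'
#' @param trk A data.frame with columns `singer_id`, `time_s`, `x_m`, `y_m`.
#' @return The validated data.frame, sorted by `(singer_id, time_s)`.
#' @export
validate_track <- function(trk) {
  need <- c("singer_id", "time_s", "x_m", "y_m")
  miss <- setdiff(need, names(trk))
  if (length(miss))
    stop_validation("track is missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (anyNA(trk$time_s) || anyNA(trk$x_m) || anyNA(trk$y_m))
    stop_validation("missing values in track")
  trk <- trk[order(trk$singer_id, trk$time_s), need, drop = FALSE]
  rownames(trk) <- NULL
  for (id in unique(trk$singer_id)) {
    tt <- trk$time_s[trk$singer_id == id]
    if (anyDuplicated(tt))
      stop_validation("duplicate timestamp for singer '%s'", id)
  }
  trk
}

#' Write a singer track file
#'
#' @param trk A valid track data.frame.
#' @param path Output path.
#' @export
write_track <- function(trk, path) {
  trk <- validate_track(trk)
  out <- data.frame(
    singer_id = trk$singer_id,
    time_s = sprintf("%.3f", trk$time_s),
    x_m = sprintf("%.3f", trk$x_m),
    y_m = sprintf("%.3f", trk$y_m),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a dyad scenario
#'
#' A scenario fixes the geometry and analysis parameters of one focal/second
#' singer pair: who the singers are, when the second singer started
#' (`onset_s`), the lengths of the BEFORE and DURING analysis periods
#' (default 45 min each, giving the 90-min total analysis span), the
#' sub-window length used for song-pattern metrics (default 15 min), the
#' sampling interval of the phrase-type grid used by the overlap test
#' (default 8 s), and the number of Monte Carlo replicates (default 1000).
#'
#' @param focal_id,second_id Singer identifiers.
#' @param onset_s Second singer's song start, seconds from recording start.
#' @param before_len_s,during_len_s Nominal period lengths in seconds.
#' @param window_len_s Sub-window length in seconds; must divide the period
#'   lengths.
#' @param grid_interval_s Phrase-type sampling interval in seconds.
#' @param mc_reps Monte Carlo replicates for the overlap null.
#' @param seed Integer seed controlling the Monte Carlo draws.
#' @return An object of class `dyad_scenario` (a named list).
#' @export
dyad_scenario <- function(focal_id, second_id, onset_s,
                          before_len_s = 2700, during_len_s = 2700,
                          window_len_s = 900, grid_interval_s = 8,
                          mc_reps = 1000, seed = 1L) {
  if (missing(focal_id) || missing(second_id) || missing(onset_s))
    stop_validation("scenario requires focal_id, second_id and onset_s")
  if (onset_s < 0) stop_validation("onset_s must be >= 0")
  if (before_len_s <= 0 || during_len_s <= 0)
    stop_validation("period lengths must be positive")
  if (window_len_s <= 0) stop_validation("window_len_s must be positive")
  if (during_len_s %% window_len_s != 0)
    stop_validation("window_len_s must divide during_len_s")
  if (grid_interval_s <= 0) stop_validation("grid_interval_s must be positive")
  if (mc_reps < 1) stop_validation("mc_reps must be >= 1")
  structure(list(
    focal_id = as.character(focal_id), second_id = as.character(second_id),
    onset_s = as.numeric(onset_s),
    before_len_s = as.numeric(before_len_s),
    during_len_s = as.numeric(during_len_s),
    window_len_s = as.numeric(window_len_s),
    grid_interval_s = as.numeric(grid_interval_s),
    mc_reps = as.integer(mc_reps), seed = as.integer(seed)
  ), class = "dyad_scenario")
}

#' @export
print.dyad_scenario <- function(x, ...) {
  cat(sprintf("Dyad scenario: focal '%s', second '%s', onset %.0f s\n",
              x$focal_id, x$second_id, x$onset_s))
  cat(sprintf("  BEFORE/DURING %.0f/%.0f s, windows %.0f s, grid %.0f s, %d MC reps (seed %d)\n",
              x$before_len_s, x$during_len_s, x$window_len_s,
              x$grid_interval_s, x$mc_reps, x$seed))
  invisible(x)
}

#' Load a dyad scenario from a config file
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose keys are
#' exactly the arguments of [dyad_scenario()]. Unspecified keys take the
#' defaults (45-min periods, 15-min windows, 8-s grid, 1000 replicates);
#' unknown keys are a config error.
#'
#' @param path Path to the config file.
#' @return A `dyad_scenario`.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml  = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_validation("unsupported scenario format '.%s' (use YAML or JSON)", ext)
  )
  allowed <- names(formals(dyad_scenario))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_validation("unknown scenario key(s): %s", paste(unknown, collapse = ", "))
  do.call(dyad_scenario, cfg)
}

#' Read a solo-singer endpoint file
#'
#' CSV with header `singer_id,start_x_m,start_y_m,end_x_m,end_y_m`: the
#' start and end positions of solo singers recorded at non-overlapping
#' times, the raw material of the spatial null distribution
#' (see [solo_pairwise_null()]).
#'
#' @param path Path to a CSV file.
#' @return A data.frame, one row per solo singer.
#' @export
read_solo_endpoints <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  ep <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("singer_id", "start_x_m", "start_y_m", "end_x_m", "end_y_m")
  miss <- setdiff(need, names(ep))
  if (length(miss))
    stop_validation("endpoint file is missing column(s): %s",
                    paste(miss, collapse = ", "))
  if (anyDuplicated(ep$singer_id))
    stop_validation("duplicate singer_id in endpoint file")
  ep[, need]
}

#' Write a solo-singer endpoint file
#'
#' @param ep Endpoint data.frame (see [read_solo_endpoints()]).
#' @param path Output path.
#' @export
write_solo_endpoints <- function(ep, path) {
  out <- data.frame(
    singer_id = ep$singer_id,
    start_x_m = sprintf("%.3f", ep$start_x_m),
    start_y_m = sprintf("%.3f", ep$start_y_m),
    end_x_m = sprintf("%.3f", ep$end_x_m),
    end_y_m = sprintf("%.3f", ep$end_y_m),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
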