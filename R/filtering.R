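## Clip-exclusion rules applied before any metric is computed:
##   (i)  target-child (CHN) clips containing cries,
##   (ii) adult (FAN/MAN) clips containing any non-speech,
##   (iii) adult clips strictly longer than the 10 s threshold
##         (clips that long tend to be diarizer mislabels).
## OTHER-tagged clips pass through untouched; downstream metrics ignore
## them anyway. An adult clip that is both contaminated and over-long is
## counted once, under non-speech (declared precedence).

#' Filter a recording's segments
#'
#' @param rec A validated `daylong_recording`.
#' @param config A `daylong_config`; `adult_max_clip_ms` sets the strict
#'   duration threshold for adult clips.
#' @return List with elements `recording` (the filtered recording) and
#'   `report` (one-row data frame: `recording_id`, `n_total`, `n_retained`,
#'   `n_removed_chn_cry`, `n_removed_adult_nonspeech`,
#'   `n_removed_adult_long`, `pct_removed` in \[0,1\]).
#' @export
filter_segments <- function(rec, config = analysis_config()) {
  s <- rec$segments
  is_adult <- s$speaker_tag %in% ADULT_TAGS
  dur <- s$offset_ms - s$onset_ms
  rm_cry <- s$speaker_tag == "CHN" & s$has_cry
  rm_ns <- is_adult & s$has_nonspeech
  rm_long <- is_adult & !s$has_nonspeech & dur > config$adult_max_clip_ms
  drop <- rm_cry | rm_ns | rm_long
  n_total <- nrow(s)
  report <- data.frame(
    recording_id = rec$recording_id,
    n_total = n_total,
    n_retained = n_total - sum(drop),
    n_removed_chn_cry = sum(rm_cry),
    n_removed_adult_nonspeech = sum(rm_ns),
    n_removed_adult_long = sum(rm_long),
    pct_removed = if (n_total) sum(drop) / n_total else 0)
  out <- rec
  out$segments <- s[!drop, , drop = FALSE]
  rownames(out$segments) <- NULL
  list(recording = out, report = report)
}

#' Filter every recording in a collection
#'
#' @param recordings Named list of `daylong_recording`.
#' @param config A `daylong_config`.
#' @return List with `recordings` (filtered, same names/order) and
#'   `report` (row-bound filter reports).
#' @export
filter_recordings <- function(recordings, config = analysis_config()) {
  if (!length(recordings))
    return(list(recordings = list(),
                report = filter_segments(recording("x", "x", 1),
                                         config)$report[0, ]))
  res <- lapply(recordings, filter_segments, config = config)
  list(recordings = lapply(res, `[[`, "recording"),
       report = do.call(rbind, c(lapply(res, `[[`, "report"),
                                 list(make.row.names = FALSE))))
}
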