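## Conversational-turn detection: a target-child utterance and an adult
## utterance spoken within 5 seconds of each other, in either order.
## Adult-adult and child-child adjacencies never count. Adjacency is
## evaluated on the stream restricted to CHN/FAN/MAN clips: an intervening
## OTHER clip does not break a pair, an intervening same-side clip does.
## The gap boundary is inclusive (<= turn_max_gap_ms) and negative gaps
## (overlapping child/adult clips) count -- overlap is stronger contingency
## than a short gap.

#' Detect conversational turns
#'
#' Scans consecutive pairs of the CHN/FAN/MAN-restricted segment stream
#' (sorted by onset) and emits one event per child/adult adjacency whose
#' onset-to-offset gap is at most `config$turn_max_gap_ms`. A single clip
#' can participate in at most two events (as second of one pair and first
#' of the next).
#'
#' @param rec A **filtered** `daylong_recording`.
#' @param config A `daylong_config`.
#' @return Data frame of turn events: `recording_id`, `first_tag`,
#'   `second_tag`, `first_offset_ms`, `second_onset_ms`, `gap_ms`.
#' @export
detect_turns <- function(rec, config = analysis_config()) {
  s <- rec$segments
  s <- s[s$speaker_tag %in% c("CHN", ADULT_TAGS), , drop = FALSE]
  n <- nrow(s)
  empty <- data.frame(recording_id = character(), first_tag = character(),
                      second_tag = character(), first_offset_ms = numeric(),
                      second_onset_ms = numeric(), gap_ms = numeric())
  if (n < 2) return(empty)
  is_child <- s$speaker_tag == "CHN"
  i <- seq_len(n - 1)
  opposite <- is_child[i] != is_child[i + 1]
  gap <- s$onset_ms[i + 1] - s$offset_ms[i]
  hit <- opposite & gap <= config$turn_max_gap_ms
  if (!any(hit)) return(empty)
  i <- i[hit]
  data.frame(recording_id = rep(rec$recording_id, length(i)),
             first_tag = s$speaker_tag[i],
             second_tag = s$speaker_tag[i + 1],
             first_offset_ms = s$offset_ms[i],
             second_onset_ms = s$onset_ms[i + 1],
             gap_ms = gap[hit])
}

#' Turn quantity and consistency
#'
#' Conversational turns per hour, and the proportion of full
#' `config$epoch_unit_s`-second epochs (5 minutes by default) containing at
#' least one turn. An epoch counts when some turn's second-utterance onset
#' falls in it; the trailing partial epoch is dropped from the denominator.
#'
#' @param turns Turn events from [detect_turns()] on `rec`.
#' @param rec The same `daylong_recording`.
#' @param config A `daylong_config`.
#' @return List `ctc_per_hr`, `turn_consistency`.
#' @export
turn_metrics <- function(turns, rec, config = analysis_config()) {
  w <- config$epoch_unit_s * 1000
  n_epoch <- floor(rec$duration_ms / w)
  if (n_epoch < 1) stop("recording shorter than one epoch")
  ctc <- hourly_rate(nrow(turns), rec$duration_ms)
  bins <- floor(turns$second_onset_ms / w)
  bins <- bins[bins < n_epoch]
  list(ctc_per_hr = ctc,
       turn_consistency = length(unique(bins)) / n_epoch)
}
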