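## Per-recording quantity and consistency measures, hourly normalized.
##
## Quantity: adult words/hr (AWC), minutes (and seconds) of adult speech/hr,
## child vocalizations/hr (CVC). Rates are total / total-duration, not a
## mean over hourly bins, so a short recording is normalized by its actual
## length. Consistency: the proportion of fixed bins (full bins from
## recording start; trailing partial bin dropped) containing at least one
## qualifying event -- a temporal-spread measure independent of quantity.

#' Hourly normalization
#' @param total A count or a duration total.
#' @param duration_ms Recording duration, positive milliseconds.
#' @return `total / (duration_ms / 3.6e6)`.
#' @export
hourly_rate <- function(total, duration_ms) {
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0))
    stop("duration_ms must be positive")
  total / (duration_ms / 3.6e6)
}

#' Quantity metrics of a filtered recording
#'
#' @param rec A filtered `daylong_recording`.
#' @return One-row data frame: `recording_id`, `awc_per_hr`,
#'   `adult_min_per_hr`, `adult_sec_per_hr` (= 60 x minutes),
#'   `cvc_per_hr`, `voc_sec_per_hr`, `n_voc`, `mean_voc_dur_ms` (NA when no
#'   vocalizations).
#' @export
quantity_metrics <- function(rec) {
  s <- rec$segments
  adult <- s$speaker_tag %in% ADULT_TAGS
  chn <- s$speaker_tag == "CHN"
  adult_ms <- sum(s$offset_ms[adult] - s$onset_ms[adult])
  voc_ms <- s$offset_ms[chn] - s$onset_ms[chn]
  data.frame(
    recording_id = rec$recording_id,
    awc_per_hr = hourly_rate(sum(s$word_count[adult]), rec$duration_ms),
    adult_min_per_hr = hourly_rate(adult_ms / 6e4, rec$duration_ms),
    adult_sec_per_hr = hourly_rate(adult_ms / 1e3, rec$duration_ms),
    cvc_per_hr = hourly_rate(sum(chn), rec$duration_ms),
    voc_sec_per_hr = hourly_rate(sum(voc_ms) / 1e3, rec$duration_ms),
    n_voc = sum(chn),
    mean_voc_dur_ms = if (any(chn)) mean(voc_ms) else NA_real_)
}

#' Child vocalization durations of a recording
#' @param rec A (filtered) `daylong_recording`.
#' @return Data frame `recording_id`, `child_id`, `dur_ms` (one row per CHN
#'   clip).
#' @export
voc_durations <- function(rec) {
  chn <- rec$segments$speaker_tag == "CHN"
  data.frame(recording_id = rep(rec$recording_id, sum(chn)),
             child_id = rep(rec$child_id, sum(chn)),
             dur_ms = rec$segments$offset_ms[chn] -
               rec$segments$onset_ms[chn])
}

## Mark which of n half-open bins of width w (ms) are overlapped by the
## half-open intervals [onset, offset). Vectorized; segments spanning >2
## bins are rare and handled in a short loop.
mark_bins <- function(onset, offset, w, n) {
  hit <- logical(n)
  if (!length(onset)) return(hit)
  lo <- pmin(floor(onset / w), n - 1)
  hi <- pmin(floor((offset - 1) / w), n - 1)
  keep <- lo <= n - 1 & hi >= 0 & onset < n * w
  lo <- pmax(lo[keep], 0); hi <- hi[keep]
  hit[unique(c(lo, hi)) + 1] <- TRUE
  wide <- which(hi - lo >= 2)
  for (i in wide) hit[(lo[i] + 1):(hi[i] + 1)] <- TRUE
  hit
}

#' Consistency of speech input or child output
#'
#' Proportion of full `unit_s`-second bins overlapped by at least one
#' qualifying clip. `ADULT_WORD`: an adult (FAN/MAN) clip carrying >= 1
#' estimated word (word estimates are clip-level, so the whole clip carries
#' its words). `CHILD_VOC`: any CHN clip.
#'
#' @param rec A filtered `daylong_recording` at least one bin long.
#' @param unit_s Bin length in seconds (60 for minutes).
#' @param predicate `"ADULT_WORD"` or `"CHILD_VOC"`.
#' @return Proportion in \[0, 1\].
#' @export
consistency <- function(rec, unit_s = 60,
                        predicate = c("ADULT_WORD", "CHILD_VOC")) {
  predicate <- match.arg(predicate)
  w <- unit_s * 1000
  n <- floor(rec$duration_ms / w)
  if (n < 1) stop("recording shorter than one ", unit_s, " s bin")
  s <- rec$segments
  q <- if (predicate == "ADULT_WORD") {
    s$speaker_tag %in% ADULT_TAGS & s$word_count >= 1
  } else {
    s$speaker_tag == "CHN"
  }
  sum(mark_bins(s$onset_ms[q], s$offset_ms[q], w, n)) / n
}

#' Per-child analysis table
#'
#' Joins per-recording environment metrics (quantity, consistency,
#' conversational-turn measures) with cohort metadata. CI children with
#' fewer than `config$min_hearing_age_mo` months of hearing experience are
#' flagged `hearing_age_excluded` (they stay in chronological-age and group
#' analyses).
#'
#' @param cohort Validated cohort data frame (see [validate_cohort()]).
#' @param recordings Named list of **filtered** `daylong_recording`.
#' @param config A `daylong_config`.
#' @return Data frame, one row per recording.
#' @export
metrics_table <- function(cohort, recordings, config = analysis_config()) {
  if (!length(recordings)) {
    empty <- merge(quantity_metrics(recording("x", "x", 1))[0, ],
                   data.frame(child_id = character(),
                              duration_hr = numeric(),
                              input_consistency = numeric(),
                              output_consistency = numeric(),
                              ctc_per_hr = numeric(),
                              turn_consistency = numeric()))
    out <- merge(empty, as.data.frame(cohort)[0, ], by = "child_id")
    out$hearing_age_excluded <- logical(0)
    return(out)
  }
  rows <- lapply(recordings, function(rec) {
    if (!rec$child_id %in% cohort$child_id)
      stop("recording ", rec$recording_id, ": child_id '", rec$child_id,
           "' not present in cohort table")
    turns <- detect_turns(rec, config)
    tm <- turn_metrics(turns, rec, config)
    q <- quantity_metrics(rec)
    q$child_id <- rec$child_id
    q$duration_hr <- rec$duration_ms / 3.6e6
    q$input_consistency <- consistency(rec, config$minute_unit_s,
                                       "ADULT_WORD")
    q$output_consistency <- consistency(rec, config$minute_unit_s,
                                        "CHILD_VOC")
    q$ctc_per_hr <- tm$ctc_per_hr
    q$turn_consistency <- tm$turn_consistency
    q
  })
  tab <- as.data.frame(data.table::rbindlist(rows))
  out <- merge(tab, cohort, by = "child_id", sort = TRUE)
  out$hearing_age_excluded <- out$hearing_group == "CI" &
    (!is.finite(out$hearing_age_mo) |
       out$hearing_age_mo < config$min_hearing_age_mo)
  out <- out[order(out$recording_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-format per-hour table for mixed models
#'
#' One row per full recording hour: adult words, adult speech seconds, and
#' child vocalization count in that hour. Clips are assigned to the hour of
#' their onset (clips are at most 10 s after filtering, so split mass is
#' negligible); the trailing partial hour is dropped, mirroring the
#' consistency convention.
#'
#' @param recordings Named list of filtered `daylong_recording`.
#' @return Data frame `recording_id`, `child_id`, `hour` (0-based),
#'   `words`, `adult_sec`, `adult_min`, `voc_count`.
#' @export
hourly_long_table <- function(recordings) {
  if (!length(recordings))
    return(data.frame(recording_id = character(), child_id = character(),
                      hour = integer(), words = numeric(),
                      adult_sec = numeric(), adult_min = numeric(),
                      voc_count = numeric()))
  rows <- lapply(recordings, function(rec) {
    n <- max(1, floor(rec$duration_ms / 3.6e6))
    s <- rec$segments
    h <- floor(s$onset_ms / 3.6e6)
    keep <- h < n
    s <- s[keep, , drop = FALSE]; h <- h[keep]
    adult <- s$speaker_tag %in% ADULT_TAGS
    chn <- s$speaker_tag == "CHN"
    hf <- factor(h, levels = 0:(n - 1))
    words <- as.numeric(tapply(s$word_count[adult], hf[adult], sum,
                               default = 0))
    asec <- as.numeric(tapply((s$offset_ms - s$onset_ms)[adult] / 1e3,
                              hf[adult], sum, default = 0))
    vc <- as.numeric(tapply(rep(1, sum(chn)), hf[chn], sum, default = 0))
    words[is.na(words)] <- 0; asec[is.na(asec)] <- 0; vc[is.na(vc)] <- 0
    data.frame(recording_id = rep(rec$recording_id, n),
               child_id = rep(rec$child_id, n),
               hour = 0:(n - 1), words = words, adult_sec = asec,
               adult_min = asec / 60, voc_count = vc)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
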