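## Canonical data model for diarized daylong recordings.
##
## A "recording" is one child-day timeline: an id, the child it belongs to,
## the total duration in integer milliseconds, and a segment table with one
## row per diarized speech clip. Timestamps are 0-based milliseconds from
## recording start; intervals are half-open [onset, offset), which removes
## double-counting ambiguity at bin boundaries.

SPEAKER_TAGS <- c("CHN", "FAN", "MAN", "OTHER")
ADULT_TAGS <- c("FAN", "MAN")

SEGMENT_COLS <- c("speaker_tag", "onset_ms", "offset_ms", "word_count",
                  "has_cry", "has_nonspeech")
TABLE_COLS <- c("recording_id", "child_id", "speaker_tag", "onset_ms",
                "offset_ms", "word_count", "has_cry", "has_nonspeech",
                "duration_ms")
COHORT_COLS <- c("child_id", "hearing_group", "chrono_age_mo",
                 "activation_age_mo", "maternal_ed", "gender")
HEARING_GROUPS <- c("CI", "CA_MATCH", "HA_MATCH")

#' Construct a recording
#'
#' @param recording_id,child_id Identifiers.
#' @param duration_ms Total recording length, positive integer milliseconds.
#' @param segments Data frame with columns `speaker_tag`, `onset_ms`,
#'   `offset_ms`, `word_count`, `has_cry`, `has_nonspeech`. Rows are sorted
#'   by (onset, offset, tag) on construction.
#' @param validate Run the invariant suite (default TRUE).
#' @return An object of class `daylong_recording`.
#' @export
recording <- function(recording_id, child_id, duration_ms,
                      segments = empty_segments(), validate = TRUE) {
  segments <- as.data.frame(segments)[, SEGMENT_COLS, drop = FALSE]
  segments$speaker_tag <- as.character(segments$speaker_tag)
  segments$onset_ms <- as.numeric(segments$onset_ms)
  segments$offset_ms <- as.numeric(segments$offset_ms)
  segments$word_count <- as.numeric(segments$word_count)
  segments$has_cry <- as.logical(segments$has_cry)
  segments$has_nonspeech <- as.logical(segments$has_nonspeech)
  o <- order(segments$onset_ms, segments$offset_ms, segments$speaker_tag)
  segments <- segments[o, , drop = FALSE]
  rownames(segments) <- NULL
  rec <- structure(list(recording_id = as.character(recording_id),
                        child_id = as.character(child_id),
                        duration_ms = as.numeric(duration_ms),
                        segments = segments),
                   class = "daylong_recording")
  if (validate) validate_recording(rec)
  rec
}

#' Empty segment table
#' @return Zero-row data frame with the canonical segment columns.
#' @export
empty_segments <- function() {
  data.frame(speaker_tag = character(), onset_ms = numeric(),
             offset_ms = numeric(), word_count = numeric(),
             has_cry = logical(), has_nonspeech = logical())
}

#' Validate a recording's invariants
#'
#' Checks positive duration, offsets strictly after onsets, segments within
#' recording bounds, sortedness, known speaker tags, and zero word counts on
#' CHN/OTHER clips.
#'
#' @param rec A `daylong_recording`.
#' @return The recording, invisibly; stops on the first violation.
#' @export
validate_recording <- function(rec) {
  s <- rec$segments
  if (!is.finite(rec$duration_ms) || rec$duration_ms <= 0)
    stop("recording ", rec$recording_id, ": duration_ms must be positive")
  bad_tag <- !s$speaker_tag %in% SPEAKER_TAGS
  if (any(bad_tag))
    stop("recording ", rec$recording_id, ": unknown speaker tag '",
         s$speaker_tag[which(bad_tag)[1]], "'")
  if (nrow(s)) {
    bad <- s$offset_ms <= s$onset_ms
    if (any(bad))
      stop("recording ", rec$recording_id, ": offset_ms <= onset_ms at row ",
           which(bad)[1])
    if (any(s$onset_ms < 0))
      stop("recording ", rec$recording_id, ": negative onset_ms")
    if (any(s$offset_ms > rec$duration_ms))
      stop("recording ", rec$recording_id,
           ": segment offset exceeds duration_ms")
    if (is.unsorted(order(s$onset_ms, s$offset_ms, s$speaker_tag)))
      stop("recording ", rec$recording_id, ": segments not sorted")
    nonadult <- s$speaker_tag %in% c("CHN", "OTHER")
    if (any(s$word_count[nonadult] != 0))
      stop("recording ", rec$recording_id,
           ": word_count must be 0 for CHN/OTHER segments")
    if (any(s$word_count < 0))
      stop("recording ", rec$recording_id, ": negative word_count")
  }
  invisible(rec)
}

#' @export
print.daylong_recording <- function(x, ...) {
  cat(sprintf("<daylong_recording %s, child %s, %.2f h, %d segments>\n",
              x$recording_id, x$child_id, x$duration_ms / 3.6e6,
              nrow(x$segments)))
  invisible(x)
}

#' Flatten recordings to a canonical segment table
#' @param recordings List of `daylong_recording`.
#' @return Data frame with the canonical columns, ordered by
#'   (recording_id, onset_ms, offset_ms, speaker_tag).
#' @export
recordings_to_table <- function(recordings) {
  if (!length(recordings)) {
    out <- cbind(data.frame(recording_id = character(),
                            child_id = character()),
                 empty_segments(), data.frame(duration_ms = numeric()))
    return(out[, TABLE_COLS])
  }
  parts <- lapply(recordings, function(r) {
    s <- r$segments
    data.frame(recording_id = rep(r$recording_id, nrow(s)),
               child_id = rep(r$child_id, nrow(s)),
               s,
               duration_ms = rep(r$duration_ms, nrow(s)))
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$recording_id, out$onset_ms, out$offset_ms,
                   out$speaker_tag), , drop = FALSE]
  rownames(out) <- NULL
  out[, TABLE_COLS]
}

#' Group a segment table into recordings
#'
#' Unknown speaker tags are mapped to OTHER with a warning (their word
#' counts are zeroed); the full invariant suite is enforced on every
#' recording.
#'
#' @param tab Data frame with the canonical columns.
#' @return Named list of `daylong_recording`, keyed and ordered by
#'   recording id.
#' @export
as_recordings <- function(tab) {
  missing <- setdiff(TABLE_COLS, names(tab))
  if (length(missing))
    stop("segment table is missing column(s): ",
         paste(missing, collapse = ", "))
  tab <- as.data.frame(tab)
  unknown <- !tab$speaker_tag %in% SPEAKER_TAGS
  if (any(unknown)) {
    warning(sum(unknown), " segment(s) with unknown speaker tag(s) [",
            paste(unique(tab$speaker_tag[unknown]), collapse = ", "),
            "] mapped to OTHER")
    tab$speaker_tag[unknown] <- "OTHER"
    tab$word_count[unknown] <- 0
  }
  bad <- which(as.numeric(tab$offset_ms) <= as.numeric(tab$onset_ms))
  if (length(bad))
    stop("offset_ms <= onset_ms at row ", bad[1])
  ids <- sort(unique(tab$recording_id))
  out <- lapply(ids, function(id) {
    sub <- tab[tab$recording_id == id, , drop = FALSE]
    child <- unique(sub$child_id)
    dur <- unique(sub$duration_ms)
    if (length(child) != 1L)
      stop("recording ", id, " maps to multiple child_id values")
    if (length(dur) != 1L)
      stop("recording ", id, " has inconsistent duration_ms")
    recording(id, child, dur, sub[, SEGMENT_COLS])
  })
  names(out) <- ids
  out
}

#' Read a canonical segment CSV
#'
#' @param path File path. UTF-8, comma-delimited, fixed header; booleans
#'   serialized as 0/1.
#' @param config Unused placeholder for pipeline symmetry.
#' @return Named list of validated `daylong_recording`.
#' @export
read_segment_table <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, colClasses = list(
    character = c("recording_id", "child_id", "speaker_tag")))
  tab <- as.data.frame(tab)
  missing <- setdiff(TABLE_COLS, names(tab))
  if (length(missing))
    stop("segment table is missing column(s): ",
         paste(missing, collapse = ", "))
  tab$has_cry <- as.logical(tab$has_cry)
  tab$has_nonspeech <- as.logical(tab$has_nonspeech)
  as_recordings(tab)
}

#' Write recordings to a canonical segment CSV
#'
#' Deterministic row order (recording_id, onset_ms, offset_ms, tag) and 0/1
#' booleans, so that read -> write -> read is the identity and repeated
#' writes are byte-identical.
#'
#' @param recordings List of `daylong_recording`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(recordings, path) {
  tab <- recordings_to_table(recordings)
  tab$has_cry <- as.integer(tab$has_cry)
  tab$has_nonspeech <- as.integer(tab$has_nonspeech)
  data.table::fwrite(tab, path)
  invisible(path)
}

#' Read a cohort metadata CSV
#'
#' Columns: child_id, hearing_group (CI / CA_MATCH / HA_MATCH),
#' chrono_age_mo, activation_age_mo (empty unless CI), maternal_ed (1-7),
#' gender (F/M). The hearing age of CI children is derived as chronological
#' age minus activation age.
#'
#' @param path File path.
#' @return Data frame with a computed `hearing_age_mo` column.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("child_id", "hearing_group", "gender"))))
  missing <- setdiff(COHORT_COLS, names(tab))
  if (length(missing))
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "))
  validate_cohort(tab)
}

#' Validate cohort metadata and derive hearing age
#' @param tab Cohort data frame.
#' @return The validated table with `hearing_age_mo` filled for CI children.
#' @export
validate_cohort <- function(tab) {
  tab <- as.data.frame(tab)
  if (!all(tab$hearing_group %in% HEARING_GROUPS))
    stop("hearing_group must be one of ",
         paste(HEARING_GROUPS, collapse = ", "))
  if (anyDuplicated(tab$child_id))
    stop("duplicated child_id in cohort table")
  if (!all(tab$maternal_ed %in% 1:7))
    stop("maternal_ed must be an integer in 1..7")
  if (!all(tab$gender %in% c("F", "M")))
    stop("gender must be F or M")
  ci <- tab$hearing_group == "CI"
  if (any(ci & !is.finite(tab$activation_age_mo)))
    stop("activation_age_mo missing for a CI child")
  if (any(!ci & is.finite(tab$activation_age_mo)))
    stop("activation_age_mo present for a non-CI child")
  tab$hearing_age_mo <- ifelse(
    ci, compute_hearing_age(tab$chrono_age_mo,
                            ifelse(ci, tab$activation_age_mo,
                                   tab$chrono_age_mo)),
    NA_real_)
  tab
}

#' Write a cohort metadata CSV
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  keep <- intersect(c(COHORT_COLS, "hearing_age_mo", "match_id"),
                    names(cohort))
  data.table::fwrite(cohort[, keep], path)
  invisible(path)
}

#' Hearing age in months
#'
#' Hearing age indexes auditory experience: the time elapsed since first
#' cochlear-implant activation, i.e. chronological age minus activation age.
#' Ages are decimal months.
#'
#' @param chrono_age_mo Current chronological age, months.
#' @param activation_age_mo Age at first CI activation, months.
#' @return `chrono_age_mo - activation_age_mo`.
#' @export
#' @examples
#' compute_hearing_age(47.72, 16.44) # 31.28
compute_hearing_age <- function(chrono_age_mo, activation_age_mo) {
  if (any(chrono_age_mo < 0) || any(activation_age_mo < 0))
    stop("ages must be non-negative")
  if (any(activation_age_mo > chrono_age_mo))
    stop("activation_age_mo exceeds chrono_age_mo")
  chrono_age_mo - activation_age_mo
}

#' Best-effort reader for LENA ITS-style XML
#'
#' Extracts `<Segment>` (or `<segment>`) elements carrying a speaker
#' attribute (`spkr`) and start/end times (`startTime`/`endTime`, ISO-8601
#' durations like "PT123.45S" or bare seconds). Female plus male adult word
#' count attributes are summed into `word_count` (rounded); LENA's
#' fractional word estimates are rounded to the nearest integer. Speaker
#' codes other than CHN/FAN/MAN map to OTHER. Segments lacking time
#' attributes are skipped and counted in a warning.
#'
#' @param path XML file path.
#' @param recording_id,child_id Identifiers for the resulting recording
#'   (default: file name without extension).
#' @return A validated `daylong_recording`.
#' @export
read_its_subset <- function(path, recording_id = NULL, child_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  base <- sub("\\.[^.]*$", "", basename(path))
  recording_id <- recording_id %||% base
  child_id <- child_id %||% base
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//Segment | //segment")
  parse_t <- function(x) {
    x <- sub("^PT", "", x, ignore.case = TRUE)
    x <- sub("S$", "", x, ignore.case = TRUE)
    suppressWarnings(as.numeric(x))
  }
  spkr <- xml2::xml_attr(nodes, "spkr")
  st <- parse_t(xml2::xml_attr(nodes, "startTime"))
  en <- parse_t(xml2::xml_attr(nodes, "endTime"))
  ok <- is.finite(st) & is.finite(en) & en > st
  n_skip <- sum(!ok)
  if (n_skip)
    warning(n_skip, " segment(s) skipped (missing/invalid time attributes)")
  spkr <- ifelse(is.na(spkr), "OTHER", spkr)
  tag <- ifelse(spkr %in% c("CHN", "FAN", "MAN"), spkr, "OTHER")
  n_other <- sum(ok & tag == "OTHER")
  if (n_other)
    message(n_other, " segment(s) with unmapped speaker codes kept as OTHER")
  faw <- suppressWarnings(as.numeric(xml2::xml_attr(nodes,
                                                    "femaleAdultWordCnt")))
  maw <- suppressWarnings(as.numeric(xml2::xml_attr(nodes,
                                                    "maleAdultWordCnt")))
  wc <- round(ifelse(is.na(faw), 0, faw) + ifelse(is.na(maw), 0, maw))
  wc[!tag %in% ADULT_TAGS] <- 0
  seg <- data.frame(speaker_tag = tag[ok],
                    onset_ms = round(st[ok] * 1000),
                    offset_ms = round(en[ok] * 1000),
                    word_count = wc[ok],
                    has_cry = FALSE, has_nonspeech = FALSE)
  dur <- if (nrow(seg)) max(seg$offset_ms) else 1
  recording(recording_id, child_id, dur, seg)
}
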