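#' Analysis configuration
#'
#' Bundles the constants of the clip-filtering and metric definitions: the
#' 10 s adult-clip exclusion threshold, the 5 s conversational-turn
#' contingency window, the 1-minute consistency bin for words and
#' vocalizations, the 5-minute epoch for turn consistency, and the 12-month
#' hearing-experience floor for hearing-age analyses.
#'
#' @param adult_max_clip_ms Adult (FAN/MAN) clips strictly longer than this
#'   are excluded as likely mislabels. Default 10000 ms.
#' @param turn_max_gap_ms Maximum onset-to-offset gap (inclusive) between a
#'   child and an adult utterance for the pair to count as a conversational
#'   turn. Default 5000 ms.
#' @param minute_unit_s Bin length for input/output consistency. Default 60.
#' @param epoch_unit_s Bin length for turn consistency. Default 300 (5 min).
#' @param min_hearing_age_mo Minimum months of hearing experience for a
#'   cochlear-implant child to enter hearing-age analyses. Default 12.
#' @param exclude_child_ids Character vector of child ids to drop in
#'   sensitivity reruns.
#' @return An object of class `daylong_config` (a named list).
#' @export
analysis_config <- function(adult_max_clip_ms = 10000,
                            turn_max_gap_ms = 5000,
                            minute_unit_s = 60,
                            epoch_unit_s = 300,
                            min_hearing_age_mo = 12,
                            exclude_child_ids = character()) {
  stopifnot(adult_max_clip_ms > 0, turn_max_gap_ms >= 0,
            minute_unit_s > 0, epoch_unit_s > 0, min_hearing_age_mo >= 0)
  structure(list(adult_max_clip_ms = as.numeric(adult_max_clip_ms),
                 turn_max_gap_ms = as.numeric(turn_max_gap_ms),
                 minute_unit_s = as.numeric(minute_unit_s),
                 epoch_unit_s = as.numeric(epoch_unit_s),
                 min_hearing_age_mo = as.numeric(min_hearing_age_mo),
                 exclude_child_ids = as.character(exclude_child_ids)),
            class = "daylong_config")
}

#' Read an analysis configuration from a flat key=value file
#'
#' Lines of the form `key = value`; `#` starts a comment;
#' `exclude_child_ids` may be a comma-separated list.
#'
#' @param path File path.
#' @return A `daylong_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  args <- formals(analysis_config)
  out <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(args)) stop("unknown config key: ", k)
    out[[k]] <- if (k == "exclude_child_ids") {
      trimws(strsplit(vals[i], ",", fixed = TRUE)[[1]])
    } else as.numeric(vals[i])
  }
  do.call(analysis_config, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# data.table is used via :: throughout; this flag makes `[.data.table`
# dispatch correctly from within the package namespace.
.datatable.aware <- TRUE
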