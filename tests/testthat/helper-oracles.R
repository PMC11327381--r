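grp_vec0 <- function() c(CI = 0, CA_MATCH = 0, HA_MATCH = 0)
grp_vec_const <- function(x) c(CI = x, CA_MATCH = x, HA_MATCH = x)

# Independent brute-force oracles and fixture builders. The oracles use
# plain loops over segments/bins/pairs and share no code with the
# implementation paths they check.

make_rec <- function(tags, onsets, offsets, words = 0, cry = FALSE,
                     nonspeech = FALSE, duration_ms = max(offsets) + 1000,
                     id = "r1", child = "c1") {
  n <- length(tags)
  recording(id, child, duration_ms, data.frame(
    speaker_tag = tags, onset_ms = onsets, offset_ms = offsets,
    word_count = rep_len(words, n), has_cry = rep_len(cry, n),
    has_nonspeech = rep_len(nonspeech, n)))
}

# A random diarized timeline with overlaps, contamination and all four
# tags; relies on the caller's RNG state.
random_timeline <- function(n_seg = 50, duration_ms = 2 * 3.6e6,
                            id = "r1", child = "c1") {
  tags <- sample(c("CHN", "FAN", "MAN", "OTHER"), n_seg, replace = TRUE,
                 prob = c(0.4, 0.3, 0.15, 0.15))
  onset <- sort(round(runif(n_seg, 0, duration_ms - 30000)))
  dur <- round(rlnorm(n_seg, log(1500), 1))
  dur <- pmax(80, pmin(dur, 25000))
  adult <- tags %in% c("FAN", "MAN")
  wc <- ifelse(adult, rpois(n_seg, pmax(0.3, dur / 400)), 0)
  recording(id, child, duration_ms, data.frame(
    speaker_tag = tags, onset_ms = onset, offset_ms = onset + dur,
    word_count = wc,
    has_cry = tags == "CHN" & runif(n_seg) < 0.15,
    has_nonspeech = adult & runif(n_seg) < 0.15))
}

oracle_turn_count <- function(rec, max_gap = 5000) {
  s <- rec$segments
  s <- s[s$speaker_tag %in% c("CHN", "FAN", "MAN"), , drop = FALSE]
  if (nrow(s) < 2) return(0L)
  n_turn <- 0L
  for (i in seq_len(nrow(s) - 1)) {
    a <- s[i, ]; b <- s[i + 1, ]
    child_a <- a$speaker_tag == "CHN"
    child_b <- b$speaker_tag == "CHN"
    if (child_a != child_b && b$onset_ms - a$offset_ms <= max_gap)
      n_turn <- n_turn + 1L
  }
  n_turn
}

oracle_consistency <- function(rec, unit_s, predicate) {
  w <- unit_s * 1000
  n <- floor(rec$duration_ms / w)
  hits <- 0L
  s <- rec$segments
  for (b in seq_len(n)) {
    lo <- (b - 1) * w; hi <- b * w
    found <- FALSE
    for (i in seq_len(nrow(s))) {
      qual <- if (predicate == "ADULT_WORD")
        s$speaker_tag[i] %in% c("FAN", "MAN") && s$word_count[i] >= 1
      else s$speaker_tag[i] == "CHN"
      if (qual && s$onset_ms[i] < hi && s$offset_ms[i] > lo) {
        found <- TRUE; break
      }
    }
    if (found) hits <- hits + 1L
  }
  hits / n
}

oracle_quantity <- function(rec) {
  s <- rec$segments
  words <- 0; adult_ms <- 0; vocs <- 0L
  for (i in seq_len(nrow(s))) {
    if (s$speaker_tag[i] %in% c("FAN", "MAN")) {
      words <- words + s$word_count[i]
      adult_ms <- adult_ms + (s$offset_ms[i] - s$onset_ms[i])
    } else if (s$speaker_tag[i] == "CHN") {
      vocs <- vocs + 1L
    }
  }
  hrs <- rec$duration_ms / 3.6e6
  list(awc_per_hr = words / hrs, adult_min_per_hr = adult_ms / 6e4 / hrs,
       cvc_per_hr = vocs / hrs)
}

oracle_filter_counts <- function(rec, max_adult_ms = 10000) {
  s <- rec$segments
  cry <- ns <- long <- 0L
  for (i in seq_len(nrow(s))) {
    tag <- s$speaker_tag[i]
    if (tag == "CHN" && s$has_cry[i]) {
      cry <- cry + 1L
    } else if (tag %in% c("FAN", "MAN")) {
      if (s$has_nonspeech[i]) ns <- ns + 1L
      else if (s$offset_ms[i] - s$onset_ms[i] > max_adult_ms)
        long <- long + 1L
    }
  }
  c(cry = cry, nonspeech = ns, long = long)
}
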