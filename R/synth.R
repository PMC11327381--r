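## Synthetic matched cohorts and daylong diarized timelines.
##
## The generator emulates the structure the analysis assumes, for three
## matched groups: children with cochlear implants (CI), chronological-age
## matches (CA_MATCH) and hearing-age matches (HA_MATCH). A child-day is a
## sequence of well-separated events on a 16 h clock:
##
##   * adult bursts -- short runs of FAN/MAN clips (lognormal durations
##     capped at 10 s, Poisson word counts at an age-calibrated rate);
##   * exchanges -- a burst whose last clip elicits a child reply within
##     the 5 s window (probability p_child_response), possibly extending
##     into a volley CHN/adult/CHN/... and closed by an adult reply with
##     probability p_adult_response. An exchange with V child vocalizations
##     and closing-reply indicator R contributes exactly 2V - 1 + R
##     detectable turns;
##   * solo bouts -- runs of child vocalizations placed > 5 s away from any
##     adult clip (vocal play out of caregiver earshot), so they never
##     create turns;
##   * OTHER clips (other talkers/TV), ignored downstream.
##
## Events are separated by more than the turn window, so planted
## contingency maps one-to-one onto detected turns and every generative
## rate has a closed-form expectation (see expected_rates). Defaults are
## calibrated to the published cohort's printed group means/SDs and age
## slopes; the per-group vocs-per-turn productivity slopes are planted by
## tying each child's solo vocalization rate linearly to their expected
## turn rate.

grp_vec <- function(ci, ca, ha) c(CI = ci, CA_MATCH = ca, HA_MATCH = ha)

#' Parameters of the synthetic cohort generator
#'
#' Per-group vectors are named `CI`, `CA_MATCH`, `HA_MATCH`. Defaults state
#' a world calibrated to a published preschool CI cohort: ~1217/1081/1106
#' adult words per hour, ~282 s of adult speech per hour, ~272/308/255
#' child vocalizations per hour, ~62-68 turns per hour, word-rate age
#' slopes 0/20.7/16.49 words per hour per month, vocalization-duration age
#' slopes 3.16/0.59/6.59 ms per month, and vocs-per-turn productivity
#' slopes 2.22/3.66/3.53.
#'
#' @param n_per_group Children per group (CI count; matches derive).
#' @param seed Base RNG seed; all generator randomness flows from it.
#' @param n_low_hearing CI children forced below the 12-month hearing-age
#'   floor (they receive no hearing-age match).
#' @param recording_hours Recording length per child-day.
#' @param match_tolerance_mo,mat_ed_tolerance Matching tolerances (months;
#'   education levels).
#' @param ci_age_range_mo Chronological-age range for CI children.
#' @param adult_burst_rate_per_hr Adult burst (event) rate.
#' @param burst_mean_segs Mean adult clips per burst (>= 1).
#' @param adult_seg_meanlog,adult_seg_sdlog Lognormal adult clip duration
#'   (ms) before the 10 s cap.
#' @param adult_seg_cap_ms Cap applied to drawn adult clip durations.
#' @param p_child_response Per-group probability a burst elicits a child
#'   reply within the turn window.
#' @param p_response_sd Between-child SD of the response probability
#'   (clamped to `p_response_clamp`).
#' @param p_response_clamp Two-element clamp for per-child response
#'   probabilities.
#' @param p_adult_response Probability an adult reply closes each volley
#'   round.
#' @param volley_mean Mean child vocalizations per exchange (>= 1).
#' @param response_window_ms Latency window for contingent links; replies
#'   are drawn uniformly in (200, 0.9 x window].
#' @param awc_base_per_hr Per-group mean adult words/hr at the group's
#'   reference age.
#' @param awc_age_slope Per-group words/hr change per month of
#'   chronological age.
#' @param awc_sdlog Between-child lognormal spread of adult word rate.
#' @param age_center_mo Per-group reference ages (group mean ages).
#' @param cvc_base_per_hr Per-group mean child vocalizations/hr.
#' @param cvc_sdlog Per-group between-child lognormal spread of the solo
#'   vocalization rate.
#' @param cvc_noise_cap Cap on the solo-rate noise factor (the capped
#'   factor is renormalized to mean 1, so expectations are unchanged);
#'   keeps extreme draws from overfilling the day.
#' @param productivity_slope Per-group planted vocs-per-turn slopes.
#' @param bout_size_mean Mean vocalizations per solo bout.
#' @param voc_dur_base_ms Per-group mean vocalization duration at the
#'   reference age.
#' @param voc_dur_age_slope_ms Per-group duration change per month.
#' @param voc_dur_min_ms Hard floor on vocalization duration (80 ms).
#' @param voc_dur_child_sd Between-child SD of mean duration.
#' @param voc_noise_mean_ms,voc_noise_sdlog Within-child right-skewed
#'   duration noise (mean-centered shifted lognormal).
#' @param other_rate_per_hr Rate of OTHER-tagged clips.
#' @param cry_rate,adult_nonspeech_rate Contamination-flag probabilities.
#' @param long_clip_rate Probability an adult clip is drawn over-long
#'   (> 10 s, uniform 10.05-25 s), to exercise the duration filter.
#' @param fan_share Probability an adult clip is FAN rather than MAN.
#' @param min_event_gap_ms Minimum spacing between events; must exceed the
#'   turn window so events cannot chain.
#' @return A `daylong_synth_params` list.
#' @export
synth_params <- function(n_per_group = 18,
                         seed = 20240216,
                         n_low_hearing = 2,
                         recording_hours = 16,
                         match_tolerance_mo = 3,
                         mat_ed_tolerance = 1,
                         ci_age_range_mo = c(31, 65),
                         adult_burst_rate_per_hr = 40,
                         burst_mean_segs = 1.6,
                         adult_seg_meanlog = log(3000),
                         adult_seg_sdlog = 0.55,
                         adult_seg_cap_ms = 10000,
                         p_child_response = grp_vec(0.79, 0.72, 0.76),
                         p_response_sd = 0.3,
                         p_response_clamp = c(0.05, 0.98),
                         p_adult_response = 0.15,
                         volley_mean = 1.5,
                         response_window_ms = 5000,
                         awc_base_per_hr = grp_vec(1217.23, 1081.49,
                                                   1105.54),
                         awc_age_slope = grp_vec(0, 20.7, 16.49),
                         awc_sdlog = 0.38,
                         age_center_mo = grp_vec(47.72, 46.28, 35),
                         cvc_base_per_hr = grp_vec(271.75, 308.03, 254.5),
                         cvc_sdlog = grp_vec(0.25, 0.5, 0.4),
                         cvc_noise_cap = 2.5,
                         productivity_slope = grp_vec(2.22, 3.66, 3.53),
                         bout_size_mean = 20,
                         voc_dur_base_ms = grp_vec(937.93, 1004.46,
                                                   966.59),
                         voc_dur_age_slope_ms = grp_vec(3.16, 0.59, 6.59),
                         voc_dur_min_ms = 80,
                         voc_dur_child_sd = 150,
                         voc_noise_mean_ms = 450,
                         voc_noise_sdlog = 1,
                         other_rate_per_hr = 20,
                         cry_rate = 0.001,
                         adult_nonspeech_rate = 0.0005,
                         long_clip_rate = 0.0005,
                         fan_share = 0.85,
                         min_event_gap_ms = 6000) {
  p <- as.list(environment())
  stopifnot(p$n_per_group >= 1, p$recording_hours > 0,
            p$burst_mean_segs >= 1, p$volley_mean >= 1,
            p$min_event_gap_ms > p$response_window_ms,
            all(p$p_child_response >= 0), all(p$p_child_response <= 1),
            p$p_adult_response >= 0, p$p_adult_response <= 1,
            all(p$cry_rate >= 0), p$voc_dur_min_ms > 0)
  for (nm in c("p_child_response", "awc_base_per_hr", "awc_age_slope",
               "age_center_mo", "cvc_base_per_hr", "cvc_sdlog",
               "productivity_slope", "voc_dur_base_ms",
               "voc_dur_age_slope_ms"))
    if (!all(HEARING_GROUPS %in% names(p[[nm]])))
      stop("per-group parameter '", nm, "' must name all of ",
           paste(HEARING_GROUPS, collapse = ", "))
  structure(p, class = "daylong_synth_params")
}

## E[min(X, cap)] for X ~ lognormal(mu, sd).
capped_lnorm_mean <- function(meanlog, sdlog, cap) {
  z <- (log(cap) - meanlog) / sdlog
  exp(meanlog + sdlog^2 / 2) * stats::pnorm(z - sdlog) +
    cap * (1 - stats::pnorm(z))
}

## E[clamp(X, lo, hi)] for X ~ N(mu, sd).
clamped_norm_mean <- function(mu, sd, lo, hi) {
  if (sd <= 0) return(pmin(hi, pmax(lo, mu)))
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b)) +
    mu * (stats::pnorm(b) - stats::pnorm(a)) +
    sd * (stats::dnorm(a) - stats::dnorm(b))
}

## Var(clamp(X, lo, hi)) for X ~ N(mu, sd).
clamped_norm_var <- function(mu, sd, lo, hi) {
  if (sd <= 0) return(0)
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  # E[X^2; a<Z<b] for X = mu + sd Z
  mid2 <- (mu^2 + sd^2) * (Fb - Fa) +
    sd^2 * (a * fa - b * fb) + 2 * mu * sd * (fa - fb)
  ex2 <- lo^2 * Fa + hi^2 * (1 - Fb) + mid2
  m <- clamped_norm_mean(mu, sd, lo, hi)
  max(0, ex2 - m^2)
}

## Internal: turns-per-exchange factor and the solo-rate link
## coefficients that plant the productivity slopes.
##
## The target slope is the *population regression slope* of measured
## hourly vocalizations on measured hourly turns across children -- the
## quantity the published analysis reports. Measured rates over a finite
## day carry compound-Poisson noise: exchanges arrive at rate
## lambda_b * p_i with V child vocalizations (V ~ 1 + Pois(v - 1)) and
## T = 2V - 1 + R turns (R ~ Bern(q)) each, so the hourly-rate
## measurement variance of turns is lambda_b p E[T^2] / H and the
## measurement covariance between vocalizations and turns is
## lambda_b p E[V T] / H. With between-child variance of the expected
## turn rate sigma_t^2 = (lambda_b tau)^2 Var(p_i), the solo-rate link
## coefficient beta solves
##   s_target = ((beta + v / tau) sigma_t^2 + C_e) / (sigma_t^2 + V_e).
synth_links <- function(params) {
  v <- params$volley_mean
  q <- params$p_adult_response
  tau <- 2 * v - 1 + q                     # E[T] per exchange
  lambda_b <- params$adult_burst_rate_per_hr
  H <- params$recording_hours
  e_t2 <- 4 * (v - 1) + q * (1 - q) + tau^2          # E[T^2]
  e_vt <- 2 * ((v - 1) + v^2) - v + v * q            # E[V T]
  s_extra <- numeric(length(HEARING_GROUPS))
  names(s_extra) <- HEARING_GROUPS
  for (g in HEARING_GROUPS) {
    p0 <- params$p_child_response[g]
    lo <- min(params$p_response_clamp[1], p0)
    var_p <- if (p0 == 0) 0 else
      clamped_norm_var(p0, params$p_response_sd, lo,
                       params$p_response_clamp[2])
    pbar <- if (p0 == 0) 0 else
      clamped_norm_mean(p0, params$p_response_sd, lo,
                        params$p_response_clamp[2])
    sigma_t2 <- (lambda_b * tau)^2 * var_p
    if (sigma_t2 > 0 && lambda_b > 0 && H > 0) {
      v_e <- lambda_b * pbar * e_t2 / H
      c_e <- lambda_b * pbar * e_vt / H
      s_extra[g] <- (params$productivity_slope[g] * (sigma_t2 + v_e) -
                       c_e) / sigma_t2 - v / tau
    } else {
      s_extra[g] <- params$productivity_slope[g] - v / tau
    }
  }
  solo_base <- params$cvc_base_per_hr -
    lambda_b * params$p_child_response * v
  list(tau = tau, lambda_b = lambda_b, s_extra = s_extra,
       solo_base = solo_base,
       ctc_ref = lambda_b * params$p_child_response * tau)
}

#' Generate a matched synthetic cohort
#'
#' CI children are drawn uniformly over the CI age range with hearing ages
#' (months since activation) of at least 12, except `n_low_hearing`
#' children forced below the floor. Each CI child is paired with a
#' chronological-age match (age within `match_tolerance_mo`) and -- when
#' hearing age is at least 12 months -- a hearing-age match (chronological
#' age within tolerance of the CI child's *hearing* age). Genders are
#' equal within pairs and maternal education matched within
#' `mat_ed_tolerance` level.
#'
#' @param params A `daylong_synth_params`; `params$seed` makes generation
#'   deterministic.
#' @return Cohort data frame (child_id, hearing_group, chrono_age_mo,
#'   activation_age_mo, hearing_age_mo, maternal_ed, gender, match_id).
#' @export
generate_cohort <- function(params = synth_params()) {
  set.seed(params$seed)
  n <- params$n_per_group
  tol <- params$match_tolerance_mo
  lo_age <- params$ci_age_range_mo[1]
  hi_age <- params$ci_age_range_mo[2]
  chrono <- runif(n, lo_age, hi_age)
  low <- seq_len(n) <= params$n_low_hearing
  hearing <- ifelse(low, runif(n, 8, 11.5),
                    runif(n, 12, pmax(12.5, chrono - 7)))
  activation <- chrono - hearing
  ed <- sample(3:7, n, replace = TRUE,
               prob = c(0.04, 0.08, 0.18, 0.35, 0.35))
  gender <- sample(c("F", "M"), n, replace = TRUE)
  id <- function(prefix) sprintf("%s%03d", prefix, seq_len(n))
  ci <- data.frame(child_id = id("ci"), hearing_group = "CI",
                   chrono_age_mo = chrono, activation_age_mo = activation,
                   maternal_ed = ed, gender = gender,
                   match_id = id("ci"))
  ed_jitter <- function() {
    d <- sample(seq(-params$mat_ed_tolerance, params$mat_ed_tolerance),
                n, replace = TRUE)
    pmin(7L, pmax(1L, ed + d))
  }
  ca <- data.frame(child_id = id("ca"), hearing_group = "CA_MATCH",
                   chrono_age_mo = chrono + runif(n, -tol, tol),
                   activation_age_mo = NA_real_,
                   maternal_ed = ed_jitter(), gender = gender,
                   match_id = id("ci"))
  ha_keep <- !low
  ha <- data.frame(child_id = id("ha"), hearing_group = "HA_MATCH",
                   chrono_age_mo = hearing + runif(n, -tol, tol),
                   activation_age_mo = NA_real_,
                   maternal_ed = ed_jitter(), gender = gender,
                   match_id = id("ci"))[ha_keep, , drop = FALSE]
  out <- rbind(ci, ca, ha)
  rownames(out) <- NULL
  validate_cohort(out)
}

grouped_cumsum <- function(x, lens) {
  cs <- cumsum(x)
  if (!length(lens)) return(cs)
  first <- cumsum(c(1, lens[-length(lens)]))
  base <- cs[first] - x[first]
  cs - rep(base, lens)
}

#' Generate one synthetic daylong recording
#'
#' Draws the event process described in the module header for one child.
#' Does not touch the RNG seed: callers (e.g. [generate_recordings()]) own
#' the stream, so a cohort's recordings are reproducible from
#' `params$seed`.
#'
#' @param child One row of a cohort data frame.
#' @param params A `daylong_synth_params`.
#' @param recording_id Identifier (default `rec_<child_id>`).
#' @return A validated `daylong_recording` (contamination flags set, no
#'   filtering applied).
#' @export
generate_recording <- function(child, params = synth_params(),
                               recording_id = NULL) {
  g <- as.character(child$hearing_group)
  age <- as.numeric(child$chrono_age_mo)
  recording_id <- recording_id %||% paste0("rec_", child$child_id)
  H <- params$recording_hours
  Tms <- round(H * 3.6e6)
  lk <- synth_links(params)
  m <- params$burst_mean_segs
  v <- params$volley_mean
  q <- params$p_adult_response
  lat_lo <- 200
  lat_hi <- 0.9 * params$response_window_ms

  ## per-child latents (the clamp floor never lifts a zero group
  ## probability off zero)
  clamp_lo <- min(params$p_response_clamp[1], params$p_child_response[g])
  p_i <- if (params$p_child_response[g] == 0) 0 else
    min(params$p_response_clamp[2],
        max(clamp_lo,
            stats::rnorm(1, params$p_child_response[g],
                         params$p_response_sd)))
  awc_mu <- max(50, params$awc_base_per_hr[g] +
                  params$awc_age_slope[g] * (age - params$age_center_mo[g]))
  awc_target <- stats::rlnorm(1, log(awc_mu) - params$awc_sdlog^2 / 2,
                              params$awc_sdlog)
  ctc_exp <- lk$lambda_b * p_i * lk$tau
  solo_mu <- max(0, lk$solo_base[g] +
                   lk$s_extra[g] * (ctc_exp - lk$ctc_ref[g]))
  sdl <- params$cvc_sdlog[g]
  noise_norm <- capped_lnorm_mean(-sdl^2 / 2, sdl, params$cvc_noise_cap)
  solo_rate <- solo_mu *
    min(stats::rlnorm(1, -sdl^2 / 2, sdl), params$cvc_noise_cap) /
    noise_norm
  dur_mu <- max(200, params$voc_dur_base_ms[g] +
                  params$voc_dur_age_slope_ms[g] *
                  (age - params$age_center_mo[g]) +
                  stats::rnorm(1, 0, params$voc_dur_child_sd))
  dbar <- capped_lnorm_mean(params$adult_seg_meanlog,
                            params$adult_seg_sdlog,
                            params$adult_seg_cap_ms)
  keep <- (1 - params$adult_nonspeech_rate) * (1 - params$long_clip_rate)
  sec_exp <- lk$lambda_b * (m + p_i * (v - 1 + q)) * keep * dbar / 1000
  wps <- if (sec_exp > 0) awc_target / sec_exp else 0

  draw_child_dur <- function(n) {
    noise <- stats::rlnorm(n, log(params$voc_noise_mean_ms) -
                             params$voc_noise_sdlog^2 / 2,
                           params$voc_noise_sdlog) -
      params$voc_noise_mean_ms
    pmax(params$voc_dur_min_ms, round(dur_mu + noise))
  }
  draw_adult_dur <- function(n) {
    long <- stats::runif(n) < params$long_clip_rate
    d <- pmin(stats::rlnorm(n, params$adult_seg_meanlog,
                            params$adult_seg_sdlog),
              params$adult_seg_cap_ms)
    d[long] <- stats::runif(sum(long), params$adult_seg_cap_ms + 50,
                            25000)
    pmax(250, round(d))
  }

  ## event skeletons -------------------------------------------------
  n_burst <- stats::rpois(1, lk$lambda_b * H)
  K <- 1 + stats::rpois(n_burst, m - 1)
  resp <- stats::runif(n_burst) < p_i
  V <- ifelse(resp, 1 + stats::rpois(n_burst, v - 1), 0L)
  reply <- resp & (stats::runif(n_burst) < q)
  tail_len <- pmax(0L, 2L * V - 1L + as.integer(reply))
  blen <- K + tail_len

  n_bout <- stats::rpois(1, solo_rate / params$bout_size_mean * H)
  G <- 1 + stats::rpois(n_bout, params$bout_size_mean - 1)

  build_bursts <- function() {
    if (!n_burst) return(NULL)
    bid <- rep(seq_len(n_burst), blen)
    pos <- sequence(blen)
    core <- pos <= K[bid]
    tailpos <- pos - K[bid]
    is_child <- !core & (tailpos %% 2L == 1L)
    N <- length(pos)
    dur <- numeric(N)
    dur[is_child] <- draw_child_dur(sum(is_child))
    dur[!is_child] <- draw_adult_dur(sum(!is_child))
    gap <- numeric(N)
    core_follow <- core & pos > 1
    gap[core_follow] <- 100 + stats::rexp(sum(core_follow), 1 / 800)
    gap[!core] <- stats::runif(sum(!core), lat_lo, lat_hi)
    lagdur <- c(0, dur[-N])
    lagdur[pos == 1] <- 0   # no leak across event boundaries
    rel <- grouped_cumsum(gap + lagdur, blen)
    list(eid = bid, child = is_child, dur = dur, rel = rel,
         len = blen)
  }
  build_bouts <- function() {
    if (!n_bout) return(NULL)
    bid <- rep(seq_len(n_bout), G)
    pos <- sequence(G)
    N <- length(pos)
    dur <- draw_child_dur(N)
    gap <- numeric(N)
    gap[pos > 1] <- 100 + stats::rexp(sum(pos > 1), 1 / 1200)
    lagdur <- c(0, dur[-N])
    lagdur[pos == 1] <- 0
    rel <- grouped_cumsum(gap + lagdur, G)
    list(eid = bid, child = rep(TRUE, N), dur = dur, rel = rel, len = G)
  }
  bu <- build_bursts()
  bo <- build_bouts()

  ev_span <- function(part) {
    if (is.null(part)) return(numeric())
    last <- cumsum(part$len)
    part$rel[last] + part$dur[last]
  }
  spans <- c(ev_span(bu), ev_span(bo))
  n_ev <- length(spans)
  onset <- dur <- numeric(0)
  is_child <- logical(0)
  if (n_ev) {
    gap_min <- params$min_event_gap_ms
    free <- Tms - sum(spans) - n_ev * gap_min - 1000
    if (free <= 0)
      stop("generation error: event process does not fit in the ",
           "recording; lower the rates or lengthen the recording")
    ord <- sample.int(n_ev)
    sp <- spans[ord]
    st <- sort(stats::runif(n_ev, 0, free)) +
      cumsum(c(0, utils::head(sp, -1) + gap_min))
    start <- numeric(n_ev)
    start[ord] <- st
    n_bursts_ev <- if (is.null(bu)) 0L else max(bu$eid)
    if (!is.null(bu)) {
      onset <- round(start[bu$eid] + bu$rel)
      dur <- bu$dur
      is_child <- bu$child
    }
    if (!is.null(bo)) {
      onset <- c(onset, round(start[bo$eid + n_bursts_ev] + bo$rel))
      dur <- c(dur, bo$dur)
      is_child <- c(is_child, bo$child)
    }
  }
  ## OTHER clips, independently placed among themselves
  n_other <- stats::rpois(1, params$other_rate_per_hr * H)
  o_onset <- o_dur <- numeric(0)
  if (n_other) {
    od <- pmax(200, round(stats::rlnorm(n_other, log(2000), 0.6)))
    free_o <- Tms - sum(od) - n_other * 100 - 1000
    if (free_o > 0) {
      o_onset <- round(sort(stats::runif(n_other, 0, free_o)) +
                         cumsum(c(0, utils::head(od, -1) + 100)))
      o_dur <- od
    }
  }
  n_main <- length(onset)
  tag <- character(n_main)
  tag[is_child] <- "CHN"
  n_adult <- sum(!is_child)
  tag[!is_child] <- ifelse(stats::runif(n_adult) < params$fan_share,
                           "FAN", "MAN")
  wc <- numeric(n_main)
  wc[!is_child] <- stats::rpois(n_adult, wps * dur[!is_child] / 1000)
  cry <- logical(n_main)
  cry[is_child] <- stats::runif(sum(is_child)) < params$cry_rate
  ns <- logical(n_main)
  ns[!is_child] <- stats::runif(n_adult) < params$adult_nonspeech_rate
  seg <- data.frame(
    speaker_tag = c(tag, rep("OTHER", length(o_onset))),
    onset_ms = c(onset, o_onset),
    offset_ms = c(onset + dur, o_onset + o_dur),
    word_count = c(wc, numeric(length(o_onset))),
    has_cry = c(cry, logical(length(o_onset))),
    has_nonspeech = c(ns, logical(length(o_onset))))
  recording(recording_id, child$child_id, Tms, seg)
}

#' Generate recordings for a whole cohort
#'
#' Seeds the RNG once from `params$seed` and draws each child's day in
#' cohort order, so identical parameters give byte-identical segment
#' tables.
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param params A `daylong_synth_params`.
#' @return Named list of `daylong_recording` (one per child).
#' @export
generate_recordings <- function(cohort, params = synth_params()) {
  set.seed(params$seed + 1L)
  out <- lapply(seq_len(nrow(cohort)), function(i)
    generate_recording(cohort[i, , drop = FALSE], params))
  names(out) <- vapply(out, `[[`, "", "recording_id")
  out
}

#' Closed-form expected rates of the generative process
#'
#' Post-filter expectations for one child, integrating over all generator
#' randomness: adult words/hr, adult minutes (and seconds) of speech/hr,
#' child vocalizations/hr, and the (approximate only through contamination
#' removal) conversational turns/hr.
#'
#' @param params A `daylong_synth_params`.
#' @param child One cohort row.
#' @return One-row data frame `awc_per_hr`, `adult_min_per_hr`,
#'   `adult_sec_per_hr`, `cvc_per_hr`, `ctc_per_hr`.
#' @export
expected_rates <- function(params, child) {
  g <- as.character(child$hearing_group)
  age <- as.numeric(child$chrono_age_mo)
  lk <- synth_links(params)
  m <- params$burst_mean_segs
  v <- params$volley_mean
  q <- params$p_adult_response
  pbar <- if (params$p_child_response[g] == 0) 0 else
    clamped_norm_mean(params$p_child_response[g],
                      params$p_response_sd,
                      min(params$p_response_clamp[1],
                          params$p_child_response[g]),
                      params$p_response_clamp[2])
  dbar <- capped_lnorm_mean(params$adult_seg_meanlog,
                            params$adult_seg_sdlog,
                            params$adult_seg_cap_ms)
  keep <- (1 - params$adult_nonspeech_rate) * (1 - params$long_clip_rate)
  sec <- lk$lambda_b * (m + pbar * (v - 1 + q)) * keep * dbar / 1000
  awc <- if (sec > 0)
    max(50, params$awc_base_per_hr[g] +
          params$awc_age_slope[g] * (age - params$age_center_mo[g]))
  else 0
  solo <- max(0, lk$solo_base[g] +
                lk$s_extra[g] * lk$lambda_b * lk$tau *
                (pbar - params$p_child_response[g]))
  cvc <- (solo + lk$lambda_b * pbar * v) * (1 - params$cry_rate)
  ctc <- lk$lambda_b * pbar * lk$tau *
    (1 - params$cry_rate) * (1 - params$adult_nonspeech_rate)
  data.frame(awc_per_hr = unname(awc),
             adult_min_per_hr = unname(sec / 60),
             adult_sec_per_hr = unname(sec),
             cvc_per_hr = unname(cvc),
             ctc_per_hr = unname(ctc))
}

#' End-to-end parameter-recovery experiment
#'
#' For each replicate: generate a matched cohort and its daylong timelines,
#' run the full pipeline (filter, metrics, turns), and estimate the
#' generative quantities -- the chronological-age word-rate slope in the
#' CA_MATCH group, the segment-level vocalization-duration age slope in
#' the HA_MATCH group, and the per-group vocs-per-turn productivity
#' slopes. Reports per-replicate estimates and a bias / RMSE / 95%
#' CI-coverage summary against the planted truths.
#'
#' @param params A `daylong_synth_params` (its `n_per_group` sets the
#'   cohort size).
#' @param n_reps Number of replicate cohorts.
#' @param seed Base seed; per-replicate seeds are drawn from R's RNG
#'   seeded with it.
#' @param config A `daylong_config`.
#' @param max_segments_per_child Subsampling cap for the segment-level
#'   duration model (runtime control; estimator unchanged).
#' @return List `estimates` (one row per replicate x parameter) and
#'   `summary` (per parameter: truth, mean estimate, bias, rmse, se of the
#'   mean, coverage).
#' @export
recovery_experiment <- function(params = synth_params(), n_reps = 10,
                                seed = params$seed,
                                config = analysis_config(),
                                max_segments_per_child = 150) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 2L, n_reps)
  one_rep <- function(r) {
    pr <- params
    pr$seed <- rep_seeds[r]
    cohort <- generate_cohort(pr)
    recs <- generate_recordings(cohort, pr)
    flt <- filter_recordings(recs, config)
    tab <- metrics_table(cohort, flt$recordings, config)
    segs <- as.data.frame(data.table::rbindlist(
      lapply(flt$recordings, voc_durations)))
    sl <- cross_sectional_slopes(tab, "awc_per_hr", "chrono", config)
    ds <- voc_duration_slopes(
      segs, cohort, "chrono", config,
      max_segments_per_child = max_segments_per_child)
    pm <- fit_productivity_model(tab)$group_slopes
    grab <- function(df, g, est, se) data.frame(
      rep = r, param = NA_character_, estimate = df[[est]][df$group == g],
      se = df[[se]][df$group == g])
    rows <- rbind(
      cbind(grab(sl, "CA_MATCH", "beta", "se")),
      cbind(grab(ds, "HA_MATCH", "beta", "se")),
      cbind(grab(pm, "CI", "slope", "se")),
      cbind(grab(pm, "CA_MATCH", "slope", "se")),
      cbind(grab(pm, "HA_MATCH", "slope", "se")))
    rows$param <- c("awc_age_slope_CA", "voc_dur_slope_HA",
                    "productivity_slope_CI", "productivity_slope_CA",
                    "productivity_slope_HA")
    rows
  }
  est <- do.call(rbind, c(lapply(seq_len(n_reps), one_rep),
                          list(make.row.names = FALSE)))
  truth <- c(awc_age_slope_CA = unname(params$awc_age_slope["CA_MATCH"]),
             voc_dur_slope_HA =
               unname(params$voc_dur_age_slope_ms["HA_MATCH"]),
             productivity_slope_CI =
               unname(params$productivity_slope["CI"]),
             productivity_slope_CA =
               unname(params$productivity_slope["CA_MATCH"]),
             productivity_slope_HA =
               unname(params$productivity_slope["HA_MATCH"]))
  est$truth <- truth[est$param]
  sm <- lapply(split(est, est$param), function(d) data.frame(
    param = d$param[1], truth = d$truth[1], n_reps = nrow(d),
    mean_estimate = mean(d$estimate),
    bias = mean(d$estimate) - d$truth[1],
    rmse = sqrt(mean((d$estimate - d$truth[1])^2)),
    se_mean = stats::sd(d$estimate) / sqrt(nrow(d)),
    coverage = mean(abs(d$estimate - d$truth[1]) <= 1.96 * d$se)))
  list(estimates = est,
       summary = do.call(rbind, c(sm, list(make.row.names = FALSE))))
}

#' Type-I-error simulation for the group and interaction LRTs
#'
#' Simulates cohorts under the fitted models' own null (zero hearing-group
#' effect; zero turns-by-group interaction) at the metrics level -- hourly
#' outcomes with child and hour random intercepts for the group test;
#' per-child regressions for the interaction test -- and reports the
#' likelihood-ratio rejection rate at `alpha`.
#'
#' @param n_reps Number of simulated cohorts.
#' @param n_per_group Children per group.
#' @param n_hours Recording hours (hourly rows per child).
#' @param alpha Nominal level.
#' @param seed RNG seed.
#' @param sd_child,sd_hour,sd_res Variance components of the hourly
#'   outcome.
#' @return List `group_rate`, `interaction_rate`, `n_reps`, and the raw p
#'   values.
#' @export
lrt_type1_sim <- function(n_reps = 500, n_per_group = 18, n_hours = 16,
                          alpha = 0.05, seed = 20240216,
                          sd_child = 1, sd_hour = 0.5, sd_res = 1) {
  set.seed(seed)
  n_child <- 3 * n_per_group
  grp <- rep(HEARING_GROUPS, each = n_per_group)
  base <- data.frame(
    child_id = factor(rep(seq_len(n_child), each = n_hours)),
    hour = factor(rep(seq_len(n_hours), n_child)),
    hearing_group = rep(grp, each = n_hours))
  p_group <- p_int <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    b_c <- stats::rnorm(n_child, 0, sd_child)
    b_h <- stats::rnorm(n_hours, 0, sd_hour)
    base$y <- b_c[as.integer(base$child_id)] +
      b_h[as.integer(base$hour)] + stats::rnorm(nrow(base), 0, sd_res)
    f0 <- suppressMessages(lme4::lmer(
      y ~ 1 + (1 | child_id) + (1 | hour), data = base, REML = FALSE))
    f1 <- suppressMessages(lme4::lmer(
      y ~ hearing_group + (1 | child_id) + (1 | hour), data = base,
      REML = FALSE))
    chi2 <- max(0, 2 * (as.numeric(stats::logLik(f1)) -
                          as.numeric(stats::logLik(f0))))
    p_group[r] <- stats::pchisq(chi2, 2, lower.tail = FALSE)

    d <- data.frame(hearing_group = factor(grp, levels = HEARING_GROUPS),
                    age_c = stats::rnorm(n_child, 0, 10),
                    ctc_c = stats::rnorm(n_child, 0, 20))
    d$cvc <- 250 + 0.5 * d$age_c + 2 * d$ctc_c +
      stats::rnorm(n_child, 0, 80)
    l0 <- stats::lm(cvc ~ age_c + ctc_c + hearing_group, data = d)
    l1 <- stats::lm(cvc ~ age_c + ctc_c * hearing_group, data = d)
    chi2i <- max(0, 2 * (as.numeric(stats::logLik(l1)) -
                           as.numeric(stats::logLik(l0))))
    p_int[r] <- stats::pchisq(chi2i, 2, lower.tail = FALSE)
  }
  list(group_rate = mean(p_group < alpha),
       interaction_rate = mean(p_int < alpha),
       n_reps = n_reps, p_group = p_group, p_interaction = p_int)
}
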