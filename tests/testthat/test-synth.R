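cfg <- analysis_config()

test_that("generation is deterministic under a fixed seed", {
  p <- synth_params(n_per_group = 2, seed = 910)
  coh1 <- generate_cohort(p); coh2 <- generate_cohort(p)
  expect_identical(coh1, coh2)
  r1 <- generate_recordings(coh1, p); r2 <- generate_recordings(coh2, p)
  expect_identical(recordings_to_table(r1), recordings_to_table(r2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_segment_table(r1, f1); write_segment_table(r2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("cohorts honour sizes, the hearing-age floor and matching", {
  coh <- generate_cohort(synth_params(n_per_group = 18, n_low_hearing = 2,
                                      seed = 911))
  expect_equal(sum(coh$hearing_group == "CI"), 18)
  expect_equal(sum(coh$hearing_group == "CA_MATCH"), 18)
  expect_equal(sum(coh$hearing_group == "HA_MATCH"), 16)
  ci <- coh[coh$hearing_group == "CI", ]
  expect_equal(sum(ci$hearing_age_mo < 12), 2)
  expect_equal(ci$hearing_age_mo, ci$chrono_age_mo - ci$activation_age_mo)

  # matching constraints over several cohorts
  for (s in 912:931) {
    p <- synth_params(n_per_group = 6, seed = s)
    coh <- generate_cohort(p)
    ci <- coh[coh$hearing_group == "CI", ]
    for (grp in c("CA_MATCH", "HA_MATCH")) {
      mm <- coh[coh$hearing_group == grp, ]
      pair <- ci[match(mm$match_id, ci$child_id), ]
      target <- if (grp == "CA_MATCH") pair$chrono_age_mo else
        pair$hearing_age_mo
      expect_true(all(abs(mm$chrono_age_mo - target) <=
                        p$match_tolerance_mo + 1e-9))
      expect_true(all(abs(mm$maternal_ed - pair$maternal_ed) <=
                        p$mat_ed_tolerance))
      expect_identical(mm$gender, pair$gender)
    }
  }
})

test_that("a single-triad cohort is exactly matched", {
  coh <- generate_cohort(synth_params(n_per_group = 1, n_low_hearing = 0,
                                      seed = 913))
  expect_equal(nrow(coh), 3)
  expect_setequal(coh$hearing_group, c("CI", "CA_MATCH", "HA_MATCH"))
})

test_that("generated recordings pass the invariant suite", {
  p <- synth_params(n_per_group = 2, seed = 914)
  coh <- generate_cohort(p)
  recs <- generate_recordings(coh, p)
  for (rec in recs) {
    expect_silent(validate_recording(rec))
    s <- rec$segments
    chn <- s[s$speaker_tag == "CHN", ]
    expect_true(all(chn$offset_ms - chn$onset_ms >= p$voc_dur_min_ms))
    # no within-speaker overlap
    for (tag in unique(s$speaker_tag)) {
      ss <- s[s$speaker_tag == tag, ]
      if (nrow(ss) > 1)
        expect_true(all(ss$onset_ms[-1] >= ss$offset_ms[-nrow(ss)]))
    }
  }
})

test_that("degenerate parameter points give empty or silent children", {
  p0 <- synth_params(n_per_group = 1, seed = 915,
                     adult_burst_rate_per_hr = 0,
                     p_child_response = grp_vec0(),
                     cvc_base_per_hr = grp_vec0(),
                     other_rate_per_hr = 0)
  coh <- generate_cohort(p0)
  rec <- generate_recording(coh[1, ], p0)
  expect_equal(nrow(rec$segments), 0)
  expect_equal(rec$duration_ms, 16 * 3.6e6)

  # child processes off, adult bursts on: no CHN clips, no turns
  p1 <- synth_params(n_per_group = 1, seed = 916,
                     p_child_response = grp_vec0(),
                     cvc_base_per_hr = grp_vec0())
  coh1 <- generate_cohort(p1)
  rec1 <- generate_recording(coh1[1, ], p1)
  expect_equal(sum(rec1$segments$speaker_tag == "CHN"), 0)
  expect_equal(nrow(detect_turns(rec1, cfg)), 0)
  expect_gt(sum(rec1$segments$speaker_tag %in% c("FAN", "MAN")), 0)
})

test_that("expected rates are linear in their drivers", {
  p <- synth_params()
  child <- data.frame(child_id = "x", hearing_group = "CI",
                      chrono_age_mo = 47.72)
  base <- expected_rates(p, child)
  p0 <- p; p0$adult_burst_rate_per_hr <- 0
  z <- expected_rates(p0, child)
  expect_equal(z$awc_per_hr, 0)
  expect_equal(z$adult_sec_per_hr, 0)
  expect_equal(z$ctc_per_hr, 0)
  p2 <- p
  p2$awc_base_per_hr <- 2 * p2$awc_base_per_hr
  d2 <- expected_rates(p2, child)
  expect_equal(d2$awc_per_hr, 2 * base$awc_per_hr)
  expect_equal(d2$adult_sec_per_hr, base$adult_sec_per_hr)
  expect_equal(d2$cvc_per_hr, base$cvc_per_hr)
})

test_that("empirical rates converge to the closed-form expectations", {
  # scaled down relative to the 500-day contract (80 days of 4 h) to stay
  # within the test budget; the comparison is still 3 Monte-Carlo SEs
  p <- synth_params(recording_hours = 4, seed = 917)
  child <- data.frame(child_id = "mc", hearing_group = "CA_MATCH",
                      chrono_age_mo = 46.28)
  exp_r <- expected_rates(p, child)
  set.seed(917)
  sims <- t(replicate(80, {
    rec <- generate_recording(child, p)
    flt <- filter_segments(rec, cfg)$recording
    q <- quantity_metrics(flt)
    c(q$awc_per_hr, q$adult_min_per_hr, q$cvc_per_hr)
  }))
  for (j in 1:3) {
    target <- c(exp_r$awc_per_hr, exp_r$adult_min_per_hr,
                exp_r$cvc_per_hr)[j]
    se <- sd(sims[, j]) / sqrt(nrow(sims))
    expect_lt(abs(mean(sims[, j]) - target), 3 * se)
  }
})

test_that("turns increase with both response probabilities", {
  child <- data.frame(child_id = "g", hearing_group = "CI",
                      chrono_age_mo = 48)
  mean_ctc <- function(pc, pa, seed) {
    p <- synth_params(recording_hours = 4,
                      p_child_response = grp_vec_const(pc),
                      p_adult_response = pa,
                      p_response_sd = 0)
    set.seed(seed)
    mean(replicate(25, {
      rec <- generate_recording(child, p)
      nrow(detect_turns(filter_segments(rec, cfg)$recording, cfg)) /
        (rec$duration_ms / 3.6e6)
    }))
  }
  grid <- vapply(c(0, 0.2, 0.4, 0.6), mean_ctc, numeric(1),
                 pa = 0.15, seed = 918)
  expect_true(all(diff(grid) > 0))
  lo_q <- mean_ctc(0.6, 0, seed = 919)
  hi_q <- mean_ctc(0.6, 0.9, seed = 919)
  expect_gt(hi_q, lo_q)
})

test_that("planted turn arithmetic matches detection exactly per exchange", {
  # one burst that always elicits a reply chain: turns = 2V - 1 + R
  p <- synth_params(recording_hours = 1, adult_burst_rate_per_hr = 6,
                    p_child_response = grp_vec_const(1),
                    p_response_sd = 0, other_rate_per_hr = 0,
                    cvc_base_per_hr = grp_vec_const(400),
                    cry_rate = 0, adult_nonspeech_rate = 0,
                    long_clip_rate = 0)
  child <- data.frame(child_id = "t", hearing_group = "CI",
                      chrono_age_mo = 48)
  set.seed(920)
  for (i in 1:10) {
    rec <- generate_recording(child, p)
    # oracle recount must agree with the detector on generated data
    expect_equal(nrow(detect_turns(rec, cfg)), oracle_turn_count(rec))
  }
})
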