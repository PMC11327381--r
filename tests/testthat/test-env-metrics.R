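cfg <- analysis_config()

test_that("hourly_rate normalizes by actual duration", {
  expect_equal(hourly_rate(160, 16 * 3.6e6), 10)
  expect_equal(hourly_rate(0, 12.83 * 3.6e6), 0)
  expect_equal(hourly_rate(4139, 12.83 * 3.6e6), 4139 / 12.83)
  expect_error(hourly_rate(10, 0), "positive")
  # scale invariance: doubling total and duration leaves the rate fixed
  expect_equal(hourly_rate(2 * 4139, 2 * 12.83 * 3.6e6),
               hourly_rate(4139, 12.83 * 3.6e6))
})

test_that("quantity metrics match forced arithmetic", {
  # 2 h recording; FAN clips totalling 300 s carrying 500 words; 40 CHN
  # clips of 1 s each
  fan_on <- seq(0, by = 60000, length.out = 10)
  chn_on <- seq(3 * 6e5, by = 10000, length.out = 40)
  rec <- make_rec(c(rep("FAN", 10), rep("CHN", 40)),
                  c(fan_on, chn_on), c(fan_on + 30000, chn_on + 1000),
                  words = c(rep(50, 10), rep(0, 40)),
                  duration_ms = 2 * 3.6e6)
  q <- quantity_metrics(rec)
  expect_equal(q$adult_min_per_hr, 2.5)
  expect_equal(q$adult_sec_per_hr, 150)
  expect_equal(q$awc_per_hr, 250)
  expect_equal(q$cvc_per_hr, 20)
  expect_equal(q$mean_voc_dur_ms, 1000)
})

test_that("an empty recording yields all-zero rates", {
  q <- quantity_metrics(recording("r", "c", 3.6e6))
  expect_equal(q$awc_per_hr, 0)
  expect_equal(q$cvc_per_hr, 0)
  expect_true(is.na(q$mean_voc_dur_ms))
})

test_that("consistency counts bins overlapped by qualifying clips", {
  # 120-minute recording, adult words only in minutes 0 and 61
  rec <- make_rec(c("FAN", "FAN"), c(30000, 61 * 60000 + 1000),
                  c(32000, 61 * 60000 + 3000), words = c(5, 5),
                  duration_ms = 2 * 3.6e6)
  expect_equal(consistency(rec, 60, "ADULT_WORD"), 2 / 120)
  # full coverage -> 1
  full <- make_rec("FAN", 0, 2 * 3.6e6, words = 100,
                   duration_ms = 2 * 3.6e6)
  expect_equal(consistency(full, 60, "ADULT_WORD"), 1)
  # a zero-word adult clip does not qualify as input
  silent <- make_rec("FAN", 0, 5000, words = 0, duration_ms = 3.6e6)
  expect_equal(consistency(silent, 60, "ADULT_WORD"), 0)
  expect_error(consistency(make_rec("CHN", 0, 1000, duration_ms = 30000),
                           60, "CHILD_VOC"), "shorter")
})

test_that("metrics equal brute-force enumeration on random timelines", {
  set.seed(301)
  for (i in 1:20) {
    rec <- random_timeline(n_seg = sample(5:150, 1))
    q <- quantity_metrics(rec)
    orc <- oracle_quantity(rec)
    expect_equal(q$awc_per_hr, orc$awc_per_hr)
    expect_equal(q$adult_min_per_hr, orc$adult_min_per_hr)
    expect_equal(q$cvc_per_hr, orc$cvc_per_hr)
    for (pred in c("ADULT_WORD", "CHILD_VOC"))
      expect_equal(consistency(rec, 60, pred),
                   oracle_consistency(rec, 60, pred))
    expect_equal(consistency(rec, 300, "CHILD_VOC"),
                 oracle_consistency(rec, 300, "CHILD_VOC"))
  }
})

test_that("consistency is monotone and split-invariant", {
  set.seed(302)
  rec <- random_timeline(n_seg = 60)
  base <- consistency(rec, 60, "CHILD_VOC")
  # adding a qualifying segment never decreases consistency
  s2 <- rbind(rec$segments,
              data.frame(speaker_tag = "CHN", onset_ms = 123456,
                         offset_ms = 124456, word_count = 0,
                         has_cry = FALSE, has_nonspeech = FALSE))
  rec2 <- recording(rec$recording_id, rec$child_id, rec$duration_ms, s2)
  expect_gte(consistency(rec2, 60, "CHILD_VOC"), base)
  # deleting all qualifying segments forces 0
  rec3 <- rec
  rec3$segments <- rec$segments[rec$segments$speaker_tag != "CHN", ]
  expect_equal(consistency(rec3, 60, "CHILD_VOC"), 0)
  # splitting one clip into two abutting clips in the same bin
  one <- make_rec("CHN", 61000, 63000, duration_ms = 3.6e6)
  two <- make_rec(c("CHN", "CHN"), c(61000, 62000), c(62000, 63000),
                  duration_ms = 3.6e6)
  expect_equal(consistency(one, 60, "CHILD_VOC"),
               consistency(two, 60, "CHILD_VOC"))
})

test_that("quantity is independent of temporal spread", {
  clustered <- make_rec(rep("FAN", 10), seq(0, by = 1000, length.out = 10),
                        seq(800, by = 1000, length.out = 10), words = 30,
                        duration_ms = 3.6e6)
  spread <- make_rec(rep("FAN", 10), seq(0, by = 3.5e5, length.out = 10),
                     seq(800, by = 3.5e5, length.out = 10), words = 30,
                     duration_ms = 3.6e6)
  expect_equal(quantity_metrics(clustered)$awc_per_hr,
               quantity_metrics(spread)$awc_per_hr)
  expect_gt(consistency(spread, 60, "ADULT_WORD"),
            consistency(clustered, 60, "ADULT_WORD"))
})

test_that("metrics_table joins metadata and flags hearing-age exclusions", {
  coh <- validate_cohort(data.frame(
    child_id = c("c1", "c2", "c3"),
    hearing_group = c("CI", "CI", "CA_MATCH"),
    chrono_age_mo = c(48, 40, 47),
    activation_age_mo = c(20, 32, NA),
    maternal_ed = c(6, 5, 6), gender = c("F", "M", "F")))
  set.seed(303)
  recs <- lapply(c("c1", "c2", "c3"), function(cid)
    random_timeline(40, id = paste0("rec_", cid), child = cid))
  names(recs) <- vapply(recs, `[[`, "", "recording_id")
  tab <- metrics_table(coh, recs, cfg)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$hearing_age_excluded[tab$child_id == "c2"], TRUE)
  expect_equal(tab$hearing_age_excluded[tab$child_id == "c1"], FALSE)
  expect_true(all(c("awc_per_hr", "ctc_per_hr", "turn_consistency",
                    "hearing_group") %in% names(tab)))
  # orphan recording -> join error naming the child
  orphan <- random_timeline(10, id = "rec_zz", child = "zz")
  expect_error(metrics_table(coh, c(recs, list(rec_zz = orphan)), cfg),
               "zz")
})

test_that("hourly long table splits totals by hour of onset", {
  rec <- make_rec(c("FAN", "CHN", "FAN"),
                  c(1000, 3.7e6, 2 * 3.6e6 + 5000),
                  c(3000, 3.7e6 + 500, 2 * 3.6e6 + 7000),
                  words = c(8, 0, 5), duration_ms = 3 * 3.6e6)
  h <- hourly_long_table(list(rec))
  expect_equal(nrow(h), 3)
  expect_equal(h$words, c(8, 0, 5))
  expect_equal(h$voc_count, c(0, 1, 0))
  expect_equal(sum(h$adult_sec), 4)
})
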