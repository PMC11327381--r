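cfg <- analysis_config()

# Small deterministic per-child table with known group structure.
toy_cohort_tab <- function(n = 20, seed = 500, noise = 0) {
  set.seed(seed)
  g <- rep(c("CI", "CA_MATCH", "HA_MATCH"), each = n)
  means <- c(CI = 0, CA_MATCH = 5, HA_MATCH = -5)
  data.frame(child_id = sprintf("c%03d", seq_along(g)), hearing_group = g,
             chrono_age_mo = runif(3 * n, 31, 65),
             y = means[g] + rnorm(3 * n, 0, noise))
}

test_that("treatment coding recovers group means exactly for OLS", {
  tab <- toy_cohort_tab(noise = 1)
  m <- fit_group_model(tab, "y", "hearing_group", random = character())
  co <- m$coefficients
  mns <- tapply(tab$y, tab$hearing_group, mean)
  expect_equal(co$estimate[co$term == "(Intercept)"], unname(mns["CI"]))
  expect_equal(co$estimate[co$term == "hearing_groupCA_MATCH"],
               unname(mns["CA_MATCH"] - mns["CI"]))
  expect_equal(co$estimate[co$term == "hearing_groupHA_MATCH"],
               unname(mns["HA_MATCH"] - mns["CI"]))
})

test_that("mixed model recovers planted group effects within 2 SE", {
  set.seed(501)
  n <- 30; n_hour <- 16
  means <- c(CI = 0, CA_MATCH = 5, HA_MATCH = -5)
  d <- expand.grid(child = seq_len(3 * n), hour = seq_len(n_hour))
  d$child_id <- sprintf("c%03d", d$child)
  d$hearing_group <- rep(names(means), each = n)[d$child]
  b_child <- rnorm(3 * n, 0, 1)
  b_hour <- rnorm(n_hour, 0, 0.5)
  d$y <- means[d$hearing_group] + b_child[d$child] + b_hour[d$hour] +
    rnorm(nrow(d), 0, 1)
  m <- fit_group_model(d, "y", "hearing_group", c("child_id", "hour"))
  co <- m$coefficients
  for (g in c("CA_MATCH", "HA_MATCH")) {
    row <- co[co$term == paste0("hearing_group", g), ]
    expect_lt(abs(row$estimate - means[g]), 2 * row$se)
  }
  expect_equal(unname(m$n_groups["child_id"]), 90L)
  expect_equal(m$p_method, "normal")
  # AIC identity on the ML refit used for comparisons
  null <- fit_group_model(d, "y", character(), c("child_id", "hour"))
  cmp <- compare_models(null, m)
  expect_equal(cmp$df, 2L)
  expect_gt(cmp$chi2, 0)
})

test_that("degenerate designs error; constant outcomes do not crash", {
  tab <- toy_cohort_tab(noise = 1)
  only_ci <- tab[tab$hearing_group == "CI", ]
  expect_error(fit_group_model(only_ci, "y", "hearing_group", character()),
               "degenerate")
  const <- tab; const$y <- 3
  m <- suppressWarnings(
    fit_group_model(const, "y", "hearing_group", character()))
  expect_equal(m$coefficients$estimate[1], 3)
  expect_equal(m$coefficients$estimate[-1], c(0, 0))
  expect_match(m$note, "constant")
  bad <- tab; bad$y[1] <- NaN
  expect_error(fit_group_model(bad, "y", "hearing_group", character()),
               "non-finite")
})

test_that("compare_models satisfies its identities", {
  tab <- toy_cohort_tab(noise = 1)
  m <- fit_group_model(tab, "y", "hearing_group", random = character())
  self <- compare_models(m, m)
  expect_equal(self$chi2, 0)
  expect_equal(self$df, 0L)
  expect_equal(self$delta_aic, 0)
  expect_error(
    compare_models(m, fit_group_model(tab[-1, ], "y", "hearing_group",
                                      character())),
    "different numbers")
})

test_that("LRT chi2 grows with planted effect size", {
  set.seed(502)
  chis <- vapply(c(0, 2, 4, 8), function(eff) {
    tab <- toy_cohort_tab(n = 60, seed = 502, noise = 4)
    tab$y <- tab$y * 0 + ifelse(tab$hearing_group == "CI", 0, eff) +
      rnorm(nrow(tab), 0, 4)
    null <- fit_group_model(tab, "y", character(), character())
    full <- fit_group_model(tab, "y", "hearing_group", character())
    compare_models(null, full)$chi2
  }, numeric(1))
  expect_true(all(diff(chis) > 0))
})

test_that("cross-sectional slopes reproduce a perfect line", {
  tab <- toy_cohort_tab()
  tab$y <- 10 + 21 * tab$chrono_age_mo
  sl <- suppressWarnings(cross_sectional_slopes(tab, "y", "chrono", cfg))
  expect_equal(sl$beta, rep(21, 3))
  expect_equal(sl$pearson_r, rep(1, 3))
  expect_true(all(sl$available))
})

test_that("slopes vanish on age-permuted outcomes", {
  set.seed(503)
  tab <- toy_cohort_tab(n = 18)[1:18, ]   # one group, n = 18
  tab$y <- 100 + 2 * tab$chrono_age_mo + rnorm(18, 0, 5)
  betas <- replicate(300, {
    perm <- tab
    perm$y <- sample(perm$y)
    cross_sectional_slopes(perm, "y", "chrono", cfg)$beta[1]
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(300))
})

test_that("hearing-age slopes use only eligible CI children", {
  tab <- toy_cohort_tab(n = 10)
  tab$hearing_age_mo <- ifelse(tab$hearing_group == "CI",
                               tab$chrono_age_mo - 20, NA)
  tab$hearing_age_mo[1] <- 8          # below the 12-month floor
  tab$hearing_age_excluded <- tab$hearing_group == "CI" &
    !is.na(tab$hearing_age_mo) & tab$hearing_age_mo < 12
  tab$y <- 5 + 3 * ifelse(is.na(tab$hearing_age_mo), 0, tab$hearing_age_mo)
  sl <- suppressWarnings(cross_sectional_slopes(tab, "y", "hearing", cfg))
  expect_equal(nrow(sl), 1)
  expect_equal(sl$n, 9)
  expect_equal(sl$beta, 3)
  # tiny groups are flagged unavailable rather than fit
  small <- tab[c(1, 2, 11, 21), ]
  sl2 <- suppressWarnings(cross_sectional_slopes(small, "y", "chrono", cfg))
  expect_false(any(sl2$available[sl2$n < 3]))
})

test_that("derived per-group slopes add the interaction deviations", {
  slopes <- derive_group_slopes(2.22, c(CA_MATCH = 1.44, HA_MATCH = 1.31))
  expect_equal(unname(slopes), c(2.22, 3.66, 3.53))
})

test_that("productivity model recovers exact planted group slopes", {
  set.seed(504)
  tab <- toy_cohort_tab(n = 20)
  tab$ctc_per_hr <- runif(nrow(tab), 20, 120)
  slopes <- c(CI = 2.22, CA_MATCH = 3.66, HA_MATCH = 3.53)
  tab$cvc_per_hr <- 100 + slopes[tab$hearing_group] * tab$ctc_per_hr
  fit <- suppressWarnings(fit_productivity_model(tab))
  got <- fit$group_slopes
  expect_equal(got$slope[match(names(slopes), got$group)],
               unname(slopes))
  expect_gt(fit$comparison$chi2, 0)
  expect_equal(fit$comparison$df, 2L)
  # mean-centering invariance: shifting turns leaves slopes unchanged
  shifted <- tab
  shifted$ctc_per_hr <- shifted$ctc_per_hr + 1000
  fit2 <- suppressWarnings(fit_productivity_model(shifted))
  expect_equal(fit2$group_slopes$slope, got$slope)
})

test_that("segment-level duration slopes recover a planted age effect", {
  set.seed(505)
  n_child <- 30
  coh <- validate_cohort(data.frame(
    child_id = sprintf("h%02d", 1:n_child), hearing_group = "HA_MATCH",
    chrono_age_mo = runif(n_child, 17, 52), activation_age_mo = NA_real_,
    maternal_ed = 6, gender = "F"))
  age <- coh$chrono_age_mo
  segs <- do.call(rbind, lapply(1:n_child, function(i) {
    mu <- 800 + 6.59 * age[i] + rnorm(1, 0, 100)
    data.frame(child_id = coh$child_id[i],
               dur_ms = pmax(80, mu + rnorm(200, 0, 300)))
  }))
  ds <- voc_duration_slopes(segs, coh, "chrono", cfg)
  row <- ds[ds$group == "HA_MATCH", ]
  expect_lt(abs(row$beta - 6.59), 2 * row$se)
  expect_false(ds$available[ds$group == "CI"])
})

test_that("sensitivity rerun warns on absent ids and tracks leverage", {
  set.seed(506)
  tab <- toy_cohort_tab(n = 12, noise = 1)
  tab$ctc_per_hr <- runif(nrow(tab), 20, 120)
  tab$cvc_per_hr <- 100 + 2.5 * tab$ctc_per_hr + rnorm(nrow(tab), 0, 10)
  tab$awc_per_hr <- 900 + 10 * tab$chrono_age_mo + rnorm(nrow(tab), 0, 50)
  tab$adult_sec_per_hr <- 280 + rnorm(nrow(tab), 0, 20)
  tab$hearing_age_mo <- ifelse(tab$hearing_group == "CI",
                               tab$chrono_age_mo - 18, NA)
  tab$hearing_age_excluded <- FALSE

  cfg_absent <- analysis_config(exclude_child_ids = "nobody")
  expect_warning(out <- sensitivity_rerun(
    tab, cfg_absent, outcomes = c("awc_per_hr", "cvc_per_hr")), "no-op")
  expect_equal(out$shifts$shift, rep(0, nrow(out$shifts)))

  # plant an extreme-leverage child in the CI group and exclude it
  lev <- tab
  lev$awc_per_hr[1] <- lev$awc_per_hr[1] + 4000
  cfg_x <- analysis_config(exclude_child_ids = lev$child_id[1])
  out2 <- sensitivity_rerun(lev, cfg_x,
                            outcomes = c("awc_per_hr", "cvc_per_hr"))
  oracle <- coef(lm(awc_per_hr ~ chrono_age_mo,
                    data = lev[lev$hearing_group == "CI", ][-1, ]))[2]
  red_beta <- out2$reduced$slopes
  red_beta <- red_beta$beta[red_beta$group == "CI" &
                              red_beta$age_basis == "chrono" &
                              red_beta$outcome_name == "awc_per_hr"]
  expect_equal(red_beta, unname(oracle))
})
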