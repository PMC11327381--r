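## Statistical layer: hearing-group mixed models with random intercepts by
## child (and by hour of recording for hourly outcomes), likelihood-ratio
## model comparison, cross-sectional age slopes per hearing group with
## Pearson correlations, the turns x group vocal-productivity regression,
## and outlier-exclusion sensitivity reruns.
##
## Hearing group is treatment-coded with CI as the reference level, so the
## CA_MATCH / HA_MATCH coefficients are deviations from the CI group.
## Continuous predictors are mean-centered before fitting. Fixed-effect p
## values for mixed fits use a normal approximation on t (recorded as
## p_method in the result); LRTs always refit by maximum likelihood.

group_factor <- function(x) factor(as.character(x), levels = HEARING_GROUPS)

new_model_result <- function(outcome, fit, data, p_method, note = NULL) {
  is_mer <- inherits(fit, "merMod")
  co <- if (is_mer) summary(fit)$coefficients else summary(fit)$coefficients
  co <- as.data.frame(co)
  tcol <- if ("t value" %in% names(co)) "t value" else names(co)[3]
  coefs <- data.frame(term = rownames(co),
                      estimate = co[, 1],
                      se = co[, 2],
                      t = co[, tcol],
                      row.names = NULL)
  coefs$p <- if (is_mer) 2 * stats::pnorm(-abs(coefs$t)) else
    as.data.frame(summary(fit)$coefficients)[, 4]
  ll <- stats::logLik(fit)
  ngrp <- if (is_mer) vapply(lme4::ngrps(fit), as.integer, 1L) else integer()
  structure(list(outcome_name = outcome,
                 coefficients = coefs,
                 loglik = as.numeric(ll),
                 df = as.integer(attr(ll, "df")),
                 aic = stats::AIC(fit),
                 n_obs = stats::nobs(fit),
                 n_groups = ngrp,
                 p_method = p_method,
                 reml = is_mer && lme4::isREML(fit),
                 note = note,
                 fit = fit,
                 data = data),
            class = "daylong_model")
}

#' @export
print.daylong_model <- function(x, ...) {
  cat(sprintf("<daylong_model %s: n=%d, logLik=%.2f, AIC=%.2f%s>\n",
              x$outcome_name, x$n_obs, x$loglik, x$aic,
              if (length(x$n_groups))
                paste0(", groups [",
                       paste(names(x$n_groups), x$n_groups, sep = "=",
                             collapse = ", "), "]") else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

center_numeric <- function(data, vars) {
  for (v in vars) {
    if (is.numeric(data[[v]])) data[[v]] <- data[[v]] - mean(data[[v]])
  }
  data
}

#' Fit a hearing-group (or covariate) mixed model
#'
#' Linear mixed model of `outcome` on `predictors` with random intercepts
#' for each factor in `random`. Hearing group, when present, is
#' treatment-coded with CI as the reference; continuous predictors are
#' mean-centered first. Hourly outcomes should pass
#' `random = c("child_id", "hour")`; repeated segment-level outcomes
#' (vocalization duration) `random = "child_id"`.
#'
#' @param data Long-format data frame (e.g. from [hourly_long_table()]
#'   merged with cohort metadata, or segment-level durations).
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of fixed-effect columns (default
#'   `"hearing_group"`; use `character()` for a random-effects-only null).
#' @param random Character vector of grouping-factor columns.
#' @param reml Fit by REML (default TRUE); LRTs refit by ML regardless.
#' @return A `daylong_model`.
#' @export
fit_group_model <- function(data, outcome, predictors = "hearing_group",
                            random = c("child_id", "hour"), reml = TRUE) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) stop("outcome column not found: ", outcome)
  y <- data[[outcome]]
  if (any(!is.finite(y))) stop("non-finite values in outcome ", outcome)
  random <- intersect(random, names(data))
  for (g in random) {
    data[[g]] <- factor(data[[g]])
    if (nlevels(data[[g]]) < 2)
      stop("degenerate design: grouping factor '", g,
           "' has a single level")
  }
  if ("hearing_group" %in% predictors) {
    data$hearing_group <- group_factor(data$hearing_group)
    data <- droplevels(data)
    if (!"CI" %in% levels(data$hearing_group) ||
        nlevels(data$hearing_group) < 2)
      stop("degenerate design: hearing_group needs the CI reference level ",
           "plus at least one comparison level")
  }
  data <- center_numeric(data, setdiff(predictors, "hearing_group"))
  rhs <- paste(c(if (length(predictors)) predictors else "1",
                 sprintf("(1 | %s)", random)), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  note <- NULL
  if (stats::sd(y) < 1e-12) {
    # Constant outcome: variance components are 0; fall back to a plain
    # linear model so the degenerate fit is still representable.
    form_lm <- stats::as.formula(paste(
      outcome, "~", if (length(predictors))
        paste(predictors, collapse = " + ") else "1"))
    fit <- stats::lm(form_lm, data = data)
    return(new_model_result(outcome, fit, data, "lm",
                            note = "constant outcome; fixed-effects fit"))
  }
  if (length(random)) {
    fit <- suppressMessages(lme4::lmer(form, data = data, REML = reml))
    new_model_result(outcome, fit, data, "normal", note = note)
  } else {
    fit <- stats::lm(form, data = data)
    new_model_result(outcome, fit, data, "lm")
  }
}

refit_ml <- function(m) {
  if (inherits(m$fit, "merMod") && lme4::isREML(m$fit))
    lme4::refitML(m$fit)
  else m$fit
}

#' Likelihood-ratio comparison of nested models
#'
#' Both models are refit by maximum likelihood (REML log-likelihoods are
#' not comparable across fixed-effect structures), then
#' `chi2 = 2 (logLik_full - logLik_null)`, with the degrees of freedom the
#' difference in estimated-parameter counts and the p value from the
#' chi-square reference distribution. `delta_aic` is `AIC_null - AIC_full`
#' (positive favours the full model).
#'
#' @param null_model,full_model Nested `daylong_model` objects fit to the
#'   same rows.
#' @return List `chi2`, `df`, `p`, `delta_aic`, class
#'   `daylong_comparison`.
#' @export
compare_models <- function(null_model, full_model) {
  if (null_model$n_obs != full_model$n_obs)
    stop("models were fit to different numbers of observations")
  f0 <- refit_ml(null_model)
  f1 <- refit_ml(full_model)
  ll0 <- stats::logLik(f0)
  ll1 <- stats::logLik(f1)
  df <- as.integer(attr(ll1, "df") - attr(ll0, "df"))
  if (df < 0)
    stop("full model has fewer parameters than the null; models must be ",
         "nested with the null smaller")
  chi2 <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  structure(list(chi2 = chi2, df = df,
                 p = if (df >= 1)
                   stats::pchisq(chi2, df, lower.tail = FALSE)
                 else NA_real_,
                 delta_aic = stats::AIC(f0) - stats::AIC(f1)),
            class = "daylong_comparison")
}

#' @export
print.daylong_comparison <- function(x, ...) {
  cat(sprintf("<LRT chi2 = %.3f, df = %d, p = %s, delta AIC = %.3f>\n",
              x$chi2, x$df, format.pval(x$p, digits = 3), x$delta_aic))
  invisible(x)
}

#' Cross-sectional age slopes by hearing group
#'
#' Per hearing group, the ordinary least-squares slope of a per-child
#' environment metric on age in months, with the Pearson correlation and
#' the slope's p value. On the chronological basis all three groups are
#' fit; on the hearing basis only CI children with at least
#' `config$min_hearing_age_mo` months of hearing experience (their typical
#' hearing matches have no activation date). Groups with fewer than 3
#' children are flagged unavailable.
#'
#' @param tab Per-child table from [metrics_table()].
#' @param outcome Name of the metric column.
#' @param age_basis `"chrono"` or `"hearing"`.
#' @param config A `daylong_config`.
#' @return Data frame: `group`, `age_basis`, `outcome_name`, `n`, `beta`,
#'   `se`, `pearson_r`, `p`, `available`.
#' @export
cross_sectional_slopes <- function(tab, outcome,
                                   age_basis = c("chrono", "hearing"),
                                   config = analysis_config()) {
  age_basis <- match.arg(age_basis)
  tab <- as.data.frame(tab)
  if (!outcome %in% names(tab)) stop("outcome column not found: ", outcome)
  groups <- if (age_basis == "chrono") HEARING_GROUPS else "CI"
  rows <- lapply(groups, function(g) {
    sub <- tab[tab$hearing_group == g, , drop = FALSE]
    if (age_basis == "hearing") {
      sub <- sub[!sub$hearing_age_excluded &
                   is.finite(sub$hearing_age_mo), , drop = FALSE]
      sub$age <- sub$hearing_age_mo
    } else {
      sub$age <- sub$chrono_age_mo
    }
    base <- data.frame(group = g, age_basis = age_basis,
                       outcome_name = outcome, n = nrow(sub))
    if (nrow(sub) < 3 || stats::sd(sub$age) == 0)
      return(cbind(base, data.frame(beta = NA_real_, se = NA_real_,
                                    pearson_r = NA_real_, p = NA_real_,
                                    available = FALSE)))
    fit <- stats::lm(stats::as.formula(paste(outcome, "~ age")), data = sub)
    sm <- summary(fit)$coefficients
    cbind(base, data.frame(beta = sm["age", 1], se = sm["age", 2],
                           pearson_r = stats::cor(sub$age, sub[[outcome]]),
                           p = sm["age", 4], available = TRUE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cross-sectional vocalization-duration slopes (segment level)
#'
#' Vocalization duration is a repeated measure (one value per CHN clip), so
#' the per-group age slope comes from a linear mixed model on segment-level
#' durations with random intercepts by child; the Pearson correlation is
#' still computed on per-child mean durations, mirroring the per-child
#' scatter the slope summarizes.
#'
#' @param seg_tab Data frame of CHN clip durations: `child_id`, `dur_ms`
#'   (e.g. row-bound [voc_durations()]).
#' @param cohort Validated cohort table.
#' @param age_basis `"chrono"` or `"hearing"`.
#' @param config A `daylong_config`.
#' @param max_segments_per_child Optional subsampling cap per child (used
#'   by large simulation harnesses; the estimator is unchanged, only less
#'   precise). Default `Inf`.
#' @return Data frame in the same layout as [cross_sectional_slopes()].
#' @export
voc_duration_slopes <- function(seg_tab, cohort,
                                age_basis = c("chrono", "hearing"),
                                config = analysis_config(),
                                max_segments_per_child = Inf) {
  age_basis <- match.arg(age_basis)
  cohort <- as.data.frame(cohort)
  dt <- data.table::as.data.table(seg_tab)[, c("child_id", "dur_ms")]
  if (is.finite(max_segments_per_child) && nrow(dt)) {
    dt <- dt[, if (.N > max_segments_per_child)
      .SD[sample.int(.N, max_segments_per_child)] else .SD,
      by = "child_id"]
  }
  meta <- data.table::as.data.table(
    cohort[, c("child_id", "hearing_group", "chrono_age_mo",
               "hearing_age_mo")])
  seg_tab <- as.data.frame(meta[dt, on = "child_id"])
  if (age_basis == "hearing") {
    keep <- cohort$hearing_group == "CI" &
      is.finite(cohort$hearing_age_mo) &
      cohort$hearing_age_mo >= config$min_hearing_age_mo
    seg_tab <- seg_tab[seg_tab$child_id %in% cohort$child_id[keep], ,
                       drop = FALSE]
    seg_tab$age <- seg_tab$hearing_age_mo
    groups <- "CI"
  } else {
    seg_tab$age <- seg_tab$chrono_age_mo
    groups <- HEARING_GROUPS
  }
  rows <- lapply(groups, function(g) {
    sub <- seg_tab[seg_tab$hearing_group == g, , drop = FALSE]
    n_child <- length(unique(sub$child_id))
    base <- data.frame(group = g, age_basis = age_basis,
                       outcome_name = "voc_dur_ms", n = n_child)
    if (n_child < 3)
      return(cbind(base, data.frame(beta = NA_real_, se = NA_real_,
                                    pearson_r = NA_real_, p = NA_real_,
                                    available = FALSE)))
    sub$age_c <- sub$age - mean(sub$age)
    fit <- suppressMessages(
      lme4::lmer(dur_ms ~ age_c + (1 | child_id), data = sub, REML = TRUE))
    sm <- summary(fit)$coefficients
    per_child <- stats::aggregate(cbind(dur_ms, age) ~ child_id, data = sub,
                                  FUN = mean)
    cbind(base, data.frame(
      beta = sm["age_c", 1], se = sm["age_c", 2],
      pearson_r = stats::cor(per_child$age, per_child$dur_ms),
      p = 2 * stats::pnorm(-abs(sm["age_c", "t value"])),
      available = TRUE))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Vocal-productivity model: turns x hearing group
#'
#' Linear regression of hourly child vocalizations on hourly conversational
#' turns, controlling for chronological age, with a turns-by-group
#' interaction; continuous terms are mean-centered and the group factor is
#' CI-referenced. Per-group turn slopes are derived as the CI slope plus
#' the group's interaction deviation, with standard errors from the
#' coefficient covariance. The interaction's contribution is tested by ML
#' likelihood ratio against the no-interaction model.
#'
#' @param tab Per-child table with `cvc_per_hr`, `ctc_per_hr`,
#'   `chrono_age_mo`, `hearing_group`.
#' @return List `model` (`daylong_model`), `comparison`
#'   (`daylong_comparison`, interaction LRT), `group_slopes` (data frame
#'   `group`, `slope`, `se`).
#' @export
fit_productivity_model <- function(tab) {
  tab <- as.data.frame(tab)
  need <- c("cvc_per_hr", "ctc_per_hr", "chrono_age_mo", "hearing_group")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(tab$cvc_per_hr))) stop("non-finite cvc_per_hr")
  tab$hearing_group <- group_factor(tab$hearing_group)
  tab <- droplevels(tab)
  if (!"CI" %in% levels(tab$hearing_group))
    stop("degenerate design: no CI children")
  tab$ctc_c <- tab$ctc_per_hr - mean(tab$ctc_per_hr)
  tab$age_c <- tab$chrono_age_mo - mean(tab$chrono_age_mo)
  full <- stats::lm(cvc_per_hr ~ age_c + ctc_c * hearing_group, data = tab)
  null <- stats::lm(cvc_per_hr ~ age_c + ctc_c + hearing_group, data = tab)
  mres <- new_model_result("cvc_per_hr", full, tab, "lm")
  cmp <- compare_models(new_model_result("cvc_per_hr", null, tab, "lm"),
                        mres)
  b <- stats::coef(full)
  V <- stats::vcov(full)
  slopes <- lapply(levels(tab$hearing_group), function(g) {
    terms <- "ctc_c"
    if (g != "CI") terms <- c(terms, paste0("ctc_c:hearing_group", g))
    terms <- intersect(terms, names(b))
    w <- as.numeric(names(b) %in% terms)
    data.frame(group = g, slope = sum(b[terms]),
               se = sqrt(drop(t(w) %*% V %*% w)))
  })
  list(model = mres, comparison = cmp,
       group_slopes = do.call(rbind, c(slopes,
                                       list(make.row.names = FALSE))))
}

#' Derived per-group slopes from a CI-referenced interaction fit
#'
#' Convenience for reading an interaction model: the reference (CI) slope
#' plus each group's interaction deviation.
#'
#' @param ci_slope Slope for the CI reference group.
#' @param deviations Named numeric vector of interaction deviations.
#' @return Named numeric vector of per-group slopes (CI first).
#' @export
#' @examples
#' derive_group_slopes(2.22, c(CA_MATCH = 1.44, HA_MATCH = 1.31))
derive_group_slopes <- function(ci_slope, deviations) {
  c(CI = unname(ci_slope), ci_slope + deviations)
}

#' Sensitivity rerun with children excluded
#'
#' Refits the cross-sectional slope tables (both age bases, every metric
#' outcome) and the vocal-productivity model on the cohort with
#' `config$exclude_child_ids` removed, and reports coefficient shifts
#' against the full-cohort fits. Used to confirm robustness to influential
#' children (e.g. an activation-age outlier).
#'
#' @param tab Per-child table from [metrics_table()].
#' @param config A `daylong_config` with non-empty `exclude_child_ids`.
#' @param seg_tab Optional segment-level CHN durations for the
#'   vocalization-duration slopes.
#' @param cohort Cohort table (required when `seg_tab` is given).
#' @param outcomes Metric columns to refit slopes for.
#' @return List `full`, `reduced` (each: `slopes`, `productivity`, and
#'   `dur_slopes` when `seg_tab` given) and `shifts` (slope differences,
#'   reduced minus full).
#' @export
sensitivity_rerun <- function(tab, config, seg_tab = NULL, cohort = NULL,
                              outcomes = c("awc_per_hr", "adult_sec_per_hr",
                                           "cvc_per_hr", "ctc_per_hr")) {
  ids <- config$exclude_child_ids
  if (!length(ids)) stop("config$exclude_child_ids is empty")
  present <- ids %in% tab$child_id
  if (!any(present)) {
    warning("no excluded child_id present in the cohort; rerun is a no-op")
  } else if (!all(present)) {
    warning("excluded child_id(s) not in cohort: ",
            paste(ids[!present], collapse = ", "))
  }
  red <- tab[!tab$child_id %in% ids, , drop = FALSE]
  for (g in HEARING_GROUPS)
    if (sum(red$hearing_group == g) == 0 && any(tab$hearing_group == g))
      stop("degenerate design: exclusion empties group ", g)
  fit_set <- function(t, s) {
    sl <- do.call(rbind, c(
      lapply(outcomes, function(o) rbind(
        cross_sectional_slopes(t, o, "chrono", config),
        cross_sectional_slopes(t, o, "hearing", config))),
      list(make.row.names = FALSE)))
    out <- list(slopes = sl, productivity = fit_productivity_model(t))
    if (!is.null(s)) {
      s <- s[s$child_id %in% t$child_id, , drop = FALSE]
      out$dur_slopes <- rbind(
        voc_duration_slopes(s, cohort[cohort$child_id %in% t$child_id, ],
                            "chrono", config),
        voc_duration_slopes(s, cohort[cohort$child_id %in% t$child_id, ],
                            "hearing", config))
    }
    out
  }
  full <- fit_set(tab, seg_tab)
  reduced <- fit_set(red, seg_tab)
  shifts <- full$slopes[, c("group", "age_basis", "outcome_name")]
  shifts$beta_full <- full$slopes$beta
  shifts$beta_reduced <- reduced$slopes$beta
  shifts$shift <- shifts$beta_reduced - shifts$beta_full
  list(full = full, reduced = reduced, shifts = shifts)
}

#' Serialize model results to JSON-ready lists
#' @param x A `daylong_model`, `daylong_comparison`, or list of them.
#' @return A plain list suitable for `jsonlite::write_json`.
#' @export
model_to_list <- function(x) {
  if (inherits(x, "daylong_model")) {
    list(outcome = x$outcome_name,
         coefficients = x$coefficients,
         loglik = x$loglik, aic = x$aic, n_obs = x$n_obs,
         n_groups = as.list(x$n_groups), p_method = x$p_method,
         reml = x$reml, note = x$note)
  } else if (inherits(x, "daylong_comparison")) {
    x[c("chi2", "df", "p", "delta_aic")]
  } else if (is.list(x)) {
    lapply(x, model_to_list)
  } else x
}
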