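#' Cohort statistics configuration
#'
#' Thresholds of the selection plan: candidates with univariate p below
#' `enter_p` are eligible for the multivariate model; forward stepwise
#' selection adds the best candidate while its entry p is below `enter_p`
#' and removes included terms whose Wald p exceeds `remove_p`;
#' `significance_p` is the reporting threshold.
#'
#' @param enter_p entry threshold (default 0.1).
#' @param remove_p removal threshold (default 0.1).
#' @param significance_p significance threshold (default 0.05).
#' @param enter_test statistic used to rank and admit candidates:
#'   `"lrt"` (partial-likelihood ratio, default) or `"wald"`.
#' @export
stats_config <- function(enter_p = 0.1, remove_p = 0.1, significance_p = 0.05,
                         enter_test = c("lrt", "wald")) {
  if (any(c(enter_p, remove_p, significance_p) <= 0) ||
      any(c(enter_p, remove_p, significance_p) >= 1)) {
    stop_tips3d("tips3d_bad_input", "thresholds must lie strictly in (0, 1)")
  }
  structure(list(enter_p = enter_p, remove_p = remove_p,
                 significance_p = significance_p,
                 enter_test = match.arg(enter_test)),
            class = "stats_config")
}

#' Nonparametric group comparison table
#'
#' One row per variable: Mann-Whitney U test for continuous variables
#' (medians with interquartile range per group), chi-square test for
#' categorical variables (counts per group). Missing values are excluded
#' pairwise; a variable constant in both groups is reported with p = 1 and
#' flagged.
#'
#' @param records a data frame of subject records.
#' @param group_flag name of a two-level grouping column (logical, factor
#'   or two-valued vector).
#' @param vars variables to compare (default: all other columns).
#' @return a tibble with columns `variable`, `type`, `group1`, `group2`
#'   (per-group summaries; levels in the `groups` attribute), `n_used`,
#'   `p_value`, `flag`.
#' @export
compare_groups <- function(records, group_flag, vars = NULL) {
  g_raw <- records[[group_flag]]
  g <- factor(g_raw)
  if (nlevels(g) != 2L) {
    stop_tips3d("tips3d_bad_input", "group_flag must have exactly two levels")
  }
  if (!all(table(g) > 0)) {
    stop_tips3d("tips3d_bad_input", "both groups must be non-empty")
  }
  if (is.null(vars)) vars <- setdiff(names(records), group_flag)

  summarise_num <- function(x) {
    if (all(is.na(x))) return(NA_character_)
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    sprintf("%.2f (%.2f-%.2f)", q[2], q[1], q[3])
  }
  summarise_cat <- function(x) {
    if (all(is.na(x))) return(NA_character_)
    tab <- table(x)
    paste(sprintf("%s=%d (%.1f%%)", names(tab), as.integer(tab),
                  100 * as.integer(tab) / sum(tab)), collapse = ", ")
  }

  rows <- lapply(vars, function(v) {
    x <- records[[v]]
    ok <- !is.na(x) & !is.na(g)
    x_ok <- x[ok]; g_ok <- droplevels(g[ok])
    numeric_var <- is.numeric(x)
    row <- tibble::tibble(variable = v,
                          type = if (numeric_var) "continuous" else "categorical",
                          group1 = NA_character_, group2 = NA_character_,
                          n_used = sum(ok), p_value = NA_real_, flag = "")
    if (sum(ok) == 0L || nlevels(g_ok) < 2L) {
      row$flag <- "all-missing"
      return(row)
    }
    split_x <- split(x_ok, g_ok)
    if (numeric_var) {
      row$group1 <- summarise_num(split_x[[1]])
      row$group2 <- summarise_num(split_x[[2]])
      if (length(unique(x_ok)) < 2L) {
        row$p_value <- 1; row$flag <- "constant"
      } else {
        row$p_value <- suppressWarnings(
          wilcox.test(split_x[[1]], split_x[[2]], exact = FALSE)$p.value)
      }
    } else {
      row$group1 <- summarise_cat(split_x[[1]])
      row$group2 <- summarise_cat(split_x[[2]])
      if (length(unique(x_ok)) < 2L) {
        row$p_value <- 1; row$flag <- "constant"
      } else {
        row$p_value <- suppressWarnings(
          chisq.test(table(g_ok, x_ok))$p.value)
      }
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "groups") <- levels(g)
  out
}

# surv formula on complete cases; returns NULL-safe pieces
cox_data <- function(records, variables, time, event) {
  need <- c(time, event, variables)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop_tips3d("tips3d_bad_input",
                paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  df <- records[stats::complete.cases(records[, need, drop = FALSE]),
                need, drop = FALSE]
  df[[event]] <- as.integer(as.logical(df[[event]]))
  df
}

fit_cox <- function(df, variables, time, event) {
  f <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", variables), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w),
                ignore.case = TRUE)) warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (warned || any(!is.finite(stats::coef(fit)[variables] %||% NA)) ||
      anyNA(stats::coef(fit))) {
    attr(fit, "unstable") <- TRUE
  }
  fit
}

cox_terms_tibble <- function(fit, n) {
  s <- summary(fit)
  co <- s$coefficients
  tibble::tibble(variable = rownames(co),
                 hr = exp(co[, "coef"]),
                 ci_low = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
                 ci_high = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
                 p = co[, "Pr(>|z|)"],
                 n = n)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Efron tie handling) of a single covariate
#' against the time-to-event endpoint; records with the covariate missing
#' are excluded for this analysis. The hazard ratio is per unit of the
#' covariate with a Wald 95% CI and p-value.
#'
#' @param records a data frame of subject records.
#' @param variable covariate column name.
#' @param time,event names of the time (days) and event-indicator columns.
#' @return a one-row tibble: `variable`, `hr`, `ci_low`, `ci_high`, `p`, `n`.
#' @export
cox_univariate <- function(records, variable,
                           time = "time_to_event_days", event = "event") {
  df <- cox_data(records, variable, time, event)
  if (sum(df[[event]]) < 2L) {
    stop_tips3d("tips3d_no_events", "fewer than 2 events")
  }
  x <- df[[variable]]
  if (is.numeric(x) && stats::var(x) == 0 ||
      !is.numeric(x) && length(unique(x)) < 2L) {
    stop_tips3d("tips3d_bad_input",
                sprintf("'%s' does not vary in the analysed cases", variable))
  }
  fit <- fit_cox(df, variable, time, event)
  if (isTRUE(attr(fit, "unstable"))) {
    stop_tips3d("tips3d_convergence",
                sprintf("Cox fit for '%s' did not converge", variable))
  }
  cox_terms_tibble(fit, nrow(df))
}

#' Forward stepwise multivariate Cox selection
#'
#' Iteratively adds the candidate with the smallest entry p-value below
#' `enter_p` (likelihood-ratio against the current model, refit on the
#' common complete cases), then removes any included term whose Wald p
#' exceeds `remove_p`, until the model is stable. Candidates are expected
#' to be pre-screened at the univariate `enter_p` (see
#' [screen_candidates()]). An empty final model is a legitimate result,
#' not an error.
#'
#' @param records a data frame of subject records.
#' @param candidates candidate covariate names.
#' @param time,event endpoint column names.
#' @param cfg a [stats_config()].
#' @return a `cox_stepwise` object; [tidy()] gives the per-variable hazard
#'   ratios of the final model, [glance()] the model summary.
#' @export
cox_forward_stepwise <- function(records, candidates,
                                 time = "time_to_event_days",
                                 event = "event", cfg = stats_config()) {
  selected <- character(0)
  steps <- list()
  if (length(candidates)) {
    df_all <- cox_data(records, character(0), time, event)
    if (sum(df_all[[event]]) < 2L) {
      stop_tips3d("tips3d_no_events", "fewer than 2 events")
    }
  }
  repeat {
    changed <- FALSE
    # entry scan
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      entry <- vapply(pool, function(v) {
        df <- tryCatch(cox_data(records, c(selected, v), time, event),
                       error = function(e) NULL)
        if (is.null(df) || sum(df[[event]]) < 2L) return(NA_real_)
        fit1 <- tryCatch(fit_cox(df, c(selected, v), time, event),
                         error = function(e) NULL)
        if (is.null(fit1) || isTRUE(attr(fit1, "unstable"))) return(NA_real_)
        if (cfg$enter_test == "wald") {
          s <- summary(fit1)$coefficients
          return(s[nrow(s), "Pr(>|z|)"])
        }
        ll1 <- fit1$loglik[2]
        ll0 <- if (length(selected)) {
          fit_cox(df, selected, time, event)$loglik[2]
        } else fit1$loglik[1]
        1 - pchisq(2 * (ll1 - ll0), df = 1)
      }, numeric(1))
      if (any(!is.na(entry)) && min(entry, na.rm = TRUE) < cfg$enter_p) {
        best <- pool[which.min(entry)]
        selected <- c(selected, best)
        steps[[length(steps) + 1L]] <- tibble::tibble(
          action = "add", variable = best, p = min(entry, na.rm = TRUE))
        changed <- TRUE
      }
    }
    # removal scan
    repeat {
      if (length(selected) == 0L) break
      df <- cox_data(records, selected, time, event)
      fit <- fit_cox(df, selected, time, event)
      co <- summary(fit)$coefficients
      worst <- which.max(co[, "Pr(>|z|)"])
      if (co[worst, "Pr(>|z|)"] > cfg$remove_p) {
        drop_v <- selected[worst]
        selected <- setdiff(selected, drop_v)
        steps[[length(steps) + 1L]] <- tibble::tibble(
          action = "remove", variable = drop_v, p = co[worst, "Pr(>|z|)"])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(selected)) {
    df <- cox_data(records, selected, time, event)
    fit <- fit_cox(df, selected, time, event)
    terms <- cox_terms_tibble(fit, nrow(df))
    n_events <- sum(df[[event]])
  } else {
    fit <- NULL
    terms <- tibble::tibble(variable = character(0), hr = numeric(0),
                            ci_low = numeric(0), ci_high = numeric(0),
                            p = numeric(0), n = integer(0))
    n_events <- NA_integer_
  }
  structure(list(terms = terms, selected = selected, fit = fit,
                 steps = dplyr::bind_rows(steps), cfg = cfg,
                 n_events = n_events),
            class = "cox_stepwise")
}

#' @export
print.cox_stepwise <- function(x, ...) {
  cat(sprintf("<cox_stepwise> %d term(s) selected\n", length(x$selected)))
  if (nrow(x$terms)) print(x$terms)
  invisible(x)
}

#' @rdname cox_forward_stepwise
#' @param x a `cox_stepwise` object.
#' @param ... unused.
#' @method tidy cox_stepwise
#' @export
tidy.cox_stepwise <- function(x, ...) x$terms

#' @rdname cox_forward_stepwise
#' @method glance cox_stepwise
#' @export
glance.cox_stepwise <- function(x, ...) {
  tibble::tibble(n_terms = length(x$selected),
                 n = if (nrow(x$terms)) x$terms$n[1] else NA_integer_,
                 n_events = x$n_events,
                 loglik = if (!is.null(x$fit)) x$fit$loglik[2] else NA_real_)
}

#' Forest plot of hazard ratios
#' @param object a `cox_stepwise` object.
#' @param ... unused.
#' @method autoplot cox_stepwise
#' @export
autoplot.cox_stepwise <- function(object, ...) {
  ggplot2::ggplot(object$terms,
                  ggplot2::aes(x = .data$hr, y = .data$variable)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Screen candidates at the univariate entry threshold
#'
#' @inheritParams cox_forward_stepwise
#' @param variables covariates to screen.
#' @return the subset of `variables` with univariate p below `cfg$enter_p`,
#'   with the univariate table as attribute `univariate`.
#' @export
screen_candidates <- function(records, variables,
                              time = "time_to_event_days", event = "event",
                              cfg = stats_config()) {
  uni <- dplyr::bind_rows(lapply(variables, function(v) {
    tryCatch(cox_univariate(records, v, time, event),
             tips3d_error = function(e) tibble::tibble(
               variable = v, hr = NA_real_, ci_low = NA_real_,
               ci_high = NA_real_, p = NA_real_, n = NA_integer_))
  }))
  keep <- uni$variable[!is.na(uni$p) & uni$p < cfg$enter_p]
  structure(keep, univariate = uni)
}

#' Sensitivity analysis for the imaging delay
#'
#' Refits the multivariate model with the time from the procedure to CT
#' acquisition added to the covariates that carried the multivariate
#' association (stent curvature and the cranial-end-to-IVC distance), using
#' the same stepwise rule. Records without the delay recorded are excluded
#' (complete-case) and counted.
#'
#' @param records a data frame of subject records.
#' @param cfg a [stats_config()].
#' @param geometry_vars the retained geometry covariates.
#' @param ct_var name of the delay column (days).
#' @param time,event endpoint column names.
#' @return a `cox_stepwise` object with attribute `n_excluded`.
#' @export
sensitivity_time_to_ct <- function(records, cfg = stats_config(),
                                   geometry_vars = c("max_curvature_deg",
                                                     "cranial_end_to_ivc_mm"),
                                   ct_var = "time_tips_to_ct_days",
                                   time = "time_to_event_days",
                                   event = "event") {
  if (nrow(records) == 0L) {
    stop_tips3d("tips3d_bad_input", "empty cohort")
  }
  vars <- c(geometry_vars, ct_var)
  complete <- stats::complete.cases(records[, c(time, event, vars),
                                           drop = FALSE])
  out <- cox_forward_stepwise(records[complete, , drop = FALSE], vars,
                              time = time, event = event, cfg = cfg)
  attr(out, "n_excluded") <- sum(!complete)
  out
}

# truncated-normal sampler (lower bound), inverse-CDF form
rtnorm_low <- function(n, mean, sd, lower = 0) {
  u <- runif(n, stats::pnorm(lower, mean, sd), 1)
  qnorm(u, mean, sd)
}

#' Simulate a synthetic TIPS cohort
#'
#' Draws geometry covariates matched to the measured cohort's medians and
#' interquartile ranges (normal with median as centre and IQR/1.349 as
#' spread, truncated at zero where negative values are meaningless),
#' procedure covariates and scores from their reported distributions, and
#' event times from an exponential proportional-hazards model
#' `hazard = baseline_rate * exp(sum(beta * x))` with independent
#' exponential censoring.
#'
#' @param n cohort size (at least 10).
#' @param effects named vector of per-unit log hazard ratios; the defaults
#'   are the reported multivariate effects: log(1.020) per degree of stent
#'   curvature and log(1.061) per mm of cranial-end-to-IVC distance.
#' @param baseline_rate baseline hazard per day (default 3.1e-4, anchoring
#'   the median event time near the cohort's 539 days at median covariates).
#' @param censor_rate exponential censoring rate per day (default 5.5e-4,
#'   about 30% censoring under the default effects).
#' @param n_noise number of additional standard-normal noise covariates
#'   (`noise1`, `noise2`, ...).
#' @param seed RNG seed; identical seeds reproduce the cohort exactly.
#' @return a tibble of subject records with endpoint columns `event` and
#'   `time_to_event_days`.
#' @export
simulate_cohort <- function(n,
                            effects = c(max_curvature_deg = log(1.020),
                                        cranial_end_to_ivc_mm = log(1.061)),
                            baseline_rate = 3.1e-4, censor_rate = 5.5e-4,
                            n_noise = 0, seed = 1L) {
  if (n < 10) stop_tips3d("tips3d_bad_input", "need n >= 10")
  if (!is.finite(baseline_rate) || baseline_rate <= 0 ||
      !is.finite(censor_rate) || censor_rate < 0) {
    stop_tips3d("tips3d_bad_input", "invalid hazard or censoring rate")
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)

  iqr_sd <- function(q1, q3) (q3 - q1) / (2 * qnorm(0.75))
  rec <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    cranial_end_to_ivc_mm = rtnorm_low(n, 9.99, iqr_sd(2.00, 17.93)),
    min_stent_diameter_mm = rtnorm_low(n, 8.27, iqr_sd(7.71, 9.01)),
    covered_length_mm = rtnorm_low(n, 63.03, iqr_sd(55.01, 72.00)),
    max_curvature_deg = rtnorm_low(n, 42.12, iqr_sd(36.47, 50.37)),
    covered_ends_angle_deg = rtnorm_low(n, 81.60, iqr_sd(66.88, 98.73)),
    alpha_angle_deg = rtnorm_low(n, 53.71, iqr_sd(40.64, 64.92)),
    confluence_to_stent_mm = rtnorm_low(n, 60.02, iqr_sd(48.02, 77.04)),
    nominal_stent_length_cm = sample(c(6, 7, 8, 9), n, replace = TRUE,
                                     prob = c(0.3, 0.3, 0.3, 0.1)),
    nominal_stent_diameter_mm = sample(c(8, 10, 12), n, replace = TRUE,
                                       prob = c(0.1, 0.8, 0.1)),
    dilatation_mm = sample(c(7, 8, 9), n, replace = TRUE,
                           prob = c(0.1, 0.8, 0.1)),
    underdilated = runif(n) < 0.865,
    stent_type = sample(c("VTS", "VCX"), n, replace = TRUE,
                        prob = c(0.57, 0.43)),
    meld = round(rtnorm_low(n, 10, iqr_sd(8, 13), lower = 6)),
    child_pugh = pmin(15, pmax(5, round(rtnorm_low(n, 9, iqr_sd(7, 10), 5)))),
    cv_pressure_pre = round(rtnorm_low(n, 6, iqr_sd(4, 10))),
    pv_pressure_pre = round(rtnorm_low(n, 26.5, iqr_sd(23, 32))),
    pspg_pre = round(rtnorm_low(n, 20, iqr_sd(16, 23))),
    cv_pressure_post = round(rtnorm_low(n, 9, iqr_sd(7, 13))),
    pv_pressure_post = round(rtnorm_low(n, 19, iqr_sd(15, 22))),
    pspg_post = round(rtnorm_low(n, 8, iqr_sd(6, 10.75))),
    time_tips_to_ct_days = rtnorm_low(n, 337, iqr_sd(29, 612))
  )
  if (n_noise > 0) {
    for (k in seq_len(n_noise)) rec[[paste0("noise", k)]] <- rnorm(n)
  }
  unknown <- setdiff(names(effects), names(rec))
  if (length(unknown)) {
    stop_tips3d("tips3d_bad_input",
                paste("effects name unknown covariates:",
                      paste(unknown, collapse = ", ")))
  }
  lp <- rep(0, n)
  for (v in names(effects)) lp <- lp + effects[[v]] * rec[[v]]
  hazard <- baseline_rate * exp(lp)
  t_event <- rexp(n, rate = hazard)
  t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
  rec$event <- t_event <= t_cens
  rec$time_to_event_days <- pmin(t_event, t_cens)
  rec
}

#' Read / write cohort tables
#'
#' CSV in RFC 4180 dialect, UTF-8, `.` decimal separator, with the column
#' dictionary of [simulate_cohort()].
#'
#' @param file a CSV file path.
#' @export
read_cohort <- function(file) {
  readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_cohort
#' @param records a data frame of subject records.
#' @export
write_cohort <- function(records, file) {
  readr::write_csv(records, file)
  invisible(file)
}
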