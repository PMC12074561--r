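test_that("group comparison handles identical, shifted and degenerate variables", {
  set.seed(21)
  x <- rnorm(100)
  df <- tibble::tibble(
    grp = rep(c(TRUE, FALSE), each = 50),
    same = c(x[1:50], x[1:50]),          # identical distribution in both
    shifted = rnorm(100) + 10 * rep(c(0, 1), each = 50),
    constant = 1,
    missing_all = NA_real_,
    cat_same = rep(c("a", "b"), 50),
    cat_diff = c(rep("a", 45), rep("b", 5), rep("b", 45), rep("a", 5))
  )
  out <- compare_groups(df, "grp")
  get <- function(v) out[out$variable == v, ]
  expect_gt(get("same")$p_value, 0.9)
  expect_lt(get("shifted")$p_value, 1e-6)
  expect_equal(get("constant")$p_value, 1)
  expect_equal(get("constant")$flag, "constant")
  expect_equal(get("missing_all")$flag, "all-missing")
  expect_gt(get("cat_same")$p_value, 0.9)
  expect_lt(get("cat_diff")$p_value, 1e-6)

  # label-swap symmetry
  df2 <- df
  df2$grp <- !df2$grp
  out2 <- compare_groups(df2, "grp")
  expect_equal(out2$p_value, out$p_value, tolerance = 1e-12)

  expect_error(compare_groups(df[df$grp, ], "grp"),
               class = "tips3d_bad_input")
})

test_that("univariate Cox recovers an analytic two-group rate ratio", {
  set.seed(31)
  n <- 1000
  x <- rep(0:1, each = n / 2)
  df <- tibble::tibble(
    x = x,
    time_to_event_days = rexp(n, rate = 0.001 * 2^x),
    event = TRUE
  )
  res <- cox_univariate(df, "x")
  expect_equal(res$variable, "x")
  expect_lt(abs(res$hr - 2) / 2, 0.1)
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)
  expect_equal(res$n, n)

  df$x0 <- 1
  expect_error(cox_univariate(df, "x0"), class = "tips3d_bad_input")
  df$event <- FALSE
  expect_error(cox_univariate(df, "x"), class = "tips3d_no_events")
})

test_that("rescaling a covariate rescales the log-HR exactly", {
  rec <- simulate_cohort(300, seed = 41)
  r1 <- cox_univariate(rec, "max_curvature_deg")
  rec$scaled <- rec$max_curvature_deg / 10
  r2 <- cox_univariate(rec, "scaled")
  expect_equal(log(r2$hr), 10 * log(r1$hr), tolerance = 1e-6)
  expect_equal(r2$p, r1$p, tolerance = 1e-9)
})

test_that("forward stepwise finds a strong true effect among noise", {
  rec <- simulate_cohort(500, seed = 51, n_noise = 5)
  candidates <- screen_candidates(
    rec, c("max_curvature_deg", "cranial_end_to_ivc_mm", paste0("noise", 1:5)))
  fit <- cox_forward_stepwise(rec, as.character(candidates))
  expect_true(all(c("max_curvature_deg", "cranial_end_to_ivc_mm") %in%
                    fit$selected))
  td <- tidy(fit)
  expect_true(all(td$ci_low <= td$hr & td$hr <= td$ci_high))
  expect_gt(glance(fit)$n_events, 100)

  # a duplicated covariate adds no information and never enters
  rec$dup <- rec$cranial_end_to_ivc_mm
  fit2 <- cox_forward_stepwise(rec, c("cranial_end_to_ivc_mm", "dup",
                                      "max_curvature_deg"))
  expect_false(all(c("cranial_end_to_ivc_mm", "dup") %in% fit2$selected))

  # empty candidate set gives an empty model, not an error
  fit3 <- cox_forward_stepwise(rec, character(0))
  expect_length(fit3$selected, 0L)
  expect_equal(nrow(tidy(fit3)), 0L)
})

test_that("simulated cohorts are reproducible with null effects truly null", {
  a <- simulate_cohort(200, seed = 61)
  b <- simulate_cohort(200, seed = 61)
  expect_identical(a, b)
  expect_false(identical(a, simulate_cohort(200, seed = 62)))

  # effects all zero: event times independent of the geometry covariates
  null <- simulate_cohort(2000, effects = c(max_curvature_deg = 0),
                          censor_rate = 0, seed = 63)
  rho <- cor(null$max_curvature_deg, null$time_to_event_days,
             method = "spearman")
  expect_lt(abs(rho), 0.1)
  rho2 <- cor(null$cranial_end_to_ivc_mm, null$time_to_event_days,
              method = "spearman")
  expect_lt(abs(rho2), 0.1)

  # overwhelming censoring censors everyone
  cen <- simulate_cohort(100, censor_rate = 1e3, seed = 64)
  expect_false(any(cen$event))

  expect_error(simulate_cohort(5, seed = 1), class = "tips3d_bad_input")
  expect_error(simulate_cohort(100, baseline_rate = -1, seed = 1),
               class = "tips3d_bad_input")
  expect_error(simulate_cohort(100, effects = c(not_a_column = 1), seed = 1),
               class = "tips3d_bad_input")
})

test_that("the imaging-delay sensitivity model drops a pure-noise delay", {
  excluded <- 0L
  kept_geometry <- 0L
  kept_ct <- 0L
  for (s in 1:20) {
    rec <- simulate_cohort(400, seed = 100 + s)
    rec$time_tips_to_ct_days <- rnorm(400, 300, 150) # independent of outcome
    fit <- sensitivity_time_to_ct(rec)
    kept_ct <- kept_ct + ("time_tips_to_ct_days" %in% fit$selected)
    kept_geometry <- kept_geometry +
      all(c("max_curvature_deg", "cranial_end_to_ivc_mm") %in% fit$selected)
  }
  expect_lte(kept_ct, 5L)       # ~enter_p of 20 replicates, with slack
  expect_gte(kept_geometry, 15L)

  # missing delays are excluded and counted
  rec <- simulate_cohort(300, seed = 77)
  rec$time_tips_to_ct_days[1:40] <- NA
  fit <- sensitivity_time_to_ct(rec)
  expect_equal(attr(fit, "n_excluded"), 40L)
  expect_error(sensitivity_time_to_ct(rec[0, ]), class = "tips3d_bad_input")
})
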