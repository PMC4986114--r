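test_that("importance summary reproduces closed-form and oracle values", {
  p <- importance_panel(matrix(c(60, 80), 2, 1))
  s <- summarize_importance(p)
  expect_equal(s$mean, 70)
  expect_equal(s$sd, sqrt(200), tolerance = 1e-12)  # ~14.142

  p100 <- importance_panel(matrix(100, 45, 3))
  s100 <- summarize_importance(p100)
  expect_equal(s100$mean, rep(100, 3))
  expect_equal(s100$sd, rep(0, 3))

  set.seed(101)
  pr <- random_importance_panel(45, 10, missing_rate = 0.05)
  sr <- summarize_importance(pr)
  ref <- oracle_mean_sd(unclass(pr))
  expect_equal(sr$n_responses, ref$n)
  expect_equal(sr$mean, ref$mean, tolerance = 1e-12)
  expect_equal(sr$sd, ref$sd, tolerance = 1e-12)
})

test_that("criteria without responses are reported, never dropped", {
  m <- matrix(c(50, 60, NA, NA, 70, NA), 2, 3)
  s <- summarize_importance(importance_panel(m))
  expect_identical(nrow(s), 3L)
  expect_identical(s$n_responses, c(2L, 0L, 1L))
  expect_true(is.na(s$mean[2]) && is.na(s$sd[2]))
  expect_true(!is.na(s$mean[3]) && is.na(s$sd[3]))
})

test_that("cronbach_alpha matches its defining formula and the oracle", {
  # all item columns identical -> perfect internal consistency
  x <- matrix(rep(c(10, 40, 70, 95), 3), 4, 3)
  expect_equal(cronbach_alpha(x), 1, tolerance = 1e-12)

  # anti-consistent panel with constant row totals degenerates
  expect_error(cronbach_alpha(matrix(c(1, 2, 2, 1), 2, 2)),
               "DegenerateScaleError")

  # non-degenerate anti-consistent panel: alpha negative, oracle-equal
  xa <- matrix(c(1, 4, 2, 4, 4, 1, 2, 2), 4, 2)
  expect_lt(cronbach_alpha(xa), 0)
  expect_equal(cronbach_alpha(xa), oracle_alpha(xa), tolerance = 1e-12)

  set.seed(202)
  xr <- matrix(sample(1:100, 100, replace = TRUE), 20, 5)
  expect_equal(cronbach_alpha(xr), oracle_alpha(xr), tolerance = 1e-12)

  # invariance to a constant shift of a single item column
  xs <- xr
  xs[, 3] <- xs[, 3] - 17
  expect_equal(cronbach_alpha(xs), cronbach_alpha(xr), tolerance = 1e-12)

  expect_error(cronbach_alpha(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("the mean/SD screen applies thresholds in both combine modes", {
  s <- data.frame(criterion_id = c("A1", "A2", "A3"),
                  n_responses = 45L,
                  mean = c(79.64, 59.9, 65),
                  sd = c(19.84, 10, 30))
  class(s) <- c("screening_summary", "data.frame")

  any_mode <- screen_criteria(s, mode = "any")
  expect_identical(any_mode$retained, c(TRUE, FALSE, FALSE))
  expect_identical(attr(any_mode, "n_retained"), 1L)

  both_mode <- screen_criteria(s, mode = "both")
  expect_identical(both_mode$retained, c(TRUE, TRUE, TRUE))

  # undefined sd names the offending criterion
  s_bad <- s
  s_bad$sd[2] <- NA_real_
  expect_error(screen_criteria(s_bad), "ScreeningError.*A2")
})

test_that("screening is idempotent and monotone in its thresholds", {
  set.seed(303)
  p <- random_importance_panel(45, 40)
  s <- summarize_importance(p)
  screened <- screen_criteria(s)

  # re-screening the retained subset changes nothing
  sub <- screened[screened$retained, ]
  class(sub) <- c("screening_summary", "data.frame")
  again <- screen_criteria(sub)
  expect_true(all(again$retained))

  n_ret <- function(mt, st, mode = "any")
    attr(screen_criteria(s, mt, st, mode), "n_retained")
  for (mt in c(20, 40, 60, 80)) {
    expect_gte(n_ret(mt, 25), n_ret(mt + 10, 25))
    expect_lte(n_ret(60, mt), n_ret(60, mt + 10))
  }
  # mode=both retains a superset of mode=any
  for (mt in c(40, 60, 75)) {
    a <- screen_criteria(s, mt, 25, "any")
    b <- screen_criteria(s, mt, 25, "both")
    expect_true(all(a$retained <= b$retained))
  }
})

test_that("retained_catalog subsets the catalog in order", {
  cat48 <- default_catalog()
  s <- data.frame(criterion_id = cat48$id, n_responses = 45L,
                  mean = c(rep(80, 10), rep(40, 38)), sd = 10)
  class(s) <- c("screening_summary", "data.frame")
  kept <- retained_catalog(cat48, screen_criteria(s))
  expect_identical(kept$id, paste0("A", 1:10))
  expect_s3_class(kept, "criteria_catalog")
})
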