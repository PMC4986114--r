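make_panel <- function(arr) likert_panel(arr)

test_that("missing Likert cells are imputed with the scale minimum", {
  a <- array(3, dim = c(2, 2, 2))
  a[1, 2, 1] <- NA
  p <- make_panel(a)
  expect_message(imp <- impute_missing(p), "1 missing cell")
  expect_equal(unclass(imp)[1, 2, 1], 1)
  expect_identical(attr(imp, "n_imputed"), 1L)

  complete <- make_panel(array(4, dim = c(2, 2, 2)))
  imp_c <- impute_missing(complete)
  expect_equal(unclass(imp_c), unclass(complete), ignore_attr = "n_imputed")
  expect_identical(attr(imp_c, "n_imputed"), 0L)

  # first respondent row entirely missing -> all cells become 1
  b2 <- array(c(NA, 2, NA, 2, NA, 2, NA, 2), c(2, 2, 2))
  imp2 <- suppressMessages(impute_missing(make_panel(b2)))
  expect_true(all(unclass(imp2)[1, , ] == 1))
})

test_that("aggregation collapses respondents as specified", {
  a <- array(c(3, 5), dim = c(2, 1, 1))  # two respondents, one cell
  dm <- aggregate_panel(make_panel(a))
  expect_equal(unname(dm$x[1, 1]), 4)

  single <- array(c(2, 5, 1, 4), dim = c(1, 2, 2))
  dm1 <- aggregate_panel(make_panel(single))
  expect_equal(unname(dm1$x), matrix(c(2, 5, 1, 4), 2, 2))

  set.seed(11)
  big <- array(sample(1:5, 45 * 48 * 4, replace = TRUE),
               dim = c(45, 48, 4))
  dmb <- aggregate_panel(make_panel(big))
  ref <- matrix(0, 48, 4)
  for (i in 1:48) for (j in 1:4) ref[i, j] <- mean(big[, i, j])
  expect_equal(unname(dmb$x), ref, tolerance = 1e-12)

  gm <- aggregate_panel(make_panel(a), method = "geometric_mean")
  expect_equal(unname(gm$x[1, 1]), sqrt(15), tolerance = 1e-12)
  expect_error(aggregate_panel(make_panel(array(NA_real_, c(1, 1, 1)))),
               "missing")
})

test_that("vector normalization yields unit columns and is scale invariant", {
  expect_equal(vector_normalize(matrix(c(3, 4), 2, 1)),
               matrix(c(0.6, 0.8), 2, 1))
  expect_equal(vector_normalize(matrix(2.7, 1, 1)), matrix(1, 1, 1))
  set.seed(12)
  x <- matrix(runif(20, 1, 5), 5, 4)
  r <- vector_normalize(x)
  expect_equal(colSums(r^2), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  x7 <- x
  x7[, 2] <- 7 * x7[, 2]
  expect_equal(vector_normalize(x7), r, tolerance = 1e-12)
  expect_error(vector_normalize(matrix(0, 2, 1)), "NormalizationError")
})

test_that("weighting, ideals and separations follow their definitions", {
  set.seed(13)
  r <- vector_normalize(matrix(runif(12, 1, 5), 3, 4))
  expect_equal(apply_weights(r, rep(0.25, 4)), r / 4)
  v10 <- apply_weights(r, c(1, 0, 0, 0))
  expect_true(all(v10[, 2:4] == 0))
  w <- c(0.4, 0.3, 0.2, 0.1)
  vw <- apply_weights(r, w)
  for (j in 1:4) expect_equal(vw[, j], w[j] * r[, j], tolerance = 1e-15)
  expect_error(apply_weights(r, c(1, 2)), "DimensionError")

  one <- matrix(c(0.2, 0.5), 1, 2)
  ref1 <- ideal_solutions(one)
  expect_equal(ref1$ideal, c(0.2, 0.5))
  expect_equal(ref1$anti_ideal, c(0.2, 0.5))
  col <- matrix(c(0.1, 0.3), 2, 1)
  expect_equal(ideal_solutions(col, "benefit")$ideal, 0.3)
  expect_equal(ideal_solutions(col, "cost")$ideal, 0.1)
  expect_equal(ideal_solutions(col, "cost")$anti_ideal, 0.3)

  v <- matrix(c(0, 3, 0, 4), 2, 2)
  sep <- separation_measures(v, ideal = c(3, 4), anti_ideal = c(0, 0))
  expect_equal(sep$d_plus, c(5, 0))
  expect_equal(sep$d_minus, c(0, 5))

  set.seed(14)
  vr <- matrix(runif(20), 5, 4)
  refs <- ideal_solutions(vr)
  sr <- separation_measures(vr, refs$ideal, refs$anti_ideal)
  for (i in 1:5) {
    expect_equal(sr$d_plus[i], sqrt(sum((vr[i, ] - refs$ideal)^2)),
                 tolerance = 1e-12)
    expect_equal(sr$d_minus[i], sqrt(sum((vr[i, ] - refs$anti_ideal)^2)),
                 tolerance = 1e-12)
  }
})

test_that("relative closeness handles boundaries and degeneracy", {
  expect_equal(as.numeric(relative_closeness(0.034, 0.042)),
               0.042 / 0.076, tolerance = 1e-12)
  expect_equal(as.numeric(relative_closeness(0, 0.3)), 1)
  expect_equal(as.numeric(relative_closeness(0.3, 0)), 0)
  expect_equal(as.numeric(relative_closeness(0.2, 0.2)), 0.5)
  c00 <- relative_closeness(c(0, 1), c(0, 1))
  expect_equal(as.numeric(c00), c(0.5, 0.5))
  expect_identical(attr(c00, "degenerate"), c(TRUE, FALSE))
  expect_error(relative_closeness(-0.1, 0.2), "ContractViolation")
})

test_that("ranking is descending in closeness with id-suffix tie-break", {
  cl <- c(A7 = 0.556, A27 = 0.399, A32 = 0.208)
  expect_identical(rank_alternatives(cl),
                   c(A7 = 1L, A27 = 2L, A32 = 3L))
  tied <- stats::setNames(rep(0.4, 4), c("A3", "A1", "A4", "A2"))
  expect_identical(rank_alternatives(tied),
                   c(A3 = 3L, A1 = 1L, A4 = 4L, A2 = 2L))
  set.seed(15)
  clr <- stats::setNames(runif(30), paste0("A", 1:30))
  rk <- rank_alternatives(clr)
  expect_identical(sort(as.integer(rk)), 1:30)
  expect_identical(names(sort(clr, decreasing = TRUE)),
                   names(sort(rk)))
})

test_that("run_topsis composes the steps and matches closed forms", {
  x <- matrix(c(4, 2), 2, 1, dimnames = list(c("A1", "A2"), "s1"))
  res <- run_topsis(x)
  expect_equal(as.numeric(res$closeness), c(1, 0))
  expect_identical(as.integer(res$ranks), c(1L, 2L))

  same <- matrix(3, 4, 2, dimnames = list(paste0("A", 1:4), NULL))
  rs <- run_topsis(same)
  expect_equal(as.numeric(rs$closeness), rep(0.5, 4))
  expect_true(all(rs$degenerate))
  expect_identical(as.integer(rs$ranks), 1:4)  # id-order tie-break
})

test_that("run_topsis equals the straight-line oracle on random instances", {
  set.seed(16)
  for (case in 1:25) {
    n <- sample(2:48, 1)
    m <- sample(1:4, 1)
    x <- matrix(runif(n * m, 1, 5), n, m,
                dimnames = list(paste0("A", seq_len(n)), NULL))
    w <- runif(m); w <- w / sum(w)
    dirs <- sample(c("benefit", "cost"), m, replace = TRUE)
    res <- run_topsis(x, weights = w, directions = dirs)
    ref <- oracle_topsis(x, w, dirs)
    expect_equal(unname(res$r), ref$r, tolerance = 1e-10)
    expect_equal(unname(res$v), ref$v, tolerance = 1e-10)
    expect_equal(res$ideal, ref$ideal, tolerance = 1e-10)
    expect_equal(res$anti_ideal, ref$anti_ideal, tolerance = 1e-10)
    expect_equal(as.numeric(res$d_plus), ref$d_plus, tolerance = 1e-10)
    expect_equal(as.numeric(res$d_minus), ref$d_minus, tolerance = 1e-10)
    expect_equal(as.numeric(res$closeness), ref$closeness,
                 tolerance = 1e-10)
    expect_identical(as.integer(res$ranks), ref$ranks)
  }
})

test_that("TOPSIS invariances hold: permutation, column scaling, C bounds", {
  set.seed(17)
  x <- matrix(runif(48 * 4, 1, 5), 48, 4,
              dimnames = list(paste0("A", 1:48), NULL))
  res <- run_topsis(x)
  expect_true(all(res$closeness >= 0 & res$closeness <= 1))
  expect_equal(colSums(res$r^2), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)

  perm <- sample(48)
  res_p <- run_topsis(x[perm, ])
  expect_equal(as.numeric(res_p$closeness),
               as.numeric(res$closeness[perm]), tolerance = 1e-12)
  expect_identical(as.integer(res_p$ranks),
                   as.integer(res$ranks[perm]))

  xs <- x
  xs[, 3] <- xs[, 3] * 11.5
  res_s <- run_topsis(xs)
  expect_equal(res_s$r, res$r, tolerance = 1e-12)
  expect_equal(as.numeric(res_s$closeness), as.numeric(res$closeness),
               tolerance = 1e-12)
  expect_identical(res_s$ranks, res$ranks)

  # C hits its bounds exactly at the ideal / anti-ideal rows
  xb <- matrix(c(5, 1, 3, 5, 1, 2, 5, 1, 4), 3, 3,
               dimnames = list(paste0("A", 1:3), NULL))
  rb <- run_topsis(xb)
  expect_equal(as.numeric(rb$closeness[1]), 1)
  expect_equal(as.numeric(rb$closeness[2]), 0)
})

test_that("run_topsis on a Likert panel imputes, aggregates and ranks", {
  set.seed(18)
  a <- array(sample(1:5, 10 * 6 * 4, replace = TRUE), dim = c(10, 6, 4))
  a[1, 1, 1] <- NA
  p <- likert_panel(a, alternative_ids = paste0("A", 1:6))
  res <- suppressMessages(run_topsis(p))
  expect_identical(res$n_imputed, 1L)
  expect_identical(sort(as.integer(res$ranks)), 1:6)
  imp <- suppressMessages(impute_missing(p))
  dm <- aggregate_panel(imp)
  expect_equal(res$x, dm$x)
})
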