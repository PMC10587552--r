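# Weighted kappa, rater selection, consensus labels, ICC, confusion matrix.

test_that("weighted kappa reproduces hand-computed anchor cases", {
  expect_equal(linear_weighted_kappa(c(1, 1, 2, 2), c(1, 2, 2, 2), 2), 0.5)
  expect_equal(linear_weighted_kappa(c(1, 2), c(2, 1), 2), -1.0)
  a <- c(1, 3, 5, 2, 8, 4)
  expect_equal(linear_weighted_kappa(a, a), 1.0)
  expect_warning(k <- linear_weighted_kappa(c(2, 2, 2), c(2, 2, 2)),
                 "convention")
  expect_equal(k, 1.0)
  expect_error(linear_weighted_kappa(1, 1), "at least 2")
  expect_error(linear_weighted_kappa(c(0, 1), c(1, 2)), "range")
})

test_that("kappa agrees with the brute-force contingency oracle", {
  set.seed(21)
  for (rep in 1:300) {
    n <- sample(5:50, 1)
    a <- sample(1:8, n, replace = TRUE)
    b <- pmin(pmax(a + sample(-2:2, n, replace = TRUE), 1), 8)
    if (length(unique(a)) == 1 && length(unique(b)) == 1) next
    k <- linear_weighted_kappa(a, b, 8)
    expect_equal(k, oracle_kappa(a, b, 8), tolerance = 1e-12)
    expect_equal(k, linear_weighted_kappa(b, a, 8), tolerance = 1e-12)
    expect_true(k >= -1 && k <= 1)
  }
})

test_that("independent raters have kappa near zero", {
  set.seed(31)
  ks <- replicate(100, {
    a <- sample(1:8, 300, replace = TRUE)
    b <- sample(1:8, 300, replace = TRUE)
    linear_weighted_kappa(a, b, 8)
  })
  expect_lt(abs(mean(ks)), 0.02)
})

test_that("pairwise matrix is symmetric and consistent with direct calls", {
  set.seed(41)
  m <- matrix(sample(1:8, 7 * 40, replace = TRUE), 40, 7)
  colnames(m) <- sprintf("r%02d", 1:7)
  pk <- pairwise_kappa_matrix(m)
  expect_identical(pk, t(pk))
  expect_equal(pk[1, 2], linear_weighted_kappa(m[, 1], m[, 2], 8))
  same <- matrix(rep(sample(1:8, 10, replace = TRUE), 3), 10, 3)
  pk1 <- pairwise_kappa_matrix(same)
  expect_true(all(pk1[upper.tri(pk1)] == 1))
})

test_that("rater ranking demotes an anti-correlated panel member", {
  set.seed(51)
  base <- sample(1:8, 30, replace = TRUE)
  m <- cbind(base, pmin(pmax(base + sample(-1:1, 30, TRUE), 1), 8),
             base, 9 - base)
  colnames(m) <- c("a", "b", "c", "weird")
  sel <- select_top_raters(m, 3)
  expect_equal(sel$ranking[4], "weird")
  expect_false("weird" %in% sel$selected)
  expect_equal(length(select_top_raters(m, 4)$ranking), 4)
  expect_error(select_top_raters(m, 0), "invalid argument")
})

test_that("median consensus requires an odd panel and returns its median", {
  m <- rbind(c(3, 4, 4), c(2, 5, 3), c(6, 6, 6))
  expect_equal(median_true_label(m), c(4L, 3L, 6L))
  expect_error(median_true_label(m[, 1:2]), "odd")
})

test_that("ICC matches the aov mean-squares oracle and pingouin conventions", {
  m <- matrix(c(2, 3, 6,
                3, 4, 5,
                2, 4, 6,
                3, 5, 7), 3, 4)
  ms <- oracle_anova_ms(m)
  r <- icc_agreement(m)
  expect_equal(unname(r$ms["msr"]), unname(ms["msr"]), tolerance = 1e-10)
  expect_equal(unname(r$ms["msc"]), unname(ms["msc"]), tolerance = 1e-10)
  expect_equal(unname(r$ms["mse"]), unname(ms["mse"]), tolerance = 1e-10)
  k <- ncol(m); ns <- nrow(m)
  icc_oracle <- (ms["msr"] - ms["mse"]) /
    (ms["msr"] + (ms["msc"] - ms["mse"]) / ns)
  expect_equal(r$icc, unname(icc_oracle), tolerance = 1e-10)
  expect_true(r$lower <= r$icc && r$icc <= r$upper)
})

test_that("identical raters on varying subjects give ICC 1", {
  m <- matrix(rep(c(1, 4, 7, 3, 6), 3), 5, 3)
  expect_equal(icc_agreement(m)$icc, 1.0)
  flat <- matrix(2, 5, 3)
  expect_error(icc_agreement(flat), "undefined ICC")
})

test_that("average-measures ICC dominates single-measures when reliability is positive", {
  # the Spearman-Brown step-up amplifies agreement, so ICC(A,k) >= ICC(A,1)
  # whenever subjects are genuinely distinguishable (positive ICC)
  set.seed(61)
  for (rep in 1:20) {
    truth <- rnorm(10, 0, 2)
    m <- truth + matrix(rnorm(30, 0, 0.6), 10, 3)
    a <- icc_agreement(m, type = "average")$icc
    s <- icc_agreement(m, type = "single")$icc
    expect_gt(s, 0)
    expect_gte(a, s - 1e-12)
  }
})

test_that("ICC recovers the closed-form variance ratio in simulation", {
  set.seed(71)
  sigma_s <- 1.2; sigma_e <- 0.8; k <- 3; n <- 500
  truth <- rnorm(n, 4.5, sigma_s)
  m <- truth + matrix(rnorm(n * k, 0, sigma_e), n, k)
  target <- sigma_s^2 / (sigma_s^2 + sigma_e^2 / k)
  expect_lt(abs(icc_agreement(m)$icc - target), 0.05)
})

test_that("statistics are invariant to subject reordering", {
  set.seed(81)
  m <- matrix(sample(1:8, 60, replace = TRUE), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  perm <- sample(20)
  expect_equal(pairwise_kappa_matrix(m), pairwise_kappa_matrix(m[perm, ]))
  expect_equal(icc_agreement(m)$icc, icc_agreement(m[perm, ])$icc)
  expect_equal(sort(median_true_label(m)), sort(median_true_label(m[perm, ])))
})

test_that("confusion matrix counts and conserves subjects", {
  p <- c(1, 2, 3, 3, 8); t <- c(1, 2, 4, 3, 8)
  cm <- confusion_matrix(p, t)
  expect_equal(sum(cm), 5)
  expect_equal(unname(rowSums(cm)), as.integer(table(factor(t, levels = 1:8))))
  expect_equal(cm[4, 3], 1L)
  d <- confusion_matrix(p, p)
  expect_true(all(d[upper.tri(d)] == 0) && all(d[lower.tri(d)] == 0))
  expect_equal(sum(confusion_matrix(2, 5)), 1)
  expect_error(confusion_matrix(c(0, 1), c(1, 1)), "invalid grade")
})

test_that("rating CSVs round-trip through the long format", {
  m <- matrix(sample(1:8, 12, replace = TRUE), 4, 3,
              dimnames = list(paste0("s", 1:4), paste0("r", 1:3)))
  f <- tempfile(fileext = ".csv")
  write_ratings(m, f)
  expect_equal(readLines(f)[1], "subject_id,rater_id,grade")
  m2 <- read_ratings(f)
  expect_equal(m2[rownames(m), colnames(m)], m)
})
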