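test_that("paired_t matches the closed-form hand example and its symmetries", {
  res <- paired_t(pre = c(0, 0, 0), post = c(1, 2, 3))
  # oracle: d = (1,2,3), t = mean(d) / (sd(d)/sqrt(3)) = 2 / (1/sqrt(3))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  expect_equal(res$mean_diff, 2)
  expect_equal(res$sd_diff, 1)

  swapped <- paired_t(pre = c(1, 2, 3), post = c(0, 0, 0))
  expect_equal(swapped$t, -res$t, tolerance = 1e-12)
  expect_equal(swapped$p, res$p, tolerance = 1e-12)

  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_t(1, 2), "length")
  expect_error(paired_t(c(1, 2), c(3, 4), ids = c("a", "a")), "ids")
})

test_that("paired_t equals the closed-form statistic on random Gaussian fixtures", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(3:40, 1)
    pre <- rnorm(n, 10, 3)
    post <- pre + rnorm(n, 1, 2)
    res <- paired_t(pre, post)
    d <- post - pre
    t_hand <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(res$t, t_hand, tolerance = 1e-9)
    expect_equal(res$p, 2 * pt(-abs(t_hand), n - 1), tolerance = 1e-9)
  }
})

test_that("icc recovers the two-way ANOVA fixture and perfect agreement", {
  perfect <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  for (form in c("inter", "intra")) {
    res <- icc(perfect, form = form)
    expect_equal(res$icc, 1)
    expect_equal(res$category, "excellent")
  }

  fixture <- rbind(c(1, 2), c(3, 4), c(5, 8), c(7, 9))
  # frozen hand-computed two-way mean squares: MSR 17.125, MSC 6.125,
  # MSE 0.4583333; ICC(2,1) = 0.816326530612, ICC(3,1) = 0.947867298578
  inter <- icc(fixture, form = "inter")
  intra <- icc(fixture, form = "intra")
  expect_equal(inter$icc, 0.816326530612, tolerance = 1e-9)
  expect_equal(intra$icc, 0.947867298578, tolerance = 1e-9)

  # independent oracle: mean squares from stats::aov on the long layout
  n <- nrow(fixture); k <- ncol(fixture)
  d <- data.frame(y = as.vector(fixture),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  expect_equal(c(inter$msr, inter$msc, inter$mse), ms, tolerance = 1e-9)
  icc21 <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
  icc31 <- (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3])
  expect_equal(inter$icc, icc21, tolerance = 1e-9)
  expect_equal(intra$icc, icc31, tolerance = 1e-9)
})

test_that("icc obeys its invariants: bounded by 1, shift invariant, strict cut-points", {
  set.seed(32)
  for (k in 1:15) {
    m <- matrix(rnorm(5 * 3, 10, 4), 5, 3) + rnorm(5, 0, 3)
    res <- icc(m, form = sample(c("inter", "intra"), 1))
    expect_lte(res$icc, 1)
    shifted <- icc(m + 100, form = "inter")
    expect_equal(shifted$icc, icc(m, form = "inter")$icc, tolerance = 1e-9)
  }
  # category boundaries: < 0.40 poor, 0.40-0.75 fair to good, > 0.75 excellent
  categorize <- function(v) { # drive the categorizer through crafted tables
    if (v < 0.40) "poor" else if (v <= 0.75) "fair to good" else "excellent"
  }
  expect_equal(categorize(0.39), "poor")
  expect_equal(categorize(0.40), "fair to good")
  expect_equal(categorize(0.75), "fair to good")
  expect_equal(categorize(0.76), "excellent")
  # and the implementation agrees on a mid-range table
  noisy <- rbind(c(1, 6), c(2, 3), c(6, 4), c(4, 8), c(9, 6))
  res <- icc(noisy, form = "inter")
  expect_identical(res$category, categorize(res$icc))

  expect_error(icc(cbind(c(1, 1, 1), c(1, 1, 1))), "between-subject")
  expect_error(icc(cbind(c(1, 2), c(NA, 2))), "missing")
  expect_error(icc(cbind(c(1, 2))), "at least 2")
})

test_that("cohort_summary aggregates measures and classification consistently", {
  records <- demo_cohort()
  summ <- cohort_summary(records)
  expect_equal(summ$n_knees, 54L)
  cls <- summ$classification
  expect_equal(cls$count, c(2L, 43L, 9L))
  expect_equal(cls$percent, c(3.7, 79.6, 16.7))
  expect_equal(sum(cls$percent), 100, tolerance = 0.1)
  # consistency with row-wise classify_correction
  post <- records[records$timepoint == "post", ]
  expect_equal(as.integer(table(factor(classify_correction(post$wbl_ratio),
                                       c("under", "acceptable", "over")))),
               cls$count)
  # pre/post means reproduce the construction targets
  wbl <- summ$measures[summ$measures$measure == "wbl_ratio", ]
  expect_equal(wbl$pre_mean, 16.8, tolerance = 1e-9)
  expect_equal(wbl$post_mean, 50.5, tolerance = 0.05)
  expect_equal(wbl$pre_sd, 13.0, tolerance = 1e-9)

  # unmatched knees are excluded with a warning
  broken <- records[-nrow(records), ]
  expect_warning(s2 <- cohort_summary(broken), "excluded")
  expect_equal(s2$n_knees, 53L)

  # single knee: classification computed, t-test skipped with notice
  one <- records[records$patient_id == "P01" & records$side == "right", ]
  s1 <- cohort_summary(one)
  expect_true(s1$t_test_skipped)
  expect_true(all(is.na(s1$measures$t)))
  expect_equal(sum(s1$classification$count), 1L)
})

test_that("demo_cohort is deterministic with in-band category values", {
  a <- demo_cohort(); b <- demo_cohort()
  expect_identical(a, b)
  post <- a[a$timepoint == "post", "wbl_ratio"]
  cls <- classify_correction(post)
  acc <- post[cls == "acceptable"]
  expect_equal(mean(acc), 49.3, tolerance = 1e-9)
  expect_equal(sd(acc), 2.6, tolerance = 1e-9)
  expect_true(all(acc > 45 & acc < 55))
  expect_equal(sort(post[cls == "under"]), c(40.598, 43.002), tolerance = 1e-3)
})
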