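test_that("5-class adjudications binarize by the not-normal-means-CI rule", {
  expect_equal(binarize_labels("normal"), "CN")
  expect_equal(binarize_labels(c("MCI", "borderline of MCI and dementia"[0],
                                 "borderline-dementia")), c("CI", "CI"))
  expect_equal(binarize_labels("borderline MCI"), "CI")
  expect_error(binarize_labels("mild"), "unknown adjudication class")

  set.seed(61)
  five <- c("normal", "borderline_mci", "mci", "borderline_dementia", "dementia")
  for (rep in 1:20) {
    v <- sample(five, 30, replace = TRUE)
    expect_equal(binarize_labels(v), ifelse(v == "normal", "CN", "CI"))
  }
})

test_that("undetermined pairs are removed with the count reported", {
  a <- c("CN", "undetermined", "CI", "undetermined")
  b <- c("CN", "CI", "CI", "CN")
  f <- filter_undetermined(a, b)
  expect_equal(f$labels_a, c("CN", "CI"))
  expect_equal(f$labels_b, c("CN", "CI"))
  expect_equal(f$excluded, 2)

  none <- filter_undetermined(c("CN", "CI"), c("CI", "CI"))
  expect_equal(none$excluded, 0)
  all_u <- filter_undetermined(rep("undetermined", 3), rep("CN", 3))
  expect_equal(length(all_u$labels_a), 0)
  expect_equal(all_u$excluded, 3)
})

test_that("cohen_kappa matches the contingency-table formula on random pairs", {
  # perfect agreement with >= 2 categories
  v <- c("CN", "CI", "CN", "CI", "CN")
  k <- cohen_kappa(v, v)
  expect_equal(k$kappa, 1)
  expect_equal(k$po, 1)

  # degenerate marginals: both raters one identical category
  k0 <- cohen_kappa(rep("CI", 5), rep("CI", 5))
  expect_false(k0$kappa_defined)
  expect_true(is.na(k0$kappa))

  expect_error(cohen_kappa(c("a", "b"), "a"), "equal length")
  expect_error(cohen_kappa(character(0), character(0)), "no label pairs")

  set.seed(71)
  for (rep in 1:200) {
    n <- sample(2:50, 1)
    cats <- sample(c("CN", "CI", "undetermined"), sample(2:3, 1))
    a <- sample(cats, n, replace = TRUE)
    b <- sample(cats, n, replace = TRUE)
    k <- cohen_kappa(a, b)
    want <- kappa_brute(a, b)
    if (is.na(want)) {
      expect_false(k$kappa_defined)
    } else {
      expect_equal(k$kappa, want, tolerance = 1e-12)
      # symmetry under rater swap
      expect_equal(cohen_kappa(b, a)$kappa, k$kappa, tolerance = 1e-12)
    }
    expect_equal(sum(k$table), n)
  }
})

test_that("cohen_kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(73)
  for (rep in 1:20) {
    a <- sample(c("CN", "CI", "undetermined"), 40, replace = TRUE)
    b <- sample(c("CN", "CI", "undetermined"), 40, replace = TRUE)
    k <- cohen_kappa(a, b)
    ref <- e1071::classAgreement(k$table)$kappa
    expect_equal(k$kappa, ref, tolerance = 1e-10)
  }
})

test_that("exact signed-rank p equals full 2^n sign enumeration for n <= 12", {
  set.seed(83)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    a <- round(runif(n, 1, 10), sample(0:1, 1))  # ties likely at 0 decimals
    b <- round(runif(n, 1, 10), 1)
    d <- a - b
    if (all(d == 0)) next
    got <- paired_timing_test(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, wilcoxon_enum_p(d), tolerance = 1e-12)
  }
})

test_that("exact p agrees with the reference implementation when ties are absent", {
  set.seed(89)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    a <- runif(n, 1, 10)
    b <- runif(n, 1, 10)
    got <- paired_timing_test(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(got$W, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the reversed-sequence example matches exhaustive enumeration", {
  a <- c(3, 4, 5, 6, 7, 8, 9, 10)
  b <- rev(a)
  got <- paired_timing_test(a, b)
  expect_equal(got$p_value, wilcoxon_enum_p(a - b), tolerance = 1e-12)
  expect_equal(got$n_zero_dropped, 0)
})

test_that("zero differences drop and an all-zero comparison is flagged", {
  a <- c(2, 3, 4, 5)
  same <- paired_timing_test(a, a)
  expect_false(same$p_defined)
  expect_equal(same$n_zero_dropped, 4)
  expect_equal(same$mean_diff, 0)

  partial <- paired_timing_test(c(2, 3, 4, 6, 7), c(2, 3, 4, 5, 5))
  expect_equal(partial$n_zero_dropped, 3)
  expect_true(partial$p_defined)
})

test_that("large-sample path uses the tie/continuity-corrected normal approximation", {
  set.seed(97)
  a <- round(rlnorm(60, 1, 0.5), 1)
  b <- round(rlnorm(60, 0.7, 0.5), 1)
  got <- paired_timing_test(a, b)
  expect_equal(got$method, "normal_approx")
  ref <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("type-I error under a symmetric null is near the nominal level", {
  # n = 30 pairs, 1000 replicates through the normal-approximation path
  rejections <- 0L
  for (s in 1:1000) {
    set.seed(s)
    a <- 5 + rnorm(30)
    b <- 5 + rnorm(30)  # difference distribution symmetric about zero
    res <- paired_timing_test(a, b)
    if (res$p_defined && res$p_value < 0.05) rejections <- rejections + 1L
  }
  ci <- stats::binom.test(rejections, 1000, conf.level = 0.99)$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("timing summaries report difference moments and ratio spread", {
  a <- c(4, 6, 2)
  b <- c(2, 2, 2)
  r <- paired_timing_test(a, b)
  expect_equal(r$mean_diff, mean(a - b))
  expect_equal(r$sd_diff, sd(a - b))
  expect_equal(r$median_ratio, median(a / b))
  expect_equal(r$min_ratio, 1)
  expect_equal(r$max_ratio, 3)
  expect_true(r$min_ratio <= r$median_ratio && r$median_ratio <= r$max_ratio)
})

test_that("learning effect splits halves at the midpoint", {
  expect_error(learning_effect(c(1, 2, 3)), "at least 4")

  const <- learning_effect(rep(5, 10))
  expect_equal(const$median_first, const$median_second)
  expect_gt(const$p_value, 0.9)

  dec <- learning_effect(seq(20, 1))
  expect_gt(dec$median_first, dec$median_second)

  set.seed(103)
  for (rep in 1:20) {
    n <- sample(4:25, 1)
    x <- runif(n, 1, 10)
    le <- learning_effect(x)
    cut <- ceiling(n / 2)
    expect_equal(le$n_first, cut)
    expect_equal(le$median_first, median(x[1:cut]))
    expect_equal(le$median_second, median(x[(cut + 1):n]))
  }
})

test_that("demographic summary reproduces printed-percent conventions", {
  mk_cohort <- function(n, n_female, n_college, n_married, groups) {
    lapply(seq_len(n), function(i) {
      eth <- "white"
      off <- 0
      for (g in names(groups)) {
        if (i > off && i <= off + groups[[g]]) eth <- g
        off <- off + groups[[g]]
      }
      patient_chart(make_patient(
        sprintf("p%03d", i),
        sex = if (i <= n_female) "female" else "male",
        education = if (i <= n_college) "college_or_more" else "less_than_college",
        marital = if (i <= n_married) "married" else "not_married",
        ethnic = eth),
        period_start = "2017-01-01", period_end = "2018-12-31")
    })
  }
  # elderly-cohort shape: 63 women of 100 -> 63.0%; 7 minorities; 51 college
  aco <- mk_cohort(100, 63, 51, 50,
                   list(black = 4, hispanic = 2, asian = 1, indigenous = 0))
  s <- demographic_summary(aco)
  expect_equal(s$sex$female$count, 63)
  expect_equal(s$sex$female$percent, 63.0)
  expect_equal(s$minority_total$count, 7)
  expect_equal(s$college$percent, 51.0)
  expect_equal(s$married$percent, 50.0)

  # a 160-of-527 cell must print as 30.4
  expect_equal(round_half_up(100 * 160 / 527, 1), 30.4)

  single <- demographic_summary(aco[1])
  expect_equal(single$sex$female$percent, 100.0)
  expect_error(demographic_summary(list()), "empty cohort")

  set.seed(107)
  for (rep in 1:10) {
    n <- sample(3:40, 1)
    cohort <- lapply(seq_len(n), function(i) {
      patient_chart(make_patient(sprintf("p%03d", i),
                                 sex = sample(c("male", "female", "missing"), 1),
                                 ethnic = sample(c("white", "black", "hispanic", "missing"), 1),
                                 education = sample(c("college_or_more", "less_than_college", "missing"), 1)),
                    period_start = "2017-01-01", period_end = "2018-12-31")
    })
    s <- demographic_summary(cohort)
    females <- sum(vapply(cohort, function(ch) ch$patient$sex == "female", NA))
    expect_equal(s$sex$female$count, females)
    expect_equal(s$sex$female$percent, round_half_up(100 * females / n, 1))
    # percents never exceed 100 per variable; missing excluded from numerators
    expect_lte(s$sex$male$percent + s$sex$female$percent, 100)
    expect_equal(s$missing$sex,
                 sum(vapply(cohort, function(ch) ch$patient$sex == "missing", NA)))
  }
})

test_that("round_half_up rounds ties away from zero", {
  expect_equal(round_half_up(62.5 / 100 * 100, 0), 63)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(30.35, 1), 30.4)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
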