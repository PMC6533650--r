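test_that("confusion counts partition the cohort at any cut-off", {
  sc <- toy_scored(c(10, 11, 12, 9), c(TRUE, TRUE, FALSE, FALSE))
  cm <- confusion_at_cutoff(sc, "pca", 11)
  expect_equal(cm[, c("tp", "fn", "fp", "tn")],
               tibble::tibble(tp = 1, fn = 1, fp = 1, tn = 1))
  low <- confusion_at_cutoff(sc, "pca", 0)
  expect_equal(c(low$fp, low$fn), c(2, 0))
  high <- confusion_at_cutoff(sc, "pca", 99)
  expect_equal(c(high$tp, high$tn), c(0, 2))
  expect_error(confusion_at_cutoff(sc[0, ], "pca", 11),
               class = "psc_validation_error")
})

test_that("operating points match the published worked fractions", {
  op11 <- operating_point(tibble::tibble(tp = 149, fn = 34, tn = 147, fp = 27), 11)
  expect_equal(round_half_up(op11$sensitivity, 3), 0.814)
  expect_equal(round_half_up(op11$specificity, 3), 0.845)
  expect_equal(round_half_up(op11$ppv, 3), 0.847)
  expect_equal(round_half_up(op11$npv, 3), 0.812)

  op12 <- operating_point(tibble::tibble(tp = 143, fn = 20, tn = 161, fp = 33), 12)
  expect_equal(round_half_up(c(op12$sensitivity, op12$specificity,
                               op12$ppv, op12$npv), 3),
               c(0.877, 0.830, 0.813, 0.890))

  perfect <- operating_point(tibble::tibble(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_equal(unlist(perfect[, 2:5]), c(sensitivity = 1, specificity = 1,
                                         ppv = 1, npv = 1))
  # zero denominators are marked undefined, never silently 0 or 1
  allpos <- operating_point(tibble::tibble(tp = 5, fn = 0, tn = 0, fp = 0))
  expect_true(is.na(allpos$specificity) && is.na(allpos$npv))
  expect_equal(allpos$sensitivity, 1)
})

test_that("metrics respect monotonicity and the Bayes identity", {
  set.seed(41)
  sc <- toy_scored(sample(4:17, 120, TRUE), runif(120) < 0.45)
  ops <- operating_points(sc, "pca", 4:18)
  expect_true(all(diff(ops$sensitivity) <= 0))
  expect_true(all(diff(ops$specificity) >= 0))
  prev <- mean(sc$pca)
  ok <- !is.na(ops$ppv)
  bayes <- ops$sensitivity * prev /
    (ops$sensitivity * prev + (1 - ops$specificity) * (1 - prev))
  expect_equal(ops$ppv[ok], bayes[ok], tolerance = 1e-12)
})

test_that("trapezoid AUC equals the tie-corrected Mann-Whitney statistic", {
  expect_equal(roc_curve(toy_scored(1:4, c(FALSE, FALSE, TRUE, TRUE)), "pca")$auc, 1)
  expect_equal(roc_curve(toy_scored(rep(3, 6), rep(c(TRUE, FALSE), 3)), "pca")$auc, 0.5)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    sc <- toy_scored(sample(1:12, n, TRUE), runif(n) < 0.5)
    if (length(unique(sc$pca)) < 2) next
    expect_equal(roc_curve(sc, "pca")$auc,
                 oracle_auc(sc$score, sc$pca),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(toy_scored(1:3, rep(TRUE, 3)), "pca"),
               class = "psc_validation_error")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  sc <- toy_scored(sample(4:17, 150, TRUE), runif(150) < 0.5)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = sc$pca, predictor = sc$score,
    levels = c(FALSE, TRUE), direction = "<"
  )))
  expect_equal(roc_curve(sc, "pca")$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("Youden cut-off maximises J with ties broken upward", {
  perfect <- toy_scored(1:4, c(FALSE, FALSE, TRUE, TRUE))
  y <- youden_optimal_cutoff(perfect, "pca")
  expect_equal(y$cutoff, 3)
  expect_equal(y$operating_point$youden_j, 1)

  ties <- toy_scored(rep(5, 8), rep(c(TRUE, FALSE), 4))
  yt <- youden_optimal_cutoff(ties, "pca")
  expect_equal(yt$cutoff, 6) # max score + 1; J = 0 everywhere
  expect_equal(yt$operating_point$youden_j, 0)

  set.seed(44)
  sc <- toy_scored(sample(1:20, 100, TRUE), runif(100) < 0.5)
  ys <- youden_optimal_cutoff(sc, "pca")
  ops <- operating_points(sc, "pca", c(sort(unique(sc$score)), max(sc$score) + 1L))
  expect_equal(ys$operating_point$youden_j, max(ops$youden_j))
})

test_that("group summaries use Student-t intervals and scale as 1/sqrt(n)", {
  x <- c(9, 11, 12, 14)
  g <- group_summary(x)
  expect_equal(g$se, sd(x) / 2)
  expect_equal(g$ci_high - g$mean, qt(0.975, 3) * g$se)
  # duplicating the data shrinks the standard error as ~1/sqrt(2); the
  # exact factor reflects the n-1 denominator of the sample sd
  n <- length(x)
  g2 <- group_summary(rep(x, 2))
  expect_equal(g2$se,
               g$sd * sqrt(2 * (n - 1) / (2 * n - 1)) / sqrt(2 * n),
               tolerance = 1e-12)
  g4 <- group_summary(rep(x, 50))
  expect_equal(g4$se,
               g$sd * sqrt(50 * (n - 1) / (50 * n - 1)) / sqrt(50 * n),
               tolerance = 1e-12)
  expect_equal(group_summary(c(5, 5))$sd, 0)
  expect_error(group_summary(7), class = "psc_validation_error")
})

test_that("one-way ANOVA matches t^2 on two groups and handles degeneracy", {
  set.seed(45)
  d <- tibble::tibble(
    y = c(rnorm(20, 0), rnorm(25, 0.8)),
    g = rep(c("a", "b"), c(20, 25))
  )
  a <- oneway_anova(d, y, g)
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(a$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(c(a$df_between, a$df_within), c(1, 43))

  sep <- tibble::tibble(y = rep(c(0, 10), each = 5), g = rep(c("a", "b"), each = 5))
  asep <- oneway_anova(sep, y, g)
  expect_equal(asep$p_value, 0)
  strong <- tibble::tibble(
    y = c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 10)),
    g = rep(c("a", "b", "c"), each = 50)
  )
  expect_lt(oneway_anova(strong, y, g)$p_value, 0.001)
  expect_error(oneway_anova(d[1:2, ], y, g), class = "psc_validation_error")
})

test_that("tau-b matches the O(n^2) pair-counting oracle", {
  x <- c(1, 2, 2, 3, 4)
  expect_equal(kendall_tau_b(x, x), 1)
  expect_equal(kendall_tau_b(1:5, 5:1), -1)
  expect_warning(t0 <- kendall_tau_b(rep(2, 5), 1:5), "undefined")
  expect_true(is.na(t0))
  set.seed(46)
  for (i in 1:15) {
    a <- sample(1:4, 30, TRUE)
    b <- sample(1:4, 30, TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(kendall_tau_b(a, b), oracle_tau_b(a, b), tolerance = 1e-12)
  }
})

test_that("logistic odds ratios reduce to ad/bc on a 2x2 design", {
  pr <- tibble::tibble(
    patient_id = sprintf("p%03d", 1:100),
    pirads = rep(c(4L, 2L), each = 50),
    psa_level = rep(c(3L, 1L), each = 50),
    psad_level = rep(c(4L, 1L), each = 50),
    ft_level = rep(c(4L, 1L), each = 50),
    gs_group = rep(c(3L, 1L), c(50, 50)),
    pca = rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40)),
    cs_pca = rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 10, 40))
  )
  tab <- logistic_odds_ratios(pr, "pca")
  row <- tab[tab$predictor == "psad_cat" & !tab$reference, ]
  expect_equal(row$or, 16, tolerance = 1e-6) # (40*40)/(10*10)
  expect_false(any(row$separation))
  expect_true(all(tab$reference == (tab$level %in% c("1-2", "<0.1", ">=0.24", "<4"))))
})

test_that("Wald intervals cover the null under independence", {
  set.seed(47)
  cover <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    pr <- tibble::tibble(
      patient_id = sprintf("p%03d", 1:120),
      pirads = sample(c(2L, 4L), 120, TRUE),
      psa_level = sample(1:4, 120, TRUE),
      psad_level = sample(c(1L, 4L), 120, TRUE),
      ft_level = sample(1:4, 120, TRUE),
      gs_group = 1L,
      pca = runif(120) < 0.5,
      cs_pca = FALSE
    )
    pr$gs_group[pr$pca] <- 3L
    tab <- logistic_odds_ratios(pr, "pca")
    row <- tab[tab$predictor == "psad_cat" & tab$level == ">=0.23", ]
    if (nrow(row) == 1 && !is.na(row$ci_low) &&
        row$ci_low <= 1 && row$ci_high >= 1) {
      cover <- cover + 1
    }
  }
  expect_gt(cover / reps, 0.90)
  expect_lt(cover / reps, 0.995)
})

test_that("single-level predictors and unlabelled records are rejected", {
  pr <- tibble::tibble(
    patient_id = c("a", "b", "c", "d"),
    pirads = c(4L, 4L, 4L, 4L), # single observed level
    psa_level = c(1L, 2L, 3L, 4L),
    psad_level = c(1L, 2L, 3L, 4L),
    ft_level = c(1L, 2L, 3L, 4L),
    gs_group = c(1L, 1L, 3L, 3L),
    pca = c(FALSE, FALSE, TRUE, TRUE),
    cs_pca = c(FALSE, FALSE, TRUE, TRUE)
  )
  expect_error(logistic_odds_ratios(pr, "pca"), class = "psc_validation_error")
  sc <- toy_scored(1:4, c(TRUE, NA, FALSE, TRUE))
  expect_error(confusion_at_cutoff(sc, "pca", 2), class = "psc_validation_error")
})
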