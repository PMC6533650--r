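## Diagnostic evaluation: confusion counts and operating points at score
## cut-offs, ROC curves with trapezoid AUC, Youden cut-off selection,
## group-mean summaries with Student-t confidence intervals, one-way ANOVA,
## tie-corrected Kendall tau-b, and logistic-regression odds ratios.

outcome_column <- function(scored, outcome = c("pca", "cs_pca")) {
  outcome <- match.arg(outcome)
  if (nrow(scored) == 0) {
    stop_validation("empty scored cohort")
  }
  labels <- scored[[outcome]]
  if (any(is.na(labels))) {
    stop_validation(paste0(
      "outcome '", outcome, "' missing for record(s): ",
      paste(scored$patient_id[is.na(labels)], collapse = ", ")
    ))
  }
  labels
}

#' Confusion counts at a score cut-off
#'
#' A record tests positive when its score is greater than or equal to the
#' cut-off.
#'
#' @param scored A scored cohort from [score_cohort()].
#' @param outcome `"pca"` or `"cs_pca"`.
#' @param cutoff Integer score cut-off.
#' @return A one-row tibble `cutoff`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutoff <- function(scored, outcome = c("pca", "cs_pca"), cutoff) {
  labels <- outcome_column(scored, outcome)
  positive_test <- scored$score >= cutoff
  tibble(
    cutoff = cutoff,
    tp = sum(positive_test & labels),
    fp = sum(positive_test & !labels),
    tn = sum(!positive_test & !labels),
    fn = sum(!positive_test & labels)
  )
}

#' Operating point from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV and the Youden index
#' `J = sensitivity + specificity - 1`.  A metric whose denominator is zero
#' is undefined and reported as `NA` rather than silently 0 or 1.
#'
#' @param confusion A one-row data frame with `tp`, `fp`, `tn`, `fn` (and
#'   optionally `cutoff`), e.g. from [confusion_at_cutoff()].
#' @param cutoff Cut-off to record in the output; defaults to
#'   `confusion$cutoff` when present.
#' @return A one-row tibble `cutoff`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `youden_j`.
#' @examples
#' operating_point(tibble::tibble(tp = 149, fn = 34, tn = 147, fp = 29), 11)
#' @export
operating_point <- function(confusion, cutoff = NULL) {
  cutoff <- cutoff %||% confusion[["cutoff"]] %||% NA_integer_
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(confusion, {
    sens <- safe_ratio(tp, tp + fn)
    spec <- safe_ratio(tn, tn + fp)
    tibble(
      cutoff = cutoff,
      sensitivity = sens,
      specificity = spec,
      ppv = safe_ratio(tp, tp + fp),
      npv = safe_ratio(tn, tn + fn),
      youden_j = sens + spec - 1
    )
  })
}

#' Operating points over several cut-offs
#'
#' @inheritParams confusion_at_cutoff
#' @param cutoffs Integer vector of cut-offs.
#' @return A tibble with one row per cut-off.
#' @export
operating_points <- function(scored, outcome = c("pca", "cs_pca"), cutoffs) {
  outcome <- match.arg(outcome)
  purrr::map_dfr(cutoffs, function(k) {
    operating_point(confusion_at_cutoff(scored, outcome, k))
  })
}

#' ROC curve and AUC for a scored cohort
#'
#' Sweeps the positivity threshold over all observed score values (from
#' high to low, plus sentinels) and computes the (FPR, TPR) path and the
#' trapezoid area under it.  With tied scores the trapezoid AUC equals the
#' tie-corrected Mann-Whitney statistic
#' `P(score+ > score-) + P(score+ = score-) / 2`.
#'
#' @inheritParams confusion_at_cutoff
#' @return An object of class `psc_roc`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `outcome`, `n_pos`, `n_neg`,
#'   `model`.
#' @export
roc_curve <- function(scored, outcome = c("pca", "cs_pca")) {
  outcome <- match.arg(outcome)
  labels <- outcome_column(scored, outcome)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop_validation("ROC needs both classes present")
  }
  thresholds <- sort(unique(scored$score), decreasing = TRUE)
  tpr <- vapply(thresholds, function(k) sum(scored$score >= k & labels), 0) / n_pos
  fpr <- vapply(thresholds, function(k) sum(scored$score >= k & !labels), 0) / n_neg
  points <- tibble(
    threshold = c(Inf, thresholds),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(
    list(
      points = points, auc = auc, outcome = outcome,
      n_pos = n_pos, n_neg = n_neg,
      model = attr(scored, "model")$name %||% NA_character_
    ),
    class = "psc_roc"
  )
}

#' @export
print.psc_roc <- function(x, ...) {
  cat(
    "ROC curve (", x$outcome, if (!is.na(x$model)) paste0(", ", x$model),
    "): AUC = ", format(x$auc, digits = 4),
    " over ", x$n_pos, " positives / ", x$n_neg, " negatives\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.psc_roc <- function(x, ...) x$points

#' @export
glance.psc_roc <- function(x, ...) {
  tibble(
    auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg,
    outcome = x$outcome, model = x$model
  )
}

#' Youden-optimal score cut-off
#'
#' Enumerates every candidate cut-off (all observed scores plus one above
#' the maximum) and returns the one maximising the Youden index
#' `J = sensitivity + specificity - 1`; ties are broken toward the larger
#' cut-off (higher specificity).
#'
#' @inheritParams confusion_at_cutoff
#' @return A list with `cutoff` and `operating_point` (one-row tibble).
#' @export
youden_optimal_cutoff <- function(scored, outcome = c("pca", "cs_pca")) {
  outcome <- match.arg(outcome)
  outcome_column(scored, outcome) # validates labels
  candidates <- c(sort(unique(scored$score)), max(scored$score) + 1L)
  ops <- operating_points(scored, outcome, candidates)
  j <- ifelse(is.na(ops$youden_j), -Inf, ops$youden_j)
  best <- max(which(j == max(j))) # ties -> larger cutoff
  list(cutoff = candidates[best], operating_point = ops[best, ])
}

#' Mean and Student-t confidence interval for a score group
#'
#' Classical summary: mean, standard deviation (n-1 denominator), standard
#' error `sd/sqrt(n)` and the t-based interval
#' `mean +/- t(1 - alpha/2, n - 1) * se`.
#'
#' @param values Numeric scores, at least two.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble `n`, `mean`, `sd`, `se`, `ci_low`, `ci_high`,
#'   `conf_level`.
#' @examples
#' group_summary(c(10, 12, 14, 11))
#' @export
group_summary <- function(values, conf_level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    stop_validation("group_summary needs at least 2 values")
  }
  m <- mean(values)
  s <- sd(values)
  se <- s / sqrt(n)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 1)
  tibble(
    n = n, mean = m, sd = s, se = se,
    ci_low = m - tcrit * se, ci_high = m + tcrit * se,
    conf_level = conf_level
  )
}

#' Per-group score summaries
#'
#' Data-frame-first wrapper around [group_summary()].
#'
#' @param data A data frame (e.g. a scored cohort).
#' @param value Column holding the scores (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @inheritParams group_summary
#' @return A tibble with one row per group.
#' @export
group_summaries <- function(data, value, group, conf_level = 0.95) {
  data |>
    dplyr::group_by({{ group }}) |>
    dplyr::reframe(group_summary({{ value }}, conf_level))
}

#' One-way ANOVA across score groups
#'
#' Classical fixed-effects one-way analysis of variance: the F statistic on
#' `(k - 1, N - k)` degrees of freedom and its p-value.  When the
#' within-group variance is exactly zero but group means differ, `F` is
#' infinite and the p-value 0.
#'
#' @param data A data frame.
#' @param value Score column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return A one-row tibble `f_stat`, `df_between`, `df_within`, `p_value`.
#' @export
oneway_anova <- function(data, value, group) {
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    group = factor(dplyr::pull(data, {{ group }}))
  )
  df <- df[!is.na(df$value) & !is.na(df$group), ]
  sizes <- table(df$group)
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop_validation("one-way ANOVA needs >= 2 groups with >= 2 values each")
  }
  # warnings about essentially perfect fits are superseded by the explicit
  # zero-within-variance handling below
  tab <- suppressWarnings(anova(lm(value ~ group, data = df)))
  f_stat <- tab[["F value"]][1]
  df_b <- tab[["Df"]][1]
  df_w <- tab[["Df"]][2]
  p <- tab[["Pr(>F)"]][1]
  if (tab[["Mean Sq"]][2] == 0) { # zero within-group variance
    if (tab[["Mean Sq"]][1] > 0) {
      f_stat <- Inf
      p <- 0
    } else {
      f_stat <- NA_real_
      p <- NA_real_
    }
  }
  tibble(f_stat = f_stat, df_between = df_b, df_within = df_w, p_value = p)
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' @param x,y Equal-length ordinal/numeric vectors, `n >= 2`.
#' @return tau-b in `[-1, 1]`, or `NA` (with a warning) when either vector
#'   is constant so the coefficient is undefined.
#' @examples
#' kendall_tau_b(c(1, 2, 2, 3), c(1, 1, 2, 3))
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) {
    stop_validation("x and y must have equal length")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) {
    stop_validation("kendall_tau_b needs at least 2 complete pairs")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warn("tau-b undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  cor(x, y, method = "kendall")
}

#' Pairwise tau-b matrix of the three serum levels
#'
#' @param profiles A profile tibble from [profile_cohort()].
#' @return A tibble with one row per unordered pair of
#'   `psa_level`/`psad_level`/`ft_level` and the tau-b value.
#' @export
tau_b_levels <- function(profiles) {
  vars <- c("psa_level", "psad_level", "ft_level")
  pairs <- utils::combn(vars, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    tibble(
      var1 = a, var2 = b,
      tau_b = kendall_tau_b(profiles[[a]], profiles[[b]])
    )
  })
}

# Factor-coded predictors with the conventional reference strata:
# PI-RADS 1-2, PSAD < 0.1, f/t >= 0.24, PSA < 4.
or_predictor_frame <- function(profiles) {
  tibble(
    pirads_cat = factor(
      ifelse(profiles$pirads <= 2, "1-2", as.character(profiles$pirads)),
      levels = c("1-2", "3", "4", "5")
    ),
    psad_cat = factor(profiles$psad_level,
      levels = 1:4,
      labels = c("<0.1", "0.1-0.19", "0.19-0.23", ">=0.23")
    ),
    ft_cat = factor(profiles$ft_level,
      levels = 1:4,
      labels = c(">=0.24", "0.18-0.24", "0.14-0.18", "<0.14")
    ),
    psa_cat = factor(profiles$psa_level,
      levels = 1:4,
      labels = c("<4", "4-10", "10-20", ">=20")
    )
  )
}

or_table_from_fit <- function(fit, predictor_names, conf_level, analysis,
                              separation_bound = 15) {
  est <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  rows <- list()
  for (pred in predictor_names) {
    f <- fit$model[[pred]]
    levs <- levels(droplevels(f))
    rows[[length(rows) + 1]] <- tibble(
      analysis = analysis, predictor = pred, level = levs[1],
      reference = TRUE, or = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p_value = NA_real_, separation = FALSE
    )
    for (lev in levs[-1]) {
      cn <- paste0(pred, lev)
      if (!cn %in% rownames(est)) next
      b <- est[cn, "Estimate"]
      se <- est[cn, "Std. Error"]
      rows[[length(rows) + 1]] <- tibble(
        analysis = analysis, predictor = pred, level = lev,
        reference = FALSE,
        or = exp(b),
        ci_low = exp(b - z * se),
        ci_high = exp(b + z * se),
        p_value = est[cn, "Pr(>|z|)"],
        separation = abs(b) > separation_bound
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Logistic-regression odds ratios for the level predictors
#'
#' Fits binomial logistic regressions of the outcome on the dummy-coded
#' categorical predictors (PI-RADS grouped 1-2/3/4/5 and the three serum
#' ladders), against the conventional reference strata (PI-RADS 1-2,
#' PSAD < 0.1, f/t >= 0.24, PSA < 4).  `adjusted = FALSE` fits one model
#' per predictor (univariate); `adjusted = TRUE` fits all four jointly
#' (multivariate).  Odds ratios are `exp(coef)` with Wald confidence
#' intervals.  Coefficients whose magnitude exceeds 15 on the log scale are
#' flagged as (quasi-)separated rather than reported silently.
#'
#' @param profiles A profile tibble from [profile_cohort()] with labels.
#' @param outcome `"pca"` or `"cs_pca"`.
#' @param adjusted Fit all predictors jointly (default `FALSE`).
#' @param conf_level Wald CI level (default 0.95).
#' @return A tibble with columns `analysis`, `predictor`, `level`,
#'   `reference`, `or`, `ci_low`, `ci_high`, `p_value`, `separation`.
#' @export
logistic_odds_ratios <- function(profiles, outcome = c("pca", "cs_pca"),
                                 adjusted = FALSE, conf_level = 0.95) {
  outcome <- match.arg(outcome)
  y <- outcome_column(profiles, outcome)
  if (length(unique(y)) < 2) {
    stop_validation("outcome must have both classes present")
  }
  preds <- or_predictor_frame(profiles)
  observed_levels <- vapply(preds, function(f) length(unique(f[!is.na(f)])), 1L)
  if (any(observed_levels < 2)) {
    stop_validation(paste0(
      "predictor(s) with a single observed level: ",
      paste(names(preds)[observed_levels < 2], collapse = ", ")
    ))
  }
  dat <- dplyr::mutate(preds, .y = y)
  analysis <- if (adjusted) "multivariate" else "univariate"
  fit_quiet <- function(formula) {
    withCallingHandlers(
      glm(formula, family = binomial(), data = dat,
          control = list(epsilon = 1e-10, maxit = 100)),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  if (adjusted) {
    fit <- fit_quiet(.y ~ pirads_cat + psad_cat + ft_cat + psa_cat)
    out <- or_table_from_fit(
      fit, c("pirads_cat", "psad_cat", "ft_cat", "psa_cat"),
      conf_level, analysis
    )
  } else {
    out <- purrr::map_dfr(names(preds), function(pred) {
      fit <- fit_quiet(stats::as.formula(paste0(".y ~ ", pred)))
      or_table_from_fit(fit, pred, conf_level, analysis)
    })
  }
  dplyr::mutate(out, outcome = outcome, .before = 1)
}
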