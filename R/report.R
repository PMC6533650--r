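## End-to-end evaluation report: AUCs for every model and outcome,
## operating points at Youden-optimal and user-supplied cut-offs,
## Gleason-group score summaries with ANOVA, and the tau-b matrix of the
## serum levels.

#' Full evaluation report for a labelled cohort
#'
#' Runs every requested model against both disease outcomes and gathers the
#' evaluation suite in one structure: per-model AUC, the operating point at
#' the Youden-optimal cut-off and at any user-supplied cut-offs,
#' Gleason-group summaries of a designated model's score (with one-way
#' ANOVA across groups), and the pairwise Kendall tau-b of the three serum
#' levels.
#'
#' @param cohort A labelled, validated cohort tibble.
#' @param models Character vector of model names (default: the full
#'   registry).
#' @param outcomes Outcomes to evaluate (default both `"pca"` and
#'   `"cs_pca"`).
#' @param cutoffs Optional named list mapping an outcome to integer
#'   cut-offs evaluated in addition to the Youden-optimal one, e.g.
#'   `list(pca = 11, cs_pca = 12)`.
#' @param summary_model Model whose score is summarised per Gleason group
#'   (default `"model6"`).
#' @param level_cutoffs Ladder cut-offs (see [level_cutoffs()]).
#' @param conf_level Confidence level for group summaries.
#' @return An object of class `psc_report`: a list of tibbles `auc`,
#'   `operating_points`, `group_scores`, `anova`, `tau`.
#' @export
evaluation_report <- function(cohort,
                              models = model_registry()$name,
                              outcomes = c("pca", "cs_pca"),
                              cutoffs = NULL,
                              summary_model = "model6",
                              level_cutoffs = prostascore::level_cutoffs(),
                              conf_level = 0.95) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  profiles <- profile_cohort(cohort, level_cutoffs)
  scored_list <- lapply(
    setNames(models, models),
    function(m) score_cohort(profiles, m)
  )

  auc_tbl <- purrr::map_dfr(models, function(m) {
    purrr::map_dfr(outcomes, function(oc) {
      r <- roc_curve(scored_list[[m]], oc)
      tibble(
        model = m, outcome = oc, auc = r$auc,
        n_pos = r$n_pos, n_neg = r$n_neg
      )
    })
  })

  op_tbl <- purrr::map_dfr(models, function(m) {
    purrr::map_dfr(outcomes, function(oc) {
      scored <- scored_list[[m]]
      yj <- youden_optimal_cutoff(scored, oc)
      rows <- dplyr::mutate(
        yj$operating_point,
        model = m, outcome = oc, cutoff_type = "youden", .before = 1
      )
      extra <- cutoffs[[oc]]
      if (!is.null(extra)) {
        user <- dplyr::mutate(
          operating_points(scored, oc, extra),
          model = m, outcome = oc, cutoff_type = "user", .before = 1
        )
        rows <- dplyr::bind_rows(rows, user)
      }
      rows
    })
  })

  summary_scored <- scored_list[[summary_model]] %||%
    score_cohort(profiles, summary_model)
  group_tbl <- group_summaries(
    summary_scored, .data$score, .data$gs_group, conf_level
  )
  anova_tbl <- oneway_anova(summary_scored, .data$score, .data$gs_group)
  tau_tbl <- tau_b_levels(profiles)

  structure(
    list(
      auc = auc_tbl,
      operating_points = op_tbl,
      group_scores = group_tbl,
      anova = anova_tbl,
      tau = tau_tbl,
      summary_model = summary_model,
      n = nrow(cohort)
    ),
    class = "psc_report"
  )
}

#' @export
print.psc_report <- function(x, ...) {
  cat("Evaluation report over", x$n, "records\n\n")
  cat("AUC by model and outcome:\n")
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x$auc, auc = round_half_up(.data$auc, 3)),
    id_cols = "model", names_from = "outcome", values_from = "auc"
  )
  print(as.data.frame(wide), row.names = FALSE)
  cat("\nScore of", x$summary_model, "by Gleason group:\n")
  print(as.data.frame(dplyr::mutate(
    x$group_scores,
    dplyr::across(dplyr::where(is.double), ~ round_half_up(.x, 2))
  )), row.names = FALSE)
  cat(sprintf(
    "\nOne-way ANOVA: F(%d, %d) = %.2f, p %s\n",
    x$anova$df_between, x$anova$df_within, x$anova$f_stat,
    ifelse(x$anova$p_value < 0.001, "< 0.001",
      paste0("= ", signif(x$anova$p_value, 3))
    )
  ))
  invisible(x)
}

#' Write a report to disk
#'
#' Emits the full report as JSON plus two TSV tables: one row per model
#' with AUCs and Youden operating points for each outcome, and one row per
#' Gleason group with the score summaries.
#'
#' @param report A `psc_report` from [evaluation_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    report[c("auc", "operating_points", "group_scores", "anova", "tau")],
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  readr::write_tsv(
    dplyr::left_join(
      report$auc,
      dplyr::filter(report$operating_points, .data$cutoff_type == "youden"),
      by = c("model", "outcome")
    ),
    file.path(dir, "model_performance.tsv")
  )
  readr::write_tsv(report$group_scores, file.path(dir, "group_scores.tsv"))
  invisible(dir)
}
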