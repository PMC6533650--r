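# Independent brute-force oracles used to cross-check the implementation.

# Level assignment as a plain chain of comparisons, written independently
# of the findInterval-based implementation.
oracle_psa_level <- function(x) {
  vapply(x, function(v) {
    if (v < 4) 1L else if (v < 10) 2L else if (v < 20) 3L else 4L
  }, 1L)
}
oracle_psad_level <- function(x) {
  vapply(x, function(v) {
    if (v < 0.1) 1L else if (v < 0.19) 2L else if (v < 0.23) 3L else 4L
  }, 1L)
}
oracle_ft_level <- function(x) {
  vapply(x, function(v) {
    if (v >= 0.24) 1L else if (v >= 0.18) 2L else if (v >= 0.14) 3L else 4L
  }, 1L)
}

# Mann-Whitney AUC over all positive x negative pairs, ties counted half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Tie-corrected Kendall tau-b by explicit O(n^2) pair counting.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j])
      dy <- sign(y[i] - y[j])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tie_x <- tie_x + 1
      else if (dy == 0) tie_y <- tie_y + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  (conc - disc) /
    sqrt((conc + disc + tie_x) * (conc + disc + tie_y))
}

# A tiny hand-written cohort with fully explicit fields.
toy_cohort <- function() {
  as_cohort(tibble::tibble(
    patient_id = c("a", "b", "c"),
    psa_total = c(3.5, 12, 25),
    psa_free = c(1.05, 1.2, 2.0),
    volume = c(30, 50, 40),
    pirads = c(2L, 4L, 5L),
    gleason_primary = c(NA, 3L, 4L),
    gleason_secondary = c(NA, 4L, 5L),
    max_core_length = c(NA, 6, 11),
    pathology = c("benign", "pca", "pca")
  ))
}

# Scored tibble built directly from scores and labels (bypasses profiling).
toy_scored <- function(scores, labels, cs = labels) {
  tibble::tibble(
    patient_id = sprintf("p%02d", seq_along(scores)),
    score = as.integer(scores),
    pca = labels,
    cs_pca = cs,
    gs_group = ifelse(labels, 3L, 1L)
  )
}
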