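## Ordinal stratification: four-level ladders for PSA, PSAD and f/t PSA,
## the four-tier Gleason grouping, and the clinically-significant flag.

#' Level ladder cut-offs
#'
#' Bundles the cut-off points that stratify the three serum markers into
#' four ordinal levels.  Defaults are the conventional clinical thresholds:
#' PSA 4/10/20 ng/mL, PSAD 0.1/0.19/0.23 ng/mL/mL, f/t PSA 0.14/0.18/0.24.
#' Ascending ladders (PSA, PSAD) are left-closed/right-open, so a value
#' equal to a cut-off belongs to the higher level; the f/t ladder is
#' reversed (lower ratio = higher risk level) with 0.24 itself mapping to
#' level 1.
#'
#' @param psa Three increasing PSA cut-offs (ng/mL).
#' @param psad Three increasing PSAD cut-offs (ng/mL/mL).
#' @param ft Three increasing f/t ratio cut-offs (dimensionless).
#' @return A list of class `psc_cutoffs`.
#' @examples
#' level_cutoffs()
#' level_cutoffs(psad = c(0.1, 0.15, 0.23)) # alternate PSAD ladder
#' @export
level_cutoffs <- function(psa = c(4, 10, 20),
                          psad = c(0.1, 0.19, 0.23),
                          ft = c(0.14, 0.18, 0.24)) {
  for (v in list(psa = psa, psad = psad, ft = ft)) {
    if (length(v) != 3 || any(!is.finite(v)) || is.unsorted(v, strictly = TRUE)) {
      stop_domain("each ladder needs exactly 3 strictly increasing finite cut-offs")
    }
  }
  structure(list(psa = psa, psad = psad, ft = ft), class = "psc_cutoffs")
}

#' Ordinal PSA level
#'
#' Maps total PSA to levels 1-4: `[0,4) -> 1`, `[4,10) -> 2`, `[10,20) -> 3`,
#' `[20,Inf) -> 4` under the default ladder.
#'
#' @param psa_total Total PSA in ng/mL (non-negative).
#' @param cutoffs A [level_cutoffs()] object.
#' @return Integer level 1-4.
#' @examples
#' psa_level(c(3.9, 11.06, 20))
#' @export
psa_level <- function(psa_total, cutoffs = level_cutoffs()) {
  if (any(!is.finite(psa_total) | psa_total < 0)) {
    stop_domain("psa_total must be non-negative and finite")
  }
  findInterval(psa_total, cutoffs$psa) + 1L
}

#' Ordinal PSAD level
#'
#' Maps PSA density to levels 1-4: `[0,0.1) -> 1`, `[0.1,0.19) -> 2`,
#' `[0.19,0.23) -> 3`, `[0.23,Inf) -> 4` under the default ladder.
#'
#' @param psad PSA density in ng/mL/mL (non-negative).
#' @inheritParams psa_level
#' @return Integer level 1-4.
#' @examples
#' psad_level(c(0.05, 0.1, 0.24))
#' @export
psad_level <- function(psad, cutoffs = level_cutoffs()) {
  if (any(!is.finite(psad) | psad < 0)) {
    stop_domain("psad must be non-negative and finite")
  }
  findInterval(psad, cutoffs$psad) + 1L
}

#' Ordinal f/t PSA level
#'
#' Reversed ladder (a low free fraction indicates higher cancer risk):
#' `[0.24,1] -> 1`, `[0.18,0.24) -> 2`, `[0.14,0.18) -> 3`, `[0,0.14) -> 4`
#' under the default ladder.  The censoring sentinel 0.001 falls in the
#' lowest stratum and maps to level 4.
#'
#' @param ft_ratio Free/total PSA ratio in `[0, 1]`.
#' @inheritParams psa_level
#' @return Integer level 1-4.
#' @examples
#' ft_level(c(0.30, 0.13, 0.001))
#' @export
ft_level <- function(ft_ratio, cutoffs = level_cutoffs()) {
  if (any(!is.finite(ft_ratio) | ft_ratio < 0 | ft_ratio > 1)) {
    stop_domain("ft_ratio must lie in [0, 1]")
  }
  4L - findInterval(ft_ratio, cutoffs$ft)
}

#' Four-tier Gleason group
#'
#' Benign records (and Gleason sums below 6) form group 1; sum 6 is group 2,
#' sum 7 group 3, and sums 8-10 group 4.
#'
#' @param pathology Character vector, `"benign"` or `"pca"`.
#' @param gleason_primary,gleason_secondary Gleason pattern components
#'   (3-5); required for PCa records.
#' @return Integer group 1-4.
#' @examples
#' gs_group("benign", NA, NA)
#' gs_group("pca", 3, 4)
#' @export
gs_group <- function(pathology, gleason_primary, gleason_secondary) {
  n <- max(length(pathology), length(gleason_primary), length(gleason_secondary))
  pathology <- rep_len(pathology, n)
  gp <- rep_len(gleason_primary, n)
  gs <- rep_len(gleason_secondary, n)
  is_pca <- !is.na(pathology) & pathology == "pca"
  if (any(is_pca & (is.na(gp) | is.na(gs)))) {
    stop_validation("PCa records require both Gleason components")
  }
  out <- rep(1L, n)
  total <- gp + gs
  out[is_pca & total == 6] <- 2L
  out[is_pca & total == 7] <- 3L
  out[is_pca & total >= 8] <- 4L
  out
}

#' Clinically significant prostate cancer flag
#'
#' A PCa record is clinically significant when the Gleason grade is at
#' least 3+4 (sum >= 7) and/or the maximum cancer core length is >= 4 mm.
#' Benign records are never significant.
#'
#' @inheritParams gs_group
#' @param max_core_length Maximum cancer core length in mm.
#' @return Logical vector.
#' @examples
#' classify_cs_pca("pca", 3, 3, 5) # GS6 but long core
#' classify_cs_pca("pca", 4, 3, NA) # GS7: significant regardless of core
#' @export
classify_cs_pca <- function(pathology, gleason_primary, gleason_secondary,
                            max_core_length) {
  n <- max(
    length(pathology), length(gleason_primary),
    length(gleason_secondary), length(max_core_length)
  )
  pathology <- rep_len(pathology, n)
  gp <- rep_len(gleason_primary, n)
  gs <- rep_len(gleason_secondary, n)
  core <- rep_len(max_core_length, n)
  if (any(is.na(pathology))) {
    stop_validation("pathology must be known to classify significance")
  }
  is_pca <- pathology == "pca"
  grade_hit <- (gp + gs) >= 7 # NA when components missing
  core_hit <- core >= 4
  out <- rep(FALSE, n)
  # TRUE | NA is TRUE, FALSE | NA is NA: undeterminable records surface as NA
  out[is_pca] <- grade_hit[is_pca] | core_hit[is_pca]
  if (any(is.na(out))) {
    stop_validation(paste0(
      "cannot classify significance (Gleason and/or core length missing) ",
      "for record(s): ", paste(which(is.na(out)), collapse = ", ")
    ))
  }
  out
}

#' Build level profiles for a cohort
#'
#' Derives, for every record, the four ordinal levels (PSA, PSAD, f/t PSA
#' via the ladder in `cutoffs`, plus the raw PI-RADS category), the
#' four-tier Gleason group and the disease flags.  Records whose PSAD or
#' f/t ratio cannot be derived cause an error naming them.  Gleason sums
#' below 6 are treated with benign disease (`pca = FALSE`, group 1),
#' matching the convention that group 1 is the benign stratum.
#'
#' @param cohort A validated cohort tibble with derivable PSAD and f/t.
#' @inheritParams psa_level
#' @return A tibble with one row per record: `patient_id`, `pirads`,
#'   `psa_level`, `psad_level`, `ft_level`, `gs_group`, `pca`, `cs_pca`.
#' @export
profile_cohort <- function(cohort, cutoffs = level_cutoffs()) {
  if (nrow(cohort) == 0) {
    stop_validation("cohort is empty")
  }
  cohort <- derive_cohort(cohort)
  missing_psad <- is.na(cohort$psad)
  missing_ft <- is.na(cohort$ft_ratio)
  if (any(missing_psad | missing_ft)) {
    stop_validation(paste0(
      "PSAD or f/t ratio underivable for patient(s): ",
      paste(cohort$patient_id[missing_psad | missing_ft], collapse = ", ")
    ))
  }
  group <- gs_group(
    cohort$pathology, cohort$gleason_primary, cohort$gleason_secondary
  )
  labelled <- !is.na(cohort$pathology)
  pca <- rep(NA, nrow(cohort))
  pca[labelled] <- group[labelled] >= 2
  cs <- rep(NA, nrow(cohort))
  if (any(labelled)) {
    cs[labelled] <- classify_cs_pca(
      cohort$pathology[labelled], cohort$gleason_primary[labelled],
      cohort$gleason_secondary[labelled], cohort$max_core_length[labelled]
    )
  }
  tibble(
    patient_id = cohort$patient_id,
    pirads = as.integer(cohort$pirads),
    psa_level = psa_level(cohort$psa_total, cutoffs),
    psad_level = psad_level(cohort$psad, cutoffs),
    ft_level = ft_level(cohort$ft_ratio, cutoffs),
    gs_group = group,
    pca = pca,
    cs_pca = cs
  )
}
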