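## Cohort data model: schema, CSV I/O, validation, and derivation of
## prostate volume, PSA density and the free/total PSA ratio.

# Documented column schema.  `mandatory` columns must be present in any CSV;
# the remaining columns are optional and filled with NA when absent.
psc_schema <- function() {
  tibble(
    column = c(
      "patient_id", "age", "psa_total", "psa_free", "ft_ratio",
      "psa_censored_high", "dim_length", "dim_width", "dim_height",
      "volume", "psad", "pirads", "gleason_primary", "gleason_secondary",
      "max_core_length", "pathology"
    ),
    type = c(
      "character", "double", "double", "double", "double",
      "logical", "double", "double", "double",
      "double", "double", "integer", "integer", "integer",
      "double", "character"
    ),
    mandatory = c(
      TRUE, FALSE, TRUE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE, TRUE, FALSE, FALSE,
      FALSE, FALSE
    )
  )
}

# Sentinel f/t ratio recorded when the laboratory reports only "PSA > 1000"
# and no explicit free fraction can be formed.
FT_CENSORED_SENTINEL <- 0.001

# PSA value stored for records censored above the assay reporting limit.
PSA_CENSOR_LIMIT <- 1000

#' Coerce a data frame to the cohort schema
#'
#' Adds any missing optional columns (filled with `NA`), coerces columns to
#' their documented types and attaches a provenance string.  This is the
#' common entry point used by [read_cohort_csv()] and the synthetic cohort
#' generator; it does not validate invariants (see [validate_cohort()]).
#'
#' @param data A data frame with at least `patient_id`, `psa_total` and
#'   `pirads` columns.
#' @param provenance Free-text origin of the records (file path or generator
#'   seed), stored as an attribute.
#' @return A tibble with the full 16-column schema.
#' @export
as_cohort <- function(data, provenance = "in-memory") {
  schema <- psc_schema()
  missing_mand <- setdiff(schema$column[schema$mandatory], names(data))
  if (length(missing_mand) > 0) {
    stop_schema(paste0(
      "missing mandatory column(s): ", paste(missing_mand, collapse = ", ")
    ))
  }
  unknown <- setdiff(names(data), schema$column)
  if (length(unknown) > 0) {
    stop_schema(paste0(
      "unknown column(s): ", paste(unknown, collapse = ", ")
    ))
  }
  out <- as_tibble(data)
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(out)) {
      out[[col]] <- switch(schema$type[i],
        character = NA_character_,
        double = NA_real_,
        integer = NA_integer_,
        logical = NA
      )
    } else {
      out[[col]] <- switch(schema$type[i],
        character = as.character(out[[col]]),
        double = as.double(out[[col]]),
        integer = as.integer(out[[col]]),
        logical = as.logical(out[[col]])
      )
    }
  }
  out <- out[, schema$column]
  out$psa_censored_high[is.na(out$psa_censored_high)] <- FALSE
  attr(out, "provenance") <- provenance
  out
}

#' Compute prostate volume from three orthogonal dimensions
#'
#' Ellipsoid approximation: length x width x height x 0.52, dimensions in
#' cm, volume in mL.
#'
#' @param length,width,height Prostate dimensions in cm; all must be
#'   positive.
#' @return Volume in mL.
#' @examples
#' derive_volume(4, 5, 5)
#' @export
derive_volume <- function(length, width, height) {
  bad <- !is.finite(length) | !is.finite(width) | !is.finite(height) |
    length <= 0 | width <= 0 | height <= 0
  if (any(bad)) {
    stop_domain("all prostate dimensions must be positive and finite")
  }
  length * width * height * 0.52
}

#' Compute PSA density
#'
#' @param psa_total Total serum PSA in ng/mL (non-negative).
#' @param volume Prostate volume in mL (positive).
#' @return PSA density in ng/mL/mL.
#' @examples
#' derive_psad(11.06, 46.08)
#' @export
derive_psad <- function(psa_total, volume) {
  if (any(!is.finite(volume) | volume <= 0)) {
    stop_domain("prostate volume must be positive")
  }
  if (any(!is.finite(psa_total) | psa_total < 0)) {
    stop_domain("psa_total must be non-negative")
  }
  psa_total / volume
}

#' Compute the free/total PSA ratio
#'
#' Returns `psa_free / psa_total`, except for records whose total PSA is
#' censored above the assay limit ("PSA > 1000"), where the conventional
#' sentinel 0.001 is returned regardless of the free value.
#'
#' @param psa_free Free PSA in ng/mL.
#' @param psa_total Total PSA in ng/mL.
#' @param psa_censored_high Logical; `TRUE` when the laboratory reported
#'   only that PSA exceeded the reporting limit.
#' @return Dimensionless ratio in `[0, 1]`, or the sentinel 0.001.
#' @examples
#' derive_ft_ratio(1.3, 10)
#' derive_ft_ratio(NA, NA, psa_censored_high = TRUE)
#' @export
derive_ft_ratio <- function(psa_free, psa_total, psa_censored_high = FALSE) {
  n <- max(length(psa_free), length(psa_total), length(psa_censored_high))
  psa_free <- rep_len(psa_free, n)
  psa_total <- rep_len(psa_total, n)
  cens <- rep_len(psa_censored_high, n)
  out <- rep(NA_real_, n)
  out[cens] <- FT_CENSORED_SENTINEL
  idx <- !cens
  if (any(idx)) {
    if (any(!is.finite(psa_total[idx]) | psa_total[idx] <= 0)) {
      stop_domain("psa_total must be positive unless censored high")
    }
    if (any(psa_free[idx] > psa_total[idx], na.rm = TRUE)) {
      stop_validation("psa_free exceeds psa_total")
    }
    if (any(psa_free[idx] < 0, na.rm = TRUE)) {
      stop_domain("psa_free must be non-negative")
    }
    out[idx] <- psa_free[idx] / psa_total[idx]
  }
  out
}

#' Fill in derivable fields of a cohort
#'
#' Completes `volume` (from the three dimensions when no explicit volume is
#' given), `psad` (PSA / volume) and `ft_ratio` (free / total PSA, or the
#' 0.001 sentinel for records censored above the PSA reporting limit).
#' Explicitly supplied values always win over derived ones; when both an
#' explicit `ft_ratio` and `psa_free` are present and disagree by more than
#' 0.005 a consistency warning is emitted.
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @return The cohort with derived columns filled in.
#' @export
derive_cohort <- function(cohort) {
  cohort <- as_cohort(cohort, provenance = attr(cohort, "provenance") %||% "in-memory")

  # explicit volume wins over dimensions
  need_vol <- is.na(cohort$volume) &
    !is.na(cohort$dim_length) & !is.na(cohort$dim_width) &
    !is.na(cohort$dim_height)
  if (any(need_vol)) {
    cohort$volume[need_vol] <- derive_volume(
      cohort$dim_length[need_vol], cohort$dim_width[need_vol],
      cohort$dim_height[need_vol]
    )
  }

  need_psad <- is.na(cohort$psad) & !is.na(cohort$volume) &
    !is.na(cohort$psa_total)
  if (any(need_psad)) {
    cohort$psad[need_psad] <- derive_psad(
      cohort$psa_total[need_psad], cohort$volume[need_psad]
    )
  }

  # censored-high records carry the sentinel unconditionally
  cens <- cohort$psa_censored_high
  cohort$ft_ratio[cens] <- FT_CENSORED_SENTINEL

  both <- !cens & !is.na(cohort$ft_ratio) & !is.na(cohort$psa_free) &
    !is.na(cohort$psa_total) & cohort$psa_total > 0
  if (any(both)) {
    disagree <- abs(
      cohort$ft_ratio[both] -
        cohort$psa_free[both] / cohort$psa_total[both]
    ) > 0.005
    if (any(disagree)) {
      warn(paste0(
        "explicit ft_ratio disagrees with psa_free/psa_total by > 0.005 ",
        "for patient(s): ",
        paste(cohort$patient_id[both][disagree], collapse = ", "),
        " (explicit ratio kept)"
      ))
    }
  }

  need_ft <- !cens & is.na(cohort$ft_ratio) & !is.na(cohort$psa_free)
  if (any(need_ft)) {
    cohort$ft_ratio[need_ft] <- derive_ft_ratio(
      cohort$psa_free[need_ft], cohort$psa_total[need_ft], FALSE
    )
  }
  cohort
}

#' Validate cohort invariants
#'
#' Checks every record against the schema invariants and returns a tibble of
#' problems (empty when the cohort is valid): one row per violated rule with
#' the row number, patient id, field and message.
#'
#' @param cohort A cohort tibble.
#' @return A tibble with columns `row`, `patient_id`, `field`, `message`.
#' @export
validate_cohort <- function(cohort) {
  problems <- list()
  note <- function(rows, field, message) {
    if (length(rows) == 0) return()
    problems[[length(problems) + 1]] <<- tibble(
      row = rows,
      patient_id = as.character(cohort$patient_id[rows]),
      field = field,
      message = message
    )
  }

  if (nrow(cohort) == 0) {
    stop_validation("cohort is empty")
  }
  dup <- which(duplicated(cohort$patient_id) | is.na(cohort$patient_id))
  note(dup, "patient_id", "patient_id must be unique and non-missing")

  note(
    which(is.na(cohort$pirads) | !cohort$pirads %in% 1:5),
    "pirads", "pirads must be an integer in 1..5"
  )
  note(
    which(is.na(cohort$psa_total) | cohort$psa_total < 0),
    "psa_total", "psa_total must be non-negative"
  )
  ft <- cohort$ft_ratio
  bad_ft <- which(!is.na(ft) & (ft < 0 | ft > 1) &
    !(ft == FT_CENSORED_SENTINEL & cohort$psa_censored_high))
  note(bad_ft, "ft_ratio", "ft_ratio must lie in [0, 1]")
  note(
    which(!is.na(cohort$volume) & cohort$volume <= 0),
    "volume", "volume must be positive when present"
  )
  note(
    which(!is.na(cohort$psad) & cohort$psad < 0),
    "psad", "psad must be non-negative"
  )
  for (d in c("dim_length", "dim_width", "dim_height")) {
    note(
      which(!is.na(cohort[[d]]) & cohort[[d]] <= 0),
      d, paste0(d, " must be positive when present")
    )
  }
  note(
    which(!is.na(cohort$pathology) &
      !cohort$pathology %in% c("benign", "pca")),
    "pathology", "pathology must be 'benign' or 'pca'"
  )
  is_pca <- !is.na(cohort$pathology) & cohort$pathology == "pca"
  for (g in c("gleason_primary", "gleason_secondary")) {
    note(
      which(is_pca & !is.na(cohort[[g]]) & !cohort[[g]] %in% 3:5),
      g, paste0(g, " must be in 3..5 for PCa records")
    )
  }
  note(
    which(!is.na(cohort$max_core_length) & cohort$max_core_length < 0),
    "max_core_length", "max_core_length must be non-negative"
  )

  if (length(problems) == 0) {
    tibble(
      row = integer(), patient_id = character(),
      field = character(), message = character()
    )
  } else {
    dplyr::arrange(dplyr::bind_rows(problems), .data$row)
  }
}

# Parse the psa_total column, which may carry censoring markers such as
# "1000+" or "> 1000".  Returns list(value=, censored=).
parse_psa_column <- function(x) {
  x_chr <- trimws(as.character(x))
  censored <- grepl("^>\\s*[0-9.]+$", x_chr) | grepl("^[0-9.]+\\s*\\+$", x_chr)
  value <- suppressWarnings(as.numeric(x_chr))
  value[censored] <- PSA_CENSOR_LIMIT
  bad <- !censored & is.na(value) & !is.na(x_chr) & x_chr != ""
  list(value = value, censored = censored, bad = which(bad))
}

#' Read a patient cohort from CSV
#'
#' Reads a comma-separated, UTF-8, headered file following the documented
#' column schema (`patient_id`, `age`, `psa_total`, `psa_free`, `ft_ratio`,
#' `psa_censored_high`, `dim_length`, `dim_width`, `dim_height`, `volume`,
#' `psad`, `pirads`, `gleason_primary`, `gleason_secondary`,
#' `max_core_length`, `pathology`).  Empty cells denote absent optional
#' values.  A `psa_total` written as `"1000+"` or `"> 1000"` marks a record
#' censored above the assay reporting limit; such records get
#' `psa_censored_high = TRUE` and the sentinel f/t ratio 0.001.
#'
#' Derivable fields (volume, PSAD, f/t ratio) are filled in via
#' [derive_cohort()] and all invariants are checked; rows that violate them
#' cause an error carrying row-level diagnostics.
#'
#' @param path Path to the CSV file.
#' @param derive Fill in derivable fields (default `TRUE`).
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path, derive = TRUE) {
  if (!file.exists(path)) {
    stop_schema(paste0("file not found: ", path))
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"),
    progress = FALSE
  )
  schema <- psc_schema()
  missing_mand <- setdiff(schema$column[schema$mandatory], names(raw))
  if (length(missing_mand) > 0) {
    stop_schema(paste0(
      "missing mandatory column(s): ", paste(missing_mand, collapse = ", ")
    ))
  }
  unknown <- setdiff(names(raw), schema$column)
  if (length(unknown) > 0) {
    stop_schema(paste0("unknown column(s): ", paste(unknown, collapse = ", ")))
  }

  psa <- parse_psa_column(raw$psa_total)
  if (length(psa$bad) > 0) {
    stop_validation(paste0(
      "unparsable psa_total in row(s): ", paste(psa$bad, collapse = ", ")
    ))
  }
  raw$psa_total <- psa$value
  if ("psa_censored_high" %in% names(raw)) {
    explicit <- toupper(trimws(raw$psa_censored_high)) %in% c("TRUE", "T", "1")
    raw$psa_censored_high <- explicit | psa$censored
  } else {
    raw$psa_censored_high <- psa$censored
  }

  numeric_cols <- schema$column[schema$type %in% c("double", "integer") &
    schema$column != "psa_total"]
  for (col in intersect(numeric_cols, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(parsed) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop_validation(paste0(
        "unparsable numeric in column '", col, "', row(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    raw[[col]] <- parsed
  }

  cohort <- as_cohort(raw, provenance = path)
  if (derive) {
    cohort <- derive_cohort(cohort)
  }
  problems <- validate_cohort(cohort)
  if (nrow(problems) > 0) {
    stop_validation(
      paste0(
        nrow(problems), " invalid row(s):\n",
        paste(
          sprintf(
            "  row %d (%s): %s", problems$row, problems$patient_id,
            problems$message
          ),
          collapse = "\n"
        )
      ),
      problems = problems
    )
  }
  cohort
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: writes the documented schema with empty
#' cells for absent optional values, so that reading the file back
#' reproduces the cohort field for field.
#'
#' @param cohort A validated, non-empty cohort tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (nrow(cohort) == 0) {
    stop_validation("refusing to write an empty cohort")
  }
  problems <- validate_cohort(cohort)
  if (nrow(problems) > 0) {
    stop_validation("cohort is invalid; see validate_cohort()")
  }
  readr::write_csv(cohort[, psc_schema()$column], path, na = "")
  invisible(path)
}
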