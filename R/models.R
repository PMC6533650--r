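## The accumulating-model registry and integer score computation.
## Each model is a non-negative integer weight vector over the raw PI-RADS
## v2 category (1-5) and the three ordinal serum levels (1-4).

#' Registry of accumulating models
#'
#' The thirteen weighted models plus the PI-RADS-only baseline.  Each row
#' gives the integer weights applied to the raw PI-RADS v2 category and the
#' ordinal levels of PSAD, f/t PSA and PSA; the model score is the weighted
#' sum.  For example `model6` adds all four terms with unit weights and
#' `model13` doubles the PI-RADS and PSAD terms.
#'
#' @return A tibble with columns `name`, `w_pirads`, `w_psad`, `w_ft`,
#'   `w_psa`.
#' @examples
#' model_registry()
#' @export
model_registry <- function() {
  tibble(
    name = c(
      "baseline",
      paste0("model", 1:13)
    ),
    w_pirads = c(1, 1, 1, 1, 1, 1, 1, 2, 2, 2, 2, 2, 2, 2),
    w_psad   = c(0, 1, 0, 0, 1, 1, 1, 3, 3, 3, 3, 2, 2, 2),
    w_ft     = c(0, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 1, 0, 1),
    w_psa    = c(0, 0, 0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 1)
  )
}

#' Look up a model specification by name
#'
#' @param name Model name (`"baseline"` or `"model1"` ... `"model13"`), or a
#'   one-row data frame with the four weight columns (returned unchanged
#'   after validation, so custom weight vectors can be supplied anywhere a
#'   model name is accepted).
#' @return A one-row tibble model specification.
#' @examples
#' get_model_spec("model6")
#' @export
get_model_spec <- function(name) {
  if (is.data.frame(name)) {
    spec <- as_tibble(name)
    needed <- c("name", "w_pirads", "w_psad", "w_ft", "w_psa")
    if (nrow(spec) != 1 || !all(needed %in% names(spec))) {
      stop_schema("a model spec needs one row with columns name, w_pirads, w_psad, w_ft, w_psa")
    }
    w <- unlist(spec[, needed[-1]])
    if (any(w < 0) || any(w != trunc(w)) || all(w == 0)) {
      stop_domain("model weights must be non-negative integers, not all zero")
    }
    return(spec)
  }
  reg <- model_registry()
  hit <- reg[reg$name == name, ]
  if (nrow(hit) == 0) {
    stop_schema(paste0(
      "unknown model '", name, "'; available: ",
      paste(reg$name, collapse = ", ")
    ))
  }
  hit
}

#' Compute accumulating-model scores
#'
#' `score = w_pirads * pirads + w_psad * psad_level + w_ft * ft_level +
#' w_psa * psa_level`.  Vectorised over the inputs.
#'
#' @param pirads Raw PI-RADS v2 category (1-5).
#' @param psad_level,ft_level,psa_level Ordinal levels 1-4.
#' @param spec Model name or specification (see [get_model_spec()]).
#' @return Integer score vector.
#' @examples
#' compute_score(5, 4, 4, 4, "model6") # cohort maximum, 17
#' compute_score(3, 2, 4, 3, "model13")
#' @export
compute_score <- function(pirads, psad_level, ft_level, psa_level,
                          spec = "model6") {
  spec <- get_model_spec(spec)
  terms <- list(
    pirads = list(w = spec$w_pirads, x = pirads, range = 1:5),
    psad_level = list(w = spec$w_psad, x = psad_level, range = 1:4),
    ft_level = list(w = spec$w_ft, x = ft_level, range = 1:4),
    psa_level = list(w = spec$w_psa, x = psa_level, range = 1:4)
  )
  n <- max(vapply(terms, function(t) length(t$x), 1L))
  out <- rep(0L, n)
  for (nm in names(terms)) {
    t <- terms[[nm]]
    if (t$w == 0) next
    x <- rep_len(t$x, n)
    if (any(is.na(x))) {
      stop_validation(paste0("missing ", nm, " required by model ", spec$name))
    }
    if (any(!x %in% t$range)) {
      stop_domain(paste0(nm, " out of range ", min(t$range), "..", max(t$range)))
    }
    out <- out + as.integer(t$w) * as.integer(x)
  }
  out
}

#' Attainable score range of a model
#'
#' Minimum and maximum score over all combinations of PI-RADS 1-5 and
#' levels 1-4, found by exhaustive enumeration.
#'
#' @inheritParams compute_score
#' @return Named integer vector `c(min = , max = )`.
#' @examples
#' score_range("model6") # 4..17
#' @export
score_range <- function(spec = "model6") {
  spec <- get_model_spec(spec)
  grid <- expand.grid(pirads = 1:5, psad = 1:4, ft = 1:4, psa = 1:4)
  scores <- compute_score(grid$pirads, grid$psad, grid$ft, grid$psa, spec)
  c(min = min(scores), max = max(scores))
}

#' Score a cohort under a model
#'
#' Profiles the cohort (unless a profile tibble from [profile_cohort()] is
#' supplied directly) and computes the model score for every record.
#' Deterministic and order-preserving.
#'
#' @param data A cohort tibble or a profile tibble.
#' @inheritParams compute_score
#' @inheritParams psa_level
#' @return A tibble `patient_id`, `score`, `pca`, `cs_pca`, `gs_group`,
#'   with the model spec attached as attribute `"model"`.
#' @export
score_cohort <- function(data, spec = "model6", cutoffs = level_cutoffs()) {
  spec <- get_model_spec(spec)
  profiles <- if (all(c("psa_level", "psad_level", "ft_level") %in% names(data))) {
    data
  } else {
    profile_cohort(data, cutoffs)
  }
  out <- tibble(
    patient_id = profiles$patient_id,
    score = compute_score(
      profiles$pirads, profiles$psad_level, profiles$ft_level,
      profiles$psa_level, spec
    ),
    pca = profiles$pca,
    cs_pca = profiles$cs_pca,
    gs_group = profiles$gs_group
  )
  attr(out, "model") <- spec
  out
}
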