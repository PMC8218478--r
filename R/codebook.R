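#' Variable codebook for the biopsychosocial reoffending design
#'
#' The codebook fixes, for every variable in a case record, its role in the
#' model (concomitant covariate, within-class predictor, or outcome), its
#' type, its category levels and the reference level used for dummy coding.
#' The nine psychosocial/background constructs act as covariates and expand
#' to 17 design columns; the eight continuous neurobiological measures act
#' as predictors; the outcome is the 3-category reoffending status at
#' 12 months (no, non-violent, violent).
#'
#' Reference levels are `ses = low`, `ethnicity = Dutch`,
#' `criminal_friends = no`, `substance_use = non-user`.  Any fixed choice is
#' statistically equivalent, but it must be fixed and recorded for
#' reproducibility, so it lives here.
#'
#' @return An object of class `lcra_codebook`: a list with one entry per
#'   variable (`role`, `type`, `levels`, `reference`) plus the canonical
#'   variable ordering.
#' @export
default_codebook <- function() {
  cat_var <- function(role, levels) {
    list(role = role, type = "categorical", levels = levels,
         reference = levels[[1L]])
  }
  num_var <- function(role) {
    list(role = role, type = "continuous", levels = NULL, reference = NULL)
  }
  vars <- list(
    age                  = num_var("covariate"),
    ses                  = cat_var("covariate", c("low", "middle", "high")),
    ethnicity            = cat_var("covariate", c("Dutch", "Western", "non-Western")),
    ypi_interpersonal    = num_var("covariate"),
    ypi_affective        = num_var("covariate"),
    ypi_behavioral       = num_var("covariate"),
    bpm_internalizing    = num_var("covariate"),
    bpm_externalizing    = num_var("covariate"),
    bpm_attention        = num_var("covariate"),
    criminal_friends     = cat_var("covariate", c("no", "yes")),
    substance_use        = cat_var("covariate",
                                   c("non-user", "recreational",
                                     "multiple-one", "multiple-multi")),
    treatment_motivation = num_var("covariate"),
    trauma               = num_var("covariate"),
    hr_rest              = num_var("predictor"),
    pep_rest             = num_var("predictor"),
    rsa_rest             = num_var("predictor"),
    hr_react             = num_var("predictor"),
    pep_react            = num_var("predictor"),
    rsa_react            = num_var("predictor"),
    cortisol             = num_var("predictor"),
    testosterone         = num_var("predictor"),
    outcome              = cat_var("outcome", c("no", "non-violent", "violent"))
  )
  # outcome "reference" above is the modelling reference category ("no")
  cb <- list(variables = vars,
             covariate_fields = names(vars)[vapply(vars, function(v)
               v$role == "covariate", logical(1))],
             predictor_fields = names(vars)[vapply(vars, function(v)
               v$role == "predictor", logical(1))],
             outcome_levels = vars$outcome$levels)
  class(cb) <- "lcra_codebook"
  cb
}

#' Names of the dummy-coded covariate design columns
#' @param codebook An `lcra_codebook`.
#' @return Character vector of length 17 (for the default codebook).
#' @export
covariate_column_names <- function(codebook = default_codebook()) {
  unlist(lapply(codebook$covariate_fields, function(f) {
    v <- codebook$variables[[f]]
    if (v$type == "continuous") return(f)
    paste(f, setdiff(v$levels, v$reference), sep = "_")
  }), use.names = FALSE)
}

#' Names of the predictor design columns
#' @inheritParams covariate_column_names
#' @export
predictor_column_names <- function(codebook = default_codebook()) {
  codebook$predictor_fields
}

#' Serialize / read a codebook as JSON
#'
#' @param codebook An `lcra_codebook`.
#' @param path File path.
#' @return `read_codebook` returns an `lcra_codebook`.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "lcra_codebook"))
  jsonlite::write_json(unclass(codebook), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$variables <- lapply(raw$variables, function(v) {
    list(role = v$role, type = v$type,
         levels = if (is.null(v$levels)) NULL else as.character(v$levels),
         reference = if (is.null(v$reference)) NULL else v$reference)
  })
  class(raw) <- "lcra_codebook"
  raw
}

#' Recode per-drug frequency ratings into the 4-category substance-use scale
#'
#' Each drug is rated on an 11-point frequency scale where 1 means never
#' used, 2 means used 1--10 times in a year, and 3 or above means used more
#' than 10 times in a year.  The categories are ordered
#' non-user < recreational < multiple-one < multiple-multi:
#' \itemize{
#'   \item all drugs rated 1: `non-user`;
#'   \item at least one drug rated 2 but none rated 3+: `recreational`
#'     (one to 10 times in a year);
#'   \item exactly one drug rated 3+ (with or without other recreational
#'     use): `multiple-one`;
#'   \item two or more drugs rated 3+: `multiple-multi`.
#' }
#' The scale does not distinguish past-month from lifetime administration;
#' ratings are interpreted as past-year frequency, which is the window the
#' category definitions refer to.
#'
#' @param ratings Numeric vector of per-drug ratings in 1..11, optionally
#'   named by drug.
#' @return One of `"non-user"`, `"recreational"`, `"multiple-one"`,
#'   `"multiple-multi"`.
#' @export
recode_substance_use <- function(ratings) {
  if (length(ratings) == 0L) stop("at least one drug rating is required")
  drugs <- names(ratings)
  if (is.null(drugs)) drugs <- paste0("drug", seq_along(ratings))
  bad <- which(!is.finite(ratings) | ratings < 1 | ratings > 11 |
                 ratings != round(ratings))
  if (length(bad) > 0L) {
    stop(sprintf("invalid substance-use rating for %s: %s (must be an integer in 1..11)",
                 drugs[bad[1L]], format(ratings[bad[1L]])))
  }
  heavy <- sum(ratings >= 3)
  if (heavy >= 2) return("multiple-multi")
  if (heavy == 1) return("multiple-one")
  if (any(ratings == 2)) return("recreational")
  "non-user"
}
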