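#' Validate a set of case records against a codebook
#'
#' Checks column presence, category levels and finiteness of continuous
#' fields, and coerces categorical columns to factors with the codebook's
#' level ordering.  The outcome column may be absent (prediction-only mode).
#'
#' @param cases A data.frame with one row per case; columns named exactly as
#'   the codebook fields, plus an `id` column.
#' @param codebook An `lcra_codebook`.
#' @param require_outcome Error if the outcome column is absent or has
#'   missing values.
#' @return The validated data.frame (categoricals as factors).
#' @export
validate_cases <- function(cases, codebook = default_codebook(),
                           require_outcome = FALSE) {
  stopifnot(is.data.frame(cases))
  if (!"id" %in% names(cases)) {
    cases$id <- if (nrow(cases)) paste0("case", seq_len(nrow(cases))) else character(0)
  }
  cases$id <- as.character(cases$id)
  fields <- c(codebook$covariate_fields, codebook$predictor_fields)
  missing_cols <- setdiff(fields, names(cases))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  for (f in fields) {
    v <- codebook$variables[[f]]
    if (v$type == "continuous") {
      cases[[f]] <- as.numeric(cases[[f]])
      bad <- !is.na(cases[[f]]) & !is.finite(cases[[f]])
      if (any(bad)) {
        stop(sprintf("non-finite value in column '%s' for case(s): %s",
                     f, paste(cases$id[bad], collapse = ", ")))
      }
    } else {
      val <- as.character(cases[[f]])
      unknown <- !is.na(val) & !(val %in% v$levels)
      if (any(unknown)) {
        stop(sprintf("unknown level '%s' in column '%s' (case %s)",
                     val[unknown][1L], f, cases$id[unknown][1L]))
      }
      cases[[f]] <- factor(val, levels = v$levels)
    }
  }
  if ("outcome" %in% names(cases)) {
    val <- as.character(cases$outcome)
    unknown <- !is.na(val) & !(val %in% codebook$outcome_levels)
    if (any(unknown)) {
      stop(sprintf("unknown outcome label '%s' (case %s)",
                   val[unknown][1L], cases$id[unknown][1L]))
    }
    cases$outcome <- factor(val, levels = codebook$outcome_levels)
  } else {
    cases$outcome <- factor(rep(NA_character_, nrow(cases)),
                            levels = codebook$outcome_levels)
  }
  if (require_outcome && anyNA(cases$outcome)) {
    stop("outcome missing for case(s): ",
         paste(cases$id[is.na(cases$outcome)], collapse = ", "))
  }
  # plausibility only: RSA at rest is expected on the log scale already
  rsa <- cases$rsa_rest
  if (any(!is.na(rsa) & (rsa < 0 | rsa > 5))) {
    warning("rsa_rest outside the plausible log-scale range [0, 5]; ",
            "this column is expected to be log-transformed")
  }
  cases
}

#' Read case records from CSV
#'
#' One row per case, UTF-8, "." decimal separator, header named exactly as
#' the codebook fields.  The outcome column is optional.
#'
#' @param path CSV file path.
#' @param codebook An `lcra_codebook`.
#' @return Validated data.frame of case records.
#' @export
read_cases <- function(path, codebook = default_codebook()) {
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    warning = function(w) stop("malformed CSV '", path, "': ", conditionMessage(w)),
    error = function(e) stop("cannot read '", path, "': ", conditionMessage(e))
  )
  n_field <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(n_field)) > 1L) {
    bad_line <- which(n_field != n_field[1L])[1L]
    stop(sprintf("malformed row at line %d of '%s' (%d fields, expected %d)",
                 bad_line, path, n_field[bad_line], n_field[1L]))
  }
  validate_cases(raw, codebook)
}

#' Write case records to CSV
#'
#' Numeric columns are written with full precision so that a write/read
#' round trip reproduces the records exactly.
#'
#' @param cases Data.frame of case records.
#' @param path Output CSV path.
#' @export
write_cases <- function(cases, path) {
  out <- cases
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], function(x)
        if (is.na(x)) NA_character_ else sprintf("%.17g", x), character(1))
    }
    if (is.factor(out[[nm]])) out[[nm]] <- as.character(out[[nm]])
  }
  if ("outcome" %in% names(out) && all(is.na(out$outcome))) {
    out$outcome <- NULL
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Dummy-encode case records into model design matrices
#'
#' Produces the covariate design matrix (17 columns for the default
#' codebook: 1 age + 2 SES + 2 ethnicity + 3 YPI + 3 BPM + 1 criminal
#' friends + 3 substance use + 1 motivation + 1 trauma), the predictor
#' matrix (8 neurobiological columns) and the integer-coded outcome
#' (0 = no, 1 = non-violent, 2 = violent, NA when unknown).  Reference
#' levels produce all-zero dummy blocks.  Intercept columns are not
#' included; the model adds them.
#'
#' Cases with any missing covariate or predictor are rejected with an
#' id-level report (complete-case analysis; the model cannot handle
#' missing information).
#'
#' @param cases Data.frame of case records (see [validate_cases()]).
#' @param codebook An `lcra_codebook`.
#' @param standardize Standardize continuous columns to mean 0, SD 1.
#'   Defaults to off: raw scales are used, and the model's parameter
#'   accounting is invariant to it.
#' @return An object of class `lcra_design`.
#' @export
encode_cases <- function(cases, codebook = default_codebook(),
                         standardize = FALSE) {
  cases <- validate_cases(cases, codebook)
  fields <- c(codebook$covariate_fields, codebook$predictor_fields)
  n <- nrow(cases)
  if (n > 0L) {
    incomplete <- rowSums(is.na(cases[fields])) > 0L
    if (any(incomplete)) {
      stop("cases rejected for missing covariate/predictor values: ",
           paste(cases$id[incomplete], collapse = ", "))
    }
  }
  enc_field <- function(f) {
    v <- codebook$variables[[f]]
    if (v$type == "continuous") {
      m <- matrix(as.numeric(cases[[f]]), ncol = 1,
                  dimnames = list(NULL, f))
      return(m)
    }
    lev <- setdiff(v$levels, v$reference)
    m <- vapply(lev, function(l) as.numeric(cases[[f]] == l), numeric(n))
    m <- matrix(m, nrow = n, ncol = length(lev),
                dimnames = list(NULL, paste(f, lev, sep = "_")))
    m
  }
  bind_fields <- function(fs, expected_names) {
    if (n == 0L) {
      return(matrix(numeric(0), nrow = 0, ncol = length(expected_names),
                    dimnames = list(NULL, expected_names)))
    }
    do.call(cbind, lapply(fs, enc_field))
  }
  cov_names <- covariate_column_names(codebook)
  pred_names <- predictor_column_names(codebook)
  covariates <- bind_fields(codebook$covariate_fields, cov_names)
  predictors <- bind_fields(codebook$predictor_fields, pred_names)
  stopifnot(identical(colnames(covariates), cov_names),
            identical(colnames(predictors), pred_names))
  scaling <- NULL
  if (standardize && n > 1L) {
    std <- function(m) {
      ctr <- colMeans(m); scl <- apply(m, 2, stats::sd)
      scl[scl == 0 | is.na(scl)] <- 1
      list(m = sweep(sweep(m, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
    }
    is_dummy <- function(m) apply(m, 2, function(x) all(x %in% c(0, 1)))
    sc <- std(covariates[, !is_dummy(covariates), drop = FALSE])
    covariates[, colnames(sc$m)] <- sc$m
    sp <- std(predictors)
    predictors <- sp$m
    scaling <- list(covariates = sc[c("center", "scale")],
                    predictors = sp[c("center", "scale")])
  }
  outcome <- as.integer(cases$outcome) - 1L
  design <- list(
    covariates = covariates,
    predictors = predictors,
    outcome = outcome,
    ids = cases$id,
    covariate_names = cov_names,
    predictor_names = pred_names,
    outcome_levels = codebook$outcome_levels,
    reference_levels = {
      cat_f <- Filter(function(f) codebook$variables[[f]]$type == "categorical",
                      codebook$covariate_fields)
      stats::setNames(lapply(cat_f, function(f) codebook$variables[[f]]$reference),
                      cat_f)
    },
    scaling = scaling
  )
  class(design) <- "lcra_design"
  design
}

#' Remove the neurobiological predictor block from a design
#'
#' Used for the reduced ("psychosocial-only") model: within-class outcome
#' regressions become intercept-only, while the classes remain formed by
#' the covariates.
#'
#' @param design An `lcra_design`.
#' @return The design with a zero-column predictor matrix.
#' @export
drop_predictors <- function(design) {
  stopifnot(inherits(design, "lcra_design"))
  design$predictors <- matrix(numeric(0), nrow = nrow(design$covariates),
                              ncol = 0)
  design$predictor_names <- character(0)
  design
}

#' @export
print.lcra_design <- function(x, ...) {
  cat(sprintf("lcra_design: %d cases, %d covariate columns, %d predictor columns\n",
              nrow(x$covariates), ncol(x$covariates), ncol(x$predictors)))
  cat(sprintf("outcomes observed: %d of %d\n",
              sum(!is.na(x$outcome)), length(x$outcome)))
  invisible(x)
}
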