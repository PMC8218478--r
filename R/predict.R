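#' Predict class membership and reoffending risk for new cases
#'
#' The new-case tool: for a case with complete covariates and predictors
#' but unknown outcome, the class posterior is the concomitant prior
#' `pi(. | zc)` (covariates only — the outcome is unknown at prediction
#' time), and the outcome distribution is the mixture
#' `sum_k pi(k | zc) f(. | k, zp)`.  Modal assignments take the highest
#' probability; outcome ties break toward the less severe category
#' (no < non-violent < violent) and are flagged when the top two outcome
#' probabilities differ by less than `tie_tol`.
#'
#' An observed outcome column, if present, is ignored unless
#' `use_outcome = TRUE`, a post-hoc mode for internal validation in which
#' the class posterior conditions on the observed outcome.
#'
#' @param record A single case: one-row data.frame (or list) of case
#'   fields; missing covariates or predictors are a rejection, not an
#'   imputation.
#' @param params An `lcra_params`.
#' @param codebook An `lcra_codebook`.
#' @param tie_tol Tie-flag tolerance on the outcome distribution.
#' @return An object of class `lcra_prediction`: `id`, `class_posterior`,
#'   `modal_class`, `outcome_probs`, `modal_outcome`, `tie_flag`.
#' @export
predict_case <- function(record, params, codebook = default_codebook(),
                         tie_tol = 1e-6) {
  rec <- as.data.frame(record, stringsAsFactors = FALSE)
  stopifnot(nrow(rec) == 1L)
  res <- predict_batch(rec, params, codebook, tie_tol = tie_tol)
  pr <- res$predictions
  K <- params$K
  structure(list(
    id = pr$id,
    class_posterior = stats::setNames(as.numeric(pr[1, paste0("post_", params$class_labels)]),
                                      params$class_labels),
    modal_class = pr$modal_class,
    outcome_probs = stats::setNames(as.numeric(pr[1, c("p_no", "p_nonviolent", "p_violent")]),
                                    params$outcome_levels),
    modal_outcome = pr$modal_outcome,
    tie_flag = pr$tie_flag
  ), class = "lcra_prediction")
}

#' @export
print.lcra_prediction <- function(x, ...) {
  cat(sprintf("case %s: modal class %s, modal outcome %s%s\n", x$id,
              x$modal_class, x$modal_outcome,
              if (x$tie_flag) " (tie flagged)" else ""))
  cat("class posterior:", paste(sprintf("%s=%.3f", names(x$class_posterior),
                                        x$class_posterior), collapse = " "), "\n")
  cat("outcome probs:  ", paste(sprintf("%s=%.3f", names(x$outcome_probs),
                                        x$outcome_probs), collapse = " "), "\n")
  invisible(x)
}

#' Batch prediction
#'
#' Vectorised [predict_case()] over a set of cases, plus summary counts of
#' the modal predicted categories.  Predictions are deterministic and
#' invariant to case ordering and to the presence of an (ignored) outcome
#' column.
#'
#' @param cases Data.frame of case records (outcome optional and ignored
#'   unless `use_outcome = TRUE`).
#' @param params An `lcra_params`.
#' @param codebook An `lcra_codebook`.
#' @param tie_tol Tie-flag tolerance.
#' @param use_outcome Post-hoc mode: condition the class posterior on an
#'   observed outcome (internal validation only).
#' @return List with `predictions` (one row per case) and `summary`
#'   (named counts over the predicted outcome categories).
#' @export
predict_batch <- function(cases, params, codebook = default_codebook(),
                          tie_tol = 1e-6, use_outcome = FALSE) {
  design <- encode_cases(cases, codebook)
  lev <- params$outcome_levels
  if (nrow(design$covariates) == 0L) {
    empty <- data.frame(id = character(0), modal_class = character(0),
                        modal_outcome = character(0), tie_flag = logical(0))
    return(list(predictions = empty,
                summary = stats::setNames(rep(0L, 3), lev)))
  }
  if (ncol(design$predictors) != params$n_predictor_cols) {
    # reduced (psychosocial-only) parameter sets carry no predictor slopes
    if (params$n_predictor_cols == 0L) design <- drop_predictors(design)
    else stop("case predictors do not match the parameter set")
  }
  if (use_outcome) {
    W <- posterior_class_probs(design, params)
  } else {
    W <- membership_matrix(params, design$covariates)
  }
  colnames(W) <- params$class_labels
  Pmix <- mixture_outcome_probs(params, design$covariates, design$predictors)
  Pmix <- matrix(Pmix, ncol = 3, dimnames = list(NULL, lev))
  modal_class <- params$class_labels[max.col(W, ties.method = "first")]
  modal_idx <- max.col(Pmix, ties.method = "first")  # first = less severe
  modal_outcome <- lev[modal_idx]
  sorted_top2 <- t(apply(Pmix, 1, function(p) sort(p, decreasing = TRUE)[1:2]))
  tie_flag <- (sorted_top2[, 1] - sorted_top2[, 2]) < tie_tol
  pr <- data.frame(id = design$ids, stringsAsFactors = FALSE)
  for (k in seq_len(params$K)) pr[[paste0("post_", params$class_labels[k])]] <- W[, k]
  pr$modal_class <- modal_class
  pr$p_no <- Pmix[, 1]; pr$p_nonviolent <- Pmix[, 2]; pr$p_violent <- Pmix[, 3]
  pr$modal_outcome <- modal_outcome
  pr$tie_flag <- tie_flag
  counts <- stats::setNames(
    as.integer(table(factor(modal_outcome, levels = lev))), lev)
  list(predictions = pr, summary = counts)
}
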