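#' Build a 3x3 confusion table
#'
#' Rows are observed categories, columns predicted; cell (r, c) counts
#' cases observed `r` and predicted `c`.
#'
#' @param observed,predicted Equal-length vectors of outcome categories.
#' @param levels Category labels (order fixes the table layout).
#' @return An object of class `lcra_confusion`: the count matrix with
#'   orientation metadata.
#' @export
build_confusion <- function(observed, predicted,
                            levels = c("no", "non-violent", "violent")) {
  if (length(observed) != length(predicted)) {
    stop(sprintf("length mismatch: %d observed vs %d predicted",
                 length(observed), length(predicted)))
  }
  of <- factor(as.character(observed), levels = levels)
  pf <- factor(as.character(predicted), levels = levels)
  if (anyNA(of)) stop("unknown observed category: ",
                      as.character(observed)[is.na(of)][1L])
  if (anyNA(pf)) stop("unknown predicted category: ",
                      as.character(predicted)[is.na(pf)][1L])
  m <- unclass(table(observed = of, predicted = pf))
  structure(list(table = m, N = sum(m), levels = levels,
                 orientation = "rows = observed, columns = predicted"),
            class = "lcra_confusion")
}

#' Confusion table from a count matrix
#'
#' For tables given directly as counts (e.g. published validation
#' tables).
#'
#' @param m 3x3 matrix of non-negative integer counts, rows observed.
#' @param levels Category labels.
#' @return An `lcra_confusion`.
#' @export
as_confusion <- function(m, levels = c("no", "non-violent", "violent")) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == length(levels), ncol(m) == length(levels),
            all(m >= 0), all(m == round(m)))
  dimnames(m) <- list(observed = levels, predicted = levels)
  structure(list(table = m, N = sum(m), levels = levels,
                 orientation = "rows = observed, columns = predicted"),
            class = "lcra_confusion")
}

#' @export
print.lcra_confusion <- function(x, ...) {
  cat("confusion table (", x$orientation, "), N =", x$N, "\n")
  print(x$table)
  invisible(x)
}

#' Multi-class sensitivity, specificity, PPV and NPV
#'
#' Per-category diagnostic metrics in one-vs-rest form.  Under the
#' `standard` convention, for category `c`: sensitivity =
#' `cell(c,c) / observed_c`, specificity = (non-c cases predicted non-c)
#' / non-c cases, PPV = `cell(c,c) / predicted_c`, NPV analogous.  The
#' `as-published` convention applies the same four formulas with the
#' observed and predicted margins exchanged — equivalently, the standard
#' metrics of the transposed table.  Published applications of this model
#' report the latter; both are provided and tagged so either is
#' reproducible.  Overall accuracy (`trace / N`) is identical under both.
#'
#' Zero-denominator metrics are reported as 0 with a degenerate flag
#' (matching the convention of printing 0.00 when no case falls in a
#' category) rather than NaN.
#'
#' @param table An `lcra_confusion` (or plain 3x3 matrix, rows observed).
#' @param convention `"standard"` or `"as-published"`.
#' @return An object of class `lcra_metrics`: data.frame of per-category
#'   metrics with degeneracy flags, overall `accuracy`, and the
#'   convention tag.
#' @export
metric_report <- function(table, convention = c("standard", "as-published")) {
  convention <- match.arg(convention)
  if (inherits(table, "lcra_confusion")) {
    m <- table$table
    levels <- table$levels
  } else {
    m <- as.matrix(table)
    levels <- rownames(m)
    if (is.null(levels)) levels <- paste0("cat", seq_len(nrow(m)))
  }
  N <- sum(m)
  accuracy <- if (N > 0) sum(diag(m)) / N else 0
  w <- if (convention == "as-published") t(m) else m
  ncat <- nrow(w)
  safe_div <- function(num, den) {
    if (den == 0) list(v = 0, flag = TRUE) else list(v = num / den, flag = FALSE)
  }
  rows <- lapply(seq_len(ncat), function(cc) {
    tp <- w[cc, cc]
    sens <- safe_div(tp, sum(w[cc, ]))
    spec <- safe_div(sum(w[-cc, -cc]), sum(w[-cc, ]))
    ppv  <- safe_div(tp, sum(w[, cc]))
    npv  <- safe_div(sum(w[-cc, -cc]), sum(w[, -cc]))
    data.frame(category = levels[cc],
               sensitivity = sens$v, specificity = spec$v,
               ppv = ppv$v, npv = npv$v,
               degenerate = sens$flag | spec$flag | ppv$flag | npv$flag,
               stringsAsFactors = FALSE)
  })
  structure(list(metrics = do.call(rbind, rows), accuracy = accuracy,
                 N = N, convention = convention),
            class = "lcra_metrics")
}

# Display rounding: half-up to 2 decimals (raw values stay in the object).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.lcra_metrics <- function(x, ...) {
  cat(sprintf("metric report (%s convention), accuracy = %.3f (N = %d)\n",
              x$convention, x$accuracy, x$N))
  disp <- x$metrics
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    disp[[nm]] <- sprintf("%.2f", round_half_up(disp[[nm]]))
  }
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Compare predictions with and without the neurobiological block
#'
#' Evaluates a full model and a reduced model (within-class outcome
#' regressions on intercepts only, classes still covariate-formed) on the
#' same holdout cases, reporting paired metric reports and their
#' differences.  No direction is assumed: the delta is reported as
#' full minus reduced.
#'
#' @param fit_full,fit_reduced `lcra_fit` objects trained on the same
#'   cases, the reduced one on a design with the predictor block removed
#'   (see [drop_predictors()]).
#' @param holdout_cases Data.frame of holdout case records with observed
#'   outcomes.
#' @param codebook An `lcra_codebook`.
#' @param convention Metric convention for both reports.
#' @return List with `full`, `reduced` (both `lcra_metrics`),
#'   `confusion_full`, `confusion_reduced`, and `delta` (full - reduced
#'   accuracy and per-metric differences).
#' @export
compare_predictor_blocks <- function(fit_full, fit_reduced, holdout_cases,
                                     codebook = default_codebook(),
                                     convention = "standard") {
  holdout_cases <- validate_cases(holdout_cases, codebook,
                                  require_outcome = TRUE)
  obs <- as.character(holdout_cases$outcome)
  pf <- predict_batch(holdout_cases, fit_full$params, codebook)
  pr <- predict_batch(holdout_cases, fit_reduced$params, codebook)
  cf <- build_confusion(obs, pf$predictions$modal_outcome)
  cr <- build_confusion(obs, pr$predictions$modal_outcome)
  mf <- metric_report(cf, convention)
  mr <- metric_report(cr, convention)
  delta_metrics <- mf$metrics
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    delta_metrics[[nm]] <- mf$metrics[[nm]] - mr$metrics[[nm]]
  }
  delta_metrics$degenerate <- mf$metrics$degenerate | mr$metrics$degenerate
  list(full = mf, reduced = mr,
       confusion_full = cf, confusion_reduced = cr,
       delta = list(accuracy = mf$accuracy - mr$accuracy,
                    metrics = delta_metrics))
}
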