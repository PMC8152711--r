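#' Screening performance metrics against a reference standard
#'
#' Computes the full measure set from the headline counts: N (corpus
#' size), N_P (documents ever predicted eligible), N_WF (eligible
#' documents identified by the workflow), N_S (eligible documents under
#' the reference standard) and the number of documents the workflow
#' screened. Percentages:
#' precision `= 100 * N_WF / N_P`, sensitivity (recall)
#' `= 100 * N_WF / N_S`, F1 the harmonic mean of the two; specificity and
#' accuracy come from the standard confusion matrix over all N documents
#' with "predicted eligible" meaning ever-predicted (TP = predicted and
#' reference-eligible, and so on). Workload reduction is
#' `100 * (N - n_screened) / N` and person-hours saved
#' `2 * (N - n_screened) / 200` (two reviewers, 200 abstracts per
#' reviewer-hour). Raw values are retained alongside integer-rounded
#' report values. A historically used shortcut formula for specificity,
#' `100 * (N - N_WF) / (N - N_S)`, exceeds 100% whenever `N_WF < N_S`; it
#' is reported separately as `specificity_shortcut` for transparency and
#' plays no part in the headline numbers.
#'
#' @param N Total number of abstracts.
#' @param N_P Predicted-eligible count.
#' @param N_WF Workflow-confirmed eligible count.
#' @param N_S Reference-standard eligible count.
#' @param n_screened Number of documents the workflow screened.
#' @param N_TP True positives of the prediction (`predicted & eligible`);
#'   defaults to `N_WF`, appropriate when every workflow-confirmed
#'   eligible was predicted.
#' @return An `eval_report` object (list with `counts`, `raw`, `rounded`).
#' @export
screening_metrics <- function(N, N_P, N_WF, N_S, n_screened,
                              N_TP = N_WF) {
  stopifnot(N >= 0, N_P >= 0, N_WF >= 0, N_S >= 0,
            n_screened >= 0, n_screened <= N)
  precision <- if (N_P > 0) 100 * N_WF / N_P else NA_real_
  sensitivity <- if (N_S > 0) 100 * N_WF / N_S else NA_real_
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
            (precision + sensitivity) > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else NA_real_
  FP <- N_P - N_TP
  FN <- N_S - N_TP
  TN <- N - N_S - FP
  specificity <- if ((TN + FP) > 0) 100 * TN / (TN + FP) else NA_real_
  accuracy <- if (N > 0) 100 * (N_TP + TN) / N else NA_real_
  wl <- workload_and_hours(N, n_screened)
  raw <- c(precision = precision, sensitivity = sensitivity, f1 = f1,
           specificity = specificity, accuracy = accuracy,
           workload_reduction_pct = wl[["workload_reduction_pct"]],
           hours_saved = wl[["hours_saved"]],
           specificity_shortcut =
             if (N > N_S) 100 * (N - N_WF) / (N - N_S) else NA_real_)
  structure(list(
    counts = c(N = N, N_P = N_P, N_WF = N_WF, N_S = N_S,
               delta_N = N_S - N_WF, n_screened = n_screened),
    raw = raw,
    rounded = c(round(raw[c("precision", "sensitivity", "f1",
                            "specificity", "accuracy",
                            "workload_reduction_pct")]),
                hours_saved = round(raw[["hours_saved"]]))
  ), class = "eval_report")
}

#' Evaluate a workflow result against the reference standard
#'
#' @param result A `workflow_result` / `screen_result`.
#' @param reference Named 0/1 vector of reference labels (names = doc
#'   ids), or a labelled `screen_corpus`. Every corpus document needs a
#'   label.
#' @param N Corpus size; defaults to the result's corpus, else
#'   `length(reference)`.
#' @return An `eval_report`; see [screening_metrics()].
#' @export
compute_metrics <- function(result, reference, N = NULL) {
  stopifnot(inherits(result, "workflow_result"))
  if (inherits(reference, "screen_corpus")) {
    reference <- stats::setNames(reference$label, reference$id)
  }
  if (anyNA(reference)) stop("reference labels must cover every document")
  if (is.null(N)) N <- result$N %||% length(reference)
  eligible_ids <- names(reference)[reference == 1L]
  N_WF <- length(intersect(result$included, eligible_ids))
  N_TP <- length(intersect(result$predicted_ever, eligible_ids))
  screening_metrics(
    N = N,
    N_P = length(result$predicted_ever),
    N_WF = N_WF,
    N_S = length(eligible_ids),
    n_screened = length(result$screened),
    N_TP = N_TP
  )
}

#' Workload reduction and person-hours saved
#'
#' `reduction_pct = 100 * (N - n_screened) / N`;
#' `hours_saved = 2 * (N - n_screened) / 200` — every abstract is screened
#' by two reviewers and a reviewer screens about 200 abstracts per hour.
#'
#' @param N Total number of abstracts.
#' @param n_screened Number screened by the workflow (0 <= n_screened <= N).
#' @return Named numeric vector `workload_reduction_pct`, `hours_saved`.
#' @export
workload_and_hours <- function(N, n_screened) {
  stopifnot(n_screened >= 0, n_screened <= N)
  unsc <- N - n_screened
  c(workload_reduction_pct = if (N > 0) 100 * unsc / N else 0,
    hours_saved = 2 * unsc / 200)
}

#' @export
print.eval_report <- function(x, ...) {
  ct <- x$counts
  cat("Screening evaluation vs reference standard\n")
  cat(sprintf("  N = %d, N_P = %d, N_WF = %d, N_S = %d, dN = %d, screened = %d\n",
              ct[["N"]], ct[["N_P"]], ct[["N_WF"]], ct[["N_S"]],
              ct[["delta_N"]], ct[["n_screened"]]))
  r <- x$raw
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f", v))
  cat(sprintf("  precision %s%%  sensitivity %s%%  F1 %s%%\n",
              fmt(r[["precision"]]), fmt(r[["sensitivity"]]),
              fmt(r[["f1"]])))
  cat(sprintf("  specificity %s%%  accuracy %s%%\n",
              fmt(r[["specificity"]]), fmt(r[["accuracy"]])))
  cat(sprintf("  workload reduction %s%%  hours saved %.1f h\n",
              fmt(r[["workload_reduction_pct"]]), r[["hours_saved"]]))
  invisible(x)
}
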