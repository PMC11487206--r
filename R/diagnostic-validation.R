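#' Build a 2x2 diagnostic contingency table
#'
#' Cross-tabulates a binary screener call against the reference-standard
#' condition. Rows with a missing screener call or condition must be removed
#' upstream (participants without a screener statistic are dropped pairwise).
#'
#' @param screener_positive Logical vector of screener calls.
#' @param condition Logical vector of condition labels, same length.
#' @return A one-row tibble of class `fs_contingency` with integer counts
#'   `tp`, `fp`, `fn`, `tn`.
#' @examples
#' contingency(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
contingency <- function(screener_positive, condition) {
  if (length(screener_positive) != length(condition)) {
    abort_input("screener and condition vectors must have equal length")
  }
  if (length(condition) < 1) abort_input("need at least one participant")
  if (anyNA(screener_positive) || anyNA(condition)) {
    abort_input("missing screener calls or conditions must be excluded upstream")
  }
  out <- tibble(
    tp = sum(screener_positive & condition),
    fp = sum(screener_positive & !condition),
    fn = sum(!screener_positive & condition),
    tn = sum(!screener_positive & !condition)
  )
  class(out) <- c("fs_contingency", class(out))
  out
}

#' Diagnostic statistics from a 2x2 table
#'
#' Computes sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), the true and
#' false positive rates (tpr = sensitivity, fpr = 1 - specificity), positive
#' predictive value tp/(tp+fp) and negative predictive value tn/(tn+fn).
#' A statistic whose denominator is zero is reported as `NA` (explicitly
#' undefined), never coerced to 0 or 1.
#'
#' @param x A table from [contingency()], or any data frame / named list with
#'   numeric `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `tpr`, `fpr`, `ppv`, `npv`.
#' @examples
#' diagnostics(list(tp = 5, fn = 0, fp = 1, tn = 16))
#' @export
diagnostics <- function(x) {
  for (f in c("tp", "fp", "fn", "tn")) {
    if (is.null(x[[f]]) || length(x[[f]]) != 1 || is.na(x[[f]]) || x[[f]] < 0) {
      abort_input(sprintf("contingency table needs a nonnegative count '%s'", f))
    }
  }
  tp <- as.numeric(x$tp); fp <- as.numeric(x$fp)
  fn <- as.numeric(x$fn); tn <- as.numeric(x$tn)
  if (tp + fp + fn + tn < 1) abort_input("contingency table is empty")
  sens <- ratio_or_na(tp, tp + fn)
  spec <- ratio_or_na(tn, tn + fp)
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens,
    specificity = spec,
    tpr = sens,
    fpr = if (is.na(spec)) NA_real_ else 1 - spec,
    ppv = ratio_or_na(tp, tp + fp),
    npv = ratio_or_na(tn, tn + fn)
  )
}

#' ROC curve over all screener cutoffs
#'
#' Sweeps every distinct operating point of a numeric screener statistic
#' against a binary condition. Candidate cutoffs are the midpoints between
#' consecutive distinct scores plus -Inf/+Inf anchors, so strict/non-strict
#' boundary semantics never matter; the curve always contains the (0,0) and
#' (1,1) anchors. The Youden-optimal cutoff and the trapezoidal AUC are
#' attached.
#'
#' @param data A data frame holding the score and condition columns.
#' @param score Column name (string) of the numeric screener statistic.
#' @param condition Column name (string) of the logical condition.
#' @param direction `"higher_is_positive"` (default; e.g. the gait risk score,
#'   or the heart-rate screener delta where a less negative value means weaker
#'   recovery) or `"lower_is_positive"`.
#' @return An object of class `fs_roc`: a list with `points` (tibble of
#'   `cutoff`, `fpr`, `tpr` sorted along the curve), `auc`, `youden_j`,
#'   `optimal_cutoff`, `direction`, `n_pos`, `n_neg`.
#' @examples
#' d <- tibble::tibble(s = c(1, 2, 3, 4), y = c(FALSE, FALSE, TRUE, TRUE))
#' r <- roc_curve(d, "s", "y")
#' r$auc
#' @export
roc_curve <- function(data, score, condition,
                      direction = c("higher_is_positive", "lower_is_positive")) {
  direction <- match.arg(direction)
  require_columns(data, c(score, condition), "screening data")
  s <- data[[score]]
  y <- data[[condition]]
  keep <- !is.na(s) & !is.na(y)
  s <- s[keep]; y <- as.logical(y[keep])
  if (any(!is.finite(s))) abort_input("screener scores must be finite")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    abort_validation(sprintf(
      "condition '%s' has a single class (%d positive / %d negative); ROC undefined",
      condition, n_pos, n_neg
    ))
  }

  u <- sort(unique(s))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  if (direction == "higher_is_positive") {
    cutoffs <- c(-Inf, mids, Inf)            # positive call: score >= cutoff
    calls <- lapply(cutoffs, function(k) s >= k)
  } else {
    cutoffs <- c(Inf, mids, -Inf)            # positive call: score <= cutoff
    calls <- lapply(cutoffs, function(k) s <= k)
  }
  tpr <- vapply(calls, function(p) sum(p & y) / n_pos, numeric(1))
  fpr <- vapply(calls, function(p) sum(p & !y) / n_neg, numeric(1))

  pts <- tibble(cutoff = cutoffs, fpr = fpr, tpr = tpr) |>
    distinct(.data$fpr, .data$tpr, .keep_all = TRUE) |>
    arrange(.data$fpr, .data$tpr)

  out <- structure(
    list(
      points = pts,
      auc = auc_trapezoid(pts),
      youden_j = NA_real_, optimal_cutoff = NA_real_,
      direction = direction, n_pos = n_pos, n_neg = n_neg
    ),
    class = "fs_roc"
  )
  opt <- youden_optimal(out)
  out$optimal_cutoff <- opt$cutoff
  out$youden_j <- opt$j
  out
}

#' Youden-optimal cutoff
#'
#' Finds the operating point maximizing the Youden index
#' J = sensitivity + specificity - 1 = tpr - fpr. Ties are broken toward the
#' point with higher specificity (lower fpr), then toward the lower cutoff,
#' so the choice is deterministic.
#'
#' @param roc An `fs_roc` object from [roc_curve()], or a data frame of
#'   `cutoff`, `fpr`, `tpr` points.
#' @return A one-row tibble with `cutoff` and `j`.
#' @export
youden_optimal <- function(roc) {
  pts <- if (inherits(roc, "fs_roc")) roc$points else as_tibble(roc)
  if (nrow(pts) == 0) abort_input("ROC has no operating points")
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[order(pts$fpr[best], pts$cutoff[best])][1]
  tibble(cutoff = pts$cutoff[best], j = j[best])
}

#' Trapezoidal area under the ROC curve
#'
#' Sums trapezoid areas between successive operating points sorted by false
#' positive rate: sum over adjacent pairs of (delta fpr) x (tpr1 + tpr2) / 2.
#' With a single interior operating point this reduces to
#' (sensitivity + specificity) / 2.
#'
#' @param roc An `fs_roc` object, or a data frame with `fpr` and `tpr`
#'   columns (the (0,0) and (1,1) anchors are added if absent).
#' @return The AUC as a single number in \[0, 1\].
#' @examples
#' auc_trapezoid(data.frame(fpr = 0.06, tpr = 1.00))  # 0.97
#' @export
auc_trapezoid <- function(roc) {
  pts <- if (inherits(roc, "fs_roc")) roc$points else as_tibble(roc)
  require_columns(pts, c("fpr", "tpr"), "ROC points")
  if (!any(pts$fpr == 0 & pts$tpr == 0)) {
    pts <- bind_rows(pts, tibble(fpr = 0, tpr = 0))
  }
  if (!any(pts$fpr == 1 & pts$tpr == 1)) {
    pts <- bind_rows(pts, tibble(fpr = 1, tpr = 1))
  }
  pts <- arrange(pts, .data$fpr, .data$tpr)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' @method tidy fs_roc
#' @export
tidy.fs_roc <- function(x, ...) x$points

#' @method glance fs_roc
#' @export
glance.fs_roc <- function(x, ...) {
  tibble(
    auc = x$auc, youden_j = x$youden_j, optimal_cutoff = x$optimal_cutoff,
    direction = x$direction, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @export
print.fs_roc <- function(x, ...) {
  cat(sprintf(
    "ROC (%s): %d points, %d pos / %d neg\n  AUC (trapezoid) = %.3f, Youden J = %.3f at cutoff %s\n",
    x$direction, nrow(x$points), x$n_pos, x$n_neg,
    x$auc, x$youden_j, format(x$optimal_cutoff)
  ))
  invisible(x)
}

#' Screener-versus-reference validation report
#'
#' The statistical core of the screening study: for every screener x
#' reference-standard pair it sweeps cutoffs into an ROC, selects the
#' Youden-optimal cutoff, evaluates the 2x2 diagnostics at that cutoff and
#' reports the trapezoidal AUC — one row per pair, mirroring a summary table
#' of operating characteristics. Pairs excluded a priori (a screener that
#' cannot physically sense a standard's construct) are emitted as
#' not-applicable rows rather than dropped.
#'
#' @param screeners Long tibble with columns `id`, `screener`, `value`
#'   (numeric statistic; `NA` for participants whose recording could not be
#'   scored — they are dropped pairwise with a warning count).
#' @param references Long label tibble from [score_references()] with
#'   `id`, `standard`, `condition_positive`.
#' @param directions Named character vector mapping screener names to ROC
#'   directions; defaults to `"higher_is_positive"` for unnamed screeners
#'   (both the gait risk score and the heart-rate screener delta are
#'   higher-is-positive by convention).
#' @param not_applicable Two-column data frame (`screener`, `standard`) of
#'   pairs to report as N/A. Default: the gait analyzer against the
#'   nonfunctional FRAIL items and the heart-rate analyzer against the
#'   functional FRAIL items.
#' @return A tibble of class `fs_validation`: one row per pair with `n`,
#'   `optimal_cutoff`, `sensitivity`, `specificity`, `tpr`, `fpr`, `ppv`,
#'   `npv`, `auc`, `youden_j`, `note`.
#' @export
validation_report <- function(screeners, references,
                              directions = NULL,
                              not_applicable = default_na_pairs()) {
  require_columns(screeners, c("id", "screener", "value"), "screener table")
  require_columns(references, c("id", "standard", "condition_positive"), "label table")
  screeners <- as_tibble(screeners)
  references <- as_tibble(references)

  scr_names <- unique(screeners$screener)
  std_names <- unique(references$standard)
  pairs <- tidyr::expand_grid(screener = scr_names, standard = std_names)

  n_total <- length(unique(screeners$id))
  rows <- purrr::pmap_dfr(pairs, function(screener, standard) {
    na_row <- tibble(
      screener = screener, standard = standard, n = NA_integer_,
      optimal_cutoff = NA_real_, sensitivity = NA_real_, specificity = NA_real_,
      tpr = NA_real_, fpr = NA_real_, ppv = NA_real_, npv = NA_real_,
      auc = NA_real_, youden_j = NA_real_, note = "not applicable"
    )
    if (nrow(not_applicable) > 0 &&
        any(not_applicable$screener == screener &
            not_applicable$standard == standard)) {
      return(na_row)
    }
    d <- screeners |>
      filter(.data$screener == !!screener) |>
      inner_join(
        filter(references, .data$standard == !!standard),
        by = "id"
      ) |>
      filter(!is.na(.data$value))
    n_scr <- sum(!is.na(screeners$value[screeners$screener == screener]))
    if (n_scr < n_total / 2) {
      abort_validation(sprintf(
        "screener '%s' is missing for more than half the cohort (%d of %d scored)",
        screener, n_scr, n_total
      ))
    }
    dir <- (directions %||% character(0))[screener]
    if (is.na(dir) || is.null(dir)) dir <- "higher_is_positive"
    roc <- tryCatch(
      roc_curve(d, "value", "condition_positive", direction = dir),
      fs_validation_error = function(e) NULL
    )
    if (is.null(roc)) {
      na_row$note <- "single-class condition"
      na_row$n <- nrow(d)
      return(na_row)
    }
    call <- if (dir == "higher_is_positive") {
      d$value >= roc$optimal_cutoff
    } else {
      d$value <= roc$optimal_cutoff
    }
    dg <- diagnostics(contingency(call, d$condition_positive))
    tibble(
      screener = screener, standard = standard, n = nrow(d),
      optimal_cutoff = roc$optimal_cutoff,
      sensitivity = dg$sensitivity, specificity = dg$specificity,
      tpr = dg$tpr, fpr = dg$fpr, ppv = dg$ppv, npv = dg$npv,
      auc = roc$auc, youden_j = roc$youden_j, note = ""
    )
  })
  class(rows) <- c("fs_validation", class(rows))
  rows
}

default_na_pairs <- function() {
  tibble(
    screener = c("gait_risk_score", "hrr_screener_delta"),
    standard = c("frail_nonfunctional", "frail_functional")
  )
}

#' Round a validation report for display
#'
#' Presentation helper: rounds all rate columns to 2 decimals, half-up
#' (internal values stay full precision in the unrounded report).
#'
#' @param report An `fs_validation` tibble.
#' @return The report with rounded rate and AUC columns.
#' @export
format_report <- function(report) {
  cols <- c("sensitivity", "specificity", "tpr", "fpr", "ppv", "npv",
            "auc", "youden_j")
  mutate(report, across(all_of(cols), ~ round_half_up(.x, 2)))
}
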