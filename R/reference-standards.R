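#' Score the FRAIL scale
#'
#' Counts positive items on the five-item FRAIL screen (Fatigue, Resistance =
#' difficulty climbing a flight of stairs, Aerobic = difficulty walking 50 m,
#' Illnesses >= 5, Loss of weight) and assigns the standard frailty bands:
#' a score of 0 is robust, 1-2 prefrail, 3-5 frail.
#'
#' @param data A data frame with one row per participant and logical columns
#'   `frail_fatigue`, `frail_resistance`, `frail_aerobic`, `frail_illnesses`,
#'   `frail_weight_loss`.
#' @return The input as a tibble with `frail_score` (integer 0-5) and
#'   `frail_category` (factor robust/prefrail/frail) appended.
#' @examples
#' frail_classify(tibble::tibble(
#'   frail_fatigue = c(FALSE, TRUE, TRUE),
#'   frail_resistance = c(FALSE, TRUE, TRUE),
#'   frail_aerobic = c(FALSE, FALSE, TRUE),
#'   frail_illnesses = FALSE, frail_weight_loss = FALSE
#' ))
#' @export
frail_classify <- function(data) {
  require_columns(data, frail_item_columns(), "FRAIL assessment")
  for (col in frail_item_columns()) {
    if (anyNA(data[[col]])) {
      abort_scoring(sprintf("FRAIL item '%s' has missing values", col))
    }
  }
  items <- as.matrix(as.data.frame(data)[, frail_item_columns()])
  storage.mode(items) <- "integer"
  score <- as.integer(rowSums(items))
  data |>
    as_tibble() |>
    mutate(
      frail_score = score,
      frail_category = frailty_band(score)
    )
}

frail_item_columns <- function() {
  c("frail_fatigue", "frail_resistance", "frail_aerobic",
    "frail_illnesses", "frail_weight_loss")
}

frailty_band <- function(score) {
  factor(
    ifelse(score == 0, "robust", ifelse(score <= 2, "prefrail", "frail")),
    levels = c("robust", "prefrail", "frail")
  )
}

#' Split FRAIL into functional and nonfunctional subscores
#'
#' The movement-related items (fatigue, resistance = climbing stairs,
#' aerobic = walking 50 m) form the functional subscore (0-3); weight loss
#' and chronic illnesses form the nonfunctional subscore (0-2). The two always
#' sum to the total FRAIL score.
#'
#' @inheritParams frail_classify
#' @return The input as a tibble with integer `frail_functional` (0-3) and
#'   `frail_nonfunctional` (0-2) appended.
#' @export
frail_split <- function(data) {
  require_columns(data, frail_item_columns(), "FRAIL assessment")
  for (col in frail_item_columns()) {
    if (anyNA(data[[col]])) {
      abort_scoring(sprintf("FRAIL item '%s' has missing values", col))
    }
  }
  data |>
    as_tibble() |>
    mutate(
      frail_functional = as.integer(.data$frail_fatigue) +
        as.integer(.data$frail_resistance) + as.integer(.data$frail_aerobic),
      frail_nonfunctional = as.integer(.data$frail_weight_loss) +
        as.integer(.data$frail_illnesses)
    )
}

#' Score the Short Physical Performance Battery
#'
#' Sums the three SPPB components (balance, gait speed, chair stand; each
#' scored 0-4) into the 0-12 total, and also the gait-plus-balance subset
#' (0-8) used when the chair-stand component is set aside as a screener
#' comparator.
#'
#' @param data A data frame with integer columns `sppb_gait`, `sppb_balance`,
#'   `sppb_chair`, each in 0-4.
#' @return The input as a tibble with `sppb_total` (0-12) and
#'   `sppb_gait_balance` (0-8) appended.
#' @export
sppb_score <- function(data) {
  comps <- c("sppb_gait", "sppb_balance", "sppb_chair")
  require_columns(data, comps, "SPPB assessment")
  for (col in comps) {
    v <- data[[col]]
    if (anyNA(v) || any(v < 0 | v > 4)) {
      abort_scoring(sprintf("SPPB component '%s' must be in 0..4", col))
    }
  }
  data |>
    as_tibble() |>
    mutate(
      sppb_total = .data$sppb_gait + .data$sppb_balance + .data$sppb_chair,
      sppb_gait_balance = .data$sppb_gait + .data$sppb_balance
    )
}

#' Classify FROP-Com falls-risk scores
#'
#' FROP-Com (Falls Risk for Older People in the Community) totals 13 risk
#' factors into a 0-60 score: <= 11 low risk, 12-18 moderate, >= 19 high.
#'
#' @param data A data frame with an integer column `frop_com` in 0-60.
#' @return The input as a tibble with `frop_com_category`
#'   (factor low/moderate/high) appended.
#' @export
frop_com_class <- function(data) {
  require_columns(data, "frop_com", "FROP-Com assessment")
  score <- data$frop_com
  if (anyNA(score) || any(score < 0 | score > 60)) {
    abort_scoring("frop_com scores must be in 0..60")
  }
  data |>
    as_tibble() |>
    mutate(frop_com_category = factor(
      ifelse(score <= 11, "low", ifelse(score <= 18, "moderate", "high")),
      levels = c("low", "moderate", "high")
    ))
}

#' Default dichotomization rules for the reference standards
#'
#' The 2x2 diagnostic framework needs each clinical standard collapsed to a
#' binary condition. Standard geriatric cutpoints are used by default; every
#' threshold is overridable and the rule applied is recorded verbatim in the
#' label table for auditability.
#'
#' @param ... Named overrides, e.g. `sppb_total_max = 8`.
#' @return A named list of thresholds: `sppb_total_max` (impaired when total
#'   <= value, default 9), `sppb_gait_balance_max` (default 6), `gait_speed_min`
#'   (slow when speed < value m/s, default 0.8), `tug_max_s` (at risk when
#'   TUG >= value, default 13.5), `frail_total_min`, `frail_functional_min`,
#'   `frail_nonfunctional_min` (positive when subscore >= value, defaults 1),
#'   `frop_com_min` (positive when score >= value, default 12 =
#'   moderate-or-high risk), `falls_min` (faller when falls >= value, default 1).
#' @export
reference_thresholds <- function(...) {
  defaults <- list(
    sppb_total_max = 9,
    sppb_gait_balance_max = 6,
    gait_speed_min = 0.8,
    tug_max_s = 13.5,
    frail_total_min = 1,
    frail_functional_min = 1,
    frail_nonfunctional_min = 1,
    frop_com_min = 12,
    falls_min = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort_config(sprintf("unknown threshold(s): %s", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, overrides)
}

reference_standard_names <- function() {
  c("sppb_total", "sppb_gait_balance", "frail_all", "frail_functional",
    "frail_nonfunctional", "frop_com", "gait_speed", "tug", "faller")
}

#' Dichotomize a reference standard into condition-positive/negative
#'
#' Applies the configured rule for one clinical standard to every participant
#' and returns an audited label table: the exact rule text travels with each
#' label so reruns are verifiably identical.
#'
#' @param data A participant assessment data frame (see [generate_cohort()]
#'   for the column convention) with an `id` column.
#' @param standard One of `"sppb_total"`, `"sppb_gait_balance"`, `"frail_all"`,
#'   `"frail_functional"`, `"frail_nonfunctional"`, `"frop_com"`,
#'   `"gait_speed"`, `"tug"`, `"faller"`.
#' @param thresholds A list from [reference_thresholds()].
#' @return A tibble with columns `id`, `standard`, `condition_positive`
#'   (logical), `detail` (the underlying category or value) and `rule`
#'   (the rule text applied).
#' @examples
#' cohort <- tibble::tibble(id = c("a", "b"), gait_speed_mps = c(0.79, 0.80))
#' dichotomize(cohort, "gait_speed")
#' @export
dichotomize <- function(data, standard, thresholds = reference_thresholds()) {
  if (length(standard) != 1 || !standard %in% reference_standard_names()) {
    abort_config(sprintf(
      "unknown reference standard '%s'; expected one of: %s",
      paste(standard, collapse = ","),
      paste(reference_standard_names(), collapse = ", ")
    ))
  }
  require_columns(data, "id", "cohort table")
  data <- as_tibble(data)

  res <- switch(standard,
    sppb_total = {
      scored <- sppb_score(data)
      list(
        positive = scored$sppb_total <= thresholds$sppb_total_max,
        detail = sprintf("total=%d", scored$sppb_total),
        rule = sprintf("sppb_total <= %g", thresholds$sppb_total_max)
      )
    },
    sppb_gait_balance = {
      scored <- sppb_score(data)
      list(
        positive = scored$sppb_gait_balance <= thresholds$sppb_gait_balance_max,
        detail = sprintf("gait_balance=%d", scored$sppb_gait_balance),
        rule = sprintf("sppb_gait_balance <= %g", thresholds$sppb_gait_balance_max)
      )
    },
    frail_all = {
      scored <- frail_classify(data)
      list(
        positive = scored$frail_score >= thresholds$frail_total_min,
        detail = as.character(scored$frail_category),
        rule = sprintf("frail_score >= %g", thresholds$frail_total_min)
      )
    },
    frail_functional = {
      scored <- frail_split(data)
      list(
        positive = scored$frail_functional >= thresholds$frail_functional_min,
        detail = sprintf("functional=%d", scored$frail_functional),
        rule = sprintf("frail_functional >= %g", thresholds$frail_functional_min)
      )
    },
    frail_nonfunctional = {
      scored <- frail_split(data)
      list(
        positive = scored$frail_nonfunctional >= thresholds$frail_nonfunctional_min,
        detail = sprintf("nonfunctional=%d", scored$frail_nonfunctional),
        rule = sprintf("frail_nonfunctional >= %g", thresholds$frail_nonfunctional_min)
      )
    },
    frop_com = {
      scored <- frop_com_class(data)
      list(
        positive = scored$frop_com >= thresholds$frop_com_min,
        detail = as.character(scored$frop_com_category),
        rule = sprintf("frop_com >= %g", thresholds$frop_com_min)
      )
    },
    gait_speed = {
      require_columns(data, "gait_speed_mps", "cohort table")
      list(
        positive = data$gait_speed_mps < thresholds$gait_speed_min,
        detail = sprintf("speed=%.2f m/s", data$gait_speed_mps),
        rule = sprintf("gait_speed_mps < %g", thresholds$gait_speed_min)
      )
    },
    tug = {
      require_columns(data, "tug_s", "cohort table")
      if (any(data$tug_s <= 0)) abort_scoring("tug_s must be positive")
      list(
        positive = data$tug_s >= thresholds$tug_max_s,
        detail = sprintf("tug=%.1f s", data$tug_s),
        rule = sprintf("tug_s >= %g", thresholds$tug_max_s)
      )
    },
    faller = {
      require_columns(data, "falls_12mo", "cohort table")
      list(
        positive = data$falls_12mo >= thresholds$falls_min,
        detail = sprintf("falls=%d", data$falls_12mo),
        rule = sprintf("falls_12mo >= %g", thresholds$falls_min)
      )
    }
  )

  tibble(
    id = data$id,
    standard = standard,
    condition_positive = res$positive,
    detail = res$detail,
    rule = res$rule
  )
}

#' Score every reference standard for a cohort
#'
#' Convenience wrapper applying [dichotomize()] across a set of standards and
#' stacking the audited label tables.
#'
#' @inheritParams dichotomize
#' @param standards Character vector of standard names; defaults to the eight
#'   screener comparators (both SPPB forms, the three FRAIL forms, FROP-Com,
#'   gait speed, TUG).
#' @return A long tibble of labels, one row per participant x standard.
#' @export
score_references <- function(data,
                             standards = setdiff(reference_standard_names(), "faller"),
                             thresholds = reference_thresholds()) {
  purrr::map_dfr(standards, function(s) dichotomize(data, s, thresholds))
}
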