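test_that("contingency counts partition the cohort", {
  y <- c(rep(TRUE, 6), rep(FALSE, 4))
  c1 <- contingency(y, y)
  expect_equal(unlist(c1[, c("tp", "fp", "fn", "tn")]),
               c(tp = 6, fp = 0, fn = 0, tn = 4))
  c2 <- contingency(!y, y)
  expect_equal(c(c2$tp, c2$tn), c(0, 0))
  # 22 participants, 5 condition-positives all screened positive, 1 false positive
  cond <- c(rep(TRUE, 5), rep(FALSE, 17))
  call <- c(rep(TRUE, 5), TRUE, rep(FALSE, 16))
  c3 <- contingency(call, cond)
  expect_equal(unlist(c3[, c("tp", "fp", "fn", "tn")]),
               c(tp = 5, fp = 1, fn = 0, tn = 16))
  expect_error(contingency(c(TRUE, NA), c(TRUE, TRUE)), class = "fs_input_error")
})

test_that("diagnostics computes the six rates and leaves 0-denominator cells undefined", {
  d <- diagnostics(list(tp = 0, fn = 0, fp = 2, tn = 8))
  expect_true(is.na(d$sensitivity))
  expect_equal(d$specificity, 0.8)
  d2 <- diagnostics(list(tp = 3, fp = 1, fn = 2, tn = 4))
  expect_equal(d2$sensitivity, 3 / 5)
  expect_equal(d2$fpr, 1 - d2$specificity)
  expect_equal(d2$tpr, d2$sensitivity)
  expect_equal(d2$ppv, 3 / 4)
  expect_equal(d2$npv, 4 / 6)
  rates <- unlist(d2[, c("sensitivity", "specificity", "tpr", "fpr", "ppv", "npv")])
  expect_true(all(rates >= 0 & rates <= 1))
})

test_that("adding a correctly classified participant never lowers sensitivity or specificity", {
  set.seed(31)
  for (i in 1:20) {
    tab <- list(tp = sample(0:8, 1), fp = sample(0:8, 1),
                fn = sample(0:8, 1), tn = sample(1:8, 1))
    base <- diagnostics(tab)
    plus_tp <- diagnostics(utils::modifyList(tab, list(tp = tab$tp + 1)))
    plus_tn <- diagnostics(utils::modifyList(tab, list(tn = tab$tn + 1)))
    if (!is.na(base$sensitivity)) expect_gte(plus_tp$sensitivity, base$sensitivity)
    expect_gte(plus_tn$specificity, base$specificity)
  }
})

test_that("roc_curve anchors, point count, and perfect/anti-informative screeners", {
  d <- tibble::tibble(s = c(1, 2, 3, 10, 11, 12),
                      y = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  r <- roc_curve(d, "s", "y")
  expect_true(any(r$points$fpr == 0 & r$points$tpr == 0))
  expect_true(any(r$points$fpr == 1 & r$points$tpr == 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden_j, 1.0)

  # integer scores 0-5 give at most 7 operating points including anchors
  set.seed(5)
  d2 <- tibble::tibble(s = sample(0:5, 40, replace = TRUE),
                       y = sample(c(TRUE, FALSE), 40, replace = TRUE))
  r2 <- roc_curve(d2, "s", "y")
  expect_lte(nrow(r2$points), 7)

  # all negatives scored above positives: no useful cutoff, J = 0 at an anchor
  d3 <- tibble::tibble(s = c(1, 2, 9, 10), y = c(TRUE, TRUE, FALSE, FALSE))
  r3 <- roc_curve(d3, "s", "y", direction = "higher_is_positive")
  expect_equal(r3$youden_j, 0)

  expect_error(roc_curve(tibble::tibble(s = 1:3, y = TRUE), "s", "y"),
               class = "fs_validation_error")
})

test_that("lower_is_positive direction mirrors the curve", {
  d <- tibble::tibble(s = c(1, 2, 3, 10, 11, 12),
                      y = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  r <- roc_curve(d, "s", "y", direction = "lower_is_positive")
  expect_equal(r$auc, 1.0)
})

test_that("Youden search matches exhaustive enumeration on random instances", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    repeat {
      y <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (any(y) && any(!y)) break
    }
    s <- sample(0:10, n, replace = TRUE)
    r <- roc_curve(tibble::tibble(s = s, y = y), "s", "y")
    expect_equal(r$youden_j, youden_brute_force(s, y), tolerance = 1e-12)
  }
})

test_that("Youden tie-break prefers higher specificity then lower cutoff", {
  # two points with identical J = 0.5: (fpr 0, tpr .5) and (fpr .5, tpr 1)
  pts <- tibble::tibble(cutoff = c(-Inf, 2, 6, Inf),
                        fpr = c(1, 0.5, 0, 0), tpr = c(1, 1, 0.5, 0))
  opt <- youden_optimal(pts)
  expect_equal(opt$j, 0.5)
  expect_equal(opt$cutoff, 6)  # the lower-fpr (higher-specificity) point
})

test_that("trapezoid AUC matches hand-computed values and the chance line", {
  expect_equal(auc_trapezoid(data.frame(fpr = 0.06, tpr = 1.00)), 0.97)
  expect_equal(auc_trapezoid(data.frame(fpr = 0.00, tpr = 0.60)), 0.80)
  expect_equal(auc_trapezoid(data.frame(fpr = numeric(0), tpr = numeric(0))), 0.5)
  # single operating point: AUC = (sensitivity + specificity) / 2 exactly
  set.seed(3)
  for (i in 1:20) {
    se <- runif(1); sp <- runif(1)
    expect_equal(auc_trapezoid(data.frame(fpr = 1 - sp, tpr = se)),
                 (se + sp) / 2)
  }
})

test_that("ROC/AUC agree with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:5) {
    n <- 60
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(y) || !any(!y)) next
    s <- rnorm(n) + y * runif(1, 0, 2)
    ours <- roc_curve(tibble::tibble(s = s, y = y), "s", "y")
    ref <- pROC::roc(response = y, predictor = s, quiet = TRUE,
                     direction = "<")
    expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  }
})

test_that("permuted labels give chance-level AUC", {
  set.seed(23)
  s <- rnorm(2000)
  aucs <- replicate(60, {
    y <- sample(rep(c(TRUE, FALSE), each = 1000))
    roc_curve(tibble::tibble(s = s, y = y), "s", "y")$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("validation report covers every pair, honours N/A cells, and is reproducible", {
  set.seed(41)
  n <- 40
  ids <- sprintf("P%03d", 1:n)
  latent <- rnorm(n)
  screeners <- dplyr::bind_rows(
    tibble::tibble(id = ids, screener = "gait_risk_score",
                   value = round(pmin(5, pmax(0, latent * 1.2 + 2)))),
    tibble::tibble(id = ids, screener = "hrr_screener_delta",
                   value = -20 + 4 * latent + rnorm(n))
  )
  refs <- dplyr::bind_rows(lapply(
    c("frail_functional", "frail_nonfunctional", "gait_speed"),
    function(s) tibble::tibble(id = ids, standard = s,
                               condition_positive = latent + rnorm(n) > 0.3)
  ))
  rep1 <- validation_report(screeners, refs)
  expect_s3_class(rep1, "fs_validation")
  expect_equal(nrow(rep1), 6)  # 2 screeners x 3 standards
  expect_equal(rep1$note[rep1$screener == "gait_risk_score" &
                           rep1$standard == "frail_nonfunctional"],
               "not applicable")
  ok <- rep1$note == ""
  expect_true(all(rep1$auc[ok] >= 0 & rep1$auc[ok] <= 1))
  # the reported operating point reproduces its own Youden index
  expect_equal(rep1$tpr[ok] - rep1$fpr[ok], rep1$youden_j[ok])
  rep2 <- validation_report(screeners, refs)
  expect_identical(rep1, rep2)
})

test_that("a screener missing for more than half the cohort aborts the report", {
  ids <- sprintf("P%02d", 1:10)
  screeners <- tibble::tibble(id = ids, screener = "hrr_screener_delta",
                              value = c(rnorm(4), rep(NA, 6)))
  refs <- tibble::tibble(id = ids, standard = "gait_speed",
                         condition_positive = rep(c(TRUE, FALSE), 5))
  expect_error(validation_report(screeners, refs, not_applicable = data.frame()),
               class = "fs_validation_error")
})

test_that("report rounding is half-up at two decimals", {
  # 0.125 is exactly representable: half-up gives 0.13 where half-even gives 0.12
  expect_equal(frailscreen:::round_half_up(0.125, 2), 0.13)
  expect_equal(frailscreen:::round_half_up(0.375, 2), 0.38)
})
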