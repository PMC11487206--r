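#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_abline
#'   geom_line geom_col facet_wrap labs theme_minimal coord_equal
NULL

#' Plot an ROC curve
#'
#' Step curve through the operating points with the chance diagonal and the
#' Youden-optimal point highlighted.
#'
#' @param object An `fs_roc` from [roc_curve()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fs_roc
#' @export
autoplot.fs_roc <- function(object, ...) {
  pts <- object$points
  opt <- pts[which.max(pts$tpr - pts$fpr), ]
  ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_step(direction = "hv", colour = "#2c7fb8") +
    geom_point(colour = "#2c7fb8") +
    geom_point(data = opt, colour = "#d95f02", size = 3) +
    coord_equal() +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC: AUC = %.2f, Youden J = %.2f at cutoff %s",
                      object$auc, object$youden_j, format(object$optimal_cutoff))
    ) +
    theme_minimal()
}

#' Plot a validation report
#'
#' Bar chart of trapezoidal AUC per reference standard, faceted by screener;
#' not-applicable pairs are omitted.
#'
#' @param object An `fs_validation` tibble from [validation_report()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fs_validation
#' @export
autoplot.fs_validation <- function(object, ...) {
  d <- object[!is.na(object$auc), ]
  ggplot(d, aes(x = .data$standard, y = .data$auc)) +
    geom_col(fill = "#2c7fb8") +
    geom_abline(slope = 0, intercept = 0.5, linetype = "dashed",
                colour = "grey50") +
    facet_wrap(~screener) +
    labs(x = NULL, y = "AUC (trapezoid)",
         title = "Screener validity against each reference standard") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an accelerometer stream's magnitude trace
#'
#' Vector-magnitude trace, decimated for long recordings so the plot stays
#' light.
#'
#' @param object An accelerometer tibble.
#' @param max_points Decimation budget; default 20000 points.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot fs_accel
#' @export
autoplot.fs_accel <- function(object, max_points = 20000, ...) {
  mag <- sqrt(object$ax_g^2 + object$ay_g^2 + object$az_g^2)
  d <- tibble(t_s = object$t_s, mag_g = mag)
  if (nrow(d) > max_points) {
    d <- d[seq(1, nrow(d), length.out = max_points), ]
  }
  ggplot(d, aes(x = .data$t_s / 3600, y = .data$mag_g)) +
    geom_line(linewidth = 0.2, colour = "#2c7fb8") +
    labs(x = "Time (h)", y = "Vector magnitude (g)") +
    theme_minimal()
}

#' @method glance fs_validation
#' @export
glance.fs_validation <- function(x, ...) {
  ok <- !is.na(x$auc)
  tibble(
    n_pairs = nrow(x),
    n_evaluated = sum(ok),
    mean_auc = mean(x$auc[ok]),
    min_auc = min(x$auc[ok]),
    max_auc = max(x$auc[ok])
  )
}
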