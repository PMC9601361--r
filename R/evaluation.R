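#' ROC AUC with DeLong confidence interval
#'
#' AUC by trapezoidal integration of the empirical ROC curve (equivalently
#' the tie-corrected Mann-Whitney statistic), with a 95% DeLong confidence
#' interval; both via pROC. For degenerate cases where the DeLong variance
#' collapses, a seeded bootstrap CI is used instead.
#'
#' @param scores numeric vector.
#' @param labels binary vector (both classes present).
#' @param conf_level confidence level (default 0.95).
#' @param boot_fallback use a 2000-rep seeded bootstrap CI if the DeLong CI
#'   is degenerate at an interior AUC.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95, boot_fallback = TRUE) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                                 method = "delong")))
  if (boot_fallback && (!all(is.finite(ci)) ||
                        (ci[1] == ci[3] && auc > 0 && auc < 1))) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(20L)
    ci <- as.numeric(suppressWarnings(
      pROC::ci.auc(r, conf.level = conf_level,
                   method = "bootstrap", boot.n = 2000)))
  }
  list(auc = auc, ci_low = ci[1], ci_high = ci[3],
       n_pos = sum(labels == 1), n_neg = sum(labels == 0))
}

#' Youden operating point
#'
#' Scans all candidate thresholds (midpoints between consecutive distinct
#' scores, plus outer sentinels) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1; ties are broken toward the lowest
#' threshold. Classification rule: positive if score > threshold.
#'
#' @param scores numeric vector.
#' @param labels binary vector.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
operating_point <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  s <- sort(unique(scores))
  cuts <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else NULL)
  best <- NULL
  for (th in cuts) {
    m <- confusion_at(scores, labels, th)
    j <- m$sensitivity + m$specificity - 1
    if (is.null(best) || j > best$youden_j + 1e-12) {
      best <- c(list(threshold = th, youden_j = j), m)
    }
  }
  best[c("threshold", "sensitivity", "specificity", "youden_j")]
}

#' Sensitivity/specificity at a fixed threshold
#' @param scores numeric vector.
#' @param labels binary vector.
#' @param threshold classification cut (positive if score > threshold).
#' @return list with `sensitivity`, `specificity`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- scores > threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  tn <- sum(!pred & labels == 0); fp <- sum(pred & labels == 0)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Evaluate one endpoint's three signatures on both cohorts
#'
#' For each scope (intra, peri, multi) and cohort (training, validation):
#' AUC with DeLong CI, plus sensitivity/specificity. The operating
#' threshold is Youden-optimal on the training cohort and, by default, that
#' fixed threshold is applied to the validation cohort
#' (`per_cohort_youden = TRUE` re-optimizes per cohort).
#'
#' @param result a [run_endpoint()] result.
#' @param labels binary labels for all rows (same order as the feature
#'   table).
#' @param per_cohort_youden re-optimize the threshold on each cohort.
#' @return data frame with one row per (scope, cohort).
#' @export
evaluate_endpoint <- function(result, labels, per_cohort_youden = FALSE) {
  labels <- as.integer(labels)
  rows <- list()
  for (scope in c("intra", "peri", "multi")) {
    sc <- result$scores[[scope]]
    op_train <- operating_point(sc[result$split$train], labels[result$split$train])
    for (cohort in c("training", "validation")) {
      idx <- if (cohort == "training") result$split$train else result$split$validation
      ra <- roc_auc(sc[idx], labels[idx])
      op <- if (cohort == "training" || !per_cohort_youden) op_train
            else operating_point(sc[idx], labels[idx])
      cm <- confusion_at(sc[idx], labels[idx], op$threshold)
      rows[[length(rows) + 1]] <- data.frame(
        endpoint = result$endpoint, scope = scope, cohort = cohort,
        auc = ra$auc, ci_low = ra$ci_low, ci_high = ra$ci_high,
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        threshold = op$threshold, n_pos = ra$n_pos, n_neg = ra$n_neg)
    }
  }
  do.call(rbind, rows)
}

#' Render the full evaluation report
#'
#' Combines per-endpoint evaluations into the 2 endpoints x 3 scopes x 2
#' cohorts grid, optionally writing machine-readable JSON and, when ggplot2
#' is available, ROC-overlay and rad-score distribution figures.
#'
#' @param results named list of [run_endpoint()] results (e.g.
#'   `list(ER = ..., PR = ...)`).
#' @param labels_list named list of label vectors matching `results`.
#' @param json_path optional path for the JSON report.
#' @param figure_dir optional directory for SVG figures.
#' @param per_cohort_youden see [evaluate_endpoint()].
#' @return data frame (the report grid), invisibly carrying attribute
#'   `figures` with any figure paths.
#' @export
render_report <- function(results, labels_list, json_path = NULL,
                          figure_dir = NULL, per_cohort_youden = FALSE) {
  grid <- do.call(rbind, lapply(names(results), function(ep) {
    evaluate_endpoint(results[[ep]], labels_list[[ep]], per_cohort_youden)
  }))
  rownames(grid) <- NULL
  if (!is.null(json_path)) {
    jsonlite::write_json(grid, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  figs <- character(0)
  if (!is.null(figure_dir) && requireNamespace("ggplot2", quietly = TRUE)) {
    dir.create(figure_dir, showWarnings = FALSE, recursive = TRUE)
    for (ep in names(results)) {
      p <- plot_roc_curves(results[[ep]], labels_list[[ep]])
      f <- file.path(figure_dir, sprintf("roc_%s.svg", ep))
      ggplot2::ggsave(f, p, width = 8, height = 4)
      figs <- c(figs, f)
    }
  }
  attr(grid, "figures") <- figs
  invisible(grid)
}

#' ROC overlay figure for one endpoint
#'
#' One panel per cohort, overlaying the intratumoral, peritumoral and
#' multiregional signature ROC curves.
#'
#' @param result a [run_endpoint()] result.
#' @param labels binary labels for all rows.
#' @return a ggplot object.
#' @export
plot_roc_curves <- function(result, labels) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  labels <- as.integer(labels)
  dd <- list()
  for (scope in c("intra", "peri", "multi")) {
    for (cohort in c("training", "validation")) {
      idx <- if (cohort == "training") result$split$train else result$split$validation
      r <- pROC::roc(labels[idx], result$scores[[scope]][idx],
                     levels = c(0, 1), direction = "<", quiet = TRUE)
      dd[[length(dd) + 1]] <- data.frame(
        fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
        scope = scope, cohort = cohort)
    }
  }
  dd <- do.call(rbind, dd)
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$scope)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Signature",
                  title = sprintf("ROC curves, %s status", result$endpoint)) +
    ggplot2::theme_minimal()
}
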