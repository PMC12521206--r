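#' AUROC with a DeLong 95% confidence interval
#'
#' Area under the ROC curve via the Mann-Whitney identity (ties receive
#' half credit), with variance and confidence interval from DeLong's
#' structural-components method as implemented in \pkg{pROC}. The ROC
#' direction is fixed (higher score = more likely responder), so an AUC
#' below 0.5 is reported as such.
#'
#' @param labels 0/1 or logical outcome; both classes must be present.
#' @param scores numeric risk scores.
#' @return List: `auc`, `ci95` (length 2).
#' @export
auroc_delong <- function(labels, scores) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present")
  r <- pROC::roc(y, scores, levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  list(auc = as.numeric(pROC::auc(r)), ci95 = ci[c(1, 3)])
}

#' Paired DeLong comparison of two models' AUROCs
#'
#' Two-sided DeLong test for the difference between the AUROCs of two
#' models evaluated on the same subjects. Identical predictions give a
#' difference of 0 with p = 1.
#'
#' @param labels shared 0/1 outcome.
#' @param probs1,probs2 the two models' predicted probabilities (or scores),
#'   paired by subject.
#' @return List: `auc1`, `auc2`, `difference`, `p`.
#' @export
delong_compare <- function(labels, probs1, probs2) {
  y <- as.integer(labels)
  stopifnot(length(probs1) == length(y), length(probs2) == length(y))
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present")
  r1 <- pROC::roc(y, probs1, levels = c(0, 1), direction = "<", quiet = TRUE)
  r2 <- pROC::roc(y, probs2, levels = c(0, 1), direction = "<", quiet = TRUE)
  a1 <- as.numeric(pROC::auc(r1)); a2 <- as.numeric(pROC::auc(r2))
  if (isTRUE(all.equal(probs1, probs2))) {
    p <- 1
  } else {
    tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    p <- as.numeric(tst$p.value)
  }
  list(auc1 = a1, auc2 = a2, difference = a1 - a2, p = p)
}

# Shared risk-decile binning: bins by quantiles of predicted probability,
# keeping ties in one bin; returns a bin index per observation.
.risk_bins <- function(probs, n_bins) {
  breaks <- unique(quantile(probs, seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) return(rep(1L, length(probs)))
  cut(probs, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

#' Observed vs expected calibration table
#'
#' Bins subjects by predicted risk (deciles by default, ties kept together)
#' and tabulates observed events, expected events (sum of predicted
#' probabilities) and rates per bin. The same binning feeds
#' [hosmer_lemeshow()] and [calibration_plot()].
#'
#' @param labels 0/1 outcome.
#' @param probs predicted probabilities.
#' @param n_bins number of risk bins (default 10).
#' @return data.frame: `bin`, `n`, `observed`, `expected`, `obs_rate`,
#'   `exp_rate`.
#' @export
calibration_table <- function(labels, probs, n_bins = 10) {
  y <- as.integer(labels)
  bin <- .risk_bins(probs, n_bins)
  agg <- lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(bin = b, n = sum(idx), observed = sum(y[idx]),
               expected = sum(probs[idx]),
               obs_rate = mean(y[idx]), exp_rate = mean(probs[idx]))
  })
  do.call(rbind, agg)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Chi-square comparison of observed vs expected event and non-event counts
#' across predicted-risk bins: `sum (O-E)^2/E` over both outcome columns,
#' referred to chi-square with (bins - 2) degrees of freedom. Bins with zero
#' expected events (or non-events) are merged with their neighbor.
#'
#' @param labels 0/1 outcome.
#' @param probs predicted probabilities.
#' @param n_bins requested bins (default 10 risk deciles); `n` must be at
#'   least `2 * n_bins`.
#' @return List: `statistic`, `p`, `n_bins` (after merging), `table` (the
#'   per-bin calibration table used).
#' @export
hosmer_lemeshow <- function(labels, probs, n_bins = 10) {
  y <- as.integer(labels)
  if (length(y) < 2 * n_bins)
    stop("need n >= 2 * n_bins (n = ", length(y), ", bins = ", n_bins, ")")
  tab <- calibration_table(y, probs, n_bins)
  # merge bins whose expected events or non-events are zero
  repeat {
    e1 <- tab$expected; e0 <- tab$n - tab$expected
    bad <- which(e1 == 0 | e0 == 0)
    if (!length(bad) || nrow(tab) == 1) break
    i <- bad[1]; j <- if (i == nrow(tab)) i - 1 else i + 1
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed[j] <- tab$observed[j] + tab$observed[i]
    tab$expected[j] <- tab$expected[j] + tab$expected[i]
    tab <- tab[-i, , drop = FALSE]
  }
  tab$obs_rate <- tab$observed / tab$n
  tab$exp_rate <- tab$expected / tab$n
  o1 <- tab$observed; e1 <- tab$expected
  o0 <- tab$n - o1;   e0 <- tab$n - e1
  stat <- sum((o1 - e1)^2 / e1 + (o0 - e0)^2 / e0)
  df <- nrow(tab) - 2
  p <- if (df < 1) NA_real_ else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, p = p, n_bins = nrow(tab), table = tab)
}

#' Threshold-based confusion metrics
#'
#' Classifies `prob >= threshold` as predicted responder and reports the
#' confusion matrix with accuracy, sensitivity, specificity, positive and
#' negative predictive value.
#'
#' @param labels 0/1 outcome.
#' @param probs predicted probabilities.
#' @param threshold classification threshold in (0, 1\] (default 0.5); 0 is
#'   accepted and predicts everything positive.
#' @return List: `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `threshold`.
#' @export
confusion_metrics <- function(labels, probs, threshold = 0.5) {
  y <- as.integer(labels)
  stopifnot(threshold >= 0, threshold <= 1)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  safe <- function(a, b) if (b == 0) NA_real_ else a / b
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y),
       sensitivity = safe(tp, tp + fn), specificity = safe(tn, tn + fp),
       ppv = safe(tp, tp + fp), npv = safe(tn, tn + fn),
       threshold = threshold)
}

#' Calibration plot (observed vs expected response rate by risk bin)
#'
#' Writes a PNG of per-bin observed vs expected response rates with the
#' identity line, and the numeric table as CSV alongside. The binning is
#' identical to [hosmer_lemeshow()]'s.
#'
#' @param labels,probs,n_bins as for [hosmer_lemeshow()].
#' @param path output PNG path (the CSV gets the same path with extension
#'   `.csv`).
#' @return The calibration table, invisibly.
#' @export
calibration_plot <- function(labels, probs, path, n_bins = 10) {
  tab <- calibration_table(labels, probs, n_bins)
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  plot(tab$exp_rate, tab$obs_rate, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "Expected response rate", ylab = "Observed response rate",
       pch = 19, main = "Calibration")
  graphics::abline(0, 1, lty = 2)
  utils::write.csv(tab, paste0(tools::file_path_sans_ext(path), ".csv"),
                   row.names = FALSE)
  invisible(tab)
}

#' Full performance report for one fitted model
#'
#' @param labels 0/1 outcome.
#' @param probs fitted response probabilities.
#' @param model_label free-text label.
#' @param n_bins Hosmer-Lemeshow bins (default 10).
#' @param threshold confusion threshold (default 0.5).
#' @return List of class `performance_report` combining [auroc_delong()],
#'   [hosmer_lemeshow()] and [confusion_metrics()] output.
#' @export
performance_report <- function(labels, probs, model_label = "model",
                               n_bins = 10, threshold = 0.5) {
  roc <- auroc_delong(labels, probs)
  hl <- hosmer_lemeshow(labels, probs, n_bins)
  cm <- confusion_metrics(labels, probs, threshold)
  structure(list(model = model_label, auroc = roc$auc,
                 auroc_ci95 = roc$ci95, hl_statistic = hl$statistic,
                 hl_p = hl$p, hl_bins = hl$n_bins, confusion = cm),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "%s: AUROC %.3f (%.3f-%.3f), HL p = %.3g (%d bins)\n  acc %.3f sens %.3f spec %.3f ppv %.3f npv %.3f @ %.2f\n",
    x$model, x$auroc, x$auroc_ci95[1], x$auroc_ci95[2], x$hl_p, x$hl_bins,
    x$confusion$accuracy, x$confusion$sensitivity, x$confusion$specificity,
    x$confusion$ppv, x$confusion$npv, x$confusion$threshold))
  invisible(x)
}
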