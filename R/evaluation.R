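#' Per-class binary classification metrics
#'
#' Standard per-class binary definitions over aligned prediction and truth
#' matrices: precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic
#' mean), accuracy `(TP+TN)/n`. Zero-division cases yield 0 and are flagged
#' in `undefined`.
#'
#' @param predictions records x classes binary matrix.
#' @param truths records x classes binary matrix of the same shape.
#' @param class_names optional class names.
#' @return Data frame with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `tn`, `precision`, `recall`, `f1`, `accuracy`, `support`, `undefined`.
#' @export
per_class_metrics <- function(predictions, truths, class_names = NULL) {
  predictions <- as.matrix(predictions); truths <- as.matrix(truths)
  if (!all(dim(predictions) == dim(truths)))
    stopf("predictions/truths shape mismatch")
  n <- nrow(truths)
  C <- ncol(truths)
  class_names <- class_names %||% colnames(truths) %||% as.character(seq_len(C))
  out <- lapply(seq_len(C), function(j) {
    p <- predictions[, j] > 0; t <- truths[, j] > 0
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
    undef <- FALSE
    prec <- if (tp + fp > 0) tp / (tp + fp) else { undef <- TRUE; 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else { undef <- TRUE; 0 }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = class_names[j], tp = tp, fp = fp, fn = fn, tn = tn,
               precision = prec, recall = rec, f1 = f1,
               accuracy = (tp + tn) / n, support = tp + fn,
               undefined = undef, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Macro-averaged metric report
#'
#' Unweighted means over classes of the per-class precision, recall,
#' accuracy and F1: the mAP / mAR / mAA / mAF1 quadruple. Note these are
#' macro classification averages, not detection-style average precision.
#'
#' @param per_class a data frame from [per_class_metrics()].
#' @return Named numeric vector `c(mAP, mAR, mAA, mAF1)`.
#' @export
macro_report <- function(per_class) {
  if (nrow(per_class) == 0L) stopf("empty per-class table")
  c(mAP = mean(per_class$precision), mAR = mean(per_class$recall),
    mAA = mean(per_class$accuracy), mAF1 = mean(per_class$f1))
}

#' Binarize probability outputs
#'
#' @param probs probability vector or records x classes matrix.
#' @param mode `"top3"` (exactly three positives per record, ties toward the
#'   lower index) or `"threshold"`.
#' @param t threshold for `mode = "threshold"`.
#' @return Binary vector/matrix of the same shape.
#' @export
binarize <- function(probs, mode = c("top3", "threshold"), t = 0.5) {
  mode <- match.arg(mode)
  if (is.matrix(probs)) {
    out <- matrix(0L, nrow(probs), ncol(probs), dimnames = dimnames(probs))
    if (mode == "threshold") out[probs >= t] <- 1L
    else for (i in seq_len(nrow(probs))) out[i, decide_top3(probs[i, ])] <- 1L
    return(out)
  }
  if (mode == "threshold") as.integer(probs >= t)
  else { v <- integer(length(probs)); v[decide_top3(probs)] <- 1L; v }
}

# Truth matrix (records x classes) from record labels.
truth_matrix <- function(records, vocab) {
  Y <- t(vapply(records, function(r) as.integer(r$labels),
                integer(n_classes(vocab))))
  colnames(Y) <- vocab$names
  rownames(Y) <- record_ids(records)
  Y
}

#' Evaluate an ensemble and its members on a labelled test set
#'
#' Builds the per-method metrics table: one row per member model plus one
#' for the ensemble, with macro mAP / mAR / mAA / mAF1 computed from the
#' chosen decision rule against the records' labels.
#'
#' @param ensemble a `tool_ensemble`.
#' @param records labelled test records (typically the clean test split).
#' @param method method name recorded in the table.
#' @param mode decision rule, `"top3"` (default) or `"threshold"`.
#' @param t threshold for `mode = "threshold"`.
#' @param aggregate ensemble aggregation rule (default mean-logit sigmoid).
#' @return Data frame of class `method_metrics` with columns `method`,
#'   `member`, `mAP`, `mAR`, `mAA`, `mAF1` (5 rows; the last is
#'   `"Ensemble"`).
#' @export
evaluate_method <- function(ensemble, records, method = "method",
                            mode = c("top3", "threshold"), t = 0.5,
                            aggregate = c("mean_sigmoid", "max_prob")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  Y <- truth_matrix(records, ensemble$vocab)
  logits <- predict(ensemble, records, type = "logit")
  rows <- lapply(names(logits), function(id) {
    P <- sigmoid(logits[[id]])
    B <- binarize(P, mode = mode, t = t)
    m <- macro_report(per_class_metrics(B, Y, ensemble$vocab$names))
    data.frame(method = method, member = id, t(m), stringsAsFactors = FALSE)
  })
  Pe <- if (aggregate == "mean_sigmoid") sigmoid(Reduce(`+`, logits) / 4)
        else Reduce(pmax, lapply(logits, sigmoid))
  Be <- binarize(Pe, mode = mode, t = t)
  me <- macro_report(per_class_metrics(Be, Y, ensemble$vocab$names))
  tab <- rbind(do.call(rbind, rows),
               data.frame(method = method, member = "Ensemble", t(me),
                          stringsAsFactors = FALSE))
  class(tab) <- c("method_metrics", class(tab))
  tab
}

#' Bundled method-comparison metrics table
#'
#' Per-member-model macro metrics (mAP, mAR, mAA, mAF1) for the four
#' training strategies of a published surgical-tool classification
#' experiment -- teacher, student, label smoothing and weighted data
#' loaders -- five model rows per strategy (four members plus the
#' ensemble). This is the printed input from which the method-comparison
#' statistics (ANOVA, Kruskal-Wallis, Tukey HSD) are reproduced.
#'
#' @return Data frame with columns `method`, `member`, `mAP`, `mAR`, `mAA`,
#'   `mAF1` (20 rows).
#' @export
example_method_tables <- function() {
  path <- system.file("extdata", "method_metrics.csv", package = "noisytools",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Compare training methods across metrics
#'
#' For each metric (mAP, mAR, mAA, mAF1), treats the per-model values of
#' each method as a group (n = 5: four members + ensemble) and computes a
#' one-way ANOVA, a Kruskal-Wallis test (tie-corrected), and Tukey HSD
#' pairwise mean differences with 95% family-wise confidence intervals.
#' Pairs are reported alphabetically with `mean_diff = mean(group2) -
#' mean(group1)`.
#'
#' @param tables a single long data frame with columns `method`, `member`
#'   and the four metric columns, or a list of per-method
#'   [evaluate_method()] tables.
#' @param metrics metric columns to analyse.
#' @return A list of class `comparison_report` with data frames `anova`
#'   (`metric`, `F`, `p`), `kruskal` (`metric`, `chisq`, `p`) and `tukey`
#'   (`metric`, `group1`, `group2`, `mean_diff`, `p`, `ci_low`, `ci_high`;
#'   six pair rows per metric for four methods).
#' @export
compare_methods <- function(tables, metrics = c("mAP", "mAR", "mAA", "mAF1")) {
  df <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  methods <- unique(df$method)
  if (length(methods) < 2L) stopf("need at least 2 methods to compare")
  sizes <- table(df$method)
  if (length(unique(sizes)) != 1L)
    warning("unequal group sizes across methods", call. = FALSE)
  g <- factor(df$method, levels = sort(methods))
  anova_rows <- list(); kw_rows <- list(); tukey_rows <- list()
  for (metric in metrics) {
    v <- df[[metric]]
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1L]]
    anova_rows[[metric]] <- data.frame(
      metric = metric, F = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
      stringsAsFactors = FALSE)
    kw <- stats::kruskal.test(v, g)
    kw_rows[[metric]] <- data.frame(
      metric = metric, chisq = unname(kw$statistic), p = kw$p.value,
      stringsAsFactors = FALSE)
    tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
    # TukeyHSD enumerates pairs in combn order with diff = later - earlier
    pairs <- utils::combn(levels(g), 2L)
    tukey_rows[[metric]] <- data.frame(
      metric = metric,
      group1 = pairs[1L, ],
      group2 = pairs[2L, ],
      mean_diff = tk[, "diff"], p = tk[, "p adj"],
      ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(anova = do.call(rbind, c(anova_rows, make.row.names = FALSE)),
                 kruskal = do.call(rbind, c(kw_rows, make.row.names = FALSE)),
                 tukey = do.call(rbind, c(tukey_rows, make.row.names = FALSE))),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, digits = 4, ...) {
  cat("Method comparison\n\nOne-way ANOVA:\n")
  print(format(x$anova, digits = digits), row.names = FALSE)
  cat("\nKruskal-Wallis (tie-corrected):\n")
  print(format(x$kruskal, digits = digits), row.names = FALSE)
  cat("\nTukey HSD (95% family-wise CIs):\n")
  print(format(x$tukey, digits = digits), row.names = FALSE)
  invisible(x)
}
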