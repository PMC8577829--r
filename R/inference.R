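# Division-number inference, accuracy evaluation against ground truth,
# baseline-ratio calibration, and class-histogram comparison.

#' Division-class histogram
#'
#' Counts per division class with proportions.  Built either from a vector of
#' class assignments or from named counts.
#'
#' @param classes factor/character vector of class labels (see
#'   [division_class_labels()]), or a named numeric vector of counts.
#' @param group optional group label (e.g. `"VZ/SVZ"`, `"deep layer"`).
#' @return object of class `icount_histogram` with `counts`, `proportions`,
#'   `total` and `group`.
#' @export
division_class_histogram <- function(classes, group = NULL) {
  labels <- .div_class_labels
  if (is.numeric(classes)) {
    if (is.null(names(classes)) || !all(names(classes) %in% labels)) {
      stop("numeric input must be counts named by division class",
           call. = FALSE)
    }
    if (any(classes < 0)) stop("counts must be non-negative", call. = FALSE)
    counts <- setNames(numeric(length(labels)), labels)
    counts[names(classes)] <- classes
  } else {
    classes <- factor(as.character(classes), levels = labels)
    if (anyNA(classes)) stop("unknown division class label", call. = FALSE)
    counts <- table(classes)
    counts <- setNames(as.numeric(counts), labels)
  }
  total <- sum(counts)
  structure(list(counts = counts,
                 proportions = if (total > 0) counts / total else counts,
                 total = total, group = group),
            class = "icount_histogram")
}

#' @export
print.icount_histogram <- function(x, ...) {
  cat(sprintf("Division-class histogram%s (n = %g)\n",
              if (!is.null(x$group)) paste0(" [", x$group, "]") else "",
              x$total))
  print(round(rbind(count = x$counts, proportion = x$proportions), 4))
  invisible(x)
}

.class_of_true <- function(k) {
  ifelse(k >= 4, "4+", paste0(k, "-", k + 1))
}

#' Per-cell division estimates and per-group class histograms
#'
#' Turns normalized cells (with green fraction `R`) into continuous division
#' estimates and division classes, and tabulates class histograms per group.
#' Cells flagged `undefined` (0/0 fraction) are excluded and their count is
#' reported.  Cells with `R = 1` receive an infinite continuous estimate and
#' the class "4+".
#'
#' @param cells data frame with an `R` column (e.g. from [normalize_fixed()]);
#'   optional `undefined` flag and `cell_id`.
#' @param C baseline intensity ratio (default 1, equally bright reporters).
#' @param group optional name of a column of `cells` to group histograms by.
#' @return a list of class `icount_classification` with `cells` (input plus
#'   `n_hat` and `div_class`), `histograms` (list of [division_class_histogram()]
#'   per group, or a single `"all"` histogram), and `n_excluded`.
#' @export
classify_dataset <- function(cells, C = 1, group = NULL) {
  if (nrow(cells) == 0L) stop("empty input", call. = FALSE)
  if (!"R" %in% names(cells)) {
    stop("`cells` must contain a green-fraction column `R`", call. = FALSE)
  }
  .check_C(C)
  drop <- if ("undefined" %in% names(cells)) {
    cells$undefined | is.na(cells$R)
  } else {
    is.na(cells$R)
  }
  kept <- cells[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no cells with a defined green fraction",
                             call. = FALSE)
  R <- kept$R
  .check_R(R)
  n_hat <- ifelse(R == 1, Inf, log1p(C * R / (1 - R)) / log(2))
  kept$n_hat <- n_hat
  kept$div_class <- factor(.class_of_true(pmin(floor(n_hat), 4)),
                           levels = .div_class_labels)
  histograms <- if (is.null(group)) {
    list(all = division_class_histogram(kept$div_class, group = "all"))
  } else {
    if (!group %in% names(cells)) {
      stop(sprintf("grouping column `%s` not found", group), call. = FALSE)
    }
    lapply(split(kept$div_class, kept[[group]]), division_class_histogram)
  }
  structure(list(cells = kept, histograms = histograms,
                 n_excluded = sum(drop), C = C),
            class = "icount_classification")
}

#' @export
print.icount_classification <- function(x, ...) {
  cat(sprintf("Division classification of %d cells (%d excluded), C = %g\n",
              nrow(x$cells), x$n_excluded, x$C))
  for (h in x$histograms) print(h)
  invisible(x)
}

#' Evaluate division-class predictions against ground truth
#'
#' An event is counted correct when the true completed-division count falls
#' inside the predicted class interval: class `"k-(k+1)"` matches a true
#' count of exactly `k` (the next division still pending), and `"4+"` matches
#' any count >= 4.
#'
#' @param predicted data frame with `cell_id` and `div_class` (e.g.
#'   `classify_dataset(...)$cells`).
#' @param truth data frame with `cell_id` and `true_divisions`.
#' @return a list of class `icount_accuracy` with `n_events`, `n_correct`,
#'   `fraction_correct` and a `confusion` table (predicted class x true
#'   class).
#' @export
evaluate_accuracy <- function(predicted, truth) {
  if (!all(c("cell_id", "div_class") %in% names(predicted)) ||
      !all(c("cell_id", "true_divisions") %in% names(truth))) {
    stop("need `cell_id`+`div_class` predictions and `cell_id`+",
         "`true_divisions` truth", call. = FALSE)
  }
  idx <- match(predicted$cell_id, truth$cell_id)
  if (anyNA(idx)) stop("predicted cell_id missing from ground truth",
                       call. = FALSE)
  true_k <- truth$true_divisions[idx]
  pred <- factor(as.character(predicted$div_class),
                 levels = .div_class_labels)
  if (anyNA(pred)) stop("unknown division class label", call. = FALSE)
  correct <- as.character(pred) == .class_of_true(true_k)
  confusion <- table(predicted = pred,
                     true = factor(.class_of_true(true_k),
                                   levels = .div_class_labels))
  structure(list(n_events = length(correct), n_correct = sum(correct),
                 fraction_correct = mean(correct), confusion = confusion),
            class = "icount_accuracy")
}

#' @export
print.icount_accuracy <- function(x, ...) {
  cat(sprintf("Accuracy: %d / %d events correct (%.1f%%)\n",
              x$n_correct, x$n_events, 100 * x$fraction_correct))
  print(x$confusion)
  invisible(x)
}

#' Calibrate the baseline intensity ratio from known one-division cells
#'
#' At exactly one division, `R = 1/(1 + C)`, so each calibration cell yields
#' `C = (1 - R)/R`; the estimate is the median over usable cells.  Cells with
#' `R` of exactly 0 or 1 carry no information and are excluded.
#'
#' @param R green fractions of cells known to have divided exactly once.
#' @return the estimated baseline ratio (positive scalar).
#' @examples
#' calibrate_C(c(0.5, 0.5, 1/3))  # 1
#' @export
calibrate_C <- function(R) {
  .check_R(R)
  usable <- R > 0 & R < 1
  if (!any(usable)) {
    stop("no usable calibration cells (all R are 0 or 1)", call. = FALSE)
  }
  median((1 - R[usable]) / R[usable])
}

#' Compare two division-class histograms
#'
#' Reports the total-variation distance between the class proportions, a
#' chi-square statistic with a Monte-Carlo p value (robust at small counts;
#' the observed counts are tested against the model proportions), and the
#' per-class proportion differences.
#'
#' @param observed,model [division_class_histogram()] objects (or vectors
#'   accepted by that constructor) on the same class support.
#' @param B number of Monte-Carlo replicates for the p value.
#' @return a list of class `icount_distance` with `tv`, `chisq_stat`,
#'   `p_value` and `per_class_diff` (observed minus model proportions).
#' @export
compare_distributions <- function(observed, model, B = 2000) {
  as_hist <- function(h) {
    if (inherits(h, "icount_histogram")) h else division_class_histogram(h)
  }
  observed <- as_hist(observed)
  model <- as_hist(model)
  if (observed$total == 0 || model$total == 0) {
    stop("cannot compare a zero-total histogram", call. = FALSE)
  }
  diff <- observed$proportions - model$proportions
  tv <- sum(abs(diff)) / 2
  # chi-square needs strictly positive model probabilities: restrict to the
  # support of the model; observed mass outside it makes the test degenerate
  keep <- model$proportions > 0
  if (any(observed$counts[!keep] > 0)) {
    chisq_stat <- Inf
    p_value <- 0
  } else {
    ct <- suppressWarnings(
      chisq.test(observed$counts[keep], p = model$proportions[keep],
                 simulate.p.value = TRUE, B = B))
    chisq_stat <- unname(ct$statistic)
    p_value <- ct$p.value
  }
  structure(list(tv = tv, chisq_stat = chisq_stat, p_value = p_value,
                 per_class_diff = diff),
            class = "icount_distance")
}

#' @export
print.icount_distance <- function(x, ...) {
  cat(sprintf("Histogram distance: TV = %.4f, chi-square = %.3f (p = %.3g)\n",
              x$tv, x$chisq_stat, x$p_value))
  invisible(x)
}
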