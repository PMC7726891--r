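#' Chair-stand-test labelling rule
#'
#' Players are labelled by their 30-s Chair-Stand Test score: `fit` when
#' the score is strictly above the cutoff, `not_fit` otherwise. The main
#' analysis uses a fixed cutoff of 12 points (chosen to even out group
#' sizes in the reference cohort); an exact score of 12 therefore labels
#' `not_fit` — the boundary is configurable via `boundary_fit`. The
#' adjusted mode looks the cutoff up in a user-supplied (age band, sex)
#' table, as age- and sex-adjusted norms prescribe.
#'
#' @param mode `"fixed"` or `"adjusted"`.
#' @param cutoff Fixed cutoff in 30CST points (default 12).
#' @param table For adjusted mode: data frame with columns `sex`,
#'   `age_min`, `age_max`, `cutoff`.
#' @param boundary_fit Label a score exactly at the cutoff as `fit`.
#' @return A `label_rule` list.
#' @export
label_rule <- function(mode = c("fixed", "adjusted"), cutoff = 12,
                       table = NULL, boundary_fit = FALSE) {
  mode <- match.arg(mode)
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  if (mode == "adjusted" &&
      (is.null(table) ||
       !all(c("sex", "age_min", "age_max", "cutoff") %in% names(table))))
    stop("adjusted mode needs a table with sex, age_min, age_max, cutoff",
         call. = FALSE)
  structure(list(mode = mode, cutoff = cutoff, table = table,
                 boundary_fit = boundary_fit), class = "label_rule")
}

#' Label 30CST scores as fit / not fit
#'
#' @param score 30CST scores (stands in 30 s); must be >= 0.
#' @param rule A [label_rule()].
#' @param age,sex Required in adjusted mode, recycled to `score`.
#' @return Character vector of `"fit"` / `"not_fit"`.
#' @examples
#' label_30cst(c(13, 11, 12))  # fit, not_fit, not_fit
#' @export
label_30cst <- function(score, rule = label_rule(), age = NULL,
                        sex = NULL) {
  if (any(score < 0, na.rm = TRUE))
    stop("30CST scores must be >= 0", call. = FALSE)
  cutoff <- if (rule$mode == "fixed") rep(rule$cutoff, length(score))
  else {
    if (is.null(age) || is.null(sex))
      stop("adjusted mode needs age and sex", call. = FALSE)
    age <- rep_len(age, length(score)); sex <- rep_len(sex, length(score))
    vapply(seq_along(score), function(i) {
      hit <- rule$table$sex == sex[i] & rule$table$age_min <= age[i] &
        rule$table$age_max >= age[i]
      if (!any(hit))
        stop("no cutoff table entry for age ", age[i], ", sex ", sex[i],
             call. = FALSE)
      rule$table$cutoff[which(hit)[1]]
    }, 0)
  }
  fit <- if (rule$boundary_fit) score >= cutoff else score > cutoff
  ifelse(fit, "fit", "not_fit")
}

#' Confusion matrix with not-fit as the positive class
#'
#' Screening convention: the positive class is `not_fit` (the group the
#' screen exists to find), so TP counts correctly flagged not-fit players
#' and FP counts fit players flagged not-fit.
#'
#' @param truth,pred Vectors of `"fit"` / `"not_fit"` labels.
#' @return An `ebb_confusion`: list `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  ok <- !is.na(truth) & !is.na(pred)
  truth <- truth[ok]; pred <- pred[ok]
  confusion_counts(tp = sum(truth == "not_fit" & pred == "not_fit"),
                   fn = sum(truth == "not_fit" & pred == "fit"),
                   tn = sum(truth == "fit" & pred == "fit"),
                   fp = sum(truth == "fit" & pred == "not_fit"))
}

#' @rdname confusion_matrix
#' @param tp,fn,tn,fp Cell counts (positive class `not_fit`).
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  cells <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(cells < 0) || any(!is.finite(cells)))
    stop("confusion counts must be non-negative", call. = FALSE)
  structure(as.list(cells), class = "ebb_confusion")
}

#' @export
print.ebb_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("not_fit", "fit"),
                              predicted = c("not_fit", "fit")))
  print(m)
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from a confusion matrix
#'
#' Per-class TP rate, FP rate, precision, recall and F-measure for the
#' `not_fit` (positive) and `fit` rows, a weighted-average row (each
#' class's metric weighted by its true-class count), the overall accuracy,
#' and the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. Zero
#' denominators yield 0 and set a QC flag.
#'
#' @param cm An `ebb_confusion`.
#' @return An `ebb_eval_metrics`: data frame with rows `not_fit`, `fit`,
#'   `weighted` and columns `tp_rate`, `fp_rate`, `precision`, `recall`,
#'   `f_measure`, `mcc`; attributes `accuracy`, `total`, `qc_zero_denom`.
#' @examples
#' metrics_from_confusion(confusion_counts(tp = 29, fn = 5, tn = 45, fp = 2))
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "ebb_confusion"))
  tp <- cm$tp; fn <- cm$fn; tn <- cm$tn; fp <- cm$fp
  total <- tp + fn + tn + fp
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  dens <- c(tp + fn, fp + tn, tp + fp, tn + fn)
  qc_zero <- any(dens == 0)

  row_for <- function(tp., fn., tn., fp.) {
    tpr <- safe_div(tp., tp. + fn.)
    prec <- safe_div(tp., tp. + fp.)
    f <- if (prec + tpr == 0) 0 else 2 * prec * tpr / (prec + tpr)
    c(tp_rate = tpr, fp_rate = safe_div(fp., fp. + tn.),
      precision = prec, recall = tpr, f_measure = f)
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den

  notfit <- row_for(tp, fn, tn, fp)
  fitrow <- row_for(tn, fp, tp, fn)  # class roles swapped
  w <- c(tp + fn, tn + fp) / total
  weighted <- w[1] * notfit + w[2] * fitrow

  out <- as.data.frame(rbind(not_fit = notfit, fit = fitrow,
                             weighted = weighted))
  out$mcc <- mcc
  structure(out, class = c("ebb_eval_metrics", "data.frame"),
            accuracy = (tp + tn) / total, total = total,
            qc_zero_denom = qc_zero)
}

#' @export
print.ebb_eval_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Accuracy: %.3f%% (%d instances)\n",
              100 * attr(x, "accuracy"), attr(x, "total")))
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' Single-threshold screening rule on the mean step interval
#'
#' The published decision rule distilled from the best classifier: a mean
#' time between steps of `threshold` seconds or lower indicates a player
#' able to maintain physical independence (`fit`); longer indicates
#' `not_fit`. A missing `step_avg` (fewer than two detected steps)
#' abstains with `NA`.
#'
#' @param step_avg Mean inter-step interval(s), seconds.
#' @param threshold Decision threshold, seconds (default 6.17).
#' @return Character vector `"fit"` / `"not_fit"` / `NA`.
#' @export
step_rule_classify <- function(step_avg, threshold = 6.17) {
  ifelse(is.na(step_avg), NA_character_,
         ifelse(step_avg <= threshold, "fit", "not_fit"))
}

entropy2 <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Information gain of one feature for a binary label
#'
#' Delta-entropy information gain in bits: `H(label)` minus the label
#' entropy conditional on the discretised feature. The default
#' discretisation is a supervised binary split — the single cut point (at
#' midpoints between consecutive distinct values) minimising conditional
#' entropy. Missing values form their own bin, so informative missingness
#' is credited. Constant labels give 0 by convention.
#'
#' @param x Numeric feature values.
#' @param y Binary labels.
#' @return The gain in bits, with attribute `cutpoint` (the chosen
#'   threshold, `NA` when no split exists).
#' @export
information_gain <- function(x, y) {
  y <- as.character(y)
  stopifnot(length(x) == length(y))
  n <- length(y)
  if (n < 2L) stop("need at least 2 instances", call. = FALSE)
  h_y <- entropy2(table(y))
  if (h_y == 0) return(structure(0, cutpoint = NA_real_))

  miss <- is.na(x)
  h_miss <- if (any(miss)) sum(miss) / n * entropy2(table(y[miss])) else 0
  xs <- x[!miss]; ys <- y[!miss]
  if (length(xs) == 0L || length(unique(xs)) < 2L) {
    h_obs <- if (length(xs)) length(xs) / n * entropy2(table(ys)) else 0
    return(structure(max(0, h_y - (h_miss + h_obs)),
                     cutpoint = NA_real_))
  }
  ord <- order(xs)
  xs <- xs[ord]; ys <- ys[ord]
  pos <- cumsum(ys == "not_fit")
  tot_pos <- pos[length(pos)]
  m <- length(xs)
  cut_idx <- which(diff(xs) > 0)  # split after these positions
  cond <- vapply(cut_idx, function(i) {
    left <- c(pos[i], i - pos[i])
    right <- c(tot_pos - pos[i], (m - i) - (tot_pos - pos[i]))
    (i * entropy2(left) + (m - i) * entropy2(right)) / n
  }, 0)
  best <- which.min(cond)
  gain <- h_y - (h_miss + cond[best])
  structure(max(0, gain),
            cutpoint = (xs[cut_idx[best]] + xs[cut_idx[best] + 1L]) / 2)
}

#' Information-gain ranking of a feature table
#'
#' @param table Feature table ([feature_table()] layout).
#' @param labels Labels; defaults to the table's `label` column.
#' @return Data frame `feature`, `info_gain`, `cutpoint`, sorted by
#'   decreasing gain.
#' @export
information_gain_table <- function(table, labels = table$label) {
  feats <- intersect(feature_names(), names(table))
  res <- lapply(feats, function(f) {
    ig <- information_gain(table[[f]], labels)
    data.frame(feature = f, info_gain = as.numeric(ig),
               cutpoint = attr(ig, "cutpoint"))
  })
  out <- do.call(rbind, res)
  out[order(-out$info_gain), ]
}

#' Hedges' g effect sizes and Welch tests per feature
#'
#' For each feature, the standardised mean difference between the not-fit
#' and fit groups with small-sample correction:
#' `g = J * (mean_notfit - mean_fit) / s_pooled`, where `s_pooled` weights
#' group variances by `n - 1` and `J = 1 - 3 / (4*df - 1)` with
#' `df = n1 + n2 - 2`. Negative g therefore means the feature runs lower
#' in the not-fit group. Significance is a two-sided Welch t-test
#' (Satterthwaite df), suited to unequal group variances. Groups with
#' fewer than two non-missing values, or zero pooled variance, give `NA`
#' (or 0 for equal means) with a QC flag.
#'
#' @param table Feature table.
#' @param labels Labels; defaults to the `label` column.
#' @return Data frame `feature`, `g`, `p`, `n_notfit`, `n_fit`, `flag`.
#' @export
effect_sizes <- function(table, labels = table$label) {
  labels <- as.character(labels)
  feats <- intersect(feature_names(), names(table))
  rows <- lapply(feats, function(f) {
    a <- table[[f]][labels == "not_fit"]; a <- a[!is.na(a)]
    b <- table[[f]][labels == "fit"]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2L || n2 < 2L)
      return(data.frame(feature = f, g = NA_real_, p = NA_real_,
                        n_notfit = n1, n_fit = n2, flag = "too_few"))
    df <- n1 + n2 - 2
    sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df)
    J <- 1 - 3 / (4 * df - 1)
    if (sp == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      return(data.frame(feature = f, g = if (eq) 0 else NA_real_,
                        p = if (eq) 1 else NA_real_,
                        n_notfit = n1, n_fit = n2, flag = "zero_var"))
    }
    g <- J * (mean(a) - mean(b)) / sp
    p <- if (stats::var(a) == 0 && stats::var(b) == 0) 1
         else stats::t.test(a, b)$p.value
    data.frame(feature = f, g = g, p = p, n_notfit = n1, n_fit = n2,
               flag = "")
  })
  do.call(rbind, rows)
}
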