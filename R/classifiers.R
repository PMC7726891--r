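# Classifiers for the fit / not-fit screening task, behind one small
# fit/predict interface so the CV harness treats them uniformly.
#
#   stump    — single-feature threshold chosen by information gain
#   tree     — CART decision tree (rpart)
#   logistic — plain logistic regression (glm)
#   lmt      — LMT-like: info-gain root split with a logistic model in
#              each branch (falls back to branch majority when a branch
#              is pure or too small)

fit_clf <- function(x, y, method) {
  y <- factor(as.character(y), levels = c("fit", "not_fit"))
  switch(method,
         stump = fit_stump(x, y),
         tree = fit_tree(x, y),
         logistic = fit_logistic(x, y),
         lmt = fit_lmt(x, y),
         stop("unknown classifier '", method, "'", call. = FALSE))
}

predict_clf <- function(obj, x) {
  switch(obj$method,
         stump = predict_stump(obj, x),
         tree = predict_tree(obj, x),
         logistic = predict_logistic(obj, x),
         lmt = predict_lmt(obj, x))
}

majority <- function(y) {
  tab <- table(y)
  names(tab)[which.max(tab)]  # ties: first level (fit)
}

# -- decision stump ---------------------------------------------------------

fit_stump <- function(x, y) {
  gains <- vapply(names(x), function(f) {
    as.numeric(information_gain(x[[f]], y))
  }, 0)
  best <- names(x)[which.max(gains)]
  cut <- attr(information_gain(x[[best]], y), "cutpoint")
  if (max(gains) == 0 || is.na(cut))
    return(list(method = "stump", feature = NA_character_,
                cutpoint = NA_real_, fallback = majority(y)))
  left <- x[[best]] <= cut
  list(method = "stump", feature = best, cutpoint = cut,
       left_class = majority(y[left & !is.na(left)]),
       right_class = majority(y[!left & !is.na(left)]),
       fallback = majority(y))
}

predict_stump <- function(obj, x) {
  if (is.na(obj$feature))
    return(rep(obj$fallback, nrow(x)))
  v <- x[[obj$feature]]
  out <- ifelse(is.na(v), obj$fallback,
                ifelse(v <= obj$cutpoint, obj$left_class,
                       obj$right_class))
  out
}

# -- CART tree --------------------------------------------------------------

fit_tree <- function(x, y) {
  dat <- cbind(data.frame(.y = y), x)
  fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                      control = rpart::rpart.control(minsplit = 5,
                                                     cp = 0.01, xval = 0))
  list(method = "tree", fit = fit)
}

predict_tree <- function(obj, x)
  as.character(predict(obj$fit, newdata = x, type = "class"))

# -- logistic regression ----------------------------------------------------

fit_logistic <- function(x, y, features = names(x)) {
  keep <- features[vapply(x[features], function(v)
    length(unique(v[!is.na(v)])) > 1L, TRUE)]
  if (length(keep) == 0L || length(unique(y)) < 2L)
    return(list(method = "logistic", fit = NULL, fallback = majority(y)))
  dat <- cbind(data.frame(.y = y), x[keep])
  fit <- suppressWarnings(
    glm(.y ~ ., data = dat, family = binomial()))
  list(method = "logistic", fit = fit, features = keep,
       fallback = majority(y))
}

predict_logistic <- function(obj, x, scores = FALSE) {
  if (is.null(obj$fit)) {
    if (scores)
      return(rep(if (obj$fallback == "not_fit") 1 else 0, nrow(x)))
    return(rep(obj$fallback, nrow(x)))
  }
  p <- suppressWarnings(predict(obj$fit, newdata = x, type = "response"))
  p[is.na(p)] <- if (obj$fallback == "not_fit") 1 else 0
  if (scores) return(as.numeric(p))
  ifelse(p > 0.5, "not_fit", "fit")
}

# -- LMT-like: root split + logistic branches -------------------------------

fit_lmt <- function(x, y, max_branch_features = 3L,
                    min_branch_n = 8L) {
  root <- fit_stump(x, y)
  if (is.na(root$feature))
    return(list(method = "lmt", root = root, branches = NULL))
  left <- x[[root$feature]] <= root$cutpoint & !is.na(x[[root$feature]])
  branch_model <- function(idx) {
    yb <- droplevels(y[idx])
    if (sum(idx) < min_branch_n || length(unique(yb)) < 2L)
      return(list(kind = "majority", class = majority(y[idx])))
    gains <- vapply(names(x), function(f)
      as.numeric(information_gain(x[[f]][idx], y[idx])), 0)
    top <- names(sort(gains, decreasing = TRUE))[
      seq_len(min(max_branch_features, sum(gains > 0)))]
    if (length(top) == 0L)
      return(list(kind = "majority", class = majority(y[idx])))
    list(kind = "logistic",
         model = fit_logistic(x[idx, , drop = FALSE], y[idx],
                              features = top))
  }
  list(method = "lmt", root = root,
       branches = list(left = branch_model(left),
                       right = branch_model(!left)))
}

predict_lmt <- function(obj, x) {
  root <- obj$root
  if (is.null(obj$branches)) return(rep(root$fallback, nrow(x)))
  v <- x[[root$feature]]
  side <- ifelse(is.na(v), NA, v <= root$cutpoint)
  out <- character(nrow(x))
  for (s in c(TRUE, FALSE)) {
    idx <- which(!is.na(side) & side == s)
    if (!length(idx)) next
    br <- if (s) obj$branches$left else obj$branches$right
    out[idx] <- if (br$kind == "majority") br$class
                else predict_logistic(br$model, x[idx, , drop = FALSE])
  }
  out[is.na(side)] <- root$fallback
  out
}

# ---------------------------------------------------------------------------

#' Stratified k-fold cross-validation of a screening classifier
#'
#' Splits the cohort into `k` label-stratified folds, fits the chosen
#' classifier on each training partition and pools the held-out
#' predictions into one confusion matrix. Missing feature values are
#' mean-imputed with means fitted on the training folds only, so no
#' information leaks from the held-out fold.
#'
#' @param table Feature table ([feature_table()] layout) with a `label`
#'   column of `"fit"` / `"not_fit"`.
#' @param classifier One of `"stump"`, `"tree"`, `"lmt"`, `"logistic"`.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param features Feature columns to use; default all 42.
#' @return An `ebb_cv`: list with `confusion`, `metrics`, `accuracy`,
#'   `folds` (per-fold classifier summaries, e.g. the stump's chosen
#'   feature and threshold), `predictions`.
#' @examples
#' cohort <- simulate_cohort(6, 6, seed = 3)
#' cv <- crossval(feature_table(cohort), classifier = "stump", k = 3,
#'                seed = 1)
#' cv$accuracy
#' @export
crossval <- function(table, classifier = c("stump", "tree", "lmt",
                                           "logistic"),
                     k = 10L, seed = 1L,
                     features = feature_names()) {
  classifier <- match.arg(classifier)
  n <- nrow(table)
  if (n < k) stop("fewer instances than folds", call. = FALSE)
  y <- as.character(table$label)
  if (!all(y %in% c("fit", "not_fit")))
    stop("labels must be 'fit' or 'not_fit'", call. = FALSE)
  x <- table[, intersect(features, names(table)), drop = FALSE]

  fold <- integer(n)
  with_seed(seed, for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  })

  pred <- character(n)
  fold_info <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
    mu <- vapply(xtr, function(v) {
      m <- mean(v, na.rm = TRUE)
      if (is.nan(m)) 0 else m
    }, 0)
    for (j in seq_along(xtr)) {
      xtr[[j]][is.na(xtr[[j]])] <- mu[j]
      xte[[j]][is.na(xte[[j]])] <- mu[j]
    }
    obj <- fit_clf(xtr, y[tr], classifier)
    pred[te] <- predict_clf(obj, xte)
    fold_info[[f]] <- switch(classifier,
      stump = list(feature = obj$feature, cutpoint = obj$cutpoint),
      lmt = list(feature = obj$root$feature,
                 cutpoint = obj$root$cutpoint),
      list())
  }

  cm <- confusion_matrix(y, pred)
  met <- metrics_from_confusion(cm)
  structure(list(confusion = cm, metrics = met,
                 accuracy = attr(met, "accuracy"),
                 classifier = classifier, k = k,
                 folds = fold_info,
                 predictions = data.frame(truth = y, pred = pred,
                                          fold = fold)),
            class = "ebb_cv")
}

#' @export
print.ebb_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV, classifier '%s': accuracy %.3f%%\n",
              x$k, x$classifier, 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}
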