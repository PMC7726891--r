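#' Canonical feature names
#'
#' The stable, ordered names of the 42 per-playthrough features: 16
#' directional com means/SDs, 4 balance asymmetries, 8 global com
#' statistics, 12 instability summaries, and 2 step-timing summaries.
#'
#' @return Character vector of length 42.
#' @export
feature_names <- function() {
  dirs <- c("up", "down", "left", "right")
  c(paste0("com_avg_", rep(dirs, each = 2), "_", c("x", "y")),
    paste0("com_std_", rep(dirs, each = 2), "_", c("x", "y")),
    paste0("balance_", c("up", "down", "right", "left")),
    "avg_x", "avg_y", "max_x", "max_y", "min_x", "min_y",
    "std_x", "std_y",
    "if_avg", "if_max",
    paste0("if_threshold_", c("0.5", "1", "1.5", "2")),
    "if_sum_avg", "if_sum_max",
    paste0("if_sum_over_", c("0.5", "1", "1.5", "2")),
    "step_avg", "step_std")
}

#' Directional centre-of-mass statistics
#'
#' Per direction (Up, Down, Left, Right): component-wise mean and sample
#' standard deviation (n - 1 denominator) of com over the samples in that
#' direction's mask. An empty mask yields `NA` for that direction's values
#' (no movement in that direction occurred). With `table1_literal = TRUE`
#' the means divide by the total sample count `n_com` instead of the mask
#' size.
#'
#' @inheritParams classify_intention
#' @param masks Output of [direction_masks()].
#' @param table1_literal Use total-count denominators for the means.
#' @return Named numeric vector of 16 values (`com_avg_*`, `com_std_*`).
#' @export
directional_com_stats <- function(com, masks, table1_literal = FALSE) {
  cm <- as_com_matrix(com)
  n_com <- nrow(cm)
  dirs <- c("up", "down", "left", "right")
  per_dir <- lapply(dirs, function(d) {
    idx <- masks[[d]]
    if (length(idx) == 0L)
      return(list(avg = c(NA_real_, NA_real_),
                  std = c(NA_real_, NA_real_)))
    sub <- cm[idx, , drop = FALSE]
    denom <- if (table1_literal) n_com else length(idx)
    list(avg = colSums(sub) / denom,
         std = if (length(idx) > 1L) apply(sub, 2, sd) else c(0, 0))
  })
  names(per_dir) <- dirs
  avgs <- unlist(lapply(dirs, function(d)
    setNames(per_dir[[d]]$avg, paste0("com_avg_", d, "_", c("x", "y")))))
  stds <- unlist(lapply(dirs, function(d)
    setNames(per_dir[[d]]$std, paste0("com_std_", d, "_", c("x", "y")))))
  c(avgs, stds)
}

#' Balance asymmetry features
#'
#' Conditional means of each com component over the samples where it is
#' strictly positive or strictly negative: `balance_up` averages `com_y`
#' where `com_y > 0`, `balance_down` where `com_y < 0`, and analogously
#' `balance_right` / `balance_left` for `com_x`. No qualifying samples
#' yields 0. With `table1_literal = TRUE` the sums divide by the total
#' sample count instead of the qualifying count.
#'
#' @inheritParams directional_com_stats
#' @return Named numeric vector `balance_up`, `balance_down`,
#'   `balance_right`, `balance_left`.
#' @export
balance_features <- function(com, table1_literal = FALSE) {
  cm <- as_com_matrix(com)
  n_com <- nrow(cm)
  cond_mean <- function(v, keep) {
    if (!any(keep)) return(0)
    sum(v[keep]) / (if (table1_literal) n_com else sum(keep))
  }
  c(balance_up = cond_mean(cm[, 2], cm[, 2] > 0),
    balance_down = cond_mean(cm[, 2], cm[, 2] < 0),
    balance_right = cond_mean(cm[, 1], cm[, 1] > 0),
    balance_left = cond_mean(cm[, 1], cm[, 1] < 0))
}

#' Global centre-of-mass statistics
#'
#' Mean, maximum, minimum and sample standard deviation of each com
#' component over the whole playthrough.
#'
#' @inheritParams classify_intention
#' @return Named numeric vector `avg_x`, `avg_y`, `max_x`, `max_y`,
#'   `min_x`, `min_y`, `std_x`, `std_y`.
#' @export
global_com_stats <- function(com) {
  cm <- as_com_matrix(com)
  if (nrow(cm) == 0L) stop("com series must be non-empty", call. = FALSE)
  x <- cm[, 1]; y <- cm[, 2]
  sdv <- function(v) if (length(v) > 1L) sd(v) else 0
  c(avg_x = mean(x), avg_y = mean(y), max_x = max(x), max_y = max(y),
    min_x = min(x), min_y = min(y), std_x = sdv(x), std_y = sdv(y))
}

#' Instability summary features
#'
#' Mean and maximum of the instability factor and of its rolling sum, plus
#' normalised exceedance counts: `if_threshold_i` is the fraction of
#' samples with `if(t) > i`, and `if_sum_over_i` the fraction with
#' `if_sum(t) > i`, for thresholds 0.5, 1, 1.5, 2. With
#' `ifsum_time_norm = TRUE` the `if_sum_over_*` counts are divided by the
#' playthrough duration in seconds (samples / 20) instead of the sample
#' count.
#'
#' @param if_values Output of [compute_if()].
#' @param if_sum Output of [compute_if_sum()]; recomputed when `NULL`.
#' @param thresholds Exceedance thresholds (per-sample units).
#' @param window Rolling window for `if_sum` when it must be recomputed.
#' @param ifsum_time_norm Normalise `if_sum_over_*` by time, not samples.
#' @return Named numeric vector of 12 values.
#' @export
instability_features <- function(if_values, if_sum = NULL,
                                 thresholds = c(0.5, 1, 1.5, 2),
                                 window = 25L, ifsum_time_norm = FALSE) {
  n <- length(if_values)
  if (n == 0L) stop("empty instability series", call. = FALSE)
  if (is.null(if_sum)) if_sum <- compute_if_sum(if_values, window)
  stopifnot(length(if_sum) == n)
  thr_names <- format(thresholds, trim = TRUE, drop0trailing = TRUE)
  over_denom <- if (ifsum_time_norm) n / 20 else n
  out <- c(if_avg = mean(if_values), if_max = max(if_values),
           setNames(vapply(thresholds,
                           function(i) sum(if_values > i) / n, 0),
                    paste0("if_threshold_", thr_names)),
           if_sum_avg = mean(if_sum), if_sum_max = max(if_sum),
           setNames(vapply(thresholds,
                           function(i) sum(if_sum > i) / over_denom, 0),
                    paste0("if_sum_over_", thr_names)))
  out
}

#' Step-timing features
#'
#' Summaries of the intervals between consecutive registered steps (the
#' first step opens the first interval but contributes no interval itself):
#' `step_avg` is the mean interval and `step_std` the sample standard
#' deviation, both in seconds. Fewer than two steps leaves both `NA`; with
#' exactly two steps (one interval) `step_std` is 0 and a QC flag is set.
#' With `table1_literal = TRUE` the interval sum divides by the step count
#' instead of the interval count.
#'
#' @param steps Data frame from [detect_steps()] (needs `step_time`).
#' @param table1_literal Use the step-count denominator for `step_avg`.
#' @return Named numeric vector `step_avg`, `step_std`, with attribute
#'   `qc_single_interval` when only one interval was available.
#' @export
step_timing_features <- function(steps, table1_literal = FALSE) {
  times <- if (is.data.frame(steps)) steps$step_time else as.numeric(steps)
  n_steps <- length(times)
  if (n_steps < 2L)
    return(c(step_avg = NA_real_, step_std = NA_real_))
  d <- diff(times)
  avg <- if (table1_literal) sum(d) / n_steps else mean(d)
  std <- if (length(d) > 1L) sd(d) else 0
  out <- c(step_avg = avg, step_std = std)
  if (length(d) == 1L) attr(out, "qc_single_interval") <- TRUE
  out
}

#' Extract the full per-playthrough feature vector
#'
#' Runs the whole derivation chain on one playthrough — intention masks,
#' step detection, instability factor and rolling sum — and assembles the
#' 42 features in the canonical [feature_names()] order. Features that are
#' undefined for the playthrough (empty direction mask, fewer than two
#' steps) are `NA`; downstream classification mean-imputes them per
#' training fold.
#'
#' @param playthrough An `ebb_playthrough` (or bare n x 2 com matrix).
#' @param main,off Intention thresholds, see [classify_intention()].
#' @param dwell Step registration dwell, see [detect_steps()].
#' @param window Rolling window for the instability sum.
#' @param thresholds Instability exceedance thresholds.
#' @param table1_literal,ifsum_time_norm Denominator variants; see
#'   [directional_com_stats()], [instability_features()].
#' @return An `ebb_features` object: named numeric vector of 42 features
#'   with attributes `player_id`, `label`, `n_com`, `n_steps`, `qc`.
#' @examples
#' pt <- simulate_playthrough(fit_archetype(n_steps = 4, seed = 1))
#' f <- extract_features(pt)
#' f[c("step_avg", "if_avg")]
#' @export
extract_features <- function(playthrough, main = 0.5, off = 0.1,
                             dwell = 1L, window = 25L,
                             thresholds = c(0.5, 1, 1.5, 2),
                             table1_literal = FALSE,
                             ifsum_time_norm = FALSE) {
  if (inherits(playthrough, "ebb_playthrough")) {
    cm <- playthrough$com
    player_id <- playthrough$player_id
    label <- playthrough$label
    out_of_range <- playthrough$qc$out_of_range_com
  } else {
    cm <- as_com_matrix(playthrough)
    player_id <- NA_character_; label <- NA_character_
    out_of_range <- sum(abs(cm[, 1]) > 1 | abs(cm[, 2]) > 1)
  }
  labels <- classify_intention(cm, main, off)
  masks <- direction_masks(labels)
  steps <- detect_steps(labels, dwell = dwell)
  if_values <- compute_if(cm)
  if_sum <- compute_if_sum(if_values, window)

  vec <- c(directional_com_stats(cm, masks, table1_literal),
           balance_features(cm, table1_literal),
           global_com_stats(cm),
           instability_features(if_values, if_sum, thresholds, window,
                                ifsum_time_norm),
           step_timing_features(steps, table1_literal))
  vec <- vec[feature_names()]
  structure(vec,
            names = feature_names(),
            player_id = player_id, label = label,
            n_com = nrow(cm), n_steps = nrow(steps),
            qc = list(n_missing = sum(is.na(vec)),
                      out_of_range_com = out_of_range),
            class = "ebb_features")
}

#' @export
print.ebb_features <- function(x, ...) {
  cat("EBB feature vector (", length(x), " features, ",
      attr(x, "qc")$n_missing, " missing) — ",
      attr(x, "n_steps"), " steps over ", attr(x, "n_com"),
      " samples\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Feature table for a set of playthroughs
#'
#' Applies [extract_features()] to each playthrough and binds the results
#' into a data frame with `player_id` and `label` columns followed by the
#' 42 features in canonical order — the unit of input for [crossval()],
#' [information_gain_table()] and [effect_sizes()].
#'
#' @param playthroughs List of `ebb_playthrough` objects.
#' @param ... Passed to [extract_features()].
#' @return Data frame with one row per playthrough.
#' @export
feature_table <- function(playthroughs, ...) {
  rows <- lapply(playthroughs, function(pt) {
    f <- extract_features(pt, ...)
    cbind(data.frame(player_id = attr(f, "player_id"),
                     label = attr(f, "label"),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(unclass(f)), check.names = FALSE))
  })
  do.call(rbind, rows)
}
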