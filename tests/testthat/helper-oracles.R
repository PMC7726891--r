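# Independent brute-force oracles and fixture builders. These deliberately
# re-derive everything with plain loops and if/else, sharing no code path
# with the package internals they check.

default_boards_for_test <- function() {
  list(
    list(x = c(-0.33, 0.00), y = c(-0.33, 0.33)),
    list(x = c(0.00, 0.33), y = c(-0.33, 0.33)),
    list(x = c(-0.33, 0.33), y = c(0.33, 1.00)),
    list(x = c(-0.33, 0.33), y = c(-1.00, -0.33)),
    list(x = c(-1.00, -0.33), y = c(-0.33, 0.33)),
    list(x = c(0.33, 1.00), y = c(-0.33, 0.33)))
}

# Board-major 24 x 2 coordinate matrix, rebuilt from the layout table.
layout_coords_for_test <- function(lay)
  as.matrix(lay[order(lay$board, lay$sensor), c("x", "y")])

# Explicit 24-term summation over boards and sensors.
oracle_com <- function(frame, layout, weight) {
  v <- as.numeric(frame)
  cx <- 0; cy <- 0
  for (i in 1:6) for (j in 1:4) {
    row <- layout[layout$board == i & layout$sensor == j, ]
    k <- (i - 1) * 4 + j
    cx <- cx + v[k] * row$x
    cy <- cy + v[k] * row$y
  }
  c(cx, cy) / weight
}

# Naive O(n * w) re-summation of the rolling instability sum.
oracle_if_sum <- function(if_values, window) {
  n <- length(if_values)
  out <- numeric(n)
  for (t in seq_len(n))
    out[t] <- sum(if_values[max(1, t - window + 1):t])
  out
}

# Plain per-sample intention labelling (thresholds written out long-hand).
oracle_label <- function(x, y) {
  if (y >= 0.5 && abs(x) <= 0.1) return("Up")
  if (y <= -0.5 && abs(x) <= 0.1) return("Down")
  if (x >= 0.5 && abs(y) <= 0.1) return("Right")
  if (x <= -0.5 && abs(y) <= 0.1) return("Left")
  if (abs(x) <= 0.1 && abs(y) <= 0.1) return("Center")
  "Undetermined"
}

# Explicit state-machine walk over a com matrix; returns 0-based times.
oracle_steps <- function(cm) {
  armed <- TRUE
  ts <- integer(0); dirs <- character(0)
  for (i in seq_len(nrow(cm))) {
    lab <- oracle_label(cm[i, 1], cm[i, 2])
    if (lab == "Center") armed <- TRUE
    else if (lab != "Undetermined" && armed) {
      ts <- c(ts, i - 1L); dirs <- c(dirs, lab)
      armed <- FALSE
    }
  }
  list(t = ts, direction = dirs)
}

sample_sd <- function(v) {
  if (length(v) < 2) return(0)
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

# Independent recomputation of all 42 features from a com matrix.
oracle_features <- function(cm) {
  n <- nrow(cm)
  labs <- character(n)
  for (i in seq_len(n)) labs[i] <- oracle_label(cm[i, 1], cm[i, 2])
  out <- c()
  for (d in c("Up", "Down", "Left", "Right")) {
    idx <- which(labs == d)
    nm <- tolower(d)
    if (length(idx) == 0) {
      avg <- c(NA, NA); std <- c(NA, NA)
    } else {
      avg <- c(sum(cm[idx, 1]) / length(idx), sum(cm[idx, 2]) / length(idx))
      std <- c(sample_sd(cm[idx, 1]), sample_sd(cm[idx, 2]))
    }
    out[paste0("com_avg_", nm, "_x")] <- avg[1]
    out[paste0("com_avg_", nm, "_y")] <- avg[2]
    out[paste0("com_std_", nm, "_x")] <- std[1]
    out[paste0("com_std_", nm, "_y")] <- std[2]
  }
  cond_mean <- function(v, keep) if (!any(keep)) 0 else mean(v[keep])
  out["balance_up"] <- cond_mean(cm[, 2], cm[, 2] > 0)
  out["balance_down"] <- cond_mean(cm[, 2], cm[, 2] < 0)
  out["balance_right"] <- cond_mean(cm[, 1], cm[, 1] > 0)
  out["balance_left"] <- cond_mean(cm[, 1], cm[, 1] < 0)
  out["avg_x"] <- mean(cm[, 1]); out["avg_y"] <- mean(cm[, 2])
  out["max_x"] <- max(cm[, 1]); out["max_y"] <- max(cm[, 2])
  out["min_x"] <- min(cm[, 1]); out["min_y"] <- min(cm[, 2])
  out["std_x"] <- sample_sd(cm[, 1]); out["std_y"] <- sample_sd(cm[, 2])

  ifv <- numeric(n)
  for (t in 2:n)
    ifv[t] <- sqrt(0.5 * (cm[t, 1] - cm[t - 1, 1])^2 +
                     0.5 * (cm[t, 2] - cm[t - 1, 2])^2)
  ifs <- oracle_if_sum(ifv, 25)
  out["if_avg"] <- mean(ifv); out["if_max"] <- max(ifv)
  for (i in c(0.5, 1, 1.5, 2))
    out[paste0("if_threshold_", format(i, drop0trailing = TRUE))] <-
      sum(ifv > i) / n
  out["if_sum_avg"] <- mean(ifs); out["if_sum_max"] <- max(ifs)
  for (i in c(0.5, 1, 1.5, 2))
    out[paste0("if_sum_over_", format(i, drop0trailing = TRUE))] <-
      sum(ifs > i) / n

  st <- oracle_steps(cm)
  if (length(st$t) < 2) {
    out["step_avg"] <- NA; out["step_std"] <- NA
  } else {
    d <- diff(st$t / 20)
    out["step_avg"] <- mean(d)
    out["step_std"] <- sample_sd(d)
  }
  out
}

# Exhaustive cut-point search for binary-split information gain.
oracle_info_gain <- function(x, y) {
  H <- function(labs) {
    if (length(labs) == 0) return(0)
    p <- table(labs) / length(labs)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  n <- length(y)
  miss <- is.na(x)
  base <- H(y)
  h_miss <- sum(miss) / n * H(y[miss])
  xs <- x[!miss]; ys <- y[!miss]
  u <- sort(unique(xs))
  if (length(u) < 2)
    return(max(0, base - h_miss - length(xs) / n * H(ys)))
  best <- Inf
  for (i in seq_len(length(u) - 1)) {
    cut <- (u[i] + u[i + 1]) / 2
    l <- ys[xs <= cut]; r <- ys[xs > cut]
    cond <- (length(l) * H(l) + length(r) * H(r)) / n
    if (cond < best) best <- cond
  }
  max(0, base - h_miss - best)
}

# Metric definitions written straight from first principles.
oracle_metrics <- function(tp, fn, tn, fp) {
  total <- tp + fn + tn + fp
  prec_nf <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec_nf <- if (tp + fn > 0) tp / (tp + fn) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(accuracy = (tp + tn) / total,
       precision_notfit = prec_nf,
       recall_notfit = rec_nf,
       mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
}

# A random com series wandering across pose zones (exercises every mask).
random_com_series <- function(n, seed) {
  set.seed(seed)
  poses <- rbind(c(0, 0), c(0, 0.8), c(0, -0.8), c(0.8, 0), c(-0.8, 0),
                 c(0.4, 0.4))
  idx <- sample(nrow(poses), ceiling(n / 8), replace = TRUE)
  base <- poses[rep(idx, each = 8), , drop = FALSE][seq_len(n), ]
  cm <- base + matrix(rnorm(2 * n, 0, 0.05), ncol = 2)
  colnames(cm) <- c("x", "y")
  pmin(pmax(cm, -1), 1)
}

# A random non-negative frame whose total equals the given weight.
random_frame <- function(weight = 700) {
  v <- runif(24)
  v / sum(v) * weight
}
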