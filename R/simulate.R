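#' Gait archetype parameters
#'
#' Parameter bundles for the synthetic playthrough generator. A simulated
#' player dwells at the centre with Gaussian sway, ramps (smoothstep) onto
#' a directional pose (main axis amplitude 0.8, off-axis jitter sd 0.03,
#' comfortably inside the intention thresholds), holds the pose, ramps
#' back, and repeats. Inter-step intervals are Normal, truncated below at
#' feasibility (two ramps + hold + 0.25 s of dwell).
#'
#' The two stock archetypes encode the behaviours the screening rule
#' separates: `fit_archetype()` steps about every 4 s with small sway;
#' `notfit_archetype()` about every 8 s with slower transitions, larger
#' sway and noisier sensors. The group means straddle the 6.17 s
#' step-interval decision threshold by construction.
#'
#' @param step_interval_mean,step_interval_sd Mean / sd of the time
#'   between consecutive steps, seconds.
#' @param transition_duration Ramp time centre -> pose (and back), s.
#' @param pose_hold Hold time on the pose, s.
#' @param sway_sd_center,sway_sd_pose Gaussian sway sd (com units) while
#'   centred / on the pose main axis.
#' @param sensor_noise_sd Additive sensor noise sd, load units.
#' @param n_steps Number of steps per playthrough.
#' @param weight Player weight, load units.
#' @param seed Optional seed; all simulator randomness flows from it.
#' @return List of class `ebb_archetype`.
#' @export
archetype_params <- function(step_interval_mean = 4,
                             step_interval_sd = 0.75,
                             transition_duration = 0.5, pose_hold = 0.5,
                             sway_sd_center = 0.03, sway_sd_pose = 0.03,
                             sensor_noise_sd = 2, n_steps = 20,
                             weight = 700, seed = NULL) {
  p <- list(step_interval_mean = step_interval_mean,
            step_interval_sd = step_interval_sd,
            transition_duration = transition_duration,
            pose_hold = pose_hold,
            sway_sd_center = sway_sd_center,
            sway_sd_pose = sway_sd_pose,
            sensor_noise_sd = sensor_noise_sd,
            n_steps = n_steps, weight = weight, seed = seed)
  num <- p[setdiff(names(p), "seed")]
  if (any(!vapply(num, function(v) is.numeric(v) && is.finite(v), TRUE)))
    stop("archetype parameters must be finite numerics", call. = FALSE)
  if (p$weight <= 0 || p$n_steps < 0 || p$step_interval_sd < 0 ||
      p$transition_duration <= 0 || p$pose_hold < 0 ||
      p$sway_sd_center < 0 || p$sway_sd_pose < 0 || p$sensor_noise_sd < 0)
    stop("invalid archetype parameter sign", call. = FALSE)
  if (p$n_steps > 0 &&
      p$step_interval_mean <= min_step_interval(p))
    stop("step_interval_mean infeasible: must exceed two ramps + hold",
         call. = FALSE)
  structure(p, class = "ebb_archetype")
}

min_step_interval <- function(p)
  2 * p$transition_duration + p$pose_hold + 0.25

#' @rdname archetype_params
#' @param ... Overrides passed to [archetype_params()].
#' @export
fit_archetype <- function(...) archetype_params(...)

#' @rdname archetype_params
#' @export
notfit_archetype <- function(...) {
  defaults <- list(step_interval_mean = 8, step_interval_sd = 1.5,
                   transition_duration = 0.8, pose_hold = 0.8,
                   sway_sd_center = 0.06, sway_sd_pose = 0.06,
                   sensor_noise_sd = 4, n_steps = 15)
  do.call(archetype_params, utils::modifyList(defaults, list(...)))
}

smoothstep <- function(u) u * u * (3 - 2 * u)

dir_vectors <- function()
  list(Up = c(0, 1), Down = c(0, -1), Left = c(-1, 0), Right = c(1, 0))

#' Simulate a centre-of-mass trajectory
#'
#' Generates one playthrough's 20 Hz com trajectory from an archetype,
#' with the ground-truth step events (the designed sample at which the
#' main axis first crosses the intention threshold during each outward
#' ramp). Directions are drawn uniformly unless supplied.
#'
#' @param params An [archetype_params()] bundle.
#' @param directions Optional character vector of commanded directions
#'   (`"Up"`, `"Down"`, `"Left"`, `"Right"`), recycled to `n_steps`.
#' @param amplitude Pose main-axis amplitude (com units).
#' @return List: `com` (n x 2 matrix), `steps` (ground-truth data frame
#'   `t`, `direction`, `step_time`), `intervals` (drawn inter-step
#'   intervals, s), `params`.
#' @export
simulate_com_trajectory <- function(params, directions = NULL,
                                    amplitude = 0.8) {
  stopifnot(inherits(params, "ebb_archetype"))
  with_seed(params$seed,
            sim_trajectory_impl(params, directions, amplitude))
}

sim_trajectory_impl <- function(params, directions, amplitude = 0.8,
                                main = 0.5, off_jitter = NULL) {
  fs <- 20
  p <- params
  # off-axis pose jitter: capped at 0.03 (inside the 0.1 tolerance), and
  # zero when the archetype itself is sway-free
  if (is.null(off_jitter))
    off_jitter <- min(0.03, max(p$sway_sd_center, p$sway_sd_pose))
  n_steps <- as.integer(p$n_steps)
  T_s <- max(1L, round(p$transition_duration * fs))
  H_s <- max(1L, round(p$pose_hold * fs))
  lead_s <- fs  # 1 s settling dwell before the first step and at the end

  if (n_steps == 0L) {
    n <- 2L * lead_s
    cm <- matrix(rnorm(2 * n, 0, p$sway_sd_center), ncol = 2)
    colnames(cm) <- c("x", "y")
    return(list(com = clamp_com(cm),
                steps = empty_steps(), intervals = numeric(0),
                params = p))
  }

  if (is.null(directions))
    directions <- sample(names(dir_vectors()), n_steps, replace = TRUE)
  directions <- rep_len(as.character(directions), n_steps)
  if (!all(directions %in% names(dir_vectors())))
    stop("directions must be Up/Down/Left/Right", call. = FALSE)

  intervals <- pmax(rnorm(n_steps, p$step_interval_mean,
                          p$step_interval_sd),
                    min_step_interval(p))
  # a step cycle is: dwell, ramp out, hold, ramp in; the interval between
  # consecutive threshold crossings is dwell + 2*ramp + hold
  dwell_s <- pmax(1L, round((intervals - 2 * p$transition_duration -
                               p$pose_hold) * fs))
  dwell_s[1] <- lead_s

  ramp_u <- seq_len(T_s) / T_s
  ramp_prof <- amplitude * smoothstep(ramp_u)
  cross_off <- min(which(ramp_prof >= main))  # samples into the ramp

  xs <- numeric(0); ys <- numeric(0)
  step_t <- integer(n_steps)
  for (i in seq_len(n_steps)) {
    d <- dir_vectors()[[directions[i]]]
    # centre dwell
    nd <- dwell_s[i]
    xs <- c(xs, rnorm(nd, 0, p$sway_sd_center))
    ys <- c(ys, rnorm(nd, 0, p$sway_sd_center))
    ramp_start <- length(xs)  # 0-based index of first ramp sample
    step_t[i] <- ramp_start + cross_off - 1L
    # ramp out, hold, ramp in; sway grows from centre to pose level
    sway_ramp <- p$sway_sd_center +
      smoothstep(ramp_u) * (p$sway_sd_pose - p$sway_sd_center)
    main_seg <- c(ramp_prof + rnorm(T_s, 0, sway_ramp),
                  rnorm(H_s, amplitude, p$sway_sd_pose),
                  rev(ramp_prof) + rnorm(T_s, 0, rev(sway_ramp)))
    off_seg <- rnorm(2L * T_s + H_s, 0, off_jitter)
    if (d[1] != 0) { xs <- c(xs, d[1] * main_seg); ys <- c(ys, off_seg) }
    else { xs <- c(xs, off_seg); ys <- c(ys, d[2] * main_seg) }
  }
  xs <- c(xs, rnorm(lead_s, 0, p$sway_sd_center))
  ys <- c(ys, rnorm(lead_s, 0, p$sway_sd_center))

  cm <- cbind(x = xs, y = ys)
  list(com = clamp_com(cm),
       steps = data.frame(
         t = step_t,
         direction = factor(directions,
                            levels = c("Up", "Down", "Left", "Right")),
         step_time = step_t / 20),
       intervals = intervals, params = p)
}

clamp_com <- function(cm) {
  cm[] <- pmin(pmax(cm, -0.99), 0.99)  # stay on the board surface
  cm
}

empty_steps <- function()
  data.frame(t = integer(0),
             direction = factor(character(0),
                                levels = c("Up", "Down", "Left", "Right")),
             step_time = numeric(0))

#' Decompose a com trajectory into sensor frames
#'
#' Inverse of [compute_com()] for simulation: each com sample is assigned
#' to the board whose rectangle contains it, the player's weight is
#' distributed over that board's four corner sensors with bilinear
#' weights, and truncated-at-zero Gaussian noise is added to every sensor
#' channel (totals are deliberately not renormalised afterwards — the
#' noise is the realism). With zero noise, `compute_com()` applied to the
#' result reproduces the input exactly.
#'
#' @inheritParams classify_intention
#' @param layout An [ebb_layout()].
#' @param weight Player weight, load units.
#' @param noise_sd Sensor noise sd, load units.
#' @param seed Optional seed for the noise.
#' @return n x 24 matrix of sensor frames.
#' @export
decompose_to_sensors <- function(com, layout = ebb_layout(), weight = 700,
                                 noise_sd = 0, seed = NULL) {
  cm <- as_com_matrix(com)
  n <- nrow(cm)
  rects <- board_rects(layout)
  tol <- 1e-9
  board <- rep(NA_integer_, n)
  for (b in seq_len(nrow(rects))) {  # first containing board wins
    hit <- is.na(board) &
      cm[, 1] >= rects$xmin[b] - tol & cm[, 1] <= rects$xmax[b] + tol &
      cm[, 2] >= rects$ymin[b] - tol & cm[, 2] <= rects$ymax[b] + tol
    board[hit] <- rects$board[b]
  }
  if (anyNA(board))
    stop("com sample outside every board rectangle (sample ",
         which(is.na(board))[1], ")", call. = FALSE)

  frames <- matrix(0, nrow = n, ncol = 24L)
  for (b in unique(board)) {
    idx <- which(board == b)
    r <- rects[rects$board == b, ]
    u <- (cm[idx, 1] - r$xmin) / (r$xmax - r$xmin)
    v <- (cm[idx, 2] - r$ymin) / (r$ymax - r$ymin)
    u <- pmin(pmax(u, 0), 1); v <- pmin(pmax(v, 0), 1)
    cols <- (b - 1L) * 4L
    frames[idx, cols + 1L] <- weight * (1 - u) * (1 - v)
    frames[idx, cols + 2L] <- weight * u * (1 - v)
    frames[idx, cols + 3L] <- weight * (1 - u) * v
    frames[idx, cols + 4L] <- weight * u * v
  }
  if (noise_sd > 0)
    frames <- with_seed(seed, pmax(
      frames + matrix(rnorm(n * 24L, 0, noise_sd), nrow = n), 0))
  frames
}

#' Simulate one labelled playthrough end to end
#'
#' Draws a com trajectory from the archetype, decomposes it into noisy
#' sensor frames, and assembles an `ebb_playthrough` through the standard
#' pipeline (by default the calibration weight is re-estimated from the
#' frames, exactly as for a field recording). The ground-truth step events
#' and drawn intervals are attached as attribute `ground_truth`.
#'
#' @inheritParams simulate_com_trajectory
#' @param layout An [ebb_layout()].
#' @param player_id,level_id,label Metadata for the playthrough.
#' @param use_true_weight Normalise with the archetype's weight instead of
#'   re-estimating it from the frames.
#' @return An `ebb_playthrough`.
#' @export
simulate_playthrough <- function(params, layout = ebb_layout(),
                                 directions = NULL, player_id = "sim",
                                 level_id = "1", label = NA_character_,
                                 use_true_weight = FALSE) {
  sim <- with_seed(params$seed, {
    traj <- sim_trajectory_impl(params, directions)
    frames <- decompose_to_sensors(traj$com, layout, params$weight,
                                   noise_sd = params$sensor_noise_sd)
    list(traj = traj, frames = frames)
  })
  pt <- build_playthrough(sim$frames, layout,
                          weight = if (use_true_weight) params$weight,
                          player_id = player_id, level_id = level_id,
                          label = label)
  attr(pt, "ground_truth") <- list(steps = sim$traj$steps,
                                   intervals = sim$traj$intervals,
                                   com = sim$traj$com,
                                   weight = params$weight)
  pt
}

#' Simulate a labelled cohort
#'
#' Generates `n_fit` playthroughs from the fit archetype and `n_notfit`
#' from the not-fit archetype, with per-playthrough seeds derived from one
#' cohort seed so the whole cohort is reproducible bit for bit.
#'
#' @param n_fit,n_notfit Playthrough counts per label.
#' @param fit_params,notfit_params Archetypes; defaults [fit_archetype()]
#'   and [notfit_archetype()].
#' @param seed Cohort seed.
#' @return List of labelled `ebb_playthrough` objects (fit first).
#' @examples
#' cohort <- simulate_cohort(2, 2, seed = 7)
#' sapply(cohort, function(p) p$label)
#' @export
simulate_cohort <- function(n_fit, n_notfit,
                            fit_params = fit_archetype(),
                            notfit_params = notfit_archetype(),
                            seed = 1L) {
  stopifnot(n_fit >= 0, n_notfit >= 0)
  seeds <- with_seed(seed,
                     sample.int(2147483646L, n_fit + n_notfit))
  make <- function(i, params, label) {
    params$seed <- seeds[i]
    simulate_playthrough(params,
                         player_id = sprintf("sim_%s_%03d", label, i),
                         level_id = "1", label = label)
  }
  c(lapply(seq_len(n_fit), function(i) make(i, fit_params, "fit")),
    lapply(seq_len(n_notfit),
           function(i) make(n_fit + i, notfit_params, "not_fit")))
}

#' Write a cohort to disk as playthrough logs plus ground truth
#'
#' Writes one XML log per playthrough and a `ground_truth.csv` recording
#' each playthrough's label, true weight and true step times — the fixture
#' format used to test ingestion end to end.
#'
#' @param playthroughs List from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param include_raw Include raw sensor frames in the logs.
#' @return Character vector of log paths, invisibly.
#' @export
write_cohort_logs <- function(playthroughs, dir, include_raw = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(playthroughs))
  gt <- list()
  for (i in seq_along(playthroughs)) {
    pt <- playthroughs[[i]]
    paths[i] <- file.path(dir, sprintf("playthrough_%03d.xml", i))
    write_log(pt, paths[i], include_raw = include_raw)
    g <- attr(pt, "ground_truth")
    gt[[i]] <- data.frame(
      file = basename(paths[i]), player_id = pt$player_id,
      label = pt$label,
      true_weight = if (!is.null(g)) g$weight else NA_real_,
      n_true_steps = if (!is.null(g)) nrow(g$steps) else NA_integer_,
      true_step_times = if (!is.null(g))
        paste(g$steps$step_time, collapse = ";") else "")
  }
  write.csv(do.call(rbind, gt), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(paths)
}
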