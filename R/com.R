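#' Centre-of-mass projection of a sensor frame
#'
#' Projects the 24 raw load values of one frame onto the board plane as the
#' weight-normalised sum `com = (1/w) * sum_ij s_ij * c_ij`, where `s_ij`
#' is the load on sensor j of board i and `c_ij` its layout coordinate.
#' With loads that sum to the player's weight, each component lies in
#' \[-1, 1\]; out-of-range values are returned unclipped (they indicate a
#' weight mismatch and are counted by the playthrough QC summary).
#'
#' @param frame Numeric vector of 24 non-negative loads (board-major sensor
#'   order) or a 6 x 4 matrix (rows = boards).
#' @param layout An [ebb_layout()].
#' @param weight Player weight in the same load units; must be > 0.
#' @return Named numeric vector `c(x = , y = )`.
#' @examples
#' lay <- ebb_layout()
#' f <- numeric(24); f[1] <- 700      # all weight on one sensor
#' compute_com(f, lay, weight = 700)  # that sensor's coordinate
#' @export
compute_com <- function(frame, layout, weight) {
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) ||
      weight <= 0)
    stop("weight must be a single positive number", call. = FALSE)
  v <- frame_values(frame)
  cm <- as.vector(crossprod(layout_coords(layout), v)) / weight
  c(x = cm[1], y = cm[2])
}

# Coerce a frame to a length-24 numeric vector, validating it.
frame_values <- function(frame) {
  if (is.matrix(frame)) {
    if (!all(dim(frame) == c(6L, 4L)))
      stop("frame matrix must be 6 x 4", call. = FALSE)
    frame <- as.vector(t(frame))  # board-major
  }
  v <- as.numeric(frame)
  if (length(v) != 24L || anyNA(v))
    stop("frame must contain all 24 sensor values", call. = FALSE)
  if (any(v < 0))
    stop("sensor loads must be non-negative", call. = FALSE)
  v
}

# Vectorised com for an n x 24 frame matrix: returns n x 2 matrix.
com_from_frames <- function(frames, layout, weight) {
  cm <- frames %*% layout_coords(layout) / weight
  colnames(cm) <- c("x", "y")
  cm
}

#' Estimate the calibration weight from a frame sequence
#'
#' The player's weight is the normalising constant of [compute_com()].
#' It is estimated as the median per-frame sensor total over frames where
#' the player stands centred (both provisional centre-of-mass components
#' within 0.1 in magnitude), after discarding frames whose total falls
#' below `dropout_frac` of the running median of totals (sensor dropout).
#' If no centred frame survives, the median over all surviving frames is
#' used.
#'
#' @param frames n x 24 matrix of sensor loads (one row per frame), or a
#'   list of frames accepted by [compute_com()].
#' @param layout An [ebb_layout()], used to find centred frames.
#' @param dropout_frac Frames with totals below this fraction of the
#'   running median are treated as dropouts. Default 0.2.
#' @return Estimated weight (load units).
#' @export
estimate_weight <- function(frames, layout = ebb_layout(),
                            dropout_frac = 0.2) {
  frames <- as_frame_matrix(frames)
  if (nrow(frames) == 0L)
    stop("cannot estimate weight from an empty frame sequence",
         call. = FALSE)
  totals <- rowSums(frames)
  n <- length(totals)
  ref <- if (n >= 3L) runmed(totals, k = min(21L, n - (1L - n %% 2L)))
         else rep(median(totals), n)
  keep <- totals >= dropout_frac * ref & totals > 0
  if (!any(keep)) keep <- totals > 0
  if (!any(keep))
    stop("all frames have zero total load", call. = FALSE)
  provisional <- median(totals[keep])
  cm <- com_from_frames(frames, layout, provisional)
  centred <- keep & abs(cm[, 1]) <= 0.1 & abs(cm[, 2]) <= 0.1
  if (any(centred)) median(totals[centred]) else provisional
}

as_frame_matrix <- function(frames) {
  if (is.matrix(frames) && ncol(frames) == 24L) return(frames)
  if (is.list(frames))
    return(do.call(rbind, lapply(frames, frame_values)))
  if (is.numeric(frames) && length(frames) == 24L)
    return(matrix(frames, nrow = 1L))
  stop("frames must be an n x 24 matrix or a list of 24-value frames",
       call. = FALSE)
}

#' Assemble a playthrough from raw sensor frames
#'
#' A playthrough is one game level's recording: the ordered frames, the
#' derived centre-of-mass series, the calibration weight, and QC counts.
#' Frames are assumed uniformly spaced at 20 Hz; sample index `t` is
#' 0-based, so wall time is `t / 20` seconds.
#'
#' @param frames n x 24 matrix (or list) of sensor frames.
#' @param layout An [ebb_layout()].
#' @param weight Optional known weight; estimated with [estimate_weight()]
#'   when `NULL`.
#' @param player_id,level_id Identifiers carried into logs and feature
#'   tables.
#' @param label Optional class label (`"fit"` / `"not_fit"`).
#' @return An `ebb_playthrough`: list with `player_id`, `level_id`,
#'   `weight`, `frames`, `com` (n x 2 matrix), `n_com`, `label`, `qc`.
#' @export
build_playthrough <- function(frames, layout = ebb_layout(), weight = NULL,
                              player_id = "anon", level_id = "1",
                              label = NA_character_) {
  frames <- as_frame_matrix(frames)
  if (nrow(frames) == 0L)
    stop("frames must be non-empty", call. = FALSE)
  if (anyNA(frames) || any(frames < 0))
    stop("frames must contain 24 non-negative values each", call. = FALSE)
  if (is.null(weight)) weight <- estimate_weight(frames, layout)
  if (!is.finite(weight) || weight <= 0)
    stop("weight must be positive", call. = FALSE)
  cm <- com_from_frames(frames, layout, weight)
  new_playthrough(com = cm, weight = weight, frames = frames,
                  player_id = player_id, level_id = level_id, label = label)
}

# Construct the ebb_playthrough container from a finished com series.
new_playthrough <- function(com, weight, frames = NULL, player_id = "anon",
                            level_id = "1", label = NA_character_,
                            if_values = NULL, steps = NULL,
                            age = NA_real_, sex = NA_character_) {
  stopifnot(is.matrix(com), ncol(com) == 2L)
  colnames(com) <- c("x", "y")
  out_of_range <- sum(abs(com[, 1]) > 1 | abs(com[, 2]) > 1)
  structure(list(
    player_id = player_id, level_id = level_id,
    age = age, sex = sex,
    weight = weight, frames = frames,
    com = com, n_com = nrow(com),
    if_values = if_values, steps = steps, label = label,
    qc = list(out_of_range_com = out_of_range)
  ), class = "ebb_playthrough")
}

#' @export
print.ebb_playthrough <- function(x, ...) {
  cat("EBB playthrough: player", x$player_id, "level", x$level_id, "\n")
  cat(sprintf("  %d samples (%.1f s at 20 Hz), weight %.1f\n",
              x$n_com, x$n_com / 20, x$weight))
  if (!is.na(x$label)) cat("  label:", x$label, "\n")
  if (x$qc$out_of_range_com > 0)
    cat("  QC: ", x$qc$out_of_range_com, " com samples out of [-1,1]^2\n",
        sep = "")
  invisible(x)
}
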