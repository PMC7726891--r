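#' Directional intention of centre-of-mass samples
#'
#' A com sample expresses a directional intention when its main axis
#' reaches at least `main` (0.5) in magnitude while the other axis stays
#' within `off` (0.1): Up/Down on the y axis, Right/Left on the x axis.
#' Both axes within `off` is Center; anything else is Undetermined (a
#' transition sample). The six labels partition the plane, so every sample
#' gets exactly one label. Thresholds are inclusive.
#'
#' @param com n x 2 matrix (columns x, y), a length-2 vector, or a
#'   playthrough's `$com`.
#' @param main Main-axis threshold (default 0.5).
#' @param off Off-axis tolerance (default 0.1).
#' @return Factor of length n with levels Up, Down, Left, Right, Center,
#'   Undetermined.
#' @examples
#' classify_intention(c(0.1, 0.9))    # Up
#' classify_intention(c(-0.8, 0.05))  # Left
#' @export
classify_intention <- function(com, main = 0.5, off = 0.1) {
  cm <- as_com_matrix(com)
  if (anyNA(cm) || any(!is.finite(cm)))
    stop("com samples must be finite", call. = FALSE)
  x <- cm[, 1]; y <- cm[, 2]
  lab <- rep("Undetermined", length(x))
  lab[y >= main & abs(x) <= off] <- "Up"
  lab[y <= -main & abs(x) <= off] <- "Down"
  lab[x >= main & abs(y) <= off] <- "Right"
  lab[x <= -main & abs(y) <= off] <- "Left"
  lab[abs(x) <= off & abs(y) <= off] <- "Center"
  factor(lab, levels = intention_levels())
}

intention_levels <- function()
  c("Up", "Down", "Left", "Right", "Center", "Undetermined")

as_com_matrix <- function(com) {
  if (inherits(com, "ebb_playthrough")) com <- com$com
  if (is.matrix(com)) {
    stopifnot(ncol(com) == 2L)
    return(com)
  }
  if (is.numeric(com) && length(com) == 2L)
    return(matrix(com, nrow = 1L, dimnames = list(NULL, c("x", "y"))))
  stop("com must be an n x 2 matrix or a length-2 vector", call. = FALSE)
}

#' Detect step events with the return-to-centre state machine
#'
#' The exergame registers a step when the player shifts onto a directional
#' pose, and requires a return to centre before the next step counts. The
#' detector starts ARMED; the first direction-labelled sample while armed
#' emits a step and disarms; a Center sample re-arms; Undetermined samples
#' change no state. With `dwell > 0`, a directional run only registers once
#' it has lasted `dwell` consecutive samples (the event time is still the
#' run's first sample).
#'
#' @inheritParams classify_intention
#' @param dwell Minimum run length, in samples, before a pose registers
#'   (default 1, i.e. immediate registration at pose entry).
#' @return Data frame of step events: `t` (0-based sample index),
#'   `direction`, `step_time` (seconds, `t / 20`).
#' @export
detect_steps <- function(com, main = 0.5, off = 0.1, dwell = 1L) {
  labels <- if (is.factor(com)) com else classify_intention(com, main, off)
  dwell <- max(1L, as.integer(dwell))
  armed <- TRUE
  run_dir <- NA_character_; run_start <- NA_integer_; run_len <- 0L
  t_out <- integer(0); dir_out <- character(0)
  lab <- as.character(labels)
  for (i in seq_along(lab)) {
    li <- lab[i]
    if (li == "Center") {
      armed <- TRUE; run_dir <- NA_character_; run_len <- 0L
    } else if (li == "Undetermined") {
      run_dir <- NA_character_; run_len <- 0L
    } else {
      if (identical(li, run_dir)) run_len <- run_len + 1L
      else { run_dir <- li; run_start <- i; run_len <- 1L }
      if (armed && run_len >= dwell) {
        t_out <- c(t_out, run_start - 1L)  # 0-based
        dir_out <- c(dir_out, li)
        armed <- FALSE
      }
    }
  }
  data.frame(t = t_out,
             direction = factor(dir_out,
                                levels = c("Up", "Down", "Left", "Right")),
             step_time = t_out / 20)
}

#' Per-direction sample masks
#'
#' For each direction, the indices of samples satisfying that direction's
#' intention condition, independent of the step state machine. The mask
#' sizes are the `n_COM,Direction` denominators of the directional feature
#' statistics.
#'
#' @inheritParams classify_intention
#' @return Named list `up`, `down`, `left`, `right` of integer index
#'   vectors (1-based).
#' @export
direction_masks <- function(com, main = 0.5, off = 0.1) {
  labels <- if (is.factor(com)) com else classify_intention(com, main, off)
  list(up = which(labels == "Up"), down = which(labels == "Down"),
       left = which(labels == "Left"), right = which(labels == "Right"))
}
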