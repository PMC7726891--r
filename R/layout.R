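#' Board-array layouts
#'
#' An `ebb_layout` assigns a dimensionless (x, y) coordinate in \[-1, 1\]^2
#' to each of the 24 load sensors (6 boards x 4 corner sensors). The
#' coordinate matrix is what projects raw sensor loads onto the board plane
#' in [compute_com()]. The default layout is a plus/cross arrangement: two
#' central boards jointly covering \[-0.33, 0.33\]^2 and four outer boards
#' (up, down, left, right) whose far edges reach +/-1, so that a full step
#' onto an outer board pushes the main centre-of-mass axis well past the
#' 0.5 intention threshold while the off-axis stays near 0.
#'
#' Within a board, sensors are numbered 1..4 in the order: (xmin, ymin),
#' (xmax, ymin), (xmin, ymax), (xmax, ymax).
#'
#' @param boards A list of 6 board rectangles, each `list(x = c(xmin, xmax),
#'   y = c(ymin, ymax))`. Defaults to the plus/cross arrangement.
#' @return An `ebb_layout`: data frame with columns `board`, `sensor`,
#'   `x`, `y` (24 rows, board-major order).
#' @examples
#' lay <- ebb_layout()
#' head(lay)
#' @export
ebb_layout <- function(boards = default_boards()) {
  if (length(boards) != 6L)
    stop("an EBB layout needs exactly 6 boards", call. = FALSE)
  rows <- lapply(seq_along(boards), function(i) {
    b <- boards[[i]]
    x <- sort(as.numeric(b$x)); y <- sort(as.numeric(b$y))
    if (length(x) != 2L || length(y) != 2L || any(!is.finite(c(x, y))))
      stop("board ", i, ": need finite x = c(xmin, xmax), y = c(ymin, ymax)",
           call. = FALSE)
    data.frame(board = i, sensor = 1:4,
               x = c(x[1], x[2], x[1], x[2]),
               y = c(y[1], y[1], y[2], y[2]))
  })
  lay <- do.call(rbind, rows)
  class(lay) <- c("ebb_layout", "data.frame")
  validate_layout(lay)
  lay
}

default_boards <- function() {
  list(
    list(x = c(-0.33, 0.00), y = c(-0.33, 0.33)),  # centre-left
    list(x = c(0.00, 0.33),  y = c(-0.33, 0.33)),  # centre-right
    list(x = c(-0.33, 0.33), y = c(0.33, 1.00)),   # up
    list(x = c(-0.33, 0.33), y = c(-1.00, -0.33)), # down
    list(x = c(-1.00, -0.33), y = c(-0.33, 0.33)), # left
    list(x = c(0.33, 1.00),  y = c(-0.33, 0.33))   # right
  )
}

#' Validate a board layout
#'
#' Checks the layout invariants: exactly 24 sensor entries, all coordinates
#' in \[-1, 1\], and the four sensors of each board forming an axis-aligned
#' rectangle (the corners of the physical board).
#'
#' @param layout An `ebb_layout`.
#' @return The layout, invisibly; errors on violation.
#' @export
validate_layout <- function(layout) {
  if (nrow(layout) != 24L)
    stop("layout must have exactly 24 sensor entries", call. = FALSE)
  if (any(!is.finite(layout$x)) || any(!is.finite(layout$y)) ||
      any(abs(layout$x) > 1) || any(abs(layout$y) > 1))
    stop("sensor coordinates must be finite and within [-1, 1]",
         call. = FALSE)
  for (b in unique(layout$board)) {
    sub <- layout[layout$board == b, ]
    if (nrow(sub) != 4L || !setequal(sub$sensor, 1:4))
      stop("board ", b, " must have sensors 1..4", call. = FALSE)
    ux <- unique(sub$x); uy <- unique(sub$y)
    if (length(ux) != 2L || length(uy) != 2L ||
        nrow(unique(sub[, c("x", "y")])) != 4L)
      stop("board ", b, ": sensors must form an axis-aligned rectangle",
           call. = FALSE)
  }
  invisible(layout)
}

# 24 x 2 coordinate matrix in board-major sensor order.
layout_coords <- function(layout) {
  ord <- order(layout$board, layout$sensor)
  as.matrix(layout[ord, c("x", "y")])
}

# Per-board bounding rectangles: data frame board, xmin, xmax, ymin, ymax.
board_rects <- function(layout) {
  do.call(rbind, lapply(sort(unique(layout$board)), function(b) {
    sub <- layout[layout$board == b, ]
    data.frame(board = b, xmin = min(sub$x), xmax = max(sub$x),
               ymin = min(sub$y), ymax = max(sub$y))
  }))
}

#' Read or write a layout configuration file
#'
#' Layout configs are YAML or JSON (by file extension) mapping each board to
#' its rectangle: `boards: [{x: [xmin, xmax], y: [ymin, ymax]}, ...]`. Files
#' are validated on load so any physical board arrangement can be expressed
#' without touching code.
#'
#' @param path File path; `.yaml`/`.yml` or `.json`.
#' @param layout An `ebb_layout` (for writing).
#' @return `read_layout()` returns an `ebb_layout`; `write_layout()` the
#'   path, invisibly.
#' @export
read_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (is.null(cfg$boards))
    stop("layout config must have a top-level 'boards' list", call. = FALSE)
  boards <- lapply(cfg$boards, function(b)
    list(x = as.numeric(unlist(b$x)), y = as.numeric(unlist(b$y))))
  ebb_layout(boards)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  rects <- board_rects(layout)
  boards <- lapply(seq_len(nrow(rects)), function(i)
    list(x = c(rects$xmin[i], rects$xmax[i]),
         y = c(rects$ymin[i], rects$ymax[i])))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json")
    jsonlite::write_json(list(boards = boards), path, auto_unbox = FALSE,
                         digits = NA)
  else yaml::write_yaml(list(boards = boards), path)
  invisible(path)
}
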