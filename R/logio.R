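#' Write a playthrough log
#'
#' Serialises one playthrough to the XML log format produced per game
#' level: a `player` block (id, weight, optional age/sex), a `level` block
#' (level id, steps-taken count), a `samples` block with one `<s>` element
#' per 20 Hz sample carrying `t`, `x`, `y` and `if` attributes, an optional
#' `raw` block with the 24 sensor loads per frame, and an optional `steps`
#' block with the registered step events. Numbers are serialised with six
#' decimal places. The schema is bundled as
#' `system.file("extdata", "playthrough.xsd", package = "ebbmetrics")`.
#'
#' @param playthrough An `ebb_playthrough` with a non-empty com series.
#' @param path Output file path.
#' @param include_raw Write the raw sensor frames when present.
#' @param include_steps Write detected step events.
#' @param digits Decimal places for serialised numbers.
#' @return `path`, invisibly.
#' @export
write_log <- function(playthrough, path, include_raw = TRUE,
                      include_steps = TRUE, digits = 6L) {
  pt <- playthrough
  if (!inherits(pt, "ebb_playthrough"))
    stop("write_log() needs an ebb_playthrough", call. = FALSE)
  if (is.null(pt$com) || nrow(pt$com) == 0L)
    stop_ebb("refusing to write a log with an empty com series",
             "ebb_validation_error")
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  if_values <- pt$if_values
  if (is.null(if_values)) if_values <- compute_if(pt$com)
  n <- nrow(pt$com)
  steps <- pt$steps
  if (is.null(steps) && include_steps) steps <- detect_steps(pt$com)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<playthrough>",
    sprintf("  <player id=\"%s\" weight=\"%s\"%s%s/>",
            xml_escape(pt$player_id), fmt(pt$weight),
            if (!is.na(pt$age)) sprintf(" age=\"%g\"", pt$age) else "",
            if (!is.na(pt$sex))
              sprintf(" sex=\"%s\"", xml_escape(pt$sex)) else ""),
    sprintf("  <level id=\"%s\" steps=\"%d\"/>",
            xml_escape(pt$level_id),
            if (is.null(steps)) 0L else nrow(steps)),
    sprintf("  <samples n=\"%d\">", n),
    sprintf("    <s t=\"%d\" x=\"%s\" y=\"%s\" if=\"%s\"/>",
            seq_len(n) - 1L, fmt(pt$com[, 1]), fmt(pt$com[, 2]),
            fmt(if_values)),
    "  </samples>")
  if (include_steps && !is.null(steps) && nrow(steps) > 0L) {
    lines <- c(lines,
               sprintf("  <steps n=\"%d\">", nrow(steps)),
               sprintf("    <step t=\"%d\" dir=\"%s\"/>",
                       steps$t, as.character(steps$direction)),
               "  </steps>")
  }
  if (include_raw && !is.null(pt$frames)) {
    vals <- apply(pt$frames, 1, function(r) paste(fmt(r), collapse = " "))
    lines <- c(lines,
               sprintf("  <raw n=\"%d\">", n),
               sprintf("    <f t=\"%d\" v=\"%s\"/>", seq_len(n) - 1L, vals),
               "  </raw>")
  }
  lines <- c(lines, "</playthrough>")
  writeLines(lines, path)
  invisible(path)
}

xml_escape <- function(s)
  gsub(">", "&gt;", gsub("<", "&lt;", gsub("&", "&amp;", as.character(s))))

#' Read a playthrough log
#'
#' Parses and validates one XML playthrough log. Three failure modes are
#' distinguished by condition class so batch ingestion can account for
#' them: `ebb_parse_error` (malformed XML), `ebb_validation_error` (schema
#' violation, reported with the offending element), and
#' `ebb_data_failure` (structurally valid but corrupt data: truncated or
#' gapped sample block, raw frames that do not reproduce the stored com).
#'
#' @param path Log file path.
#' @param layout Layout used to recompute com from raw frames.
#' @param recompute Recompute the instability series from com and warn if
#'   it disagrees with the stored values by more than `1e-4`.
#' @param raw_tol Maximum |stored - recomputed| com discrepancy tolerated
#'   when a raw block is present.
#' @return An `ebb_playthrough`.
#' @export
read_log <- function(path, layout = ebb_layout(), recompute = FALSE,
                     raw_tol = 1e-6) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_ebb(paste0("malformed XML in ", path, ": ",
                    conditionMessage(e)), "ebb_parse_error"))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "playthrough")
    stop_ebb("root element must be <playthrough>", "ebb_validation_error")

  player <- xml2::xml_find_first(root, "./player")
  level <- xml2::xml_find_first(root, "./level")
  samples <- xml2::xml_find_first(root, "./samples")
  for (blk in list(c("player", inherits(player, "xml_missing")),
                   c("level", inherits(level, "xml_missing")),
                   c("samples", inherits(samples, "xml_missing"))))
    if (as.logical(blk[2]))
      stop_ebb(paste0("missing <", blk[1], "> block"),
               "ebb_validation_error")

  weight <- as.numeric(xml2::xml_attr(player, "weight"))
  if (!is.finite(weight) || weight <= 0)
    stop_ebb("player weight missing or non-positive at <player>",
             "ebb_validation_error")

  s_nodes <- xml2::xml_find_all(samples, "./s")
  n_declared <- as.integer(xml2::xml_attr(samples, "n"))
  if (length(s_nodes) == 0L)
    stop_ebb("empty <samples> block", "ebb_data_failure")
  if (!is.na(n_declared) && n_declared != length(s_nodes))
    stop_ebb(sprintf(
      "truncated sample block: %d samples declared, %d present",
      n_declared, length(s_nodes)), "ebb_data_failure")

  t_idx <- as.integer(xml2::xml_attr(s_nodes, "t"))
  x <- as.numeric(xml2::xml_attr(s_nodes, "x"))
  y <- as.numeric(xml2::xml_attr(s_nodes, "y"))
  if_stored <- as.numeric(xml2::xml_attr(s_nodes, "if"))
  if (anyNA(t_idx) || anyNA(x) || anyNA(y) || anyNA(if_stored) ||
      any(!is.finite(c(x, y, if_stored))))
    stop_ebb("non-numeric sample attributes in <samples>",
             "ebb_validation_error")
  if (any(diff(t_idx) != 1L) || t_idx[1] != 0L)
    stop_ebb("gap in sample indices (t must run 0,1,2,...)",
             "ebb_data_failure")

  cm <- cbind(x = x, y = y)

  frames <- NULL
  raw <- xml2::xml_find_first(root, "./raw")
  if (!inherits(raw, "xml_missing")) {
    f_nodes <- xml2::xml_find_all(raw, "./f")
    if (length(f_nodes) != nrow(cm))
      stop_ebb("raw block length does not match sample block",
               "ebb_data_failure")
    parsed <- lapply(strsplit(xml2::xml_attr(f_nodes, "v"), " ",
                              fixed = TRUE),
                     function(s) suppressWarnings(as.numeric(s)))
    if (any(lengths(parsed) != 24L) || anyNA(unlist(parsed)))
      stop_ebb("raw frame with missing sensor values", "ebb_data_failure")
    frames <- do.call(rbind, parsed)
    rec <- com_from_frames(frames, layout, weight)
    if (max(abs(rec - cm)) > raw_tol)
      stop_ebb(sprintf(
        "raw frames do not reproduce stored com (max dev %.2e)",
        max(abs(rec - cm))), "ebb_data_failure")
  }

  if_values <- if_stored
  if (recompute) {
    rec_if <- compute_if(cm)
    if (max(abs(rec_if - if_stored)) > 1e-4)
      warning(sprintf(
        "stored if(t) deviates from recomputed values by up to %.2e",
        max(abs(rec_if - if_stored))), call. = FALSE)
    if_values <- rec_if
  }

  steps_node <- xml2::xml_find_first(root, "./steps")
  steps <- NULL
  if (!inherits(steps_node, "xml_missing")) {
    st <- xml2::xml_find_all(steps_node, "./step")
    t_s <- as.integer(xml2::xml_attr(st, "t"))
    steps <- data.frame(
      t = t_s,
      direction = factor(xml2::xml_attr(st, "dir"),
                         levels = c("Up", "Down", "Left", "Right")),
      step_time = t_s / 20)
  }

  age <- suppressWarnings(as.numeric(xml2::xml_attr(player, "age")))
  new_playthrough(com = cm, weight = weight, frames = frames,
                  player_id = xml2::xml_attr(player, "id"),
                  level_id = xml2::xml_attr(level, "id"),
                  if_values = if_values, steps = steps,
                  age = age, sex = xml2::xml_attr(player, "sex"))
}

#' Batch-ingest playthrough logs with discard accounting
#'
#' Reads every log in `paths`, keeping the playthroughs that parse and
#' validate, and counting the ones discarded for data failure — mirroring
#' field deployments where e.g. low sensor batteries corrupt a fraction of
#' the recorded levels.
#'
#' @param paths Character vector of log file paths.
#' @inheritParams read_log
#' @return List with `playthroughs` (the accepted ones), `n_accepted`,
#'   `n_discarded`, and `discards` (data frame of path + error message +
#'   error class).
#' @export
read_logs <- function(paths, layout = ebb_layout(), recompute = FALSE) {
  kept <- list(); disc <- list()
  for (p in paths) {
    res <- tryCatch(read_log(p, layout = layout, recompute = recompute),
                    ebb_error = function(e) e)
    if (inherits(res, "ebb_playthrough")) kept[[length(kept) + 1L]] <- res
    else disc[[length(disc) + 1L]] <-
        data.frame(path = p, message = conditionMessage(res),
                   class = class(res)[1], stringsAsFactors = FALSE)
  }
  list(playthroughs = kept,
       n_accepted = length(kept),
       n_discarded = length(disc),
       discards = if (length(disc)) do.call(rbind, disc)
                  else data.frame(path = character(0),
                                  message = character(0),
                                  class = character(0)))
}

#' Write / read a feature table
#'
#' Feature tables hold one row per playthrough: `player_id`, `label`, then
#' the 42 features in [feature_names()] order. CSV encodes missing values
#' as empty fields; ARFF (for attribute-based ML tools) encodes them as
#' `?`.
#'
#' @param table Data frame from [feature_table()].
#' @param path Output path.
#' @param format `"csv"` or `"arff"`; default inferred from the extension.
#' @return `path` (write) or the data frame (read).
#' @export
write_feature_table <- function(table, path, format = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("feature table must be a non-empty data frame", call. = FALSE)
  need <- c("player_id", "label", feature_names())
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("feature table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  table <- table[, need]
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "csv") {
    write.csv(table, path, row.names = FALSE, na = "")
  } else if (format == "arff") {
    tab <- table
    tab$label <- factor(tab$label, levels = c("fit", "not_fit"))
    foreign::write.arff(tab, path)
  } else stop("format must be 'csv' or 'arff'", call. = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  tab <- if (format == "csv")
    read.csv(path, stringsAsFactors = FALSE)
  else if (format == "arff") foreign::read.arff(path)
  else stop("format must be 'csv' or 'arff'", call. = FALSE)
  names(tab) <- sub("^X(if_(threshold|sum_over)_)", "\\1", names(tab))
  tab$label <- as.character(tab$label)
  tab
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
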