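#' Section definitions for a recording
#'
#' Sections partition a walking course ("parcours") into named intervals on
#' the recording clock, e.g. hallway, stairs, outdoor. Stairs carry
#' `include_in_speed = FALSE`: the measuring wheel cannot be used on stairs,
#' so those intervals contribute to step counts but are excluded from all
#' speed calculations.
#'
#' @param name Character vector of section names.
#' @param t_start,t_end Section bounds in seconds (recording clock);
#'   `t_start < t_end`, sections must not overlap.
#' @param include_in_speed Logical; `FALSE` for stairs.
#' @param is_walking Logical; `FALSE` for rest intervals.
#' @return A `data.frame` of class `section_definitions`.
#' @export
section_definitions <- function(name, t_start, t_end,
                                include_in_speed = TRUE, is_walking = TRUE) {
  df <- data.frame(name = as.character(name),
                   t_start = as.numeric(t_start), t_end = as.numeric(t_end),
                   include_in_speed = rep_len(include_in_speed, length(name)),
                   is_walking = rep_len(is_walking, length(name)),
                   stringsAsFactors = FALSE)
  if (any(df$t_start >= df$t_end)) stop("each section needs t_start < t_end")
  o <- order(df$t_start)
  if (any(df$t_end[o][-nrow(df)] > df$t_start[o][-1] + 1e-9))
    stop("sections overlap")
  class(df) <- c("section_definitions", "data.frame")
  df
}

#' Read section definitions from a key-list config block
#'
#' Format: one `section:` line starting each block, followed by indented
#' `key: value` lines (`name`, `t_start`, `t_end`, `include_in_speed`,
#' `is_walking`). Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return A [section_definitions()] table.
#' @export
read_sections <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  blocks <- list(); cur <- NULL
  for (ln in lines) {
    if (grepl("^section\\s*:", ln)) {
      if (!is.null(cur)) blocks[[length(blocks) + 1]] <- cur
      cur <- list()
    } else if (!is.null(cur)) {
      kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(kv) >= 2)
        cur[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1]] <- cur
  if (!length(blocks)) stop("no section blocks in ", path)
  as_lgl <- function(x, default) {
    if (is.null(x)) default else tolower(x) %in% c("true", "yes", "1")
  }
  section_definitions(
    name = vapply(blocks, function(b) b$name, ""),
    t_start = vapply(blocks, function(b) as.numeric(b$t_start), 0),
    t_end = vapply(blocks, function(b) as.numeric(b$t_end), 0),
    include_in_speed = vapply(blocks, function(b) as_lgl(b$include_in_speed, TRUE), TRUE),
    is_walking = vapply(blocks, function(b) as_lgl(b$is_walking, TRUE), TRUE))
}

#' Write section definitions
#' @param sections A [section_definitions()] table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sections <- function(sections, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(sections))) {
    writeLines(c("section:",
                 sprintf("  name: %s", sections$name[i]),
                 sprintf("  t_start: %.10g", sections$t_start[i]),
                 sprintf("  t_end: %.10g", sections$t_end[i]),
                 sprintf("  include_in_speed: %s",
                         tolower(sections$include_in_speed[i])),
                 sprintf("  is_walking: %s", tolower(sections$is_walking[i]))),
               con)
  }
  invisible(path)
}
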