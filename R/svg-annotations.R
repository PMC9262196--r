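# Instance annotations as SVG paths: the interchange format used to draw
# insect outlines in a vector editor. Absolute M/L/C/Z commands (and their
# relative m/l/c/z forms) are supported; cubic Bezier segments are flattened.

# Tokenise an SVG path `d` attribute into commands and numbers.
svg_path_tokens <- function(d) {
  d <- gsub(",", " ", d)
  d <- gsub("([MmLlCcZzHhVv])", " \\1 ", d)
  d <- gsub("([0-9])-", "\\1 -", d)
  toks <- strsplit(trimws(d), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

# Flatten one path into a polygon matrix; returns NULL (with a reason
# attribute) for unclosed or degenerate paths.
svg_path_polygon <- function(d, bezier_steps = 8) {
  toks <- svg_path_tokens(d)
  pts <- matrix(numeric(0), ncol = 2)
  cur <- c(0, 0); start <- NULL; cmd <- NULL; closed <- FALSE
  i <- 1L
  num <- function(k) as.numeric(toks[k])
  while (i <= length(toks)) {
    if (grepl("^[MmLlCcZzHhVv]$", toks[i])) { cmd <- toks[i]; i <- i + 1L }
    if (is.null(cmd)) return(NULL)
    if (cmd %in% c("Z", "z")) { closed <- TRUE; cmd <- NULL; next }
    if (cmd %in% c("M", "m", "L", "l")) {
      p <- c(num(i), num(i + 1)); i <- i + 2L
      if (cmd %in% c("m", "l")) p <- cur + p
      cur <- p
      if (is.null(start)) start <- p
      pts <- rbind(pts, p)
      # subsequent coordinate pairs after M behave as L (SVG spec)
      if (cmd == "M") cmd <- "L"
      if (cmd == "m") cmd <- "l"
    } else if (cmd %in% c("H", "h", "V", "v")) {
      val <- num(i); i <- i + 1L
      p <- switch(cmd, H = c(val, cur[2]), h = cur + c(val, 0),
                  V = c(cur[1], val), v = cur + c(0, val))
      cur <- p; pts <- rbind(pts, p)
    } else if (cmd %in% c("C", "c")) {
      cps <- c(num(i), num(i + 1), num(i + 2), num(i + 3), num(i + 4),
               num(i + 5)); i <- i + 6L
      if (cmd == "c") cps <- cps + rep(cur, 3)
      p0 <- cur; p1 <- cps[1:2]; p2 <- cps[3:4]; p3 <- cps[5:6]
      tt <- seq_len(bezier_steps) / bezier_steps
      bx <- (1 - tt)^3 * p0[1] + 3 * (1 - tt)^2 * tt * p1[1] +
        3 * (1 - tt) * tt^2 * p2[1] + tt^3 * p3[1]
      by <- (1 - tt)^3 * p0[2] + 3 * (1 - tt)^2 * tt * p1[2] +
        3 * (1 - tt) * tt^2 * p2[2] + tt^3 * p3[2]
      pts <- rbind(pts, cbind(bx, by))
      cur <- p3
    } else {
      return(NULL)
    }
  }
  if (!closed) return(NULL)
  if (nrow(pts) < 3) return(NULL)
  # drop an explicit closing vertex duplicating the start
  if (all(abs(pts[nrow(pts), ] - pts[1, ]) < 1e-9))
    pts <- pts[-nrow(pts), , drop = FALSE]
  unname(pts)
}

#' Read instance annotations from an SVG document
#'
#' Every closed `<path>` element becomes one detection instance; overlapping
#' contours of adjacent animals are allowed. Unclosed or unsupported paths
#' are skipped with a single warning carrying the count; any embedded raster
#' image is ignored.
#'
#' @param path file path (or literal SVG string) of an SVG 1.1 document.
#' @param frame_id,time frame metadata attached to each instance.
#' @param filter apply the standard size filter ([filter_by_size()])?
#' @param min_len,max_len size-filter bounds when `filter = TRUE`.
#' @return List of [new_instance()] records.
#' @export
read_svg_annotations <- function(path, frame_id = NA_integer_, time = NA,
                                 filter = FALSE, min_len = 30,
                                 max_len = 600) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed SVG: ", conditionMessage(e), call. = FALSE))
  paths <- xml2::xml_find_all(doc, ".//*[local-name() = 'path']")
  out <- list(); skipped <- 0L
  for (p in paths) {
    d <- xml2::xml_attr(p, "d")
    if (is.na(d)) { skipped <- skipped + 1L; next }
    poly <- svg_path_polygon(d)
    if (is.null(poly)) { skipped <- skipped + 1L; next }
    id <- xml2::xml_attr(p, "id")
    out[[length(out) + 1L]] <- new_instance(
      poly, frame_id = frame_id, time = time,
      id = if (is.na(id)) length(out) + 1L else id)
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d unusable path(s)", skipped), call. = FALSE)
  if (filter) out <- filter_by_size(out, min_len, max_len)
  out
}

#' Write instances as an SVG annotation document
#'
#' Inverse of [read_svg_annotations()]: one absolute `M/L/Z` path per
#' instance. Round-tripping preserves vertex counts and areas.
#'
#' @param instances list of instances.
#' @param path output file.
#' @param width,height canvas size in px.
#' @export
write_svg_annotations <- function(instances, path, width = 2592,
                                  height = 1944) {
  path_d <- vapply(instances, function(inst) {
    v <- inst$polygon
    paste0("M ", paste(sprintf("%.3f %.3f", v[, 1], v[, 2]),
                       collapse = " L "), " Z")
  }, character(1))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            width, height),
    sprintf('  <path id="i%d" d="%s" fill="none" stroke="red"/>',
            seq_along(instances), path_d),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}
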