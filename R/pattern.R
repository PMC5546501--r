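#' Immunogold point pattern
#'
#' A set of gold-particle coordinates observed inside a rectangular window,
#' together with the labels needed for grouped analysis. Coordinates are
#' continuous nanometre positions with the origin at the window's lower-left
#' corner, y increasing upward; both window edges are included
#' (`0 <= x <= width`, `0 <= y <= height`).
#'
#' Duplicate coordinates are permitted — the K-function estimator is defined
#' for them — but a physical gold particle excludes others from its own
#' footprint, so duplicates are worth flagging with [validate_pattern()].
#'
#' @param x,y Numeric vectors of equal length: particle positions in nm.
#' @param window An [nc_window()].
#' @param image_id Label identifying the source image / membrane sheet.
#' @param condition Label identifying the experimental condition.
#'
#' @return An object of class `"point_pattern"`: a list with elements `x`,
#'   `y`, `n`, `window`, `image_id`, `condition`.
#' @examples
#' pp <- point_pattern(c(100, 200), c(100, 200), nc_window(1000))
#' pp$n
#' @seealso [read_point_pattern()], [validate_pattern()], [k_function()]
#' @export
point_pattern <- function(x, y, window, image_id = NA_character_,
                          condition = NA_character_) {
  window <- assert_window(window)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("coordinates must not contain NA", call. = FALSE)
  }
  bad <- x < 0 | x > window$width | y < 0 | y > window$height
  if (any(bad)) {
    stop(sprintf("%d point(s) fall outside the %g x %g nm window (first at row %d)",
                 sum(bad), window$width, window$height, which(bad)[1L]),
         call. = FALSE)
  }
  structure(
    list(x = x, y = y, n = length(x), window = window,
         image_id = as.character(image_id), condition = as.character(condition)),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in %g x %g nm window\n",
              x$n, x$window$width, x$window$height))
  if (!is.na(x$image_id))  cat(" image_id:  ", x$image_id, "\n", sep = "")
  if (!is.na(x$condition)) cat(" condition: ", x$condition, "\n", sep = "")
  invisible(x)
}

is_point_pattern <- function(x) inherits(x, "point_pattern")

assert_pattern <- function(pattern) {
  if (!is_point_pattern(pattern)) {
    stop("expected a `point_pattern` object", call. = FALSE)
  }
  pattern
}

#' Read a point pattern from a delimited coordinate table
#'
#' Reads a two-column numeric table of x/y gold-particle coordinates (nm).
#' The delimiter (comma, tab or whitespace) is detected automatically and a
#' single header line is skipped if present. An empty file yields a valid
#' empty pattern.
#'
#' Out-of-window coordinates violate the premise that the window is the full
#' study area, so they are an error by default. `mode = "clip"` instead snaps
#' points within `clip_tolerance` of the boundary onto it (digitisation
#' slop); points beyond the tolerance remain an error.
#'
#' @param path Path to a CSV/TSV/whitespace-delimited file with columns x, y.
#' @param window An [nc_window()] giving the study area.
#' @param image_id,condition Labels attached to the pattern.
#' @param mode `"reject"` (default) errors on out-of-window points;
#'   `"clip"` snaps near-boundary points onto the boundary.
#' @param clip_tolerance Maximum distance (nm) a point may lie outside the
#'   window and still be clipped in `"clip"` mode. Default 1 nm.
#'
#' @return A `point_pattern`; coordinate order is preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x = c(100, 200), y = c(100, 200)), f, row.names = FALSE)
#' read_point_pattern(f, nc_window(1000))
#' @export
read_point_pattern <- function(path, window, image_id = NA_character_,
                               condition = NA_character_,
                               mode = c("reject", "clip"),
                               clip_tolerance = 1) {
  mode <- match.arg(mode)
  window <- assert_window(window)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(point_pattern(numeric(0), numeric(0), window, image_id, condition))
  }
  sep <- detect_delimiter(lines[[1L]])
  first <- strsplit(trimws(lines[[1L]]), sep)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first[first != ""])))
  if (has_header) lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(point_pattern(numeric(0), numeric(0), window, image_id, condition))
  }
  fields <- strsplit(trimws(lines), sep)
  ncol_seen <- lengths(fields)
  if (any(ncol_seen < 2L)) {
    stop(sprintf("row %d of %s has fewer than two columns",
                 which(ncol_seen < 2L)[1L] + has_header, path), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(x) || anyNA(y)) {
    stop(sprintf("non-numeric coordinate in %s (data row %d)",
                 path, which(is.na(x) | is.na(y))[1L]), call. = FALSE)
  }
  if (mode == "clip") {
    out <- pmax(0 - x, x - window$width, 0 - y, y - window$height, 0)
    if (any(out > clip_tolerance)) {
      stop(sprintf("point %.6g nm outside the window exceeds clip_tolerance = %g nm",
                   max(out), clip_tolerance), call. = FALSE)
    }
    x <- pmin(pmax(x, 0), window$width)
    y <- pmin(pmax(y, 0), window$height)
  }
  point_pattern(x, y, window, image_id, condition)
}

detect_delimiter <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  "[[:space:]]+"
}

#' Write a point pattern to CSV
#'
#' Writes the coordinates as a two-column CSV with header `x,y`, using full
#' double precision so that a read/write/read cycle round-trips coordinates
#' exactly.
#'
#' @param pattern A `point_pattern`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  assert_pattern(pattern)
  lines <- c("x,y",
             paste(format(pattern$x, digits = 17, scientific = FALSE, trim = TRUE),
                   format(pattern$y, digits = 17, scientific = FALSE, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Check a pattern for physically implausible point pairs
#'
#' Gold nanoparticles have a finite diameter (4.5 nm in the assay this
#' package models), so two labels cannot sit closer than the particle
#' footprint. This check warns about — but never removes or moves — point
#' pairs closer than `min_separation`, and about exact duplicates. The
#' pattern is returned unchanged; the offending pairs are attached as the
#' attribute `"close_pairs"` (a data.frame with columns `i`, `j`, `d`).
#'
#' @param pattern A `point_pattern`.
#' @param min_separation Minimum plausible pair distance in nm; `0`
#'   (default) disables the check entirely.
#' @return The input pattern, with attribute `"close_pairs"` when any pair
#'   falls below `min_separation`.
#' @examples
#' pp <- point_pattern(c(10, 12), c(10, 10), nc_window(1000))
#' validate_pattern(pp, min_separation = 4.5)  # warns: pair at 2 nm
#' @export
validate_pattern <- function(pattern, min_separation = 0) {
  assert_pattern(pattern)
  stopifnot(is.numeric(min_separation), length(min_separation) == 1L,
            min_separation >= 0)
  if (min_separation == 0 || pattern$n < 2L) {
    return(pattern)
  }
  d <- stats::dist(cbind(pattern$x, pattern$y))
  idx <- dist_pair_indices(pattern$n)
  close <- which(d < min_separation)
  if (length(close)) {
    pairs <- data.frame(i = idx$i[close], j = idx$j[close],
                        d = as.numeric(d[close]))
    pairs <- pairs[order(pairs$d), , drop = FALSE]
    rownames(pairs) <- NULL
    attr(pattern, "close_pairs") <- pairs
    ndup <- sum(pairs$d == 0)
    warning(sprintf(
      "%d point pair(s) closer than %g nm (closest %.3g nm%s)",
      nrow(pairs), min_separation, pairs$d[1L],
      if (ndup > 0) sprintf(", %d exact duplicate(s)", ndup) else ""),
      call. = FALSE)
  }
  pattern
}

# index vectors (i > j) matching the storage order of stats::dist
dist_pair_indices <- function(n) {
  j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- sequence((n - 1L):1L) + j
  list(i = i, j = j)
}

#' Group replicate patterns that share a condition
#'
#' Spatial-mapping studies summarise each condition over many independent
#' membrane sheets; published curve averages and bootstrap comparisons in
#' this assay use at least 15 sheets per condition. The group records that
#' requirement and refuses silently under-powered groups unless told not to.
#'
#' @param patterns A list of `point_pattern`s sharing one condition label.
#' @param minimum_images Minimum number of replicate patterns the group must
#'   contain before group-level analysis is meaningful. Default 15.
#' @param enforce_minimum If `TRUE` (default) an undersized group is an
#'   error; if `FALSE`, a warning.
#' @return An object of class `"condition_group"`: list with `patterns`,
#'   `condition`, `n_images`, `total_points`, `minimum_images`.
#' @export
condition_group <- function(patterns, minimum_images = 15,
                            enforce_minimum = TRUE) {
  if (!is.list(patterns) || !length(patterns) ||
      !all(vapply(patterns, is_point_pattern, logical(1)))) {
    stop("`patterns` must be a non-empty list of point_pattern objects",
         call. = FALSE)
  }
  conds <- unique(vapply(patterns, function(p) p$condition, character(1)))
  if (length(conds) != 1L) {
    stop(sprintf("patterns mix conditions: %s", paste(conds, collapse = ", ")),
         call. = FALSE)
  }
  if (length(patterns) < minimum_images) {
    msg <- sprintf("condition '%s' has %d image(s); %d required for group analysis",
                   conds, length(patterns), minimum_images)
    if (enforce_minimum) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(
    list(patterns = patterns, condition = conds,
         n_images = length(patterns),
         total_points = sum(vapply(patterns, function(p) p$n, numeric(1))),
         minimum_images = minimum_images),
    class = "condition_group"
  )
}

#' @export
print.condition_group <- function(x, ...) {
  cat(sprintf("condition group '%s': %d images, %d gold particles total\n",
              x$condition, x$n_images, x$total_points))
  invisible(x)
}
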