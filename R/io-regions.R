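## Region maps: labeled, disjoint alignment-column intervals (0-based,
## half-open). Canonical labels are B..W for the 13 LVRs of 18S and D2..D11
## (with D3-1/D3-2/D3-3 subdivision) for 28S, but any labels are accepted.

#' Create a region map
#'
#' @param label Character vector of unique region labels.
#' @param start,end Integer vectors; 0-based half-open column intervals.
#'   Intervals must be disjoint; rows are sorted by `start`.
#' @param n_cols Optional alignment width; when given, intervals must lie in
#'   `[0, n_cols)`.
#' @return A data frame of class `region_map` with columns
#'   `label`, `start`, `end`.
#' @export
region_map <- function(label = character(0), start = integer(0),
                       end = integer(0), n_cols = NULL) {
  stopifnot(length(label) == length(start), length(start) == length(end))
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start) | is.na(end))) stop("NA region bounds", call. = FALSE)
  if (any(start < 0L) || any(end < start)) {
    stop("regions need 0 <= start <= end", call. = FALSE)
  }
  if (!is.null(n_cols) && any(end > n_cols)) {
    bad <- label[end > n_cols]
    stop(
      "region(s) beyond alignment width ", n_cols, ": ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  check_unique_ids(as.character(label))
  out <- data.frame(
    label = as.character(label), start = start, end = end,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 1L) {
    # zero-length regions may touch; positive-length regions must not overlap
    prev_end <- cummax(c(0L, out$end[-nrow(out)]))
    if (any(out$start < prev_end)) {
      bad <- out$label[out$start < prev_end]
      stop(
        "overlapping regions: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  class(out) <- c("region_map", "data.frame")
  out
}

#' Write a region map to CSV
#'
#' The file carries a header comment documenting the coordinate convention
#' (0-based, half-open), then `label,start,end` rows.
#'
#' @param map A [region_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(map, path) {
  stopifnot(inherits(map, "region_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(
    c(
      "# region map: alignment columns, 0-based, half-open [start,end)",
      "label,start,end"
    ),
    con
  )
  if (nrow(map) > 0L) {
    writeLines(sprintf("%s,%d,%d", map$label, map$start, map$end), con)
  }
  invisible(path)
}

#' Read a region map from CSV
#'
#' @param path Input path (as written by [write_region_map()]).
#' @param n_cols Optional alignment width to validate against.
#' @return A [region_map()]. Overlapping intervals are an error.
#' @export
read_region_map <- function(path, n_cols = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("label", "start", "end") %in% names(tab))) {
    stop("region map CSV must have columns label,start,end", call. = FALSE)
  }
  region_map(tab$label, tab$start, tab$end, n_cols = n_cols)
}

region_columns <- function(map, label) {
  row <- map[map$label == label, , drop = FALSE]
  if (nrow(row) == 0L) stop("unknown region label: ", label, call. = FALSE)
  if (row$end == row$start) return(integer(0))
  seq.int(row$start, row$end - 1L) # 0-based columns
}
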