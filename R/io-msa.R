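## Multiple-alignment container; FASTA and Stockholm readers/writers.

#' Create a multiple sequence alignment object
#'
#' Rows are equal-length gapped strings over `A,C,G,U,N,-`. Gap characters
#' `.` and `-` are normalized to `-`; `T` is transcribed to `U`. Columns are
#' indexed 0-based throughout the package.
#'
#' @param ids Character vector of row identifiers (unique).
#' @param seqs Character vector of aligned rows, same length as `ids`.
#' @return An object of class `msa` with fields `ids`, `seqs`, `n_cols`.
#' @export
msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(ids) > 0L)
  check_unique_ids(ids)
  seqs <- vapply(seqs, normalize_aligned, "", USE.NAMES = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[[1]])
    stop(
      "ragged alignment rows: ",
      paste(sprintf("%s (%d)", ids[off], lens[off]), collapse = ", "),
      " vs ", ids[[1]], " (", lens[[1]], ")",
      call. = FALSE
    )
  }
  bad_rows <- vapply(
    seqs,
    function(s) any(!strsplit(s, "")[[1]] %in% c(RNA_ALPHABET, "-")),
    NA
  )
  if (any(bad_rows)) {
    stop(
      "alignment rows with characters outside {A,C,G,U,N,-}: ",
      paste(ids[bad_rows], collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(ids = ids, seqs = stats::setNames(seqs, ids), n_cols = lens[[1]]),
    class = "msa"
  )
}

normalize_aligned <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  chartr("tT.", "uU-", toupper(x))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d rows x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' One row per sequence, one column per alignment column.
#'
#' @param x An [msa()] object.
#' @return A character matrix with rownames = ids.
#' @export
msa_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  m <- do.call(rbind, strsplit(unname(x$seqs), ""))
  rownames(m) <- x$ids
  m
}

#' Ungapped residue strings of an alignment
#'
#' @param x An [msa()] object.
#' @return Named character vector of degapped rows.
#' @export
msa_ungapped <- function(x) {
  stopifnot(inherits(x, "msa"))
  gsub("-", "", x$seqs, fixed = TRUE)
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA and Stockholm 1.0. For Stockholm, a `#=GC SS_cons`
#' line (dot-bracket/WUSS) is returned alongside the alignment when present.
#'
#' @param path Input path.
#' @param format `"fasta"` or `"stockholm"`.
#' @return An [msa()] object; for Stockholm input with an `SS_cons` line, the
#'   object carries it in `attr(, "ss_cons")` (length `n_cols`).
#' @export
read_msa <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "fasta") {
    recs <- read_fasta_aligned(path)
    return(msa(recs$ids, recs$seqs))
  }
  read_stockholm(path)
}

## FASTA reader that keeps gap characters (read_fasta() validates residues).
read_fasta_aligned <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  check_unique_ids(ids)
  list(ids = ids, seqs = as.character(set))
}

read_stockholm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[[1]])) {
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path,
      call. = FALSE
    )
  }
  seqs <- list()
  ss <- character(0)
  order <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      next
    }
    if (grepl("^#", ln)) next # other annotation lines ignored
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) {
      stop("malformed Stockholm sequence line: '", ln, "'", call. = FALSE)
    }
    id <- parts[[1]]
    if (!id %in% order) order <- c(order, id)
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], parts[[2]])
  }
  if (length(order) == 0L) stop("no sequences in Stockholm file: ", path, call. = FALSE)
  out <- msa(order, unlist(seqs[order], use.names = FALSE))
  if (length(ss) > 0L) {
    ss_full <- paste(ss, collapse = "")
    if (nchar(ss_full) != out$n_cols) {
      stop(
        "SS_cons length (", nchar(ss_full), ") != alignment columns (",
        out$n_cols, ")",
        call. = FALSE
      )
    }
    attr(out, "ss_cons") <- ss_full
  }
  out
}

#' Write an alignment as Stockholm 1.0
#'
#' @param x An [msa()] object.
#' @param path Output path.
#' @param ss_cons Optional consensus structure string (dot-bracket), length
#'   `n_cols`.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(x, path, ss_cons = NULL) {
  stopifnot(inherits(x, "msa"))
  if (is.null(ss_cons)) ss_cons <- attr(x, "ss_cons")
  pad <- max(nchar(x$ids), nchar("#=GC SS_cons"))
  lines <- c(
    "# STOCKHOLM 1.0",
    sprintf("%-*s %s", pad, x$ids, unname(x$seqs))
  )
  if (!is.null(ss_cons)) {
    stopifnot(nchar(ss_cons) == x$n_cols)
    lines <- c(lines, sprintf("%-*s %s", pad, "#=GC SS_cons", ss_cons))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Write an alignment as gapped FASTA
#'
#' @param x An [msa()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  writeLines(
    as.vector(rbind(paste0(">", x$ids), unname(x$seqs))),
    path
  )
  invisible(path)
}
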