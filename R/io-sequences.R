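## Sequence container and FASTA input/output.

RNA_ALPHABET <- c("A", "C", "G", "U", "N")

#' Create an RNA sequence record
#'
#' The elementary record of the package: one homologous rRNA sequence with
#' taxon metadata. DNA residues are transcribed on construction (`T` mapped to
#' `U`) and case-folded to upper case.
#'
#' @param id Unique accession-like identifier.
#' @param residues Residue string over `A,C,G,U,N` (or `T`, transcribed).
#' @param taxon Terminal taxon name; defaults to `id`.
#' @param description Free-text description.
#' @return An object of class `rna_sequence` with fields `id`, `taxon`,
#'   `residues`, `description`.
#' @examples
#' rna_sequence("JX997807-like", "ACGUACGU", taxon = "Eurydema maracandica")
#' @export
rna_sequence <- function(id, residues, taxon = id, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- normalize_residues(residues)
  if (!nzchar(residues)) {
    stop("empty residue string for sequence '", id, "'", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), RNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(
      "sequence '", id, "' contains characters outside {A,C,G,U,N}: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(id = id, taxon = taxon, residues = residues, description = description),
    class = "rna_sequence"
  )
}

normalize_residues <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  chartr("tT", "uU", toupper(x))
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(
    sprintf(
      "<rna_sequence> %s (%s), %d nt\n", x$id, x$taxon, nchar(x$residues)
    )
  )
  invisible(x)
}

check_unique_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

#' Read sequences from a FASTA file
#'
#' Reads a (possibly wrapped) FASTA file into a list of [rna_sequence()]
#' records. `T` is transcribed to `U`; the id is the first
#' whitespace-delimited token of the header, the remainder becomes the
#' description. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A named list of `rna_sequence` objects.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(
    grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers),
    ""
  )
  check_unique_ids(ids)
  seqs <- as.character(set)
  if (any(!nzchar(gsub("[[:space:]]", "", seqs)))) {
    empty <- ids[!nzchar(gsub("[[:space:]]", "", seqs))]
    stop("empty FASTA record(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_along(ids), function(k) {
    rna_sequence(ids[[k]], seqs[[k]], description = desc[[k]])
  })
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs A list of [rna_sequence()] objects (or a single one).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "rna_sequence")) seqs <- list(seqs)
  check_unique_ids(vapply(seqs, `[[`, "", "id"))
  lines <- unlist(lapply(seqs, function(s) {
    header <- if (nzchar(s$description)) {
      paste(s$id, s$description)
    } else {
      s$id
    }
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", s$residues)
    c(paste0(">", header), strsplit(body, "\n")[[1]])
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
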