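## Affine-gap global alignment (Gotoh) and coordinate transfer of reference
## region annotations onto query sequences. This is the route by which a new
## accession gets LVR coordinates: align it to an annotated reference, then
## map the reference intervals through the alignment columns.

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment. A gap of length L costs
#' `gap_open + L * gap_extend`. Traceback is deterministic: at equal scores,
#' prefer the diagonal move, then the vertical (consume `a`), then the
#' horizontal (consume `b`); within gap states, opening from the match state
#' is preferred over extending.
#'
#' @param a,b [rna_sequence()] objects (or residue strings).
#' @param match,mismatch Per-column substitution scores. Defaults (+2/-1)
#'   with `gap_open = -5`, `gap_extend = -1` suit the conserved-rRNA regime.
#' @param gap_open,gap_extend Affine gap penalties (both typically negative).
#' @return An object of class `pairwise_alignment`: `a_id`, `b_id`,
#'   `aligned_a`, `aligned_b` (equal-length gapped strings with no
#'   double-gap column), `score`.
#' @export
global_align <- function(a, b, match = 2, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  a_id <- if (inherits(a, "rna_sequence")) a$id else "a"
  b_id <- if (inherits(b, "rna_sequence")) b$id else "b"
  sa <- if (inherits(a, "rna_sequence")) a$residues else normalize_residues(a)
  sb <- if (inherits(b, "rna_sequence")) b$residues else normalize_residues(b)
  if (!nzchar(sa) || !nzchar(sb)) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  NEG <- -Inf
  M <- matrix(NEG, n + 1L, m + 1L) # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1L, m + 1L) # a[i] aligned to gap (vertical)
  Y <- matrix(NEG, n + 1L, m + 1L) # gap aligned to b[j] (horizontal)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- gap_open + i * gap_extend
  for (j in seq_len(m)) Y[1L, j + 1L] <- gap_open + j * gap_extend
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[[i]] == cb[[j]]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- gap_extend + max(
        M[i, j + 1L] + gap_open,
        X[i, j + 1L],
        Y[i, j + 1L] + gap_open
      )
      Y[i + 1L, j + 1L] <- gap_extend + max(
        M[i + 1L, j] + gap_open,
        X[i + 1L, j] + gap_open,
        Y[i + 1L, j]
      )
    }
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback
  state <- c("M", "X", "Y")[which.max(
    c(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  )]
  out_a <- character(0)
  out_b <- character(0)
  i <- n
  j <- m
  while (i > 0L || j > 0L) {
    if (state == "M") {
      out_a <- c(ca[[i]], out_a)
      out_b <- c(cb[[j]], out_b)
      s <- if (ca[[i]] == cb[[j]]) match else mismatch
      cur <- M[i + 1L, j + 1L]
      state <- if (i - 1L >= 0L && cur == s + M[i, j]) {
        "M"
      } else if (cur == s + X[i, j]) {
        "X"
      } else {
        "Y"
      }
      i <- i - 1L
      j <- j - 1L
    } else if (state == "X") {
      out_a <- c(ca[[i]], out_a)
      out_b <- c("-", out_b)
      cur <- X[i + 1L, j + 1L]
      state <- if (cur == gap_extend + gap_open + M[i, j + 1L]) {
        "M"
      } else if (cur == gap_extend + X[i, j + 1L]) {
        "X"
      } else {
        "Y"
      }
      i <- i - 1L
    } else {
      out_a <- c("-", out_a)
      out_b <- c(cb[[j]], out_b)
      cur <- Y[i + 1L, j + 1L]
      state <- if (cur == gap_extend + gap_open + M[i + 1L, j]) {
        "M"
      } else if (cur == gap_extend + gap_open + X[i + 1L, j]) {
        "X"
      } else {
        "Y"
      }
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- "Y"
    if (j == 0L && i > 0L) state <- "X"
  }
  structure(
    list(
      a_id = a_id, b_id = b_id,
      aligned_a = paste(out_a, collapse = ""),
      aligned_b = paste(out_b, collapse = ""),
      score = score
    ),
    class = "pairwise_alignment"
  )
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf(
    "<pairwise_alignment> %s vs %s, score %g\n  %s\n  %s\n",
    x$a_id, x$b_id, x$score, x$aligned_a, x$aligned_b
  ))
  invisible(x)
}

#' Transfer region annotations through a pairwise alignment
#'
#' Maps a [region_map()] defined on reference sequence positions (the `a`
#' row of `aln`) onto query (`b` row) positions. A boundary landing in a
#' query gap rounds rightward for starts and leftward for ends, so flanking
#' gaps never inflate a transferred region; a region fully deleted in the
#' query maps to a zero-length interval.
#'
#' @param ref_regions [region_map()] on reference sequence positions
#'   (0-based, half-open).
#' @param aln A [pairwise_alignment()] with the reference as its `a` row.
#' @return A [region_map()] on query sequence positions.
#' @export
transfer_regions <- function(ref_regions, aln) {
  stopifnot(inherits(ref_regions, "region_map"), inherits(aln, "pairwise_alignment"))
  a <- strsplit(aln$aligned_a, "")[[1]]
  b <- strsplit(aln$aligned_b, "")[[1]]
  ref_len <- sum(a != "-")
  if (nrow(ref_regions) > 0L && any(ref_regions$end > ref_len)) {
    bad <- ref_regions$label[ref_regions$end > ref_len]
    stop(
      "region(s) outside reference length ", ref_len, ": ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  col_of_a <- which(a != "-") # column (1-based) of each ref position
  cum_b <- cumsum(b != "-") # query residues up to and incl. each column
  q_start <- integer(nrow(ref_regions))
  q_end <- integer(nrow(ref_regions))
  for (r in seq_len(nrow(ref_regions))) {
    s <- ref_regions$start[r]
    e <- ref_regions$end[r]
    if (s == e) {
      c_s <- if (s < ref_len) col_of_a[s + 1L] else length(a) + 1L
      q_start[r] <- if (c_s > 1L) cum_b[c_s - 1L] else 0L
      q_end[r] <- q_start[r]
    } else {
      c_s <- col_of_a[s + 1L]
      c_e <- col_of_a[e] # column of last ref residue in region
      q_start[r] <- if (c_s > 1L) cum_b[c_s - 1L] else 0L
      q_end[r] <- cum_b[c_e]
      if (q_end[r] < q_start[r]) q_end[r] <- q_start[r]
    }
  }
  region_map(ref_regions$label, q_start, q_end)
}
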