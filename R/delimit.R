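## Delimiting length-variable regions (LVRs) from a multiple alignment.
##
## Variability is gap-driven: a column is length-variable when its gap
## fraction exceeds a threshold. Substitution variability alone does not
## create length variation, so per-column entropy is reported but not used
## for delimitation. LVRs are maximal runs of variable columns; short
## conserved runs sandwiched between variable runs (the "short
## length-conservative regions" that interspace LVR sections) are absorbed.

#' Per-column conservation profile of an alignment
#'
#' @param msa An [msa()].
#' @param gap_threshold Gap fraction above which a column counts as
#'   length-variable; must lie in (0, 1). Default 0.2.
#' @return A data frame of class `column_profile` with columns `col`
#'   (0-based), `gap_fraction`, `residue_entropy` (bits, over non-gap
#'   A/C/G/U), `is_variable`.
#' @export
column_profile <- function(msa, gap_threshold = 0.2) {
  stopifnot(inherits(msa, "msa"))
  if (!(gap_threshold > 0 && gap_threshold < 1)) {
    stop("gap_threshold must lie in (0, 1)", call. = FALSE)
  }
  m <- msa_matrix(msa)
  n_rows <- nrow(m)
  gap_fraction <- colMeans(m == "-")
  residue_entropy <- apply(m, 2, function(col) {
    res <- col[col %in% c("A", "C", "G", "U")]
    if (length(res) == 0L) return(0)
    p <- table(res) / length(res)
    -sum(p * log2(p))
  })
  out <- data.frame(
    col = seq_len(msa$n_cols) - 1L,
    gap_fraction = as.numeric(gap_fraction),
    residue_entropy = as.numeric(residue_entropy),
    is_variable = as.numeric(gap_fraction) > gap_threshold
  )
  attr(out, "gap_threshold") <- gap_threshold
  class(out) <- c("column_profile", "data.frame")
  out
}

#' Delimit length-variable regions from a column profile
#'
#' LVRs are maximal runs of variable columns separated by conserved runs of
#' at least `min_conserved_block` columns; shorter conserved runs between
#' variable runs are absorbed into the surrounding LVR. Runs shorter than
#' `min_lvr_cols` after absorption are discarded (the proxy separating bona
#' fide LVRs from scattered single-column indels). Labels follow the chosen
#' scheme: alphabetic capital letters starting at `B` (the 18S convention,
#' where up to 13 LVRs are lettered B..W), or the 28S divergent-domain "D
#' system" `D2, D3, ...`; supplying `parent` relabels regions inside a parent
#' interval as dash-suffixed sections (`D3-1, D3-2, D3-3`).
#'
#' @param profile A [column_profile()].
#' @param min_conserved_block Minimum conserved run length that separates two
#'   LVRs (default 5).
#' @param min_lvr_cols Minimum LVR width in columns (default 2).
#' @param label_scheme `"alpha"` or `"d"`.
#' @param alpha_start First letter for the alphabetic scheme (default `"B"`;
#'   `A` is conventionally not used).
#' @param d_start First number for the D scheme (default 2).
#' @param parent Optional one-row [region_map()]; recovered regions falling
#'   inside it are labeled `<parent label>-1`, `<parent label>-2`, ...
#' @return A [region_map()] (empty when no variable columns exist).
#' @export
delimit_lvrs <- function(profile, min_conserved_block = 5L, min_lvr_cols = 2L,
                         label_scheme = c("alpha", "d"), alpha_start = "B",
                         d_start = 2L, parent = NULL) {
  stopifnot(inherits(profile, "column_profile"))
  label_scheme <- match.arg(label_scheme)
  v <- profile$is_variable
  n <- length(v)
  if (!any(v)) return(region_map())
  # absorb short conserved runs flanked by variable runs on both sides
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] && r$lengths[k] < min_conserved_block &&
      k > 1L && k < length(r$values)) {
      v[starts[k]:ends[k]] <- TRUE
    }
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_lvr_cols
  if (!any(keep)) return(region_map())
  s0 <- starts[keep] - 1L # 0-based
  e0 <- ends[keep] # half-open
  labels <- if (!is.null(parent)) {
    stopifnot(inherits(parent, "region_map"), nrow(parent) == 1L)
    inside <- s0 >= parent$start & e0 <= parent$end
    if (!all(inside)) {
      stop("with `parent`, all recovered regions must fall inside it",
        call. = FALSE
      )
    }
    sprintf("%s-%d", parent$label, seq_along(s0))
  } else if (label_scheme == "alpha") {
    first <- match(alpha_start, LETTERS)
    if (is.na(first) || first + length(s0) - 1L > 26L) {
      stop("alphabetic labels exhausted (", length(s0), " regions)",
        call. = FALSE
      )
    }
    LETTERS[seq.int(first, length.out = length(s0))]
  } else {
    sprintf("D%d", seq.int(d_start, length.out = length(s0)))
  }
  region_map(labels, s0, e0, n_cols = n)
}

#' Per-sequence LVR lengths
#'
#' The substrate of the synapomorphy scan: the ungapped length (non-gap
#' residue count, `N` included — it is a real residue) of every sequence in
#' every labeled region. The result is the complete cross-product of
#' sequence ids and region labels.
#'
#' @param msa An [msa()].
#' @param map A [region_map()] within the alignment columns.
#' @return A data frame of class `lvr_length_table` with columns `id`,
#'   `region`, `length`.
#' @export
lvr_lengths <- function(msa, map) {
  stopifnot(inherits(msa, "msa"), inherits(map, "region_map"))
  if (nrow(map) > 0L && any(map$end > msa$n_cols)) {
    stop("region map extends beyond alignment columns", call. = FALSE)
  }
  m <- msa_matrix(msa)
  rows <- list()
  for (r in seq_len(nrow(map))) {
    cols <- region_columns(map, map$label[r])
    len <- if (length(cols) == 0L) {
      integer(nrow(m))
    } else {
      as.integer(rowSums(m[, cols + 1L, drop = FALSE] != "-"))
    }
    rows[[r]] <- data.frame(
      id = msa$ids, region = map$label[r], length = len,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0L) {
    data.frame(
      id = character(0), region = character(0), length = integer(0),
      stringsAsFactors = FALSE
    )
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  class(out) <- c("lvr_length_table", "data.frame")
  out
}

#' Construct an LVR length table directly
#'
#' For curated tables (e.g. literature-derived length states) rather than
#' tables measured from an alignment. `NA` lengths mean "sequence not
#' examined for this region" and are excluded from scan tallies.
#'
#' @param id,region Character vectors.
#' @param length Integer vector (`NA` allowed).
#' @return A data frame of class `lvr_length_table`.
#' @export
lvr_length_table <- function(id, region, length) {
  out <- data.frame(
    id = as.character(id), region = as.character(region),
    length = as.integer(length), stringsAsFactors = FALSE
  )
  if (anyDuplicated(out[c("id", "region")]) > 0L) {
    stop("duplicate (id, region) cells", call. = FALSE)
  }
  if (any(!is.na(out$length) & out$length < 0L)) {
    stop("negative lengths", call. = FALSE)
  }
  class(out) <- c("lvr_length_table", "data.frame")
  out
}

#' Check that region maps do not overlap
#'
#' TRUE iff all intervals across the supplied maps (e.g. LVR maps of
#' adjacent domains) are pairwise disjoint on the same alignment.
#'
#' @param ... [region_map()] objects, or a single list of them.
#' @return Logical scalar.
#' @export
check_no_overlap <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && !inherits(maps[[1]], "region_map")) {
    maps <- maps[[1]]
  }
  all_iv <- do.call(rbind, lapply(maps, function(m) {
    as.data.frame(m)[c("start", "end")]
  }))
  if (is.null(all_iv) || nrow(all_iv) < 2L) return(TRUE)
  all_iv <- all_iv[all_iv$end > all_iv$start, , drop = FALSE]
  if (nrow(all_iv) < 2L) return(TRUE)
  all_iv <- all_iv[order(all_iv$start), , drop = FALSE]
  all(all_iv$start[-1] >= all_iv$end[-nrow(all_iv)])
}
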