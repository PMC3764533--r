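## Consensus structure models on alignment columns and the stem-retention
## (co-variation) criterion for choosing among candidate models: the model
## whose paired columns are least disrupted across the aligned sequences —
## equivalently, the one under which each sequence keeps the longest stems —
## is preferred.

#' Create a helix (consensus stem) on alignment columns
#'
#' A helix pairs two equal-length column runs: the k-th column of the 5' side
#' pairs with the (len-1-k)-th column of the 3' side. Intervals are 0-based,
#' half-open.
#'
#' @param side5_start,side5_end 5' side columns `[side5_start, side5_end)`.
#' @param side3_start,side3_end 3' side columns; must lie entirely right of
#'   the 5' side and have the same length.
#' @return A one-row data frame of class `helix`.
#' @export
helix <- function(side5_start, side5_end, side3_start, side3_end) {
  v <- as.integer(c(side5_start, side5_end, side3_start, side3_end))
  if (any(is.na(v))) stop("NA helix bounds", call. = FALSE)
  len5 <- v[2] - v[1]
  len3 <- v[4] - v[3]
  if (len5 < 1L || len5 != len3) {
    stop("helix sides must have equal length >= 1", call. = FALSE)
  }
  if (v[1] < 0L || v[2] > v[3]) {
    stop("5' side must lie entirely left of 3' side", call. = FALSE)
  }
  out <- data.frame(
    side5_start = v[1], side5_end = v[2],
    side3_start = v[3], side3_end = v[4]
  )
  class(out) <- c("helix", "data.frame")
  out
}

helix_length <- function(h) h$side5_end - h$side5_start

## Column pairs of one helix row: matrix (a, b), 0-based columns.
helix_column_pairs <- function(h) {
  len <- h$side5_end - h$side5_start
  k <- seq_len(len) - 1L
  cbind(a = h$side5_start + k, b = h$side3_start + (len - 1L - k))
}

#' Create a consensus structure model
#'
#' A set of mutually compatible helices on alignment columns, optionally with
#' a region map labeling LVR intervals.
#'
#' @param n_cols Alignment width the model lives on.
#' @param helices A data frame of helix rows (as from [helix()], possibly
#'   `rbind`-ed) or a list of them.
#' @param region_map Optional [region_map()].
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(n_cols, helices = NULL, region_map = NULL) {
  n_cols <- as.integer(n_cols)
  if (is.list(helices) && !is.data.frame(helices)) {
    helices <- do.call(rbind, helices)
  }
  if (is.null(helices) || nrow(helices) == 0L) {
    helices <- helix(0, 1, 1, 2)[0, ]
  }
  cp <- do.call(rbind, lapply(seq_len(nrow(helices)), function(r) {
    helix_column_pairs(helices[r, ])
  }))
  if (!is.null(cp) && nrow(cp) > 0L) {
    if (any(cp < 0L) || any(cp >= n_cols)) {
      stop("helix columns outside [0, n_cols)", call. = FALSE)
    }
    if (anyDuplicated(as.vector(cp)) > 0L) {
      stop("helices share alignment columns", call. = FALSE)
    }
    if (has_crossing(cp[order(cp[, 1]), , drop = FALSE])) {
      stop("helices cross (column-level pseudoknot)", call. = FALSE)
    }
  }
  structure(
    list(n_cols = n_cols, helices = helices, region_map = region_map),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %d columns, %d helices (%d column pairs)\n",
    x$n_cols, nrow(x$helices),
    sum(x$helices$side5_end - x$helices$side5_start)
  ))
  invisible(x)
}

model_column_pairs <- function(model) {
  if (nrow(model$helices) == 0L) {
    return(cbind(a = integer(0), b = integer(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(model$helices)), function(r) {
    helix_column_pairs(model$helices[r, ])
  }))
}

#' Stem retention of one aligned sequence under a model
#'
#' Counts the column pairs (across all helices) at which the sequence has
#' non-gap residues on both sides forming a pair allowed by `rule`. Gaps and
#' disallowed residue combinations contribute nothing. This is the
#' per-sequence "how much of the stems does this sequence keep" statistic
#' that drives model selection.
#'
#' @param model A [structure_model()].
#' @param row Aligned sequence string, length `model$n_cols`.
#' @param rule A [pair_rule()]; the default counts canonical and wobble pairs
#'   as stem support, treating noncanonical pairs as annotations rather than
#'   support.
#' @return Integer count of retained column pairs.
#' @export
retained_stem_length <- function(model, row, rule = pair_rule()) {
  stopifnot(inherits(model, "structure_model"))
  row <- normalize_aligned(row)
  if (nchar(row) != model$n_cols) {
    stop(
      "row length ", nchar(row), " != model n_cols ", model$n_cols,
      call. = FALSE
    )
  }
  cp <- model_column_pairs(model)
  if (nrow(cp) == 0L) return(0L)
  chars <- strsplit(row, "")[[1]]
  a <- chars[cp[, 1] + 1L]
  b <- chars[cp[, 2] + 1L]
  sum(a != "-" & b != "-" & pair_allowed(a, b, rule))
}

#' Score a model against an alignment
#'
#' @param model A [structure_model()].
#' @param msa An [msa()] with `n_cols` matching the model.
#' @param rule A [pair_rule()].
#' @return A list with `total` (summed retained stem length over rows),
#'   `min_per_row`, `n_helices`, and the per-row vector `per_row`.
#' @export
model_score <- function(model, msa, rule = pair_rule()) {
  stopifnot(inherits(model, "structure_model"), inherits(msa, "msa"))
  if (msa$n_cols != model$n_cols) {
    stop(
      "msa has ", msa$n_cols, " columns but model expects ", model$n_cols,
      call. = FALSE
    )
  }
  cp <- model_column_pairs(model)
  if (nrow(cp) == 0L) {
    per_row <- stats::setNames(integer(length(msa$ids)), msa$ids)
    return(list(
      total = 0L, min_per_row = 0L, n_helices = 0L, per_row = per_row
    ))
  }
  m <- msa_matrix(msa)
  pm <- pair_matrix(rule)
  per_row <- integer(nrow(m))
  a_cols <- m[, cp[, 1] + 1L, drop = FALSE]
  b_cols <- m[, cp[, 2] + 1L, drop = FALSE]
  ok <- a_cols != "-" & b_cols != "-"
  allowed <- matrix(FALSE, nrow(m), nrow(cp))
  idx <- which(ok)
  if (length(idx) > 0L) {
    aa <- a_cols[idx]
    bb <- b_cols[idx]
    good <- aa %in% rownames(pm) & bb %in% rownames(pm)
    val <- logical(length(idx))
    val[good] <- pm[cbind(aa[good], bb[good])]
    allowed[idx] <- val
  }
  per_row <- rowSums(allowed)
  names(per_row) <- msa$ids
  list(
    total = as.integer(sum(per_row)),
    min_per_row = as.integer(min(per_row)),
    n_helices = nrow(model$helices),
    per_row = as.integer(per_row) |> stats::setNames(msa$ids)
  )
}

#' Select the best consensus model by stem retention
#'
#' Pure ranking of candidate models under the co-variation criterion: the
#' candidate maximizing total retained stem length wins; ties are broken by
#' larger per-row minimum, then by fewer helices, then by input order.
#'
#' @param candidates Nonempty list of [structure_model()] objects, all on the
#'   same column count as `msa`.
#' @param msa An [msa()].
#' @param rule A [pair_rule()].
#' @return The selected model, with its score list in `attr(, "score")`.
#' @export
select_model <- function(candidates, msa, rule = pair_rule()) {
  if (!is.list(candidates) || length(candidates) == 0L) {
    stop("need a nonempty list of candidate models", call. = FALSE)
  }
  scores <- lapply(candidates, model_score, msa = msa, rule = rule)
  total <- vapply(scores, `[[`, 0L, "total")
  minr <- vapply(scores, `[[`, 0L, "min_per_row")
  nh <- vapply(scores, `[[`, 0L, "n_helices")
  ord <- order(-total, -minr, nh, seq_along(candidates))
  best <- ord[[1]]
  out <- candidates[[best]]
  attr(out, "score") <- scores[[best]]
  attr(out, "rank_index") <- best
  out
}

#' Project a column-level model onto one sequence
#'
#' Maps each helix column pair onto ungapped sequence positions of `row`.
#' Pairs with a gap on either side are dropped; pairs whose residues are not
#' allowed by `rule` are retained but flagged as noncanonical (mirroring how
#' structure diagrams draw noncanonical pairs with distinct symbols).
#'
#' @inheritParams retained_stem_length
#' @return A [secondary_structure()] on the ungapped sequence, with
#'   `attr(, "noncanonical")`: logical vector, one per pair.
#' @export
sequence_structure_from_model <- function(model, row, rule = pair_rule()) {
  stopifnot(inherits(model, "structure_model"))
  row <- normalize_aligned(row)
  if (nchar(row) != model$n_cols) {
    stop(
      "row length ", nchar(row), " != model n_cols ", model$n_cols,
      call. = FALSE
    )
  }
  chars <- strsplit(row, "")[[1]]
  # 0-based sequence position at each column (NA at gaps)
  seqpos <- ifelse(chars == "-", NA_integer_, cumsum(chars != "-") - 1L)
  cp <- model_column_pairs(model)
  keep <- if (nrow(cp) > 0L) {
    !is.na(seqpos[cp[, 1] + 1L]) & !is.na(seqpos[cp[, 2] + 1L])
  } else {
    logical(0)
  }
  cp <- cp[keep, , drop = FALSE]
  pairs <- cbind(seqpos[cp[, 1] + 1L], seqpos[cp[, 2] + 1L])
  noncanonical <- if (nrow(cp) > 0L) {
    !pair_allowed(chars[cp[, 1] + 1L], chars[cp[, 2] + 1L], rule)
  } else {
    logical(0)
  }
  out <- secondary_structure(sum(chars != "-"), pairs)
  ord <- order(pairs[, 1])
  attr(out, "noncanonical") <- noncanonical[ord]
  out
}

#' Read / write helix tables
#'
#' Model files are CSV helix tables with columns
#' `side5_start,side5_end,side3_start,side3_end` (0-based, half-open).
#'
#' @param path CSV path.
#' @param n_cols Alignment width of the model.
#' @param region_map Optional [region_map()] to attach.
#' @return `read_model_csv()`: a [structure_model()].
#' @export
read_model_csv <- function(path, n_cols, region_map = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("side5_start", "side5_end", "side3_start", "side3_end")
  if (!all(need %in% names(tab))) {
    stop("model CSV must have columns ", paste(need, collapse = ","),
      call. = FALSE
    )
  }
  hx <- lapply(seq_len(nrow(tab)), function(r) {
    helix(
      tab$side5_start[r], tab$side5_end[r],
      tab$side3_start[r], tab$side3_end[r]
    )
  })
  structure_model(n_cols, hx, region_map = region_map)
}

#' @rdname read_model_csv
#' @param model A [structure_model()] to write.
#' @return `write_model_csv()`: `path`, invisibly.
#' @export
write_model_csv <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  utils::write.csv(
    as.data.frame(model$helices),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Sample a random rival model
#'
#' Draws a model with the given helix lengths at uniformly random valid
#' column positions: the helices' 2k side runs are laid out left to right
#' with random spacing (a random composition of the free columns), with at
#' least `min_sep` columns between the two sides of each helix. The layout
#' is always non-conflicting and column-level pseudoknot-free. Used as the
#' null comparison when testing whether a planted or curated model outscores
#' chance under the stem-retention criterion.
#'
#' @param n_cols Alignment width.
#' @param helix_lengths Integer vector of helix lengths to place.
#' @param min_sep Minimum columns between a helix's two sides.
#' @return A [structure_model()].
#' @export
sample_random_model <- function(n_cols, helix_lengths, min_sep = 3L) {
  m <- length(helix_lengths)
  stopifnot(m >= 1L)
  slack <- n_cols - (2L * sum(helix_lengths) + min_sep * m)
  if (slack < 0L) {
    stop("n_cols too small for the requested helix lengths", call. = FALSE)
  }
  # random composition of slack into 2m + 1 non-negative spacer widths
  n_slots <- 2L * m + 1L
  spacers <- if (slack == 0L) {
    integer(n_slots)
  } else {
    bars <- sort(sample.int(slack + n_slots - 1L, n_slots - 1L))
    diff(c(0L, bars, slack + n_slots)) - 1L
  }
  placed <- vector("list", m)
  cursor <- 0L
  for (t in seq_len(m)) {
    len <- helix_lengths[[t]]
    cursor <- cursor + spacers[[2L * t - 1L]]
    s5 <- cursor
    cursor <- cursor + len + min_sep + spacers[[2L * t]]
    s3 <- cursor
    cursor <- cursor + len
    placed[[t]] <- helix(s5, s5 + len, s3, s3 + len)
  }
  structure_model(n_cols, placed)
}
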