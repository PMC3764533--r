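## Scanning named clades for LVR length states that behave as molecular
## synapomorphies: a length state (near-)invariant inside a monophyletic
## group and rare outside it. The scan is descriptive — it tabulates and
## flags; it performs no ancestral-state reconstruction and no significance
## test, because a flagged state is a candidate synapomorphy, not an
## inference about the ancestor.

#' Length-state distribution of a clade in one region
#'
#' @param table An `lvr_length_table` (see [lvr_lengths()]).
#' @param clade_members Character vector of sequence ids (must all appear in
#'   the table).
#' @param region Region label.
#' @return Named integer vector: length state -> count. `NA` lengths (not
#'   examined) are excluded.
#' @export
state_distribution <- function(table, clade_members, region) {
  stopifnot(inherits(table, "lvr_length_table"))
  if (!region %in% table$region) {
    stop("unknown region label: ", region, call. = FALSE)
  }
  missing <- setdiff(clade_members, unique(table$id))
  if (length(missing) > 0L) {
    stop(
      "clade member(s) absent from length table: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  lens <- table$length[table$region == region & table$id %in% clade_members]
  lens <- lens[!is.na(lens)]
  if (length(lens) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(lens)
  stats::setNames(as.integer(tab), names(tab))
}

#' Flag candidate synapomorphies
#'
#' For every (clade, region), a length state `L` is flagged when its share
#' among examined clade members is at least `min_share` and its frequency
#' among examined non-members is at most `outside_max_freq`. Members
#' deviating from the flagged state are counted as exceptions and reported,
#' not hidden. `unique_within_parent` marks states absent outside the clade
#' (outside frequency exactly 0) — the "same unique length" situation.
#' Clades that cover every examined sequence of a region are never flagged
#' (no outgroup exists to establish rarity).
#'
#' @param table An `lvr_length_table`.
#' @param clades A [clade_map()] whose terminals are sequence ids; every
#'   member of every clade must appear in the table.
#' @param min_share Minimum within-clade share of the state; must exceed 0.5
#'   (a meaningful state must at least be a majority). Default 0.9, which
#'   tolerates the "few exceptions" seen in real groups.
#' @param outside_max_freq Maximum frequency of the state among non-members.
#'   Default 0.5, which admits dominant-but-not-unique states.
#' @return A data frame of class `synapomorphy_candidates` with columns
#'   `clade`, `region`, `state_length`, `n_in` (examined members),
#'   `n_in_state`, `n_exceptions`, `outside_freq`, `unique_within_parent`,
#'   sorted by clade then region.
#' @export
flag_synapomorphies <- function(table, clades, min_share = 0.9,
                                outside_max_freq = 0.5) {
  stopifnot(inherits(table, "lvr_length_table"), inherits(clades, "clade_map"))
  if (min_share <= 0.5) {
    stop("min_share must exceed 0.5 (majority state required)", call. = FALSE)
  }
  if (outside_max_freq < 0 || outside_max_freq > 1) {
    stop("outside_max_freq must lie in [0, 1]", call. = FALSE)
  }
  ids <- unique(table$id)
  for (nm in names(clades$clades)) {
    missing <- setdiff(clades$clades[[nm]], ids)
    if (length(missing) > 0L) {
      stop(
        "clade '", nm, "' member(s) absent from length table: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
  }
  regions <- unique(table$region)
  out <- list()
  for (nm in sort(names(clades$clades))) {
    members <- clades$clades[[nm]]
    for (reg in regions) {
      sub <- table[table$region == reg & !is.na(table$length), , drop = FALSE]
      in_len <- sub$length[sub$id %in% members]
      out_len <- sub$length[!sub$id %in% members]
      n_in <- length(in_len)
      n_out <- length(out_len)
      if (n_in == 0L || n_out == 0L) next
      tab <- table(in_len)
      shares <- as.integer(tab) / n_in
      for (k in seq_along(tab)) {
        if (shares[k] < min_share) next
        L <- as.integer(names(tab)[k])
        freq_out <- sum(out_len == L) / n_out
        if (freq_out > outside_max_freq) next
        out[[length(out) + 1L]] <- data.frame(
          clade = nm, region = reg, state_length = L,
          n_in = n_in, n_in_state = as.integer(tab[k]),
          n_exceptions = n_in - as.integer(tab[k]),
          outside_freq = freq_out,
          unique_within_parent = freq_out == 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(out) == 0L) {
    data.frame(
      clade = character(0), region = character(0),
      state_length = integer(0), n_in = integer(0), n_in_state = integer(0),
      n_exceptions = integer(0), outside_freq = numeric(0),
      unique_within_parent = logical(0), stringsAsFactors = FALSE
    )
  } else {
    do.call(rbind, out)
  }
  res <- res[order(res$clade, res$region), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("synapomorphy_candidates", "data.frame")
  res
}

#' Render a candidate report
#'
#' One row per candidate in the conventional `"<L>nt <region> (<n>)"` form
#' (e.g. `"9nt U (131)"`), grouped by clade; `(<n>)` is the number of
#' examined clade sequences, with exceptions appended when present.
#'
#' @param candidates A `synapomorphy_candidates` data frame.
#' @param format `"text"` (grouped plain text) or `"csv"`.
#' @return Character vector of report lines.
#' @export
report_table <- function(candidates, format = c("text", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(candidates, "data.frame"))
  if (format == "csv") {
    header <- paste(
      "clade,region,state_length,n_in,n_in_state,n_exceptions,outside_freq,unique_within_parent",
      collapse = ","
    )
    if (nrow(candidates) == 0L) return(header)
    return(c(header, sprintf(
      "%s,%s,%d,%d,%d,%d,%g,%s",
      candidates$clade, candidates$region, candidates$state_length,
      candidates$n_in, candidates$n_in_state, candidates$n_exceptions,
      candidates$outside_freq, tolower(candidates$unique_within_parent)
    )))
  }
  lines <- "Monophyletic group\tLVR (number of sequences examined)"
  for (nm in unique(candidates$clade)) {
    sub <- candidates[candidates$clade == nm, , drop = FALSE]
    cells <- sprintf("%dnt %s (%d)", sub$state_length, sub$region, sub$n_in)
    exc <- ifelse(
      sub$n_exceptions > 0L,
      sprintf(" [%d exception%s]", sub$n_exceptions,
        ifelse(sub$n_exceptions > 1L, "s", "")
      ),
      ""
    )
    lines <- c(lines, sprintf("%s\t%s", nm, paste0(cells, exc, collapse = "; ")))
  }
  lines
}
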