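## Synthetic rRNA-like datasets with planted ground truth.
##
## The generator emulates the statistical structure of comparative rRNA
## data: a conserved core (with stems whose substitutions are compensated at
## a controllable rate) interrupted by LVRs whose ungapped length is a
## discrete, clade-determined state, with a small per-region exception
## process (+/-1 nt) and no indels outside LVRs. Every run returns the true
## alignment, region map, structure model, and length table, so each
## pipeline stage can be checked against planted truth.

#' Generator specification
#'
#' Defaults describe the reference study condition used throughout the test
#' suite: 5 families of 6 sequences, a conserved core of five 20-column
#' blocks each carrying a 5-bp stem, and four LVRs (labeled `B..E`) with
#' family-determined length states. Two of the LVR states are planted
#' synapomorphies: clade `cladeP` (families F1+F2) has the unique state 5 nt
#' in LVR `C`, and clade `cladeQ` (families F4+F5) the unique state 9 nt in
#' LVR `E`. A third mapped clade, `cladeX` (F2+F3+F4), is a deliberate decoy
#' with no diagnostic state. The non-synapomorphic states are chosen so that
#' (at the scan defaults) only the two planted states are diagnostic, every
#' LVR column is recoverable from the gap profile, and each LVR's minimum
#' state is held by at least two families.
#'
#' @param n_families Number of families.
#' @param seqs_per_family Sequences per family.
#' @param clades Named list mapping clade names to character vectors of
#'   family names (`"F1"`, ...).
#' @param lvr_states Named list: LVR label -> named integer vector of length
#'   states per family.
#' @param hairpin Named logical: should each LVR's content fold into a
#'   hairpin (stem-loop built by reverse complement)?
#' @param planted Data frame (`clade`, `region`, `length`) of deliberately
#'   planted synapomorphies.
#' @param core_block_len Columns per conserved core block (one more block
#'   than LVRs).
#' @param stem_len Stem length (bp) planted in each core block.
#' @param sub_rate Per-site substitution probability in the core.
#' @param compensatory_rate Probability that a substitution hitting a stem
#'   position replaces the whole pair with another allowed pair.
#' @param lvr_indel_rate Per-(sequence, region) probability of a +/-1 nt
#'   deviation from the clade state (the "exception" process).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_families = 5L,
                           seqs_per_family = 6L,
                           clades = list(
                             cladeP = c("F1", "F2"),
                             cladeQ = c("F4", "F5"),
                             cladeX = c("F2", "F3", "F4")
                           ),
                           lvr_states = list(
                             B = c(F1 = 3L, F2 = 3L, F3 = 3L, F4 = 7L, F5 = 3L),
                             C = c(F1 = 5L, F2 = 5L, F3 = 2L, F4 = 8L, F5 = 2L),
                             D = c(F1 = 4L, F2 = 8L, F3 = 8L, F4 = 4L, F5 = 8L),
                             E = c(F1 = 2L, F2 = 6L, F3 = 2L, F4 = 9L, F5 = 9L)
                           ),
                           hairpin = NULL,
                           planted = data.frame(
                             clade = c("cladeP", "cladeQ"),
                             region = c("C", "E"),
                             length = c(5L, 9L),
                             stringsAsFactors = FALSE
                           ),
                           core_block_len = 20L,
                           stem_len = 5L,
                           sub_rate = 0,
                           compensatory_rate = 0.9,
                           lvr_indel_rate = 0,
                           seed = 1L) {
  fams <- paste0("F", seq_len(n_families))
  rates <- c(sub_rate, compensatory_rate, lvr_indel_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  for (nm in names(clades)) {
    unknown <- setdiff(clades[[nm]], fams)
    if (length(unknown) > 0L) {
      stop(
        "clade '", nm, "' references unknown family: ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  for (lab in names(lvr_states)) {
    st <- lvr_states[[lab]]
    if (!all(fams %in% names(st))) {
      stop("lvr_states[['", lab, "']] must name every family", call. = FALSE)
    }
    if (any(st < 0L)) stop("LVR length states must be >= 0", call. = FALSE)
  }
  if (!is.null(planted) && nrow(planted) > 0L) {
    if (!all(planted$clade %in% names(clades))) {
      stop("planted synapomorphy references unknown clade", call. = FALSE)
    }
    if (!all(planted$region %in% names(lvr_states))) {
      stop("planted synapomorphy references unknown region", call. = FALSE)
    }
  }
  if (is.null(hairpin)) {
    hairpin <- stats::setNames(
      rep(TRUE, length(lvr_states)), names(lvr_states)
    )
  }
  if (core_block_len < 2L * stem_len + 3L) {
    stop("core_block_len too small for stem_len with a 3-nt loop", call. = FALSE)
  }
  structure(
    list(
      n_families = as.integer(n_families),
      seqs_per_family = as.integer(seqs_per_family),
      families = fams,
      clades = clades,
      lvr_states = lvr_states,
      hairpin = hairpin,
      planted = planted,
      core_block_len = as.integer(core_block_len),
      stem_len = as.integer(stem_len),
      sub_rate = sub_rate,
      compensatory_rate = compensatory_rate,
      lvr_indel_rate = lvr_indel_rate,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
}

RNA_BASES <- c("A", "C", "G", "U")
COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")
ALLOWED_PAIRS <- rbind(
  c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"), c("G", "U"), c("U", "G")
)

random_bases <- function(n) {
  if (n == 0L) return(character(0))
  sample(RNA_BASES, n, replace = TRUE)
}

## Deterministic-per-call hairpin content of length l: stem of
## floor((l - 3) / 2) bp closed by reverse complement, random loop.
lvr_content <- function(l, hairpin) {
  if (l == 0L) return(character(0))
  if (!hairpin || l < 5L) return(random_bases(l))
  k <- (l - 3L) %/% 2L
  stem5 <- random_bases(k)
  loop <- random_bases(l - 2L * k)
  c(stem5, loop, rev(unname(COMPLEMENT[stem5])))
}

#' Generate a synthetic dataset with planted truth
#'
#' See [generator_spec()] for the model. Deterministic for a fixed spec
#' (including its seed): two calls yield byte-identical output. In the
#' zero-noise limit all sequences of the same family are identical and the
#' realized length table equals the planted states exactly.
#'
#' @param spec A [generator_spec()].
#' @return A list with `sequences` (list of [rna_sequence()]) and `truth`, a
#'   list holding `msa` (true alignment, `ss_cons` attribute set from the
#'   true model), `region_map`, `model` ([structure_model()]), `lengths`
#'   (realized `lvr_length_table`), `states` (planted state per sequence and
#'   region), `exceptions` (logical, same shape), `clade_map` (over sequence
#'   ids) and `planted` (the planted synapomorphy triples).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  fams <- spec$families
  lvr_labels <- names(spec$lvr_states)
  n_lvr <- length(lvr_labels)
  ids <- unlist(lapply(fams, function(f) {
    sprintf("%s_s%02d", f, seq_len(spec$seqs_per_family))
  }))
  fam_of <- rep(fams, each = spec$seqs_per_family)
  n_seq <- length(ids)

  # conserved core blocks (n_lvr + 1), each with one planted stem
  n_blocks <- n_lvr + 1L
  blocks <- lapply(seq_len(n_blocks), function(b) {
    bl <- random_bases(spec$core_block_len)
    stem5 <- bl[seq_len(spec$stem_len)]
    bl[seq.int(spec$core_block_len - spec$stem_len + 1L, spec$core_block_len)] <-
      rev(unname(COMPLEMENT[stem5]))
    bl
  })

  # realized lengths: planted state +/- exception
  states <- matrix(0L, n_seq, n_lvr, dimnames = list(ids, lvr_labels))
  for (lab in lvr_labels) {
    states[, lab] <- spec$lvr_states[[lab]][fam_of]
  }
  exceptions <- matrix(
    stats::rbinom(n_seq * n_lvr, 1L, spec$lvr_indel_rate) == 1L,
    n_seq, n_lvr,
    dimnames = list(ids, lvr_labels)
  )
  deviation <- matrix(0L, n_seq, n_lvr, dimnames = list(ids, lvr_labels))
  if (any(exceptions)) {
    deviation[exceptions] <- sample(c(-1L, 1L), sum(exceptions), replace = TRUE)
  }
  realized <- pmax(states + deviation, 0L)
  exceptions <- realized != states # a -1 on a 0-state is no deviation

  # LVR content: one draw per (label, realized length) so that equal states
  # imply identical content (the zero-noise identity contract)
  content <- lapply(lvr_labels, function(lab) {
    lens <- sort(unique(realized[, lab]))
    stats::setNames(
      lapply(lens, function(l) lvr_content(l, spec$hairpin[[lab]])),
      as.character(lens)
    )
  })
  names(content) <- lvr_labels
  windows <- vapply(lvr_labels, function(lab) max(realized[, lab]), 0L)

  # column layout: block 1, LVR 1, block 2, ..., LVR n, block n+1
  seg_widths <- integer(0)
  seg_kind <- character(0)
  for (k in seq_len(n_lvr)) {
    seg_widths <- c(seg_widths, spec$core_block_len, windows[[k]])
    seg_kind <- c(seg_kind, "core", "lvr")
  }
  seg_widths <- c(seg_widths, spec$core_block_len)
  seg_kind <- c(seg_kind, "core")
  seg_start <- cumsum(c(0L, seg_widths[-length(seg_widths)]))
  n_cols <- sum(seg_widths)

  lvr_start <- seg_start[seg_kind == "lvr"]
  names(lvr_start) <- lvr_labels
  core_start <- seg_start[seg_kind == "core"]

  # assemble aligned rows (LVR content centered in its window)
  aligned <- character(n_seq)
  for (s in seq_len(n_seq)) {
    row <- rep("-", n_cols)
    for (b in seq_len(n_blocks)) {
      row[core_start[b] + seq_len(spec$core_block_len)] <- blocks[[b]]
    }
    for (k in seq_len(n_lvr)) {
      lab <- lvr_labels[[k]]
      l <- realized[s, lab]
      if (l > 0L) {
        off <- (windows[[k]] - l) %/% 2L
        row[lvr_start[[k]] + off + seq_len(l)] <-
          content[[lab]][[as.character(l)]]
      }
    }
    aligned[s] <- paste(row, collapse = "")
  }

  # core substitutions, compensated at stem positions with the given rate
  stem_pair_of <- rep(NA_integer_, n_cols) # partner column (1-based) or NA
  for (b in seq_len(n_blocks)) {
    for (t in seq_len(spec$stem_len)) {
      p5 <- core_start[b] + t
      p3 <- core_start[b] + spec$core_block_len - t + 1L
      stem_pair_of[p5] <- p3
      stem_pair_of[p3] <- p5
    }
  }
  core_cols <- unlist(lapply(seq_len(n_blocks), function(b) {
    core_start[b] + seq_len(spec$core_block_len)
  }))
  if (spec$sub_rate > 0) {
    for (s in seq_len(n_seq)) {
      row <- strsplit(aligned[s], "")[[1]]
      hit <- core_cols[stats::runif(length(core_cols)) < spec$sub_rate]
      for (p in hit) {
        partner <- stem_pair_of[[p]]
        if (!is.na(partner) &&
          stats::runif(1) < spec$compensatory_rate) {
          pick <- ALLOWED_PAIRS[sample.int(nrow(ALLOWED_PAIRS), 1L), ]
          row[p] <- pick[[1]]
          row[partner] <- pick[[2]]
        } else {
          row[p] <- sample(setdiff(RNA_BASES, row[p]), 1L)
        }
      }
      aligned[s] <- paste(row, collapse = "")
    }
  }

  truth_msa <- msa(ids, aligned)
  truth_map <- region_map(
    lvr_labels, lvr_start, lvr_start + windows,
    n_cols = n_cols
  )
  helices <- lapply(seq_len(n_blocks), function(b) {
    helix(
      core_start[b], core_start[b] + spec$stem_len,
      core_start[b] + spec$core_block_len - spec$stem_len,
      core_start[b] + spec$core_block_len
    )
  })
  truth_model <- structure_model(n_cols, helices, region_map = truth_map)
  attr(truth_msa, "ss_cons") <- model_ss_cons(truth_model)

  lengths <- lvr_length_table(
    id = rep(ids, times = n_lvr),
    region = rep(lvr_labels, each = n_seq),
    length = as.vector(realized)
  )
  cm <- clade_map(
    terminals = ids,
    clades = lapply(spec$clades, function(f) ids[fam_of %in% f])
  )
  sequences <- lapply(seq_len(n_seq), function(s) {
    rna_sequence(
      ids[[s]], gsub("-", "", aligned[[s]], fixed = TRUE),
      taxon = ids[[s]],
      description = paste0("family=", fam_of[[s]])
    )
  })
  names(sequences) <- ids
  list(
    sequences = sequences,
    truth = list(
      msa = truth_msa,
      region_map = truth_map,
      model = truth_model,
      lengths = lengths,
      states = states,
      realized = realized,
      exceptions = exceptions,
      clade_map = cm,
      planted = spec$planted,
      families = stats::setNames(fam_of, ids)
    )
  )
}

## Consensus dot-bracket string on model columns.
model_ss_cons <- function(model) {
  chars <- rep(".", model$n_cols)
  cp <- model_column_pairs(model)
  if (nrow(cp) > 0L) {
    chars[cp[, 1] + 1L] <- "("
    chars[cp[, 2] + 1L] <- ")"
  }
  paste(chars, collapse = "")
}

#' Write generator truth to disk
#'
#' Emits the true alignment (Stockholm, `SS_cons` from the true model, plus
#' gapped FASTA), the unaligned sequences (FASTA), and truth CSVs (region
#' map, length table, helix table), all round-trippable through the package
#' readers.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_truth <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- dataset$truth
  paths <- c(
    sequences = file.path(dir, "sequences.fasta"),
    alignment_stockholm = file.path(dir, "alignment.sto"),
    alignment_fasta = file.path(dir, "alignment.fasta"),
    region_map = file.path(dir, "regions.csv"),
    lengths = file.path(dir, "lengths.csv"),
    model = file.path(dir, "model.csv")
  )
  write_fasta(dataset$sequences, paths[["sequences"]])
  write_stockholm(truth$msa, paths[["alignment_stockholm"]])
  write_msa_fasta(truth$msa, paths[["alignment_fasta"]])
  write_region_map(truth$region_map, paths[["region_map"]])
  utils::write.csv(
    as.data.frame(truth$lengths), paths[["lengths"]],
    row.names = FALSE, quote = FALSE
  )
  write_model_csv(truth$model, paths[["model"]])
  invisible(paths)
}
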