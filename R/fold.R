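## Pseudoknot-free secondary structures and base-pair maximization folding.
##
## The folding objective is Nussinov-style pair maximization with a secondary
## objective (maximize the number of stacked pairs) as tie-break, which keeps
## the optimum oracle-verifiable by exhaustive enumeration at small lengths
## while favoring the helix-like candidates that consensus-model selection
## needs. Full nearest-neighbor thermodynamics is deliberately out of scope;
## users with an external folder can feed its dot-bracket output through
## [parse_dot_bracket()].

#' Create a secondary structure
#'
#' A pseudoknot-free set of base pairs on one sequence. Pairs are `(i, j)`
#' with `i < j`, 0-based sequence positions. Invariants enforced: each
#' position in at most one pair; no crossing pairs; hairpin loops of at least
#' `min_loop` unpaired residues.
#'
#' @param length Sequence length.
#' @param pairs Two-column matrix (or empty) of 0-based pair positions.
#' @param min_loop Minimum hairpin loop size to validate against.
#' @return An object of class `secondary_structure`.
#' @export
secondary_structure <- function(length, pairs = matrix(integer(0), ncol = 2),
                                min_loop = 0L) {
  length <- as.integer(length)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  colnames(pairs) <- c("i", "j")
  if (nrow(pairs) > 0L) {
    if (any(pairs < 0L) || any(pairs >= length)) {
      stop("pair positions out of range [0, length)", call. = FALSE)
    }
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs need i < j", call. = FALSE)
    if (anyDuplicated(as.vector(pairs)) > 0L) {
      stop("a position occurs in more than one pair", call. = FALSE)
    }
    if (any(pairs[, 2] - pairs[, 1] - 1L < min_loop)) {
      stop("hairpin loop below min_loop = ", min_loop, call. = FALSE)
    }
    ord <- order(pairs[, 1])
    pairs <- pairs[ord, , drop = FALSE]
    if (has_crossing(pairs)) stop("crossing pairs (pseudoknot)", call. = FALSE)
  }
  structure(list(length = length, pairs = pairs), class = "secondary_structure")
}

has_crossing <- function(pairs) {
  n <- nrow(pairs)
  if (n < 2L) return(FALSE)
  for (a in seq_len(n - 1L)) {
    for (b in (a + 1L):n) {
      i <- pairs[a, 1]; j <- pairs[a, 2]
      k <- pairs[b, 1]; l <- pairs[b, 2]
      if (i < k && k < j && j < l) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf(
    "<secondary_structure> length %d, %d pairs\n  %s\n",
    x$length, nrow(x$pairs), dot_bracket(x)
  ))
  invisible(x)
}

#' Number of base pairs
#' @param structure A [secondary_structure()].
#' @return Integer pair count.
#' @export
n_pairs <- function(structure) nrow(structure$pairs)

## DP tables for pair maximization. Value at (i,j) is the lexicographic
## maximum of (pairs, stacked pairs) over all valid structures of seq[i..j].
## Fp is the same quantity restricted to structures that pair (i,j)
## (-Inf when (i,j) cannot pair). 1-based indices internally.
fold_tables <- function(chars, rule, min_loop) {
  n <- length(chars)
  pm <- pair_matrix(rule)
  can <- function(i, j) {
    (j - i - 1L) >= min_loop && pm[chars[[i]], chars[[j]]]
  }
  Fp_ <- matrix(0L, n, n) # pairs component of F
  Fs_ <- matrix(0L, n, n) # stacks component of F
  Pp_ <- matrix(-1L, n, n) # pairs component of Fp (-1 = cannot pair)
  Ps_ <- matrix(0L, n, n)
  if (n == 0L) {
    return(list(Fp = Fp_, Fs = Fs_, Pp = Pp_, Ps = Ps_, can = can, n = n))
  }
  for (span in seq_len(n)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      # paired (i,j) table
      if (can(i, j)) {
        if (i + 1L > j - 1L) {
          Pp_[i, j] <- 1L
          Ps_[i, j] <- 0L
        } else {
          bp <- Fp_[i + 1L, j - 1L] + 1L
          bs <- Fs_[i + 1L, j - 1L]
          if (Pp_[i + 1L, j - 1L] >= 0L) {
            sp <- Pp_[i + 1L, j - 1L] + 1L
            ss <- Ps_[i + 1L, j - 1L] + 1L
            if (sp > bp || (sp == bp && ss > bs)) {
              bp <- sp
              bs <- ss
            }
          }
          Pp_[i, j] <- bp
          Ps_[i, j] <- bs
        }
      }
      # general table: i unpaired, or i paired with some k
      bp <- Fp_[i + 1L, j]
      bs <- Fs_[i + 1L, j]
      ks <- seq.int(i, j)
      ks <- ks[ks >= i + min_loop + 1L]
      for (k in ks) {
        if (Pp_[i, k] < 0L) next
        rp <- Pp_[i, k] + (if (k + 1L <= j) Fp_[k + 1L, j] else 0L)
        rs <- Ps_[i, k] + (if (k + 1L <= j) Fs_[k + 1L, j] else 0L)
        if (rp > bp || (rp == bp && rs > bs)) {
          bp <- rp
          bs <- rs
        }
      }
      Fp_[i, j] <- bp
      Fs_[i, j] <- bs
    }
  }
  list(Fp = Fp_, Fs = Fs_, Pp = Pp_, Ps = Ps_, can = can, n = n)
}

## Deterministic traceback: at each subproblem prefer pairing the left end
## (smallest partner k first) over leaving it unpaired; inside a pair prefer
## the stacked continuation when it ties.
fold_traceback <- function(tb, min_loop) {
  pairs <- list()
  trace <- function(i, j) {
    while (i < j) {
      target_p <- tb$Fp[i, j]
      target_s <- tb$Fs[i, j]
      if (target_p == 0L) return(invisible(NULL))
      done <- FALSE
      ks <- seq.int(i + min_loop + 1L, j)
      for (k in ks) {
        if (tb$Pp[i, k] < 0L) next
        rest_p <- if (k + 1L <= j) tb$Fp[k + 1L, j] else 0L
        rest_s <- if (k + 1L <= j) tb$Fs[k + 1L, j] else 0L
        if (tb$Pp[i, k] + rest_p == target_p &&
          tb$Ps[i, k] + rest_s == target_s) {
          trace_paired(i, k)
          i <- k + 1L
          done <- TRUE
          break
        }
      }
      if (!done) i <- i + 1L # i unpaired
    }
    invisible(NULL)
  }
  trace_paired <- function(i, j) {
    repeat {
      pairs[[length(pairs) + 1L]] <<- c(i, j)
      if (i + 1L > j - 1L) return(invisible(NULL))
      # stacked continuation first (ties resolved toward stacking)
      if (tb$Pp[i + 1L, j - 1L] >= 0L &&
        tb$Pp[i + 1L, j - 1L] + 1L == tb$Pp[i, j] &&
        tb$Ps[i + 1L, j - 1L] + 1L == tb$Ps[i, j]) {
        i <- i + 1L
        j <- j - 1L
        next
      }
      trace(i + 1L, j - 1L)
      return(invisible(NULL))
    }
  }
  if (tb$n >= 2L) trace(1L, tb$n)
  if (length(pairs) == 0L) {
    matrix(integer(0), ncol = 2)
  } else {
    do.call(rbind, pairs) - 1L # back to 0-based
  }
}

#' Fold a sequence by base-pair maximization
#'
#' Dynamic-programming maximization of the base-pair count over all
#' pseudoknot-free structures, with the number of stacked pairs (pairs
#' `(i, j)` whose neighbor `(i+1, j-1)` is also paired) as a deterministic
#' tie-break. `N` never pairs. An empty sequence yields an empty structure.
#'
#' @param seq Residue string over `A,C,G,U,N` (T accepted, transcribed).
#' @param rule A [pair_rule()]; default canonical + wobble.
#' @param min_loop Minimum hairpin loop length (unpaired residues enclosed by
#'   a pair); default 3, the standard steric minimum.
#' @return A [secondary_structure()].
#' @examples
#' dot_bracket(fold_max_pairs("GGGAAACCC", pair_rule("canonical")))
#' @export
fold_max_pairs <- function(seq, rule = pair_rule(), min_loop = 3L) {
  seq <- normalize_residues(seq)
  if (!nzchar(seq)) return(secondary_structure(0L))
  chars <- strsplit(seq, "")[[1]]
  if (any(!chars %in% RNA_ALPHABET)) {
    stop("sequence contains characters outside {A,C,G,U,N}", call. = FALSE)
  }
  min_loop <- as.integer(min_loop)
  stopifnot(min_loop >= 0L)
  tb <- fold_tables(chars, rule, min_loop)
  secondary_structure(length(chars), fold_traceback(tb, min_loop),
    min_loop = min_loop
  )
}

#' Enumerate all maximum-pair structures
#'
#' Returns every structure achieving the optimal base-pair count (the
#' co-optimal set used as a candidate pool for consensus-model selection),
#' in lexicographic order of their sorted pair lists, truncated to
#' `max_structures`. Meant for short segments; the co-optimal set can grow
#' quickly with length.
#'
#' @inheritParams fold_max_pairs
#' @param max_structures Maximum number of structures to return.
#' @return List of [secondary_structure()] objects.
#' @export
enumerate_cooptimal <- function(seq, rule = pair_rule(), min_loop = 3L,
                                max_structures = 100L) {
  seq <- normalize_residues(seq)
  if (!nzchar(seq)) return(list(secondary_structure(0L)))
  chars <- strsplit(seq, "")[[1]]
  min_loop <- as.integer(min_loop)
  tb <- fold_tables(chars, rule, min_loop)
  n <- tb$n
  # enumerate structures of seq[i..j] achieving pair count tb$Fp[i, j];
  # first-position decomposition, so each structure arises exactly once
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- list()
    target <- tb$Fp[i, j]
    if (tb$Fp[i + 1L, j] == target ||
      (i + 1L == j && target == 0L)) {
      sub <- if (i + 1L <= j) rec(i + 1L, j) else list(list())
      out <- c(out, sub)
    }
    ks <- seq.int(i, j)
    ks <- ks[ks >= i + min_loop + 1L]
    for (k in ks) {
      if (tb$Pp[i, k] < 0L) next
      rest <- if (k + 1L <= j) tb$Fp[k + 1L, j] else 0L
      if (tb$Pp[i, k] + rest != target) next
      inner_list <- if (i + 1L <= k - 1L) {
        # structures of (i+1, k-1) achieving Pp[i,k] - 1 pairs
        if (tb$Fp[i + 1L, k - 1L] == tb$Pp[i, k] - 1L) {
          rec(i + 1L, k - 1L)
        } else {
          rec_exact(i + 1L, k - 1L, tb$Pp[i, k] - 1L)
        }
      } else {
        list(list())
      }
      rest_list <- if (k + 1L <= j) rec(k + 1L, j) else list(list())
      for (inner in inner_list) {
        for (tail in rest_list) {
          out[[length(out) + 1L]] <- c(list(c(i, k)), inner, tail)
        }
      }
    }
    out
  }
  # structures of seq[i..j] with exactly m pairs (m may be < optimum when an
  # enclosing pair constrains the inner optimum); only reached when
  # m == Fp[i, j], so rec() suffices in practice
  rec_exact <- function(i, j, m) {
    if (m == tb$Fp[i, j]) return(rec(i, j))
    stop("internal error: non-optimal inner enumeration requested")
  }
  structs <- rec(1L, n)
  mats <- lapply(structs, function(ps) {
    if (length(ps) == 0L) {
      matrix(integer(0), ncol = 2)
    } else {
      m <- do.call(rbind, ps) - 1L
      m[order(m[, 1]), , drop = FALSE]
    }
  })
  keys <- vapply(
    mats,
    function(m) paste(sprintf("%04d-%04d", m[, 1], m[, 2]), collapse = ";"),
    ""
  )
  mats <- mats[order(keys)]
  mats <- utils::head(mats, max_structures)
  lapply(mats, function(m) secondary_structure(n, m, min_loop = min_loop))
}

#' Dot-bracket notation
#'
#' @param structure A [secondary_structure()].
#' @return Dot-bracket string (`(`, `)`, `.`), length = sequence length.
#' @export
dot_bracket <- function(structure) {
  stopifnot(inherits(structure, "secondary_structure"))
  chars <- rep(".", structure$length)
  if (nrow(structure$pairs) > 0L) {
    chars[structure$pairs[, 1] + 1L] <- "("
    chars[structure$pairs[, 2] + 1L] <- ")"
  }
  paste(chars, collapse = "")
}

#' Parse dot-bracket notation
#'
#' @param x Dot-bracket string over `(`, `)`, `.` (WUSS letters and `_,:`
#'   treated as unpaired; `<>` as brackets).
#' @param min_loop Loop constraint to validate against (default 0: accept any
#'   balanced string).
#' @return A [secondary_structure()]. Unbalanced input is an error reporting
#'   the 0-based offending position.
#' @export
parse_dot_bracket <- function(x, min_loop = 0L) {
  chars <- strsplit(x, "")[[1]]
  open <- integer(0)
  pairs <- list()
  for (p in seq_along(chars)) {
    ch <- chars[[p]]
    if (ch %in% c("(", "<", "[")) {
      open <- c(open, p)
    } else if (ch %in% c(")", ">", "]")) {
      if (length(open) == 0L) {
        stop("unbalanced ')' at position ", p - 1L, call. = FALSE)
      }
      i <- open[[length(open)]]
      open <- open[-length(open)]
      pairs[[length(pairs) + 1L]] <- c(i, p)
    }
  }
  if (length(open) > 0L) {
    stop("unbalanced '(' at position ", open[[1]] - 1L, call. = FALSE)
  }
  m <- if (length(pairs) == 0L) {
    matrix(integer(0), ncol = 2)
  } else {
    do.call(rbind, pairs) - 1L
  }
  secondary_structure(length(chars), m, min_loop = min_loop)
}
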