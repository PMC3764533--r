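# Independent brute-force oracles. These deliberately avoid the package's
# dynamic-programming code paths: folding structures are enumerated by naive
# recursion over the leftmost position, and alignments by naive recursion
# over edit operations with an affine-gap state.

# All pseudoknot-free structures (lists of 1-based pair vectors) of
# chars[i..j] under a pairing predicate and loop constraint.
brute_structures <- function(chars, allowed, min_loop, i = 1L,
                             j = length(chars)) {
  if (i >= j) {
    return(list(list()))
  }
  out <- brute_structures(chars, allowed, min_loop, i + 1L, j) # i unpaired
  ks <- seq.int(i, j)
  ks <- ks[ks >= i + min_loop + 1L]
  for (k in ks) {
    if (!allowed(chars[[i]], chars[[k]])) next
    inner <- brute_structures(chars, allowed, min_loop, i + 1L, k - 1L)
    rest <- brute_structures(chars, allowed, min_loop, k + 1L, j)
    for (x in inner) {
      for (y in rest) {
        out[[length(out) + 1L]] <- c(list(c(i, k)), x, y)
      }
    }
  }
  out
}

pair_pred <- function(rule_name) {
  allowed <- switch(rule_name,
    canonical = c("AU", "UA", "GC", "CG"),
    `canonical+wobble` = c("AU", "UA", "GC", "CG", "GU", "UG"),
    extended = c(
      "AU", "UA", "GC", "CG", "GU", "UG", "AG", "GA", "AC", "CA"
    )
  )
  function(a, b) paste0(a, b) %in% allowed
}

brute_max_pairs <- function(seq, rule_name = "canonical+wobble",
                            min_loop = 3L) {
  chars <- strsplit(seq, "")[[1]]
  structs <- brute_structures(chars, pair_pred(rule_name), min_loop)
  max(vapply(structs, length, 0L))
}

brute_count_cooptimal <- function(seq, rule_name = "canonical+wobble",
                                  min_loop = 3L) {
  chars <- strsplit(seq, "")[[1]]
  structs <- brute_structures(chars, pair_pred(rule_name), min_loop)
  sizes <- vapply(structs, length, 0L)
  sum(sizes == max(sizes))
}

# Brute-force optimal global alignment score with affine gaps
# (gap of length L costs open + L * ext). Recursion over (i, j, last state).
brute_align_score <- function(sa, sb, match = 2, mismatch = -1,
                              open = -5, ext = -1) {
  ca <- strsplit(sa, "")[[1]]
  cb <- strsplit(sb, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, state) {
    # best score of aligning a[i..], b[j..] given the previous column state
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    if (i > length(ca) && j > length(cb)) {
      return(0)
    }
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[[i]] == cb[[j]]) match else mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(ca)) {
      cost <- ext + if (state == "X") 0 else open
      best <- max(best, cost + rec(i + 1L, j, "X"))
    }
    if (j <= length(cb)) {
      cost <- ext + if (state == "Y") 0 else open
      best <- max(best, cost + rec(i, j + 1L, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "M")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Independent per-pair recount of retained stems: walks helices column by
# column with plain string indexing.
brute_retained <- function(model, row, rule_name = "canonical+wobble") {
  pred <- pair_pred(rule_name)
  total <- 0L
  for (r in seq_len(nrow(model$helices))) {
    h <- model$helices[r, ]
    len <- h$side5_end - h$side5_start
    for (k in seq_len(len) - 1L) {
      a <- substr(row, h$side5_start + k + 1L, h$side5_start + k + 1L)
      b <- substr(
        row, h$side3_start + (len - 1L - k) + 1L,
        h$side3_start + (len - 1L - k) + 1L
      )
      if (a != "-" && b != "-" && pred(a, b)) total <- total + 1L
    }
  }
  total
}
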