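test_that("identical sequences align gap-free at score n * match", {
  a <- rna_sequence("a", "ACGUACGU")
  b <- rna_sequence("b", "ACGUACGU")
  aln <- global_align(a, b)
  expect_equal(aln$score, 16)
  expect_equal(aln$aligned_a, "ACGUACGU")
  expect_equal(aln$aligned_b, "ACGUACGU")
})

test_that("alignment scores equal the brute-force optimum", {
  set.seed(123)
  for (rep in 1:30) {
    sa <- random_rna(sample(2:6, 1))
    sb <- random_rna(sample(2:6, 1))
    aln <- global_align(sa, sb)
    expect_equal(aln$score, brute_align_score(sa, sb), info = paste(sa, sb))
  }
  # with unit costs too
  expect_equal(
    global_align("ACGU", "AGU",
      match = 1, mismatch = -1, gap_open = -1, gap_extend = -1
    )$score,
    brute_align_score("ACGU", "AGU", 1, -1, -1, -1)
  )
})

test_that("alignment score is symmetric and rejects empty input", {
  set.seed(321)
  for (rep in 1:10) {
    sa <- random_rna(5)
    sb <- random_rna(7)
    expect_equal(global_align(sa, sb)$score, global_align(sb, sa)$score)
  }
  expect_error(global_align("", "ACGU"), "empty")
})

test_that("aligned strings reconstruct the inputs and realize the score", {
  set.seed(456)
  for (rep in 1:20) {
    sa <- random_rna(sample(3:12, 1))
    sb <- random_rna(sample(3:12, 1))
    aln <- global_align(sa, sb)
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    expect_equal(gsub("-", "", aln$aligned_a), sa)
    expect_equal(gsub("-", "", aln$aligned_b), sb)
    expect_false(any(ca == "-" & cb == "-"))
    # recompute the score of the emitted alignment
    score <- 0
    state <- "M"
    for (k in seq_along(ca)) {
      if (ca[k] != "-" && cb[k] != "-") {
        score <- score + if (ca[k] == cb[k]) 2 else -1
        state <- "M"
      } else if (cb[k] == "-") {
        score <- score - 1 - if (state == "X") 0 else 5
        state <- "X"
      } else {
        score <- score - 1 - if (state == "Y") 0 else 5
        state <- "Y"
      }
    }
    expect_equal(score, aln$score)
  }
})

test_that("alignment scores agree with Biostrings::pairwiseAlignment", {
  mat <- matrix(-1, 4, 4,
    dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U"))
  )
  diag(mat) <- 2
  set.seed(654)
  for (rep in 1:15) {
    sa <- random_rna(sample(10:40, 1))
    sb <- random_rna(sample(10:40, 1))
    ref <- Biostrings::pairwiseAlignment(
      sa, sb,
      type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 1
    )
    expect_equal(global_align(sa, sb)$score, Biostrings::score(ref),
      info = paste(sa, sb)
    )
  }
})

test_that("region transfer through an identity alignment is the identity", {
  ref <- rna_sequence("ref", "ACGUACGUACGU")
  regions <- region_map(c("B", "C"), c(2, 8), c(5, 10))
  aln <- global_align(ref, rna_sequence("q", "ACGUACGUACGU"))
  expect_equal(
    as.data.frame(transfer_regions(regions, aln)),
    as.data.frame(regions)
  )
})

test_that("a region deleted in the query maps to a zero-length interval", {
  aln <- structure(
    list(
      a_id = "ref", b_id = "q",
      aligned_a = "AAAACGGGUUUU",
      aligned_b = "AAAA----UUUU",
      score = 0
    ),
    class = "pairwise_alignment"
  )
  regions <- region_map("L", 4, 8) # the CGGG block
  out <- transfer_regions(regions, aln)
  expect_equal(out$start, 4L)
  expect_equal(out$end, 4L)
})

test_that("boundaries in query gaps round inward (start right, end left)", {
  # query misses the first and last residue of the region
  aln <- structure(
    list(
      a_id = "ref", b_id = "q",
      aligned_a = "AAACGGGCUUU",
      aligned_b = "AAA-GGG-UUU",
      score = 0
    ),
    class = "pairwise_alignment"
  )
  regions <- region_map("L", 3, 8) # CGGGC on the reference
  out <- transfer_regions(regions, aln)
  expect_equal(out$start, 3L)
  expect_equal(out$end, 6L) # only GGG survives in the query
})

test_that("transferred regions contain exactly the query residues aligned in-region", {
  set.seed(789)
  for (rep in 1:20) {
    sa <- random_rna(sample(20:40, 1))
    sb <- random_rna(sample(15:40, 1))
    aln <- global_align(sa, sb)
    n <- nchar(sa)
    s <- sample(0:(n - 5), 1)
    e <- s + sample(2:5, 1)
    out <- transfer_regions(region_map("R", s, e), aln)
    # independent recount through alignment columns
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    acum <- cumsum(ca != "-")
    in_region <- acum >= (s + 1) & acum <= e & !(ca == "-" & acum == s)
    # columns whose reference coordinate lies in [s, e), including
    # insertion columns inside the region span
    first_col <- which(acum == s + 1 & ca != "-")[1]
    last_col <- max(which(acum == e & ca != "-"))
    expected <- sum(cb[first_col:last_col] != "-")
    expect_equal(out$end - out$start, expected)
    expect_lte(out$end - out$start, nchar(sb))
  }
})

test_that("transferred maps stay disjoint and ordered", {
  set.seed(999)
  for (rep in 1:10) {
    sa <- random_rna(30)
    sb <- random_rna(sample(20:35, 1))
    aln <- global_align(sa, sb)
    regions <- region_map(c("B", "C", "D"), c(2, 12, 22), c(8, 18, 28))
    out <- transfer_regions(regions, aln)
    expect_equal(out$label, c("B", "C", "D"))
    expect_true(all(out$start[-1] >= out$end[-3]))
    expect_lte(sum(out$end - out$start), nchar(sb))
  }
})

test_that("regions beyond the reference are rejected", {
  aln <- global_align("ACGUACGU", "ACGUACGU")
  expect_error(
    transfer_regions(region_map("B", 5, 12), aln),
    "outside reference"
  )
})
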