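make_small_model <- function() {
  # one 3-bp helix: columns 0,1,2 pair with 9,8,7
  structure_model(10, helix(0, 3, 7, 10))
}

test_that("retained stem length counts allowed, gap-free column pairs", {
  m <- make_small_model()
  # G-C, A-U, G-U under canonical+wobble: all three retained
  expect_equal(retained_stem_length(m, "GAGUUUUUUC"), 3L)
  # gap in one paired column destroys one pair
  expect_equal(retained_stem_length(m, "GA-UUUUUUC"), 2L)
  # disallowed pair contributes 0
  expect_equal(retained_stem_length(m, "AAGUUUUUUC"), 2L)
  expect_error(retained_stem_length(m, "GAGU"), "length")
})

test_that("retained stem length equals a brute-force recount on random models", {
  set.seed(77)
  for (rep in 1:20) {
    n_cols <- 30L
    hx <- list(
      helix(0, 3, 12, 15),
      helix(16, 18, 25, 27)
    )
    model <- structure_model(n_cols, hx)
    chars <- sample(c("A", "C", "G", "U", "-"), n_cols, replace = TRUE)
    row <- paste(chars, collapse = "")
    expect_equal(
      retained_stem_length(model, row),
      brute_retained(model, row)
    )
  }
})

test_that("model_score totals per-row retention and reports the minimum", {
  m <- make_small_model()
  aln <- msa(c("a", "b"), c("GAGUUUUUUC", "GA-UUUUUUC"))
  sc <- model_score(m, aln)
  expect_equal(sc$total, 5L)
  expect_equal(sc$min_per_row, 2L)
  expect_equal(sc$n_helices, 1L)
  expect_equal(
    sc$total,
    sum(vapply(aln$seqs, function(r) retained_stem_length(m, r), 0L))
  )
  # empty model scores zero
  sc0 <- model_score(structure_model(10), aln)
  expect_equal(sc0[c("total", "min_per_row", "n_helices")],
    list(total = 0L, min_per_row = 0L, n_helices = 0L)
  )
})

test_that("select_model ranks by total, then min-per-row, then helix count, then order", {
  aln <- msa(c("a", "b"), c("GAGUUUUUUC", "GAGUUUUUUC"))
  strong <- make_small_model() # total 6
  weak <- structure_model(10, helix(3, 4, 8, 9)) # U-U: total 0
  expect_identical(
    select_model(list(weak, strong), aln)$helices,
    strong$helices
  )
  # tie on total: prefer larger min_per_row
  aln2 <- msa(c("a", "b"), c("GC--------", "--------GC"))
  m1 <- structure_model(10, helix(0, 1, 1, 2)) # row a retains 1, row b 0
  m2 <- structure_model(10, helix(8, 9, 9, 10)) # row a 0, row b 1
  # both have total 1, min 0; tie falls through to input order
  expect_equal(attr(select_model(list(m1, m2), aln2), "rank_index"), 1L)
  expect_equal(attr(select_model(list(m2, m1), aln2), "rank_index"), 1L)
  expect_error(select_model(list(), aln), "nonempty")
})

test_that("select_model is invariant to row permutation", {
  set.seed(88)
  ds <- generate_dataset(generator_spec(
    sub_rate = 0.1, compensatory_rate = 0.9, seed = 99L
  ))
  aln <- ds$truth$msa
  rivals <- lapply(1:5, function(k) {
    sample_random_model(
      aln$n_cols,
      rep(5L, 6L)
    )
  })
  cands <- c(list(ds$truth$model), rivals)
  pick1 <- select_model(cands, aln)
  perm <- sample(length(aln$ids))
  aln_perm <- msa(aln$ids[perm], unname(aln$seqs)[perm])
  pick2 <- select_model(cands, aln_perm)
  expect_identical(pick1$helices, pick2$helices)
})

test_that("adding a helix never decreases the total score", {
  set.seed(89)
  ds <- generate_dataset(generator_spec(seed = 7L))
  aln <- ds$truth$msa
  base <- ds$truth$model
  for (k in seq_len(nrow(base$helices) - 1L)) {
    sub <- structure_model(base$n_cols, base$helices[seq_len(k), ])
    ext <- structure_model(base$n_cols, base$helices[seq_len(k + 1L), ])
    expect_lte(model_score(sub, aln)$total, model_score(ext, aln)$total)
  }
})

test_that("projection onto a sequence drops gapped pairs and flags noncanonical ones", {
  m <- make_small_model()
  # gapless row: pairs shift to sequence positions identically
  st <- sequence_structure_from_model(m, "GAGUUUUUUC")
  expect_equal(st$pairs, cbind(i = 0:2, j = 9:7)[order(0:2), ],
    ignore_attr = TRUE
  )
  expect_equal(attr(st, "noncanonical"), c(FALSE, FALSE, FALSE))
  # a fully gapped 3' side yields no pairs
  st2 <- sequence_structure_from_model(m, "GAGUUUU---")
  expect_equal(n_pairs(st2), 0L)
  expect_equal(st2$length, 7L)
  # disallowed pairs are kept but flagged
  st3 <- sequence_structure_from_model(m, "AAGUUUUUUC")
  expect_equal(n_pairs(st3), 3L)
  expect_equal(sum(attr(st3, "noncanonical")), 1L)
  # projection then dot-bracket has ungapped length
  expect_equal(nchar(dot_bracket(st2)), 7L)
})

test_that("model CSV round-trips", {
  m <- structure_model(40, list(helix(0, 5, 15, 20), helix(22, 25, 30, 33)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_model_csv(m, f)
  back <- read_model_csv(f, n_cols = 40)
  expect_equal(as.data.frame(back$helices), as.data.frame(m$helices))
})

test_that("structure_model rejects conflicting or crossing helices", {
  expect_error(
    structure_model(20, list(helix(0, 3, 10, 13), helix(2, 4, 15, 17))),
    "share"
  )
  expect_error(
    structure_model(20, list(helix(0, 2, 8, 10), helix(4, 6, 14, 16))),
    "cross"
  )
  expect_error(structure_model(5, helix(0, 3, 7, 10)), "outside")
})
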