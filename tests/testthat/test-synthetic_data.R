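test_that("zero-noise generation yields identical same-family sequences and exact states", {
  ds <- generate_dataset(generator_spec(seed = 3L))
  truth <- ds$truth
  fams <- truth$families
  for (f in unique(fams)) {
    members <- names(fams)[fams == f]
    res <- vapply(ds$sequences[members], `[[`, "", "residues")
    expect_equal(length(unique(res)), 1L, info = f)
  }
  # realized lengths equal planted states exactly
  expect_equal(truth$realized, truth$states)
  expect_false(any(truth$exceptions))
  # the length table is consistent with the alignment + region map
  expect_equal(
    as.data.frame(lvr_lengths(truth$msa, truth$region_map)),
    as.data.frame(truth$lengths)
  )
})

test_that("generation is deterministic for a fixed seed", {
  d1 <- generate_dataset(generator_spec(seed = 42L, sub_rate = 0.1, lvr_indel_rate = 0.05))
  d2 <- generate_dataset(generator_spec(seed = 42L, sub_rate = 0.1, lvr_indel_rate = 0.05))
  expect_identical(d1$truth$msa$seqs, d2$truth$msa$seqs)
  expect_identical(d1$truth$lengths, d2$truth$lengths)
  d3 <- generate_dataset(generator_spec(seed = 43L, sub_rate = 0.1, lvr_indel_rate = 0.05))
  expect_false(identical(d1$truth$msa$seqs, d3$truth$msa$seqs))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_dataset(generator_spec(seed = 9L)))
  expect_identical(.Random.seed, before)
})

test_that("exception counts follow the indel-rate binomial", {
  # 1000 (sequence, region) draws at rate 0.05; 99% binomial CI
  spec <- generator_spec(
    n_families = 5L, seqs_per_family = 50L,
    lvr_indel_rate = 0.05, seed = 11L
  )
  ds <- generate_dataset(spec)
  n_cells <- length(ds$truth$exceptions)
  expect_equal(n_cells, 1000L)
  k <- sum(ds$truth$exceptions)
  ci <- qbinom(c(0.005, 0.995), n_cells, 0.05)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
  # exceptions deviate by exactly 1 nt
  dev <- abs(ds$truth$realized - ds$truth$states)
  expect_true(all(dev[ds$truth$exceptions] == 1L))
  expect_true(all(dev[!ds$truth$exceptions] == 0L))
})

test_that("hairpin LVR content folds back on itself", {
  ds <- generate_dataset(generator_spec(seed = 21L))
  truth <- ds$truth
  m <- msa_matrix(truth$msa)
  # LVR E of family F4 has the 9-nt state: stem of 3 bp around a 3-nt loop
  cols <- region_columns(truth$region_map, "E") + 1L
  row <- m["F4_s01", cols]
  content <- paste(row[row != "-"], collapse = "")
  expect_equal(nchar(content), 9L)
  st <- fold_max_pairs(content, pair_rule("canonical"))
  expect_gte(n_pairs(st), 3L)
})

test_that("invalid generator specs are rejected", {
  expect_error(
    generator_spec(clades = list(bad = c("F9"))),
    "unknown family"
  )
  expect_error(generator_spec(sub_rate = 1.5), "rates")
  expect_error(
    generator_spec(lvr_states = list(B = c(F1 = 1L))),
    "every family"
  )
})

test_that("truth files round-trip through the package readers", {
  ds <- generate_dataset(generator_spec(seed = 13L, sub_rate = 0.05))
  dir <- withr::local_tempdir()
  paths <- write_truth(ds, dir)
  truth <- ds$truth

  aln <- read_msa(paths[["alignment_stockholm"]], "stockholm")
  expect_equal(aln$seqs, truth$msa$seqs)
  expect_equal(attr(aln, "ss_cons"), attr(truth$msa, "ss_cons"))

  aln2 <- read_msa(paths[["alignment_fasta"]], "fasta")
  expect_equal(aln2$seqs, truth$msa$seqs)

  map <- read_region_map(paths[["region_map"]])
  expect_equal(as.data.frame(map), as.data.frame(truth$region_map))

  seqs <- read_fasta(paths[["sequences"]])
  expect_equal(
    vapply(seqs, `[[`, "", "residues"),
    vapply(ds$sequences, `[[`, "", "residues")
  )

  tab <- utils::read.csv(paths[["lengths"]], stringsAsFactors = FALSE)
  expect_equal(
    lvr_length_table(tab$id, tab$region, tab$length),
    truth$lengths
  )

  model <- read_model_csv(paths[["model"]], n_cols = truth$msa$n_cols)
  expect_equal(
    as.data.frame(model$helices),
    as.data.frame(truth$model$helices)
  )
})

test_that("column profile on zero-noise truth marks exactly the planted LVR columns", {
  ds <- generate_dataset(generator_spec(seed = 8L))
  truth <- ds$truth
  prof <- column_profile(truth$msa)
  lvr_cols <- unlist(lapply(
    truth$region_map$label,
    function(l) region_columns(truth$region_map, l)
  ))
  # variable columns all lie inside planted LVRs; conserved runs inside an
  # LVR (the common central columns) are shorter than the absorption block
  expect_true(all(prof$col[prof$is_variable] %in% lvr_cols))
  got <- delimit_lvrs(prof)
  expect_equal(as.data.frame(got), as.data.frame(truth$region_map))
})

test_that("zero-noise end-to-end recovers the planted synapomorphies exactly", {
  for (seed in 1:5) {
    ds <- generate_dataset(generator_spec(seed = seed))
    truth <- ds$truth
    map <- delimit_lvrs(column_profile(truth$msa))
    tab <- lvr_lengths(truth$msa, map)
    cand <- flag_synapomorphies(tab, truth$clade_map)
    key <- paste(cand$clade, cand$region, cand$state_length)
    planted <- paste(
      truth$planted$clade, truth$planted$region, truth$planted$length
    )
    expect_setequal(key, planted)
    expect_true(all(cand$unique_within_parent))
  }
})

test_that("the planted model outscores random rivals under compensatory noise", {
  set.seed(55)
  wins <- 0L
  trials <- 10L
  for (t in seq_len(trials)) {
    ds <- generate_dataset(generator_spec(
      sub_rate = 0.1, compensatory_rate = 0.9, seed = 1000L + t
    ))
    aln <- ds$truth$msa
    planted_total <- model_score(ds$truth$model, aln)$total
    lens <- ds$truth$model$helices
    lens <- lens$side5_end - lens$side5_start
    rival_totals <- vapply(1:20, function(k) {
      model_score(sample_random_model(aln$n_cols, lens), aln)$total
    }, 0L)
    if (all(rival_totals < planted_total)) wins <- wins + 1L
  }
  expect_equal(wins, trials)
})
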