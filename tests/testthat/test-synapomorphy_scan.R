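toy_table <- function() {
  # 6 ids, 2 regions; clade {a1,a2,a3} fixed at 5 nt in R1, varied elsewhere
  lvr_length_table(
    id = rep(c("a1", "a2", "a3", "b1", "b2", "b3"), times = 2),
    region = rep(c("R1", "R2"), each = 6),
    length = c(5, 5, 5, 7, 8, 7, 4, 6, 4, 4, 6, 4)
  )
}

toy_clades <- function() {
  clade_map(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    list(A = c("a1", "a2", "a3"), B = c("b1", "b2", "b3"))
  )
}

test_that("state distributions tally clade lengths", {
  tab <- toy_table()
  expect_equal(
    state_distribution(tab, c("a1", "a2", "a3"), "R1"),
    c("5" = 3L)
  )
  expect_equal(length(state_distribution(tab, character(0), "R1")), 0L)
  set.seed(9)
  for (rep in 1:10) {
    ids <- paste0("s", 1:20)
    tab <- lvr_length_table(ids, rep("R", 20), sample(3:6, 20, replace = TRUE))
    members <- sample(ids, 8)
    got <- state_distribution(tab, members, "R")
    manual <- table(tab$length[tab$id %in% members])
    expect_equal(got, stats::setNames(as.integer(manual), names(manual)))
    expect_equal(sum(got), length(members))
  }
})

test_that("clade-fixed states rare outside are flagged, with uniqueness noted", {
  cand <- flag_synapomorphies(toy_table(), toy_clades())
  a_r1 <- cand[cand$clade == "A" & cand$region == "R1", ]
  expect_equal(nrow(a_r1), 1L)
  expect_equal(a_r1$state_length, 5L)
  expect_equal(a_r1$n_in, 3L)
  expect_equal(a_r1$n_exceptions, 0L)
  expect_true(a_r1$unique_within_parent)
  # clade A in R2 has lengths {4,6,4}: no 90% state
  expect_equal(nrow(cand[cand$clade == "A" & cand$region == "R2", ]), 0L)
  # clade B in R2 has {4,6,4} too: 2/3 < 0.9, not flagged
  expect_equal(nrow(cand[cand$clade == "B" & cand$region == "R2", ]), 0L)
})

test_that("a 50/50 split is never a state and min_share must exceed 0.5", {
  tab <- lvr_length_table(
    id = c("a1", "a2", "a3", "a4", "b1", "b2"),
    region = rep("R", 6),
    length = c(5, 5, 7, 7, 9, 9)
  )
  cm <- clade_map(
    c("a1", "a2", "a3", "a4", "b1", "b2"),
    list(A = c("a1", "a2", "a3", "a4"))
  )
  expect_equal(nrow(flag_synapomorphies(tab, cm, min_share = 0.9)), 0L)
  expect_error(flag_synapomorphies(tab, cm, min_share = 0.5), "min_share")
})

test_that("flags match an exhaustive scan over (clade, region, length) triples", {
  set.seed(19)
  for (rep in 1:10) {
    ids <- paste0("s", 1:24)
    regions <- c("B", "C", "D")
    tab <- lvr_length_table(
      id = rep(ids, times = 3),
      region = rep(regions, each = 24),
      length = sample(3:7, 72, replace = TRUE)
    )
    clades <- list(
      X = ids[1:8], Y = ids[9:20], Z = ids[c(1:4, 21:24)]
    )
    cm <- clade_map(ids, clades)
    min_share <- 0.7
    outside_max <- 0.3
    got <- flag_synapomorphies(tab, cm, min_share, outside_max)
    # brute force over all triples
    expected <- list()
    for (nm in names(clades)) {
      for (reg in regions) {
        for (L in 3:7) {
          inside <- tab$length[tab$region == reg & tab$id %in% clades[[nm]]]
          outside <- tab$length[tab$region == reg & !tab$id %in% clades[[nm]]]
          if (mean(inside == L) >= min_share &&
            mean(outside == L) <= outside_max) {
            expected[[length(expected) + 1L]] <- c(nm, reg, L)
          }
        }
      }
    }
    expect_equal(nrow(got), length(expected))
    for (e in expected) {
      hit <- got[got$clade == e[1] & got$region == e[2], ]
      expect_equal(as.character(hit$state_length), e[3])
    }
  }
})

test_that("flags are invariant to row order and id renaming", {
  tab <- toy_table()
  cm <- toy_clades()
  base <- flag_synapomorphies(tab, cm)
  perm <- sample(nrow(tab))
  tab2 <- lvr_length_table(tab$id[perm], tab$region[perm], tab$length[perm])
  expect_equal(flag_synapomorphies(tab2, cm), base)
  # renaming ids consistently changes nothing but the ids
  ren <- function(x) paste0("z_", x)
  tab3 <- lvr_length_table(ren(tab$id), tab$region, tab$length)
  cm3 <- clade_map(ren(cm$terminals), lapply(cm$clades, ren))
  expect_equal(
    flag_synapomorphies(tab3, cm3)[-1],
    base[-1]
  )
})

test_that("tightening thresholds never adds a flag", {
  set.seed(29)
  ids <- paste0("s", 1:30)
  tab <- lvr_length_table(
    id = rep(ids, 2), region = rep(c("B", "C"), each = 30),
    length = sample(3:6, 60, replace = TRUE)
  )
  cm <- clade_map(ids, list(X = ids[1:10], Y = ids[11:30]))
  loose <- flag_synapomorphies(tab, cm, min_share = 0.6, outside_max_freq = 0.6)
  tight_share <- flag_synapomorphies(tab, cm, min_share = 0.8, outside_max_freq = 0.6)
  tight_out <- flag_synapomorphies(tab, cm, min_share = 0.6, outside_max_freq = 0.2)
  key <- function(x) paste(x$clade, x$region, x$state_length)
  expect_true(all(key(tight_share) %in% key(loose)))
  expect_true(all(key(tight_out) %in% key(loose)))
})

test_that("NA lengths mean 'not examined' and shrink n_in", {
  tab <- lvr_length_table(
    id = c("a1", "a2", "a3", "b1", "b2"),
    region = rep("R", 5),
    length = c(5, 5, NA, 7, 7)
  )
  cm <- clade_map(c("a1", "a2", "a3", "b1", "b2"), list(A = c("a1", "a2", "a3")))
  cand <- flag_synapomorphies(tab, cm)
  expect_equal(cand$n_in, 2L)
  expect_equal(cand$state_length, 5L)
})

test_that("clade members absent from the table are an error", {
  expect_error(
    flag_synapomorphies(
      toy_table(),
      clade_map(c("a1", "ghost"), list(A = c("a1", "ghost")))
    ),
    "absent.*ghost"
  )
})

test_that("reports render in the conventional '<L>nt <region> (<n>)' form", {
  cand <- data.frame(
    clade = c("Neoheteroptera", "Acanthosomatidae+Lestoniidae"),
    region = c("U", "D3-1"),
    state_length = c(9L, 5L),
    n_in = c(131L, 8L),
    n_in_state = c(131L, 8L),
    n_exceptions = c(0L, 0L),
    outside_freq = c(0, 0),
    unique_within_parent = c(TRUE, TRUE)
  )
  txt <- report_table(cand, "text")
  expect_true(any(grepl("9nt U (131)", txt, fixed = TRUE)))
  expect_true(any(grepl("5nt D3-1 (8)", txt, fixed = TRUE)))
  # empty candidate list renders a header-only report
  empty <- flag_synapomorphies(
    lvr_length_table(c("a", "b"), c("R", "R"), c(1, 2)),
    clade_map(c("a", "b"), list())
  )
  expect_length(report_table(empty, "text"), 1L)
  expect_length(report_table(empty, "csv"), 1L)
})
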