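## Curated demonstration datasets: LVR length-state tables across
## Heteroptera, reconstructed at the group level from published comparative
## tallies (140 18S sequences spanning 37 families; 84 28S D3 sequences
## spanning 51 families). The group-level counts and modal states are the
## published ones; the individual rows are SYNTHETIC stand-ins (constructed
## ids and filler states), since the underlying per-accession data are not
## redistributed here. Useful for exercising the scan and report stages at
## realistic scale.

cyc <- function(vals, n) rep_len(vals, n)

#' Heteroptera 18S LVR length table (synthetic reconstruction)
#'
#' 140 sequences x 5 LVRs (B, M, T, U, W). Group-level structure: 9nt U
#' near-fixed across 131 examined Neoheteroptera; 10nt M dominant across 117
#' examined Cimicomorpha+Pentatomomorpha; 11nt B (39 examined) and 4nt T (37
#' examined) near-fixed within Pentatomomorpha with a few exceptions; 5nt W
#' unique to the 36 examined Naboidea+Cimicoidea. `NA` = not examined.
#' Individual row identities are synthetic.
#'
#' @return An `lvr_length_table` (see [lvr_length_table()]).
#' @seealso [heteroptera_18s_clades()]
#' @export
heteroptera_18s_lvr_table <- function() {
  basal <- sprintf("bas%03d", 1:7)
  pen <- sprintf("pen%03d", 1:40) # Pentatomomorpha
  cim <- sprintf("cim%03d", 1:79) # Cimicomorpha (first 36 = Naboidea+Cimicoidea)
  neo <- sprintf("neo%03d", 1:14) # other Neoheteroptera
  ids <- c(basal, pen, cim, neo)

  U <- c(cyc(c(7, 8, 10), 7), rep(9, 40 + 79 + 14))
  names(U) <- ids
  U[c("pen001", "cim037")] <- NA # not examined

  M <- c(cyc(c(8, 11, 12), 7), rep(10, 40 + 79), cyc(c(10, 10, 10, 10, 10, 8, 9, 11, 12, 8, 9, 11, 12, 8), 14))
  names(M) <- ids
  M[c("pen002", "cim038")] <- NA
  M[c("pen003", "pen005", "cim040", "cim042")] <- 9 # exceptions
  M[c("pen004", "cim039", "cim041")] <- 11

  B <- c(cyc(c(8, 9, 10), 7), rep(11, 40), cyc(c(9, 10, 12, 11), 79), cyc(c(9, 10, 12), 14))
  names(B) <- ids
  B["pen006"] <- NA
  B["pen007"] <- 10
  B["pen008"] <- 12

  T_ <- c(cyc(c(6, 7), 7), rep(4, 40), cyc(c(5, 6, 7, 4), 79), cyc(c(5, 6), 14))
  names(T_) <- ids
  T_[c("pen009", "pen010", "pen011")] <- NA
  T_["pen012"] <- 3
  T_["pen013"] <- 5

  W <- c(cyc(c(4, 6), 7), cyc(c(6, 7), 40), c(rep(5, 36), cyc(c(6, 7, 8), 43)), cyc(c(7, 8), 14))
  names(W) <- ids

  lvr_length_table(
    id = rep(ids, times = 5),
    region = rep(c("B", "M", "T", "U", "W"), each = length(ids)),
    length = c(B, M, T_, U, W)
  )
}

#' Named clades for the 18S demonstration table
#'
#' Neoheteroptera, Cimicomorpha+Pentatomomorpha, Pentatomomorpha and
#' Naboidea+Cimicoidea, as id sets over [heteroptera_18s_lvr_table()].
#'
#' @return A [clade_map()].
#' @export
heteroptera_18s_clades <- function() {
  pen <- sprintf("pen%03d", 1:40)
  cim <- sprintf("cim%03d", 1:79)
  neo <- sprintf("neo%03d", 1:14)
  clade_map(
    terminals = c(sprintf("bas%03d", 1:7), pen, cim, neo),
    clades = list(
      "Neoheteroptera" = c(pen, cim, neo),
      "Cimicomorpha+Pentatomomorpha" = c(pen, cim),
      "Pentatomomorpha" = pen,
      "Naboidea+Cimicoidea" = cim[1:36]
    )
  )
}

#' Heteroptera 28S D3 LVR length table (synthetic reconstruction)
#'
#' 84 sequences x 3 D3 sections (D3-1, D3-2, D3-3). Group-level structure:
#' Paraphrynoveliidae+Macroveliidae share 4nt/6nt/15nt across the three
#' sections (3 sequences); Gelastocoridae+Ochteridae share 4nt D3-1 (4
#' sequences); Acanthosomatidae+Lestoniidae share 5nt D3-1 and 19nt D3-2 (8
#' sequences). Individual row identities are synthetic.
#'
#' @return An `lvr_length_table`.
#' @seealso [heteroptera_d3_clades()]
#' @export
heteroptera_d3_lvr_table <- function() {
  pm <- sprintf("pm%03d", 1:3)
  go <- sprintf("go%03d", 1:4)
  al <- sprintf("al%03d", 1:8)
  oth <- sprintf("oth%03d", 1:69)
  ids <- c(pm, go, al, oth)
  d31 <- c(rep(4, 3), rep(4, 4), rep(5, 8), cyc(c(3, 6, 7), 69))
  d32 <- c(rep(6, 3), cyc(c(9, 11), 4), rep(19, 8), cyc(c(8, 10, 12, 14), 69))
  d33 <- c(rep(15, 3), cyc(c(11, 13), 4), cyc(c(12, 14), 8), cyc(c(10, 12, 16), 69))
  lvr_length_table(
    id = rep(ids, times = 3),
    region = rep(c("D3-1", "D3-2", "D3-3"), each = length(ids)),
    length = c(d31, d32, d33)
  )
}

#' Named clades for the D3 demonstration table
#'
#' @return A [clade_map()] with Paraphrynoveliidae+Macroveliidae,
#'   Gelastocoridae+Ochteridae and Acanthosomatidae+Lestoniidae.
#' @export
heteroptera_d3_clades <- function() {
  pm <- sprintf("pm%03d", 1:3)
  go <- sprintf("go%03d", 1:4)
  al <- sprintf("al%03d", 1:8)
  clade_map(
    terminals = c(pm, go, al, sprintf("oth%03d", 1:69)),
    clades = list(
      "Paraphrynoveliidae+Macroveliidae" = pm,
      "Gelastocoridae+Ochteridae" = go,
      "Acanthosomatidae+Lestoniidae" = al
    )
  )
}
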