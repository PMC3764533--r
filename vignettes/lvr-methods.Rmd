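---
title: "Methods: length-variable regions of rRNA, from folding to synapomorphy scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: length-variable regions of rRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnalvr)
```

This vignette is the package's account of its methods: what each stage
computes, which assumptions it makes, why its defaults are what they are,
and what the test suite does and does not establish.

## The scientific setting

Ribosomal RNA genes interleave two regimes. Length-conservative blocks are
nearly indel-free across deep divergences and anchor alignments; the
length-variable regions (LVRs; the expansion segments of the general rRNA
literature) between them vary in ungapped length among taxa. LVR length is
a discrete character: when one length state is (near-)fixed within a
monophyletic group and rare or absent elsewhere, it is a candidate
molecular synapomorphy — evidence of a single indel event in the group's
stem lineage. The package's pipeline measures those lengths from a
structure-aware alignment and tabulates, per named clade, the states that
qualify.

The package treats the multiple alignment as an input. Structure-guided
manual alignment (and progressive MSA generally) is out of scope; what the
package adds around a given alignment is folding of LVR fragments,
selection among consensus structure models, region delimitation and the
clade scan, plus pairwise annotation transfer for single new accessions.

## Folding LVR fragments

`fold_max_pairs()` maximizes the number of base pairs over all
pseudoknot-free structures (Nussinov-style dynamic programming), under an
explicit pair-rule set: `canonical` = {A–U, G–C}; `canonical+wobble` adds
G·U (the default — wobble pairs are ordinary stem constituents in rRNA);
`extended` adds the A:G and A:C classes that structure diagrams mark as
noncanonical annotations. Pair maximization is a deliberate simplification
of free-energy folding: LVR fragments are short (mostly 2–60 nt) and
hairpin-dominated, where the maximum-pairing optimum and the thermodynamic
optimum usually agree on the stem layout, and the simpler objective is
verifiable against exhaustive enumeration — a property the test suite
exercises directly. Users with a thermodynamic folder can inject its output
through `parse_dot_bracket()` anywhere a structure is accepted.

Numerical choices:

* **Tie-break.** Among equal-pair-count structures the DP maximizes the
  number of stacked pairs (pairs whose inner neighbor is also paired),
  lexicographically after pair count. This prefers contiguous helices over
  scattered isolated pairs, which is what consensus-model building needs.
  Traceback is deterministic: the left end of each subproblem pairs with
  the smallest compatible partner achieving the optimum, and stacked
  continuations win ties inside a helix.
* **`min_loop = 3`** (nt): the standard steric minimum for a hairpin loop.
* **Degenerate inputs:** the empty sequence folds to the empty structure;
  `N` never pairs.
* `enumerate_cooptimal()` returns every optimal-count structure in
  lexicographic pair-list order (first-position decomposition, so each
  structure is produced exactly once), truncated to `max_structures`. The
  co-optimal set grows quickly with length; it is intended for fragments,
  not full molecules.

## Consensus models and the stem-retention criterion

A `structure_model` places helices on alignment columns (the k-th 5'-side
column pairs the (len−1−k)-th 3'-side column). The selection criterion
formalizes the co-variation principle — the best model is the one whose
paired regions are least destroyed across the sequence set — as a total
order:

1. total retained stem length: summed over rows, the number of helix column
   pairs where the row has non-gap residues forming an allowed pair;
2. larger per-row minimum (a model should not sacrifice one taxon entirely
   to fit the rest);
3. fewer helices (parsimony among otherwise equal models);
4. input order (determinism).

As stated in the comparative-rRNA literature the criterion is qualitative;
this ordering is the package's own formalization, chosen as the simplest one
consistent with
both "the longer the stems kept, the better" and "the fewer elements
destroyed, the better". Loop (unpaired-column) conservation is deliberately
ignored: the criterion concerns paired regions. Noncanonical pairs do not
count as retention under the default rule but survive projection
(`sequence_structure_from_model()` flags them), mirroring how structure
diagrams draw them with distinct symbols rather than treating them as stem
support.

`sample_random_model()` draws rival models with the same helix lengths at
random valid positions (a uniform random composition of the free columns;
always conflict-free and pseudoknot-free at column level). It is the null
model for the selection experiments below.

## Annotation transfer

`global_align()` is a textbook Gotoh affine-gap global aligner; a gap of
length L costs `gap_open + L*gap_extend`. Defaults `match = +2`,
`mismatch = −1`, `gap_open = −5`, `gap_extend = −1` suit the
conserved-with-local-indels regime of rRNA and are exposed as arguments.
Traceback prefers diagonal, then vertical, then horizontal moves at ties,
so output is deterministic. `transfer_regions()` maps region boundaries
through alignment columns; a boundary landing in a query gap rounds
rightward (starts) or leftward (ends). The convention is conservative by
design: the scan's statistic is an exact length, and inflating a
transferred region with flanking gap columns would manufacture false
length mismatches. A region whose columns are all deleted in the query
maps to a zero-length interval — a real observation (LVR loss), not an
error.

## Delimiting LVRs

`column_profile()` computes per-column gap fraction and residue entropy
(bits, base-2, over non-gap A/C/G/U). Delimitation is **gap-driven**:
`is_variable = gap_fraction > gap_threshold`. Substitution entropy is
reported for inspection but does not enter delimitation — a column can be
substitutionally saturated yet length-conservative, and LVRs are defined by
length variation. `delimit_lvrs()` then takes maximal variable runs,
absorbing conserved runs shorter than `min_conserved_block` that are
flanked by variable runs on both sides, and discards runs shorter than
`min_lvr_cols`.

Defaults and rationale (all exposed in the API and the pipeline config):

* **`gap_threshold = 0.2`**: a column where more than a fifth of sequences
  have no residue reflects genuine length variation rather than one or two
  stray indels; in a family-structured sample it corresponds to roughly
  one family in five differing in length.
* **`min_conserved_block = 5`** columns: LVR sections are interspaced by
  *short* length-conservative runs; runs of five or more columns are
  treated as genuine conserved spacers that split regions (this is what
  separates the three D3 sections), shorter ones are absorbed.
* **`min_lvr_cols = 2`**: a single variable column is recorded as a
  scattered indel, not an LVR. This threshold is the package's proxy for
  the qualitative distinction between scattered indels and bona fide LVRs,
  which has no agreed quantitative definition in the field.

Labels follow field conventions: capital letters from `B` for 18S (the
letter A is conventionally unused), `D2, D3, ...` for 28S divergent
domains, and `<parent>-1, -2, ...` when subdividing a parent region.

`lvr_lengths()` counts non-gap residues per sequence per region. `N`
counts toward length (it is a real residue of unknown identity); it only
refuses to pair.

## The synapomorphy scan

`flag_synapomorphies()` flags a state `L` for clade `C` in region `R` when

* share of `L` among examined members of `C` ≥ `min_share`, and
* frequency of `L` among examined non-members ≤ `outside_max_freq`.

Defaults `min_share = 0.9`, `outside_max_freq = 0.5`: real groups show "a
few exceptions" around otherwise fixed states, and dominant-but-not-unique
states are still phylogenetically informative; uniqueness (outside
frequency exactly 0) is reported as `unique_within_parent` rather than
being a separate mode. `min_share ≤ 0.5` is rejected outright — a state
held by half the clade is not a state. Exceptions are counted and printed,
never hidden. `NA` lengths mean "sequence not examined for this region"
and are excluded from both tallies; this is how tables whose per-region
sample sizes differ (a common situation with partial GenBank coverage) are
represented. A clade covering every examined sequence of a region yields
no candidate: with no outgroup there is no rarity to establish.

The scan is deliberately descriptive. It performs no ancestral-state
reconstruction and attaches no significance test: a flagged state is a
candidate synapomorphy to be weighed against independent phylogenetic
evidence, and inventing a probability model here would overstate what the
tabulation can support.

## The synthetic generator

`generate_dataset()` emulates exactly the features of comparative rRNA
data that the pipeline exploits:

* a conserved core (blocks identical across sequences up to point
  substitutions, each block carrying a planted stem whose substitutions
  are pair-compensated with probability `compensatory_rate`);
* LVRs whose ungapped length is a discrete family-determined state,
  content deterministic per (region, length) and optionally constrained to
  fold into a hairpin, centered in the region's alignment window;
* an exception process: per (sequence, region), probability
  `lvr_indel_rate` of a ±1 nt deviation from the clade state;
* indels confined to LVRs; no indels in the core.

The default specification is the reference study condition used across the
test suite: 5 families × 6 sequences, four LVRs `B..E`, and two planted
synapomorphies — the unique 5 nt state of LVR `C` in clade P (families
F1+F2) and the unique 9 nt state of LVR `E` in clade Q (F4+F5) — plus a
decoy clade X (F2+F3+F4) constructed to have no diagnostic state. The
family length states were fixed once, from two a-priori constraints:
every LVR's minimum state is held by at least two families, so no column's
gap fraction sits exactly at the 0.2 threshold (with five equal families a
column missing exactly one family has gap fraction 0.2, a knife edge); and
minimum states are ≤ 4 nt, so the gap-free central run of each LVR window
is shorter than `min_conserved_block` and absorbed, making planted
boundaries exactly recoverable at zero noise.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: substitution-model realism (no GTR, no
rate heterogeneity, no branch-length structure; noise is i.i.d. per site),
alignment error (the truth alignment is given, whereas real LVR alignments
are exactly where aligners err), arbitrary-length exceptions (real
exceptions can deviate by more than 1 nt), intra-family length variation,
and pseudoknots or long-range LVR structure. Results on synthetic data
bound the pipeline's behavior under its own assumptions; they do not
certify performance on a difficult real alignment.

## Experiment sizes and determinism

The test suite and the acceptance script run, as the package's chosen
reference experiments: oracle equivalence of the folding DP against
exhaustive enumeration on 200 random sequences of length ≤ 12 (all three
rule sets); oracle equivalence of the aligner against a brute-force
recursion on 100 random pairs of length ≤ 6; zero-noise end-to-end
recovery over 50 seeds (recovery 100%, false positives 0); recall under
`lvr_indel_rate = 0.05` at `min_share = 0.9` over 50 seeds; and planted-
versus-rival model selection over 100 trials × 100 rivals at
`sub_rate = 0.1`, `compensatory_rate = 0.9`.

The noise-robustness experiment uses 15 sequences per family (clades of
30) rather than the zero-noise experiment's 6. This is a sample-size
statement, not a tuning choice: with a clade of size n, the `min_share =
0.9` criterion tolerates `floor(0.1 n)` deviant members, so expected
recall at a 5% exception rate is P(Binomial(n, 0.05) ≤ floor(0.1 n)) —
0.88 at n = 12 purely because `floor` rounds 1.2 down to 1, and 0.94 at
n = 30. Small clades make the 0.9 threshold effectively stricter than 0.9;
users scanning clades of a dozen sequences should read `min_share`
accordingly (11/12 ≈ 0.917 is the smallest attainable share above 0.9).

Everything is deterministic given seeds: the generator restores the
caller's RNG state, folding and alignment tracebacks are tie-broken
explicitly, and pipeline reruns with the same configuration are
byte-identical (the manifest records parameter values and input/output
checksums, no timestamps).

## Known limitations

* Pair maximization is not free-energy minimization; for multi-helix LVRs
  with competing stems the two can disagree. The co-optimal enumerator plus
  model selection mitigates this at the consensus level, and external
  folder output can be substituted.
* The aligner is quadratic in time and memory in pure R; it is meant for
  desk-scale work (single accessions against a reference, up to full-length
  28S), not for aligning hundreds of sequences.
* Curated demonstration tables ship with synthetic row identities; they
  reproduce published group-level counts and states, not the underlying
  per-accession data, and are labeled accordingly.
* Clade maps are taken on faith: the scan evaluates character support for
  groups someone else inferred; it does not test monophyly.
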