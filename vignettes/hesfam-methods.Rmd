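---
title: "Methods: how hesfam identifies, classifies and analyses the HES/HEY family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how hesfam identifies, classifies and analyses the HES/HEY family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hesfam)
```

`hesfam` packages the recurring computations of a comparative study of the
HES/HEY transcription-factor family: proteome-wide identification by
dual-domain architecture, domain-based phylogeny and group classification,
exon/intron phase evolution, C-terminal motif classification, tandem-array
detection and a lineage-expansion test. This vignette explains each model,
its assumptions, the tunable parameters, and the numerical choices; it also
describes exactly what the synthetic-data generator does and does not
emulate, which bounds what a green test suite can claim about real data.

## 1. Membership: PSSM scan with an empirical permutation null

Family membership is defined structurally: a significant bHLH domain hit
followed by a significant Orange domain hit. The original tooling for this
kind of search is a profile-HMM scan against curated domain profiles plus a
BLAST cross-check with a hard E-value cutoff. `hesfam` instead ships a
self-contained equivalent:

* `build_profile()` turns an aligned seed into a position-specific scoring
  matrix. Columns with more than 50% gaps are dropped; retained columns get
  pseudocounted probabilities
  $p_j(a) = \frac{n_j(a) + \beta q(a)}{N_j + \beta}$ and log-odds scores
  $S_j(a) = \log_2 p_j(a)/q(a)$. Defaults: $\beta = 1$, uniform background
  $q(a) = 1/20$. The pseudocount guarantees finite scores for residues
  absent from a column.
* `scan_profile()` scores every ungapped window, including terminal windows
  covering at least half the profile columns; those are flagged
  `truncated`, because incomplete domains must be tracked (they are kept in
  member tables but excluded from trees). Hits are selected greedily,
  highest score first, among non-overlapping windows at or above a 0-bit
  reporting floor.
* `empirical_pvalue()` replaces the non-transferable E-value cutoff: the
  observed best-window score is compared with best-window scores of residue
  permutations of the same sequence,
  $p = (1 + \#\{\text{null} \ge s\})/(n_{\text{shuffles}} + 1)$.
  This null conditions on composition and length, is distribution-free,
  and is super-uniform by construction. Defaults: 200 shuffles,
  $\alpha = 0.01$ per domain. Permutation seeds are derived by hashing the
  record id with the user seed, which makes calls invariant to the order of
  records in a FASTA file.

A `call_membership()` rejection always carries a reason (`no_bhlh`,
`no_orange`, `wrong_order`), mirroring the way partial-domain candidates
are excluded in curated surveys. An optional cap on the bHLH-to-Orange gap
exists but is off by default, since the architecture definition imposes
none.

Redundancy removal (`deduplicate()`) re-implements the greedy scheme of
CD-HIT: sequences sorted by decreasing length (ties broken by id), each
assigned to the first representative with global-alignment identity at or
above 0.9, where identity is exact matches divided by the *shorter*
sequence's length. The procedure is idempotent, and its tie-breaks are
fully specified, so clustering is reproducible.

## 2. Alignment and trees

The phylogenetic substrate is the concatenation of each member's bHLH and
Orange hit regions — the conserved cores — rather than full-length
proteins, whose linkers and tails are unalignable across phyla.

* `nw_align()` is an affine-gap Gotoh alignment (gap of length $k$ costs
  `gap_open` $+ (k-1)\,$`gap_extend`; defaults 10 and 1, BLOSUM62), with a
  deterministic traceback preference (diagonal, then gap in the first
  sequence). The dynamic program runs in C++; tests verify it against
  exhaustive enumeration of all alignments for short pairs and against an
  independent implementation.
* `progressive_align()` follows the classical progressive scheme: a UPGMA
  guide tree on fractional 3-mer distances, then profile–profile alignment
  up the tree with columns scored by frequency-weighted substitution
  scores. This is deliberately simpler than iterative refiners; for
  domain-length, high-identity inputs the result is dominated by the
  pairwise optimum.
* `pdistance()` computes the proportion of differing sites. Gap handling
  follows the three standard modes; the default is partial deletion at 95%
  site coverage, the conventional cutoff when none is stated. An optional
  Poisson correction $-\ln(1-p)$ and a Gamma variant are provided; full
  empirical-matrix ML distances are out of scope because at these
  divergences the classification depends on topology, which p-distances
  preserve.
* `nj_tree()` is Saitou–Nei neighbor joining with negative branch lengths
  clamped to zero and ties in the $Q$ criterion broken by the
  lexicographically smallest pair of cluster ids (a cluster is keyed by its
  smallest leaf id). On additive matrices it provably recovers the
  generating tree; tests assert this exactly.
* `support_resample()` attaches column-bootstrap support percentages to
  internal edges — the same interface (percent per edge) as the
  interior-branch tests of desktop phylogeny suites, but implemented as
  bipartition frequency, which is standard and directly testable. An
  alignment with no variable columns yields degenerate 100% supports plus a
  warning.
* `me_brute()` is the oracle: it enumerates all $(2n-5)!!$ unrooted
  topologies, fits ordinary-least-squares branch lengths (clamped at zero
  after fitting), and returns the minimum-total-length topology. It is
  intentionally exponential and capped at 8 taxa.

## 3. Group classification on unrooted trees

The four groups are defined by the 13 human genes used as anchors
(`default_anchor_map()`): HEY1/HEY2/HEYL, BHLHE40/BHLHE41 (DEC1/DEC2),
HELT (HESL) and HES1–HES7. `assign_groups()` formalises visual tree
reading: for each non-anchor leaf, the smallest clade — evaluated on both
sides of every edge, so rooting is irrelevant — containing the leaf and
anchors of only one group supplies the label. When every candidate clade
mixes groups (rogue placements do occur in this family, e.g. the unstable
HES3/HES6 positions across methods), the leaf falls back to the anchor at
minimal path length, ties to the lexicographically smaller anchor id, and
the method is recorded per leaf so downstream users can distinguish
confident clade assignments from fallbacks.

`detect_species_clusters()` reports maximal single-species clades with at
least `min_size = 3` leaves. Three is the smallest size that cannot arise
from one ordinary vertebrate paralog triplet plus tree error; the
biologically interesting clusters in this family have five or more
members.

## 4. Gene structure: phases and event scripts

The intron phase after coding exon $i$ is $\left(\sum_{j\le i} L_j\right)
\bmod 3$ over CDS lengths in transcription order. UTR-only exons are
excluded from the count and reported separately — a first exon converted
to 5' UTR thus appears as a reduced coding exon count with
`utr_exons = 1`, not as a separate event type.

`infer_events()` relates an observed phase string to the ancestral
five-exon `2-0-0-1` structure by exhaustive breadth-first search over
scripts of four event types: 5' exon loss (drops the first phase), 3' exon
loss (drops the last), intron loss (deletes a phase — an exon fusion) and
intron gain (inserts a phase). Phases are compared as observed label
strings and are *not* recomputed after hypothetical losses: that is the
convention under which the family's printed transitions
(`2-0-0-1 -> 0-0-1`, `2-0-0-1 -> 2-0-1`) hold exactly, and it keeps the
search over a small discrete space. Numerical choices:

* search depth capped at cost 6 (strings here have at most 7 phases);
  deeper queries are flagged `unalignable` rather than guessed;
* intermediate states are restricted to lengths within 2 of the band
  spanned by query and reference — a value change costs one loss plus one
  gain, so minimal scripts never dip further;
* cost ties prefer `EXON_LOSS_5P` over `EXON_LOSS_3P` over `INTRON_LOSS`
  over `INTRON_GAIN`; among equivalent intron losses within a run of equal
  phases the 3'-most intron is reported, matching the fused-exon reading
  of such transitions (the nematode case is "the third intron lost", not
  the second), while intron gains prefer the smallest insertion point.

Because breadth-first search expands candidates in exactly this canonical
order, the returned script is the lexicographically preferred one among
all minimum-cost scripts, and replaying it on the reference reproduces the
query exactly (a fuzz-tested invariant).

## 5. Tetrapeptide motifs and conserved blocks

`classify_tetrapeptide()` searches the last 10 residues (configurable; the
motifs sit at or very near the C-terminus, but degenerate tails exist).
Priority encodes the family's evolutionary series FRPW → YRPW → WRPW:
exact `[WYF]RPW` first (rightmost match wins), then `YxxW` followed within
10 residues by `TE(I/V)GAF`, then any 4-mer ending in W whose middle is
not `RP` — a deliberately broad `DEGENERATE_W` bucket whose matched 4-mer
is always reported verbatim, because the observed variants (VLGW, VQGW,
AQGW, GSGW, AQAW) follow no tighter rule. The 10-residue window for the
TE(I/V)GAF follow-up is this package's choice; no published value exists,
and it is recorded in the call output's documentation.

`find_conserved_blocks()` is the automated analogue of manual motif
retrieval: per-column conservation is modal-residue frequency among
non-gap rows scaled by the non-gap fraction, and blocks are maximal runs
of at least 6 columns at conservation 0.5 or higher, reported with full
per-column frequency tables (logo data) rather than rendered graphics.

## 6. Tandem arrays and the expansion test

`detect_tandem_clusters()` chains loci per chromosome (and species and
group, by default) in coordinate order while each *intergenic* distance —
next start minus previous end, floored at zero for overlaps — stays within
40 kb. Intergenic distance is the strictest reading of a "within 40 kb"
rule that still chains directly adjacent arrays; strand is ignored because
real tandem arrays mix orientations. The same-group requirement is
switchable off.

`wilcoxon_rank_sum()` uses midranks for ties; for $n_1 + n_2 \le 12$ the
two-sided p-value is exact by complete enumeration of the
$\binom{n}{n_1}$ rank assignments, $p = \min(1, 2\min(P(W\le w), P(W\ge
w)))$ — with ties the permutation distribution is not symmetric, so the
doubled smaller tail is the appropriate two-sided definition. Beyond that
a normal approximation with tie-corrected variance and continuity
correction takes over (tests bound its error against the exact tail at
0.02 for 6 vs 6). The pipeline runs exactly one expansion test, so no
multiplicity correction is applied. Two-sided reporting is the
conservative choice when sidedness is unstated.

## 7. What the synthetic generator emulates — and what it does not

`generator_config()` defaults define the study conditions the package is
validated under:

* two clades of six species — six teleosts and six non-teleosts — with
  per-group gene counts of (2, 1, 1, 3) for HEY1/2/L, DEC1/2, HESL and
  HES1-7 in non-teleosts and exactly double in teleosts, emulating the
  post-duplication pattern under test;
* domain sequences sampled column-wise from the packaged seed profiles,
  diverged 25% between groups (so groups form separable clades) and 5%
  within groups (`mu = 0.05`; `mu = 0` for exact-recovery checks);
* gene models whose CDS exon lengths realise each group's phase template
  exactly by constrained sampling (cut points congruent to the required
  phases mod 3) — truth by construction, not post-hoc adjustment —
  with the ancestral `2-0-0-1` for HEY1/2/L and DEC1/2 and the derived
  `0-0-1` for HESL and HES1-7;
* one 7-gene tandem array planted in zebrafish with gaps of 5–35 kb,
  while all other genes are spaced at 60–120 kb, beyond the 40 kb rule;
* group-specific tetrapeptides (YRPW for HEY1/2/L, WRPW for HES1-7, none
  for DEC1/2 and HESL) with a 10% chance of a degenerate W variant;
* per-species decoys — bHLH-only, Orange-only, wrong-order and random —
  exercising every membership rejection reason;
* one global seed; outputs are byte-identical for identical
  configurations.

The packaged seed alignments are themselves synthetic: eight sequences per
domain generated once from a fixed invented consensus with controlled
variation and gap columns (files are labelled `*_seed_synthetic.fasta`).
They exercise the profile machinery but are not curated domain profiles.

Deliberately *not* emulated: insertions/deletions within domains (the
evolved sequences are equal length, so alignment recovery is easier than
on real data), realistic genome background (repeats, GC structure), codon
usage, alternative transcripts, assembly artefacts, and incomplete gene
models. Consequently, a green suite demonstrates correctness of the
algorithms under their stated models — exact phase arithmetic, exact
membership logic, additive-tree recovery — but not robustness to the
messiness of real annotation pipelines.

## 8. Problem sizes and determinism

The default validation study uses 181 sequences (133 members including
the 7-gene array, 48 decoys) across 12 species; membership testing uses
100–200 permutations per domain and trees use 20–100 bootstrap
replicates interactively (1000 is the conventional publication setting).
These sizes were chosen so a full end-to-end run completes in a few
minutes on one core while keeping every planted signal comfortably above
its detection threshold. All stochastic stages take explicit seeds; the
pipeline persists no timestamps in data outputs, so identical
configuration and seed reproduce every artifact byte for byte.

## 9. Known limitations

* The PSSM scan is ungapped; a domain split by a large insertion would be
  reported as truncated or missed. A profile-HMM with insert states would
  be needed for gapped domain hits.
* p-distances saturate at high divergence; across-phyla branch lengths
  are compressed (topology, which drives classification, is less
  affected). The Poisson/Gamma corrections help only moderately.
* The anchored-clade classifier inherits tree error: in regions of method
  instability it falls back to nearest-anchor and says so, but cannot
  adjudicate genuinely conflicting signals (tree placement versus gene
  structure), which it leaves to the analyst by reporting both.
* Event scripts are minimal-cost under unit costs; evolution is not
  parsimonious by obligation, and equally minimal alternative scripts are
  resolved by a stated convention, not by evidence.
* The rank-sum test treats species as independent observations;
  phylogenetic non-independence of counts is not modelled.
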