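---
title: "Methods: mining and characterizing compact CRISPR-Cas9 systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and characterizing compact CRISPR-Cas9 systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casforge)
```

casforge re-implements, as seeded and testable code, the computational
workflow used to discover compact Cas9 nucleases in metagenome-assembled
genomes (MAGs) and to characterize them: CRISPR-Cas locus mining, tracrRNA
and sgRNA inference, PAM determination from randomized-library cleavage
reads, and targeting-range / base-editor targetability estimation. This
vignette explains each model and procedure, its assumptions, the tunable
parameters, and the choices made where the underlying methods literature
leaves the design open. Every empirical number quoted here is computed by
the package's test suite or by `scripts/acceptance.R`.

## Locus mining

**Array detection.** CRISPR arrays are found by a CRT/MinCED-style
seed-and-extend search. Exact 8-mer recurrences at array-compatible periods
(repeat + spacer length, 49–97 bp under the default bounds) seed candidate
repeat chains; successive chain members are chosen by the similarity of
their 20-nt seed context, which distinguishes true repeat copies from
chance k-mer recurrences inside spacers. Chains are extended outward
column-by-column: a column extends the repeat while at most one copy
disagrees with the column consensus, each copy carries a budget of
`max_repeat_mismatches` (default 1), and a budget-consuming column must be
confirmed by a fully conserved column beyond it — without this lookahead,
chance agreement among three copies (probability about 0.5 per column)
creeps the boundary into the spacers. Candidate arrays are validated
against the default length bounds (repeats 23–47 nt, spacers 26–50 nt, at
least 3 repeats) and accepted greedily by decreasing repeat count, so that
a fragment seeded at a spacer/repeat junction k-mer never displaces the
full array.

**Locus assembly and filters.** A locus is an array plus *cas9*, *cas1*
and *cas2* annotations on the same contig with every pairwise edge-to-edge
gap at most 10 kbp (the co-localization rule; midpoint distance was the
alternative, edge-to-edge is implemented and config-exposed). Loci keep
only Cas9 proteins of 950–1099 aa and arrays with more than 5 spacers.
Within a species group, proteins are globally aligned (+1/−1, gap −2 per
position) to the group reference; a gap run of ≥ 5 aa inside a configured
nuclease-domain span discards the member, and the survivor with the
highest sequencing coverage is kept (ties: longer protein, then
lexicographic id). Species labels, coverage and domain spans are inputs:
they belong to MAG construction, upstream of this workflow.

**Clustering.** Greedy incremental clustering in the CD-HIT style: records
sorted by decreasing length join the first centroid reached at the identity
threshold over an alignment covering the required fraction of the shorter
sequence; identity is matches over alignment columns excluding terminal
gaps. Length outliers more than two *population* standard deviations below
the cluster median are excluded (population rather than sample sd is a
declared choice; the filter's behaviour is identical on the fixtures
either way).

## tracrRNA and sgRNA inference

**Anti-repeat search.** The direct repeat is aligned against both strands
of windows flanking the locus (up to 3000 bp per side) by seed-and-extend
local alignment: exact 8-mer seeds, match +1, mismatch −1, affine gaps
(first gap position 2, each further position 1). E-values use the ungapped
Karlin–Altschul approximation for the ±1 walk: λ = log((1−q)/q) with q the
match probability under the observed flank composition, and K computed
numerically from the lattice formula (for uniform composition λ = ln 3 and
K = 1/3, matching simulation); gapped hits inherit the ungapped estimate.
The default cutoff (e-value ≤ 1) is permissive, as in short-word BLAST
searches. Hits overlapping the array are removed.

**Candidacy.** A hit becomes a tracrRNA candidate only if its alignment
covers at least `min_aligned_frac` (default 0.7) of the repeat. This
threshold is this package's own criterion: an anti-repeat pairs most of
the repeat, whereas any exact 8-mer seed alone already guarantees an 8-bp
duplex, so without a coverage requirement seed-only chance alignments plus
incidental hairpins in random RNA pass the module check at a few percent
per locus. The candidate transcript runs from the anti-repeat to the end
of the best downstream terminator, or to the first run of ≥ 4 T when no
terminator is found.

**Terminators.** Rho-independent terminators are called by an explicit
rule replacing covariance-model machinery: a hairpin with stem ≥ 5 bp
(G·T wobble allowed) and loop 3–10 nt followed within 3 nt by a 6-nt
window containing ≥ 4 T, scored `2·stem + T-count`. Because maximal
outward stem extension can swallow an A-rich run pairing with the T-tract
itself, the stem length (≤ maximal) giving the best-scoring valid
terminator is reported.

**sgRNA scaffolds.** The repeat (crRNA side) is fused to the candidate
through a GAAA tetraloop. The duplex is the best ungapped antiparallel
register (Watson–Crick + G·U) between repeat and anti-repeat; fewer than 8
pairable positions is an error. `FS` keeps the full duplex; `TS` trims it
to `trim_len` (default 12) pairs nearest the tetraloop; `-opt` forms apply
a caller-supplied substitution list (the published engineered sequences
live in supplementary material, so the transforms are parameterized rather
than hard-coded).

**Folding and module check.** The default folding engine maximizes base
pairs (Nussinov-style dynamic programming in C++) under hairpin loops ≥ 3
nt, no pseudoknots and no lonely pairs, and enumerates every structure
within `band_pairs` (default 1) of the optimum — the counterpart of a
suboptimal-ensemble prediction, with the 5 kcal/mol energy band mapped to
one pair. ViennaRNA's `RNAsubopt --noLP -e 5` is available as an optional
external engine and as an independent cross-check. A scaffold passes when
some structure simultaneously shows: (i) a contiguous helix of ≥
`duplex_min_bp` (8) *annotated-register* pairs — counting arbitrary
cross-pairing between the segments would let scrambled anti-repeats pass,
because a pair-maximizing folder can thread an interrupted duplex through
any two random segments; (ii) a nexus stem-loop (≥ 2 bp) starting within 6
nt of the duplex end; (iii) a hairpin wholly within the 3'-terminal 60 nt,
realized by a structural element distinct from the nexus (otherwise the
duplex-plus-tetraloop hairpin satisfies the rule on truncated scaffolds).
These thresholds operationalize the qualitative description of the duplex,
nexus and 3' hairpin modules and are all config-exposed.

## PAM discovery

Reads from cleaved and uncleaved randomized-PAM libraries are anchored by
the protospacer 3' end (≤ 1 mismatch; alignment-free matching suffices at
amplicon scale) and the 8 bases 3' of the anchor are counted. Position
profiles report per-position base frequencies and information content
(2 − H bits). The four most informative positions (ties leftmost) define
256 four-mer combinations; marginal counts (summed over the unselected
positions) with pseudocount 1 give cleaved/control frequency ratios — the
heatmap quantity. The logo matrix uses raw cleaved frequencies; an
enrichment-weighted variant was considered and not made the default since
the published logos are consistent with raw frequencies.

**Consensus calling.** The enriched set E contains combinations with ratio
≥ `tau` × maximum ratio (relative threshold, default 0.2; no absolute
threshold is published). The consensus is the minimal set of per-position
IUPAC product patterns covering E losslessly. Ties among minimal covers
are resolved by smallest total expansion (a disjoint partition beats
overlapping products), then largest product of pattern degeneracies (the
most jointly degenerate description), then alphabetically — this
canonicalization makes the call a well-posed combinatorial problem with a
unique answer; the search is exhaustive branch-and-bound for |E| ≤ 32 and
greedy beyond.

**Cut-site geometry.** Adapter-ligation end positions are counted upstream
from the PAM's 5' edge into the protospacer; "3 bp upstream of the PAM"
means a cut between protospacer positions 3 and 4 from the PAM-proximal
end, the convention shared by the simulator, the caller and
`design_guides`. Modal per-strand positions give the call: coinciding
modes are blunt, otherwise the signed difference is a 5'/3' overhang;
fewer than `min_support` (10) reads per strand is "undetermined".

## Targeting range and editability

`scan_genome` counts genomic positions that can serve as the PAM-proximal
protospacer base on either strand (the declared site denominator —
publications rarely state theirs). Genomic N matches only the pattern
symbol N, and positions within one PAM length of contig ends are excluded
from the denominator. On i.i.d. uniform genomes the targetable fraction
converges to 1 − (1 − p)² with p the fraction of PAM space matched
(14/256 for the compact nuclease's three patterns; 1/16 for NGG; 1/64 for
NNGRRT; 1/16 for N4CC), which the test suite verifies within three
standard errors. Comparator schemes use the canonical PAMs of the cited
orthologs, as the source analysis does not print them.

Editing windows are spacer positions (numbered from the PAM-proximal end)
whose across-guide mean editing reaches 10%; across-guide rather than
per-locus means is the implemented reading of the rule. An SNV is
editor-targetable when a PAM on the appropriate strand places the mutated
adenine (G>A on the plus strand; C>T via its adenine on the minus strand)
at a window position; the logic is invariant under
reverse-complement-plus-class-swap, and `exclusive_targetability` reduces
per-editor verdict sets to solely/union fractions by plain set algebra.

## Synthetic data and what passing tests show

The generators are pure functions of a seed (via named Mersenne-Twister
streams), and every planted feature is recorded in a truth object, so
recall and precision are measurable for each stage without re-running
generators.

* `make_crispr_genome`: 30-kb contigs each with one locus — a 36-nt repeat
  array of 24 spacers (spacers 30–40 nt), cas9/cas1/cas2 genes (1004, 300,
  100 aa) within 10 kbp, and a tracrRNA between cas1 and the array built
  from the repeat's reverse complement with 2 substitutions placed away
  from the termini, a nexus stem-loop and a terminator hairpin. Decoy
  contigs (plain background, and cas genes without an array) are included
  so precision, not only recall, is always scored. Boundary fixtures
  (900-aa Cas9, 5-spacer array, 12-kbp gap, missing cas1) are generated by
  per-locus overrides.
* `make_pam_library`: control PAMs uniform over 4^8; cleaved reads
  accepted with probability 0.9 when the PAM matches a planted pattern and
  0.02 otherwise, then 0.1% per-base substitution errors. Acceptance
  sampling stands in for digestion/ligation/PCR because the analysis only
  consumes frequencies. Under these defaults the cleaved-library match
  fraction has the closed form (14/256·0.9)/(14/256·0.9 + 242/256·0.02) ≈
  0.722, which the acceptance tests verify within ±0.01 over ten seeds.
* `make_cut_fragments`: per-strand end positions with 90% at the planted
  offset and 10% displaced by ±1.
* `make_reference_and_snvs`: an i.i.d. genome at GC 0.41 (echoing the
  human-genome composition without shipping it) with G>A / C>T SNVs at
  well-separated positions. Intended verdicts are planted constructively:
  positives get a PAM instantiated at a window position; negatives are
  enforced by re-drawing a discriminative base wherever a chance match
  arises, with per-position constraints tracking which planted symbol owns
  each base so one editor's planting can be adjusted within its own
  degeneracy to escape another's patterns. By default each SNV is
  targetable by at most one editor, since overlapping editing windows make
  simultaneously planting two editors' PAMs around one adenine
  geometrically infeasible for most window draws.
* `make_editing_matrix`: in-window means at `peak`, out-of-window at
  `off_window`, Gaussian guide noise truncated to [0, 1].

What these fixtures do not emulate: real MAG fragmentation and coverage
structure, PCR/ligation bias, indel sequencing errors, hg38's dinucleotide
composition (notably CpG depletion — an i.i.d. GC-matched genome gives a
higher targetable fraction for the compact nuclease's patterns than the
real assembly), and real ClinVar variant spectra. Passing tests therefore
demonstrate the correctness of the algorithms under their stated models,
not performance on real sequencing data.

## Problem sizes and determinism

Default fixtures are desk-scale by design: 2 locus contigs of 30 kb plus
decoys for mining, 100,000 read pairs per PAM library, a 100-kb reference
with 100 SNVs, and 1-Mb uniform genomes for scan calibration. The full
pipeline (`run_pipeline`) derives all randomness from named streams of one
seed and writes byte-identical outputs across runs, which the acceptance
suite checks by hashing two complete runs.

## Known limitations

* Pair-count folding is a structural, not thermodynamic, model; the
  external ViennaRNA engine is the bridge to energies.
* The e-value filter uses ungapped statistics for gapped alignments
  (conservative at the permissive default cutoff).
* The consensus canonicalization (partition-preferring, degeneracy-product
  tie-break) is one defensible convention among several; alternatives can
  yield different but equally lossless covers.
* Locus mining assumes annotation-supplied cas gene calls and treats
  species/coverage as inputs; it does not call genes from DNA.
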