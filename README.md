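# casforge

casforge is an R package for people who mine microbial (meta)genomes for
new CRISPR-Cas9 systems and characterize what they find. It implements the
full desk-side of that workflow as seeded, tested code:

* **Locus mining** — CRT/MinCED-style CRISPR array detection
  (seed-and-extend over exact k-mer recurrences, repeats 23–47 nt, spacers
  26–50 nt, ≥ 3 repeats), assembly of `cas1`–`cas2`–`cas9` loci under the
  10-kbp co-localization rule, and the published filters (Cas9 950–1099 aa,
  > 5 spacers, nuclease-domain-deletion and coverage deduplication,
  CD-HIT-style identity clustering with length-outlier exclusion).
* **tracrRNA / sgRNA inference** — anti-repeat search by seeded local
  alignment (+1/−1, affine gaps, Karlin–Altschul e-values), rule-based
  Rho-independent terminator calling, sgRNA scaffold construction through a
  GAAA tetraloop (FS / TS / -opt forms), base-pair-maximization folding with
  banded suboptimals (Rcpp; ViennaRNA `RNAsubopt` as optional engine) and a
  structural check for the repeat:anti-repeat duplex, nexus and 3' hairpin
  modules.
* **PAM discovery** — from cleaved vs control randomized 8-nt PAM read
  libraries: position profiles (sequence-logo matrices), the 256-combination
  enrichment table over the four most informative positions
  (cleaved/control marginal frequency ratios with pseudocount 1), minimal
  lossless degenerate-consensus calling, and cut-site geometry from
  adapter-ligated fragment ends.
* **Targeting range** — degenerate-PAM genome scanning on both strands,
  base-editing-window estimation (≥ 10% mean editing across guides), and
  per-editor SNV targetability with solely/union set reports.
* **Synthetic data** — seeded generators for every input above, with
  machine-readable ground truth, so each stage's recall and precision are
  measurable.

The statistic at the core of PAM discovery is, for each 4-mer combination
`c` at the informative positions,

    ratio(c) = [(n_cleaved(c) + 1) / (N_cleaved + 256)] /
               [(n_control(c) + 1) / (N_control + 256)]

and the consensus is the minimal set of IUPAC product patterns whose
expansions exactly cover the enriched set `{c : ratio(c) >= 0.2 * max ratio}`.
Genome-wide targetability of a scheme with match fraction `p` of PAM space
obeys `1 − (1 − p)²` on i.i.d. genomes, which calibrates the scanner.

## Worked example

```r
library(casforge)

# a synthetic MAG with one planted locus, then mine it
g <- make_crispr_genome(n_loci = 1, seed = 42)
arrays <- detect_crispr_arrays(g$contigs[1, ])
arrays[[1]]
#> <crispr_array contig01:7473-9183  25 repeats (36 nt), 24 spacers>
filter_loci(assemble_loci(arrays, g$features))[[1]]
#> <crispr_locus contig01_7473_1990  species species01  cas9 1004 aa  24 spacers  coverage 30x>

# PAM discovery from a simulated randomized-PAM cleavage assay
des <- pam_library_design()
lib <- make_pam_library(des, builtin_schemes()$cocas9$patterns,
                        n_reads = 20000, seed = 42)
cl <- extract_pams(lib$cleaved, des); co <- extract_pams(lib$control, des)
posn <- select_informative_positions(position_profile(cl), 4)
posn
#> [1] 5 6 7 8
call_consensus(pam_enrichment(cl, co, posn))
#> <pam_consensus> 14 enriched combinations, tau = 0.2
#>   patterns: NNNNATDT, NNNNGCDT, NNNNGWNT

# cut-site geometry and targeting range
infer_cut_site(make_cut_fragments(seed = 42))
#> <cut_site_call offset 3 bp, blunt, support 400>
set.seed(42)
genome <- paste(sample(c("A","C","G","T"), 1e6, TRUE), collapse = "")
scan_genome(genome, builtin_schemes()$cocas9)
#> <genome_scan CoCas9: 106531/999984 positions targetable (0.1065)>
```

The mined array is the planted 24-spacer, 36-nt-repeat array with a
1004-aa Cas9; the recovered consensus is exactly the three planted
degenerate patterns (the relaxed PAM written N4GWNT / N4GCDT / N4ATDT);
the cut call is the blunt cut 3 bp upstream of the PAM; and the scan
fraction 0.1065 sits on the closed form 1 − (1 − 14/256)² ≈ 0.1064 for a
uniform genome.

## Package layout

```
R/                  io, mining, tracrrna, fold, pam, targeting, synthetic, pipeline
src/fold.cpp        base-pair-maximization folding engine
tests/testthat/     unit, property and acceptance suites (oracle helpers included)
scripts/acceptance.R
vignettes/casforge-methods.Rmd   the methods account of every model above
inst/scripts/casforge            CLI entry point
```
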