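# cladeMotifs

Promoter motif conservation analysis across a clade of related yeast
species — for regulatory genomicists who have a differential-expression gene
list and per-species genome annotations, and want to know which short
promoter elements the regulated genes share and whether those elements are
evolutionarily conserved.

## What it computes

Given regulated genes selected with inclusive thresholds
(*p* ≤ 0.01 and log₂FC ≥ 1.5 by default), the package extracts fixed-length
promoter fragments (1,000 bp) 5′ of each gene's start codon on the coding
strand, scans them on both strands for short motifs with
start-codon-anchored offsets (offset −1 is the base immediately upstream of
the start codon), and applies a clade-conservation criterion per gene and
motif: with the focal-species hit nearest the start codon as the reference
*r*, the motif is **conserved** when at least a fraction *t* (default 0.75,
inclusive) of the gene's collected ortholog promoters have a hit within a
window *w* (default ±200 bp) of *r*,

> conserved ⇔ #{species s : ∃ hit o_s with |o_s − r| ≤ w} / n_collected ≥ t,

provided the group is evaluable (≥ 8 collected promoters and a focal hit).
A weaker **majority** call requires a hit anywhere in > half of the
collected promoters. Summaries report, per motif: presence in the focal
promoter (over genes with a promoter), and conservation / majority (over
genes with evaluable ortholog groups — a separate denominator). The package
also discovers conserved k-mers de novo from a seed gene cluster, folding
each k-mer with its reverse complement into one canonical key and ranking
by conservation score, background occurrences, then lexicographically.
TPM/FPKM normalization, row-normalized heatmap matrices, and exact
cross-condition overlap counts round out the expression side. A
synthetic-data generator (planted motifs with positional jitter over a
12-species clade, DE tables with known truth, genome fixtures that
round-trip through extraction) makes every stage testable offline.

## Worked example

```r
library(cladeMotifs)

# scan a sequence on both strands; offsets are start-codon-anchored
scanMotif("GGATGCAGGTGCAT", "ATGCA")
#>   gene_id species_id motif offset strand match
#> 1     seq       <NA> ATGCA    -12      + ATGCA
#> 2     seq       <NA> ATGCA     -5      - TGCAT

# a synthetic 12-species ortholog group with ATGCA planted at -150 +/- 30 bp
spec <- syntheticSpec(presenceProb = 0.85, jitterSd = 30, seed = 42)
grp  <- generateOrthologGroup(spec)
classifyConservation(grp$promoters, "ATGCA", focalSpecies = "sp01")
#>   gene_id motif n_orthologs_collected n_with_hit_anywhere n_with_hit_in_window
#> 1    g001 ATGCA                    12                  12                   12
#>   presence_fraction reference_offset conserved majority evaluable group_evaluable
#> 1                 1             -119      TRUE     TRUE      TRUE            TRUE
```

All 12 species carry a hit within ±200 bp of the focal reference at −119,
so the presence fraction is 1 and the call is conserved.

The one-command demonstration builds a complete fixture (12 species, a
150-gene regulated set whose first five genes form the discovery cluster,
genomes, ortholog table, DE table, counts) and runs the whole pipeline:

```r
demo <- makeDemo("demo_dir", seed = 1)
runPipeline(demo$config)
read.delim("demo_dir/results/summary.tsv")
#>    motif n_present_focal den_focal pct_present_focal n_conserved n_majority
#> 1  ATGCA             148       148               100         140        148
#> 2  CGGAT              86       148                58           5         87
#> 3 CGGCTT              24       148                16           5          5
#>   den_evaluable pct_conserved pct_majority
#> 1           148            95          100
#> 2           148             3           59
#> 3           148             3            3
```

Reading the first row: 148 genes passed selection and all have a focal
promoter carrying `ATGCA` (planted in every regulated gene, plus abundant
background occurrences); 140 of the 148 evaluable genes (95%) carry it at a
conserved position across the clade. `CGGAT` and `CGGCTT` were planted only
in the five cluster genes, so their conservation columns are near the
background floor (5/148 each — the cluster itself) while the presence and
majority columns reflect pure background abundance, highest for the AT-rich
5-mer and lowest for the GC-rich 6-mer. `results/discovered_motifs.tsv`
holds the ranked de-novo candidates with per-gene conservation calls, and
`results/manifest.json` echoes every parameter, input checksum and stage
count.

A thin CLI wraps the same functions
(`Rscript inst/scripts/clademotifs.R simulate|run|extract|select|scan|discover|conserve|summarize ...`;
exit codes 0/2/3 for success / validation error / stage failure).

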