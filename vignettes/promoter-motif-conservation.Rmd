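---
title: "Promoter motif conservation across a yeast clade: methods and design"
author: "cladeMotifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter motif conservation across a yeast clade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(cladeMotifs))
```

## The analysis

A transcription factor's regulon can be characterized without any binding
data by asking whether the genes it regulates share short sequence elements
in their promoters, and whether those elements are *conserved* — present at
similar positions in the orthologous promoters of related species. This
package implements that analysis end to end for a clade of yeast species:

1. **Selection.** Regulated genes are taken from a differential-expression
   table with inclusive thresholds: a gene is up-regulated in a comparison
   when `p <= p_max` **and** `log2FC >= lfc_min` (down-regulation mirrors the
   magnitude rule, `log2FC <= -lfc_min`). Defaults are `p_max = 0.01` and
   `lfc_min = 1.5`, applied to the p-value column the table provides; the
   thresholds and the column choice are configuration, not code. Gene sets
   from several comparisons can be unioned, and exact cross-condition
   overlap counts (disjoint Venn regions plus plain intersections) are
   reported.
2. **Normalization.** Raw counts with per-gene effective lengths are
   converted to TPM (`rate = count / length_kb`, rescaled so each sample
   sums to $10^6$) and FPKM (`count * 10^9 / (length_bp * library_size)`),
   and FPKM matrices can be row-normalized (z-score with the population SD,
   or min–max) for heatmap display.
3. **Promoter extraction.** For every annotated gene the fragment of
   `promoter_length` bp (default 1,000) immediately 5' of the start codon is
   taken on the gene's coding strand: the reference slice
   `[start - L, start - 1]` for `+` genes, the reverse complement of
   `[end + 1, end + L]` for `-` genes. Fragments are clipped at contig
   boundaries and flagged `truncated`; they are **not** clipped at upstream
   genes — a neighbouring gene inside the window only sets an
   `upstream_overlap` flag, because the analysis is defined on fixed-length
   fragments, not intergenic regions.
4. **Scanning.** Motifs are short IUPAC patterns matched on both strands.
   Offsets use a start-codon anchor: the base immediately 5' of the start
   codon is offset −1, so a k-mer flush against the start codon starts at
   offset −k. `N` in a promoter matches nothing; overlapping hits are all
   reported; a palindromic pattern counts each window once. Repeat counts
   collapse overlapping hits greedily left-to-right, which is optimal for
   equal-length windows.
5. **Conservation.** For a gene with collected ortholog promoters, the
   *reference* is the focal-species hit nearest the start codon. An ortholog
   agrees when it has at least one hit (either strand) within
   `position_window` bp of the reference. The motif is **conserved** for the
   gene when the group is evaluable (at least `min_orthologs` collected
   promoters and a focal hit) and the agreeing fraction reaches
   `presence_threshold` — inclusively, so 9 of 12 at the default 0.75 is
   conserved. **Majority** is the weaker call: a hit anywhere in strictly
   more than half of the collected promoters, with no positional constraint,
   computed even when the focal promoter lacks the motif.
6. **Summary.** The three-column table mirrors the field's presentation:
   per motif, (i) regulated genes whose focal promoter carries the motif,
   over the genes with a focal promoter; (ii) conserved genes and (iii)
   majority genes, both over the *smaller* denominator of genes with
   evaluable ortholog groups. The two denominators are printed explicitly in
   every output because collapsing them silently would misstate the
   percentages. Percentages are rounded half-up to integers, matching
   printed-table convention.
7. **Discovery.** Conserved k-mers are found from a seed cluster of genes:
   every k-mer occurring in the cluster's focal promoters is folded with its
   reverse complement into a canonical key (the lexicographically smaller of
   the pair), classified with the same conservation criterion against every
   cluster gene's ortholog group, kept when conserved in at least
   `min_cluster_fraction` of the cluster, and ranked by conservation score,
   then fewer total occurrences across the cluster promoters, then
   lexicographically. The occurrence tie-break matters: low-complexity
   AT-rich words are frequently "conserved everywhere" purely by abundance,
   and ranking them below equally-scoring rare words keeps genuinely planted
   or biological elements on top.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `promoter_length` | 1000 | bp | fragment length used throughout the clade comparison |
| `p_max`, `lfc_min` | 0.01, 1.5 | —, log2 | inclusive selection cutoffs |
| `presence_threshold` | 0.75 | fraction | "at least 75% of collected orthologs", inclusive |
| `position_window` | 200 | bp | operationalizes "similar position to the start codon"; no published number exists, so this is a package choice — conservative relative to 1,000 bp fragments and echoed in every report and manifest |
| `min_orthologs` | 8 | promoters | two-thirds of a 12-species clade; groups below it are excluded from the conservation denominators, reproducing the collected-ortholog funnel |
| `min_cluster_fraction` | 0.8 | fraction | 4 of 5 seed-cluster genes |

## The synthetic generator

Real promoter sets for this clade are not redistributable, so every stage is
exercised against generated data with known truth:

* Background promoters have i.i.d. bases with `P(G) = P(C) = gc/2`. The
  default GC content is 0.30 — AT-rich, as yeast intergenic DNA is. No
  dinucleotide structure is modelled; for calibrating false-positive rates
  of 5–6-mers the i.i.d. model is adequate and has a closed form: the
  expected both-strand hit count of a k-mer is `2 (L - k + 1) \prod_i p(b_i)`
  (under the generator's strand-symmetric composition), which the test suite
  verifies empirically to within Monte-Carlo error.
* A planted motif is written at `anchor_offset` (default −150 bp, a typical
  proximal-element position in compact yeast promoters) plus rounded
  Gaussian jitter (`jitter_sd`, default 30 bp), clipped to the valid window.
  Each species carries the motif independently with `presence_prob`.
* By default the focal species always carries the planted motif
  (`plantInFocal = TRUE`). This mirrors the analysis itself: clade
  conservation is only ever assessed for motifs already observed in the
  focal promoter, so the interesting operating characteristic is the
  classifier's response to *ortholog* presence. It also makes the expected
  conserved rate a clean binomial tail — with 11 orthologs carrying at
  probability $p$ and the focal promoter anchored, the conserved probability
  is approximately $P(\mathrm{Binom}(11, p) \ge 8)$: 0.98 at $p = 0.9$ and
  0.03 at $p = 0.4$, which the Monte-Carlo acceptance checks measure at 500
  seeded groups per band. Setting `plantInFocal = FALSE` restores fully
  independent carriage (used for background-only calibration).
* The calibration experiments use the 6 bp motif `CGGCTT` rather than the
  5-mer. A 5-mer such as `ATGCA` occurs roughly twice per kilobase of
  background at any realistic GC — high enough that background hits inside
  the position window, not the presence probability, would dominate the
  measured rates. That abundance is not a defect: it is exactly why the
  positional criterion exists, and it is visible in the summary's majority
  column. The 6-mer isolates the quantity being calibrated.
* `writeFixtureGenome` lays promoters and gene bodies onto a contig so that
  extraction provably inverts construction on both strands; explicit
  coordinates are checked for collisions. The generator does **not** emulate
  promoter evolution (indels, phylogenetic correlation among species) or
  read-level sequencing data, so passing tests demonstrate algorithmic
  correctness and calibration under the stated model, not performance on
  real genomes.

## Numerical and degenerate-input choices

* Fraction-versus-threshold comparisons subtract `1e-9` before testing
  `>=`, so exact boundaries (9/12 vs 0.75) are decided by arithmetic, not
  floating-point luck.
* Discovery ties are fully ordered (score desc, occurrences asc,
  lexicographic) for determinism; the z-score uses the population SD
  (divisor *n*), the common heatmap-tool convention, and constant rows
  become zeros with a warning.
* All-zero samples: TPM emits a zero column with a warning; FPKM refuses
  (division undefined) unless `allowZeroLibraries` is set.
* A single-sequence scan errors when the motif is longer than the sequence;
  scanning a promoter *set* silently yields no hits for fragments shorter
  than the motif, so one truncated promoter cannot abort a clade-wide run.
* The pipeline is byte-deterministic for a fixed seed and inputs, except
  wall-clock values, which are confined to the run log and the manifest's
  `timestamp` field.

## Problem sizes used by the checks

The shipped verification suite uses sizes chosen to finish quickly while
keeping Monte-Carlo error well inside the asserted margins: 1,000 random
promoter/motif scan comparisons against a naive every-window oracle; 10,000
reverse-complement involutions; 500 genome-fixture round trips; 500 seeded
groups per conservation operating band; 200 discovery replicates of a
5-gene, 12-species cluster; a million-gene null selection table; and the
full 150-regulated-gene demonstration pipeline run twice for byte-identity.

## Limitations

Species are treated as exchangeable — there is no phylogeny-aware weighting
of conservation, matching the analysis this package reproduces. No
statistical significance is attached to a conservation call (no null model
is applied in the summary), and position-weight-matrix motifs and
enrichment E-values are out of scope. The GFF3 reader deliberately handles
only `gene` features with `ID=` attributes; transcript isoforms and TSS
resolution are not modelled, so "promoter" always means the fixed-length
window upstream of the annotated gene start.
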