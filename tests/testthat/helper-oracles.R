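# Independent oracles used to check the implementation. These deliberately
# avoid the package's scanning/conservation code paths: matching is done by
# per-window character comparison and reverse complements via chartr.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleRevcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(s))
    paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# 1-based start positions of windows matching an IUPAC pattern; N in the
# sequence matches nothing (it is outside every IUPAC set here).
oracleMatchStarts <- function(seq, motif) {
  s <- strsplit(toupper(seq), "")[[1L]]
  p <- strsplit(toupper(motif), "")[[1L]]
  L <- length(s); k <- length(p)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) ok <- ok & s[seq_len(n) + j - 1L] %in% IUPAC_SETS[[p[j]]]
  which(ok)
}

# Naive every-window both-strand scan in the package's hit-table layout.
oracleScan <- function(seq, motif, bothStrands = TRUE, geneId = "seq",
                       speciesId = NA_character_) {
  L <- nchar(seq); k <- nchar(motif)
  ps <- oracleMatchStarts(seq, motif)
  rcm <- oracleRevcomp(motif)
  ms <- if (bothStrands && !identical(rcm, toupper(motif)))
    oracleMatchStarts(seq, rcm) else integer(0)
  start1 <- c(ps, ms)
  if (!length(start1))
    return(data.frame(gene_id = character(0), species_id = character(0),
                      motif = character(0), offset = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE))
  strand <- rep(c("+", "-"), c(length(ps), length(ms)))
  off <- start1 - 1L - L
  ord <- order(off, strand)
  data.frame(gene_id = geneId, species_id = speciesId,
             motif = toupper(motif), offset = off[ord], strand = strand[ord],
             match = substring(toupper(seq), start1[ord],
                               start1[ord] + k - 1L),
             stringsAsFactors = FALSE)
}

# Maximum number of non-overlapping occurrences of equal-length windows,
# by exhaustive dynamic programming over sorted offsets.
oracleMaxNonOverlapping <- function(offsets, k) {
  offs <- sort(unique(offsets))
  n <- length(offs)
  if (!n) return(0L)
  best <- integer(n)
  for (i in seq_len(n)) {
    prev <- which(offs <= offs[i] - k)
    best[i] <- 1L + if (length(prev)) max(best[prev]) else 0L
  }
  max(best)
}

# Brute-force membership-table overlap counts for a list of gene-id vectors.
oracleOverlap <- function(lists) {
  genes <- unique(unlist(lists))
  member <- sapply(lists, function(g) genes %in% g)
  if (length(genes) == 1L) member <- matrix(member, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(lists)))[-1L, ,
                                                                  drop = FALSE]
  region <- apply(combos, 1L, function(pat)
    sum(apply(member, 1L, function(r) all(r == as.logical(pat)))))
  inter <- apply(combos, 1L, function(pat)
    sum(apply(member[, as.logical(pat), drop = FALSE], 1L, all)))
  list(region = as.integer(region), intersection = as.integer(inter))
}

# Naive conservation call over raw sequences, independent of the package's
# scanner and classifier.
oracleConservation <- function(seqs, species, focalSpecies, motif,
                               threshold = 0.75, window = 200,
                               minOrthologs = 8) {
  offs <- lapply(seqs, function(s) oracleScan(s, motif)$offset)
  nCollected <- length(seqs)
  fi <- match(focalSpecies, species)
  hasHit <- vapply(offs, function(o) length(o) > 0L, logical(1))
  majority <- sum(hasHit) > nCollected / 2
  if (!length(offs[[fi]]))
    return(list(conserved = FALSE, majority = majority,
                evaluable = FALSE, nIn = 0L))
  ref <- max(offs[[fi]])
  nIn <- sum(vapply(offs, function(o)
    length(o) > 0L && any(abs(o - ref) <= window), logical(1)))
  evaluable <- nCollected >= minOrthologs
  list(conserved = evaluable && nIn / nCollected >= threshold - 1e-9,
       majority = majority, evaluable = evaluable, nIn = nIn)
}

# Random IUPAC string for involution checks.
randIupac <- function(len) {
  paste(sample(names(IUPAC_SETS), len, replace = TRUE), collapse = "")
}

# Random ACGT sequence with the given GC content (test-local generator).
randSeq <- function(len, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Build a 12-promoter group with the motif planted in `carriers` at the given
# offsets, on an A-only background that cannot contain accidental hits.
plantedGroup <- function(motif, carriers, offsets, nSpecies = 12,
                         L = 1000) {
  species <- sprintf("sp%02d", seq_len(nSpecies))
  seqs <- rep(strrep("A", L), nSpecies)
  for (i in seq_along(carriers)) {
    j <- carriers[i]
    seqs[j] <- plantMotif(seqs[j], motif, offsets[i])
  }
  PromoterSet(seqs, geneId = paste0("g1", c("", paste0("_", species[-1]))),
              speciesId = species, requestedLength = L)
}
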