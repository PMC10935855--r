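#' @include AllGenerics.R AllClasses.R
NULL

# Motif scanning with start-codon-anchored offsets, repeat counting, and
# canonical k-mer folding. Window matching delegates to
# Biostrings::vmatchPattern with fixed = "subject": IUPAC codes in the
# pattern are expanded while N in the scanned sequence matches nothing.

#' Reverse complement of IUPAC strings
#'
#' Standard complement with the full IUPAC degeneracy mapping, reversed.
#' Applying it twice is the identity.
#'
#' @param x character vector of IUPAC strings
#' @return character vector of the same length
#' @examples
#' reverseComplementIupac(c("CGGAT", "CGGCTT"))  # "ATCCG", "AAGCCG"
#' @export
reverseComplementIupac <- function(x) {
  if (!is.character(x) || !length(x)) stopInput("'x' must be a character vector")
  bad <- !.isIupac(x)
  if (any(bad))
    stopInput("'%s' contains non-IUPAC characters", x[which(bad)[1L]])
  .revcompChr(toupper(x))
}

#' Canonical form of k-mers
#'
#' Folds each k-mer with its reverse complement into one identity: the
#' lexicographically smaller of the pair.
#'
#' @param x character vector of ACGT k-mers
#' @return canonical k-mers
#' @export
canonicalKmer <- function(x) {
  x <- toupper(x)
  rc <- reverseComplementIupac(x)
  ifelse(x <= rc, x, rc)
}

.checkMotif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stopInput("'motif' must be a single non-empty pattern")
  motif <- toupper(motif)
  if (!.isIupac(motif)) stopInput("'%s' is not an IUPAC pattern", motif)
  motif
}

# Core scanner over a DNAStringSet with per-sequence gene/species labels.
.scanImpl <- function(seqs, geneId, speciesId, motif, bothStrands) {
  k <- nchar(motif)
  W <- width(seqs)
  chars <- as.character(seqs)
  empty <- data.frame(gene_id = character(0), species_id = character(0),
                      motif = character(0), offset = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE)
  scannable <- which(W >= k)
  if (!length(scannable)) return(empty)
  sub <- seqs[scannable]
  plus <- Biostrings::startIndex(
    Biostrings::vmatchPattern(motif, sub, fixed = "subject"))
  rcm <- .revcompChr(motif)
  minus <- if (bothStrands && !identical(rcm, motif))
    Biostrings::startIndex(
      Biostrings::vmatchPattern(rcm, sub, fixed = "subject"))
  else vector("list", length(sub))
  rows <- vector("list", length(sub))
  for (j in seq_along(sub)) {
    i <- scannable[j]
    ps <- plus[[j]] %||% integer(0)
    ms <- minus[[j]] %||% integer(0)
    if (!length(ps) && !length(ms)) next
    start1 <- c(ps, ms)
    strand <- rep(c("+", "-"), c(length(ps), length(ms)))
    off <- start1 - 1L - W[i]
    ord <- order(off, strand)
    rows[[j]] <- data.frame(
      gene_id = geneId[i], species_id = speciesId[i], motif = motif,
      offset = off[ord], strand = strand[ord],
      match = substring(chars[i], start1[ord], start1[ord] + k - 1L),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' @describeIn scanMotif scan a single sequence (gene/species labelled
#'   `"seq"`/`"NA"` unless given); errors when the motif is longer than the
#'   sequence
#' @param bothStrands also report reverse-complement matches as strand `-`
#' @param geneId,speciesId labels used in the hit table
#' @export
setMethod("scanMotif", "character",
          function(x, motif, bothStrands = TRUE, geneId = "seq",
                   speciesId = NA_character_) {
  if (length(x) != 1L) stopInput("scan one sequence at a time, or pass a PromoterSet")
  motif <- .checkMotif(motif)
  if (nchar(motif) > nchar(x))
    stopInput("motif (%d bp) longer than sequence (%d bp)",
              nchar(motif), nchar(x))
  .scanImpl(Biostrings::DNAStringSet(toupper(x)), geneId, speciesId,
            motif, bothStrands)
})

#' @describeIn scanMotif scan a named `DNAStringSet`; sequences shorter than
#'   the motif yield no hits
#' @export
setMethod("scanMotif", "DNAStringSet",
          function(x, motif, bothStrands = TRUE, speciesId = NA_character_) {
  motif <- .checkMotif(motif)
  ids <- names(x) %||% as.character(seq_along(x))
  .scanImpl(x, ids, rep_len(speciesId, length(x)), motif, bothStrands)
})

#' @describeIn scanMotif scan a \linkS4class{PromoterSet}; gene and species
#'   labels come from the fragment metadata
#' @export
setMethod("scanMotif", "PromoterSet",
          function(x, motif, bothStrands = TRUE) {
  motif <- .checkMotif(motif)
  .scanImpl(x, geneIds(x), speciesIds(x), motif, bothStrands)
})

#' Count non-overlapping motif repeats
#'
#' Hits from both strands are merged by offset and counted greedily left to
#' right; overlapping occurrences collapse to one. For equal-length windows
#' the greedy count equals the maximum number of non-overlapping occurrences.
#'
#' @param hits hit table from [scanMotif()] for a single (gene, motif) pair
#' @return data.frame with `gene_id`, `motif`, `count`
#' @export
countRepeats <- function(hits) {
  if (!nrow(hits))
    return(data.frame(gene_id = character(0), motif = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  if (length(unique(hits$gene_id)) != 1L) stopInput("hits mix gene ids")
  if (length(unique(hits$motif)) != 1L) stopInput("hits mix motifs")
  k <- nchar(hits$motif[1L])
  offs <- sort(unique(hits$offset))
  count <- 0L; last <- -Inf
  for (o in offs) {
    if (o >= last + k) { count <- count + 1L; last <- o }
  }
  data.frame(gene_id = hits$gene_id[1L], motif = hits$motif[1L],
             count = count, stringsAsFactors = FALSE)
}

#' Export motif hits as BED-like intervals
#'
#' Coordinates are 0-based half-open and local to each promoter fragment
#' (column 1 is the gene id); the anchored signed offset is kept as an extra
#' column.
#'
#' @param hits hit table from [scanMotif()]
#' @param promoters the \linkS4class{PromoterSet} that was scanned (provides
#'   fragment lengths)
#' @return data.frame with columns `gene_id`, `start`, `end`, `motif`,
#'   `score`, `strand`, `offset`, `species_id`
#' @export
hitsAsBed <- function(hits, promoters) {
  stopifnot(is(promoters, "PromoterSet"))
  if (!nrow(hits))
    return(data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      score = character(0), strand = character(0),
                      offset = integer(0), species_id = character(0),
                      stringsAsFactors = FALSE))
  key <- paste(speciesIds(promoters), geneIds(promoters))
  L <- stats::setNames(width(promoters), key)[paste(hits$species_id,
                                                    hits$gene_id)]
  if (anyNA(L)) stopInput("hit for a gene absent from 'promoters'")
  k <- nchar(hits$motif)
  data.frame(gene_id = hits$gene_id, start = unname(L) + hits$offset,
             end = unname(L) + hits$offset + k, motif = hits$motif,
             score = ".", strand = hits$strand, offset = hits$offset,
             species_id = hits$species_id, stringsAsFactors = FALSE)
}
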