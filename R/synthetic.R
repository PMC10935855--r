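#' Parameters for synthetic promoter clades
#'
#' Bundles the knobs of the synthetic-data generator. Defaults describe the
#' emulated study system: a 12-species yeast clade, 1,000 bp promoter
#' fragments, AT-rich intergenic base composition (GC = 0.30), and a short
#' motif planted around a fixed anchor upstream of the start codon with
#' Gaussian positional jitter.
#'
#' @param nSpecies number of clade species (one promoter each)
#' @param promoterLength fragment length in bp
#' @param gcContent GC fraction of the background sequence, in \[0, 1\]
#' @param motif planted pattern (plain ACGT)
#' @param presenceProb probability that a species carries the planted motif
#' @param anchorOffset planted anchor in start-codon-anchored convention
#'   (negative; -1 is the base immediately 5' of the start codon)
#' @param jitterSd SD (bp) of the Gaussian jitter added to the anchor;
#'   planted offsets are rounded and clipped to the valid window
#' @param plantInFocal if TRUE (default) the focal (first) species always
#'   carries the motif, emulating conservation analysis seeded from motifs
#'   already present in the focal promoter; if FALSE the focal species carries
#'   it with `presenceProb` like every other species
#' @param seed integer seed making all generated material reproducible
#' @return a validated list of class `"SyntheticSpec"`
#' @examples
#' spec <- syntheticSpec(presenceProb = 1, jitterSd = 0)
#' grp <- generateOrthologGroup(spec)
#' grp$truth
#' @export
syntheticSpec <- function(nSpecies = 12L, promoterLength = 1000L,
                          gcContent = 0.30, motif = "ATGCA",
                          presenceProb = 0.85, anchorOffset = -150L,
                          jitterSd = 30, plantInFocal = TRUE, seed = 1L) {
  if (!.isCount(nSpecies) || nSpecies < 1) stopInput("nSpecies must be a positive count")
  if (!.isCount(promoterLength) || promoterLength < 1)
    stopInput("promoterLength must be a positive count")
  if (!.isScalarNumber(gcContent) || gcContent < 0 || gcContent > 1)
    stopInput("gcContent must be in [0, 1]")
  if (!is.character(motif) || length(motif) != 1L || !grepl("^[ACGT]+$", motif))
    stopInput("motif must be a plain ACGT pattern")
  k <- nchar(motif)
  if (promoterLength < k) stopInput("promoterLength must be >= motif length")
  if (!.isScalarNumber(presenceProb) || presenceProb < 0 || presenceProb > 1)
    stopInput("presenceProb must be in [0, 1]")
  if (!.isScalarNumber(anchorOffset) ||
      anchorOffset < -promoterLength || anchorOffset > -k)
    stopInput("anchorOffset must lie in [-promoterLength, -motif length]")
  if (!.isScalarNumber(jitterSd) || jitterSd < 0)
    stopInput("jitterSd must be non-negative")
  structure(list(nSpecies = as.integer(nSpecies),
                 promoterLength = as.integer(promoterLength),
                 gcContent = gcContent, motif = motif,
                 presenceProb = presenceProb,
                 anchorOffset = as.integer(anchorOffset),
                 jitterSd = jitterSd,
                 plantInFocal = isTRUE(plantInFocal),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' @export
print.SyntheticSpec <- function(x, ...) {
  cat(sprintf(
    "SyntheticSpec: %d species, %d bp promoters (GC %.2f), motif %s\n",
    x$nSpecies, x$promoterLength, x$gcContent, x$motif))
  cat(sprintf(
    "  presenceProb %.2f, anchor %d bp, jitter SD %g bp, focal planted: %s, seed %d\n",
    x$presenceProb, x$anchorOffset, x$jitterSd, x$plantInFocal, x$seed))
  invisible(x)
}

#' Generate a random promoter sequence
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length sequence length in bp (>= 1)
#' @param gc GC fraction in \[0, 1\]
#' @param seed optional seed; the same seed yields the identical sequence and
#'   the caller's RNG stream is left untouched
#' @return an uppercase character string over ACGT of exactly `length` bases
#' @examples
#' generatePromoter(20, gc = 0, seed = 1)   # A/T only
#' @export
generatePromoter <- function(length, gc = 0.30, seed = NULL) {
  if (!.isCount(length) || length < 1) stopInput("'length' must be a positive count")
  if (!.isScalarNumber(gc) || gc < 0 || gc > 1) stopInput("'gc' must be in [0, 1]")
  .withSeed(seed, .randomSeqs(1L, as.integer(length), gc))
}

#' Plant a motif into a sequence at a start-codon-anchored offset
#'
#' The motif occupies the window `[offset, offset + k - 1]` where offset -1 is
#' the base immediately 5' of the start codon; on strand `-` the reverse
#' complement is written instead. Only the window changes; length is
#' preserved.
#'
#' @param sequence a single character string
#' @param motif plain ACGT pattern
#' @param offset signed bp, `-L <= offset` and `offset + k <= 0`
#' @param strand `"+"` or `"-"`
#' @return the modified sequence
#' @examples
#' plantMotif("AAAAAAAAAA", "ATGCA", -10)        # "ATGCAAAAAA"
#' plantMotif("AAAAAAAAAA", "ATGCA", -5, "-")    # "AAAAATGCAT"
#' @export
plantMotif <- function(sequence, motif, offset, strand = "+") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stopInput("'sequence' must be a single string")
  if (!grepl("^[ACGT]+$", motif)) stopInput("'motif' must be a plain ACGT pattern")
  if (!(strand %in% c("+", "-"))) stopInput("'strand' must be \"+\" or \"-\"")
  L <- nchar(sequence); k <- nchar(motif)
  if (!.isScalarNumber(offset) || offset != as.integer(offset))
    stopInput("'offset' must be an integer")
  if (offset < -L || offset + k > 0)
    stopInput("motif window [%d, %d] falls outside a %d bp sequence",
              offset, offset + k - 1, L)
  w0 <- L + offset                      # 0-based window start
  ins <- if (strand == "-") .revcompChr(motif) else motif
  paste0(substr(sequence, 1L, w0), ins, substr(sequence, w0 + k + 1L, L))
}

#' Generate one synthetic ortholog promoter group with known truth
#'
#' One promoter per species. Each species carries the planted motif with
#' probability `presenceProb` (the focal species always does when
#' `plantInFocal` is set), at `anchorOffset` plus rounded Gaussian jitter,
#' clipped to the valid window. The focal species is the first one.
#'
#' @param spec a [syntheticSpec()]
#' @param groupId focal gene id for the group (ortholog gene ids are derived
#'   as `<groupId>_<species>`)
#' @param speciesIds optional species ids (default `sp01`, `sp02`, ...)
#' @return a list with elements `promoters` (a \linkS4class{PromoterSet}) and
#'   `truth` (data.frame: `group_id`, `species_id`, `gene_id`, `carrier`,
#'   `offset`)
#' @export
generateOrthologGroup <- function(spec, groupId = "g001", speciesIds = NULL) {
  if (!inherits(spec, "SyntheticSpec")) stopInput("'spec' must be a SyntheticSpec")
  sps <- if (is.null(speciesIds)) sprintf("sp%02d", seq_len(spec$nSpecies))
         else as.character(speciesIds)
  if (length(sps) != spec$nSpecies) stopInput("speciesIds length must equal nSpecies")
  .withSeed(spec$seed, .generateGroupImpl(spec, groupId, sps))
}

# RNG-consuming core; callers control seeding.
.generateGroupImpl <- function(spec, groupId, sps) {
  L <- spec$promoterLength; k <- nchar(spec$motif)
  n <- length(sps)
  seqs <- character(n); carrier <- logical(n); offs <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- .randomSeqs(1L, L, spec$gcContent)
    carry <- if (i == 1L && spec$plantInFocal) TRUE
             else runif(1) < spec$presenceProb
    if (carry) {
      off <- as.integer(round(spec$anchorOffset + rnorm(1, 0, spec$jitterSd)))
      off <- max(-L, min(-k, off))
      s <- plantMotif(s, spec$motif, off)
      offs[i] <- off
    }
    carrier[i] <- carry
    seqs[i] <- s
  }
  gids <- c(groupId, paste0(groupId, "_", sps[-1L]))
  list(promoters = PromoterSet(seqs, geneId = gids, speciesId = sps,
                               requestedLength = L),
       truth = data.frame(group_id = groupId, species_id = sps,
                          gene_id = gids, carrier = carrier, offset = offs,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic differential-expression table with known truth
#'
#' Null genes receive `p ~ Uniform(0,1)` and `log2FC ~ Normal(0, 0.3)`;
#' regulated genes receive `p ~ Beta(pAltShape, 1)` (small shape gives small
#' p-values) and `log2FC ~ Normal(+/- lfcAltMean, 0.3)` with a recorded sign.
#'
#' @param nGenes total genes
#' @param nRegulated number of regulated genes (`<= nGenes`)
#' @param pAltShape Beta shape parameter of the regulated p-value distribution
#' @param lfcAltMean magnitude of the regulated mean log2 fold change
#' @param comparison comparison identifier written into the table
#' @param seed optional seed
#' @param regulated optional gene ids to mark as regulated (default: random)
#' @param direction optional per-regulated-gene direction (`"up"`/`"down"`,
#'   recycled; default: random signs)
#' @param geneIds optional gene ids (default `gene0001`, ...)
#' @return a list with `table` (data.frame: `gene_id`, `comparison`,
#'   `log2fc`, `pvalue`) and `truth` (data.frame: `gene_id`, `direction`)
#' @export
generateDETable <- function(nGenes, nRegulated, pAltShape = 0.05,
                            lfcAltMean = 3, comparison = "cond1",
                            seed = NULL, regulated = NULL, direction = NULL,
                            geneIds = NULL) {
  if (!.isCount(nGenes) || nGenes < 1) stopInput("nGenes must be a positive count")
  if (!.isCount(nRegulated)) stopInput("nRegulated must be a count")
  if (nRegulated > nGenes) stopInput("nRegulated exceeds nGenes")
  if (!.isScalarNumber(pAltShape) || pAltShape <= 0)
    stopInput("pAltShape must be positive")
  ids <- if (is.null(geneIds)) sprintf("gene%04d", seq_len(nGenes))
         else as.character(geneIds)
  if (length(ids) != nGenes) stopInput("geneIds length must equal nGenes")
  .withSeed(seed, {
    reg <- if (is.null(regulated)) sample(ids, nRegulated) else {
      if (!all(regulated %in% ids)) stopInput("unknown gene id in 'regulated'")
      if (length(regulated) != nRegulated)
        stopInput("length of 'regulated' must equal nRegulated")
      as.character(regulated)
    }
    isReg <- ids %in% reg
    p <- runif(nGenes)
    lfc <- rnorm(nGenes, 0, 0.3)
    if (nRegulated > 0) {
      sgn <- if (is.null(direction)) sample(c(1, -1), nRegulated, replace = TRUE)
             else ifelse(rep_len(direction, nRegulated) == "down", -1, 1)
      ord <- match(reg, ids)
      p[ord] <- rbeta(nRegulated, pAltShape, 1)
      lfc[ord] <- rnorm(nRegulated, sgn * lfcAltMean, 0.3)
      truth <- data.frame(gene_id = reg,
                          direction = ifelse(sgn > 0, "up", "down"),
                          stringsAsFactors = FALSE)
    } else {
      truth <- data.frame(gene_id = character(0), direction = character(0),
                          stringsAsFactors = FALSE)
    }
    list(table = data.frame(gene_id = ids, comparison = comparison,
                            log2fc = lfc, pvalue = p,
                            stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a synthetic counts matrix
#'
#' Negative-binomial counts with log-normal per-gene means, packaged as a
#' `SummarizedExperiment` with a `counts` assay, a `length` column in
#' `rowData`, and sample metadata in `colData`.
#'
#' @param geneIds gene identifiers
#' @param samples data.frame of sample metadata (one row per sample; its
#'   rownames or a `sample` column become the column names)
#' @param seed optional seed
#' @return a `SummarizedExperiment`
#' @export
generateCountsMatrix <- function(geneIds, samples, seed = NULL) {
  if (!length(geneIds)) stopInput("no gene ids")
  if (!is.data.frame(samples) || !nrow(samples)) stopInput("'samples' must be a non-empty data.frame")
  sn <- if ("sample" %in% colnames(samples)) as.character(samples$sample)
        else rownames(samples)
  .withSeed(seed, {
    mu <- rlnorm(length(geneIds), log(200), 1)
    len <- sample(300:4000, length(geneIds), replace = TRUE)
    m <- matrix(rnbinom(length(geneIds) * nrow(samples),
                        mu = rep(mu, nrow(samples)), size = 8),
                nrow = length(geneIds), ncol = nrow(samples),
                dimnames = list(geneIds, sn))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = m),
      rowData = S4Vectors::DataFrame(length = len, row.names = geneIds),
      colData = S4Vectors::DataFrame(samples, row.names = sn))
  })
}

#' Write a synthetic genome (FASTA + GFF3) whose promoters are known exactly
#'
#' Builds one contig carrying the supplied genes so that
#' [extractPromoters()] recovers each intended promoter sequence exactly, for
#' both strands: a plus-strand gene is laid down as `promoter | body`, a
#' minus-strand gene as `revcomp(body) | revcomp(promoter)` with the
#' annotation on the body. Genes are placed left to right with random spacers
#' unless explicit `start` coordinates (1-based, of the gene body) are given,
#' in which case overlapping layouts raise an input error.
#'
#' @param genes data.frame with columns `gene_id`, `strand`, `promoter`
#'   (sequence) and optionally `body` (default: ATG + 87 random bases) and
#'   `start`
#' @param outPrefix path prefix; `<prefix>.fasta` and `<prefix>.gff3` are
#'   written
#' @param speciesId species id recorded in the annotations
#' @param contigId contig name (default `<speciesId>_c1`)
#' @param spacer spacer length (bp) between auto-placed genes
#' @param gc GC fraction of spacer/filler sequence
#' @param seed seed for spacer/body sequence generation
#' @return invisibly, a list with `fasta`, `gff3`, `annotations` (data.frame)
#'   and `contig` (the full contig sequence)
#' @export
writeFixtureGenome <- function(genes, outPrefix, speciesId = "sp01",
                               contigId = NULL, spacer = 60L, gc = 0.30,
                               seed = 1L) {
  if (!is.data.frame(genes) || !nrow(genes)) stopInput("'genes' must be a non-empty data.frame")
  need <- c("gene_id", "strand", "promoter")
  if (!all(need %in% colnames(genes)))
    stopInput("'genes' needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stopInput("duplicated gene_id in layout")
  if (!all(genes$strand %in% c("+", "-"))) stopInput("strand must be + or -")
  if (is.null(contigId)) contigId <- paste0(speciesId, "_c1")
  .withSeed(seed, {
    bodies <- if ("body" %in% colnames(genes)) as.character(genes$body)
              else paste0("ATG", vapply(seq_len(nrow(genes)),
                                        function(i) .randomSeqs(1L, 87L, gc),
                                        character(1)))
    promoters <- as.character(genes$promoter)
    pl <- nchar(promoters); bl <- nchar(bodies)
    n <- nrow(genes)
    if (!is.null(genes$start) && !all(is.na(genes$start))) {
      if (anyNA(genes$start)) stopInput("either all or no 'start' coordinates must be given")
      start <- as.integer(genes$start)
      # segment span on the reference for gene i
      segFrom <- ifelse(genes$strand == "+", start - pl, start)
      segTo   <- ifelse(genes$strand == "+", start + bl - 1L,
                        start + bl - 1L + pl)
      if (any(segFrom < 1L))
        stopInput("gene '%s' lacks room for its promoter",
                  genes$gene_id[which(segFrom < 1L)[1L]])
      ord <- order(segFrom)
      if (any(segFrom[ord][-1L] <= segTo[ord][-n]))
        stopInput("layout collision: gene segments overlap")
      contigLen <- max(segTo)
      contig <- strsplit(.randomSeqs(1L, contigLen, gc), "")[[1L]]
    } else {
      start <- integer(n); segFrom <- integer(n); segTo <- integer(n)
      pos <- 1L
      for (i in seq_len(n)) {
        pos <- pos + spacer
        segFrom[i] <- pos
        if (genes$strand[i] == "+") start[i] <- pos + pl[i]
        else start[i] <- pos
        segTo[i] <- segFrom[i] + pl[i] + bl[i] - 1L
        pos <- segTo[i] + 1L
      }
      contigLen <- pos + spacer - 1L
      contig <- strsplit(.randomSeqs(1L, contigLen, gc), "")[[1L]]
    }
    rcBodies <- .revcompChr(bodies)
    rcPromoters <- .revcompChr(promoters)
    geneStart <- integer(n); geneEnd <- integer(n)
    for (i in seq_len(n)) {
      if (genes$strand[i] == "+") {
        seg <- paste0(promoters[i], bodies[i])
        geneStart[i] <- segFrom[i] + pl[i]
        geneEnd[i] <- geneStart[i] + bl[i] - 1L
      } else {
        seg <- paste0(rcBodies[i], rcPromoters[i])
        geneStart[i] <- segFrom[i]
        geneEnd[i] <- segFrom[i] + bl[i] - 1L
      }
      contig[segFrom[i]:(segFrom[i] + nchar(seg) - 1L)] <-
        strsplit(seg, "")[[1L]]
    }
    contigSeq <- paste(contig, collapse = "")
    ann <- data.frame(gene_id = genes$gene_id, contig = contigId,
                      start = geneStart, end = geneEnd,
                      strand = genes$strand, species_id = speciesId,
                      stringsAsFactors = FALSE)
    fasta <- paste0(outPrefix, ".fasta"); gff <- paste0(outPrefix, ".gff3")
    ss <- Biostrings::DNAStringSet(contigSeq)
    names(ss) <- contigId
    Biostrings::writeXStringSet(ss, fasta, width = 60L)
    .writeGff3(ann, gff)
    invisible(list(fasta = fasta, gff3 = gff, annotations = ann,
                   contig = contigSeq))
  })
}
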