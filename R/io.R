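# Readers/writers for the pipeline's file formats. FASTA goes through
# Biostrings; GFF3 uses a small streaming reader restricted to `gene`
# features with `ID=` attributes so that format errors can cite line numbers.

#' Read a genome FASTA into a named DNAStringSet
#'
#' Sequences are uppercased; ids must be unique; characters outside ACGTN are
#' rejected with the offending record named.
#'
#' @param path FASTA file
#' @return a named `DNAStringSet`, one entry per contig
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopFormat("%s: %s", path, conditionMessage(e)))
  if (!length(raw)) stopFormat("%s: no FASTA records", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopFormat("%s: duplicate contig id '%s'", path, dup[1L])
  seqs <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stopFormat("%s: record '%s' contains characters outside ACGTN",
               path, ids[which(bad)[1L]])
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

# GFF3 writer: version pragma, 1-based inclusive coordinates, gene features.
.writeGff3 <- function(annotations, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcladeMotifs\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotations$contig, annotations$start, annotations$end,
                     annotations$strand, annotations$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Only `gene` features are retained; coordinates stay 1-based inclusive as
#' in the file. The `ID=` attribute names the gene. Malformed lines raise
#' format errors citing the line number; a file without any gene feature
#' returns an empty set with a warning.
#'
#' @param path GFF3 file
#' @param speciesId species id attached to every annotation
#' @return data.frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `species_id`
#' @export
readAnnotationsGff3 <- function(path, speciesId) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  out <- vector("list", length(rows))
  nGene <- 0L; nOther <- 0L
  for (i in rows) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L)
      stopFormat("%s line %d: expected 9 tab-separated fields, got %d",
                 path, i, length(f))
    if (f[3L] != "gene") { nOther <- nOther + 1L; next }
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end))
      stopFormat("%s line %d: non-numeric coordinates", path, i)
    if (end < start)
      stopFormat("%s line %d: end (%d) < start (%d)", path, i, end, start)
    if (!(f[7L] %in% c("+", "-")))
      stopFormat("%s line %d: strand must be + or -", path, i)
    id <- regmatches(f[9L], regexpr("(?<=(^|;)ID=)[^;]+", f[9L], perl = TRUE))
    if (!length(id))
      stopFormat("%s line %d: gene feature lacks an ID attribute", path, i)
    nGene <- nGene + 1L
    out[[nGene]] <- data.frame(gene_id = id, contig = f[1L], start = start,
                               end = end, strand = f[7L],
                               species_id = speciesId,
                               stringsAsFactors = FALSE)
  }
  if (nGene == 0L) {
    warning(sprintf("%s: no gene features found (%d other feature lines)",
                    path, nOther))
    return(data.frame(gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), species_id = character(0),
                      stringsAsFactors = FALSE))
  }
  ann <- do.call(rbind, out[seq_len(nGene)])
  if (anyDuplicated(ann$gene_id))
    stopFormat("%s: duplicate gene id '%s'", path,
               ann$gene_id[duplicated(ann$gene_id)][1L])
  ann
}

#' Extract strand-aware promoter fragments
#'
#' For a plus-strand gene the fragment is the reference slice
#' `[start - length, start - 1]` (1-based inclusive); for a minus-strand gene
#' it is the reverse complement of `[end + 1, end + length]`. Fragments are
#' clipped at contig boundaries and flagged `truncated`; the start codon is
#' never included. A fragment whose reference window intersects another
#' annotated gene's span is flagged `upstream_overlap` (it is not truncated
#' there).
#'
#' @param genome named `DNAStringSet` (see [readGenomeFasta()])
#' @param annotations data.frame as returned by [readAnnotationsGff3()]
#' @param length requested fragment length in bp (default 1000)
#' @return a \linkS4class{PromoterSet}, one fragment per annotation
#' @examples
#' g <- Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 500), collapse = "")))
#' ann <- data.frame(gene_id = "g1", contig = "c1", start = 1001, end = 1500,
#'                   strand = "+", species_id = "sp01")
#' extractPromoters(g, ann, length = 1000)
#' @export
extractPromoters <- function(genome, annotations, length = 1000L) {
  if (!is(genome, "DNAStringSet")) {
    if (!is.character(genome) || is.null(names(genome)))
      stopInput("'genome' must be a named DNAStringSet or named character vector")
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!.isCount(length) || length < 1) stopInput("'length' must be a positive count")
  if (!nrow(annotations))
    return(PromoterSet(character(0), character(0), character(0),
                       requestedLength = integer(0)))
  unknown <- setdiff(unique(annotations$contig), names(genome))
  if (length(unknown)) stopInput("unknown contig '%s' in annotations", unknown[1L])
  chr <- as.character(genome)
  clen <- nchar(chr)[match(annotations$contig, names(genome))]
  plus <- annotations$strand == "+"
  # reference window of the promoter, before clipping
  winFrom <- ifelse(plus, annotations$start - length, annotations$end + 1L)
  winTo   <- ifelse(plus, annotations$start - 1L, annotations$end + length)
  from <- pmax(winFrom, 1L)
  to <- pmin(winTo, clen)
  seqs <- character(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    seqs[i] <- if (to[i] < from[i]) "" else
      substr(chr[[annotations$contig[i]]], from[i], to[i])
  }
  rc <- which(!plus & nzchar(seqs))
  if (length(rc)) seqs[rc] <- .revcompChr(seqs[rc])
  # empty fragments are representable: DNAStringSet handles ""
  overlap <- logical(nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    same <- which(annotations$contig == annotations$contig[i])
    same <- setdiff(same, i)
    if (length(same))
      overlap[i] <- any(annotations$start[same] <= to[i] &
                        annotations$end[same] >= from[i])
  }
  PromoterSet(seqs, geneId = annotations$gene_id,
              speciesId = annotations$species_id,
              requestedLength = as.integer(length),
              upstreamOverlap = overlap)
}

#' Write promoter fragments as FASTA with structured headers
#'
#' Header format:
#' `>gene_id species=... requested=... truncated=0/1 upstream_gene=0/1`.
#'
#' @param promoters a \linkS4class{PromoterSet}
#' @param path output FASTA path
#' @return the path, invisibly
#' @export
writePromoters <- function(promoters, path) {
  stopifnot(is(promoters, "PromoterSet"))
  mc <- S4Vectors::mcols(promoters)
  ss <- Biostrings::DNAStringSet(as.character(promoters))
  names(ss) <- sprintf("%s species=%s requested=%d truncated=%d upstream_gene=%d",
                       mc$gene_id, mc$species_id, mc$requested_length,
                       as.integer(mc$truncated), as.integer(mc$upstream_overlap))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read promoter fragments written by [writePromoters()]
#' @param path FASTA file with structured headers
#' @return a \linkS4class{PromoterSet}
#' @export
readPromoters <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  hdr <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopFormat("%s: %s", path, conditionMessage(e)))
  if (!length(hdr)) stopFormat("%s: no FASTA records", path)
  bad <- grepl("[^ACGTNacgtn]", as.character(hdr))
  if (any(bad))
    stopFormat("%s: record %d contains characters outside ACGTN", path,
               which(bad)[1L])
  full <- names(hdr)
  field <- function(key) {
    m <- regmatches(full, regexpr(sprintf("(?<=%s=)\\S+", key), full,
                                  perl = TRUE))
    if (length(m) != length(full))
      stopFormat("%s: missing '%s=' in a promoter header", path, key)
    m
  }
  PromoterSet(toupper(as.character(hdr)),
              geneId = sub("\\s.*$", "", full),
              speciesId = field("species"),
              requestedLength = as.integer(field("requested")),
              upstreamOverlap = field("upstream_gene") == "1")
}

#' Read an ortholog table
#'
#' Tab-separated with a header row: the first column holds focal gene ids and
#' each remaining column one clade species; empty cells mean "no ortholog".
#'
#' @param path TSV file
#' @param focalSpecies which species column is the focal one (default: the
#'   first species column)
#' @param species optional expected species set; an unknown column raises a
#'   format error
#' @return an \linkS4class{OrthologTable}
#' @export
readOrthologTable <- function(path, focalSpecies = NULL, species = NULL) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stopFormat("%s: need a focal id column plus species columns", path)
  sp <- colnames(df)[-1L]
  if (!is.null(species)) {
    unknown <- setdiff(sp, species)
    if (length(unknown))
      stopFormat("%s: unknown species column '%s'", path, unknown[1L])
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stopFormat("%s: duplicated focal id '%s'", path, ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m == ""] <- NA_character_
  rownames(m) <- ids
  if (is.null(focalSpecies)) focalSpecies <- sp[1L]
  OrthologTable(m, focalSpecies)
}

#' Write an ortholog table (inverse of [readOrthologTable()])
#' @param table an \linkS4class{OrthologTable}
#' @param path output TSV path
#' @return the path, invisibly
#' @export
writeOrthologTable <- function(table, path) {
  m <- orthologMap(table)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[is.na(df)] <- ""
  .writeTsv(df, path)
}

#' Resolve ortholog promoter groups
#'
#' For each focal gene, collects the promoters of its per-species orthologs
#' from `promoters`. Species without an ortholog id, or whose ortholog has no
#' promoter in `promoters`, are simply absent from the group (the group's
#' size is the number of *collected* promoters).
#'
#' @param table an \linkS4class{OrthologTable}
#' @param promoters a \linkS4class{PromoterSet} covering all species
#' @param genes optional subset of focal genes
#' @return named list of \linkS4class{PromoterSet} groups (one per focal
#'   gene), each with at most one promoter per species
#' @export
orthologGroups <- function(table, promoters, genes = NULL) {
  stopifnot(is(table, "OrthologTable"), is(promoters, "PromoterSet"))
  m <- orthologMap(table)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing))
      stopInput("gene '%s' not present in the ortholog table", missing[1L])
    m <- m[genes, , drop = FALSE]
  }
  key <- paste(speciesIds(promoters), geneIds(promoters))
  lookup <- stats::setNames(seq_along(promoters), key)
  sp <- colnames(m)
  out <- lapply(seq_len(nrow(m)), function(i) {
    want <- paste(sp, m[i, ])
    idx <- lookup[want[!is.na(m[i, ])]]
    idx <- idx[!is.na(idx)]
    promoters[sort(unname(idx))]
  })
  names(out) <- rownames(m)
  out
}

#' Read a differential-expression results table
#'
#' Tab-separated with header `gene_id`, `comparison`, `log2fc`, `pvalue`.
#'
#' @param path TSV file
#' @return validated data.frame
#' @export
readDETable <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "comparison", "log2fc", "pvalue")
  if (!all(need %in% colnames(df)))
    stopFormat("%s: need columns %s", path, paste(need, collapse = ", "))
  if (any(!is.finite(df$pvalue)) || any(df$pvalue < 0 | df$pvalue > 1))
    stopFormat("%s: p-values must lie in [0, 1]", path)
  if (anyDuplicated(df[, c("gene_id", "comparison")]))
    stopFormat("%s: duplicated (gene, comparison) row", path)
  df
}

#' Read a counts matrix with gene lengths
#'
#' Tab-separated with header: `gene_id`, `length`, then one column per
#' sample. Sample names of the form `strain_medium_time_replicate` are parsed
#' into `colData`.
#'
#' @param path TSV file
#' @return a `SummarizedExperiment` with a `counts` assay and `length` in
#'   `rowData`
#' @export
readCountsMatrix <- function(path) {
  if (!file.exists(path)) stopInput("no such file: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("gene_id", "length") %in% colnames(df)))
    stopFormat("%s: need 'gene_id' and 'length' columns", path)
  geneLen <- as.integer(df$length)
  if (any(!is.finite(geneLen)) || any(geneLen <= 0))
    stopFormat("%s: gene lengths must be positive", path)
  sampleCols <- setdiff(colnames(df), c("gene_id", "length"))
  if (!length(sampleCols)) stopFormat("%s: no sample columns", path)
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m < 0)) stopFormat("%s: counts must be non-negative integers", path)
  rownames(m) <- df$gene_id
  parts <- strsplit(sampleCols, "_", fixed = TRUE)
  cd <- if (all(vapply(parts, length, integer(1)) == 4L)) {
    p <- do.call(rbind, parts)
    S4Vectors::DataFrame(strain = p[, 1L], medium = p[, 2L], time = p[, 3L],
                         replicate = p[, 4L], row.names = sampleCols)
  } else S4Vectors::DataFrame(row.names = sampleCols)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(length = geneLen, row.names = df$gene_id),
    colData = cd)
}

#' Write a counts SummarizedExperiment back to TSV
#' @param se `SummarizedExperiment` with a `counts` assay and `length` rowData
#' @param path output TSV path
#' @return the path, invisibly
#' @export
writeCountsMatrix <- function(se, path) {
  df <- data.frame(gene_id = rownames(se),
                   length = SummarizedExperiment::rowData(se)$length,
                   SummarizedExperiment::assay(se, "counts"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, path)
}
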