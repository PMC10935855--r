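#' @include AllGenerics.R
NULL

#' PromoterSet: upstream promoter fragments with provenance
#'
#' A `DNAStringSet` whose element metadata records, for every fragment, the
#' gene and species it belongs to, the requested extraction length, whether
#' the fragment was truncated at a contig boundary, and whether another
#' annotated gene overlaps the promoter window. Sequences are written 5'->3'
#' on the gene's coding strand and end at the base immediately before the
#' start codon.
#'
#' @slot .Data inherited `DNAStringSet` payload
#' @seealso [extractPromoters()], [generateOrthologGroup()]
#' @export
setClass("PromoterSet", contains = "DNAStringSet")

setValidity("PromoterSet", function(object) {
  mc <- S4Vectors::mcols(object)
  need <- c("gene_id", "species_id", "requested_length", "truncated",
            "upstream_overlap")
  if (is.null(mc) || !all(need %in% colnames(mc)))
    return(sprintf("mcols must contain columns: %s",
                   paste(need, collapse = ", ")))
  if (length(object) == 0L) return(TRUE)
  if (anyNA(mc$gene_id) || anyNA(mc$species_id))
    return("gene_id and species_id must not contain NA")
  if (any(width(object) > mc$requested_length))
    return("actual length exceeds requested length")
  if (!identical(as.logical(mc$truncated),
                 width(object) < mc$requested_length))
    return("'truncated' must hold exactly when actual < requested length")
  if (anyDuplicated(paste(mc$species_id, mc$gene_id)))
    return("gene ids must be unique within species")
  bad <- grepl("[^ACGTN]", as.character(object))
  if (any(bad))
    return(sprintf("sequence %d contains characters outside ACGTN",
                   which(bad)[1L]))
  TRUE
})

#' Construct a PromoterSet
#'
#' @param sequences character vector or `DNAStringSet` of promoter fragments
#'   (uppercase ACGTN)
#' @param geneId,speciesId character vectors, one entry per fragment
#' @param requestedLength requested extraction length(s) in bp; fragments
#'   shorter than this are flagged truncated
#' @param upstreamOverlap logical: does another gene's span intersect the
#'   promoter window? (default FALSE)
#' @return a \linkS4class{PromoterSet}
#' @examples
#' ps <- PromoterSet("ACGTACGT", geneId = "g1", speciesId = "sp01",
#'                   requestedLength = 8)
#' geneIds(ps)
#' @export
PromoterSet <- function(sequences, geneId, speciesId,
                        requestedLength = NULL,
                        upstreamOverlap = FALSE) {
  seqs <- if (is(sequences, "DNAStringSet")) sequences else {
    if (!is.character(sequences)) stopInput("'sequences' must be character or DNAStringSet")
    Biostrings::DNAStringSet(toupper(sequences))
  }
  n <- length(seqs)
  if (length(geneId) != n || length(speciesId) != n)
    stopInput("geneId/speciesId must have one entry per sequence")
  if (is.null(requestedLength)) requestedLength <- width(seqs)
  requestedLength <- as.integer(rep_len(requestedLength, n))
  upstreamOverlap <- as.logical(rep_len(upstreamOverlap, n))
  names(seqs) <- geneId
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    gene_id = as.character(geneId),
    species_id = as.character(speciesId),
    requested_length = requestedLength,
    actual_length = width(seqs),
    truncated = width(seqs) < requestedLength,
    upstream_overlap = upstreamOverlap)
  new("PromoterSet", seqs)
}

#' @describeIn PromoterSet gene ids of the fragments
#' @param x a `PromoterSet`
#' @export
setMethod("geneIds", "PromoterSet", function(x) S4Vectors::mcols(x)$gene_id)

#' @describeIn PromoterSet species ids of the fragments
#' @export
setMethod("speciesIds", "PromoterSet",
          function(x) S4Vectors::mcols(x)$species_id)

#' Truncation flags of promoter fragments
#' @param x a \linkS4class{PromoterSet}
#' @return logical vector, TRUE where the fragment is shorter than requested
#' @export
isTruncated <- function(x) {
  stopifnot(is(x, "PromoterSet"))
  S4Vectors::mcols(x)$truncated
}

setMethod("show", "PromoterSet", function(object) {
  mc <- S4Vectors::mcols(object)
  cat(sprintf("PromoterSet with %d fragment(s) from %d species\n",
              length(object),
              length(unique(mc$species_id))))
  if (length(object)) {
    cat(sprintf("  requested length: %s bp; truncated: %d; upstream overlap: %d\n",
                paste(unique(mc$requested_length), collapse = "/"),
                sum(mc$truncated), sum(mc$upstream_overlap)))
  }
  invisible(NULL)
})

#' OrthologTable: focal genes mapped to their per-species orthologs
#'
#' Rows are focal genes; columns are clade species. Entries are per-species
#' ortholog gene ids (`NA` where no ortholog was identified). The focal
#' species' column holds the focal gene ids themselves.
#'
#' @slot focalSpecies the species whose genes index the rows
#' @slot map character matrix, rownames = focal gene ids, colnames = species
#' @export
setClass("OrthologTable",
         representation(focalSpecies = "character", map = "matrix"))

setValidity("OrthologTable", function(object) {
  m <- object@map
  if (!is.character(m)) return("map must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("map must have focal gene rownames and species colnames")
  if (anyDuplicated(rownames(m))) return("duplicated focal gene id")
  if (length(object@focalSpecies) != 1L ||
      !(object@focalSpecies %in% colnames(m)))
    return("focalSpecies must name one of the species columns")
  TRUE
})

#' Construct an OrthologTable
#' @param map character matrix of ortholog gene ids (rownames = focal genes,
#'   colnames = species, `NA` = no ortholog)
#' @param focalSpecies which column is the focal species
#' @return an \linkS4class{OrthologTable}
#' @export
OrthologTable <- function(map, focalSpecies) {
  new("OrthologTable", focalSpecies = focalSpecies, map = map)
}

#' @describeIn OrthologTable focal gene ids (row names)
#' @param x an `OrthologTable`
#' @export
focalGenes <- function(x) {
  stopifnot(is(x, "OrthologTable"))
  rownames(x@map)
}

#' @describeIn OrthologTable the clade species (column names)
#' @export
cladeSpecies <- function(x) {
  stopifnot(is(x, "OrthologTable"))
  colnames(x@map)
}

#' @describeIn OrthologTable the focal species id
#' @export
focalSpecies <- function(x) {
  stopifnot(is(x, "OrthologTable"))
  x@focalSpecies
}

#' @describeIn OrthologTable the ortholog id matrix
#' @export
orthologMap <- function(x) {
  stopifnot(is(x, "OrthologTable"))
  x@map
}

setMethod("show", "OrthologTable", function(object) {
  m <- object@map
  resolved <- rowSums(!is.na(m))
  cat(sprintf("OrthologTable: %d focal gene(s) x %d species (focal: %s)\n",
              nrow(m), ncol(m), object@focalSpecies))
  if (nrow(m))
    cat(sprintf("  resolved orthologs per gene: %d-%d (median %g)\n",
                min(resolved), max(resolved), stats::median(resolved)))
  invisible(NULL)
})

#' GeneSet: a direction-labelled set of regulated genes
#'
#' @slot comparison comparison identifier (e.g. medium + time point)
#' @slot direction `"up"` or `"down"`; "up" means higher expression in the
#'   strain carrying the functional regulator
#' @slot genes unique member gene ids
#' @seealso [selectRegulated()], [overlapSummary()]
#' @export
setClass("GeneSet",
         representation(comparison = "character", direction = "character",
                        genes = "character"))

setValidity("GeneSet", function(object) {
  if (length(object@direction) != 1L ||
      !(object@direction %in% c("up", "down")))
    return("direction must be \"up\" or \"down\"")
  if (anyDuplicated(object@genes)) return("member gene ids must be unique")
  TRUE
})

#' Construct a GeneSet
#' @param comparison comparison identifier
#' @param direction `"up"` or `"down"`
#' @param genes member gene ids (deduplicated, order preserved)
#' @return a \linkS4class{GeneSet}
#' @export
GeneSet <- function(comparison, direction, genes) {
  new("GeneSet", comparison = as.character(comparison),
      direction = direction, genes = unique(as.character(genes)))
}

#' @describeIn GeneSet member gene ids
#' @param x a `GeneSet`
#' @export
setMethod("geneIds", "GeneSet", function(x) x@genes)

#' Comparison identifier of a GeneSet
#' @param x a \linkS4class{GeneSet}
#' @export
comparisonId <- function(x) {
  stopifnot(is(x, "GeneSet"))
  x@comparison
}

#' Direction of a GeneSet
#' @param x a \linkS4class{GeneSet}
#' @export
setDirection <- function(x) {
  stopifnot(is(x, "GeneSet"))
  x@direction
}

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%s): %d gene(s)\n",
              paste(object@comparison, collapse = "+"), object@direction,
              length(object@genes)))
  invisible(NULL)
})

#' Union of gene sets sharing a direction
#' @param sets list of \linkS4class{GeneSet} objects with the same direction
#' @return a \linkS4class{GeneSet} whose comparison id joins the inputs
#' @export
geneSetUnion <- function(sets) {
  if (!length(sets)) stopInput("empty list of gene sets")
  dirs <- unique(vapply(sets, setDirection, character(1)))
  if (length(dirs) != 1L) stopInput("cannot union gene sets of mixed direction")
  GeneSet(paste(vapply(sets, function(s) paste(s@comparison, collapse = "+"),
                       character(1)), collapse = "+"),
          dirs, unlist(lapply(sets, geneIds)))
}
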