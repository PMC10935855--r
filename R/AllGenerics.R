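#' Gene identifiers of an object
#' @param x an object carrying gene identifiers
#' @param ... further arguments for methods
#' @return character vector of gene ids
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' Species identifiers of an object
#' @param x an object carrying species identifiers
#' @param ... further arguments for methods
#' @return character vector of species ids
#' @export
setGeneric("speciesIds", function(x, ...) standardGeneric("speciesIds"))

#' Compute transcripts-per-million from raw counts
#'
#' Per sample, each gene's count is divided by its length in kilobases to give
#' a rate, and rates are rescaled so the sample sums to one million.
#'
#' @param object a counts matrix (genes x samples) or a
#'   \linkS4class{SummarizedExperiment} with a `counts` assay and a `length`
#'   column in `rowData`
#' @param ... further arguments for methods
#' @return for the matrix method, a TPM matrix (attribute `unit = "TPM"`);
#'   for the SummarizedExperiment method, the object with a `TPM` assay added
#' @export
setGeneric("computeTPM", function(object, ...) standardGeneric("computeTPM"))

#' Compute fragments-per-kilobase-per-million from raw counts
#'
#' `FPKM = count * 1e9 / (length_bp * library_size)`.
#'
#' @inheritParams computeTPM
#' @param ... further arguments for methods
#' @return for the matrix method, an FPKM matrix (attribute `unit = "FPKM"`);
#'   for the SummarizedExperiment method, the object with an `FPKM` assay added
#' @export
setGeneric("computeFPKM", function(object, ...) standardGeneric("computeFPKM"))

#' Scan sequences for a short motif on one or both strands
#'
#' Every window matching the IUPAC pattern yields a hit; with
#' `bothStrands = TRUE`, windows matching the reverse complement yield
#' strand `-` hits at the same anchored offsets. Offsets use the
#' start-codon-anchored convention: the base immediately 5' of the start codon
#' is offset -1, so a k-mer hit flush against the start codon has offset -k.
#' `N` in a sequence matches nothing. Overlapping hits are all reported.
#' Palindromic patterns (equal to their reverse complement) report each window
#' once, on the plus strand.
#'
#' @param x sequences to scan: a single character string, a named
#'   `DNAStringSet`, or a \linkS4class{PromoterSet}
#' @param motif IUPAC pattern (plain ACGT allowed), length >= 1
#' @param ... further arguments for methods
#' @return a data.frame with columns `gene_id`, `species_id`, `motif`,
#'   `offset`, `strand`, `match`, sorted by gene then offset
#' @export
setGeneric("scanMotif", function(x, motif, ...) standardGeneric("scanMotif"))
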