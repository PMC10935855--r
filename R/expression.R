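#' @include AllGenerics.R AllClasses.R
NULL

# Expression-side operations: within-sample normalization, threshold
# selection of regulated gene sets, cross-condition overlap accounting, and
# row normalization for heatmap matrices.

.checkCountsArgs <- function(counts, lengths) {
  if (!is.matrix(counts)) stopInput("'object' must be a genes x samples matrix")
  if (length(lengths) != nrow(counts))
    stopInput("length of 'lengths' (%d) does not match rows of counts (%d)",
              length(lengths), nrow(counts))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stopInput("gene lengths must be positive")
}

#' @describeIn computeTPM matrix method; `lengths` are gene lengths in bp
#' @param lengths per-gene effective lengths in bp
#' @export
setMethod("computeTPM", "matrix", function(object, lengths) {
  .checkCountsArgs(object, lengths)
  rate <- object / (lengths / 1000)
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero sample(s); TPM column set to zero", sum(zero)))
    tot[zero] <- 1
  }
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  attr(tpm, "unit") <- "TPM"
  tpm
})

#' @describeIn computeTPM SummarizedExperiment method; uses the `counts`
#'   assay and the `length` column of `rowData`, adds a `TPM` assay
#' @export
setMethod("computeTPM", "SummarizedExperiment", function(object) {
  tpm <- computeTPM(SummarizedExperiment::assay(object, "counts"),
                    SummarizedExperiment::rowData(object)$length)
  SummarizedExperiment::assays(object)$TPM <- tpm
  object
})

#' @describeIn computeFPKM matrix method
#' @param lengths per-gene effective lengths in bp
#' @param allowZeroLibraries all-zero samples are an error unless this flag
#'   is set, in which case their FPKM column is zero
#' @export
setMethod("computeFPKM", "matrix",
          function(object, lengths, allowZeroLibraries = FALSE) {
  .checkCountsArgs(object, lengths)
  lib <- colSums(object)
  zero <- lib == 0
  if (any(zero)) {
    if (!allowZeroLibraries)
      stopInput("sample %s has zero total counts (FPKM undefined)",
                colnames(object)[which(zero)[1L]] %||% which(zero)[1L])
    lib[zero] <- 1
  }
  fpkm <- sweep(object * 1e9 / lengths, 2L, lib, "/")
  attr(fpkm, "unit") <- "FPKM"
  fpkm
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn computeFPKM SummarizedExperiment method; adds an `FPKM` assay
#' @export
setMethod("computeFPKM", "SummarizedExperiment",
          function(object, allowZeroLibraries = FALSE) {
  fpkm <- computeFPKM(SummarizedExperiment::assay(object, "counts"),
                      SummarizedExperiment::rowData(object)$length,
                      allowZeroLibraries = allowZeroLibraries)
  SummarizedExperiment::assays(object)$FPKM <- fpkm
  object
})

#' Select regulated genes with inclusive thresholds
#'
#' Up-regulated: `pvalue <= pMax` and `log2fc >= lfcMin`.
#' Down-regulated: `pvalue <= pMax` and `log2fc <= -lfcMin`.
#' Boundary values are included, matching the printed `<=` / `>=` cutoffs.
#'
#' @param de data.frame with columns `gene_id`, `comparison`, `log2fc`,
#'   `pvalue` (see [readDETable()])
#' @param comparison which comparison to select from (must exist in `de`)
#' @param direction `"up"` or `"down"`
#' @param pMax p-value cutoff (default 0.01)
#' @param lfcMin log2-fold-change magnitude cutoff (default 1.5)
#' @return a \linkS4class{GeneSet}
#' @export
selectRegulated <- function(de, comparison, direction = c("up", "down"),
                            pMax = 0.01, lfcMin = 1.5) {
  direction <- match.arg(direction)
  if (!.isScalarNumber(pMax) || pMax <= 0 || !.isScalarNumber(lfcMin) ||
      lfcMin <= 0)
    stopInput("thresholds must be positive")
  if (!(comparison %in% de$comparison))
    stopInput("unknown comparison id '%s'", comparison)
  rows <- de[de$comparison == comparison, , drop = FALSE]
  keep <- rows$pvalue <= pMax &
    (if (direction == "up") rows$log2fc >= lfcMin else rows$log2fc <= -lfcMin)
  GeneSet(comparison, direction, rows$gene_id[keep])
}

#' Cross-condition overlap counts of gene sets
#'
#' For every combination of comparisons, reports both the exclusive (disjoint
#' Venn-region) count and the plain intersection count. The per-set totals
#' equal the sum of the disjoint regions containing that set.
#'
#' @param sets list of at least two \linkS4class{GeneSet} objects sharing a
#'   direction
#' @return data.frame with one logical membership column per comparison plus
#'   `region_count` (genes exactly in that combination) and
#'   `intersection_count` (genes in at least that combination); the per-set
#'   totals are attached as attribute `totals`
#' @export
overlapSummary <- function(sets) {
  if (length(sets) < 2L) stopInput("need at least two gene sets")
  if (!all(vapply(sets, is, logical(1), "GeneSet")))
    stopInput("'sets' must be a list of GeneSet objects")
  dirs <- unique(vapply(sets, setDirection, character(1)))
  if (length(dirs) != 1L) stopInput("gene sets have mixed directions")
  comps <- vapply(sets, comparisonId, character(1))
  if (anyDuplicated(comps)) stopInput("duplicated comparison ids")
  genes <- unique(unlist(lapply(sets, geneIds)))
  membership <- vapply(sets, function(s) genes %in% geneIds(s),
                       logical(length(genes)))
  if (length(genes) == 1L) membership <- matrix(membership, nrow = 1L)
  m <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1L, , drop = FALSE]
  colnames(combos) <- comps
  region <- integer(nrow(combos)); inter <- integer(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    pat <- as.logical(combos[i, ])
    region[i] <- sum(apply(membership, 1L, function(r) all(r == pat)))
    inter[i] <- sum(apply(membership[, pat, drop = FALSE], 1L, all))
  }
  out <- data.frame(combos, region_count = region,
                    intersection_count = inter, check.names = FALSE)
  attr(out, "totals") <- stats::setNames(
    vapply(sets, function(s) length(geneIds(s)), integer(1)), comps)
  attr(out, "direction") <- dirs
  out
}

#' Row-normalize a matrix for heatmap display
#'
#' `zscore` centers and scales each row with the population SD (divisor `n`);
#' constant rows become all zeros with a warning. `minmax` rescales each row
#' to \[0, 1\].
#'
#' @param x numeric matrix
#' @param method `"zscore"` or `"minmax"`
#' @return matrix of the same shape (attribute `unit = "row-normalized"`)
#' @export
rowNormalize <- function(x, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  if (!is.matrix(x) || !length(x)) stopInput("'x' must be a non-empty matrix")
  out <- x
  nConst <- 0L
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    if (method == "zscore") {
      s <- sqrt(mean((r - mean(r))^2))
      if (s == 0) { out[i, ] <- 0; nConst <- nConst + 1L }
      else out[i, ] <- (r - mean(r)) / s
    } else {
      rng <- range(r)
      if (diff(rng) == 0) { out[i, ] <- 0; nConst <- nConst + 1L }
      else out[i, ] <- (r - rng[1L]) / diff(rng)
    }
  }
  if (nConst) warning(sprintf("%d constant row(s) set to zero", nConst))
  attr(out, "unit") <- "row-normalized"
  out
}
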