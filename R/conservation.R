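# Clade-conservation criterion: a motif is conserved for a gene when it is
# present in at least `presenceThreshold` of the collected ortholog promoters
# at a similar position to the start codon (within `positionWindow` bp of the
# focal reference hit).

# Core classifier working on per-species offset lists; shared by
# classifyConservation and the k-mer discovery fast path.
.conservationCore <- function(offsets, focalIdx, presenceThreshold,
                              positionWindow, minOrthologs) {
  nCollected <- length(offsets)
  hasHit <- vapply(offsets, function(o) length(o) > 0L, logical(1))
  nAnywhere <- sum(hasHit)
  focalOff <- offsets[[focalIdx]]
  groupEvaluable <- nCollected >= minOrthologs
  if (length(focalOff)) {
    ref <- max(focalOff)  # focal hit nearest the start codon (least |offset|)
    nIn <- sum(vapply(offsets, function(o)
      length(o) > 0L && any(abs(o - ref) <= positionWindow), logical(1)))
  } else {
    ref <- NA_integer_
    nIn <- 0L
  }
  presence <- if (nCollected > 0L) nIn / nCollected else 0
  evaluable <- groupEvaluable && length(focalOff) > 0L
  list(n_orthologs_collected = nCollected,
       n_with_hit_anywhere = nAnywhere,
       n_with_hit_in_window = nIn,
       presence_fraction = presence,
       reference_offset = as.integer(ref),
       conserved = evaluable && presence >= presenceThreshold - 1e-9,
       majority = nAnywhere > nCollected / 2,
       evaluable = evaluable,
       group_evaluable = groupEvaluable)
}

#' Classify clade conservation of a motif for one ortholog group
#'
#' The reference offset is the focal-species hit closest to the start codon
#' (largest signed offset). An ortholog "agrees" when it has at least one hit
#' on either strand within `positionWindow` bp of the reference. The call is
#' `conserved` when the group is evaluable (at least `minOrthologs` collected
#' promoters and a focal hit) and the agreeing fraction reaches
#' `presenceThreshold` (inclusive). `majority` requires a hit anywhere in
#' strictly more than half of the collected promoters, with no positional
#' constraint, and is computed even when the focal promoter lacks the motif.
#'
#' @param group a \linkS4class{PromoterSet} with one promoter per species
#'   (see [orthologGroups()])
#' @param motif IUPAC pattern
#' @param focalSpecies species id of the focal promoter (must be present)
#' @param presenceThreshold minimal agreeing fraction, inclusive
#'   (default 0.75)
#' @param positionWindow positional-agreement half-width in bp (default 200)
#' @param minOrthologs minimal number of collected promoters for the group to
#'   be evaluable (default 8)
#' @return one-row data.frame: `gene_id`, `motif`, `n_orthologs_collected`,
#'   `n_with_hit_anywhere`, `n_with_hit_in_window`, `presence_fraction`,
#'   `reference_offset`, `conserved`, `majority`, `evaluable`,
#'   `group_evaluable`
#' @export
classifyConservation <- function(group, motif, focalSpecies,
                                 presenceThreshold = 0.75,
                                 positionWindow = 200L, minOrthologs = 8L) {
  stopifnot(is(group, "PromoterSet"))
  motif <- .checkMotif(motif)
  if (!.isScalarNumber(presenceThreshold) || presenceThreshold < 0 ||
      presenceThreshold > 1)
    stopInput("presenceThreshold must be in [0, 1]")
  sp <- speciesIds(group)
  if (anyDuplicated(sp)) stopInput("group has more than one promoter per species")
  focalIdx <- match(focalSpecies, sp)
  if (is.na(focalIdx)) stopInput("group is missing a focal ('%s') promoter",
                                 focalSpecies)
  hits <- scanMotif(group, motif, bothStrands = TRUE)
  offsets <- lapply(sp, function(s) hits$offset[hits$species_id == s])
  core <- .conservationCore(offsets, focalIdx, presenceThreshold,
                            positionWindow, minOrthologs)
  data.frame(gene_id = geneIds(group)[focalIdx], motif = motif,
             core[c("n_orthologs_collected", "n_with_hit_anywhere",
                    "n_with_hit_in_window", "presence_fraction",
                    "reference_offset", "conserved", "majority", "evaluable",
                    "group_evaluable")],
             stringsAsFactors = FALSE)
}

#' Table-style summary of motif presence and conservation
#'
#' Mirrors a three-column presence/conservation/majority summary over a
#' regulated gene set. Column 1 counts regulated genes whose focal promoter
#' carries at least one hit; its denominator is the number of regulated genes
#' with a focal promoter. Columns 2 and 3 count conserved and
#' majority-positive genes over the genes with evaluable ortholog groups (at
#' least `minOrthologs` collected promoters) — a separate, smaller
#' denominator. Percentages are rounded half-up to integers.
#'
#' @param regulated a \linkS4class{GeneSet} or character vector of gene ids
#' @param focalPromoters \linkS4class{PromoterSet} of focal-species promoters
#' @param groups named list of ortholog groups (see [orthologGroups()])
#' @param motifs character vector of IUPAC patterns (non-empty)
#' @param focalSpecies focal species id
#' @param presenceThreshold,positionWindow,minOrthologs passed to
#'   [classifyConservation()]
#' @param calls optional precomputed per-gene call table (from
#'   [conservationCalls()]) to avoid re-scanning
#' @return data.frame with one row per motif: counts, denominators and
#'   percentages. Regulated genes lacking a focal promoter are recorded in
#'   attribute `missing_promoter`; the per-gene calls in attribute `calls`.
#' @export
summarizeMotifs <- function(regulated, focalPromoters, groups, motifs,
                            focalSpecies, presenceThreshold = 0.75,
                            positionWindow = 200L, minOrthologs = 8L,
                            calls = NULL) {
  if (!length(motifs)) stopInput("empty motif list")
  genes <- if (is(regulated, "GeneSet")) geneIds(regulated)
           else as.character(regulated)
  stopifnot(is(focalPromoters, "PromoterSet"))
  focal <- focalPromoters[speciesIds(focalPromoters) == focalSpecies]
  withProm <- genes[genes %in% geneIds(focal)]
  missing <- setdiff(genes, withProm)
  if (is.null(calls))
    calls <- conservationCalls(withProm, groups, motifs, focalSpecies,
                               presenceThreshold, positionWindow,
                               minOrthologs)
  evalGenes <- unique(calls$gene_id[calls$group_evaluable])
  focalSub <- focal[match(withProm, geneIds(focal))]
  rows <- lapply(motifs, function(m) {
    mc <- calls[calls$motif == toupper(m), , drop = FALSE]
    focalHits <- scanMotif(focalSub, m)
    presentFocal <- withProm %in% focalHits$gene_id
    ev <- mc[mc$gene_id %in% evalGenes, , drop = FALSE]
    nCons <- sum(ev$conserved)
    nMaj <- sum(ev$majority)
    data.frame(motif = toupper(m),
               n_present_focal = sum(presentFocal),
               den_focal = length(withProm),
               pct_present_focal = .pctHalfUp(sum(presentFocal),
                                              length(withProm)),
               n_conserved = nCons,
               n_majority = nMaj,
               den_evaluable = length(evalGenes),
               pct_conserved = .pctHalfUp(nCons, length(evalGenes)),
               pct_majority = .pctHalfUp(nMaj, length(evalGenes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "missing_promoter") <- missing
  attr(out, "calls") <- calls
  attr(out, "params") <- list(presence_threshold = presenceThreshold,
                              position_window = positionWindow,
                              min_orthologs = minOrthologs)
  out
}

#' Per-gene conservation calls for a set of motifs
#'
#' Runs [classifyConservation()] for every (gene, motif) pair. Genes without
#' an ortholog group get a non-evaluable row with zero collected promoters.
#'
#' @param genes character vector (or focal \linkS4class{PromoterSet}) of
#'   genes to call
#' @param groups named list of ortholog groups
#' @param motifs character vector of patterns
#' @param focalSpecies focal species id
#' @param presenceThreshold,positionWindow,minOrthologs see
#'   [classifyConservation()]
#' @return data.frame, one row per gene x motif
#' @export
conservationCalls <- function(genes, groups, motifs, focalSpecies,
                              presenceThreshold = 0.75,
                              positionWindow = 200L, minOrthologs = 8L) {
  ids <- if (is(genes, "PromoterSet")) geneIds(genes) else as.character(genes)
  grps <- groups[ids]
  # scan the union of group promoters once per motif, then classify each
  # group from the shared offset map (equivalent to per-group scanning)
  haveGrp <- !vapply(grps, is.null, logical(1))
  allChr <- unlist(lapply(grps[haveGrp], as.character), use.names = FALSE)
  allGene <- unlist(lapply(grps[haveGrp], geneIds), use.names = FALSE)
  allSp <- unlist(lapply(grps[haveGrp], speciesIds), use.names = FALSE)
  key <- paste(allSp, allGene)
  first <- !duplicated(key)
  comb <- if (any(first))
    PromoterSet(allChr[first], allGene[first], allSp[first])
  else NULL
  rows <- lapply(motifs, function(m) {
    m <- .checkMotif(m)
    offsetsByKey <- if (is.null(comb)) list()
      else {
        hits <- scanMotif(comb, m, bothStrands = TRUE)
        split(hits$offset, paste(hits$species_id, hits$gene_id))
      }
    do.call(rbind, lapply(ids, function(g) {
      grp <- grps[[g]]
      if (is.null(grp) || !(focalSpecies %in% speciesIds(grp))) {
        return(data.frame(
          gene_id = g, motif = m,
          n_orthologs_collected = if (is.null(grp)) 0L else length(grp),
          n_with_hit_anywhere = 0L, n_with_hit_in_window = 0L,
          presence_fraction = 0, reference_offset = NA_integer_,
          conserved = FALSE, majority = FALSE, evaluable = FALSE,
          group_evaluable = FALSE, stringsAsFactors = FALSE))
      }
      sp <- speciesIds(grp)
      gkeys <- paste(sp, geneIds(grp))
      offsets <- lapply(gkeys, function(kk) offsetsByKey[[kk]] %||% integer(0))
      core <- .conservationCore(offsets, match(focalSpecies, sp),
                                presenceThreshold, positionWindow,
                                minOrthologs)
      data.frame(gene_id = g, motif = m,
                 core[c("n_orthologs_collected", "n_with_hit_anywhere",
                        "n_with_hit_in_window", "presence_fraction",
                        "reference_offset", "conserved", "majority",
                        "evaluable", "group_evaluable")],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  # one block per gene (all motifs), preserving input gene order
  out[order(match(out$gene_id, ids)), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}
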