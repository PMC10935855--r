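# Conserved k-mer discovery seeded from a gene cluster: enumerate canonical
# k-mers occurring in the focal promoters, test each against every cluster
# gene's ortholog group with the clade-conservation criterion, and rank.

# Per-sequence map: canonical k-mer -> start-codon-anchored offsets of every
# window matching it on either strand. Windows containing N are skipped.
# Both orientations come for free: the reverse complement of window j of the
# sequence is window (n - j + 1) of the reverse-complemented sequence.
.kmerOffsetMap <- function(seqChar, k) {
  L <- nchar(seqChar)
  if (L < k) return(list())
  n <- L - k + 1L
  w <- substring(seqChar, seq_len(n), seq_len(n) + k - 1L)
  wrc <- rev(substring(.revcompChr(seqChar), seq_len(n), seq_len(n) + k - 1L))
  canon <- ifelse(w <= wrc, w, wrc)
  keep <- !grepl("N", w, fixed = TRUE)
  split(seq_len(n)[keep] - 1L - L, canon[keep])
}

#' Discover conserved k-mers from a cluster of ortholog groups
#'
#' Enumerates every k-mer (for `k` in `[kmin, kmax]`) occurring in the focal
#' promoters of the cluster, folds each with its reverse complement into one
#' canonical key, classifies its conservation against every cluster gene's
#' ortholog group, and returns the candidates conserved in at least
#' `minClusterFraction` of the cluster genes, ranked by conservation score,
#' then fewer total occurrences across the cluster promoters (background
#' occurrences), then lexicographically.
#'
#' @param groups named list of ortholog groups (names are focal gene ids);
#'   at least two
#' @param focalSpecies focal species id
#' @param kmin,kmax k-mer length range, `3 <= kmin <= kmax <= 12`
#' @param minClusterFraction minimal fraction of cluster genes for which a
#'   candidate must be conserved (default 0.8)
#' @param presenceThreshold,positionWindow,minOrthologs conservation
#'   parameters (see [classifyConservation()])
#' @return data.frame ranked best-first with columns `kmer`, `k`, `score`
#'   (fraction of cluster genes conserved), `n_conserved`, `n_groups`,
#'   `background_occurrences`, and one logical `conserved_<gene>` column per
#'   cluster gene
#' @export
discoverConservedKmers <- function(groups, focalSpecies, kmin = 5L,
                                   kmax = 6L, minClusterFraction = 0.8,
                                   presenceThreshold = 0.75,
                                   positionWindow = 200L,
                                   minOrthologs = 8L) {
  if (!length(groups)) stopInput("empty cluster")
  if (length(groups) < 2L) stopInput("need at least two cluster genes")
  if (!.isCount(kmin) || !.isCount(kmax) || kmin < 3 || kmax > 12 ||
      kmin > kmax)
    stopInput("require 3 <= kmin <= kmax <= 12")
  geneNames <- names(groups) %||% as.character(seq_along(groups))
  # per group: species ids, focal index, per-species sequence strings
  prep <- lapply(groups, function(g) {
    stopifnot(is(g, "PromoterSet"))
    sp <- speciesIds(g)
    fi <- match(focalSpecies, sp)
    if (is.na(fi)) stopInput("a cluster group lacks a focal promoter")
    list(sp = sp, focalIdx = fi, chars = as.character(g))
  })
  allRows <- list()
  for (k in seq(kmin, kmax)) {
    maps <- lapply(prep, function(p) lapply(p$chars, .kmerOffsetMap, k = k))
    focalKeys <- lapply(seq_along(prep), function(gi)
      names(maps[[gi]][[prep[[gi]]$focalIdx]]))
    # a candidate conserved for a gene needs a focal hit there, so it must
    # occur in the focal promoters of at least ceil(fraction * n) groups
    minGroups <- ceiling(minClusterFraction * length(groups) - 1e-9)
    occ <- table(unlist(lapply(focalKeys, unique), use.names = FALSE))
    candidates <- sort(names(occ)[occ >= minGroups])
    if (!length(candidates)) next
    nc <- length(candidates)
    consMat <- matrix(FALSE, nc, length(groups),
                      dimnames = list(candidates, geneNames))
    bgOcc <- stats::setNames(numeric(nc), candidates)
    for (gi in seq_along(groups)) {
      gm <- maps[[gi]]
      fi <- prep[[gi]]$focalIdx
      nCollected <- length(gm)
      groupEvaluable <- nCollected >= minOrthologs
      # candidate x species index into each per-species offset map
      idx <- vapply(gm, function(m) match(candidates, names(m)), integer(nc))
      if (nc == 1L) idx <- matrix(idx, nrow = 1L)
      lens <- vapply(seq_along(gm), function(s) {
        ll <- lengths(gm[[s]])[idx[, s]]
        ll[is.na(ll)] <- 0L
        ll
      }, integer(nc))
      if (nc == 1L) lens <- matrix(lens, nrow = 1L)
      bgOcc <- bgOcc + rowSums(lens)
      for (ci in seq_len(nc)) {
        fIdx <- idx[ci, fi]
        if (is.na(fIdx) || !groupEvaluable) next
        ref <- max(gm[[fi]][[fIdx]])
        nIn <- 0L
        for (s in seq_along(gm)) {
          j <- idx[ci, s]
          if (!is.na(j) &&
              any(abs(gm[[s]][[j]] - ref) <= positionWindow))
            nIn <- nIn + 1L
        }
        consMat[ci, gi] <- nIn / nCollected >= presenceThreshold - 1e-9
      }
    }
    score <- rowMeans(consMat)
    keep <- score >= minClusterFraction - 1e-9
    if (!any(keep)) next
    df <- data.frame(kmer = candidates[keep], k = k,
                     score = unname(score[keep]),
                     n_conserved = unname(rowSums(consMat)[keep]),
                     n_groups = length(groups),
                     background_occurrences = unname(bgOcc[keep]),
                     stringsAsFactors = FALSE)
    cm <- consMat[keep, , drop = FALSE]
    colnames(cm) <- paste0("conserved_", geneNames)
    allRows[[length(allRows) + 1L]] <- cbind(df, as.data.frame(cm))
  }
  if (!length(allRows)) {
    out <- data.frame(kmer = character(0), k = integer(0), score = numeric(0),
                      n_conserved = integer(0), n_groups = integer(0),
                      background_occurrences = numeric(0),
                      stringsAsFactors = FALSE)
    for (g in geneNames) out[[paste0("conserved_", g)]] <- logical(0)
    return(out)
  }
  out <- do.call(rbind, allRows)
  out <- out[order(-out$score, out$background_occurrences, out$kmer), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
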