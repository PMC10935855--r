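# One-command synthetic demonstration: a 12-species clade with a 5-gene
# seed cluster, a 150-gene regulated set, planted motifs, genomes, ortholog
# table, DE table, counts, and a ready-to-run configuration.

#' Build a complete synthetic demonstration fixture
#'
#' Generates, under `dir`: per-species genome FASTA + GFF3 files whose
#' promoters are known exactly, an ortholog table (most genes resolved in
#' 11-12 species, emulating the collected-ortholog funnel), a
#' differential-expression table over four comparisons (two media x two time
#' points), a counts matrix, and `config.yaml` wired for [runPipeline()].
#' Three motifs are planted in the regulated genes' promoters: `ATGCA` for
#' all regulated genes, plus `CGGAT` and `CGGCTT` for the five cluster genes
#' that seed motif discovery.
#'
#' @param dir output directory (created if needed, must be writable)
#' @param seed integer seed; the fixture is byte-identical for a fixed seed
#' @param nRegulated number of regulated genes (default 150; the first five
#'   form the cluster)
#' @param nBackground additional unregulated genes (default 25)
#' @param nSpecies clade size (default 12)
#' @param orthologProb probability that a non-focal species has an ortholog
#' @param presenceProb probability that an ortholog promoter carries a
#'   planted motif
#' @param gc background GC fraction
#' @param promoterLength promoter fragment length in bp
#' @return invisibly, a list with `config` (path to `config.yaml`), `truth`
#'   (planting truth data.frame) and `regulated` (true regulated gene ids)
#' @export
makeDemo <- function(dir, seed = 1L, nRegulated = 150L, nBackground = 25L,
                     nSpecies = 12L, orthologProb = 0.92,
                     presenceProb = 0.85, gc = 0.30,
                     promoterLength = 1000L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stopInput("directory '%s' is not writable", dir)
  if (nRegulated < 5L) stopInput("need at least the 5 cluster genes")
  species <- sprintf("sp%02d", seq_len(nSpecies))
  focal <- species[1L]
  nGenes <- nRegulated + nBackground
  gids <- sprintf("g%03d", seq_len(nGenes))
  cluster <- gids[1:5]
  regulatedIds <- gids[seq_len(nRegulated)]
  plantings <- list(list(motif = "ATGCA", anchor = -150L, genes = regulatedIds),
                    list(motif = "CGGAT", anchor = -230L, genes = cluster),
                    list(motif = "CGGCTT", anchor = -90L, genes = cluster))
  .withSeed(seed, {
    # ortholog presence: focal always; cluster genes in all species
    present <- matrix(TRUE, nGenes, nSpecies,
                      dimnames = list(gids, species))
    present[-(1:5), -1L] <-
      matrix(runif((nGenes - 5L) * (nSpecies - 1L)) < orthologProb,
             nGenes - 5L, nSpecies - 1L)
    map <- matrix(NA_character_, nGenes, nSpecies,
                  dimnames = list(gids, species))
    map[, 1L] <- gids
    for (j in 2:nSpecies)
      map[present[, j], j] <- paste0(gids[present[, j]], "_", species[j])

    # promoters: background plus planted motifs with jitter
    truth <- list()
    promo <- matrix(NA_character_, nGenes, nSpecies,
                    dimnames = list(gids, species))
    for (i in seq_len(nGenes)) {
      for (j in seq_len(nSpecies)) {
        if (!present[i, j]) next
        s <- .randomSeqs(1L, promoterLength, gc)
        for (pl in plantings) {
          if (!(gids[i] %in% pl$genes)) next
          carry <- if (j == 1L) TRUE else runif(1) < presenceProb
          if (!carry) next
          off <- as.integer(round(pl$anchor + rnorm(1, 0, 30)))
          off <- max(-promoterLength, min(-nchar(pl$motif), off))
          s <- plantMotif(s, pl$motif, off)
          truth[[length(truth) + 1L]] <-
            data.frame(gene_id = gids[i], species_id = species[j],
                       motif = pl$motif, offset = off,
                       stringsAsFactors = FALSE)
        }
        promo[i, j] <- s
      }
    }

    # genomes: one contig per species, random strands
    genomes <- character(nSpecies); gffs <- character(nSpecies)
    names(genomes) <- species; names(gffs) <- species
    for (j in seq_len(nSpecies)) {
      idx <- which(present[, j])
      layout <- data.frame(gene_id = map[idx, j],
                           strand = sample(c("+", "-"), length(idx),
                                           replace = TRUE),
                           promoter = promo[idx, j],
                           stringsAsFactors = FALSE)
      fx <- writeFixtureGenome(layout,
                               file.path(dir, paste0("genome_", species[j])),
                               speciesId = species[j], gc = gc,
                               seed = NULL)
      genomes[j] <- fx$fasta; gffs[j] <- fx$gff3
    }

    orthoPath <- file.path(dir, "orthologs.tsv")
    writeOrthologTable(OrthologTable(map, focal), orthoPath)

    # DE tables: strong regulation at 33 h, weak early response at 24 h
    comparisons <- list(
      ERY_24h = gids[intersect(6:30, seq_len(nGenes))],
      GLU_24h = gids[intersect(6:17, seq_len(nGenes))],
      ERY_33h = regulatedIds,
      GLU_33h = gids[seq_len(min(100L, nRegulated))])
    de <- do.call(rbind, lapply(names(comparisons), function(cmp) {
      reg <- comparisons[[cmp]]
      generateDETable(nGenes, length(reg), pAltShape = 0.02,
                      lfcAltMean = 3, comparison = cmp,
                      regulated = reg, direction = "up",
                      geneIds = gids)$table
    }))
    dePath <- file.path(dir, "de_table.tsv")
    .writeTsv(de, dePath)

    samples <- expand.grid(strain = c("MK1", "K1"), medium = c("ERY", "GLU"),
                           time = c("24h", "33h"), replicate = c("r1", "r2"),
                           stringsAsFactors = FALSE)
    samples$sample <- with(samples, paste(strain, medium, time, replicate,
                                          sep = "_"))
    counts <- generateCountsMatrix(gids, samples, seed = NULL)
    countsPath <- file.path(dir, "counts.tsv")
    writeCountsMatrix(counts, countsPath)

    cfg <- list(
      species = as.list(species), focal_species = focal,
      genomes = as.list(stats::setNames(basename(genomes), species)),
      annotations = as.list(stats::setNames(basename(gffs), species)),
      ortholog_table = basename(orthoPath), de_table = basename(dePath),
      counts = basename(countsPath),
      comparisons = list("ERY_33h", "GLU_33h"), direction = "up",
      p_max = 0.01, lfc_min = 1.5, promoter_length = promoterLength,
      motifs = list("ATGCA", "CGGAT", "CGGCTT"),
      discovery = list(cluster_genes = as.list(cluster), kmin = 5L,
                       kmax = 6L, min_cluster_fraction = 0.8),
      presence_threshold = 0.75, position_window = 200L, min_orthologs = 8L,
      seed = as.integer(seed), out_dir = "results")
    cfgPath <- file.path(dir, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    invisible(list(config = cfgPath,
                   truth = if (length(truth)) do.call(rbind, truth)
                           else data.frame(),
                   regulated = regulatedIds))
  })
}
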