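# End-to-end orchestration: configuration validation, staged execution with
# persisted intermediates, and a run manifest echoing every parameter.

.configDefaults <- list(
  promoter_length = 1000L, p_max = 0.01, lfc_min = 1.5, direction = "up",
  presence_threshold = 0.75, position_window = 200L, min_orthologs = 8L,
  seed = 1L)

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file with input paths (`genomes`,
#' `annotations` — per-species maps — `ortholog_table`, `de_table`, optional
#' `counts`), the species list and `focal_species`, the comparisons to
#' select, the motifs to score (and/or a `discovery` block with
#' `cluster_genes`, `kmin`, `kmax`, `min_cluster_fraction`), the conservation
#' parameters, `seed` and `out_dir`. Missing parameters take the documented
#' defaults; missing files raise a configuration error before any stage runs.
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return validated config list (class `"cladeMotifsConfig"`)
#' @export
readRunConfig <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stopConfig("no such config file: %s", config)
    base <- dirname(normalizePath(config))
    x <- yaml::read_yaml(config)
    x$.base <- base
    x
  } else if (is.list(config)) config
  else stopConfig("'config' must be a path or a list")
  for (nm in names(.configDefaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- .configDefaults[[nm]]
  resolve <- function(p) {
    if (is.null(cfg$.base) || grepl("^/", p)) p else file.path(cfg$.base, p)
  }
  need <- c("species", "focal_species", "genomes", "annotations",
            "ortholog_table", "de_table", "comparisons", "out_dir")
  miss <- need[vapply(need, function(n) is.null(cfg[[n]]), logical(1))]
  if (length(miss))
    stopConfig("config lacks required field(s): %s", paste(miss, collapse = ", "))
  cfg$species <- as.character(cfg$species)
  if (!(cfg$focal_species %in% cfg$species))
    stopConfig("focal_species '%s' not in species list", cfg$focal_species)
  for (what in c("genomes", "annotations")) {
    m <- cfg[[what]]
    missSp <- setdiff(cfg$species, names(m))
    if (length(missSp))
      stopConfig("%s: no path for species '%s'", what, missSp[1L])
    cfg[[what]] <- lapply(m, resolve)
  }
  for (f in c("ortholog_table", "de_table", "counts")) {
    if (is.null(cfg[[f]])) next
    cfg[[f]] <- resolve(cfg[[f]])
  }
  cfg$out_dir <- resolve(cfg$out_dir)
  paths <- c(unlist(cfg$genomes), unlist(cfg$annotations), cfg$ortholog_table,
             cfg$de_table, cfg$counts)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopConfig("input file does not exist: %s", missing[1L])
  if (is.null(cfg$motifs) && is.null(cfg$discovery))
    stopConfig("config needs 'motifs' and/or a 'discovery' block")
  if (!is.null(cfg$motifs)) {
    cfg$motifs <- toupper(as.character(cfg$motifs))
    ok <- vapply(cfg$motifs, .isIupac, logical(1))
    if (!all(ok)) stopConfig("invalid motif pattern '%s'", cfg$motifs[!ok][1L])
  }
  if (!(cfg$direction %in% c("up", "down")))
    stopConfig("direction must be 'up' or 'down'")
  if (cfg$p_max <= 0 || cfg$lfc_min <= 0 || cfg$position_window < 0 ||
      cfg$presence_threshold < 0 || cfg$presence_threshold > 1)
    stopConfig("thresholds out of range")
  cfg$.base <- NULL
  class(cfg) <- c("cladeMotifsConfig", "list")
  cfg
}

.logLine <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  message("[cladeMotifs] ", line)
  cat(sprintf("%s  %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%OS2"), line),
      file = state$log, append = TRUE)
}

#' Run the full promoter-conservation pipeline
#'
#' Stages, in order: DE selection (with cross-condition overlap accounting
#' when several comparisons are configured), optional TPM/FPKM
#' normalization, promoter extraction for every species, ortholog group
#' resolution, motif scanning, conservation calls, the summary table, and
#' optional conserved k-mer discovery. Every stage persists a TSV under
#' `out_dir`; a JSON manifest records parameters, input checksums and
#' per-stage record counts (written even on stage failure). With a fixed
#' seed and identical inputs all outputs are byte-identical except the run
#' log and the manifest's timestamp field.
#'
#' @param config a config path or list (see [readRunConfig()])
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "cladeMotifsConfig")) config
         else readRunConfig(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  state$log <- file.path(cfg$out_dir, "run.log")
  cat("", file = state$log)
  inputs <- c(unlist(cfg$genomes), unlist(cfg$annotations),
              cfg$ortholog_table, cfg$de_table, cfg$counts)
  manifest <- list(
    tool = "cladeMotifs", version = as.character(packageVersion("cladeMotifs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = cfg[setdiff(names(cfg), c("genomes", "annotations"))],
    input_checksums = as.list(tools::md5sum(unname(inputs))),
    stage_counts = list(), status = "running")
  writeManifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$status <<- sprintf("failed at stage '%s': %s", name,
                                  conditionMessage(e))
      writeManifest()
      stopStage("stage '%s' failed: %s", name, conditionMessage(e))
    })
    .logLine(state, "stage %-10s done in %.2fs", name,
             proc.time()[["elapsed"]] - t0)
    res
  }

  sel <- stage("select", {
    de <- readDETable(cfg$de_table)
    sets <- lapply(cfg$comparisons, function(cmp)
      selectRegulated(de, cmp, cfg$direction, cfg$p_max, cfg$lfc_min))
    regulated <- if (length(sets) > 1L) geneSetUnion(sets) else sets[[1L]]
    .writeTsv(data.frame(gene_id = geneIds(regulated)),
              file.path(cfg$out_dir, "selected_genes.tsv"))
    if (length(sets) > 1L) {
      ov <- overlapSummary(sets)
      .writeTsv(ov, file.path(cfg$out_dir, "overlaps.tsv"))
    }
    manifest$stage_counts$genes_selected <- length(geneIds(regulated))
    list(sets = sets, regulated = regulated)
  })

  if (!is.null(cfg$counts)) stage("normalize", {
    se <- readCountsMatrix(cfg$counts)
    tpm <- computeTPM(SummarizedExperiment::assay(se, "counts"),
                      SummarizedExperiment::rowData(se)$length)
    fpkm <- computeFPKM(SummarizedExperiment::assay(se, "counts"),
                        SummarizedExperiment::rowData(se)$length)
    .writeTsv(data.frame(gene_id = rownames(se), tpm, check.names = FALSE),
              file.path(cfg$out_dir, "tpm.tsv"))
    .writeTsv(data.frame(gene_id = rownames(se), fpkm, check.names = FALSE),
              file.path(cfg$out_dir, "fpkm.tsv"))
    .writeTsv(data.frame(gene_id = rownames(se),
                         rowNormalize(fpkm, "zscore"), check.names = FALSE),
              file.path(cfg$out_dir, "fpkm_row_normalized.tsv"))
    manifest$stage_counts$normalized_genes <- nrow(se)
  })

  promoters <- stage("extract", {
    ps <- lapply(cfg$species, function(sp) {
      genome <- readGenomeFasta(cfg$genomes[[sp]])
      ann <- readAnnotationsGff3(cfg$annotations[[sp]], sp)
      extractPromoters(genome, ann, cfg$promoter_length)
    })
    all <- do.call(c, ps)
    all <- PromoterSet(Biostrings::DNAStringSet(as.character(all)),
                       geneId = unlist(lapply(ps, geneIds)),
                       speciesId = unlist(lapply(ps, speciesIds)),
                       requestedLength = cfg$promoter_length,
                       upstreamOverlap = unlist(lapply(
                         ps, function(p) S4Vectors::mcols(p)$upstream_overlap)))
    writePromoters(all, file.path(cfg$out_dir, "promoters.fasta"))
    manifest$stage_counts$promoters_collected <- length(all)
    all
  })

  groupsInfo <- stage("groups", {
    tab <- readOrthologTable(cfg$ortholog_table,
                             focalSpecies = cfg$focal_species,
                             species = cfg$species)
    inTable <- intersect(geneIds(sel$regulated), focalGenes(tab))
    groups <- orthologGroups(tab, promoters, genes = inTable)
    sizes <- vapply(groups, length, integer(1))
    manifest$stage_counts$groups_resolved <- length(groups)
    manifest$stage_counts$groups_evaluable <-
      sum(sizes >= cfg$min_orthologs)
    list(table = tab, groups = groups)
  })

  if (!is.null(cfg$motifs)) {
    stage("scan", {
      inGroups <- unique(unlist(lapply(groupsInfo$groups, function(g)
        paste(speciesIds(g), geneIds(g)))))
      scanSet <- promoters[paste(speciesIds(promoters), geneIds(promoters))
                           %in% inGroups]
      h <- do.call(rbind, lapply(cfg$motifs, function(m)
        scanMotif(scanSet, m, bothStrands = TRUE)))
      .writeTsv(h, file.path(cfg$out_dir, "hits.tsv"))
      .writeTsv(hitsAsBed(h, scanSet), file.path(cfg$out_dir, "hits_bed.tsv"))
      manifest$stage_counts$motif_hits <- nrow(h)
      h
    })

    stage("summarize", {
      calls <- conservationCalls(
        intersect(geneIds(sel$regulated), names(groupsInfo$groups)),
        groupsInfo$groups, cfg$motifs, cfg$focal_species,
        cfg$presence_threshold, cfg$position_window, cfg$min_orthologs)
      .writeTsv(calls, file.path(cfg$out_dir, "conservation_calls.tsv"))
      smry <- summarizeMotifs(sel$regulated, promoters, groupsInfo$groups,
                              cfg$motifs, cfg$focal_species,
                              cfg$presence_threshold, cfg$position_window,
                              cfg$min_orthologs, calls = calls)
      .writeTsv(smry, file.path(cfg$out_dir, "summary.tsv"))
      jsonlite::write_json(
        list(parameters = list(presence_threshold = cfg$presence_threshold,
                               position_window = cfg$position_window,
                               min_orthologs = cfg$min_orthologs,
                               p_max = cfg$p_max, lfc_min = cfg$lfc_min,
                               promoter_length = cfg$promoter_length),
             summary = smry),
        file.path(cfg$out_dir, "summary.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
      manifest$stage_counts$genes_with_promoter <-
        sum(geneIds(sel$regulated) %in%
              geneIds(promoters[speciesIds(promoters) == cfg$focal_species]))
      manifest$stage_counts$genes_evaluable <- smry$den_evaluable[1L]
      smry
    })
  }

  if (!is.null(cfg$discovery)) stage("discover", {
    d <- cfg$discovery
    if (is.null(d$cluster_genes)) stopInput("discovery block lacks cluster_genes")
    tab <- groupsInfo$table
    clusterGroups <- orthologGroups(tab, promoters,
                                    genes = as.character(d$cluster_genes))
    disc <- discoverConservedKmers(
      clusterGroups, cfg$focal_species,
      kmin = d$kmin %||% 5L, kmax = d$kmax %||% 6L,
      minClusterFraction = d$min_cluster_fraction %||% 0.8,
      presenceThreshold = cfg$presence_threshold,
      positionWindow = cfg$position_window,
      minOrthologs = cfg$min_orthologs)
    .writeTsv(disc, file.path(cfg$out_dir, "discovered_motifs.tsv"))
    manifest$stage_counts$discovered_motifs <- nrow(disc)
  })

  manifest$status <- "ok"
  writeManifest()
  .logLine(state, "pipeline complete; outputs in %s", cfg$out_dir)
  invisible(manifest)
}
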