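test_that("the 75% presence boundary is inclusive", {
  # 9 of 12 carriers at identical positions: exactly 0.75 -> conserved
  g9 <- plantedGroup("ATGCA", carriers = 1:9, offsets = rep(-150L, 9))
  c9 <- classifyConservation(g9, "ATGCA", "sp01")
  expect_identical(c9$n_with_hit_in_window, 9L)
  expect_equal(c9$presence_fraction, 0.75)
  expect_true(c9$conserved)

  g8 <- plantedGroup("ATGCA", carriers = 1:8, offsets = rep(-150L, 8))
  c8 <- classifyConservation(g8, "ATGCA", "sp01")
  expect_equal(c8$presence_fraction, 2 / 3, tolerance = 1e-12)
  expect_false(c8$conserved)
  expect_true(c8$majority)   # 8 of 12 anywhere is a strict majority
})

test_that("focal absence blocks conservation but not the majority call", {
  # all non-focal species carry the motif; the focal promoter lacks it
  g <- plantedGroup("ATGCA", carriers = 2:12, offsets = rep(-150L, 11))
  cc <- classifyConservation(g, "ATGCA", "sp01")
  expect_false(cc$evaluable)
  expect_false(cc$conserved)
  expect_true(cc$majority)
  expect_identical(cc$n_with_hit_anywhere, 11L)
  expect_true(is.na(cc$reference_offset))

  noFocal <- g[speciesIds(g) != "sp01"]
  expect_error(classifyConservation(noFocal, "ATGCA", "sp01"),
               class = "cm_input_error")

  # fewer collected promoters than minOrthologs -> not evaluable
  small <- g9 <- plantedGroup("ATGCA", carriers = 1:5,
                              offsets = rep(-150L, 5), nSpecies = 5)
  cs <- classifyConservation(small, "ATGCA", "sp01")
  expect_false(cs$group_evaluable)
  expect_false(cs$conserved)
})

test_that("the reference hit is the focal hit nearest the start codon", {
  g <- plantedGroup("ATGCA", carriers = 2:12, offsets = rep(-700L, 11))
  s <- as.character(g)[1L]
  s <- plantMotif(s, "ATGCA", -700L)
  s <- plantMotif(s, "ATGCA", -20L)   # nearer the start codon: wins
  seqs <- as.character(g); seqs[1L] <- s
  g2 <- PromoterSet(seqs, geneId = geneIds(g), speciesId = speciesIds(g),
                    requestedLength = 1000L)
  cc <- classifyConservation(g2, "ATGCA", "sp01", positionWindow = 100L)
  expect_identical(cc$reference_offset, -20L)
  # orthologs sit at -700, outside the 100 bp window around -20
  expect_identical(cc$n_with_hit_in_window, 1L)
  expect_false(cc$conserved)
})

test_that("widening the window or lowering the bar never breaks a call", {
  set.seed(53)
  for (i in 1:30) {
    g <- generateOrthologGroup(syntheticSpec(presenceProb = runif(1),
                                             jitterSd = 80,
                                             seed = sample.int(1e6, 1)))
    base <- classifyConservation(g$promoters, "ATGCA", "sp01",
                                 presenceThreshold = 0.75,
                                 positionWindow = 150L)
    wide <- classifyConservation(g$promoters, "ATGCA", "sp01",
                                 presenceThreshold = 0.75,
                                 positionWindow = 400L)
    low <- classifyConservation(g$promoters, "ATGCA", "sp01",
                                presenceThreshold = 0.5,
                                positionWindow = 150L)
    if (base$conserved) {
      expect_true(wide$conserved)
      expect_true(low$conserved)
    }
    expect_gte(wide$n_with_hit_in_window, base$n_with_hit_in_window)
  }
})

test_that("an added in-window ortholog never lowers the agreeing count", {
  set.seed(61)
  for (i in 1:10) {
    g <- generateOrthologGroup(syntheticSpec(nSpecies = 11,
                                             presenceProb = 0.6,
                                             seed = sample.int(1e6, 1)))
    base <- classifyConservation(g$promoters, "ATGCA", "sp01")
    extraSeq <- plantMotif(strrep("A", 1000), "ATGCA",
                           base$reference_offset)
    aug <- PromoterSet(c(as.character(g$promoters), extraSeq),
                       geneId = c(geneIds(g$promoters), "g001_sp12"),
                       speciesId = c(speciesIds(g$promoters), "sp12"),
                       requestedLength = 1000L)
    got <- classifyConservation(aug, "ATGCA", "sp01")
    expect_identical(got$n_with_hit_in_window,
                     base$n_with_hit_in_window + 1L)
  }
})

test_that("batched conservationCalls equals per-group classification", {
  set.seed(71)
  groups <- lapply(1:8, function(i)
    generateOrthologGroup(syntheticSpec(presenceProb = 0.7, jitterSd = 60,
                                        seed = 100 + i),
                          groupId = paste0("g", i))$promoters)
  names(groups) <- paste0("g", 1:8)
  motifs <- c("ATGCA", "CGGAT")
  batched <- conservationCalls(names(groups), groups, motifs, "sp01")
  for (g in names(groups)) for (m in motifs) {
    single <- classifyConservation(groups[[g]], m, "sp01")
    row <- batched[batched$gene_id == g & batched$motif == m, ]
    rownames(row) <- NULL
    expect_equal(row, single)
  }
})

test_that("summarizeMotifs counts match construction and the brute force", {
  set.seed(83)
  # ten regulated genes, motif planted in every promoter of every group
  mkGroup <- function(gid, carriers) {
    seqs <- vapply(1:12, function(j) {
      s <- randSeq(600, 0.3)
      if (j %in% carriers) s <- plantMotif(s, "CGGCTT", -200L) else s
    }, character(1))
    PromoterSet(seqs, geneId = c(gid, paste0(gid, "_sp",
                                             sprintf("%02d", 2:12))),
                speciesId = sprintf("sp%02d", 1:12))
  }
  genes <- paste0("g", 1:10)
  full <- lapply(genes, mkGroup, carriers = 1:12)
  names(full) <- genes
  focal <- do.call(c, lapply(full, function(g) as.character(g)[1]))
  focalPs <- PromoterSet(unname(focal), geneId = genes,
                         speciesId = rep("sp01", 10))
  smry <- summarizeMotifs(genes, focalPs, full, "CGGCTT", "sp01")
  expect_identical(smry$n_present_focal, 10L)
  expect_identical(smry$n_conserved, 10L)
  expect_identical(smry$n_majority, 10L)
  expect_identical(smry$pct_present_focal, 100L)
  expect_identical(smry$pct_conserved, 100L)

  # focal-only planting: column 1 full, columns 2-3 empty
  solo <- lapply(genes, mkGroup, carriers = 1)
  names(solo) <- genes
  focalSolo <- PromoterSet(
    unname(vapply(solo, function(g) as.character(g)[1], character(1))),
    geneId = genes, speciesId = rep("sp01", 10))
  s2 <- summarizeMotifs(genes, focalSolo, solo, "CGGCTT", "sp01")
  expect_identical(s2$pct_present_focal, 100L)
  expect_identical(s2$n_conserved, 0L)
  expect_identical(s2$n_majority, 0L)

  # randomized fixture vs an independent per-gene recount
  mixed <- lapply(genes, function(g)
    mkGroup(g, carriers = sort(sample(1:12, sample(0:12, 1)))))
  names(mixed) <- genes
  focalMix <- PromoterSet(
    unname(vapply(mixed, function(g) as.character(g)[1], character(1))),
    geneId = genes, speciesId = rep("sp01", 10))
  s3 <- summarizeMotifs(genes, focalMix, mixed, "CGGCTT", "sp01")
  oracle <- lapply(genes, function(g) {
    grp <- mixed[[g]]
    oracleConservation(as.character(grp), speciesIds(grp), "sp01", "CGGCTT")
  })
  focalPresent <- vapply(genes, function(g)
    nrow(oracleScan(as.character(mixed[[g]])[1], "CGGCTT")) > 0, logical(1))
  expect_identical(s3$n_present_focal, sum(focalPresent))
  expect_identical(s3$n_conserved,
                   sum(vapply(oracle, `[[`, logical(1), "conserved")))
  expect_identical(s3$n_majority,
                   sum(vapply(oracle, `[[`, logical(1), "majority")))

  expect_error(summarizeMotifs(genes, focalMix, mixed, character(0), "sp01"),
               class = "cm_input_error")
})

test_that("background-only conservation shrinks with the position window", {
  set.seed(97)
  nGroups <- 120
  groups <- lapply(seq_len(nGroups), function(i)
    generateOrthologGroup(syntheticSpec(presenceProb = 0,
                                        plantInFocal = FALSE,
                                        seed = 2000 + i))$promoters)
  consAt <- function(w) sum(vapply(groups, function(g)
    classifyConservation(g, "ATGCA", "sp01",
                         positionWindow = w)$conserved, logical(1)))
  c50 <- consAt(50L); c100 <- consAt(100L); c200 <- consAt(200L)
  expect_lte(c50, c100)
  expect_lte(c100, c200)
  expect_lt(c200 / nGroups, 0.15)
})
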