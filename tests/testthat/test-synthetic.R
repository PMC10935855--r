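test_that("generatePromoter respects length, alphabet and composition", {
  expect_error(generatePromoter(0), class = "cm_input_error")
  expect_error(generatePromoter(10, gc = 1.2), class = "cm_input_error")

  s <- generatePromoter(5, gc = 0, seed = 42)
  expect_match(s, "^[AT]{5}$")
  expect_identical(generatePromoter(1000, gc = 0.5, seed = 7),
                   generatePromoter(1000, gc = 0.5, seed = 7))

  # G+C count within 4 binomial SDs of the expectation, across many seeds
  sdGC <- sqrt(1000 * 0.25)
  for (seed in 1:100) {
    s <- generatePromoter(1000, gc = 0.5, seed = seed)
    gcCount <- nchar(gsub("[AT]", "", s))
    expect_lt(abs(gcCount - 500), 4 * sdGC)
  }
})

test_that("plantMotif writes exactly the requested window on either strand", {
  expect_identical(plantMotif("AAAAAAAAAA", "ATGCA", -10), "ATGCAAAAAA")
  expect_identical(plantMotif("AAAAAAAAAA", "ATGCA", -5, "-"), "AAAAATGCAT")
  expect_error(plantMotif("AAAA", "ATGCA", -4), class = "cm_input_error")
  expect_error(plantMotif("AAAAAAAAAA", "ATGCA", -3), class = "cm_input_error")

  # only the window changes; length preserved
  set.seed(1)
  for (i in 1:20) {
    s <- randSeq(50)
    off <- sample(-50:-5, 1)
    out <- plantMotif(s, "ATGCA", off)
    expect_identical(nchar(out), 50L)
    w0 <- 50 + off
    expect_identical(substr(out, w0 + 1, w0 + 5), "ATGCA")
    expect_identical(substr(out, 1, w0), substr(s, 1, w0))
    expect_identical(substr(out, w0 + 6, 50), substr(s, w0 + 6, 50))
  }
})

test_that("generateOrthologGroup honors presence, anchor and determinism", {
  spec <- syntheticSpec(presenceProb = 1, jitterSd = 0)
  grp <- generateOrthologGroup(spec)
  expect_length(grp$promoters, 12L)
  expect_true(all(grp$truth$carrier))
  expect_true(all(grp$truth$offset == -150L))
  for (i in seq_len(12)) {
    s <- unname(as.character(grp$promoters)[i])
    expect_identical(substr(s, 1000 - 150 + 1, 1000 - 150 + 5), "ATGCA")
  }

  # byte-identical under a fixed seed
  spec3 <- syntheticSpec(presenceProb = 0.8, seed = 3)
  a <- generateOrthologGroup(spec3); b <- generateOrthologGroup(spec3)
  expect_identical(as.character(a$promoters), as.character(b$promoters))
  expect_identical(a$truth, b$truth)

  # without focal planting, presence 0 means no planted motifs at all
  none <- generateOrthologGroup(syntheticSpec(presenceProb = 0,
                                              plantInFocal = FALSE))
  expect_false(any(none$truth$carrier))

  # planted offsets always index windows fully inside the promoter
  for (seed in 1:25) {
    g <- generateOrthologGroup(syntheticSpec(presenceProb = 0.7,
                                             jitterSd = 400, seed = seed))
    offs <- g$truth$offset[!is.na(g$truth$offset)]
    expect_true(all(offs >= -1000 & offs <= -5))
  }
})

test_that("background motif occurrence matches the closed-form expectation", {
  # presence 0 clades carry only i.i.d. background; mean ATGCA hit count per
  # promoter (both strands) should match 2*(L-k+1)*prod(base probs)
  gc <- 0.30; L <- 1000L
  pWord <- ((1 - gc) / 2)^3 * (gc / 2)^2
  expected <- 2 * (L - 5 + 1) * pWord
  n <- 5000L
  seqs <- vapply(seq_len(n), function(i) generatePromoter(L, gc, seed = i),
                 character(1))
  ps <- PromoterSet(seqs, geneId = sprintf("g%04d", seq_len(n)),
                    speciesId = rep("sp01", n), requestedLength = L)
  hits <- scanMotif(ps, "ATGCA")
  counts <- tabulate(match(hits$gene_id, geneIds(ps)), nbins = n)
  se <- sd(counts) / sqrt(n)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("generateDETable separates null and regulated statistics", {
  expect_error(generateDETable(10, 11), class = "cm_input_error")

  d <- generateDETable(500, 50, seed = 5)
  expect_identical(d, generateDETable(500, 50, seed = 5))
  expect_identical(nrow(d$table), 500L)
  expect_identical(length(unique(d$truth$gene_id)), 50L)
  expect_true(all(d$truth$gene_id %in% d$table$gene_id))

  # strong-effect limit: every regulated gene passes the default thresholds
  lim <- generateDETable(100, 100, pAltShape = 1e-4, lfcAltMean = 5,
                         seed = 2)
  up <- selectRegulated(lim$table, "cond1", "up")
  dn <- selectRegulated(lim$table, "cond1", "down")
  expect_identical(sort(unique(c(geneIds(up), geneIds(dn)))),
                   sort(lim$table$gene_id))

  # null-only table: pass rate matches the analytic tail product at mild
  # thresholds (p <= 0.1 and |lfc| >= 0.3, i.e. 1 SD of the null lfc)
  nul <- generateDETable(20000, 0, seed = 9)$table
  pass <- mean(nul$pvalue <= 0.1 & abs(nul$log2fc) >= 0.3)
  analytic <- 0.1 * 2 * pnorm(-1)
  se <- sqrt(analytic * (1 - analytic) / 20000)
  expect_lt(abs(pass - analytic), 4 * se)
})

test_that("writeFixtureGenome round-trips promoters on both strands", {
  dir <- withr::local_tempdir()
  genes <- data.frame(gene_id = c("gp", "gm"), strand = c("+", "-"),
                      promoter = c(randSeq(200), randSeq(200)),
                      stringsAsFactors = FALSE)
  fx <- writeFixtureGenome(genes, file.path(dir, "fx"), seed = 4)
  genome <- readGenomeFasta(fx$fasta)
  ann <- readAnnotationsGff3(fx$gff3, "sp01")
  ps <- extractPromoters(genome, ann, length = 200)
  expect_identical(unname(as.character(ps)[match(genes$gene_id,
                                              geneIds(ps))]),
                   genes$promoter)

  # minus-strand fragment equals revcomp of the reference slice 3' of the gene
  gm <- ann[ann$gene_id == "gm", ]
  slice <- substr(as.character(genome)[[gm$contig]], gm$end + 1, gm$end + 200)
  expect_identical(oracleRevcomp(slice),
                   unname(as.character(ps)[geneIds(ps) == "gm"]))

  # explicit overlapping layout is rejected
  bad <- data.frame(gene_id = c("a", "b"), strand = "+",
                    promoter = c(randSeq(50), randSeq(50)),
                    start = c(60, 80), stringsAsFactors = FALSE)
  expect_error(writeFixtureGenome(bad, file.path(dir, "bad")),
               class = "cm_input_error")
})
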