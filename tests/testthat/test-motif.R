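test_that("reverseComplementIupac reproduces the named pairs and involutes", {
  expect_identical(reverseComplementIupac("ATGCA"), "TGCAT")
  expect_identical(reverseComplementIupac("CGGAT"), "ATCCG")
  expect_identical(reverseComplementIupac("CGGCTT"), "AAGCCG")
  expect_identical(reverseComplementIupac("N"), "N")
  expect_error(reverseComplementIupac("ACGX"), class = "cm_input_error")

  set.seed(12)
  for (i in 1:1000) {
    s <- randIupac(sample(1:15, 1))
    expect_identical(reverseComplementIupac(reverseComplementIupac(s)), s)
    expect_identical(reverseComplementIupac(s), oracleRevcomp(s))
  }
})

test_that("canonicalKmer folds orientations into the smaller of the pair", {
  expect_identical(canonicalKmer(c("ATGCA", "TGCAT")), c("ATGCA", "ATGCA"))
  expect_identical(canonicalKmer("CGGCTT"), "AAGCCG")
  expect_identical(canonicalKmer("ACGT"), "ACGT")  # palindrome
})

test_that("scanMotif reports anchored offsets on both strands", {
  h <- scanMotif("GGATGCAGG", "ATGCA")
  expect_identical(h$offset, -7L)
  expect_identical(h$strand, "+")
  expect_identical(h$match, "ATGCA")

  h2 <- scanMotif("GGTGCATGG", "ATGCA")
  expect_identical(h2$strand, "-")
  expect_identical(h2$offset, -7L)
  expect_identical(h2$match, "TGCAT")

  expect_identical(nrow(scanMotif("AAAAA", "ATGCA")), 0L)
  expect_error(scanMotif("AAAA", "ATGCA"), class = "cm_input_error")

  # overlapping hits are all reported
  h3 <- scanMotif("ATATATA", "ATA", bothStrands = FALSE)
  expect_identical(h3$offset, c(-7L, -5L, -3L))

  # N in the sequence matches nothing; N in the pattern matches any base
  expect_identical(nrow(scanMotif("GGATGCNGG", "ATGCA")), 0L)
  hN <- scanMotif("GGATGTAGG", "ATGNA", bothStrands = FALSE)
  expect_identical(hN$offset, -7L)

  # palindromic pattern: each window reported once, on the plus strand
  hp <- scanMotif("AAACGTAA", "ACGT")
  expect_identical(nrow(hp), 1L)
  expect_identical(hp$strand, "+")
})

test_that("scanMotif equals the naive every-window oracle", {
  set.seed(99)
  motifPool <- c("ATGCA", "CGGAT", "CGGCTT", "TGCAT", "ANGCA", "CGRAT",
                 "WWSS", "ACGT")
  for (i in 1:200) {
    L <- sample(20:300, 1)
    gc <- runif(1, 0.2, 0.8)
    s <- randSeq(L, gc)
    if (runif(1) < 0.2) substr(s, sample(L, 1), sample(L, 1)) <- "N"
    m <- sample(motifPool, 1)
    got <- scanMotif(s, m)
    want <- oracleScan(s, m)
    expect_identical(got$offset, want$offset)
    expect_identical(got$strand, want$strand)
    expect_identical(got$match, want$match)
  }
})

test_that("strand folding equals the union of plus-strand scans", {
  set.seed(17)
  for (i in 1:50) {
    s <- randSeq(200)
    m <- sample(c("ATGCA", "CGGAT", "CGGCTT"), 1)  # non-palindromic
    both <- scanMotif(s, m)
    plus <- scanMotif(s, m, bothStrands = FALSE)
    minusAsPlus <- scanMotif(s, reverseComplementIupac(m),
                             bothStrands = FALSE)
    expect_identical(sort(both$offset[both$strand == "+"]),
                     sort(plus$offset))
    expect_identical(sort(both$offset[both$strand == "-"]),
                     sort(minusAsPlus$offset))
  }
})

test_that("hit offsets address the matched window within the fragment", {
  set.seed(23)
  for (i in 1:50) {
    L <- sample(30:200, 1)
    s <- randSeq(L, runif(1, 0.25, 0.75))
    h <- scanMotif(s, "ATGCA")
    if (!nrow(h)) next
    for (r in seq_len(nrow(h))) {
      w0 <- L + h$offset[r]
      expect_identical(substr(s, w0 + 1, w0 + 5), h$match[r])
      expect_gte(h$offset[r], -L)
      expect_lte(h$offset[r], -5L)
    }
  }
})

test_that("countRepeats collapses overlaps greedily and optimally", {
  mkHits <- function(offs) data.frame(gene_id = "g", species_id = "sp01",
                                      motif = "ATGCA", offset = offs,
                                      strand = "+", match = "ATGCA")
  expect_identical(countRepeats(mkHits(c(-20L, -10L)))$count, 2L)
  expect_identical(countRepeats(mkHits(c(-10L, -8L)))$count, 1L)
  expect_identical(nrow(countRepeats(mkHits(-10L)[0, ])), 0L)
  expect_error(countRepeats(rbind(mkHits(-10L),
                                  transform(mkHits(-20L), gene_id = "h"))),
               class = "cm_input_error")

  set.seed(31)
  for (i in 1:200) {
    offs <- sort(sample(-100:-5, sample(1:12, 1)))
    got <- countRepeats(mkHits(as.integer(offs)))$count
    expect_identical(got, oracleMaxNonOverlapping(offs, 5L))
  }

  # repeats planted 2-4 times are recovered from a scan
  s <- strrep("A", 300)
  for (off in c(-280L, -150L, -40L)) s <- plantMotif(s, "ATGCA", off)
  ps <- PromoterSet(s, geneId = "g", speciesId = "sp01")
  expect_identical(countRepeats(scanMotif(ps, "ATGCA"))$count, 3L)
})

test_that("discoverConservedKmers returns planted keys and applies the bar", {
  set.seed(41)
  # five groups; ATGCA planted everywhere, CCCGG only in the first two
  groups <- lapply(1:5, function(gi) {
    seqs <- vapply(1:12, function(j) {
      s <- randSeq(400, 0.3)
      s <- plantMotif(s, "ATGCA", -150L)
      if (gi <= 2) s <- plantMotif(s, "CCCGG", -300L)
      s
    }, character(1))
    PromoterSet(seqs,
                geneId = c(paste0("g", gi),
                           paste0("g", gi, "_sp", sprintf("%02d", 2:12))),
                speciesId = sprintf("sp%02d", 1:12))
  })
  names(groups) <- paste0("g", 1:5)
  disc <- discoverConservedKmers(groups, "sp01", kmin = 5, kmax = 5,
                                 minClusterFraction = 0.8)
  expect_true("ATGCA" %in% disc$kmer)
  expect_identical(disc$score[disc$kmer == "ATGCA"], 1)
  expect_false("CCCGG" %in% disc$kmer)
  expect_true(all(disc$score >= 0.8 - 1e-9))

  # every returned candidate really re-passes the conservation classifier
  top <- head(disc$kmer, 3)
  for (kk in top) {
    calls <- vapply(groups, function(g)
      classifyConservation(g, kk, "sp01")$conserved, logical(1))
    expect_gte(mean(calls), 0.8 - 1e-9)
  }

  expect_error(discoverConservedKmers(list(), "sp01"),
               class = "cm_input_error")
  expect_error(discoverConservedKmers(groups, "sp01", kmin = 2),
               class = "cm_input_error")
})
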