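# Internal helpers shared across modules.

.IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

.isIupac <- function(x) {
  grepl(sprintf("^[%s]+$", .IUPAC_CHARS), toupper(x))
}

.isScalarNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

.isCount <- function(x) {
  .isScalarNumber(x) && x >= 0 && x == as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!.isScalarNumber(seed)) stopInput("'seed' must be a single number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# n random sequences of the given length with i.i.d. bases,
# P(G) = P(C) = gc/2, P(A) = P(T) = (1 - gc)/2.
.randomSeqs <- function(n, length, gc) {
  bases <- sample(c("A", "C", "G", "T"), n * length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (n == 1L) return(paste(bases, collapse = ""))
  dim(bases) <- c(n, length)
  do.call(paste0, lapply(seq_len(length), function(j) bases[, j]))
}

# Reverse complement of a character vector of IUPAC strings.
.revcompChr <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

# Integer percentage, rounded half-up (printed-table convention).
.pctHalfUp <- function(num, den) {
  ifelse(den > 0, as.integer(floor(100 * num / den + 0.5)), NA_integer_)
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
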