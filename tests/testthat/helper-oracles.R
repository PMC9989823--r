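# Independent brute-force oracles, deliberately written on a different code
# path (character sets, nested loops) than the package implementation
# (bitmask vectors).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleRevComp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

# Position-by-position set-membership mismatch count.
oracleMismatch <- function(window, consensus) {
  w <- strsplit(toupper(window), "")[[1]]
  k <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(length(w) == length(k))
  mm <- 0L
  for (j in seq_along(k)) {
    if (k[j] == "N") next
    if (!(w[j] %in% c("A", "C", "G", "T")) ||
        !(w[j] %in% IUPAC_SETS[[k[j]]]))
      mm <- mm + 1L
  }
  mm
}

# Exhaustive both-strand scan; palindromic consensus counted once (plus).
oracleScan <- function(seq, consensus, maxMismatches) {
  m <- nchar(consensus)
  L <- nchar(seq)
  rows <- list()
  if (L >= m) {
    rcCons <- oracleRevComp(consensus)
    palindromic <- identical(toupper(consensus), rcCons)
    for (off in 0:(L - m)) {
      win <- substr(seq, off + 1, off + m)
      if (oracleMismatch(win, consensus) <= maxMismatches)
        rows[[length(rows) + 1L]] <- data.frame(
          offset = off, strand = "+",
          mismatches = oracleMismatch(win, consensus))
      if (!palindromic) {
        # minus-strand hit: window matches revcomp(consensus)
        if (oracleMismatch(oracleRevComp(win), consensus) <= maxMismatches)
          rows[[length(rows) + 1L]] <- data.frame(
            offset = off, strand = "-",
            mismatches = oracleMismatch(oracleRevComp(win), consensus))
      }
    }
  }
  if (!length(rows))
    return(data.frame(offset = integer(), strand = character(),
                      mismatches = integer()))
  out <- do.call(rbind, rows)
  out[order(out$offset, out$strand == "-"), ]   # plus strand first
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# Textbook Welch-Satterthwaite formula.
oracleWelch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Run-length-encoding region oracle over a significance/sign pattern.
oracleMerge <- function(sig, sgn) {
  runs <- list()
  i <- 1
  n <- length(sig)
  while (i <= n) {
    if (!sig[i]) { i <- i + 1; next }
    j <- i
    while (j + 1 <= n && sig[j + 1] && sgn[j + 1] == sgn[i]) j <- j + 1
    runs[[length(runs) + 1L]] <- c(first = i, last = j, sign = sgn[i])
    i <- j + 1
  }
  runs
}

# Default two-origin 500-kb study chromosome used by pipeline-level tests.
studyConfig <- function(...) {
  simConfig(c(chrS = 500000),
            data.frame(name = c("oriEarly", "oriLate"), chrom = "chrS",
                       position = c(150000, 350000),
                       firingTime = c(16, 30), firingSd = 3,
                       efficiency = c(0.9, 0.8)),
            ...)
}
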