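test_that("mismatch counting equals IUPAC set-membership oracle", {
  expect_equal(mismatchCount("AGTTAAAC", "ANWWAAAN"), 0)
  expect_equal(mismatchCount("CGTTAAAC", "ANWWAAAN"), 1)
  expect_error(mismatchCount("ACGT", "ANWWAAAN"), "equal length")

  set.seed(101)
  for (i in 1:1000) {
    w <- randomDNA(8)
    expect_equal(mismatchCount(w, "ANWWAAAN"), oracleMismatch(w, "ANWWAAAN"))
  }
  # ambiguous genome base is a mismatch unless consensus is N
  expect_equal(mismatchCount("AGTWAAAC", "ANWWAAAN"), 1)
  expect_equal(mismatchCount("WGTTAAAC", "NNWWAAAN"), 0)
})

test_that("scanning finds planted instances on both strands", {
  set.seed(7)
  bg <- paste(sample(c("A", "C"), 60, replace = TRUE), collapse = "")
  cons <- "RTCGYKAT"  # non-palindromic
  mot <- motifDef("m", cons, 0)
  planted <- sub("R", "G", sub("Y", "C", sub("K", "T", cons)))
  s <- paste0(substr(bg, 1, 10), planted, substr(bg, 19, 60))
  hits <- scanSequence(s, mot)
  expect_true(any(hits$offset == 10 & hits$strand == "+"))
  expect_equal(hits[, c("offset", "strand", "mismatches")],
               oracleScan(s, cons, 0), ignore_attr = TRUE)

  rcs <- paste0(substr(bg, 1, 10), oracleRevComp(planted),
                substr(bg, 19, 60))
  rhits <- scanSequence(rcs, mot)
  expect_true(any(rhits$offset == 10 & rhits$strand == "-"))

  expect_equal(nrow(scanSequence("ACG", mot)), 0)  # shorter than consensus
})

test_that("scanning a consensus against itself hits at offset 0", {
  for (cons in c("WTTTAYRTTTW", "ANWWAAAN", "RTCRYNNNNNACG")) {
    inst <- vapply(strsplit(cons, "")[[1]],
                   function(k) IUPAC_SETS[[k]][1], "")
    h <- scanSequence(paste(inst, collapse = ""), motifDef("x", cons, 0))
    expect_true(any(h$offset == 0 & h$mismatches == 0))
  }
})

test_that("hit sets are reverse-complement symmetric and budget-monotone", {
  set.seed(33)
  mot2 <- function(k) motifDef("B2", "ANWWAAAN", k)
  for (i in 1:20) {
    s <- randomDNA(300)
    h0 <- scanSequence(s, mot2(0))
    h1 <- scanSequence(s, mot2(1))
    h2 <- scanSequence(s, mot2(2))
    expect_lte(nrow(h0), nrow(h1))
    expect_lte(nrow(h1), nrow(h2))
    # reverse-complementing the sequence mirrors offsets and swaps strands
    rc <- oracleRevComp(s)
    hrc <- scanSequence(rc, mot2(1))
    mirrored <- data.frame(offset = nchar(s) - 8 - h1$offset,
                           strand = ifelse(h1$strand == "+", "-", "+"),
                           mismatches = h1$mismatches)
    mirrored <- mirrored[order(mirrored$offset, mirrored$strand == "-"), ]
    expect_equal(hrc[, c("offset", "strand", "mismatches")], mirrored,
                 ignore_attr = TRUE)
  }
})

test_that("B1 search obeys the 17-19 bp 3' offset window on the ACS strand", {
  acs <- motifDef("ACS", "WTTTAYRTTTW", 0)
  b1 <- motifDef("B1", "WTW", 0, anchor = "ACS")
  acsInst <- "ATTTACGTTTA"
  mk <- function(gap, probe = "TTT") {
    paste0(strrep("C", 5), acsInst, strrep("C", gap), probe,
           strrep("C", 25))
  }
  s17 <- mk(17)
  h <- scanSequence(s17, acs)
  b <- scanB1(s17, h, b1)
  expect_equal(nrow(b), 1)
  expect_equal(b$offset, 5 + 11 + 17)
  expect_equal(b$strand, "+")

  expect_equal(nrow(scanB1(mk(21), scanSequence(mk(21), acs), b1)), 0)
  expect_equal(nrow(scanB1(s17, scanSequence("CCCC", acs), b1)), 0)

  # minus-strand ACS: 3' runs leftward on the plus strand
  sMinus <- paste0(strrep("C", 25), "AAA", strrep("C", 17),
                   oracleRevComp(acsInst), strrep("C", 5))
  hM <- scanSequence(sMinus, acs)
  expect_true(any(hM$strand == "-"))
  bM <- scanB1(sMinus, hM[hM$strand == "-", ], b1)
  expect_equal(nrow(bM), 1)
  expect_equal(bM$offset, 25)      # TTT on the T-rich (minus) strand
  expect_equal(bM$strand, "-")

  # ACS too close to the edge contributes no B1, silently
  sEdge <- paste0(strrep("C", 5), acsInst, strrep("C", 3))
  expect_equal(nrow(scanB1(sEdge, scanSequence(sEdge, acs), b1)), 0)
})

test_that("per-origin counting respects per-motif flank and chaining rules", {
  b2 <- motifDef("B2", "ANWWAAAN", 0)
  # two non-overlapping exact B2 instances
  core <- paste0(strrep("C", 10), "AGTTAAAC", strrep("C", 10),
                 "ATATAAAT", strrep("C", 10))
  tab <- countMotifs(c(ori1 = core), list(b2))
  expect_gte(tab$B2[1], 2)
  expect_equal(tab$B2[1], nrow(oracleScan(core, "ANWWAAAN", 0)))

  # heavy mismatch load: all-G sequence yields zero B2 even at budget 2
  tab2 <- countMotifs(c(x = strrep("G", 100)),
                      list(motifDef("B2", "ANWWAAAN", 2)))
  expect_equal(tab2$B2[1], 0)

  # B3 flank rule: instance 100 bp upstream of the core window is counted
  # for B3 (flank 200) but an identical-position ACS (flank 0) is not
  probe <- "GTCACTGGGTACG"  # matches RTCRYNNNNNACG exactly
  acsProbe <- "ATTTACGTTTA"
  flank5 <- paste0(strrep("C", 87), probe, acsProbe,
                   strrep("C", 200 - 87 - 13 - 11))
  seqs <- c(o = paste0(flank5, strrep("C", 300), strrep("C", 200)))
  mots <- list(motifDef("ACS", "WTTTAYRTTTW", 0),
               motifDef("B3", "RTCRYNNNNNACG", 0, flankBp = 200))
  tab3 <- countMotifs(seqs, mots, flankProvided = 200)
  expect_gte(tab3$B3[1], 1)
  expect_equal(tab3$ACS[1], 0)

  # missing sequence flagged, excluded from counts
  tab4 <- countMotifs(c(a = core, b = NA), list(b2))
  expect_true(tab4$missing[2])
  expect_true(is.na(tab4$B2[2]))
})

test_that("count-vs-timing correlation handles signal, noise and degeneracy", {
  ori <- data.frame(name = paste0("o", 1:30), chrom = "c",
                    position = 1:30, rt = sort(runif(30, 5, 40)),
                    efficiency = NA_real_)
  counts <- data.frame(origin = ori$name, M = rank(ori$rt))
  set.seed(5)
  res <- correlateCounts(counts, ori, "rt", nPerm = 200)
  expect_equal(res$coefficient, 1)
  expect_lt(res$pValue, 0.05)

  flat <- data.frame(origin = ori$name, M = rep(2, 30))
  res2 <- correlateCounts(flat, ori, "rt", nPerm = 50)
  expect_true(is.na(res2$coefficient))
  expect_match(res2$reason, "zero variance")

  # independent counts: permutation p roughly uniform across motifs
  set.seed(17)
  indep <- data.frame(origin = ori$name)
  for (m in 1:20) indep[[paste0("m", m)]] <- rpois(30, 2)
  res3 <- correlateCounts(indep, ori, "rt", nPerm = 400)
  expect_lte(mean(res3$pValue < 0.05), 0.2)
  expect_gte(mean(res3$pValue < 0.5), 0.2)
})
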