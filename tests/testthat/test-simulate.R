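test_that("expected copy number obeys the replication model limits", {
  cfg <- studyConfig()
  x <- seq(0, 500000, by = 5000)
  expect_equal(expectedCopyNumber(x, 0, cfg), rep(1, length(x)))

  cfgFull <- studyConfig()
  cfgFull$origins$efficiency <- c(1, 0.8)
  expect_equal(expectedCopyNumber(x, 1000, cfgFull), rep(2, length(x)))

  # bounds and monotonicity in t
  set.seed(21)
  xs <- sample(0:500000, 30)
  prev <- expectedCopyNumber(xs, 0, cfg)
  for (t in c(5, 10, 20, 30, 60)) {
    cur <- expectedCopyNumber(xs, t, cfg)
    expect_true(all(cur >= prev - 1e-12))
    expect_true(all(cur >= 1 & cur <= 2))
    prev <- cur
  }
  # single origin: decreasing away from the origin before completion
  one <- simConfig(c(c1 = 200000),
                   data.frame(name = "o", chrom = "c1", position = 100000,
                              firingTime = 10, firingSd = 3,
                              efficiency = 1))
  d <- expectedCopyNumber(seq(100000, 180000, by = 2000), 30, one)
  expect_true(all(diff(d) <= 1e-12))
})

test_that("deterministic firing gives a sharp fork-arrival front", {
  # origin fires at 5 min, fork 2 kb/min, locus 10 kb away: jump at t = 10
  cfg <- simConfig(c(c1 = 100000),
                   data.frame(name = "o", chrom = "c1", position = 40000,
                              firingTime = 5, firingSd = 0,
                              efficiency = 1),
                   forkSpeed = 2)
  x <- 50000
  expect_equal(expectedCopyNumber(x, 9.9, cfg), 1)
  expect_equal(expectedCopyNumber(x, 10, cfg), 2)
  expect_equal(expectedCopyNumber(x, 10.1, cfg), 2)
})

test_that("closed form agrees with Monte Carlo cell simulation", {
  cfg <- studyConfig()
  set.seed(77)
  pts <- data.frame(x = sample(0:500000, 20),
                    t = runif(20, 5, 45))
  for (i in seq_len(nrow(pts))) {
    closed <- expectedCopyNumber(pts$x[i], pts$t[i], cfg)
    mc <- monteCarloCopyNumber(pts$x[i], pts$t[i], cfg, nCells = 10000)
    se <- max(mc$se, sqrt((closed - 1) * (2 - closed) / 10000))
    expect_lt(abs(closed - mc$copy), 3 * max(se, 1e-4))
  }
})

test_that("HU mode confines replication to the fork-travel cap", {
  hu <- simConfig(c(c1 = 200000),
                  data.frame(name = "o", chrom = "c1", position = 100000,
                             firingTime = 5, firingSd = 1, efficiency = 1),
                  huMode = TRUE, huCapBp = 5000)
  x <- seq(0, 200000, by = 250)
  cn <- expectedCopyNumber(x, 60, hu)
  repl <- x[cn > 1.5]
  expect_lte(diff(range(repl)), 2 * 5000)
  expect_gte(diff(range(repl)), 2 * 5000 - 1000)
  expect_true(all(abs(repl - 100000) <= 5000))
  # without the cap the same model replicates far beyond 5 kb
  noHu <- hu
  noHu$huMode <- FALSE
  expect_gt(sum(expectedCopyNumber(x, 60, noHu) > 1.5) , sum(cn > 1.5))
})

test_that("simulated counts are reproducible and Poisson-consistent", {
  cfg <- studyConfig(readsPerSample = 2e5)
  s1 <- simulateBinnedCounts(cfg, seed = 5)
  s2 <- simulateBinnedCounts(cfg, seed = 5)
  expect_identical(lapply(s1$tracks, trackValues),
                   lapply(s2$tracks, trackValues))
  expect_equal(names(s1$tracks),
               c("G1_rep1", "S_rep1", "G1_rep2", "S_rep2",
                 "G1_rep3", "S_rep3"))

  # G1 track is flat up to bias and Poisson noise
  g1 <- trackValues(s1$tracks$G1_rep1)$chrS
  expect_lt(abs(mean(g1) - 2e5 / 1000), 3 * sd(g1) / sqrt(1000))

  # S/G1 mean count ratio near vs far from the early origin matches the
  # expected copy-number ratio (averaged over replicates and seeds)
  near <- 290:310   # bins around 150 kb
  far <- 30:80      # left telomere-proximal region, still unreplicated
  ratios <- vapply(1:8, function(s) {
    sim <- simulateBinnedCounts(cfg, seed = 100 + s)$tracks
    sv <- rowSums(vapply(paste0("S_rep", 1:3), function(id)
      trackValues(sim[[id]])$chrS, numeric(1000)))
    gv <- rowSums(vapply(paste0("G1_rep", 1:3), function(id)
      trackValues(sim[[id]])$chrS, numeric(1000)))
    (sum(sv[near]) / sum(gv[near])) / (sum(sv[far]) / sum(gv[far]))
  }, numeric(1))
  mids <- ((1:1000) - 1) * 500 + 250
  cn <- expectedCopyNumber(mids, 24, cfg)
  expected <- mean(cn[near]) / mean(cn[far])
  expect_lt(abs(mean(ratios) - expected),
            3 * sd(ratios) / sqrt(length(ratios)) + 0.01)
})

test_that("perturbation shifts firing times and records ground truth", {
  cfg <- studyConfig()
  p0 <- applyPerturbation(cfg, "oriLate", 0)
  expect_equal(p0$cfg$origins$firingTime, cfg$origins$firingTime)
  expect_equal(nrow(p0$truth), 0)

  adv <- applyPerturbation(cfg, "oriLate", -10)
  expect_equal(adv$cfg$origins$firingTime, c(16, 20))
  mids <- ((1:1000) - 1) * 500 + 250
  d <- expectedCopyNumber(mids, 24, adv$cfg) -
       expectedCopyNumber(mids, 24, cfg)
  expect_true(all(d >= -1e-12))            # advancing never delays
  expect_gt(max(d), 0.1)
  expect_equal(nrow(adv$truth), 1)
  expect_equal(adv$truth$direction, "advanced")
  # ground-truth interval covers the perturbed origin
  expect_lte(adv$truth$start, 350000)
  expect_gte(adv$truth$end, 350000)

  expect_error(applyPerturbation(cfg, "nope", -5), "unknown origin")
})

test_that("planted motif sequences are found at, and only at, their budget", {
  b2 <- motifDef("B2", "ANWWAAAN")
  sim0 <- simulateOriginSequences(
    10, list(list(motif = b2, count = 1, mismatches = 0)), seed = 40)
  sim0b <- simulateOriginSequences(
    10, list(list(motif = b2, count = 1, mismatches = 0)), seed = 40)
  expect_identical(sim0$sequences, sim0b$sequences)
  expect_equal(nrow(sim0$truth), 10)

  for (i in 1:10) {
    s <- sim0$sequences[[i]]
    tr <- sim0$truth[sim0$truth$origin == names(sim0$sequences)[i], ]
    hits <- scanSequence(s, motifDef("B2", "ANWWAAAN", 0))
    expect_true(tr$offset %in% hits$offset)
  }

  # exactly-2-mismatch plants: present at budget 2, absent at budget 1
  # at the recorded position (background can hit elsewhere)
  acs <- motifDef("ACS", "WTTTAYRTTTW")
  sim2 <- simulateOriginSequences(
    20, list(list(motif = acs, count = 1, mismatches = 2)), seed = 41)
  for (i in 1:20) {
    s <- sim2$sequences[[i]]
    tr <- sim2$truth[i, ]
    h2 <- scanSequence(s, motifDef("ACS", "WTTTAYRTTTW", 2))
    h1 <- scanSequence(s, motifDef("ACS", "WTTTAYRTTTW", 1))
    at2 <- h2[h2$offset == tr$offset & h2$strand == tr$strand, ]
    expect_equal(nrow(at2), 1)
    expect_equal(at2$mismatches, 2)
    expect_false(any(h1$offset == tr$offset & h1$strand == tr$strand))
  }

  # over-packed windows are refused
  expect_error(simulateOriginSequences(
    1, list(list(motif = b2, count = 100, mismatches = 0)), width = 100),
    "fit|over-packed")
})

test_that("simulated protein tables plant effects reproducibly", {
  s1 <- simulateProteinTable(50, c(hitA = 1.5), seed = 9)
  s2 <- simulateProteinTable(50, c(hitA = 1.5), seed = 9)
  expect_identical(s1$table, s2$table)
  expect_equal(dim(s1$table), c(51, 6))
  # the planted effect shows up as roughly 2^1.5 target/control
  r <- median(s1$table["hitA", s1$targetCols]) /
       median(s1$table["hitA", s1$controlCols])
  expect_gt(r, 2^(1.5 - 0.6))
  expect_lt(r, 2^(1.5 + 0.6))
  expect_error(simulateProteinTable(10), ">= 30")
})

test_that("simulation annotation mirrors the config origins", {
  cfg <- studyConfig()
  ann <- simAnnotation(cfg, centromeres = data.frame(chrom = "chrS",
                                                     position = 250000))
  expect_equal(origins(ann)$name, c("oriEarly", "oriLate"))
  expect_equal(origins(ann)$rt, c(16, 30))
  expect_equal(origins(ann)$efficiency, c(90, 80))
  expect_equal(centromeres(ann)$position, 250000)
})
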