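test_that("Welch test matches the Welch-Satterthwaite formula oracle", {
  w0 <- welchTest(c(0.3, 0.4, 0.5), c(0.3, 0.4, 0.5))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)

  a <- c(0.50, 0.60, 0.55)
  b <- c(0.10, 0.15, 0.20)
  w <- welchTest(a, b)
  o <- oracleWelch(a, b)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)
  expect_equal(w$meanDiff, mean(b) - mean(a))

  # antisymmetry under group swap
  ws <- welchTest(b, a)
  expect_equal(ws$t, -w$t)
  expect_equal(ws$p, w$p)

  # degenerate zero-variance contracts
  d <- welchTest(c(1, 1, 1), c(2, 2, 2))
  expect_equal(d$p, 0)
  expect_true(d$degenerate)
  expect_error(welchTest(1, c(1, 2)), "at least 2")
})

test_that("per-bin testing flags exactly the constructed effect bins", {
  set.seed(88)
  cfg <- pipelineConfig()
  ctrl <- matrix(rnorm(300, 0, 0.02), 100, 3)
  trt <- matrix(rnorm(300, 0, 0.02), 100, 3)
  trt[41:50, ] <- trt[41:50, ] + 0.5
  bt <- testAllBins(ctrl, trt, chrom = "chr1", cfg = cfg)
  expect_equal(which(bt$significant), 41:50)
  expect_true(all(bt$meanDiff[41:50] > 0.4))

  # identical matrices: nothing passes
  bt2 <- testAllBins(ctrl, ctrl, cfg = cfg)
  expect_false(any(bt2$significant))

  # strong p but effect below the 0.1 gate: nothing passes
  trt3 <- ctrl + 0.05
  bt3 <- testAllBins(ctrl, trt3, cfg = cfg)
  expect_true(any(bt3$p < 0.05, na.rm = TRUE))
  expect_false(any(bt3$significant))

  # bins lacking 2 unmasked replicates per side are skipped with reason
  ctrl[1, 2:3] <- NA
  bt4 <- testAllBins(ctrl, trt, cfg = cfg)
  expect_false(bt4$tested[1])
  expect_true(is.na(bt4$p[1]))
})

test_that("region merging equals the run-length-encoding oracle", {
  cfg <- pipelineConfig(binWidth = 500)
  mkTests <- function(sig, diff) {
    data.frame(chrom = "c", bin = seq_along(sig) - 1L,
               meanA = 0, meanB = diff, meanDiff = diff,
               t = NA, p = ifelse(sig, 0.01, 0.5),
               nA = 3, nB = 3, tested = TRUE, significant = sig)
  }
  r1 <- mergeRegions(mkTests(c(TRUE, TRUE, FALSE, TRUE),
                             c(0.2, 0.2, 0, 0.2)), cfg)
  expect_equal(nrow(r1), 2)
  expect_equal(r1$start, c(0, 1500))
  expect_equal(r1$end, c(1000, 2000))
  expect_equal(r1$nBins, c(2, 1))

  # adjacent sign break splits the region
  r2 <- mergeRegions(mkTests(c(TRUE, TRUE), c(0.2, -0.2)), cfg)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$direction, c("advanced", "delayed"))

  set.seed(55)
  for (i in 1:500) {
    n <- sample(5:30, 1)
    sig <- runif(n) < 0.4
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    regions <- mergeRegions(mkTests(sig, sgn * 0.2), cfg)
    runs <- oracleMerge(sig, sgn)
    expect_equal(nrow(regions), length(runs))
    if (length(runs)) {
      expect_equal(regions$start, vapply(runs, function(r)
        (r[["first"]] - 1) * 500, numeric(1)))
      expect_equal(regions$nBins, vapply(runs, function(r)
        r[["last"]] - r[["first"]] + 1, numeric(1)))
      expect_equal(regions$direction, vapply(runs, function(r)
        if (r[["sign"]] > 0) "advanced" else "delayed", ""))
    }
    # idempotent under re-merging, invariant to chromosome order
    two <- rbind(mkTests(sig, sgn * 0.2),
                 within(mkTests(sig, sgn * 0.2), chrom <- "b"))
    fwd <- mergeRegions(two, cfg)
    bwd <- mergeRegions(two[rev(seq_len(nrow(two))), ], cfg)
    expect_equal(fwd[order(fwd$chrom, fwd$start), ]$start,
                 bwd[order(bwd$chrom, bwd$start), ]$start)
  }
})

test_that("region classification applies the 5-kb rule with CEN precedence", {
  ann <- genomeAnnotation(
    c(chr1 = 200000),
    origins = data.frame(name = c("ARS_a", "ARS_b"), chrom = "chr1",
                         position = c(23000, 101000)),
    centromeres = data.frame(chrom = "chr1", position = 102000))
  cfg <- pipelineConfig()
  regions <- data.frame(
    chrom = "chr1",
    start = c(15000, 150000, 99000),
    end = c(20000, 155000, 100000),
    direction = "advanced")
  cls <- classifyRegions(regions, ann, cfg)$class
  expect_equal(cls[1], "ORI")           # 3 kb from ARS_a, 82 kb from CEN
  expect_equal(cls[2], "inter-origin")  # > 5 kb from everything
  expect_equal(cls[3], "CEN")           # 1 kb from ARS_b, 2 kb from CEN

  # strictly-below threshold: exactly 5 kb away is NOT proximal
  edge <- data.frame(chrom = "chr1", start = 28000, end = 29000,
                     direction = "delayed")
  expect_equal(classifyRegions(edge, ann, cfg)$class, "inter-origin")
})

test_that("class summaries reproduce count/percentage arithmetic", {
  mk <- function(direction, ori, cen, total) {
    data.frame(chrom = "c", start = 0, end = 1, direction = direction,
               class = c(rep("ORI", ori), rep("CEN", cen),
                         rep("inter-origin", total - ori - cen)))
  }
  regions <- rbind(mk("delayed", 29, 10, 224), mk("advanced", 80, 12, 236))
  s <- summarizeClasses(regions)
  expect_equal(s$pctOri[s$direction == "delayed"], 13)
  expect_equal(s$pctOri[s$direction == "advanced"], 34)
  expect_equal(s$total, c(236, 224))
  # counts are conserved across classes
  expect_equal(s$cen + s$ori + s$interOrigin, s$total)

  s0 <- summarizeClasses(mk("delayed", 0, 0, 10))
  expect_equal(s0$pctOri[s0$direction == "delayed"], 0)
  expect_true(is.na(s0$pctOri[s0$direction == "advanced"]))
})

test_that("origin-class intersections equal exhaustive set operations", {
  out <- intersectOriginClasses(list(A = c("a", "b", "c"),
                                     B = c("b", "c", "d")))
  expect_equal(out$pairwise["A", "B"], 2L)
  expect_equal(out$exclusive, c(A = 1L, B = 1L))
  expect_equal(intersectOriginClasses(
    list(X = c("a", "b"), Y = c("c", "d")))$pairwise["X", "Y"], 0L)

  set.seed(77)
  catalog <- paste0("ARS", 1:300)
  sets <- lapply(1:4, function(i) sample(catalog, 50))
  names(sets) <- paste0("S", 1:4)
  out2 <- intersectOriginClasses(sets, catalog = catalog)
  for (i in 1:4) for (j in 1:4)
    expect_equal(out2$pairwise[i, j],
                 length(intersect(sets[[i]], sets[[j]])))
  expect_warning(
    intersectOriginClasses(list(A = "zzz", B = "a"), catalog = catalog),
    "not in catalog")
})

test_that("class-property comparison tests timing differences by Welch", {
  set.seed(14)
  ori <- data.frame(name = paste0("o", 1:40), chrom = "c", position = 1:40,
                    rt = c(rnorm(20, 10, 1), rnorm(20, 40, 1)),
                    efficiency = NA_real_)
  early <- paste0("o", 1:20)
  late <- paste0("o", 21:40)
  cmp <- compareClassProperties(early, late, ori, "rt")
  expect_true(cmp$testable)
  expect_lt(cmp$p, 0.05)
  expect_lt(cmp$meanA, cmp$meanB)

  same <- compareClassProperties(early, early, ori, "rt")
  expect_equal(same$p, 1)

  # variable absent on one side -> untestable
  none <- compareClassProperties(early, late, ori, "efficiency")
  expect_false(none$testable)
})
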