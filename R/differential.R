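#' @include AllClasses.R binning.R
NULL

#' Welch two-sample t-test with degenerate-input handling
#'
#' Unequal-variance (Welch) two-sided t-test between two groups of
#' replicate values, the per-bin statistic of the differential
#' replication-timing caller. The statistic is oriented so that its sign
#' matches \code{mean(b) - mean(a)} (treated minus control). Degenerate
#' inputs that the textbook formula cannot handle are resolved by
#' contract: zero variance in both groups with equal means gives t = 0,
#' p = 1; zero variance in both groups with unequal means gives p -> 0,
#' flagged degenerate.
#'
#' @param a,b numeric vectors of replicate values (each of length >= 2
#'   after NA removal).
#' @return list with \code{t}, \code{df}, \code{p}, \code{meanDiff}
#'   (\code{mean(b) - mean(a)}), \code{nA}, \code{nB} and logical
#'   \code{degenerate}.
#' @examples
#' welchTest(c(0.5, 0.6, 0.55), c(0.1, 0.15, 0.2))
#' @export
welchTest <- function(a, b) {
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2)
        stop("welchTest needs at least 2 finite values per group")
    if (any(!is.finite(a)) || any(!is.finite(b)))
        stop("welchTest needs finite values")
    va <- stats::var(a)
    vb <- stats::var(b)
    md <- mean(b) - mean(a)
    if (va == 0 && vb == 0) {
        if (md == 0)
            return(list(t = 0, df = NA_real_, p = 1, meanDiff = 0,
                        nA = length(a), nB = length(b), degenerate = FALSE))
        return(list(t = sign(md) * Inf, df = NA_real_, p = 0, meanDiff = md,
                    nA = length(a), nB = length(b), degenerate = TRUE))
    }
    ht <- t.test(b, a, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, meanDiff = md,
         nA = length(a), nB = length(b), degenerate = FALSE)
}

#' Per-bin Welch tests between two replicate matrices
#'
#' Runs [welchTest()] in every genomic bin of one chromosome, comparing
#' treated against control replicate log2-ratio values. Bins without at
#' least 2 unmasked replicates on each side are skipped (reported with
#' \code{tested = FALSE}). A bin is \code{significant} when its p-value
#' (optionally BH-adjusted across tested bins) is below \code{pCutoff}
#' and its absolute mean difference is at least \code{deltaMin}.
#'
#' @param control,treated numeric matrices (bins x replicates) aligned to
#'   the same binning; NA marks masked bins.
#' @param chrom chromosome name recorded in the output.
#' @param cfg a [pipelineConfig()].
#' @return data.frame with one row per bin: \code{chrom}, \code{bin}
#'   (0-based index), \code{meanA}, \code{meanB}, \code{meanDiff},
#'   \code{t}, \code{p}, \code{nA}, \code{nB}, \code{tested},
#'   \code{significant}.
#' @export
testAllBins <- function(control, treated, chrom = "chr",
                        cfg = pipelineConfig()) {
    control <- as.matrix(control)
    treated <- as.matrix(treated)
    if (nrow(control) != nrow(treated))
        stop("control and treated matrices are not aligned")
    n <- nrow(control)
    meanA <- meanB <- tt <- pp <- rep(NA_real_, n)
    nA <- rowSums(!is.na(control))
    nB <- rowSums(!is.na(treated))
    tested <- nA >= 2 & nB >= 2
    if (!any(tested))
        warning("no testable bins")
    for (i in which(tested)) {
        w <- welchTest(control[i, ], treated[i, ])
        meanA[i] <- mean(control[i, ], na.rm = TRUE)
        meanB[i] <- mean(treated[i, ], na.rm = TRUE)
        tt[i] <- w$t
        pp[i] <- w$p
    }
    pGate <- pp
    if (cfg$adjust == "BH")
        pGate[tested] <- p.adjust(pp[tested], method = "BH")
    md <- meanB - meanA
    sig <- tested & !is.na(pGate) & pGate < cfg$pCutoff &
        abs(md) >= cfg$deltaMin
    data.frame(chrom = chrom, bin = seq_len(n) - 1L,
               meanA = meanA, meanB = meanB, meanDiff = md,
               t = tt, p = pp, nA = nA, nB = nB,
               tested = tested, significant = sig)
}

#' Merge significant bins into differential regions
#'
#' Maximal runs of adjacent significant bins sharing the direction of the
#' mean difference become one region (gap tolerance 0 bins; a sign change
#' between adjacent significant bins breaks the region). The region
#' interval spans the first bin's start to the last bin's end, 0-based
#' half-open.
#'
#' @param binTests data.frame from [testAllBins()] (one or more
#'   chromosomes row-bound together).
#' @param cfg a [pipelineConfig()] (bin width).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{direction} ("advanced" for positive treated-minus-control
#'   differences, "delayed" for negative), \code{nBins},
#'   \code{maxAbsDiff}, \code{minP}.
#' @export
mergeRegions <- function(binTests, cfg = pipelineConfig()) {
    empty <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), direction = character(),
                        nBins = integer(), maxAbsDiff = numeric(),
                        minP = numeric())
    if (!nrow(binTests)) return(empty)
    out <- list()
    for (ch in unique(binTests$chrom)) {
        d <- binTests[binTests$chrom == ch, , drop = FALSE]
        d <- d[order(d$bin), , drop = FALSE]
        sig <- which(d$significant)
        if (!length(sig)) next
        sgn <- sign(d$meanDiff[sig])
        newRun <- c(TRUE, diff(d$bin[sig]) != 1L | diff(sgn) != 0)
        runId <- cumsum(newRun)
        for (r in unique(runId)) {
            idx <- sig[runId == r]
            out[[length(out) + 1L]] <- data.frame(
                chrom = ch,
                start = d$bin[idx[1]] * cfg$binWidth,
                end = (d$bin[idx[length(idx)]] + 1) * cfg$binWidth,
                direction = if (sgn[runId == r][1] > 0) "advanced"
                            else "delayed",
                nBins = length(idx),
                maxAbsDiff = max(abs(d$meanDiff[idx])),
                minP = min(d$p[idx]))
        }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Classify regions by genomic context
#'
#' A region is \code{CEN} if any centromere lies within
#' \code{proximityKb} of its boundary, else \code{ORI} if any origin
#' does, else \code{inter-origin}. CEN takes precedence over ORI because
#' centromeres sit atop centromeric origins. Distances are measured from
#' the region boundary to the feature point ([nearestFeatureDistance()]);
#' the threshold is strict (\code{< proximityKb * 1000}).
#'
#' @param regions data.frame from [mergeRegions()].
#' @param annot a [GenomeAnnotation-class] with origins (centromeres
#'   optional).
#' @param cfg a [pipelineConfig()] (\code{proximityKb}).
#' @return \code{regions} with an added \code{class} column.
#' @export
classifyRegions <- function(regions, annot, cfg = pipelineConfig()) {
    lim <- cfg$proximityKb * 1000
    cen <- annot@centromeres
    ori <- annot@origins
    cls <- character(nrow(regions))
    for (i in seq_len(nrow(regions))) {
        ch <- regions$chrom[i]
        dCen <- nearestFeatureDistance(regions$start[i], regions$end[i],
                                       cen$position[cen$chrom == ch])
        dOri <- nearestFeatureDistance(regions$start[i], regions$end[i],
                                       ori$position[ori$chrom == ch])
        cls[i] <- if (dCen < lim) "CEN"
                  else if (dOri < lim) "ORI"
                  else "inter-origin"
    }
    regions$class <- cls
    regions
}

#' Summarize region classes per direction
#'
#' Counts and integer-rounded percentages of centromeric,
#' origin-proximal and inter-origin regions among regions that advanced
#' or delayed replication.
#'
#' @param regions classified data.frame from [classifyRegions()].
#' @return data.frame with one row per direction: \code{direction},
#'   \code{total}, \code{cen}, \code{ori}, \code{interOrigin},
#'   \code{pctCen}, \code{pctOri}, \code{pctInterOrigin} (NA percentages
#'   when a direction has no regions).
#' @examples
#' # 29 of 224 delayed regions near origins is reported as 13%
#' r <- data.frame(chrom = "c", start = 0, end = 1, direction = "delayed",
#'                 class = rep(c("ORI", "inter-origin"), c(29, 195)))
#' summarizeClasses(r)$pctOri
#' @export
summarizeClasses <- function(regions) {
    dirs <- c("advanced", "delayed")
    rows <- lapply(dirs, function(d) {
        r <- regions[regions$direction == d, , drop = FALSE]
        tot <- nrow(r)
        cnt <- c(cen = sum(r$class == "CEN"),
                 ori = sum(r$class == "ORI"),
                 inter = sum(r$class == "inter-origin"))
        pct <- if (tot > 0) round(100 * cnt / tot) else rep(NA_real_, 3)
        data.frame(direction = d, total = tot,
                   cen = cnt[["cen"]], ori = cnt[["ori"]],
                   interOrigin = cnt[["inter"]],
                   pctCen = pct[[1]], pctOri = pct[[2]],
                   pctInterOrigin = pct[[3]])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Pairwise intersections of origin classes
#'
#' Cardinalities of all pairwise intersections between origin-class
#' member sets (e.g. activated/repressed classes from two different
#' regulators), plus per-set exclusive counts (members in no other set).
#'
#' @param sets named list of character vectors of origin names.
#' @param catalog optional character vector of valid origin names;
#'   members outside it trigger a warning but are kept.
#' @return list with \code{pairwise} (square count matrix; the diagonal
#'   holds set sizes) and \code{exclusive} (named vector).
#' @export
intersectOriginClasses <- function(sets, catalog = NULL) {
    stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
    sets <- lapply(sets, unique)
    if (!is.null(catalog)) {
        stray <- setdiff(unlist(sets), catalog)
        if (length(stray))
            warning("members not in catalog: ",
                    paste(head(stray, 5), collapse = ", "))
    }
    n <- length(sets)
    m <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
    for (i in seq_len(n))
        for (j in seq_len(n))
            m[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    excl <- vapply(seq_len(n), function(i)
        length(setdiff(sets[[i]], unlist(sets[-i]))), integer(1))
    names(excl) <- names(sets)
    list(pairwise = m, exclusive = excl)
}

#' Compare timing or efficiency between two origin classes
#'
#' Welch test of the per-origin replication time or efficiency between
#' two origin classes, as used to ask whether activated classes replicate
#' earlier / more efficiently than repressed ones.
#'
#' @param classA,classB character vectors of origin names.
#' @param origins origin catalog data.frame or [GenomeAnnotation-class].
#' @param variable "rt" or "efficiency".
#' @return list with \code{meanA}, \code{meanB}, \code{t}, \code{p},
#'   \code{nA}, \code{nB} and logical \code{testable} (FALSE with the
#'   other fields NA when fewer than 2 members per side carry the
#'   variable).
#' @export
compareClassProperties <- function(classA, classB, origins,
                                   variable = c("rt", "efficiency")) {
    variable <- match.arg(variable)
    if (is(origins, "GenomeAnnotation")) origins <- origins@origins
    va <- origins[[variable]][match(classA, origins$name)]
    vb <- origins[[variable]][match(classB, origins$name)]
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
    if (length(va) < 2 || length(vb) < 2)
        return(list(meanA = NA_real_, meanB = NA_real_, t = NA_real_,
                    p = NA_real_, nA = length(va), nB = length(vb),
                    testable = FALSE))
    w <- welchTest(va, vb)
    list(meanA = mean(va), meanB = mean(vb), t = w$t, p = w$p,
         nA = length(va), nB = length(vb), testable = TRUE)
}
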