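#' @include AllClasses.R differential.R
NULL

#' Read a protein abundance matrix
#'
#' Wide TSV: first column protein identifiers, remaining columns one
#' abundance value per run (condition/replicate). Empty cells become NA
#' (protein not detected in that run; missing, never zero).
#'
#' @param path TSV path.
#' @return numeric matrix, proteins x runs, with dimnames.
#' @export
readProteinTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1]]
    if (any(!is.na(m) & m < 0)) stop("abundances must be >= 0")
    m
}

#' Normalize abundance columns to equal totals
#'
#' Scales every run (column) so that all column totals equal the mean of
#' the original totals, correcting sample-loading differences.
#'
#' @param table numeric matrix, proteins x runs.
#' @return Matrix of the same shape with equal column sums.
#' @export
normalizeColumns <- function(table) {
    tot <- colSums(table, na.rm = TRUE)
    if (any(tot <= 0)) stop("zero column total; cannot normalize")
    sweep(table, 2, tot, "/") * mean(tot)
}

#' Median target/control abundance ratio for one protein
#'
#' The protein's enrichment ratio: median abundance over the target
#' replicates divided by median over the control replicates. Replicates
#' where the protein was not detected are missing, not zero. A zero or
#' missing control median makes the ratio a lower bound (flagged), using
#' \code{floor} as the control value when supplied.
#'
#' @param table numeric matrix, proteins x runs.
#' @param protein protein row name.
#' @param targetCols,controlCols column names or indices per condition.
#' @param floor optional positive value imputed for an undetected
#'   control.
#' @return list with \code{ratio}, logical \code{lowerBound} and
#'   logical \code{imputed}.
#' @export
medianRatio <- function(table, protein, targetCols, controlCols,
                        floor = NULL) {
    x <- table[protein, targetCols]
    y <- table[protein, controlCols]
    mT <- median(x, na.rm = TRUE)
    mC <- median(y, na.rm = TRUE)
    if (is.na(mT))
        return(list(ratio = NA_real_, lowerBound = FALSE, imputed = FALSE))
    if (is.na(mC) || mC <= 0) {
        if (is.null(floor))
            return(list(ratio = Inf, lowerBound = TRUE, imputed = FALSE))
        return(list(ratio = mT / floor, lowerBound = TRUE, imputed = TRUE))
    }
    list(ratio = mT / mC, lowerBound = FALSE, imputed = FALSE)
}

#' Background-variance test on log2 enrichment ratios
#'
#' Two-sided p-values for each protein's log2 ratio against the
#' background of non-changing proteins, which dominate the table. The
#' background location and scale are estimated robustly from the central
#' 80% of log2 ratios: the location is the core median, the scale the
#' core MAD rescaled by the normal-consistency factor for the trimming
#' (without it, an 80% truncation understates a normal background's
#' sigma by ~22% and inflates false positives). Each protein is scored
#' by its standardized deviation from that background. Scale
#' equivariant: doubling the spread doubles the estimated sigma and
#' leaves the ranking unchanged.
#'
#' @param log2Ratios named numeric vector of per-protein log2 ratios
#'   (length >= 30 so the background is estimable).
#' @param trim fraction trimmed from each tail before estimating the
#'   background (default 0.1, keeping the central 80%).
#' @return list with \code{p} (named vector), \code{z}, \code{center}
#'   and \code{sigma}.
#' @export
backgroundTest <- function(log2Ratios, trim = 0.1) {
    x <- log2Ratios[is.finite(log2Ratios)]
    if (length(x) < 30)
        stop("background test needs >= 30 proteins; use a per-protein ",
             "Welch test for smaller tables")
    qs <- quantile(x, c(trim, 1 - trim), names = FALSE)
    core <- x[x >= qs[1] & x <= qs[2]]
    center <- median(core)
    # mad() is normal-consistent for a full sample; the trimmed core's
    # median absolute deviation sits at qnorm(0.5 + 0.25 * (1 - 2 trim))
    # sigmas, so rescale to keep sigma unbiased under trimming
    sigma <- mad(core, center = center) *
        qnorm(0.75) / qnorm(0.5 + 0.25 * (1 - 2 * trim))
    if (sigma == 0) stop("degenerate background: zero spread")
    z <- (log2Ratios - center) / sigma
    p <- 2 * pnorm(-abs(z))
    list(p = p, z = z, center = center, sigma = sigma)
}

#' Score protein enrichment against control purifications
#'
#' The label-free enrichment pipeline: columns are normalized to equal
#' totals ([normalizeColumns()]), each protein gets a median
#' target/control ratio ([medianRatio()]; proteins undetected in the
#' control are imputed at the table's 1st-percentile abundance and
#' flagged), and p-values come from the background-variance test on the
#' log2 ratios ([backgroundTest()]). Tables with fewer than 30 proteins
#' fall back to a per-protein Welch test on log2 abundances, with a
#' warning. Proteins detected in fewer than \code{minReplicates} target
#' replicates are dropped.
#'
#' @param table numeric matrix, proteins x runs.
#' @param targetCols,controlCols column names or indices per condition.
#' @param minReplicates minimum target replicates with a detection
#'   (default 1).
#' @return data.frame with columns \code{protein}, \code{ratio},
#'   \code{log2fc}, \code{p}, \code{imputed}, \code{lowerBound}.
#' @seealso [enrichmentFilter()]
#' @export
scoreEnrichment <- function(table, targetCols, controlCols,
                            minReplicates = 1) {
    norm <- normalizeColumns(table)
    det <- rowSums(!is.na(norm[, targetCols, drop = FALSE]) &
                   norm[, targetCols, drop = FALSE] > 0)
    keep <- rownames(norm)[det >= minReplicates]
    pos <- norm[!is.na(norm) & norm > 0]
    floor <- quantile(pos, 0.01, names = FALSE)
    rows <- lapply(keep, function(pr) {
        r <- medianRatio(norm, pr, targetCols, controlCols, floor = floor)
        data.frame(protein = pr, ratio = r$ratio,
                   log2fc = log2(r$ratio),
                   imputed = r$imputed, lowerBound = r$lowerBound)
    })
    res <- do.call(rbind, rows)
    if (nrow(res) >= 30) {
        bt <- backgroundTest(stats::setNames(res$log2fc, res$protein))
        res$p <- unname(bt$p)
    } else {
        warning("fewer than 30 proteins: falling back to per-protein ",
                "Welch test")
        res$p <- vapply(res$protein, function(pr) {
            x <- log2(pmax(norm[pr, targetCols], floor))
            y <- log2(pmax(norm[pr, controlCols], floor))
            x <- x[is.finite(x)]; y <- y[is.finite(y)]
            if (length(x) < 2 || length(y) < 2) return(NA_real_)
            welchTest(y, x)$p
        }, numeric(1))
    }
    rownames(res) <- NULL
    res[, c("protein", "ratio", "log2fc", "p", "imputed", "lowerBound")]
}

#' Filter enriched proteins
#'
#' Proteins at least \code{fcMin}-fold enriched (inclusive: a ratio of
#' exactly 1.4 passes the default) with p-value at most \code{pCut}.
#' Monotone in \code{fcMin}: lowering it never removes a protein.
#'
#' @param results data.frame from [scoreEnrichment()].
#' @param fcMin minimum fold change (default 1.4).
#' @param pCut maximum p-value (default 0.05). Use \code{Inf} to apply
#'   the fold-change gate alone.
#' @return Subset of \code{results} flagged enriched.
#' @export
enrichmentFilter <- function(results, fcMin = 1.4, pCut = 0.05) {
    keep <- !is.na(results$ratio) & results$ratio >= fcMin &
        (!is.finite(pCut) | (!is.na(results$p) & results$p <= pCut))
    results[keep, , drop = FALSE]
}

#' Relative enrichment of one protein complex over another
#'
#' Mean enrichment ratio over the quantified members of complex A
#' divided by the mean over members of complex B (e.g. MCM2-7 over
#' canonical histones), with a Welch test across the member-level
#' enrichments. Identical member sets give a ratio of exactly 1.
#'
#' @param results data.frame from [scoreEnrichment()].
#' @param membersA,membersB character vectors of member protein names
#'   (>= 2 members of each must be quantified).
#' @return list with \code{ratio}, \code{p}, \code{nA}, \code{nB} and
#'   logical \code{testable}.
#' @export
complexRatio <- function(results, membersA, membersB) {
    rA <- results$ratio[match(membersA, results$protein)]
    rB <- results$ratio[match(membersB, results$protein)]
    rA <- rA[is.finite(rA)]
    rB <- rB[is.finite(rB)]
    if (length(rA) < 2 || length(rB) < 2)
        return(list(ratio = NA_real_, p = NA_real_,
                    nA = length(rA), nB = length(rB), testable = FALSE))
    w <- welchTest(rB, rA)   # sign irrelevant; two-sided p
    list(ratio = mean(rA) / mean(rB), p = w$p,
         nA = length(rA), nB = length(rB), testable = TRUE)
}

#' Multi-way overlaps of enriched protein sets
#'
#' Cardinalities of every 2-way and higher intersection among the
#' enriched sets of several purifications (the Venn counts).
#'
#' @param sets named list of character vectors.
#' @return data.frame with columns \code{sets} (comma-joined combination)
#'   and \code{count} (size of the intersection), for every combination
#'   of 2 or more sets.
#' @export
overlapSets <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
    sets <- lapply(sets, unique)
    n <- length(sets)
    rows <- list()
    for (k in 2:n) {
        for (combo in as.data.frame(combn(names(sets), k),
                                    stringsAsFactors = FALSE)) {
            inter <- Reduce(intersect, sets[combo])
            rows[[length(rows) + 1L]] <-
                data.frame(sets = paste(combo, collapse = ","),
                           count = length(inter))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
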