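#' @include AllClasses.R
NULL

## IUPAC letters as 4-bit base sets (A=1, C=2, G=4, T=8).
.IUPAC_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

.maskOf <- function(s) {
    m <- .IUPAC_MASK[strsplit(toupper(s), "")[[1]]]
    m[is.na(m)] <- 0L   # unknown characters match nothing
    unname(m)
}

.revComp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

.isPalindromic <- function(consensus)
    identical(toupper(consensus), .revComp(consensus))

## Degenerate-match rule: a consensus N matches any genome character;
## otherwise the genome base must be a concrete A/C/G/T inside the
## consensus letter's IUPAC set (ambiguous genome bases count as mismatch).
.positionMatches <- function(seqMask, consMaskLetter) {
    if (consMaskLetter == 15L) return(rep(TRUE, length(seqMask)))
    seqMask %in% c(1L, 2L, 4L, 8L) & bitwAnd(seqMask, consMaskLetter) > 0L
}

#' Count mismatches of a window against an IUPAC consensus
#'
#' Number of positions where the window base is not in the consensus
#' letter's IUPAC set. The window must be the same length as the
#' consensus. Ambiguous genome bases (anything outside A/C/G/T) count as
#' a mismatch unless the consensus letter is N.
#'
#' @param window DNA string over A/C/G/T (case-insensitive).
#' @param consensus IUPAC consensus string of the same length.
#' @return Integer mismatch count.
#' @examples
#' mismatchCount("AGTTAAAC", "ANWWAAAN")  # 0
#' mismatchCount("CGTTAAAC", "ANWWAAAN")  # 1
#' @export
mismatchCount <- function(window, consensus) {
    if (nchar(window) != nchar(consensus))
        stop("window and consensus must have equal length")
    sm <- .maskOf(window)
    cm <- .maskOf(consensus)
    mm <- 0L
    for (j in seq_along(cm))
        mm <- mm + !.positionMatches(sm[j], cm[j])
    as.integer(mm)
}

## All offsets (0-based) on one strand with mismatch count <= budget.
.scanStrand <- function(seqMask, consMask, maxMismatches) {
    L <- length(seqMask); m <- length(consMask)
    if (L < m)
        return(data.frame(offset = integer(), mismatches = integer()))
    nw <- L - m + 1L
    mm <- integer(nw)
    for (j in seq_len(m)) {
        ok <- .positionMatches(seqMask[j:(j + nw - 1L)], consMask[j])
        mm <- mm + !ok
    }
    hit <- which(mm <= maxMismatches)
    data.frame(offset = hit - 1L, mismatches = mm[hit])
}

#' Scan a sequence for a degenerate motif on both strands
#'
#' Reports every offset, on either strand, where the motif consensus
#' matches within its mismatch budget. Minus-strand hits are computed
#' against the reverse complement and reported in plus-strand window
#' coordinates (the offset of the leftmost base of the matched window).
#' Overlapping hits are all reported. For a palindromic consensus the
#' identical hit on the two strands at the same locus is counted once
#' (reported as plus strand).
#'
#' @param seq DNA string.
#' @param motif a [MotifDef-class].
#' @return data.frame with columns \code{offset} (0-based), \code{strand}
#'   ("+"/"-"), \code{mismatches} and \code{width}; zero rows if the
#'   sequence is shorter than the consensus.
#' @examples
#' hits <- scanSequence("CCCCANAAAAACCCC", motifDef("B2", "ANWWAAAN", 0))
#' @export
scanSequence <- function(seq, motif) {
    stopifnot(is(motif, "MotifDef"))
    cons <- motif@consensus
    m <- nchar(cons)
    sm <- .maskOf(seq)
    cm <- .maskOf(cons)
    L <- length(sm)
    plus <- .scanStrand(sm, cm, motif@maxMismatches)
    rcMask <- .maskOf(.revComp(paste(
        c("A", "C", "G", "T", "N")[match(sm, c(1L, 2L, 4L, 8L, 15L),
                                         nomatch = 5L)],
        collapse = "")))
    minus <- .scanStrand(rcMask, cm, motif@maxMismatches)
    if (nrow(minus))
        minus$offset <- L - m - minus$offset
    out <- rbind(
        if (nrow(plus)) cbind(plus, strand = "+") else NULL,
        if (nrow(minus)) cbind(minus, strand = "-") else NULL)
    if (is.null(out) || !nrow(out))
        return(data.frame(offset = integer(), strand = character(),
                          mismatches = integer(), width = integer()))
    if (.isPalindromic(cons))
        out <- out[!(out$strand == "-" &
                     out$offset %in% out$offset[out$strand == "+"]), ,
                   drop = FALSE]
    out <- out[order(out$offset, out$strand == "-"),
               c("offset", "strand", "mismatches")]   # locale-independent
    out$width <- m
    rownames(out) <- NULL
    out
}

#' B1 element search anchored to ACS hits
#'
#' For each ACS hit, examines the three 3-mers starting 17, 18 and 19 bp
#' 3' of the ACS end on the ACS's T-rich strand and reports those that
#' match the B1 consensus (WTW) within its mismatch budget. For a
#' minus-strand ACS the 3' direction runs leftward on the plus strand; B1
#' hits are reported in plus-strand coordinates with the ACS's strand. An
#' ACS whose offset window runs off the sequence contributes no B1 hit.
#'
#' @param seq the scanned DNA string (the same sequence the ACS hits were
#'   produced from).
#' @param acsHits data.frame of ACS hits from [scanSequence()].
#' @param b1 the B1 [MotifDef-class] (consensus, budget and the 3'
#'   offset window are taken from it).
#' @return data.frame of B1 hits with columns \code{offset}, \code{strand},
#'   \code{mismatches}, \code{width} and \code{acsOffset} (the anchoring
#'   ACS hit).
#' @export
scanB1 <- function(seq, acsHits, b1) {
    stopifnot(is(b1, "MotifDef"))
    empty <- data.frame(offset = integer(), strand = character(),
                        mismatches = integer(), width = integer(),
                        acsOffset = integer())
    if (!nrow(acsHits)) return(empty)
    m <- nchar(b1@consensus)
    offsets3p <- seq(b1@offsetMin, b1@offsetMax)
    L <- nchar(seq)
    rows <- list()
    for (i in seq_len(nrow(acsHits))) {
        aOff <- acsHits$offset[i]
        aW <- acsHits$width[i]
        for (d in offsets3p) {
            if (acsHits$strand[i] == "+") {
                s <- aOff + aW + d          # 0-based start of 3-mer
                if (s + m > L) next
                win <- substr(seq, s + 1L, s + m)
                mm <- mismatchCount(win, b1@consensus)
            } else {
                s <- aOff - d - m           # 3' runs leftward
                if (s < 0) next
                win <- .revComp(substr(seq, s + 1L, s + m))
                mm <- mismatchCount(win, b1@consensus)
            }
            if (mm <= b1@maxMismatches)
                rows[[length(rows) + 1L]] <-
                    data.frame(offset = s, strand = acsHits$strand[i],
                               mismatches = mm, width = m,
                               acsOffset = aOff)
        }
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Count motif occurrences per origin
#'
#' Scans each origin sequence for every motif and tabulates occurrence
#' counts. Anchored motifs (B1) are counted by chaining [scanB1()] to the
#' hits of their anchor motif; all others use [scanSequence()]. A motif
#' with \code{flankBp = f} is scanned over the core window extended by
#' \code{f} bp on each side; for that to be possible the supplied
#' sequences must already include \code{flankProvided} bp of flank on both
#' sides, and motifs with smaller flanks are scanned on the corresponding
#' inner subsequence. Origins with missing sequence (NA) are flagged and
#' get NA counts.
#'
#' @param seqs named character vector (or \code{Biostrings::DNAStringSet})
#'   of per-origin sequences, each consisting of the origin window plus
#'   \code{flankProvided} bp on each side.
#' @param motifs list of [MotifDef-class], e.g. [defaultMotifs()].
#' @param flankProvided bp of flank included on each side of every
#'   supplied sequence (default 0).
#' @return data.frame with column \code{origin}, one count column per
#'   motif, and logical \code{missing}.
#' @seealso [correlateCounts()]
#' @export
countMotifs <- function(seqs, motifs = defaultMotifs(), flankProvided = 0) {
    if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    if (is.null(names(seqs)))
        names(seqs) <- paste0("origin_", seq_along(seqs))
    mNames <- vapply(motifs, function(m) m@name, "")
    names(motifs) <- mNames
    maxFlank <- max(vapply(motifs, function(m) m@flankBp, 0))
    if (maxFlank > flankProvided)
        warning(sprintf(
            "motif flank (%g bp) exceeds provided flank (%g bp); scans are capped at the provided flank",
            maxFlank, flankProvided))
    out <- data.frame(origin = names(seqs))
    for (nm in mNames) out[[nm]] <- NA_integer_
    out$missing <- is.na(seqs) | !nzchar(ifelse(is.na(seqs), "", seqs))
    for (i in seq_along(seqs)) {
        if (out$missing[i]) next
        s <- seqs[[i]]
        L <- nchar(s)
        anchorHits <- list()
        for (nm in mNames) {
            mot <- motifs[[nm]]
            trim <- max(0, flankProvided - min(mot@flankBp, flankProvided))
            sub <- substr(s, trim + 1L, L - trim)
            if (!is.na(mot@anchor)) {
                aHits <- anchorHits[[mot@anchor]]
                if (is.null(aHits)) {
                    anchor <- motifs[[mot@anchor]]
                    if (is.null(anchor))
                        stop("anchor motif '", mot@anchor, "' not in motif set")
                    aTrim <- max(0, flankProvided -
                                     min(anchor@flankBp, flankProvided))
                    aHits <- scanSequence(substr(s, aTrim + 1L, L - aTrim),
                                          anchor)
                    anchorHits[[mot@anchor]] <- aHits
                }
                out[[nm]][i] <- nrow(scanB1(sub, aHits, mot))
            } else {
                hits <- scanSequence(sub, mot)
                anchorHits[[nm]] <- hits
                out[[nm]][i] <- nrow(hits)
            }
        }
    }
    out
}

#' Correlate motif counts with origin timing or efficiency
#'
#' Spearman rank correlation of per-origin motif counts against
#' replication time (minutes) or efficiency (percent), with a permutation
#' p-value: the variable is permuted across origins and the two-sided
#' p-value is the fraction of permuted |rho| at least as large as the
#' observed one (with the +1 correction). Origins missing either the
#' count or the variable are dropped pairwise. Constant counts or a
#' constant variable make the coefficient undefined; such motifs are
#' reported with NA and a reason.
#'
#' @param counts data.frame from [countMotifs()].
#' @param origins origin catalog data.frame (columns \code{name},
#'   \code{rt}, \code{efficiency}) or a [GenomeAnnotation-class].
#' @param variable "rt" or "efficiency".
#' @param nPerm number of permutations (seed the RNG for reproducibility).
#' @return data.frame with columns \code{motif}, \code{variable},
#'   \code{coefficient}, \code{pValue}, \code{n} and \code{reason}.
#' @export
correlateCounts <- function(counts, origins, variable = c("rt", "efficiency"),
                            nPerm = 1000) {
    variable <- match.arg(variable)
    if (is(origins, "GenomeAnnotation")) origins <- origins@origins
    v <- origins[[variable]][match(counts$origin, origins$name)]
    mNames <- setdiff(names(counts), c("origin", "missing"))
    res <- lapply(mNames, function(nm) {
        x <- counts[[nm]]
        if (!is.null(counts$missing)) x[counts$missing] <- NA
        keep <- !is.na(x) & !is.na(v)
        xx <- x[keep]; vv <- v[keep]
        n <- length(xx)
        if (n < 3)
            return(data.frame(motif = nm, variable = variable,
                              coefficient = NA_real_, pValue = NA_real_,
                              n = n, reason = "fewer than 3 origins"))
        if (sd(xx) == 0 || sd(vv) == 0)
            return(data.frame(motif = nm, variable = variable,
                              coefficient = NA_real_, pValue = NA_real_,
                              n = n, reason = "zero variance"))
        rho <- cor(xx, vv, method = "spearman")
        null <- vapply(seq_len(nPerm), function(i)
            cor(xx, sample(vv), method = "spearman"), numeric(1))
        p <- (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (nPerm + 1)
        data.frame(motif = nm, variable = variable, coefficient = rho,
                   pValue = p, n = n, reason = NA_character_)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
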