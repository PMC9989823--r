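#' @import methods
#' @importFrom stats median quantile rnorm rpois runif sd mad pnorm qnorm
#'   cor p.adjust t.test
#' @importFrom utils head read.delim write.table combn
NULL

## All genomic coordinates inside the package are 0-based, half-open
## ([start, end)), i.e. native BED convention. Readers for 1-based tables
## convert at the boundary; nothing downstream ever re-converts.

#' GenomeAnnotation: chromosomes, origins and centromeres
#'
#' The coordinate frame shared by every other module: chromosome names and
#' lengths, the replication-origin catalog (midpoint position, replication
#' time in minutes, firing efficiency in percent) and centromere positions.
#' Mitochondrial contigs are carried as a name set and excluded from all
#' read counting.
#'
#' @slot chromosomes data.frame with columns \code{name}, \code{length} (bp).
#' @slot mitoNames character vector of chromosome names treated as
#'   mitochondrial and excluded from counting.
#' @slot origins data.frame with columns \code{name}, \code{chrom},
#'   \code{position} (bp midpoint), \code{rt} (minutes, may be NA) and
#'   \code{efficiency} (percent in [0,100], may be NA), sorted by
#'   (chrom, position).
#' @slot centromeres data.frame with columns \code{chrom}, \code{position}.
#'
#' @seealso [genomeAnnotation()]
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
    representation(
        chromosomes = "data.frame",
        mitoNames   = "character",
        origins     = "data.frame",
        centromeres = "data.frame"
    )
)

setValidity("GenomeAnnotation", function(object) {
    msg <- character()
    ch <- object@chromosomes
    if (!all(c("name", "length") %in% names(ch)))
        msg <- c(msg, "chromosomes must have columns 'name' and 'length'")
    else {
        if (anyDuplicated(ch$name))
            msg <- c(msg, "chromosome names must be unique")
        if (any(ch$length <= 0))
            msg <- c(msg, "chromosome lengths must be positive")
    }
    ori <- object@origins
    need <- c("name", "chrom", "position", "rt", "efficiency")
    if (nrow(ori) > 0) {
        if (!all(need %in% names(ori)))
            msg <- c(msg, sprintf("origins must have columns %s",
                                  paste(need, collapse = ", ")))
        else {
            if (anyDuplicated(ori$name))
                msg <- c(msg, "origin names must be unique")
            if (!all(ori$chrom %in% ch$name))
                msg <- c(msg, "origin chrom not in chromosome table")
            else {
                len <- ch$length[match(ori$chrom, ch$name)]
                if (any(ori$position < 0 | ori$position >= len))
                    msg <- c(msg, "origin position outside [0, length)")
            }
            if (any(!is.na(ori$rt) & ori$rt < 0))
                msg <- c(msg, "origin rt must be >= 0 when present")
            eff <- ori$efficiency
            if (any(!is.na(eff) & (eff < 0 | eff > 100)))
                msg <- c(msg, "origin efficiency must be in [0,100]")
            o <- order(ori$chrom, ori$position)
            if (!identical(o, seq_len(nrow(ori))))
                msg <- c(msg, "origins must be sorted by (chrom, position)")
        }
    }
    cen <- object@centromeres
    if (nrow(cen) > 0) {
        if (!all(c("chrom", "position") %in% names(cen)))
            msg <- c(msg, "centromeres must have columns 'chrom', 'position'")
        else if (!all(cen$chrom %in% ch$name))
            msg <- c(msg, "centromere chrom not in chromosome table")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param chromosomes data.frame with columns \code{name}, \code{length}
#'   (bp), or a named numeric vector of lengths.
#' @param origins data.frame with columns \code{name}, \code{chrom},
#'   \code{position} and optionally \code{rt} (minutes) and
#'   \code{efficiency} (percent). Missing values stay \code{NA}, never 0.
#'   Rows are sorted by (chrom, position).
#' @param centromeres data.frame with columns \code{chrom}, \code{position},
#'   or NULL.
#' @param mitoNames chromosome names excluded as mitochondrial.
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' ann <- genomeAnnotation(
#'   c(chrIII = 316620),
#'   origins = data.frame(name = "ARS305", chrom = "chrIII",
#'                        position = 39158, rt = 14, efficiency = 85))
#' origins(ann)
#' @export
genomeAnnotation <- function(chromosomes,
                             origins = NULL,
                             centromeres = NULL,
                             mitoNames = c("chrM", "chrMito", "Mito")) {
    if (is.numeric(chromosomes) && !is.null(names(chromosomes)))
        chromosomes <- data.frame(name = names(chromosomes),
                                  length = as.numeric(chromosomes))
    chromosomes <- data.frame(name = as.character(chromosomes$name),
                              length = as.numeric(chromosomes$length))
    if (is.null(origins))
        origins <- data.frame(name = character(), chrom = character(),
                              position = numeric(), rt = numeric(),
                              efficiency = numeric())
    else {
        if (is.null(origins$rt)) origins$rt <- NA_real_
        if (is.null(origins$efficiency)) origins$efficiency <- NA_real_
        origins <- data.frame(name = as.character(origins$name),
                              chrom = as.character(origins$chrom),
                              position = as.numeric(origins$position),
                              rt = as.numeric(origins$rt),
                              efficiency = as.numeric(origins$efficiency))
        origins <- origins[order(origins$chrom, origins$position), ,
                           drop = FALSE]
        rownames(origins) <- NULL
    }
    if (is.null(centromeres))
        centromeres <- data.frame(chrom = character(), position = numeric())
    else
        centromeres <- data.frame(chrom = as.character(centromeres$chrom),
                                  position = as.numeric(centromeres$position))
    new("GenomeAnnotation", chromosomes = chromosomes,
        mitoNames = as.character(mitoNames),
        origins = origins, centromeres = centromeres)
}

#' BinnedTrack: fixed-width binned values for one sample
#'
#' One sequencing sample (a phase/condition/replicate combination) binned
#' into consecutive fixed-width genomic windows. The \code{stage} tag
#' records how far the track has moved through the profiling pipeline:
#' \code{raw} integer read-pair counts, \code{normalized} counts-per-million
#' style values, \code{smoothed} rolling means, or \code{log2ratio}
#' S/G1 log2 ratios. Masked bins (percentile filter, smoothing edges) are
#' \code{NA}.
#'
#' @slot sampleId character sample identifier.
#' @slot phase "G1" or "S" (or NA for derived tracks).
#' @slot condition free-text condition/genotype label.
#' @slot replicate replicate number.
#' @slot binWidth bin width in bp (500 or 1000 in practice).
#' @slot stage one of "raw", "normalized", "smoothed", "log2ratio".
#' @slot values named list, one numeric vector per chromosome; the vector
#'   length is \code{ceiling(chromosome length / binWidth)}.
#'
#' @seealso [binnedTrack()], [countFragments()], [normalizeTotal()],
#'   [rollingMean()], [log2Ratio()]
#' @exportClass BinnedTrack
setClass("BinnedTrack",
    representation(
        sampleId  = "character",
        phase     = "character",
        condition = "character",
        replicate = "numeric",
        binWidth  = "numeric",
        stage     = "character",
        values    = "list"
    )
)

.TRACK_STAGES <- c("raw", "normalized", "smoothed", "log2ratio")

setValidity("BinnedTrack", function(object) {
    msg <- character()
    if (length(object@stage) != 1L || !object@stage %in% .TRACK_STAGES)
        msg <- c(msg, sprintf("stage must be one of %s",
                              paste(.TRACK_STAGES, collapse = ", ")))
    if (length(object@binWidth) != 1L || object@binWidth <= 0)
        msg <- c(msg, "binWidth must be a single positive number")
    v <- object@values
    if (is.null(names(v)) || any(names(v) == ""))
        msg <- c(msg, "values must be a named list (one entry per chromosome)")
    if (!all(vapply(v, is.numeric, logical(1))))
        msg <- c(msg, "values must be numeric vectors")
    if (identical(object@stage, "raw")) {
        ok <- vapply(v, function(x) {
            x <- x[!is.na(x)]
            all(x >= 0) && all(x == round(x))
        }, logical(1))
        if (!all(ok))
            msg <- c(msg, "raw counts must be non-negative integers")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a BinnedTrack
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param binWidth bin width in bp.
#' @param stage pipeline stage tag (see [BinnedTrack-class]).
#' @param sampleId,phase,condition,replicate sample metadata.
#' @return A [BinnedTrack-class] object.
#' @export
binnedTrack <- function(values, binWidth, stage = "raw", sampleId = "",
                        phase = NA_character_, condition = "",
                        replicate = 1) {
    new("BinnedTrack", sampleId = as.character(sampleId),
        phase = as.character(phase), condition = as.character(condition),
        replicate = as.numeric(replicate), binWidth = as.numeric(binWidth),
        stage = stage, values = values)
}

#' MotifDef: a degenerate consensus motif definition
#'
#' An IUPAC consensus string with a mismatch budget, an optional
#' per-motif flank added to the scanned origin window (200 bp for the
#' Abf1/B3 site), and an optional positional rule anchoring the motif to
#' another motif's hits (the B1 element is searched 17-19 bp 3' of each
#' ACS hit on the ACS T-rich strand).
#'
#' @slot name motif name.
#' @slot consensus IUPAC consensus string (A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N).
#' @slot maxMismatches maximum mismatches per reported instance.
#' @slot flankBp bp added on both sides of the origin window for this
#'   motif only.
#' @slot anchor name of the anchoring motif for the positional rule, or NA.
#' @slot offsetMin,offsetMax 3' offset window (bp) of the positional rule.
#' @seealso [motifDef()], [defaultMotifs()], [scanSequence()], [scanB1()]
#' @exportClass MotifDef
setClass("MotifDef",
    representation(
        name          = "character",
        consensus     = "character",
        maxMismatches = "numeric",
        flankBp       = "numeric",
        anchor        = "character",
        offsetMin     = "numeric",
        offsetMax     = "numeric"
    )
)

.IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

setValidity("MotifDef", function(object) {
    msg <- character()
    cons <- object@consensus
    if (length(cons) != 1L || nchar(cons) == 0L)
        msg <- c(msg, "consensus must be a non-empty string")
    else {
        letters <- strsplit(toupper(cons), "")[[1]]
        if (!all(letters %in% .IUPAC_LETTERS))
            msg <- c(msg, "consensus contains non-IUPAC letters")
    }
    if (object@maxMismatches < 0)
        msg <- c(msg, "maxMismatches must be >= 0")
    if (object@flankBp < 0)
        msg <- c(msg, "flankBp must be >= 0")
    if (object@offsetMin > object@offsetMax)
        msg <- c(msg, "offsetMin must be <= offsetMax")
    if (length(msg)) msg else TRUE
})

#' Construct a MotifDef
#'
#' @param name motif name.
#' @param consensus IUPAC consensus string.
#' @param maxMismatches mismatch budget (default 2, as used for the
#'   origin-element survey).
#' @param flankBp per-motif flank in bp added on both sides of the origin
#'   window (default 0; the Abf1/B3 site uses 200).
#' @param anchor name of an anchoring motif for positionally constrained
#'   elements (the B1 element anchors to "ACS"), or NA for plain scanning.
#' @param offsetMin,offsetMax 3' offset window in bp for the anchored rule.
#' @return A [MotifDef-class] object.
#' @examples
#' motifDef("B2", "ANWWAAAN")
#' @export
motifDef <- function(name, consensus, maxMismatches = 2, flankBp = 0,
                     anchor = NA_character_, offsetMin = 17, offsetMax = 19) {
    new("MotifDef", name = as.character(name),
        consensus = toupper(as.character(consensus)),
        maxMismatches = as.numeric(maxMismatches),
        flankBp = as.numeric(flankBp), anchor = as.character(anchor),
        offsetMin = as.numeric(offsetMin), offsetMax = as.numeric(offsetMax))
}

#' Default origin motif set
#'
#' The five origin sequence elements surveyed at yeast origins: the 11-bp
#' ARS consensus sequence (ACS), its 17-bp extended form (eACS), the B1
#' element (WTW, searched 17-19 bp 3' of each ACS match on the ACS T-rich
#' strand), the B2 element (ANWWAAAN) and the B3 element (an Abf1 binding
#' site, scanned with 200 bp of additional flank on both sides). All use a
#' mismatch budget of 2. The ACS, eACS and B3 consensus strings are
#' configurable defaults taken from the origin literature.
#'
#' @return Named list of [MotifDef-class] objects.
#' @examples
#' names(defaultMotifs())
#' @export
defaultMotifs <- function() {
    list(
        ACS  = motifDef("ACS",  "WTTTAYRTTTW",       2, 0),
        eACS = motifDef("eACS", "WWWWTTTAYRTTTWGTT", 2, 0),
        B1   = motifDef("B1",   "WTW",               2, 0, anchor = "ACS"),
        B2   = motifDef("B2",   "ANWWAAAN",          2, 0),
        B3   = motifDef("B3",   "RTCRYNNNNNACG",     2, 200)
    )
}

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:", nrow(object@chromosomes), "chromosomes,",
        nrow(object@origins), "origins,",
        nrow(object@centromeres), "centromeres\n")
    if (nrow(object@chromosomes))
        cat("  genome:", sum(object@chromosomes$length), "bp;",
            "mito excluded:", paste(object@mitoNames, collapse = ","), "\n")
    nrt <- sum(!is.na(object@origins$rt))
    nef <- sum(!is.na(object@origins$efficiency))
    if (nrow(object@origins))
        cat("  origins with rt:", nrt, "; with efficiency:", nef, "\n")
    invisible(NULL)
})

setMethod("show", "BinnedTrack", function(object) {
    nb <- sum(vapply(object@values, length, integer(1)))
    cat(sprintf(
        "BinnedTrack '%s' [%s] phase=%s condition=%s rep=%g: %d bins x %g bp on %d chromosome(s)\n",
        object@sampleId, object@stage, object@phase, object@condition,
        object@replicate, nb, object@binWidth, length(object@values)))
    invisible(NULL)
})

setMethod("show", "MotifDef", function(object) {
    cat(sprintf("MotifDef %s: %s (<=%g mismatches, flank %g bp%s)\n",
                object@name, object@consensus, object@maxMismatches,
                object@flankBp,
                if (!is.na(object@anchor))
                    sprintf(", %g-%g bp 3' of %s", object@offsetMin,
                            object@offsetMax, object@anchor) else ""))
    invisible(NULL)
})
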