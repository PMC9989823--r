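#' @include AllClasses.R binning.R differential.R simulate.R
NULL

## Raw G1/S replicate tracks -> per-replicate log2 S/G1 tracks.
.replicateRatios <- function(tracks, cfg) {
    phases <- vapply(tracks, function(t) t@phase, "")
    reps <- vapply(tracks, function(t) t@replicate, numeric(1))
    g1 <- tracks[phases == "G1"]
    s <- tracks[phases == "S"]
    if (!length(g1) || !length(s))
        stop("need both G1 and S tracks")
    lapply(sort(unique(reps)), function(r) {
        gi <- which(vapply(g1, function(t) t@replicate, numeric(1)) == r)
        si <- which(vapply(s, function(t) t@replicate, numeric(1)) == r)
        if (!length(gi) || !length(si))
            stop("replicate ", r, " lacks a G1/S pair")
        gN <- normalizeTotal(g1[[gi[1]]])
        sN <- normalizeTotal(s[[si[1]]])
        if (cfg$smoothWindow > 1) {
            gN <- rollingMean(gN, cfg$smoothWindow)
            sN <- rollingMean(sN, cfg$smoothWindow)
        }
        log2Ratio(sN, gN, cfg)
    })
}

#' Call differential replication-timing regions between two conditions
#'
#' The full copy-number profiling and differential calling pipeline:
#' per replicate, G1 and S tracks are depth-normalized, smoothed
#' (rolling mean of \code{smoothWindow} bins; skipped when 1) and turned
#' into percentile-filtered log2 S/G1 ratios; every bin with at least 2
#' unmasked replicates per condition gets a Welch test of treated
#' against control; significant bins (p below \code{pCutoff} and
#' absolute mean difference at least \code{deltaMin}) are merged into
#' direction-consistent regions, which are classified by proximity to
#' centromeres and origins when an annotation is supplied.
#'
#' @param controlTracks,treatedTracks lists of raw [BinnedTrack-class]
#'   objects (G1 and S phases, matching replicate numbers), e.g. the
#'   \code{tracks} element of [simulateBinnedCounts()].
#' @param cfg a [pipelineConfig()].
#' @param annot optional [GenomeAnnotation-class] for region
#'   classification.
#' @param excludeReplicates character vector of sample ids dropped
#'   before analysis (manual outlier exclusion).
#' @return list with \code{binTests} (data.frame across chromosomes),
#'   \code{regions} (classified when \code{annot} given),
#'   \code{controlRatios} and \code{treatedRatios} (per-replicate log2
#'   tracks).
#' @export
callDifferentialRT <- function(controlTracks, treatedTracks,
                               cfg = pipelineConfig(), annot = NULL,
                               excludeReplicates = character()) {
    drop <- function(tr) tr[!vapply(tr, function(t)
        t@sampleId %in% excludeReplicates, logical(1))]
    ctrlR <- .replicateRatios(drop(controlTracks), cfg)
    trtR <- .replicateRatios(drop(treatedTracks), cfg)
    ctrlM <- averageReplicates(ctrlR)$matrix
    trtM <- averageReplicates(trtR)$matrix
    tests <- do.call(rbind, lapply(names(ctrlM), function(ch)
        testAllBins(ctrlM[[ch]], trtM[[ch]], chrom = ch, cfg = cfg)))
    rownames(tests) <- NULL
    regions <- mergeRegions(tests, cfg)
    if (!is.null(annot) && nrow(regions))
        regions <- classifyRegions(regions, annot, cfg)
    list(binTests = tests, regions = regions,
         controlRatios = ctrlR, treatedRatios = trtR)
}

#' Does any called region of a direction overlap a target within a margin?
#'
#' Convenience for recovery checks: TRUE when at least one region with
#' the requested direction lies within \code{marginBp} of the target
#' position (boundary distance).
#'
#' @param regions data.frame from [mergeRegions()]/[classifyRegions()].
#' @param chrom,position target locus.
#' @param direction "advanced" or "delayed" (NULL for either).
#' @param marginBp distance margin in bp (default 5000).
#' @return logical.
#' @export
regionsHitTarget <- function(regions, chrom, position, direction = NULL,
                             marginBp = 5000) {
    r <- regions[regions$chrom == chrom, , drop = FALSE]
    if (!is.null(direction))
        r <- r[r$direction == direction, , drop = FALSE]
    if (!nrow(r)) return(FALSE)
    any(vapply(seq_len(nrow(r)), function(i)
        nearestFeatureDistance(r$start[i], r$end[i], position) <= marginBp,
        logical(1)))
}
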