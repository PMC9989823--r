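#' @include AllClasses.R AllGenerics.R
NULL

#' Pipeline configuration for replication-timing profiling
#'
#' Bundles the thresholds of the copy-number profiling and differential
#' calling pipeline. Defaults follow the published analysis settings:
#' read pairs counted in 500 bp windows after a mapping-quality filter of
#' 12; the lowest 5th percentile of normalized bin values masked before
#' the log2 transformation; per-bin Welch test gated at p < 0.05 with a
#' mean log2 difference of at least 0.1; region context classified within
#' 5 kb of centromeres or origins. The smoothing window (in bins) is a
#' package default of 5, chosen to smooth visibly at 500-bp bins without
#' erasing single-origin peaks.
#'
#' @param binWidth bin width in bp (500 or 1000).
#' @param mapqMin minimum mapping quality for a fragment to be counted.
#' @param smoothWindow rolling-mean window in bins (odd; 1 disables).
#' @param lowPercentile percentile (0-100) of normalized bin values masked
#'   before the log2 ratio.
#' @param pCutoff per-bin Welch p-value cutoff.
#' @param deltaMin minimum absolute mean log2 difference.
#' @param proximityKb proximity threshold (kb) for region classification.
#' @param adjust p-value adjustment across bins: "none" (default,
#'   matching the published per-bin gate) or "BH".
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(binWidth = 500, mapqMin = 12, smoothWindow = 5,
                           lowPercentile = 5, pCutoff = 0.05,
                           deltaMin = 0.1, proximityKb = 5,
                           adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    stopifnot(binWidth > 0, mapqMin >= 0, smoothWindow >= 1,
              lowPercentile > 0, lowPercentile < 100,
              pCutoff > 0, deltaMin >= 0, proximityKb > 0)
    if (smoothWindow %% 2 == 0)
        stop("smoothWindow must be odd")
    structure(list(binWidth = binWidth, mapqMin = mapqMin,
                   smoothWindow = smoothWindow,
                   lowPercentile = lowPercentile, pCutoff = pCutoff,
                   deltaMin = deltaMin, proximityKb = proximityKb,
                   adjust = adjust),
              class = "PipelineConfig")
}

.nBins <- function(len, bw) as.integer(ceiling(len / bw))

#' Count aligned fragments into fixed-width bins
#'
#' Assigns each read-pair fragment passing the mapping-quality filter to
#' exactly one bin by its midpoint. Fragments on mitochondrial
#' chromosomes are dropped. The genome-wide sum of counts equals the
#' number of passing, non-mitochondrial fragments.
#'
#' @param frags data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based, half-open) and \code{mapq}.
#' @param annot a [GenomeAnnotation-class].
#' @param cfg a [pipelineConfig()] (bin width and MAPQ threshold).
#' @param sampleId,phase,condition,replicate metadata stored on the track.
#' @return A [BinnedTrack-class] with stage \code{"raw"} covering every
#'   non-mitochondrial chromosome of \code{annot}.
#' @export
countFragments <- function(frags, annot, cfg = pipelineConfig(),
                           sampleId = "", phase = NA_character_,
                           condition = "", replicate = 1) {
    ch <- annot@chromosomes
    ch <- ch[!ch$name %in% annot@mitoNames, , drop = FALSE]
    frags <- frags[!frags$chrom %in% annot@mitoNames, , drop = FALSE]
    unknown <- setdiff(unique(frags$chrom), ch$name)
    if (length(unknown))
        stop("fragment chromosome not in annotation: ", unknown[1])
    len <- ch$length[match(frags$chrom, ch$name)]
    bad <- which(frags$end > len)
    if (length(bad))
        stop(sprintf(
            "fragment beyond chromosome end: %s:%g-%g (length %g)",
            frags$chrom[bad[1]], frags$start[bad[1]], frags$end[bad[1]],
            len[bad[1]]))
    frags <- frags[frags$mapq >= cfg$mapqMin, , drop = FALSE]
    vals <- lapply(seq_len(nrow(ch)), function(i) {
        nb <- .nBins(ch$length[i], cfg$binWidth)
        f <- frags[frags$chrom == ch$name[i], , drop = FALSE]
        if (!nrow(f)) return(numeric(nb))
        mid <- (f$start + f$end) %/% 2
        bin <- mid %/% cfg$binWidth
        tabulate(bin + 1L, nbins = nb)
    })
    names(vals) <- ch$name
    binnedTrack(vals, cfg$binWidth, stage = "raw", sampleId = sampleId,
                phase = phase, condition = condition, replicate = replicate)
}

#' Normalize a raw track by its total count
#'
#' Each bin is divided by the genome-wide total and scaled by 1e6
#' (CPM-like), so tracks from different sequencing depths become directly
#' comparable and the genome-wide sum is 1e6. The constant cancels in
#' S/G1 ratios.
#'
#' @param track a raw [BinnedTrack-class].
#' @return A [BinnedTrack-class] with stage \code{"normalized"}.
#' @export
normalizeTotal <- function(track) {
    stopifnot(is(track, "BinnedTrack"))
    tot <- sum(unlist(track@values), na.rm = TRUE)
    if (tot <= 0) stop("zero total count; cannot normalize")
    out <- track
    out@values <- lapply(track@values, function(v) v / tot * 1e6)
    out@stage <- "normalized"
    validObject(out)
    out
}

.rollmeanVec <- function(x, window) {
    stopifnot(window >= 1, window %% 2 == 1)
    if (window == 1) return(x)
    if (window > length(x)) {
        warning("window larger than vector; all values set to NA")
        return(rep(NA_real_, length(x)))
    }
    zoo::rollmean(x, window, fill = NA, align = "center")
}

#' @describeIn rollingMean centered moving average of a numeric vector;
#'   \code{(window-1)/2} edge positions become NA (no partial windows)
#'   and NA inputs propagate into every window containing them.
#' @export
setMethod("rollingMean", "numeric", function(x, window) {
    .rollmeanVec(x, window)
})

#' @describeIn rollingMean per-chromosome rolling mean of a
#'   [BinnedTrack-class]; the result has stage \code{"smoothed"}.
#' @export
setMethod("rollingMean", "BinnedTrack", function(x, window) {
    out <- x
    out@values <- lapply(x@values, .rollmeanVec, window = window)
    out@stage <- "smoothed"
    out
})

#' Log2 S/G1 ratio with low-percentile masking
#'
#' Per-bin \code{log2(S / G1)} of an S-phase track against the paired
#' G1-phase track of the same replicate. Before the log2 transformation,
#' bins whose normalized value falls in the lowest \code{lowPercentile}
#' of either sample (computed genome-wide per sample over non-NA bins)
#' are masked, which removes near-empty bins that would otherwise blow up
#' the ratio. A bin with a zero G1 value that still survives the filter
#' is masked with a warning rather than producing an infinite ratio.
#'
#' @param sTrack,g1Track normalized (optionally smoothed)
#'   [BinnedTrack-class] objects with identical binning.
#' @param cfg a [pipelineConfig()] (\code{lowPercentile}).
#' @return A [BinnedTrack-class] with stage \code{"log2ratio"}, carrying
#'   the S track's condition and replicate.
#' @export
log2Ratio <- function(sTrack, g1Track, cfg = pipelineConfig()) {
    stopifnot(is(sTrack, "BinnedTrack"), is(g1Track, "BinnedTrack"))
    if (sTrack@binWidth != g1Track@binWidth)
        stop("bin widths differ")
    if (!identical(names(sTrack@values), names(g1Track@values)))
        stop("chromosome sets differ")
    sAll <- unlist(sTrack@values)
    gAll <- unlist(g1Track@values)
    qS <- quantile(sAll, cfg$lowPercentile / 100, na.rm = TRUE, names = FALSE)
    qG <- quantile(gAll, cfg$lowPercentile / 100, na.rm = TRUE, names = FALSE)
    zeroG1 <- FALSE
    vals <- mapply(function(s, g) {
        mask <- is.na(s) | is.na(g) | s < qS | g < qG
        out <- rep(NA_real_, length(s))
        bad <- !mask & g <= 0
        if (any(bad)) { zeroG1 <<- TRUE; mask <- mask | bad }
        out[!mask] <- log2(s[!mask] / g[!mask])
        out
    }, sTrack@values, g1Track@values, SIMPLIFY = FALSE)
    if (zeroG1)
        warning("bins with zero G1 value survived the percentile filter; masked")
    binnedTrack(vals, sTrack@binWidth, stage = "log2ratio",
                sampleId = paste0(sTrack@sampleId, "/", g1Track@sampleId),
                phase = NA_character_, condition = sTrack@condition,
                replicate = sTrack@replicate)
}

#' Average replicate log2-ratio tracks
#'
#' Per-bin mean across replicates with pairwise deletion of masked (NA)
#' bins. The per-replicate matrix is retained so the per-bin Welch test
#' can be run on exactly the values that were averaged.
#'
#' @param tracks list of log2-ratio [BinnedTrack-class] objects with
#'   identical binning.
#' @return list with \code{average} (a [BinnedTrack-class]) and
#'   \code{matrix} (named list of bins x replicates matrices, one per
#'   chromosome). A single replicate is returned as its own average with
#'   a warning (no variance available).
#' @export
averageReplicates <- function(tracks) {
    stopifnot(length(tracks) >= 1,
              all(vapply(tracks, function(t) is(t, "BinnedTrack"),
                         logical(1))))
    chroms <- names(tracks[[1]]@values)
    for (t in tracks)
        if (!identical(names(t@values), chroms))
            stop("replicate tracks are not identically binned")
    if (length(tracks) == 1)
        warning("single replicate: no variance available")
    mats <- lapply(chroms, function(ch)
        do.call(cbind, lapply(tracks, function(t) t@values[[ch]])))
    names(mats) <- chroms
    avg <- lapply(mats, function(m) {
        v <- rowMeans(m, na.rm = TRUE)
        v[is.nan(v)] <- NA_real_
        v
    })
    tmpl <- tracks[[1]]
    list(average = binnedTrack(avg, tmpl@binWidth, stage = "log2ratio",
                               sampleId = "replicate_mean",
                               condition = tmpl@condition,
                               replicate = length(tracks)),
         matrix = mats)
}

#' Averaged, smoothed ChIP-Exo strand profile
#'
#' Element-wise mean of forward- and reverse-strand coverage followed by
#' a centered rolling mean.
#'
#' @param fwd,rev equal-length numeric coverage vectors.
#' @param window odd rolling-mean window.
#' @return Numeric vector of the same length (edges NA).
#' @export
chipexoProfile <- function(fwd, rev, window = 5) {
    if (length(fwd) != length(rev))
        stop("forward and reverse coverage lengths differ")
    .rollmeanVec((fwd + rev) / 2, window)
}

#' Write a BinnedTrack as bedgraph
#'
#' Four-column bedgraph (chrom, start, end, value), 0-based half-open;
#' NA bins are skipped. The last bin of a chromosome is clipped to the
#' chromosome length when one is supplied.
#'
#' @param track a [BinnedTrack-class].
#' @param path output path.
#' @param annot optional [GenomeAnnotation-class] used to clip the final
#'   bin.
#' @return Invisibly, \code{path}.
#' @export
writeBedGraph <- function(track, path, annot = NULL) {
    stopifnot(is(track, "BinnedTrack"))
    bw <- track@binWidth
    rows <- lapply(names(track@values), function(ch) {
        v <- track@values[[ch]]
        n <- length(v)
        start <- (seq_len(n) - 1L) * bw
        end <- start + bw
        if (!is.null(annot)) {
            len <- annot@chromosomes$length[
                match(ch, annot@chromosomes$name)]
            if (!is.na(len)) end[n] <- min(end[n], len)
        }
        keep <- !is.na(v)
        data.frame(chrom = ch, start = start[keep], end = end[keep],
                   value = v[keep])
    })
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a bedgraph file into a BinnedTrack
#'
#' Expects consecutive fixed-width bins (the format this package writes);
#' bins absent from the file become NA.
#'
#' @param path bedgraph path.
#' @param annot a [GenomeAnnotation-class] giving chromosome lengths.
#' @param binWidth bin width in bp.
#' @param stage stage tag to assign (default "normalized").
#' @param ... further metadata passed to [binnedTrack()].
#' @return A [BinnedTrack-class].
#' @export
readBedGraph <- function(path, annot, binWidth, stage = "normalized", ...) {
    df <- read.delim(path, header = FALSE,
                     col.names = c("chrom", "start", "end", "value"))
    ch <- annot@chromosomes
    ch <- ch[!ch$name %in% annot@mitoNames, , drop = FALSE]
    vals <- lapply(seq_len(nrow(ch)), function(i) {
        nb <- .nBins(ch$length[i], binWidth)
        v <- rep(NA_real_, nb)
        d <- df[df$chrom == ch$name[i], , drop = FALSE]
        if (nrow(d)) {
            bin <- d$start %/% binWidth + 1L
            v[bin] <- d$value
        }
        v
    })
    names(vals) <- ch$name
    binnedTrack(vals, binWidth, stage = stage, ...)
}
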