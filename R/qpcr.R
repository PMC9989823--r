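#' @include AllClasses.R
NULL

#' Read a qPCR quantity table
#'
#' Tab-separated with header columns \code{fraction} (purification
#' fraction: CX, P, IN, FT, B, E, or a time point label), \code{locus},
#' \code{quantity} (relative quantity, > 0), optional \code{spike}
#' (spike-in plasmid quantity) and optional \code{fractionAssayed}
#' (proportion of the sample loaded into the assay, in (0, 1]; defaults
#' to 1 when absent).
#'
#' @param path TSV path.
#' @return data.frame with the columns above.
#' @export
readQpcrTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
    if (!all(c("fraction", "locus", "quantity") %in% names(df)))
        stop("qPCR table needs columns 'fraction', 'locus', 'quantity'")
    if (is.null(df$spike)) df$spike <- NA_real_
    if (is.null(df$fractionAssayed)) df$fractionAssayed <- 1
    if (any(!is.na(df$quantity) & df$quantity <= 0))
        stop("quantities must be > 0")
    fa <- df$fractionAssayed
    if (any(!is.na(fa) & (fa <= 0 | fa > 1)))
        stop("fractionAssayed must be in (0, 1]")
    df
}

#' Convert quantification cycles to relative quantities
#'
#' Relative quantity \code{efficiency^(-Cq)}; with the default perfect
#' amplification efficiency of 2 this is \code{2^-Cq}.
#'
#' @param cq numeric Cq values.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return Relative quantities.
#' @export
cqToQuantity <- function(cq, efficiency = 2) {
    stopifnot(efficiency > 1)
    efficiency^(-cq)
}

.qpcrRow <- function(table, fraction, locus) {
    i <- which(table$fraction == fraction & table$locus == locus)
    if (!length(i))
        stop(sprintf("no qPCR row for fraction '%s', locus '%s'",
                     fraction, locus))
    table[i[1], , drop = FALSE]
}

#' Spike-in normalized recovery of a locus in a purification fraction
#'
#' Percent of the input material recovered in a fraction, using the
#' spike-in plasmid (added in equal amount to every assayed sample) to
#' normalize for extraction efficiency, and correcting for the different
#' proportions of each sample loaded into the assay:
#' \deqn{recovery = 100 \cdot \frac{(locus/spike)_{frac} / assayed_{frac}}
#'   {(locus/spike)_{input} / assayed_{input}}}
#'
#' @param table data.frame as from [readQpcrTable()].
#' @param fraction fraction to evaluate (e.g. "E" for elution).
#' @param locus locus name.
#' @param input name of the input fraction (default "IN").
#' @return Recovery in percent.
#' @examples
#' tab <- data.frame(fraction = c("IN", "E"), locus = "ARS305",
#'                   quantity = c(1, 1), spike = c(1, 1),
#'                   fractionAssayed = c(0.001, 0.01))
#' spikeRecovery(tab, "E", "ARS305")  # 10
#' @export
spikeRecovery <- function(table, fraction, locus, input = "IN") {
    f <- .qpcrRow(table, fraction, locus)
    i <- .qpcrRow(table, input, locus)
    if (is.na(f$spike) || is.na(i$spike))
        stop("spike quantities required for spike-in recovery")
    rf <- (f$quantity / f$spike) / f$fractionAssayed
    ri <- (i$quantity / i$spike) / i$fractionAssayed
    100 * rf / ri
}

#' Fold enrichment of a target locus over a reference locus
#'
#' Enrichment of a purified target locus relative to an unrelated
#' single-copy reference locus (PDC1 by default), comparing elution to
#' input: \code{(target/reference)_elution / (target/reference)_input}.
#' If the reference is undetected in the elution, the smallest positive
#' quantity in the elution rows is substituted as a detection floor and
#' the result is flagged as a lower bound.
#'
#' @param table data.frame as from [readQpcrTable()].
#' @param target target locus name.
#' @param reference reference locus name (default "PDC1").
#' @param elution,input fraction names (defaults "E" and "IN").
#' @return list with \code{value} (dimensionless fold enrichment) and
#'   logical \code{lowerBound}.
#' @export
foldEnrichment <- function(table, target, reference = "PDC1",
                           elution = "E", input = "IN") {
    tE <- .qpcrRow(table, elution, target)$quantity
    tI <- .qpcrRow(table, input, target)$quantity
    rI <- .qpcrRow(table, input, reference)$quantity
    rEr <- .qpcrRow(table, elution, reference)
    rE <- rEr$quantity
    lower <- FALSE
    if (is.na(rE) || rE <= 0) {
        eQ <- table$quantity[table$fraction == elution]
        rE <- min(eQ[!is.na(eQ) & eQ > 0])
        lower <- TRUE
    }
    list(value = (tE / rE) / (tI / rI), lowerBound = lower)
}

#' Purity of target-derived DNA from fold enrichment
#'
#' Fraction of DNA molecules derived from the target locus, given the
#' fold enrichment \eqn{F} of the target over single-copy background, the
#' target length \eqn{L} (~1 kb for an excised origin domain) and the
#' genome size \eqn{G} (~12,000 kb for yeast):
#' \deqn{purity = 100 \cdot \frac{F L}{F L + (G - L)}}
#' The enriched target competes against the \eqn{G - L} kb of genomic
#' background present at single-copy level.
#'
#' @param foldEnrichment dimensionless fold enrichment (> 0), e.g. the
#'   \code{value} from [foldEnrichment()].
#' @param targetKb target locus length in kb (default 1).
#' @param genomeKb genome size in kb (default 12000).
#' @return Purity in percent, strictly increasing in the enrichment and
#'   bounded in (0, 100).
#' @examples
#' purityEstimate(30000)    # ~71.4
#' purityEstimate(150000)   # ~92.6
#' @export
purityEstimate <- function(foldEnrichment, targetKb = 1, genomeKb = 12000) {
    stopifnot(all(foldEnrichment > 0), targetKb > 0, genomeKb > targetKb)
    fl <- foldEnrichment * targetKb
    100 * fl / (fl + (genomeKb - targetKb))
}

#' Copy-number ratio time course between loci
#'
#' Replication-timing readout by qPCR: each locus's copy number is first
#' normalized to its own G1 (t = 0) value, then expressed as a ratio to a
#' late-replicating reference locus at every shared time point. An early
#' locus rises above 1 while it replicates ahead of the reference and
#' returns to ~1 once S-phase completes. The ratio at t = 0 is 1 by
#' construction; time points missing for either locus are gaps, not
#' interpolated. The result is invariant to global qPCR scale factors.
#'
#' @param copyNumbers data.frame with columns \code{locus}, \code{time}
#'   (minutes) and \code{copyNumber}.
#' @param locus locus of interest (e.g. an early origin).
#' @param reference late-replicating reference locus.
#' @return data.frame with columns \code{time} and \code{ratio}.
#' @export
rtRatioTimecourse <- function(copyNumbers, locus, reference) {
    get0 <- function(l) {
        v <- copyNumbers$copyNumber[copyNumbers$locus == l &
                                    copyNumbers$time == 0]
        if (!length(v))
            stop(sprintf("locus '%s' has no G1 (t = 0) value", l))
        v[1]
    }
    l0 <- get0(locus)
    r0 <- get0(reference)
    lt <- copyNumbers[copyNumbers$locus == locus, , drop = FALSE]
    rt <- copyNumbers[copyNumbers$locus == reference, , drop = FALSE]
    times <- sort(intersect(lt$time, rt$time))
    ratio <- vapply(times, function(t) {
        (lt$copyNumber[lt$time == t][1] / l0) /
        (rt$copyNumber[rt$time == t][1] / r0)
    }, numeric(1))
    data.frame(time = times, ratio = ratio)
}
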