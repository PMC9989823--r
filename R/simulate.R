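#' @include AllClasses.R binning.R
NULL

#' Configuration for the origin-firing / fork-progression simulator
#'
#' Describes a stochastic replication model: per cell, each origin fires
#' with probability \code{efficiency} at a time drawn from
#' Normal(\code{firingTime}, \code{firingSd}); from a fired origin two
#' forks move outward at \code{forkSpeed}; a locus is replicated once any
#' fork reaches it. In HU mode (hydroxyurea arrest), fork travel is
#' capped at \code{huCapBp} from the origin, which confines replication
#' to a ~5 kb region around early origins. Defaults reflect the
#' experimental design being emulated: G1 sample at t = 0 and S sample at
#' t = 24 min, fork speed 1.5 kb/min, firing-time SD 3 min, 3 replicates.
#' Sequencing depth defaults to 2000 read pairs per bin, giving per-bin
#' copy-number noise of a few percent, comparable to published sorted
#' S/G1 profiles.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param origins data.frame with columns \code{name}, \code{chrom},
#'   \code{position} (bp), \code{firingTime} (min), \code{firingSd}
#'   (min) and \code{efficiency} (probability in [0,1]).
#' @param forkSpeed fork speed in kb/min.
#' @param sampleTimes named numeric vector of sampling times in minutes
#'   (default \code{c(G1 = 0, S = 24)}).
#' @param huMode logical; cap fork travel at \code{huCapBp}.
#' @param huCapBp maximum fork travel distance in bp under HU.
#' @param replicates number of replicates.
#' @param readsPerSample total read pairs per sample (default: 2000 per
#'   bin).
#' @param binWidth bin width in bp.
#' @param noiseSd SD of the log-normal per-bin multiplicative bias,
#'   shared across the samples of a replicate (so it cancels in S/G1).
#' @param condition condition label stamped on simulated tracks.
#' @return A list of class \code{SimConfig}.
#' @export
simConfig <- function(chromLengths, origins, forkSpeed = 1.5,
                      sampleTimes = c(G1 = 0, S = 24), huMode = FALSE,
                      huCapBp = 5000, replicates = 3,
                      readsPerSample = NULL, binWidth = 500,
                      noiseSd = 0.05, condition = "control") {
    stopifnot(is.numeric(chromLengths), !is.null(names(chromLengths)),
              all(chromLengths > 0), forkSpeed > 0, huCapBp > 0,
              replicates >= 1, binWidth > 0, noiseSd >= 0)
    need <- c("name", "chrom", "position", "firingTime", "firingSd",
              "efficiency")
    miss <- setdiff(need, names(origins))
    if (length(miss))
        stop("origins missing columns: ", paste(miss, collapse = ", "))
    stopifnot(all(origins$chrom %in% names(chromLengths)),
              all(origins$firingTime >= 0), all(origins$firingSd >= 0),
              all(origins$efficiency >= 0 & origins$efficiency <= 1))
    nbins <- sum(ceiling(chromLengths / binWidth))
    if (is.null(readsPerSample)) readsPerSample <- 2000 * nbins
    stopifnot(readsPerSample > 0)
    structure(list(chromLengths = chromLengths,
                   origins = as.data.frame(origins), forkSpeed = forkSpeed,
                   sampleTimes = sampleTimes, huMode = huMode,
                   huCapBp = huCapBp, replicates = replicates,
                   readsPerSample = readsPerSample, binWidth = binWidth,
                   noiseSd = noiseSd, condition = condition),
              class = "SimConfig")
}

#' Expected copy number under the independent-origin model
#'
#' Closed-form expected copy number (in [1, 2]) at positions \code{x} on
#' one chromosome at time \code{t} after release: each origin fires
#' independently with its efficiency at a Normal(firingTime, firingSd)
#' time, forks travel at the configured speed (capped in HU mode), and a
#' locus is replicated when the first fork arrives. With arrival
#' probability \eqn{p_i(x,t) = e_i \Phi((t - d_i/v - \mu_i)/\sigma_i)}
#' per origin,
#' \deqn{E[copy] = 2 - \prod_i (1 - p_i(x, t)).}
#' A zero firing SD degenerates to a deterministic firing time.
#'
#' @param x numeric vector of positions (bp) on \code{chrom}.
#' @param t time in minutes (single value).
#' @param cfg a [simConfig()].
#' @param chrom chromosome name (default: first chromosome).
#' @return Numeric vector of expected copy numbers, same length as
#'   \code{x}.
#' @seealso [monteCarloCopyNumber()] for the cell-simulation reference.
#' @export
expectedCopyNumber <- function(x, t, cfg, chrom = names(cfg$chromLengths)[1]) {
    stopifnot(length(t) == 1L)
    ori <- cfg$origins[cfg$origins$chrom == chrom, , drop = FALSE]
    v <- cfg$forkSpeed * 1000   # bp/min
    pNot <- rep(1, length(x))
    for (i in seq_len(nrow(ori))) {
        d <- abs(x - ori$position[i])
        tArr <- t - d / v - ori$firingTime[i]
        pFire <- if (ori$firingSd[i] > 0)
            pnorm(tArr / ori$firingSd[i])
        else
            as.numeric(tArr >= 0)
        if (cfg$huMode) pFire[d > cfg$huCapBp] <- 0
        pNot <- pNot * (1 - ori$efficiency[i] * pFire)
    }
    2 - pNot
}

#' Monte Carlo copy number by explicit cell simulation
#'
#' Reference implementation of [expectedCopyNumber()]: simulates
#' \code{nCells} cells, drawing each origin's firing decision and time
#' explicitly, and returns the fraction of cells in which each position
#' is replicated by time \code{t}, as 1 + fraction. The standard error of
#' the replicated fraction is returned so closed form and simulation can
#' be compared on equal terms.
#'
#' @param x numeric vector of positions (bp).
#' @param t time in minutes.
#' @param cfg a [simConfig()].
#' @param chrom chromosome name.
#' @param nCells number of simulated cells.
#' @return list with \code{copy} (numeric, 1 + replicated fraction) and
#'   \code{se} (standard error of the fraction).
#' @export
monteCarloCopyNumber <- function(x, t, cfg,
                                 chrom = names(cfg$chromLengths)[1],
                                 nCells = 10000) {
    ori <- cfg$origins[cfg$origins$chrom == chrom, , drop = FALSE]
    v <- cfg$forkSpeed * 1000
    nOri <- nrow(ori)
    fired <- matrix(runif(nCells * nOri) < rep(ori$efficiency,
                                               each = nCells),
                    nCells, nOri)
    times <- matrix(rnorm(nCells * nOri, mean = rep(ori$firingTime,
                                                    each = nCells),
                          sd = rep(ori$firingSd, each = nCells)),
                    nCells, nOri)
    frac <- vapply(x, function(xx) {
        d <- abs(xx - ori$position)
        reach <- if (cfg$huMode) d <= cfg$huCapBp else rep(TRUE, nOri)
        arrive <- sweep(times, 2, d / v, "+") <= t
        arrive <- arrive & fired
        arrive[, !reach] <- FALSE
        mean(rowSums(arrive) > 0)
    }, numeric(1))
    list(copy = 1 + frac, se = sqrt(frac * (1 - frac) / nCells))
}

#' Simulate binned read counts for all replicates and sample times
#'
#' Generates raw count tracks emulating copy-number sequencing of G1-
#' and S-phase samples. Per replicate, one log-normal per-bin bias field
#' (SD \code{noiseSd}) is drawn and shared across that replicate's
#' samples, so it cancels in the S/G1 ratio as technical bin bias does in
#' real data; counts are Poisson with mean proportional to
#' \code{expectedCopyNumber(bin midpoint, t) * bias}, scaled to
#' \code{readsPerSample} in total. Reproducible under a seed.
#'
#' @param cfg a [simConfig()].
#' @param seed optional integer seed.
#' @return list with \code{tracks} (list of raw [BinnedTrack-class], one
#'   per sample time x replicate, named like "S_rep2") and
#'   \code{truth} (list recording the generating config).
#' @export
simulateBinnedCounts <- function(cfg, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    bw <- cfg$binWidth
    chroms <- names(cfg$chromLengths)
    mids <- lapply(chroms, function(ch) {
        nb <- ceiling(cfg$chromLengths[[ch]] / bw)
        (seq_len(nb) - 1) * bw + bw / 2
    })
    names(mids) <- chroms
    tracks <- list()
    for (r in seq_len(cfg$replicates)) {
        bias <- lapply(mids, function(m)
            exp(rnorm(length(m), 0, cfg$noiseSd)))
        for (s in seq_along(cfg$sampleTimes)) {
            phase <- names(cfg$sampleTimes)[s]
            tt <- cfg$sampleTimes[[s]]
            cn <- lapply(chroms, function(ch)
                expectedCopyNumber(mids[[ch]], tt, cfg, chrom = ch))
            names(cn) <- chroms
            w <- mapply(function(c1, b1) c1 * b1, cn, bias,
                        SIMPLIFY = FALSE)
            tot <- sum(unlist(w))
            counts <- lapply(w, function(wc)
                rpois(length(wc), cfg$readsPerSample * wc / tot))
            names(counts) <- chroms
            id <- sprintf("%s_rep%d", phase, r)
            tracks[[id]] <- binnedTrack(counts, bw, stage = "raw",
                                        sampleId = id, phase = phase,
                                        condition = cfg$condition,
                                        replicate = r)
        }
    }
    list(tracks = tracks, truth = list(config = cfg))
}

#' Perturb origin firing times
#'
#' Shifts the firing time of the named origins by \code{deltaT} minutes
#' (negative = advanced) and records the ground-truth differential
#' interval: the run of positions where the expected copy number at the
#' S sampling time changes by at least \code{threshold} relative to the
#' unperturbed model.
#'
#' @param cfg a [simConfig()].
#' @param targets origin names to perturb.
#' @param deltaT shift in minutes (negative advances firing).
#' @param threshold minimum expected copy-number change entering the
#'   ground-truth interval (default 0.1).
#' @param condition condition label for the perturbed config.
#' @return list with \code{cfg} (perturbed [simConfig()]) and
#'   \code{truth}: data.frame of ground-truth intervals (\code{chrom},
#'   \code{start}, \code{end}, 0-based half-open, plus
#'   \code{direction}).
#' @export
applyPerturbation <- function(cfg, targets, deltaT, threshold = 0.1,
                              condition = "perturbed") {
    unknown <- setdiff(targets, cfg$origins$name)
    if (length(unknown))
        stop("unknown origin: ", paste(unknown, collapse = ", "))
    cfg2 <- cfg
    hit <- cfg2$origins$name %in% targets
    cfg2$origins$firingTime <- pmax(0, cfg2$origins$firingTime +
                                       ifelse(hit, deltaT, 0))
    cfg2$condition <- condition
    sTime <- max(cfg$sampleTimes)
    bw <- cfg$binWidth
    rows <- list()
    for (ch in names(cfg$chromLengths)) {
        nb <- ceiling(cfg$chromLengths[[ch]] / bw)
        m <- (seq_len(nb) - 1) * bw + bw / 2
        d <- expectedCopyNumber(m, sTime, cfg2, chrom = ch) -
             expectedCopyNumber(m, sTime, cfg, chrom = ch)
        sig <- which(abs(d) >= threshold)
        if (!length(sig)) next
        runId <- cumsum(c(TRUE, diff(sig) != 1L))
        for (rr in unique(runId)) {
            idx <- sig[runId == rr]
            rows[[length(rows) + 1L]] <- data.frame(
                chrom = ch, start = (idx[1] - 1) * bw,
                end = idx[length(idx)] * bw,
                direction = if (mean(d[idx]) > 0) "advanced" else "delayed")
        }
    }
    truth <- if (length(rows)) do.call(rbind, rows)
             else data.frame(chrom = character(), start = numeric(),
                             end = numeric(), direction = character())
    rownames(truth) <- NULL
    list(cfg = cfg2, truth = truth)
}

.BASES <- c("A", "C", "G", "T")
.IUPAC_SET <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

## A concrete realization of an IUPAC consensus with exactly nMismatches
## positions mutated to bases outside their consensus set.
.realizeInstance <- function(consensus, nMismatches) {
    letters <- strsplit(toupper(consensus), "")[[1]]
    sets <- .IUPAC_SET[letters]
    inst <- vapply(sets, function(s) sample(s, 1)[1], "")
    if (nMismatches > 0) {
        mutable <- which(vapply(sets, length, 1L) < 4L)
        if (length(mutable) < nMismatches)
            stop("consensus too degenerate for requested mismatches")
        pos <- sample(mutable, nMismatches)
        for (p in pos)
            inst[p] <- sample(setdiff(.BASES, sets[[p]]), 1)
    }
    paste(inst, collapse = "")
}

#' Simulate origin sequences with planted motifs
#'
#' Uniform-random A/C/G/T background sequences with motif instances
#' planted at recorded, non-overlapping positions. Each plant realizes
#' its consensus concretely (random choice within each IUPAC set) and
#' then mutates exactly the requested number of positions to bases
#' outside their consensus set, so the planted instance matches at that
#' mismatch budget and not below. Strands are chosen at random;
#' minus-strand plants insert the reverse complement. The background can
#' contain incidental matches: the truth table records plants, not all
#' matches.
#'
#' @param n number of sequences.
#' @param plants list of plant specs, each a list with elements
#'   \code{motif} (a [MotifDef-class]), \code{count} (instances per
#'   sequence) and \code{mismatches} (exact mismatch count per instance,
#'   default 0).
#' @param width sequence length in bp (default 500, a midpoint +/- 250 bp
#'   origin window).
#' @param seed optional integer seed.
#' @return list with \code{sequences} (named character vector) and
#'   \code{truth} (data.frame: \code{origin}, \code{motif},
#'   \code{offset} 0-based, \code{strand}, \code{mismatches}).
#' @export
simulateOriginSequences <- function(n, plants, width = 500, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    totalLen <- sum(vapply(plants, function(p)
        p$count * nchar(p$motif@consensus), numeric(1)))
    if (totalLen > width)
        stop("planted motifs do not fit in the window")
    seqs <- character(n)
    truthRows <- list()
    for (i in seq_len(n)) {
        s <- sample(.BASES, width, replace = TRUE)
        occupied <- rep(FALSE, width)
        for (p in plants) {
            m <- nchar(p$motif@consensus)
            mm <- if (is.null(p$mismatches)) 0L else p$mismatches
            for (k in seq_len(p$count)) {
                placed <- FALSE
                for (try in seq_len(200)) {
                    pos <- sample(width - m + 1L, 1)  # 1-based start
                    if (any(occupied[pos:(pos + m - 1L)])) next
                    inst <- .realizeInstance(p$motif@consensus, mm)
                    strand <- sample(c("+", "-"), 1)
                    ins <- if (strand == "-") .revComp(inst) else inst
                    s[pos:(pos + m - 1L)] <- strsplit(ins, "")[[1]]
                    occupied[pos:(pos + m - 1L)] <- TRUE
                    truthRows[[length(truthRows) + 1L]] <- data.frame(
                        origin = paste0("origin_", i),
                        motif = p$motif@name, offset = pos - 1L,
                        strand = strand, mismatches = mm)
                    placed <- TRUE
                    break
                }
                if (!placed)
                    stop("window over-packed: could not place motif ",
                         p$motif@name)
            }
        }
        seqs[i] <- paste(s, collapse = "")
    }
    names(seqs) <- paste0("origin_", seq_len(n))
    truth <- if (length(truthRows)) do.call(rbind, truthRows)
             else data.frame(origin = character(), motif = character(),
                             offset = integer(), strand = character(),
                             mismatches = integer())
    rownames(truth) <- NULL
    list(sequences = seqs, truth = truth)
}

#' Simulate a protein abundance table with planted enrichments
#'
#' Background proteins have log2 target/control ratios ~
#' Normal(0, \code{noiseSd}); planted proteins are offset by their log2
#' effect. Abundances are exponentiated around per-protein base levels,
#' with independent replicate noise in each run.
#'
#' @param nBackground number of background proteins (>= 30 so the
#'   background test is estimable).
#' @param planted named numeric vector: log2 effects keyed by protein
#'   name (may be empty).
#' @param replicates replicates per condition (default 3).
#' @param noiseSd replicate noise SD in log2 units (default 0.2).
#' @param seed optional integer seed.
#' @return list with \code{table} (matrix proteins x runs, target
#'   columns "target_1"... then "control_1"...), \code{targetCols},
#'   \code{controlCols} and \code{truth} (names of planted proteins).
#' @export
simulateProteinTable <- function(nBackground, planted = numeric(0),
                                 replicates = 3, noiseSd = 0.2,
                                 seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    stopifnot(nBackground >= 30)
    prots <- c(names(planted), paste0("bg_", seq_len(nBackground)))
    effects <- c(unname(planted), rep(0, nBackground))
    nP <- length(prots)
    base <- exp(rnorm(nP, log(1e6), 1))
    tCols <- paste0("target_", seq_len(replicates))
    cCols <- paste0("control_", seq_len(replicates))
    m <- matrix(NA_real_, nP, 2 * replicates,
                dimnames = list(prots, c(tCols, cCols)))
    for (r in seq_len(replicates)) {
        m[, tCols[r]] <- base * 2^(effects + rnorm(nP, 0, noiseSd))
        m[, cCols[r]] <- base * 2^(rnorm(nP, 0, noiseSd))
    }
    list(table = m, targetCols = tCols, controlCols = cCols,
         truth = names(planted))
}

#' GenomeAnnotation matching a simulation config
#'
#' Builds the annotation the differential caller needs from a simulator
#' config: the simulated chromosomes and origins (replication time =
#' firing time; efficiency converted to percent). Centromeres may be
#' supplied for classification tests.
#'
#' @param cfg a [simConfig()].
#' @param centromeres optional data.frame (\code{chrom},
#'   \code{position}).
#' @return A [GenomeAnnotation-class].
#' @export
simAnnotation <- function(cfg, centromeres = NULL) {
    genomeAnnotation(
        cfg$chromLengths,
        origins = data.frame(name = cfg$origins$name,
                             chrom = cfg$origins$chrom,
                             position = cfg$origins$position,
                             rt = cfg$origins$firingTime,
                             efficiency = 100 * cfg$origins$efficiency),
        centromeres = centromeres)
}
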