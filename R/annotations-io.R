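#' @include AllClasses.R
NULL

#' Read a BED file of genomic intervals
#'
#' Reads a 3+ column BED file (0-based, half-open). Columns beyond the
#' third are preserved under the usual BED names (\code{name},
#' \code{score}, \code{strand}, then \code{extra1}, ...). \code{track} and
#' \code{browser} header lines are skipped.
#'
#' @param path path to a BED file.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based, half-open) plus any extra columns.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr3\t0\t500", p)
#' readBed(p)
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(track|browser)\\b", lines) & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                     lineno[which(nf < 3L)[1]]))
    ncol <- min(nf)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad))
        stop(sprintf("BED parse error at line %d: non-numeric coordinates",
                     lineno[bad[1]]))
    bad <- which(!(start < end) | start < 0)
    if (length(bad))
        stop(sprintf(
            "BED validation error at line %d: need 0 <= start < end",
            lineno[bad[1]]))
    out <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                      start = start, end = end)
    extra <- c("name", "score", "strand")
    if (ncol > 3L) {
        for (j in 4:ncol) {
            nm <- if (j - 3L <= length(extra)) extra[j - 3L]
                  else paste0("extra", j - 6L)
            col <- vapply(fields, `[[`, "", j)
            num <- suppressWarnings(as.numeric(col))
            out[[nm]] <- if (!anyNA(num)) num else col
        }
    }
    out
}

#' Write intervals as BED
#'
#' Inverse of [readBed()]: a table read and rewritten round-trips
#' byte-identically.
#'
#' @param x data.frame with \code{chrom}, \code{start}, \code{end} and
#'   optional extra columns.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBed <- function(x, path) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    df <- x
    df$start <- format(df$start, scientific = FALSE, trim = TRUE)
    df$end <- format(df$end, scientific = FALSE, trim = TRUE)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an origin catalog table
#'
#' Tab-separated table with header columns \code{name}, \code{chrom},
#' \code{position}, \code{rt} (replication time, minutes) and
#' \code{efficiency} (percent). Empty efficiency cells become \code{NA}
#' (absent, never 0). Rows are returned sorted by (chrom, position).
#'
#' @param path path to the TSV file.
#' @return data.frame of origins sorted by (chrom, position).
#' @seealso [writeOriginTable()], [genomeAnnotation()]
#' @export
readOriginTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
    need <- c("name", "chrom", "position", "rt", "efficiency")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("origin table missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$name))
        stop("duplicate origin name: ",
             df$name[duplicated(df$name)][1])
    for (col in c("position", "rt", "efficiency")) {
        if (!is.numeric(df[[col]]) && !all(is.na(df[[col]])))
            stop(sprintf("origin table column '%s' is not numeric", col))
        df[[col]] <- as.numeric(df[[col]])
    }
    df <- df[order(df$chrom, df$position), need, drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Write an origin catalog table
#'
#' @param x data.frame of origins as returned by [readOriginTable()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeOriginTable <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    invisible(path)
}

#' Read a centromere table
#'
#' Tab-separated with header columns \code{chrom} and \code{position} (bp).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns \code{chrom}, \code{position}.
#' @export
readCentromereTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("chrom", "position") %in% names(df)))
        stop("centromere table must have columns 'chrom' and 'position'")
    data.frame(chrom = as.character(df$chrom),
               position = as.numeric(df$position))
}

#' Distance from an interval to the nearest feature point
#'
#' Minimum gap between a 0-based half-open interval \code{[start, end)}
#' and a set of point features on the same chromosome, measured from the
#' interval boundary: 0 if a feature lies inside the interval, otherwise
#' the boundary gap in bp. Used for the "within < 5 kb" proximity rule
#' that classifies differential regions as centromeric, origin-proximal
#' or inter-origin.
#'
#' @param start,end interval coordinates (0-based, half-open).
#' @param features numeric vector of feature positions on the same
#'   chromosome. If empty, \code{Inf} is returned ("no feature"; callers
#'   treat this as infinitely distant).
#' @return Minimum distance in bp (>= 0), or \code{Inf}.
#' @examples
#' nearestFeatureDistance(100, 200, c(150))  # 0: containment
#' nearestFeatureDistance(100, 200, c(250))  # 50: boundary gap
#' @export
nearestFeatureDistance <- function(start, end, features) {
    stopifnot(length(start) == 1L, length(end) == 1L, start < end)
    if (!length(features)) return(Inf)
    min(pmax(0, pmax(start - features, features - end)))
}
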