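## Readers and writers for the standard formats the pipeline consumes.
## Parsing is delegated to rtracklayer; a light pre-validation pass gives
## line-numbered error messages for malformed input.  BED and bedGraph are
## 0-based half-open on disk, GTF and fixedStep wiggle 1-based; everything
## is converted to 1-based closed GRanges coordinates at this boundary.

formatError <- function(...) {
    stop(errorCondition(paste0(...), class = "pasScout_format_error"))
}

bedDataLines <- function(lines) {
    !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
}

validateBed12 <- function(path) {
    lines <- readLines(path)
    for (i in which(bedDataLines(lines))) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 12L)
            formatError("malformed BED12 at line ", i, ": expected >= 12 ",
                        "tab-separated fields, found ", length(f))
        cs <- suppressWarnings(as.integer(f[2]))
        ce <- suppressWarnings(as.integer(f[3]))
        nb <- suppressWarnings(as.integer(f[10]))
        sizes <- suppressWarnings(as.integer(
            strsplit(f[11], ",", fixed = TRUE)[[1]]))
        starts <- suppressWarnings(as.integer(
            strsplit(f[12], ",", fixed = TRUE)[[1]]))
        if (anyNA(c(cs, ce, nb)) || anyNA(sizes) || anyNA(starts))
            formatError("malformed BED12 at line ", i,
                        ": non-numeric coordinate field")
        if (length(sizes) != nb || length(starts) != nb)
            formatError("malformed BED12 at line ", i, ": blockCount ", nb,
                        " does not match blockSizes/blockStarts")
        if (starts[1] != 0L || cs + starts[nb] + sizes[nb] != ce)
            formatError("malformed BED12 at line ", i, ": blocks are not ",
                        "consistent with chromStart/chromEnd")
        if (nb > 1L && any(diff(starts) - sizes[-nb] < 0L))
            formatError("malformed BED12 at line ", i,
                        ": overlapping or unsorted blocks")
    }
    invisible(TRUE)
}

bed12Blocks <- function(gr) {
    bl <- gr$blocks
    n <- lengths(bl)
    flat <- shift(unlist(bl, use.names = FALSE), rep(start(gr) - 1L, n))
    out <- relist(GRanges(rep(seqnames(gr), n), flat,
                          strand = rep(strand(gr), n)), bl)
    names(out) <- gr$name
    out
}

#' Read a BED12 file
#'
#' Each record's blocks become absolute genomic intervals.  Records are
#' returned in file order (as models these are re-sorted per transcript by
#' genomic position, which BED12 guarantees anyway).
#'
#' @param path path to a tab-separated BED12 file.
#' @param as \code{"transcripts"} to build \code{\link{TranscriptModels}}
#'   (BED has no gene attribute, so the record name serves as both
#'   transcript and gene id) or \code{"ests"} for
#'   \code{\link{EstAlignments}}.
#' @return a \code{TranscriptModels} or \code{EstAlignments} object.
#' @export
readBed12 <- function(path, as = c("transcripts", "ests")) {
    as <- match.arg(as)
    if (!file.exists(path)) formatError("no such file: ", path)
    validateBed12(path)
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) {
        empty <- GRangesList()
        return(if (as == "transcripts") TranscriptModels(empty)
               else EstAlignments(empty))
    }
    if (anyDuplicated(gr$name))
        gr$name <- make.unique(gr$name, sep = "#")
    bl <- bed12Blocks(gr)
    if (as == "transcripts") TranscriptModels(bl) else EstAlignments(bl)
}

#' Write models to BED12
#'
#' Inverse of \code{\link{readBed12}}: coordinates round-trip exactly.
#'
#' @param x a \code{TranscriptModels} or \code{EstAlignments} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBed12 <- function(x, path) {
    bl <- if (is(x, "TranscriptModels")) exonRanges(x) else estBlocks(x)
    sp <- unlist(range(bl), use.names = FALSE)
    rel <- relist(shift(unlist(ranges(bl), use.names = FALSE),
                        -rep(start(sp), lengths(bl)) + 1L),
                  ranges(bl))
    out <- GRanges(seqnames(sp), ranges(sp), strand = strand(sp))
    out$name <- names(bl)
    out$score <- 0L
    out$thick <- ranges(sp)
    out$blocks <- rel
    rtracklayer::export(out, path, format = "bed")
    invisible(path)
}

#' Read transcript models from GTF
#'
#' Consumes \code{exon} features grouped by their \code{transcript_id}
#' attribute; other feature types are ignored.  Exons arrive in any order
#' and are sorted ascending per transcript.
#'
#' @param path path to a GTF file.
#' @return a \code{TranscriptModels} object.
#' @export
readGtf <- function(path) {
    if (!file.exists(path)) formatError("no such file: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) formatError("GTF parse error: ",
                                                   conditionMessage(e)))
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L)
        return(TranscriptModels(GRangesList()))
    if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
        formatError("GTF exon feature without a transcript_id attribute")
    txid <- gr$transcript_id
    if (any(tapply(as.character(strand(gr)), txid,
                   function(s) length(unique(s))) != 1L))
        formatError("GTF transcript with exons on mixed strands")
    bl <- split(granges(gr), txid)
    gid <- tapply(if (is.null(gr$gene_id)) txid else gr$gene_id,
                  txid, `[`, 1L)
    TranscriptModels(bl, geneId = as.character(gid[names(bl)]))
}

#' Write transcript models to GTF
#'
#' Emits one \code{exon} feature per exon with \code{gene_id} and
#' \code{transcript_id} attributes; round-trips through
#' \code{\link{readGtf}}.
#'
#' @param x a \code{TranscriptModels} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGtf <- function(x, path) {
    ex <- exonRanges(x)
    flat <- unlist(ex, use.names = FALSE)
    flat$source <- "pasScout"
    flat$type <- "exon"
    flat$gene_id <- rep(unname(geneIds(x)), lengths(ex))
    flat$transcript_id <- rep(names(ex), lengths(ex))
    rtracklayer::export(flat, path, format = "gtf")
    invisible(path)
}

#' Read a per-base signal track
#'
#' Accepts fixedStep/variableStep wiggle (1-based) or bedGraph (0-based
#' half-open); the dialect is auto-detected from the first data/header line.
#' The role determines missing-data semantics: bases without a record are
#' missing for \code{"conservation"} and depth 0 for \code{"coverage"}.
#'
#' @param path path to the track file.
#' @param role \code{"conservation"} or \code{"coverage"}.
#' @return a \code{\link{ScoreTrack}}.
#' @export
readTrack <- function(path, role = c("conservation", "coverage")) {
    role <- match.arg(role)
    if (!file.exists(path)) formatError("no such file: ", path)
    head_lines <- readLines(path, n = 50L)
    head_lines <- head_lines[nzchar(trimws(head_lines))]
    is_wig <- any(grepl("^(fixedStep|variableStep)\\b", head_lines))
    data1 <- head_lines[!grepl("^(#|track\\b|browser\\b)", head_lines)][1]
    fmt <- if (is_wig) {
        "wig"
    } else if (!is.na(data1) &&
               length(strsplit(data1, "[\t ]+")[[1]]) == 4L) {
        "bedGraph"
    } else {
        formatError("unrecognised track format in ", path,
                    " (expected fixedStep/variableStep wiggle or bedGraph)")
    }
    gr <- tryCatch(rtracklayer::import(path, format = fmt),
                   error = function(e) formatError("track parse error: ",
                                                   conditionMessage(e)))
    if (!isDisjoint(gr))
        formatError("overlapping records in track ", path)
    if (role == "coverage" && any(gr$score < 0))
        formatError("negative depth in coverage track ", path)
    ScoreTrack(granges(gr, use.mcols = TRUE), role = role)
}

#' Write a signal track
#'
#' Conservation tracks are written as wiggle, coverage as bedGraph (zero-depth
#' runs are dropped, matching the sparse on-disk convention).
#'
#' @param x a \code{\link{ScoreTrack}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrack <- function(x, path) {
    gr <- trackRanges(x)
    if (trackRole(x) == "coverage") {
        gr <- gr[gr$score != 0]
        rtracklayer::export(gr, path, format = "bedGraph")
    } else {
        rtracklayer::export(gr, path, format = "wig")
    }
    invisible(path)
}

## ---- window statistics -----------------------------------------------------

#' @rdname meanOver
#' @export
setGeneric("meanOver", function(x, which) standardGeneric("meanOver"))
#' @rdname meanOver
#' @export
setGeneric("coveredFraction", function(x, which)
    standardGeneric("coveredFraction"))

#' Window statistics over a signal track
#'
#' \code{meanOver} averages the signal over each query interval.  For a
#' conservation track only bases with a value contribute to the mean, and
#' \code{value_fraction} reports the fraction of interval bases that had
#' one; for a coverage track absent bases count as depth 0 and
#' \code{value_fraction} is 1.  \code{coveredFraction} (coverage role)
#' returns the fraction of interval bases with depth >= 1 -- the binarised
#' covered/not-covered classification used by the Coverage Difference.
#'
#' @param x a \code{\link{ScoreTrack}}.
#' @param which a \code{GRanges} of query intervals.
#' @return \code{meanOver}: a data.frame with columns \code{mean} and
#'   \code{value_fraction}, one row per query; \code{coveredFraction}: a
#'   numeric vector of per-query covered fractions.
#' @name meanOver
NULL

trackOverlapSums <- function(gr, which, weight) {
    hits <- findOverlaps(which, gr)
    ov_w <- width(pintersect(ranges(which)[queryHits(hits)],
                             ranges(gr)[subjectHits(hits)]))
    w <- ov_w * weight[subjectHits(hits)]
    list(
        bases = as.numeric(tapply(ov_w, factor(queryHits(hits),
                                               levels = seq_along(which)),
                                  sum, default = 0)),
        sum = as.numeric(tapply(w, factor(queryHits(hits),
                                          levels = seq_along(which)),
                                sum, default = 0))
    )
}

#' @rdname meanOver
setMethod("meanOver", "ScoreTrack", function(x, which) {
    gr <- x@ranges
    s <- trackOverlapSums(gr, which, gr$score)
    if (x@role == "conservation") {
        data.frame(mean = ifelse(s$bases > 0, s$sum / s$bases, NA_real_),
                   value_fraction = s$bases / width(which))
    } else {
        data.frame(mean = s$sum / width(which),
                   value_fraction = rep(1, length(which)))
    }
})

#' @rdname meanOver
setMethod("coveredFraction", "ScoreTrack", function(x, which) {
    if (x@role != "coverage")
        stop("coveredFraction is defined for coverage tracks")
    gr <- x@ranges[x@ranges$score >= 1]
    s <- trackOverlapSums(gr, which, rep(1, length(gr)))
    s$bases / width(which)
})

#' Pool coverage evidence across tissues
#'
#' Per-base depths are summed, so a base is covered in the pooled track iff
#' it is covered in any input track.
#'
#' @param tracks a list of coverage \code{\link{ScoreTrack}}s on the same
#'   genome.
#' @return a pooled coverage \code{ScoreTrack}.
#' @export
mergeTissueCoverage <- function(tracks) {
    stopifnot(length(tracks) >= 1L)
    for (t in tracks)
        if (!is(t, "ScoreTrack") || trackRole(t) != "coverage")
            stop("mergeTissueCoverage expects coverage ScoreTracks")
    if (length(tracks) == 1L) return(tracks[[1]])
    grs <- lapply(tracks, trackRanges)
    lens <- lapply(grs, function(g) {
        tapply(end(g), as.character(seqnames(g)), max)
    })
    chroms <- unique(unlist(lapply(lens, names)))
    seqlen <- vapply(chroms, function(ch) {
        max(vapply(lens, function(l) {
            if (ch %in% names(l)) as.numeric(l[[ch]]) else 0
        }, numeric(1)))
    }, numeric(1))
    covs <- lapply(grs, function(g) {
        GenomeInfoDb::seqlevels(g) <- chroms
        GenomeInfoDb::seqlengths(g) <- seqlen
        coverage(g, weight = g$score)
    })
    total <- Reduce(`+`, covs)
    out <- as(total, "GRanges")
    out <- out[out$score != 0]
    GenomeInfoDb::seqlengths(out) <- NA
    ScoreTrack(out, role = "coverage")
}
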