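## Generics and accessors for the core classes.  All positions reported by
## these accessors are 1-based genomic coordinates.

#' @rdname TranscriptModels-accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname TranscriptModels-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname TranscriptModels-accessors
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))
#' @rdname TranscriptModels-accessors
#' @export
setGeneric("txSpans", function(x) standardGeneric("txSpans"))
#' @rdname TranscriptModels-accessors
#' @export
setGeneric("tssPositions", function(x) standardGeneric("tssPositions"))
#' @rdname TranscriptModels-accessors
#' @export
setGeneric("pasPositions", function(x) standardGeneric("pasPositions"))
#' @rdname TranscriptModels-accessors
#' @export
setGeneric("intronRanges", function(x) standardGeneric("intronRanges"))
#' @rdname TranscriptModels-accessors
#' @export
setGeneric("lastIntrons", function(x) standardGeneric("lastIntrons"))

#' Accessors for TranscriptModels
#'
#' \code{tssPositions} and \code{pasPositions} are strand-aware: on the plus
#' strand the TSS is the leftmost transcribed base and the PAS the rightmost;
#' on the minus strand the roles swap.  \code{lastIntrons} returns, for every
#' multi-exon transcript, the intron nearest the 3' end (single-exon models
#' are omitted).
#'
#' @param x a \code{TranscriptModels} object.
#' @return \code{exonRanges}: the exon \code{GRangesList}; \code{txSpans}: a
#'   \code{GRanges} of transcript spans with \code{transcript_id} and
#'   \code{gene_id} columns; \code{tssPositions}/\code{pasPositions}: named
#'   integer vectors; \code{intronRanges}: a \code{GRangesList} of introns;
#'   \code{lastIntrons}: a \code{GRanges} with a \code{transcript_id} column.
#' @name TranscriptModels-accessors
NULL

#' @rdname TranscriptModels-accessors
setMethod("transcriptIds", "TranscriptModels", function(x) names(x@exons))
#' @rdname TranscriptModels-accessors
setMethod("geneIds", "TranscriptModels", function(x) {
    stats::setNames(x@geneId, names(x@exons))
})
#' @rdname TranscriptModels-accessors
setMethod("exonRanges", "TranscriptModels", function(x) x@exons)

#' @rdname TranscriptModels-accessors
setMethod("txSpans", "TranscriptModels", function(x) {
    sp <- unlist(range(x@exons), use.names = FALSE)
    sp$transcript_id <- names(x@exons)
    sp$gene_id <- x@geneId
    names(sp) <- names(x@exons)
    sp
})

#' @rdname TranscriptModels-accessors
setMethod("tssPositions", "TranscriptModels", function(x) {
    sp <- txSpans(x)
    pos <- ifelse(as.character(strand(sp)) == "+", start(sp), end(sp))
    stats::setNames(as.integer(pos), names(x@exons))
})

#' @rdname TranscriptModels-accessors
setMethod("pasPositions", "TranscriptModels", function(x) {
    sp <- txSpans(x)
    pos <- ifelse(as.character(strand(sp)) == "+", end(sp), start(sp))
    stats::setNames(as.integer(pos), names(x@exons))
})

#' @rdname TranscriptModels-accessors
setMethod("intronRanges", "TranscriptModels", function(x) {
    psetdiff(unlist(range(x@exons), use.names = FALSE), x@exons)
})

#' @rdname TranscriptModels-accessors
setMethod("lastIntrons", "TranscriptModels", function(x) {
    intr <- intronRanges(x)
    multi <- lengths(intr) >= 1L
    intr <- intr[multi]
    if (length(intr) == 0L) {
        out <- GRanges()
        out$transcript_id <- character(0)
        return(out)
    }
    minus <- as.character(strand(txSpans(x)))[multi] == "-"
    idx <- ifelse(minus, 1L, lengths(intr))  # genomically first intron is 3'-most on minus
    flat <- unlist(intr, use.names = FALSE)
    pick <- cumsum(lengths(intr)) - lengths(intr) + idx
    out <- flat[pick]
    out$transcript_id <- names(intr)
    names(out) <- names(intr)
    out
})

setMethod("length", "TranscriptModels", function(x) length(x@exons))

setMethod("[", "TranscriptModels", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@exons))
    new("TranscriptModels", exons = x@exons[i], geneId = x@geneId[i])
})

## ---- EST accessors ---------------------------------------------------------

#' @rdname EstAlignments-accessors
#' @export
setGeneric("estIds", function(x) standardGeneric("estIds"))
#' @rdname EstAlignments-accessors
#' @export
setGeneric("estBlocks", function(x) standardGeneric("estBlocks"))
#' @rdname EstAlignments-accessors
#' @export
setGeneric("isSpliced", function(x) standardGeneric("isSpliced"))
#' @rdname EstAlignments-accessors
#' @export
setGeneric("estExtremes", function(x) standardGeneric("estExtremes"))
#' @rdname EstAlignments-accessors
#' @export
setGeneric("spliceSites", function(x) standardGeneric("spliceSites"))

#' Accessors for EstAlignments
#'
#' \code{estExtremes} returns both genomic termini of every alignment (the
#' leftmost and the rightmost aligned base) as candidate transcript extremes;
#' EST orientation is deliberately ignored.  \code{spliceSites} returns every
#' internal block boundary (donor and acceptor base) of spliced alignments.
#'
#' @param x an \code{EstAlignments} object.
#' @return \code{estExtremes}: a data.frame with columns \code{est_id},
#'   \code{chrom}, \code{pos}, \code{side} (two rows per EST);
#'   \code{spliceSites}: a data.frame with columns \code{chrom}, \code{pos}.
#' @name EstAlignments-accessors
NULL

#' @rdname EstAlignments-accessors
setMethod("estIds", "EstAlignments", function(x) names(x@blocks))
#' @rdname EstAlignments-accessors
setMethod("estBlocks", "EstAlignments", function(x) x@blocks)
#' @rdname EstAlignments-accessors
setMethod("isSpliced", "EstAlignments", function(x) {
    stats::setNames(lengths(x@blocks) >= 2L, names(x@blocks))
})

#' @rdname EstAlignments-accessors
setMethod("estExtremes", "EstAlignments", function(x) {
    sp <- unlist(range(x@blocks), use.names = FALSE)
    if (length(sp) == 0L)
        return(data.frame(est_id = character(0), chrom = character(0),
                          pos = integer(0), side = character(0)))
    data.frame(
        est_id = rep(names(x@blocks), 2L),
        chrom = rep(as.character(seqnames(sp)), 2L),
        pos = c(start(sp), end(sp)),
        side = rep(c("left", "right"), each = length(sp))
    )
})

#' @rdname EstAlignments-accessors
setMethod("spliceSites", "EstAlignments", function(x) {
    bl <- x@blocks[lengths(x@blocks) >= 2L]
    if (length(bl) == 0L)
        return(data.frame(chrom = character(0), pos = integer(0)))
    flat <- unlist(bl, use.names = FALSE)
    n <- lengths(bl)
    last_of_est <- cumsum(n)
    first_of_est <- last_of_est - n + 1L
    # internal boundaries: block ends except each EST's last; block starts
    # except each EST's first
    keep_end <- !(seq_along(flat) %in% last_of_est)
    keep_start <- !(seq_along(flat) %in% first_of_est)
    data.frame(
        chrom = c(as.character(seqnames(flat))[keep_end],
                  as.character(seqnames(flat))[keep_start]),
        pos = c(end(flat)[keep_end], start(flat)[keep_start])
    )
})

## ---- ScoreTrack accessors --------------------------------------------------

#' @rdname ScoreTrack-accessors
#' @export
setGeneric("trackRole", function(x) standardGeneric("trackRole"))
#' @rdname ScoreTrack-accessors
#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' Accessors for ScoreTrack
#'
#' @param x a \code{ScoreTrack}.
#' @return \code{trackRole}: the declared role; \code{trackRanges}: the
#'   scored \code{GRanges}.
#' @name ScoreTrack-accessors
NULL

#' @rdname ScoreTrack-accessors
setMethod("trackRole", "ScoreTrack", function(x) x@role)
#' @rdname ScoreTrack-accessors
setMethod("trackRanges", "ScoreTrack", function(x) x@ranges)
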