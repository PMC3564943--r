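#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom BiocGenerics strand start end width sort
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevelsInUse
NULL

#' Set of multi-exon transcript models
#'
#' Holds stranded gene models as a \code{GRangesList} of exons (one element
#' per transcript, exons sorted in ascending genomic order) together with a
#' parallel gene identifier.  Coordinates are 1-based closed, the native
#' \code{GRanges} convention; readers convert from the 0-based half-open
#' BED/bedGraph conventions at the boundary.
#'
#' @slot exons \code{GRangesList} named by transcript id; every element has a
#'   single chromosome and strand, and consecutive exons are separated by at
#'   least one intronic base.
#' @slot geneId character vector parallel to \code{exons}.
#' @export
setClass("TranscriptModels",
         slots = c(exons = "CompressedGRangesList", geneId = "character"))

setValidity("TranscriptModels", function(object) {
    ex <- object@exons
    if (length(ex) != length(object@geneId))
        return("geneId must be parallel to the exon list")
    if (length(ex) == 0L) return(TRUE)
    if (is.null(names(ex)) || anyDuplicated(names(ex)))
        return("transcripts must carry unique ids")
    n_ex <- lengths(ex)
    if (any(n_ex < 1L)) return("every transcript needs at least one exon")
    flat <- unlist(ex, use.names = FALSE)
    grp <- rep(seq_along(ex), n_ex)
    if (any(tapply(as.character(seqnames(flat)), grp,
                   function(x) length(unique(x))) != 1L))
        return("exons of one transcript must share a chromosome")
    st <- as.character(strand(flat))
    if (any(st == "*")) return("transcripts must be stranded (+ or -)")
    if (any(tapply(st, grp, function(x) length(unique(x))) != 1L))
        return("exons of one transcript must share a strand")
    # ascending, non-overlapping, >= 1 base apart
    for (i in which(n_ex > 1L)) {
        e <- ex[[i]]
        if (is.unsorted(start(e), strictly = TRUE))
            return("exons must be sorted in ascending genomic order")
        if (any(start(e)[-1L] - end(e)[-length(e)] < 2L))
            return("consecutive exons must be separated by >= 1 base")
    }
    TRUE
})

#' EST alignments as block models
#'
#' An EST alignment is an ordered set of aligned blocks on one chromosome.
#' Orientation is carried through from the input but never consulted by the
#' clustering and filtering logic, which treats both termini of every
#' alignment as candidate transcript extremes.
#'
#' @slot blocks \code{GRangesList} named by EST id.
#' @export
setClass("EstAlignments", slots = c(blocks = "CompressedGRangesList"))

setValidity("EstAlignments", function(object) {
    bl <- object@blocks
    if (length(bl) == 0L) return(TRUE)
    if (is.null(names(bl)) || anyDuplicated(names(bl)))
        return("ESTs must carry unique ids")
    if (any(lengths(bl) < 1L)) return("every EST needs at least one block")
    flat <- unlist(bl, use.names = FALSE)
    grp <- rep(seq_along(bl), lengths(bl))
    if (any(tapply(as.character(seqnames(flat)), grp,
                   function(x) length(unique(x))) != 1L))
        return("blocks of one EST must share a chromosome")
    TRUE
})

#' Per-base numeric signal track
#'
#' A sparse per-base signal: conservation scores (real-valued, bases without
#' a record are \emph{missing}) or read depth (non-negative, bases without a
#' record have depth 0).  The role is declared at load time, not inferred.
#'
#' @slot ranges disjoint, sorted \code{GRanges} with a numeric \code{score}.
#' @slot role \code{"conservation"} or \code{"coverage"}.
#' @export
setClass("ScoreTrack", slots = c(ranges = "GRanges", role = "character"))

setValidity("ScoreTrack", function(object) {
    if (length(object@role) != 1L ||
        !object@role %in% c("conservation", "coverage"))
        return("role must be 'conservation' or 'coverage'")
    gr <- object@ranges
    if (is.null(gr$score) || !is.numeric(gr$score))
        return("track ranges need a numeric score column")
    if (!isDisjoint(gr)) return("track records must not overlap")
    if (object@role == "coverage" && any(gr$score < 0))
        return("coverage depth must be non-negative")
    TRUE
})

## ---- constructors ----------------------------------------------------------

#' Build a TranscriptModels object
#'
#' @param exons \code{GRangesList} of exons, one element per transcript,
#'   named by transcript id.  Elements are sorted in ascending order.
#' @param geneId gene id per transcript; defaults to the transcript ids.
#' @return a \code{TranscriptModels} object.
#' @export
TranscriptModels <- function(exons, geneId = names(exons)) {
    exons <- sortExonList(exons)
    if (is.null(geneId)) geneId <- names(exons)
    new("TranscriptModels", exons = exons, geneId = as.character(geneId))
}

sortExonList <- function(grl) {
    grl <- as(grl, "CompressedGRangesList")
    sort(grl)
}

#' Build an EstAlignments object
#'
#' @param blocks \code{GRangesList} of aligned blocks named by EST id.
#' @return an \code{EstAlignments} object.
#' @export
EstAlignments <- function(blocks) {
    new("EstAlignments", blocks = sortExonList(blocks))
}

#' Build a ScoreTrack
#'
#' @param ranges \code{GRanges} with a numeric \code{score} column; records
#'   must be disjoint.
#' @param role signal semantics: \code{"conservation"} (absent bases are
#'   missing) or \code{"coverage"} (absent bases have depth 0).
#' @return a \code{ScoreTrack}.
#' @export
ScoreTrack <- function(ranges, role = c("conservation", "coverage")) {
    role <- match.arg(role)
    new("ScoreTrack", ranges = sort(ranges), role = role)
}

## ---- show ------------------------------------------------------------------

setMethod("show", "TranscriptModels", function(object) {
    cat("TranscriptModels with", length(object@exons), "transcripts (",
        length(unique(object@geneId)), "genes )\n")
})

setMethod("show", "EstAlignments", function(object) {
    n <- length(object@blocks)
    cat("EstAlignments with", n, "alignments;",
        sum(lengths(object@blocks) >= 2L), "spliced\n")
})

setMethod("show", "ScoreTrack", function(object) {
    cat("ScoreTrack (", object@role, ") covering ",
        sum(width(object@ranges)), " bases on ",
        length(seqlevelsInUse(object@ranges)), " sequence(s)\n", sep = "")
})
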