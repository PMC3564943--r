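## Orthology-predicted 3'UTR extensions and the Coverage Difference (CD).
## An orthologous transcript projected onto the same genome that shares a
## reference transcript's last intron but reaches a more distal PAS
## proposes a 3'UTR extension; RNA-seq coverage over the extension (Up)
## versus an equal-length interval just beyond the proposed PAS (Down)
## scores whether transcription really stops there.

lastIntronKeys <- function(x) {
    li <- lastIntrons(x)
    if (length(li) == 0L)
        return(stats::setNames(character(0), character(0)))
    stats::setNames(
        paste0(as.character(seqnames(li)), ":",
               as.character(strand(li)), ":", start(li), "-", end(li)),
        li$transcript_id)
}

allIntronKeys <- function(x) {
    intr <- intronRanges(x)
    flat <- unlist(intr, use.names = FALSE)
    if (length(flat) == 0L) return(character(0))
    st <- rep(as.character(strand(txSpans(x))), lengths(intr))
    unique(paste0(as.character(seqnames(flat)), ":", st, ":",
                  start(flat), "-", end(flat)))
}

#' Find orthology-predicted 3'UTR extension candidates
#'
#' A (reference, ortholog) transcript pair becomes a candidate when both
#' are on the same chromosome and strand, their last introns are
#' coordinate-identical, and the ortholog's PAS is strictly more distal in
#' the transcription direction.  The Up interval spans from just past the
#' annotated PAS to the putative PAS; Down is the equal-length interval
#' immediately beyond (truncated and flagged at the chromosome start;
#' candidates whose Down would be empty are dropped).  Single-exon models
#' have no last intron and are skipped with a notice.
#'
#' @param reference a \code{\link{TranscriptModels}} object (annotation
#'   under examination).
#' @param ortho a \code{\link{TranscriptModels}} object of projected
#'   orthologous models (e.g. TransMap output), same genome coordinates.
#' @param min_extension minimum extension length in nt.
#' @param collapse \code{"none"} keeps every pair; \code{"most-distal"}
#'   keeps only the farthest extension per reference transcript.
#' @return data.frame with columns \code{reference_transcript_id},
#'   \code{ortho_transcript_id}, \code{chrom}, \code{strand},
#'   \code{annotated_pas}, \code{putative_pas}, \code{up_start},
#'   \code{up_end}, \code{down_start}, \code{down_end},
#'   \code{down_truncated}.
#' @export
findExtensionCandidates <- function(reference, ortho, min_extension = 1L,
                                    collapse = c("none", "most-distal")) {
    collapse <- match.arg(collapse)
    empty <- data.frame(reference_transcript_id = character(0),
                        ortho_transcript_id = character(0),
                        chrom = character(0), strand = character(0),
                        annotated_pas = integer(0),
                        putative_pas = integer(0),
                        up_start = integer(0), up_end = integer(0),
                        down_start = integer(0), down_end = integer(0),
                        down_truncated = logical(0))
    n_single <- sum(lengths(exonRanges(reference)) == 1L) +
        sum(lengths(exonRanges(ortho)) == 1L)
    if (n_single > 0L)
        message("skipping ", n_single,
                " single-exon model(s) without a last intron")
    ref_keys <- lastIntronKeys(reference)
    ortho_keys <- lastIntronKeys(ortho)
    if (length(ref_keys) == 0L || length(ortho_keys) == 0L) return(empty)
    pairs <- merge(
        data.frame(ref = names(ref_keys), key = unname(ref_keys)),
        data.frame(ortho = names(ortho_keys), key = unname(ortho_keys)))
    if (nrow(pairs) == 0L) return(empty)
    ref_pas <- pasPositions(reference)[pairs$ref]
    ortho_pas <- pasPositions(ortho)[pairs$ortho]
    ref_sp <- txSpans(reference)[pairs$ref]
    st <- as.character(strand(ref_sp))
    ext <- ifelse(st == "+", ortho_pas - ref_pas, ref_pas - ortho_pas)
    keep <- ext >= max(1L, as.integer(min_extension))
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L) return(empty)
    a <- unname(ref_pas[keep]); p <- unname(ortho_pas[keep])
    st <- st[keep]; ext <- ext[keep]
    up_start <- ifelse(st == "+", a + 1L, p)
    up_end <- ifelse(st == "+", p, a - 1L)
    down_start <- ifelse(st == "+", p + 1L, p - ext)
    down_end <- ifelse(st == "+", p + ext, p - 1L)
    trunc <- down_start < 1L
    down_start <- pmax(down_start, 1L)
    out <- data.frame(reference_transcript_id = pairs$ref,
                      ortho_transcript_id = pairs$ortho,
                      chrom = as.character(seqnames(ref_sp))[keep],
                      strand = st,
                      annotated_pas = as.integer(a),
                      putative_pas = as.integer(p),
                      up_start = as.integer(up_start),
                      up_end = as.integer(up_end),
                      down_start = as.integer(down_start),
                      down_end = as.integer(down_end),
                      down_truncated = trunc, row.names = NULL)
    out <- out[out$down_end >= out$down_start, , drop = FALSE]
    if (collapse == "most-distal" && nrow(out) > 0L) {
        ext_len <- out$up_end - out$up_start + 1L
        ord <- order(out$reference_transcript_id, -ext_len,
                     out$ortho_transcript_id)
        out <- out[ord, , drop = FALSE]
        out <- out[!duplicated(out$reference_transcript_id), , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' Compute the Coverage Difference
#'
#' Each base of the Up and Down intervals is classified as covered (depth
#' >= 1) or not; the CD is the percent of covered Up bases minus the
#' percent of covered Down bases.  CD = 100 means the proposed extension
#' is fully covered with silence beyond the putative PAS; CD = 0 means no
#' transcriptional change across it.  Read orientation is never consulted.
#' Percentages are computed over each interval's own (possibly truncated)
#' length; a candidate with an empty interval is flagged invalid.
#'
#' @param candidates candidate data.frame from
#'   \code{\link{findExtensionCandidates}}.
#' @param coverage a coverage \code{\link{ScoreTrack}} (pool tissues first
#'   with \code{\link{mergeTissueCoverage}} if desired).
#' @return \code{candidates} with added columns \code{up_pct},
#'   \code{down_pct}, \code{cd} and \code{valid}.
#' @export
computeCd <- function(candidates, coverage) {
    if (trackRole(coverage) != "coverage")
        stop("computeCd expects a coverage track")
    out <- data.frame(candidates, row.names = NULL)
    if (nrow(out) == 0L) {
        out$up_pct <- numeric(0); out$down_pct <- numeric(0)
        out$cd <- numeric(0); out$valid <- logical(0)
        return(out)
    }
    up <- GRanges(out$chrom, IRanges(out$up_start, out$up_end))
    down <- GRanges(out$chrom, IRanges(out$down_start, out$down_end))
    out$up_pct <- 100 * coveredFraction(coverage, up)
    out$down_pct <- 100 * coveredFraction(coverage, down)
    out$valid <- width(up) > 0L & width(down) > 0L
    out$cd <- ifelse(out$valid, out$up_pct - out$down_pct, NA_real_)
    out
}
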