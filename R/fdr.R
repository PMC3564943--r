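## Cross-database support decisions and cutoff-ranked empirical FDR curves.
## A putative PAS counts as supported when some transcript of a validating
## database ends at (about) the same position AND shares its last intron
## with an intron of the examined database -- positional agreement alone is
## not enough, the validating transcript must also tie into a known gene
## structure.  The FDR at a score cutoff is simply the fraction of
## putative PASs at or above the cutoff that lack such support.

#' Decide database support for putative PASs
#'
#' A putative PAS is supported if any validating transcript (i) has its
#' PAS within \code{pas_tolerance} nt of the putative position and (ii)
#' has a last intron coordinate-identical to some intron of some
#' transcript in the examined database.  Several validating databases are
#' OR-combined.  Because true sites may simply be missing from every
#' validating database, FDRs built from these decisions are conservative
#' (overestimated).
#'
#' @param pas data.frame of putative PASs with columns \code{pas_id},
#'   \code{chrom}, \code{position}.
#' @param validating a \code{\link{TranscriptModels}} object or a named
#'   list of them.
#' @param examined the examined-database \code{\link{TranscriptModels}}.
#' @param pas_tolerance positional tolerance in nt (0 for a literal
#'   same-position reading).
#' @return data.frame with columns \code{pas_id}, \code{chrom},
#'   \code{position}, \code{supported}, \code{supporting_transcript_id},
#'   \code{validating_db}.
#' @export
isSupported <- function(pas, validating, examined, pas_tolerance = 25L) {
    if (is(validating, "TranscriptModels"))
        validating <- list(validating = validating)
    if (is.null(names(validating)))
        names(validating) <- paste0("validating", seq_along(validating))
    out <- data.frame(pas_id = pas$pas_id, chrom = pas$chrom,
                      position = pas$position, supported = FALSE,
                      supporting_transcript_id = NA_character_,
                      validating_db = NA_character_, row.names = NULL)
    if (nrow(out) == 0L) return(out)
    exam_keys <- allIntronKeys(examined)
    for (db in names(validating)) {
        v <- validating[[db]]
        keys <- lastIntronKeys(v)  # multi-exon validating transcripts only
        ok <- names(keys)[unname(keys) %in% exam_keys]
        if (length(ok) == 0L) next
        vp <- pasPositions(v)[ok]
        sp <- txSpans(v)[ok]
        vchrom <- as.character(seqnames(sp))
        for (i in which(!out$supported)) {
            hit <- which(vchrom == out$chrom[i] &
                         abs(vp - out$position[i]) <= pas_tolerance)
            if (length(hit) > 0L) {
                # nearest match first, then lexicographic for determinism
                d <- abs(vp[hit] - out$position[i])
                hit <- hit[order(d, ok[hit])]
                out$supported[i] <- TRUE
                out$supporting_transcript_id[i] <- ok[hit[1]]
                out$validating_db[i] <- db
            }
        }
    }
    out
}

#' Cutoff-ranked FDR curve
#'
#' Every distinct observed score is used once as a cutoff; at cutoff c the
#' curve reports n, the number of putative PASs with score >= c,
#' n_unsupported, those among them lacking database support, and
#' FDR = n_unsupported / n.  Points are sorted by descending cutoff, and
#' \code{rank} gives the rank-scale x-axis (equal spacing per PTE
#' irrespective of score gaps).  Scores that are NA (undefined) are
#' excluded.
#'
#' @param scores data.frame with columns \code{pas_id} and \code{score}.
#' @param support support decisions from \code{\link{isSupported}} (only
#'   \code{pas_id} and \code{supported} are used); every scored PAS must
#'   appear.
#' @return data.frame with columns \code{cutoff}, \code{rank}, \code{n},
#'   \code{n_unsupported}, \code{fdr}.
#' @export
fdrCurve <- function(scores, support) {
    empty <- data.frame(cutoff = numeric(0), rank = integer(0),
                        n = integer(0), n_unsupported = integer(0),
                        fdr = numeric(0))
    scores <- scores[!is.na(scores$score), , drop = FALSE]
    if (nrow(scores) == 0L) return(empty)
    m <- match(scores$pas_id, support$pas_id)
    if (anyNA(m))
        stop("every scored PAS needs a support decision")
    sup <- support$supported[m]
    ord <- order(scores$score, decreasing = TRUE)
    s <- scores$score[ord]
    cum_unsup <- cumsum(!sup[ord])
    # last index of each distinct score block = all PASs with score >= it
    last <- which(!duplicated(s, fromLast = TRUE))
    data.frame(cutoff = s[last], rank = last, n = last,
               n_unsupported = cum_unsup[last],
               fdr = cum_unsup[last] / last, row.names = NULL)
}
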