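## Conservation Drop Index: mean per-base conservation of the terminal
## window of the mature transcript ("T") minus the mean of a window a fixed
## gap beyond the transcript end ("NT").  At a genuine PAS conservation
## collapses downstream, so the CDI is strongly positive; the gap skips the
## downstream sequence element, which is itself under selection.

#' Configuration for the Conservation Drop Index
#'
#' @param window width in nt of the T and NT windows.
#' @param gap nt between the transcript end and the start of the NT window
#'   (accounts for the conserved downstream sequence element).
#' @param min_value_fraction minimum fraction of window bases that must
#'   carry a conservation value for the CDI to be considered defined.
#' @return a \code{CdiConfig} list.
#' @export
cdiConfig <- function(window = 50L, gap = 50L, min_value_fraction = 0.5) {
    window <- as.integer(window); gap <- as.integer(gap)
    if (is.na(window) || window < 1L) stop("window must be >= 1")
    if (is.na(gap) || gap < 0L) stop("gap must be >= 0")
    if (!(min_value_fraction > 0 && min_value_fraction <= 1))
        stop("min_value_fraction must be in (0, 1]")
    structure(list(window = window, gap = gap,
                   min_value_fraction = min_value_fraction),
              class = c("CdiConfig", "list"))
}

#' Window geometry for a transcript extreme
#'
#' Computes the transcribed (T) and non-transcribed (NT) windows for an
#' anchor, the terminal transcribed base of a mature transcript (1-based).
#' The anchor base itself belongs to the T window.  For a 3' end the NT
#' window lies downstream of transcription; for a 5' end it lies upstream.
#' Windows running past the chromosome start are truncated and flagged.
#'
#' @param anchors data.frame with columns \code{chrom}, \code{position}
#'   (1-based terminal transcribed base), \code{strand} (\code{+}/\code{-})
#'   and \code{end_type} (\code{three_prime}/\code{five_prime}).
#' @param config a \code{\link{cdiConfig}}.
#' @return list with \code{GRanges} elements \code{t} and \code{nt}
#'   (parallel to \code{anchors}) and a logical \code{truncated}.
#' @export
cdiWindows <- function(anchors, config = cdiConfig()) {
    stopifnot(all(anchors$strand %in% c("+", "-")),
              all(anchors$end_type %in% c("three_prime", "five_prime")))
    w <- config$window; g <- config$gap
    b <- as.integer(anchors$position)
    # TRUE when the transcript body lies to the left of the anchor
    body_left <- (anchors$strand == "+") == (anchors$end_type == "three_prime")
    t_start <- ifelse(body_left, b - w + 1L, b)
    t_end <- ifelse(body_left, b, b + w - 1L)
    nt_start <- ifelse(body_left, b + g + 1L, b - g - w)
    nt_end <- ifelse(body_left, b + g + w, b - g - 1L)
    truncated <- t_start < 1L | nt_start < 1L | nt_end < 1L
    clip <- function(s, e) {
        s <- pmax(s, 1L); e <- pmax(e, 0L)
        IRanges(pmin(s, e + 1L), e)  # empty range when fully clipped
    }
    list(t = GRanges(anchors$chrom, clip(t_start, t_end),
                     strand = anchors$strand),
         nt = GRanges(anchors$chrom, clip(nt_start, nt_end),
                      strand = anchors$strand),
         truncated = truncated)
}

#' Compute the Conservation Drop Index
#'
#' CDI = mean conservation over the T window minus mean over the NT window,
#' averaging only bases that carry a value.  A result is flagged undefined
#' when either window has fewer than \code{min_value_fraction} of its bases
#' with values (PhyloP-style tracks have gaps).
#'
#' @param anchors anchor data.frame (see \code{\link{cdiWindows}});
#'   additional columns are carried through.
#' @param track a conservation \code{\link{ScoreTrack}}.
#' @param config a \code{\link{cdiConfig}}.
#' @return \code{anchors} with added columns \code{t_mean}, \code{nt_mean},
#'   \code{t_value_fraction}, \code{nt_value_fraction}, \code{cdi},
#'   \code{defined} and \code{truncated}.
#' @export
computeCdi <- function(anchors, track, config = cdiConfig()) {
    if (trackRole(track) != "conservation")
        stop("computeCdi expects a conservation track")
    out <- data.frame(anchors, row.names = NULL)
    if (nrow(out) == 0L) {
        for (col in c("t_mean", "nt_mean", "t_value_fraction",
                      "nt_value_fraction", "cdi"))
            out[[col]] <- numeric(0)
        out$defined <- logical(0); out$truncated <- logical(0)
        return(out)
    }
    wins <- cdiWindows(anchors, config)
    t_stat <- meanOver(track, wins$t)
    nt_stat <- meanOver(track, wins$nt)
    # value fraction is measured against the nominal window width, so
    # truncation also counts against usability
    out$t_mean <- t_stat$mean
    out$nt_mean <- nt_stat$mean
    t_bases <- ifelse(width(wins$t) == 0L, 0,
                      t_stat$value_fraction * width(wins$t))
    nt_bases <- ifelse(width(wins$nt) == 0L, 0,
                       nt_stat$value_fraction * width(wins$nt))
    out$t_value_fraction <- t_bases / config$window
    out$nt_value_fraction <- nt_bases / config$window
    out$defined <- !is.na(out$t_mean) & !is.na(out$nt_mean) &
        out$t_value_fraction >= config$min_value_fraction &
        out$nt_value_fraction >= config$min_value_fraction
    out$cdi <- ifelse(out$defined, out$t_mean - out$nt_mean, NA_real_)
    out$truncated <- wins$truncated
    out
}

#' Batch CDI table
#'
#' Order-preserving batch form of \code{\link{computeCdi}} over a list of
#' anchors of either end type.
#'
#' @inheritParams computeCdi
#' @return see \code{\link{computeCdi}}.
#' @export
cdiTable <- function(anchors, track, config = cdiConfig()) {
    computeCdi(anchors, track, config)
}

#' Anchors for annotated transcript extremes
#'
#' @param x a \code{\link{TranscriptModels}} object.
#' @param end \code{"pas"} for 3' ends or \code{"tss"} for 5' ends.
#' @return an anchor data.frame with columns \code{id}, \code{chrom},
#'   \code{position}, \code{strand}, \code{end_type}.
#' @export
transcriptAnchors <- function(x, end = c("pas", "tss")) {
    end <- match.arg(end)
    sp <- txSpans(x)
    pos <- if (end == "pas") pasPositions(x) else tssPositions(x)
    data.frame(id = names(pos),
               chrom = as.character(seqnames(sp)),
               position = unname(pos),
               strand = as.character(strand(sp)),
               end_type = if (end == "pas") "three_prime" else "five_prime")
}

#' Anchors for classified PTEs
#'
#' A putative PAS becomes a 3'-end anchor on the strand of its classifying
#' gene and a putative TSS a 5'-end anchor.  An undetermined PTE has no
#' resolved orientation, so both window geometries are emitted as a pair
#' (\code{three_prime} on each strand) and can be told apart by the
#' \code{orientation} column.
#'
#' @param classified classified PTE data.frame from
#'   \code{\link{classifyPtes}}.
#' @return an anchor data.frame with columns \code{id}, \code{chrom},
#'   \code{position}, \code{strand}, \code{end_type}, \code{identity},
#'   \code{orientation}.
#' @export
pteAnchors <- function(classified) {
    mk <- function(df, strand, end_type, orientation) {
        if (nrow(df) == 0L) return(NULL)
        data.frame(id = paste0(df$chrom, ":", df$position),
                   chrom = df$chrom, position = df$position,
                   strand = strand, end_type = end_type,
                   identity = df$identity, orientation = orientation)
    }
    pas <- classified[classified$identity == "putative_PAS", ]
    tss <- classified[classified$identity == "putative_TSS", ]
    und <- classified[classified$identity == "undetermined", ]
    out <- rbind(
        mk(pas, pas$inferred_strand, "three_prime", "resolved"),
        mk(tss, tss$inferred_strand, "five_prime", "resolved"),
        mk(und, "+", "three_prime", "body_left"),
        mk(und, "-", "three_prime", "body_right"))
    if (is.null(out))
        out <- data.frame(id = character(0), chrom = character(0),
                          position = integer(0), strand = character(0),
                          end_type = character(0), identity = character(0),
                          orientation = character(0))
    out
}

#' Histogram of CDI values
#'
#' Bins defined CDI values for plotting.  A central band (e.g. |CDI| <
#' 0.5) can be excluded from the histogram, a common presentation choice
#' that removes the uninformative near-zero bulk; the underlying tables
#' always keep all values.
#'
#' @param cdi_table output of \code{\link{computeCdi}}.
#' @param binwidth histogram bin width.
#' @param exclude_band optional half-width of a central band to omit.
#' @return data.frame with columns \code{bin_low}, \code{bin_high},
#'   \code{count}.
#' @export
cdiHistogram <- function(cdi_table, binwidth = 0.25, exclude_band = NULL) {
    v <- cdi_table$cdi[!is.na(cdi_table$cdi)]
    if (!is.null(exclude_band)) v <- v[abs(v) > exclude_band]
    if (length(v) == 0L)
        return(data.frame(bin_low = numeric(0), bin_high = numeric(0),
                          count = integer(0)))
    lo <- floor(min(v) / binwidth) * binwidth
    hi <- ceiling(max(v) / binwidth) * binwidth
    if (hi <= lo) hi <- lo + binwidth
    br <- seq(lo, hi, by = binwidth)
    h <- graphics::hist(v, breaks = br, plot = FALSE)
    data.frame(bin_low = h$breaks[-length(h$breaks)],
               bin_high = h$breaks[-1], count = h$counts)
}
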