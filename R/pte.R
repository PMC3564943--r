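## Clustering of EST extremes into Potential mature Transcript Extremes
## (PTEs), proximity merging, filtering, and classification into putative
## PAS / TSS by the orientation of the nearest reference gene.

#' Configuration for PTE detection
#'
#' Houses the method's positional constants: extremes at most
#' \code{linkage_distance} apart are chained into one cluster; clusters
#' closer than \code{merge_distance} are collapsed to the most distal one;
#' clusters need at least \code{min_support} member extremes; clusters
#' within \code{splice_site_exclusion} of a spliced-EST splice site are
#' discarded; and classification ignores genes farther than
#' \code{max_gene_distance}.
#'
#' @param linkage_distance single-linkage chaining distance in nt.
#' @param merge_distance minimum separation between surviving clusters, nt.
#' @param min_support minimum number of member EST extremes.
#' @param splice_site_exclusion exclusion radius around splice sites, nt
#'   (inclusive: a cluster exactly this far away is removed).
#' @param max_gene_distance maximum PTE-to-gene distance for
#'   classification, nt.
#' @return a \code{PteConfig} list.
#' @export
pteConfig <- function(linkage_distance = 1L, merge_distance = 25L,
                      min_support = 4L, splice_site_exclusion = 25L,
                      max_gene_distance = 1000000L) {
    cfg <- list(linkage_distance = as.integer(linkage_distance),
                merge_distance = as.integer(merge_distance),
                min_support = as.integer(min_support),
                splice_site_exclusion = as.integer(splice_site_exclusion),
                max_gene_distance = as.integer(max_gene_distance))
    if (any(vapply(cfg, function(v) is.na(v) || v < 1L, logical(1))))
        stop("all PteConfig fields must be positive integers")
    structure(cfg, class = c("PteConfig", "list"))
}

#' Cluster EST extremes into PTEs
#'
#' Single-linkage clustering of extreme positions: two extremes join the
#' same cluster when they are at most \code{linkage_distance} apart, and
#' chaining is transitive.  The representative position of a cluster is its
#' modal member position (ties resolved to the larger coordinate).
#'
#' @param extremes data.frame with columns \code{chrom} and \code{pos}
#'   (e.g. from \code{\link{estExtremes}}).
#' @param config a \code{\link{pteConfig}}.
#' @return data.frame of clusters with columns \code{chrom},
#'   \code{position}, \code{support}, \code{min_pos}, \code{max_pos},
#'   sorted by chromosome then position.
#' @export
clusterEstEnds <- function(extremes, config = pteConfig()) {
    empty <- data.frame(chrom = character(0), position = integer(0),
                        support = integer(0), min_pos = integer(0),
                        max_pos = integer(0))
    if (nrow(extremes) == 0L) return(empty)
    out <- lapply(split(extremes$pos, extremes$chrom), function(pos) {
        pos <- sort(as.integer(pos))
        brk <- c(0L, which(diff(pos) > config$linkage_distance), length(pos))
        cl <- rep(seq_len(length(brk) - 1L), diff(brk))
        do.call(rbind, lapply(split(pos, cl), function(p) {
            tab <- table(p)
            modal <- as.integer(names(tab)[tab == max(tab)])
            data.frame(position = max(modal), support = length(p),
                       min_pos = min(p), max_pos = max(p))
        }))
    })
    chrom <- rep(names(out), vapply(out, nrow, integer(1)))
    out <- do.call(rbind, out)
    out <- data.frame(chrom = chrom, out, row.names = NULL)
    out[order(out$chrom, out$position), , drop = FALSE]
}

## distance from positions to the nearest transcript end (0 when the
## position falls inside a transcript span); returns the distance and the
## index of the nearest transcript (NA when none within max_dist)
nearestTxEnd <- function(chrom, pos, spans, max_dist) {
    q <- GRanges(chrom, IRanges(pos, pos))
    d <- rep(NA_integer_, length(q))
    idx <- rep(NA_integer_, length(q))
    if (length(spans) > 0L) {
        hits <- distanceToNearest(q, spans)
        d[queryHits(hits)] <- mcols(hits)$distance
        idx[queryHits(hits)] <- subjectHits(hits)
        far <- !is.na(d) & d > max_dist
        d[far] <- NA_integer_
        idx[far] <- NA_integer_
    }
    list(distance = d, index = idx)
}

#' Merge proximal PTE clusters
#'
#' Clusters chained at pairwise distance below \code{merge_distance} are
#' collapsed to a single survivor: the most distal cluster in the
#' transcription direction of the nearest reference transcript (the larger
#' coordinate for a plus-strand neighbour, the smaller for minus).  When no
#' transcript lies within \code{max_gene_distance} of the run, the cluster
#' with the highest support survives (ties to the larger coordinate).
#' Surviving clusters are pairwise at least \code{merge_distance} apart and
#' the operation is idempotent.
#'
#' @param clusters cluster data.frame from \code{\link{clusterEstEnds}}.
#' @param reference a \code{\link{TranscriptModels}} object.
#' @param config a \code{\link{pteConfig}}.
#' @return the surviving subset of \code{clusters}.
#' @export
mergeProximalClusters <- function(clusters, reference,
                                  config = pteConfig()) {
    if (nrow(clusters) == 0L) return(clusters)
    spans <- txSpans(reference)
    keep <- logical(nrow(clusters))
    for (rows in split(seq_len(nrow(clusters)), clusters$chrom)) {
        pos <- clusters$position[rows]
        stopifnot(!is.unsorted(pos))
        brk <- c(0L, which(diff(pos) >= config$merge_distance), length(pos))
        run_id <- rep(seq_len(length(brk) - 1L), diff(brk))
        for (run in split(rows, run_id)) {
            if (length(run) == 1L) { keep[run] <- TRUE; next }
            near <- nearestTxEnd(clusters$chrom[run[1]],
                                 clusters$position[run], spans,
                                 config$max_gene_distance)
            pick <- if (all(is.na(near$index))) {
                NA_integer_
            } else {
                best <- which.min(ifelse(is.na(near$distance), Inf,
                                         near$distance))
                near$index[best]
            }
            p <- clusters$position[run]
            if (is.na(pick)) {
                s <- clusters$support[run]
                cand <- run[s == max(s)]
                keep[cand[which.max(clusters$position[cand])]] <- TRUE
            } else if (as.character(strand(spans))[pick] == "+") {
                keep[run[which.max(p)]] <- TRUE
            } else {
                keep[run[which.min(p)]] <- TRUE
            }
        }
    }
    clusters[keep, , drop = FALSE]
}

#' Filter PTE clusters
#'
#' Removes clusters that (a) have support below \code{min_support}, (b)
#' fall inside an exon of the reference annotation, or (c) lie within
#' \code{splice_site_exclusion} nt (inclusive) of any splice site of a
#' spliced EST -- likely unannotated exon boundaries rather than transcript
#' ends.  Clusters inside reference introns are retained: they may be
#' alternative promoters or alternative last exons.
#'
#' @param clusters cluster data.frame.
#' @param reference a \code{\link{TranscriptModels}} object.
#' @param ests an \code{\link{EstAlignments}} object (source of splice
#'   sites).
#' @param config a \code{\link{pteConfig}}.
#' @return the surviving subset of \code{clusters}.
#' @export
filterPtes <- function(clusters, reference, ests, config = pteConfig()) {
    if (nrow(clusters) == 0L) return(clusters)
    keep <- clusters$support >= config$min_support
    q <- GRanges(clusters$chrom, IRanges(clusters$position,
                                         clusters$position))
    ex <- unlist(exonRanges(reference), use.names = FALSE)
    if (length(ex) > 0L)
        keep <- keep & countOverlaps(q, ex, ignore.strand = TRUE) == 0L
    ss <- spliceSites(ests)
    if (nrow(ss) > 0L) {
        ssg <- GRanges(ss$chrom,
                       IRanges(ss$pos - config$splice_site_exclusion,
                               ss$pos + config$splice_site_exclusion))
        keep <- keep & countOverlaps(q, ssg, ignore.strand = TRUE) == 0L
    }
    clusters[keep, , drop = FALSE]
}

#' Classify PTEs as putative PAS or TSS
#'
#' A PTE is classified by the orientation of the closest reference gene
#' (distance to the nearest transcript end, 0 when contained): a gene
#' transcribed towards the PTE makes it a putative PAS, a gene transcribed
#' away makes it a putative TSS.  A PTE inside a reference intron is
#' classified by the orientation of the containing transcripts (the gene
#' body is transcribed towards it, hence putative PAS of an alternative
#' last exon); containment in transcripts of opposite strands, conflicting
#' equidistant neighbours, or no gene within \code{max_gene_distance} give
#' \code{undetermined}.
#'
#' @param clusters cluster data.frame (typically after
#'   \code{\link{filterPtes}} and \code{\link{mergeProximalClusters}}).
#' @param reference a \code{\link{TranscriptModels}} object.
#' @param config a \code{\link{pteConfig}}.
#' @return \code{clusters} with added columns \code{identity}
#'   (\code{putative_PAS}, \code{putative_TSS} or \code{undetermined}),
#'   \code{nearest_transcript}, \code{distance} and \code{inferred_strand}.
#' @export
classifyPtes <- function(clusters, reference, config = pteConfig()) {
    n <- nrow(clusters)
    out <- data.frame(clusters,
                      identity = rep("undetermined", n),
                      nearest_transcript = rep(NA_character_, n),
                      distance = rep(NA_integer_, n),
                      inferred_strand = rep("*", n),
                      row.names = NULL)
    if (n == 0L) return(out)
    spans <- txSpans(reference)
    spans <- spans[order(spans$transcript_id)]  # order-invariance
    q <- GRanges(clusters$chrom, IRanges(clusters$position,
                                         clusters$position))
    inside <- findOverlaps(q, spans, ignore.strand = TRUE)
    for (i in seq_len(n)) {
        cont <- subjectHits(inside)[queryHits(inside) == i]
        if (length(cont) > 0L) {
            st <- unique(as.character(strand(spans)[cont]))
            out$distance[i] <- 0L
            out$nearest_transcript[i] <- spans$transcript_id[cont[1]]
            if (length(st) == 1L) {
                out$identity[i] <- "putative_PAS"
                out$inferred_strand[i] <- st
            }
            next
        }
        p <- clusters$position[i]
        # all transcripts at exactly the minimum distance to an end
        dd <- pmin(abs(p - start(spans)), abs(p - end(spans)))
        same <- as.character(seqnames(spans)) == clusters$chrom[i]
        if (!any(same) || min(dd[same]) > config$max_gene_distance) next
        cand <- which(same & dd == min(dd[same]))
        lab <- vapply(cand, function(j) {
            plus <- as.character(strand(spans))[j] == "+"
            after <- p > end(spans)[j]
            if (plus == after) "putative_PAS" else "putative_TSS"
        }, character(1))
        out$distance[i] <- as.integer(min(dd[same]))
        out$nearest_transcript[i] <- spans$transcript_id[cand[1]]
        if (length(unique(lab)) == 1L) {
            out$identity[i] <- lab[1]
            out$inferred_strand[i] <- as.character(strand(spans))[cand[1]]
        }
    }
    out
}

#' Run the full PTE detection stage
#'
#' Convenience wrapper applying, in order: extreme clustering, the support
#' filter, the exon filter, the splice-site filter, proximity merging and
#' classification.
#'
#' @param ests an \code{\link{EstAlignments}} object.
#' @param reference a \code{\link{TranscriptModels}} object.
#' @param config a \code{\link{pteConfig}}.
#' @return a classified PTE data.frame (see \code{\link{classifyPtes}}).
#' @export
detectPtes <- function(ests, reference, config = pteConfig()) {
    cl <- clusterEstEnds(estExtremes(ests), config)
    cl <- filterPtes(cl, reference, ests, config)
    cl <- mergeProximalClusters(cl, reference, config)
    classifyPtes(cl, reference, config)
}
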