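suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# Compact constructors ------------------------------------------------------

# tx("id", "chr1", "+", c(101,300), c(601,900)) -> one transcript with the
# given exon start/end pairs (1-based closed)
txModel <- function(id, chrom, strand, ..., gene = id) {
    ex <- do.call(rbind, list(...))
    gr <- GRanges(chrom, IRanges(ex[, 1], ex[, 2]), strand = strand)
    grl <- GRangesList(setNames(list(gr), id))
    TranscriptModels(grl, geneId = gene)
}

combineTx <- function(...) {
    models <- list(...)
    ex <- do.call(c, lapply(models, exonRanges))
    TranscriptModels(ex, geneId = unlist(lapply(models,
                                                function(m) unname(geneIds(m)))))
}

estModel <- function(ids, chrom, starts, ends, strand = "*") {
    stopifnot(length(starts) == length(ends))
    gr <- GRanges(chrom, IRanges(starts, ends),
                  strand = rep(strand, length.out = length(starts)))
    EstAlignments(split(gr, factor(ids, levels = unique(ids))))
}

# per-base track from a value vector starting at `from` (1-based)
valueTrack <- function(chrom, from, values, role = "conservation") {
    ScoreTrack(GRanges(chrom, IRanges(seq_along(values) + from - 1L,
                                      width = 1L), score = values),
               role = role)
}

# coverage track from explicit covered intervals (depth 1 unless given)
coverTrack <- function(chrom, starts, ends, depth = 1) {
    ScoreTrack(GRanges(chrom, IRanges(starts, ends),
                       score = rep(depth, length.out = length(starts))),
               role = "coverage")
}

# Brute-force oracles --------------------------------------------------------

# O(n^2) single-linkage clustering by union-find over pairwise distances
oracleCluster <- function(pos, link = 1L) {
    n <- length(pos)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(pos[i] - pos[j]) <= link) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[ri] <- rj
        }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    out <- do.call(rbind, lapply(split(pos, comp), function(p) {
        tab <- table(p)
        modal <- as.integer(names(tab)[tab == max(tab)])
        data.frame(position = max(modal), support = length(p),
                   min_pos = min(p), max_pos = max(p))
    }))
    out[order(out$position), , drop = FALSE]
}

# per-base mean over a sparse value map (named vector position -> value)
oracleMean <- function(valmap, from, to) {
    if (to < from) return(list(mean = NA_real_, fraction = NaN))
    pos <- as.character(seq(from, to))
    v <- valmap[pos]
    v <- v[!is.na(v)]
    list(mean = if (length(v)) sum(v) / length(v) else NA_real_,
         fraction = length(v) / (to - from + 1))
}

# filter-then-count FDR recomputation, one pass per distinct cutoff
oracleFdr <- function(score, supported) {
    cuts <- sort(unique(score), decreasing = TRUE)
    do.call(rbind, lapply(cuts, function(c0) {
        sel <- score >= c0
        data.frame(cutoff = c0, n = sum(sel),
                   n_unsupported = sum(sel & !supported),
                   fdr = sum(sel & !supported) / sum(sel))
    }))
}

# O(n^2) truth matching for evaluateRecovery
oracleRecovery <- function(pred, sites, tol = 25L) {
    matched <- vapply(seq_len(nrow(sites)), function(i)
        any(pred$chrom == sites$chrom[i] &
            abs(pred$position - sites$true_pas[i]) <= tol), logical(1))
    is_false <- vapply(seq_len(nrow(pred)), function(j)
        !any(sites$chrom == pred$chrom[j] &
             abs(sites$true_pas - pred$position[j]) <= tol), logical(1))
    list(sensitivity = mean(matched),
         empirical_fdr = if (nrow(pred)) mean(is_false) else NA_real_)
}

# Genome mirror transform ----------------------------------------------------
# reflects every base p to L - p + 1 and flips strands; every downstream
# statistic must be invariant under this transform

mirrorPos <- function(p, L) L - p + 1L

flipStrand <- function(s) {
    c("+" = "-", "-" = "+", "*" = "*")[as.character(s)]
}

mirrorTx <- function(x, L) {
    ex <- exonRanges(x)
    ids <- rep(names(ex), lengths(ex))
    flat0 <- unlist(ex, use.names = FALSE)
    refl <- GRanges(seqnames(flat0),
                    IRanges(L - end(flat0) + 1L, L - start(flat0) + 1L),
                    strand = flipStrand(strand(flat0)))
    TranscriptModels(split(refl, factor(ids, levels = names(ex))),
                     geneId = unname(geneIds(x)))
}

mirrorEsts <- function(x, L) {
    bl <- estBlocks(x)
    flat <- unlist(bl, use.names = FALSE)
    refl <- GRanges(seqnames(flat),
                    IRanges(L - end(flat) + 1L, L - start(flat) + 1L),
                    strand = flipStrand(strand(flat)))
    EstAlignments(split(refl, factor(rep(names(bl), lengths(bl)),
                                     levels = names(bl))))
}

mirrorTrack <- function(x, L) {
    gr <- trackRanges(x)
    out <- GRanges(seqnames(gr),
                   IRanges(L - end(gr) + 1L, L - start(gr) + 1L),
                   score = gr$score)
    ScoreTrack(out, role = trackRole(x))
}

# Shared strong-signal scenario (generated once per test run) ----------------

.shared <- new.env()

strongScenario <- function() {
    if (is.null(.shared$sc))
        .shared$sc <- generateScenario(scenarioConfig(seed = 101L))
    .shared$sc
}

strongPtes <- function() {
    if (is.null(.shared$ptes))
        .shared$ptes <- detectPtes(strongScenario()$ests,
                                   strongScenario()$reference)
    .shared$ptes
}

strongCandidates <- function() {
    if (is.null(.shared$cands)) {
        sc <- strongScenario()
        cands <- findExtensionCandidates(sc$reference, sc$ortho)
        .shared$cands <- computeCd(cands, sc$coverage)
    }
    .shared$cands
}
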