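## Truth-labelled synthetic scenarios.  The generator emulates the three
## signals the method exploits: (i) per-base conservation that is elevated
## over the mature transcript and collapses immediately beyond the true
## PAS, (ii) clouds of EST 3' extremes within ~1 nt of true PASs plus
## uniformly placed decoy extreme clusters, and (iii) RNA-seq coverage that
## is dense up to the true PAS and near-silent beyond it.  Everything is
## deterministic given the seed, and all outputs round-trip through the
## package's own readers.

#' Configuration of a synthetic scenario
#'
#' Defaults describe a strong-signal genome: 30 three-exon genes on a 400
#' kb chromosome, 20 of which have an unannotated distal PAS 0.5-1.5 kb
#' beyond the annotated one; conservation is Normal per base with a 2.0
#' drop in mean beyond the mature transcript; true PASs attract
#' Poisson(8) EST ends jittered by at most 1 nt; per-base coverage
#' probability is 0.9 inside the transcribed region and 0.02 outside; and
#' every true extension is echoed by an orthologous model while 30% of
#' unextended genes get a decoy ortholog extension.
#'
#' @param seed RNG seed; all randomness flows from it.
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in nt.
#' @param n_genes number of genes (three exons each).
#' @param n_true_extended genes given a true distal PAS.
#' @param exon_len,intron_len,extension_len integer ranges
#'   \code{c(min, max)} for exon, intron and extension lengths.
#' @param intergene_gap range of extra space between gene slots.
#' @param mu_in,mu_out,sigma per-base conservation Normal means inside and
#'   outside mature transcripts, and common sd.
#' @param lambda_true Poisson mean of EST ends per true distal PAS (chosen
#'   so the expected support comfortably clears the support filter).
#' @param est_len range of EST alignment lengths.
#' @param decoy_rate_per_kb decoy extreme clusters per kb of chromosome.
#' @param decoy_support_extra decoy cluster support is 4 + Poisson(this).
#' @param p_in,p_out per-base covered probability inside the transcribed
#'   region (up to the true PAS) and outside it.
#' @param ortho_echo_frac fraction of true extensions echoed by an
#'   orthologous transcript.
#' @param ortho_decoy_frac fraction of unextended genes given a decoy
#'   ortholog extension (into untranscribed sequence).
#' @param promoter_flank nt upstream of each TSS kept at \code{mu_in}
#'   conservation: promoter elements are under selection, so the
#'   conservation drop is a 3'-end signature, not a 5' one.
#' @return a \code{ScenarioConfig} list.
#' @export
scenarioConfig <- function(seed = 1L, chrom = "chrS",
                           chrom_length = 400000L,
                           n_genes = 30L, n_true_extended = 20L,
                           exon_len = c(150L, 400L),
                           intron_len = c(500L, 1500L),
                           extension_len = c(500L, 1500L),
                           intergene_gap = c(1500L, 3000L),
                           mu_in = 1.5, mu_out = -0.5, sigma = 0.5,
                           lambda_true = 8,
                           est_len = c(200L, 500L),
                           decoy_rate_per_kb = 0.5,
                           decoy_support_extra = 2,
                           p_in = 0.9, p_out = 0.02,
                           ortho_echo_frac = 1.0,
                           ortho_decoy_frac = 0.3,
                           promoter_flank = 200L) {
    cfg <- as.list(environment())
    probs <- c(p_in = p_in, p_out = p_out,
               ortho_echo_frac = ortho_echo_frac,
               ortho_decoy_frac = ortho_decoy_frac)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]: ",
             paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
    if (n_true_extended > n_genes)
        stop("n_true_extended cannot exceed n_genes")
    structure(cfg, class = c("ScenarioConfig", "list"))
}

runifInt <- function(n, range) {
    if (range[1] >= range[2]) return(rep(as.integer(range[1]), n))
    as.integer(range[1] + floor(stats::runif(n) *
                                (range[2] - range[1] + 1L)))
}

jitter1 <- function(n) {
    sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(0.15, 0.7, 0.15))
}

#' Generate a complete synthetic scenario
#'
#' Builds a reference annotation, orthologous models, EST alignments, a
#' conservation track, a coverage track and a truth table; optionally
#' writes them to \code{out_dir} as \code{ref.gtf}, \code{ortho.bed12},
#' \code{ests.bed12}, \code{cons.wig}, \code{cov.bedgraph} and
#' \code{truth.tsv} (all parseable by the package's readers, byte-identical
#' for identical configs).
#'
#' @param config a \code{\link{scenarioConfig}}.
#' @param out_dir optional output directory.
#' @return list with elements \code{reference}, \code{ortho}, \code{ests}
#'   (package objects), \code{conservation}, \code{coverage}
#'   (\code{ScoreTrack}s), \code{truth} (data.frame), \code{config}, and
#'   \code{files} (named paths when \code{out_dir} was given).
#' @export
generateScenario <- function(config = scenarioConfig(), out_dir = NULL) {
    set.seed(config$seed)
    clear3 <- 2L * config$extension_len[2] + 200L
    clear5 <- 500L
    cursor <- 1000L
    ext_set <- sort(sample(config$n_genes, config$n_true_extended))
    genes <- list(); ref_ex <- list(); ortho_ex <- list()
    ortho_gid <- character(0)
    # EST blocks accumulated as flat vectors, assembled into one
    # GRangesList at the end (much cheaper than element-wise growth)
    est_id <- character(0); est_s <- integer(0); est_e <- integer(0)
    est_st <- character(0)
    addEst <- function(id, s, e, st) {
        est_id <<- c(est_id, id); est_s <<- c(est_s, s)
        est_e <<- c(est_e, e)
        est_st <<- c(est_st, rep(st, length.out = length(s)))
    }
    for (i in seq_len(config$n_genes)) {
        st <- sample(c("+", "-"), 1L)
        e <- runifInt(3L, config$exon_len)
        ints <- runifInt(2L, config$intron_len)
        extended <- i %in% ext_set
        L <- if (extended) runifInt(1L, config$extension_len) else NA_integer_
        g0 <- cursor + (if (st == "+") clear5 else clear3)
        starts <- g0 + cumsum(c(0L, e[1] + ints[1], e[2] + ints[2]))
        ends <- starts + e - 1L
        gw_end <- ends[3]
        tx <- sprintf("tx%02d", i)
        gid <- sprintf("g%02d", i)
        exons <- GRanges(config$chrom, IRanges(starts, ends), strand = st)
        ref_ex[[tx]] <- exons
        if (st == "+") {
            tss <- starts[1]; apas <- ends[3]
            tpas <- if (extended) apas + L else NA_integer_
        } else {
            tss <- ends[3]; apas <- starts[1]
            tpas <- if (extended) apas - L else NA_integer_
        }
        ortho_id <- NA_character_; decoy_pas <- NA_integer_
        if (extended && stats::runif(1) < config$ortho_echo_frac) {
            ortho_id <- paste0("ortho_", tx)
            oex <- exons
            if (st == "+") end(oex)[3] <- tpas else start(oex)[1] <- tpas
            ortho_ex[[ortho_id]] <- oex
            ortho_gid <- c(ortho_gid, gid)
        } else if (!extended && stats::runif(1) < config$ortho_decoy_frac) {
            ortho_id <- paste0("orthodecoy_", tx)
            Ld <- runifInt(1L, config$extension_len)
            oex <- exons
            if (st == "+") {
                end(oex)[3] <- ends[3] + Ld
                decoy_pas <- ends[3] + Ld
            } else {
                start(oex)[1] <- starts[1] - Ld
                decoy_pas <- starts[1] - Ld
            }
            ortho_ex[[ortho_id]] <- oex
            ortho_gid <- c(ortho_gid, gid)
        }
        # EST cloud at the true distal PAS
        if (extended) {
            n_est <- stats::rpois(1L, config$lambda_true)
            if (n_est > 0L) {
                jit <- jitter1(n_est)
                len <- runifInt(n_est, config$est_len)
                endp <- tpas + jit
                ids <- sprintf("est_%s_%02d", tx, seq_len(n_est))
                if (st == "+") addEst(ids, endp - len + 1L, endp, st)
                else addEst(ids, endp, endp + len - 1L, st)
            }
        }
        # spliced ESTs spanning each intron (exercise the splice-site filter)
        for (j in 1:2) {
            id <- sprintf("estsp_%s_%d", tx, j)
            addEst(rep(id, 2L), c(ends[j] - 79L, starts[j + 1]),
                   c(ends[j], starts[j + 1] + 79L), st)
        }
        genes[[i]] <- data.frame(
            record = "gene", id = gid, transcript_id = tx,
            chrom = config$chrom, strand = st, tss = tss,
            annotated_pas = apas, true_pas = tpas, extended = extended,
            ortho_id = ortho_id, ortho_decoy_pas = decoy_pas,
            decoy_pos = NA_integer_, decoy_support = NA_integer_,
            expected_identity = NA_character_,
            nearest_gene = NA_character_, region = NA_character_,
            near_splice = NA)
        cursor <- gw_end + (if (st == "+") clear3 else clear5) +
            runifInt(1L, config$intergene_gap)
    }
    if (cursor + 1000L > config$chrom_length)
        stop("infeasible geometry: genes and extensions exceed ",
             "chrom_length (need ~", cursor + 1000L, " nt)")
    genes <- do.call(rbind, genes)

    ## decoy extreme clusters, uniform over the chromosome
    n_decoy <- stats::rpois(1L, config$decoy_rate_per_kb *
                            config$chrom_length / 1000)
    decoys <- NULL
    if (n_decoy > 0L) {
        dpos <- sort(sample(seq(5000L, config$chrom_length - 5000L),
                            n_decoy))
        dsup <- 4L + stats::rpois(n_decoy, config$decoy_support_extra)
        for (j in seq_len(n_decoy)) {
            dir_right <- stats::runif(1) < 0.5
            jit <- jitter1(dsup[j])
            len <- runifInt(dsup[j], config$est_len)
            p <- dpos[j] + jit
            ids <- sprintf("estdec_%03d_%02d", j, seq_len(dsup[j]))
            if (dir_right) addEst(ids, p, p + len - 1L, "*")
            else addEst(ids, p - len + 1L, p, "*")
        }
        lab <- decoyExpectedIdentity(dpos, genes, ref_ex)
        decoys <- data.frame(
            record = "decoy", id = sprintf("decoy%03d", seq_len(n_decoy)),
            transcript_id = NA_character_, chrom = config$chrom,
            strand = NA_character_, tss = NA_integer_,
            annotated_pas = NA_integer_, true_pas = NA_integer_,
            extended = NA, ortho_id = NA_character_,
            ortho_decoy_pas = NA_integer_, decoy_pos = dpos,
            decoy_support = dsup, expected_identity = lab$identity,
            nearest_gene = lab$nearest_gene, region = lab$region,
            near_splice = lab$near_splice)
    }
    truth <- rbind(genes, decoys)
    rownames(truth) <- NULL

    reference <- TranscriptModels(GRangesList(ref_ex),
                                  geneId = genes$id)
    ortho <- TranscriptModels(GRangesList(ortho_ex), geneId = ortho_gid)
    est_flat <- GRanges(config$chrom, IRanges(est_s, est_e),
                        strand = est_st)
    ests <- EstAlignments(split(est_flat,
                                factor(est_id, levels = unique(est_id))))

    ## per-base conservation and coverage
    mature <- matureSpans(genes)
    mu <- rep(config$mu_out, config$chrom_length)
    pcov <- rep(config$p_out, config$chrom_length)
    for (r in seq_len(nrow(mature))) {
        idx <- mature$start[r]:mature$end[r]
        mu[idx] <- config$mu_in
        pcov[idx] <- config$p_in
        # conserved promoter flank upstream of the TSS: conservation (but
        # not transcription) extends past the 5' end, so the conservation
        # drop is specific to 3' ends
        fl <- if (genes$strand[r] == "+") {
            max(1L, mature$start[r] - config$promoter_flank):mature$start[r]
        } else {
            mature$end[r]:min(config$chrom_length,
                              mature$end[r] + config$promoter_flank)
        }
        mu[fl] <- config$mu_in
    }
    cons_val <- round(stats::rnorm(config$chrom_length, mu, config$sigma), 4)
    conservation <- ScoreTrack(
        GRanges(config$chrom,
                IRanges(seq_len(config$chrom_length), width = 1L),
                score = cons_val),
        role = "conservation")
    depth <- stats::rbinom(config$chrom_length, 1L, pcov)
    drle <- Rle(depth)
    dend <- cumsum(runLength(drle))
    dstart <- dend - runLength(drle) + 1L
    keep <- runValue(drle) > 0L
    coverage <- ScoreTrack(
        GRanges(config$chrom, IRanges(dstart[keep], dend[keep]),
                score = runValue(drle)[keep]),
        role = "coverage")

    out <- list(reference = reference, ortho = ortho, ests = ests,
                conservation = conservation, coverage = coverage,
                truth = truth, config = config)
    if (!is.null(out_dir)) {
        dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
        files <- c(ref = file.path(out_dir, "ref.gtf"),
                   ortho = file.path(out_dir, "ortho.bed12"),
                   ests = file.path(out_dir, "ests.bed12"),
                   cons = file.path(out_dir, "cons.wig"),
                   cov = file.path(out_dir, "cov.bedgraph"),
                   truth = file.path(out_dir, "truth.tsv"))
        writeGtf(reference, files[["ref"]])
        writeBed12(ortho, files[["ortho"]])
        writeBed12(ests, files[["ests"]])
        writeTrack(conservation, files[["cons"]])
        writeTrack(coverage, files[["cov"]])
        utils::write.table(truth, files[["truth"]], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        out$files <- files
    }
    out
}

## genomic span of each mature transcript (TSS through true distal PAS
## where one exists, annotated PAS otherwise), introns included
matureSpans <- function(genes) {
    pas <- ifelse(is.na(genes$true_pas), genes$annotated_pas,
                  genes$true_pas)
    data.frame(start = pmin(genes$tss, pas), end = pmax(genes$tss, pas))
}

## geometric expectation for decoy classification, derived directly from
## the stated rule (nearest annotated gene end; orientation towards the
## decoy means putative PAS) -- independent of classifyPtes
decoyExpectedIdentity <- function(pos, genes, ref_ex) {
    gs <- pmin(genes$tss, genes$annotated_pas)
    ge <- pmax(genes$tss, genes$annotated_pas)
    bounds <- sort(unique(unlist(lapply(ref_ex, function(g)
        c(start(g), end(g))))))
    n <- length(pos)
    identity <- character(n); nearest <- character(n)
    region <- character(n); near_splice <- logical(n)
    for (i in seq_len(n)) {
        p <- pos[i]
        near_splice[i] <- any(abs(bounds - p) <= 25L)
        inside <- which(p >= gs & p <= ge)
        if (length(inside) > 0L) {
            in_exon <- any(vapply(inside, function(g)
                any(p >= start(ref_ex[[g]]) & p <= end(ref_ex[[g]])),
                logical(1)))
            region[i] <- if (in_exon) "exon" else "intron"
            nearest[i] <- genes$transcript_id[inside[1]]
            st <- unique(genes$strand[inside])
            identity[i] <- if (in_exon) "in_exon"
                           else if (length(st) > 1L) "undetermined"
                           else "putative_PAS"
            next
        }
        region[i] <- "intergenic"
        dd <- pmin(abs(p - gs), abs(p - ge))
        cand <- which(dd == min(dd))
        lab <- vapply(cand, function(g) {
            towards <- (genes$strand[g] == "+") == (p > ge[g])
            if (towards) "putative_PAS" else "putative_TSS"
        }, character(1))
        nearest[i] <- genes$transcript_id[cand[1]]
        identity[i] <- if (length(unique(lab)) == 1L) lab[1]
                       else "undetermined"
    }
    list(identity = identity, nearest_gene = nearest, region = region,
         near_splice = near_splice)
}

#' Score recovery of planted PASs
#'
#' A prediction matches a planted true distal PAS when it lies within
#' \code{match_tolerance} nt on the same chromosome.  Sensitivity is the
#' fraction of planted sites matched by at least one prediction; the
#' empirical FDR is the fraction of predictions matching no planted site
#' (undefined, and flagged, when there are no predictions).
#'
#' @param predictions data.frame with columns \code{chrom} and
#'   \code{position}.
#' @param truth truth table from \code{\link{generateScenario}}.
#' @param match_tolerance matching tolerance in nt.
#' @return list with \code{sensitivity}, \code{empirical_fdr},
#'   \code{fdr_defined}, \code{n_true}, \code{n_matched}, \code{n_pred},
#'   \code{n_false}.
#' @export
evaluateRecovery <- function(predictions, truth, match_tolerance = 25L) {
    sites <- truth[truth$record == "gene" & !is.na(truth$true_pas), ]
    n_true <- nrow(sites)
    n_pred <- nrow(predictions)
    matched <- vapply(seq_len(n_true), function(i) {
        any(predictions$chrom == sites$chrom[i] &
            abs(predictions$position - sites$true_pas[i]) <=
                match_tolerance)
    }, logical(1))
    is_false <- vapply(seq_len(n_pred), function(j) {
        !any(sites$chrom == predictions$chrom[j] &
             abs(sites$true_pas - predictions$position[j]) <=
                 match_tolerance)
    }, logical(1))
    list(sensitivity = if (n_true > 0) sum(matched) / n_true else NA_real_,
         empirical_fdr = if (n_pred > 0) sum(is_false) / n_pred
                         else NA_real_,
         fdr_defined = n_pred > 0,
         n_true = n_true, n_matched = sum(matched),
         n_pred = n_pred, n_false = sum(is_false))
}
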