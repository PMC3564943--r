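## End-to-end orchestration: PTE detection -> CDI -> classification ->
## (optional) orthology extension + CD -> FDR curves, with TSV outputs and
## a machine-readable manifest.

#' Write a table with a commented header line
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
    if (nrow(df) > 0L)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a table written by \code{\link{writeTsv}}
#'
#' @param path input path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
    header <- sub("^#\\s*", "", readLines(path, n = 1L))
    cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            col.names = cols, stringsAsFactors = FALSE,
                            na.strings = "NA")
    df
}

readModels <- function(path) {
    if (grepl("\\.gtf$", path, ignore.case = TRUE)) readGtf(path)
    else readBed12(path, as = "transcripts")
}

#' Run the full discovery pipeline
#'
#' Executes PTE detection, CDI scoring, classification, optional
#' orthology-based extension scoring (CD), and FDR estimation, writing all
#' stage tables plus a JSON manifest of per-stage counts to
#' \code{out_dir}.  When no explicit validating annotation is given the
#' orthologous models serve as the validating database.
#'
#' @param paths named list of input paths: \code{reference} (GTF or
#'   BED12), \code{ests} (BED12), \code{conservation} (wig/bedGraph);
#'   optional \code{ortho} (BED12 or GTF), \code{coverage} (one or more
#'   bedGraph paths, pooled), \code{validating} (named vector of
#'   annotation paths).
#' @param out_dir output directory.
#' @param pte_config a \code{\link{pteConfig}}.
#' @param cdi_config a \code{\link{cdiConfig}}.
#' @param pas_tolerance positional tolerance for database support, nt.
#' @param min_extension,collapse passed to
#'   \code{\link{findExtensionCandidates}}.
#' @param min_cd report candidates with CD above this in the manifest
#'   count.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return invisibly, a list with the stage tables (\code{ptes},
#'   \code{cdi}, \code{candidates}, \code{fdr_cdi}, \code{fdr_cd}) and the
#'   \code{manifest}.
#' @export
runAll <- function(paths, out_dir, pte_config = pteConfig(),
                   cdi_config = cdiConfig(), pas_tolerance = 25L,
                   min_extension = 1L, collapse = "none", min_cd = 50,
                   seed = NA_integer_) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    reference <- readModels(paths$reference)
    ests <- readBed12(paths$ests, as = "ests")
    conservation <- readTrack(paths$conservation, role = "conservation")

    classified <- detectPtes(ests, reference, pte_config)
    writeTsv(classified, file.path(out_dir, "ptes.tsv"))

    anchors <- pteAnchors(classified)
    cdi <- computeCdi(anchors, conservation, cdi_config)
    writeTsv(cdi, file.path(out_dir, "cdi.tsv"))

    ortho <- NULL; candidates <- NULL
    if (!is.null(paths$ortho)) {
        ortho <- readModels(paths$ortho)
        candidates <- findExtensionCandidates(reference, ortho,
                                              min_extension = min_extension,
                                              collapse = collapse)
        if (!is.null(paths$coverage)) {
            tracks <- lapply(paths$coverage, readTrack, role = "coverage")
            pooled <- mergeTissueCoverage(tracks)
            candidates <- computeCd(candidates, pooled)
            candidates <- candidates[order(-ifelse(is.na(candidates$cd),
                                                   -Inf, candidates$cd)), ,
                                     drop = FALSE]
        }
        writeTsv(candidates, file.path(out_dir, "candidates.tsv"))
    }

    validating <- list()
    if (!is.null(paths$validating)) {
        validating <- lapply(paths$validating, readModels)
        if (is.null(names(validating)))
            names(validating) <- basename(unlist(paths$validating))
    } else if (!is.null(ortho)) {
        validating <- list(ortho = ortho)
    }

    fdr_cdi <- NULL; fdr_cd <- NULL
    if (length(validating) > 0L) {
        pas_cdi <- cdi[cdi$identity == "putative_PAS" & cdi$defined, ,
                       drop = FALSE]
        if (nrow(pas_cdi) > 0L) {
            sup <- isSupported(
                data.frame(pas_id = pas_cdi$id, chrom = pas_cdi$chrom,
                           position = pas_cdi$position),
                validating, reference, pas_tolerance)
            fdr_cdi <- fdrCurve(
                data.frame(pas_id = pas_cdi$id, score = pas_cdi$cdi), sup)
            writeTsv(fdr_cdi, file.path(out_dir, "fdr_cdi.tsv"))
        }
        if (!is.null(candidates) && !is.null(candidates$cd) &&
            nrow(candidates) > 0L) {
            ids <- paste0(candidates$reference_transcript_id, "|",
                          candidates$ortho_transcript_id)
            sup <- isSupported(
                data.frame(pas_id = ids, chrom = candidates$chrom,
                           position = candidates$putative_pas),
                validating, reference, pas_tolerance)
            fdr_cd <- fdrCurve(
                data.frame(pas_id = ids, score = candidates$cd), sup)
            writeTsv(fdr_cd, file.path(out_dir, "fdr_cd.tsv"))
        }
    }

    manifest <- list(
        seed = seed,
        n_transcripts = length(reference),
        n_ests = length(estIds(ests)),
        n_ptes = nrow(classified),
        n_putative_pas = sum(classified$identity == "putative_PAS"),
        n_putative_tss = sum(classified$identity == "putative_TSS"),
        n_undetermined = sum(classified$identity == "undetermined"),
        n_cdi_defined = sum(cdi$defined),
        n_candidates = if (is.null(candidates)) 0L else nrow(candidates),
        n_candidates_above_min_cd =
            if (is.null(candidates) || is.null(candidates$cd)) 0L
            else sum(!is.na(candidates$cd) & candidates$cd > min_cd),
        min_cd = min_cd,
        pte_config = unclass(pte_config),
        cdi_config = unclass(cdi_config),
        pas_tolerance = pas_tolerance)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(ptes = classified, cdi = cdi, candidates = candidates,
                   fdr_cdi = fdr_cdi, fdr_cd = fdr_cd,
                   manifest = manifest))
}
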