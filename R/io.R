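#' @importFrom utils read.delim write.table packageVersion
NULL

.readTsv <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path, what = "table") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c(
        sprintf("# dmsfunc %s: %s", as.character(packageVersion("dmsfunc")),
                what),
        "# positions are 1-based residues; CDS positions 1-based nucleotides"),
        con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a screen sample sheet
#'
#' @param path tab-separated file with columns `sample_id`, `replicate_id`,
#'   `timepoint` (`early`/`late`).
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
    ss <- .readTsv(path)
    need <- c("sample_id", "replicate_id", "timepoint")
    if (!all(need %in% colnames(ss)))
        stop("sample sheet must have columns: ", paste(need, collapse = ", "))
    bad <- !ss$timepoint %in% c("early", "late")
    if (any(bad))
        stop("invalid timepoint in sample sheet row(s) ",
             paste(which(bad), collapse = ", "),
             " (expected 'early' or 'late')")
    if (anyDuplicated(ss$sample_id))
        stop("duplicate sample_id in sample sheet")
    ss
}

#' Read variant counts
#'
#' Accepts the long dialect (columns `variant_id`, `sample_id`, `count`)
#' or a wide matrix dialect (`variant_id` plus one column per sample).
#' Counts are validated against the sample sheet: unknown samples,
#' negative counts and duplicate variant ids are rejected with the
#' offending row/column named.
#'
#' @param path counts file (tab-separated).
#' @param sample_sheet path to the sample sheet, or a data.frame from
#'   [readSampleSheet()].
#' @param library optional [DmsLibrary-class] attached as rowData.
#' @return A [ScreenCounts-class].
#' @export
readCounts <- function(path, sample_sheet, library = NULL) {
    if (is.character(sample_sheet))
        sample_sheet <- readSampleSheet(sample_sheet)
    tab <- .readTsv(path)
    if (all(c("variant_id", "sample_id", "count") %in% colnames(tab))) {
        bad <- which(!is.finite(tab$count) | tab$count < 0 |
                     tab$count != round(tab$count))
        if (length(bad))
            stop("invalid count at row ", bad[1L], " of ", path,
                 " (variant ", tab$variant_id[bad[1L]], ", sample ",
                 tab$sample_id[bad[1L]], ")")
        unknown <- setdiff(unique(tab$sample_id), sample_sheet$sample_id)
        if (length(unknown))
            stop("counts reference samples absent from the sample sheet: ",
                 paste(unknown, collapse = ", "))
        vids <- unique(tab$variant_id)
        sids <- sample_sheet$sample_id
        m <- matrix(0L, length(vids), length(sids),
                    dimnames = list(vids, sids))
        m[cbind(match(tab$variant_id, vids),
                match(tab$sample_id, sids))] <- as.integer(tab$count)
    } else if ("variant_id" %in% colnames(tab)) {
        vids <- tab$variant_id
        if (anyDuplicated(vids))
            stop("duplicate variant_id in ", path, ": ",
                 vids[duplicated(vids)][1L])
        m <- as.matrix(tab[, setdiff(colnames(tab), "variant_id"),
                           drop = FALSE])
        rownames(m) <- vids
        if (any(!is.finite(m) | m < 0 | m != round(m))) {
            bad <- which(!is.finite(m) | m < 0 | m != round(m),
                         arr.ind = TRUE)[1L, ]
            stop("invalid count in ", path, " at variant ",
                 vids[bad[1L]], ", column ", colnames(m)[bad[2L]])
        }
        storage.mode(m) <- "integer"
    } else {
        stop(path, ": unrecognized counts dialect (need variant_id/",
             "sample_id/count columns, or variant_id plus sample columns)")
    }
    missing <- setdiff(sample_sheet$sample_id, colnames(m))
    if (length(missing))
        stop("sample sheet samples missing from counts: ",
             paste(missing, collapse = ", "))
    ScreenCounts(m[, sample_sheet$sample_id, drop = FALSE], sample_sheet,
                 library = library)
}

#' Write counts in the long dialect
#'
#' @param counts a [ScreenCounts-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeCounts <- function(counts, path) {
    cts <- SummarizedExperiment::assay(counts, "counts")
    long <- data.frame(
        variant_id = rep(rownames(cts), times = ncol(cts)),
        sample_id = rep(colnames(cts), each = nrow(cts)),
        count = as.vector(cts))
    .writeTsv(long, path, "variant counts (long dialect)")
}

#' Write a variant library table
#'
#' @param library a [DmsLibrary-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeLibrary <- function(library, path) {
    v <- as.data.frame(variantTable(library))
    v$alt_codon_or_fs <- ifelse(v$consequence == "frameshift",
                                sprintf("del%+d", v$fs_offset), v$alt_codon)
    .writeTsv(v[, c("variant_id", "position", "ref_codon",
                    "alt_codon_or_fs", "ref_aa", "alt_aa", "consequence")],
              path, paste("variant library for", library@orf_id))
}

#' Write a functional score table
#'
#' One row per variant: position, consequence, per-replicate z columns
#' (`z.<replicate>`), mean and SD across replicates, replicate count and
#' flag.
#'
#' @param scores a [FunctionalScores-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeScores <- function(scores, path) {
    s <- as.data.frame(scoreTable(scores))
    z <- replicateZ(scores)
    colnames(z) <- paste0("z.", colnames(z))
    .writeTsv(cbind(s[, c("variant_id", "position", "consequence")],
                    as.data.frame(z),
                    s[, c("mean_z", "sd_z", "n_replicates", "flag")]),
              path, "functional z-scores")
}

#' Read a predictor score table
#'
#' Two dialects are recognized: the CADD-style dialect (`Chrom`, `Pos`,
#' `Ref`, `Alt`, `RawScore`, `PHRED`; `Pos` is taken as the 1-based CDS
#' position and `PHRED` as the score) and a generic dialect
#' (`cds_position`, `ref`, `alt`, `score`, optional `consequence`).
#'
#' @param path tab-separated predictor file.
#' @param tool `"CADD"`, `"REVEL"` or `"AlphaMissense"` (stored as the
#'   table's `tool` attribute).
#' @param library optional [DmsLibrary-class]; when given, a `consequence`
#'   column is derived for rows resolvable against the library.
#' @return data.frame with a `tool` attribute.
#' @export
readPredictorTable <- function(path, tool, library = NULL) {
    if (!tool %in% .TOOLS)
        stop("unknown tool: ", tool)
    tab <- .readTsv(path)
    if (all(c("Pos", "Ref", "Alt", "PHRED") %in% colnames(tab))) {
        tab <- data.frame(cds_position = as.integer(tab$Pos),
                          ref = tab$Ref, alt = tab$Alt,
                          score = as.numeric(tab$PHRED))
    } else if (all(c("cds_position", "ref", "alt", "score") %in%
                   colnames(tab))) {
        tab$cds_position <- as.integer(tab$cds_position)
        tab$score <- as.numeric(tab$score)
    } else {
        stop(path, ": unrecognized predictor dialect")
    }
    if (any(!is.finite(tab$score)))
        stop(path, ": non-finite predictor scores")
    if (any(tab$ref == tab$alt))
        stop(path, ": ref and alt base must differ")
    if (!is.null(library) && !"consequence" %in% colnames(tab)) {
        tab$consequence <- vapply(seq_len(nrow(tab)), function(i) {
            hit <- .matchSnv(tab$cds_position[i], tab$ref[i], tab$alt[i],
                             library)
            if (is.na(hit$variant)) NA_character_
            else variantTable(library)$consequence[
                match(hit$variant, variantTable(library)$variant_id)]
        }, character(1L))
    }
    attr(tab, "tool") <- tool
    tab
}

#' Read a pathogenicity label table
#'
#' @param path tab-separated file with columns `variant_id` (or
#'   `protein_change`), `label` and optional `provenance`. Labels may be
#'   `positive`/`negative`, `TRUE`/`FALSE` or 1/0.
#' @return data.frame with `variant_id`, logical `label`, `provenance`.
#' @export
readLabelTable <- function(path) {
    tab <- .readTsv(path)
    if (!"variant_id" %in% colnames(tab) &&
        "protein_change" %in% colnames(tab))
        tab$variant_id <- tab$protein_change
    if (!all(c("variant_id", "label") %in% colnames(tab)))
        stop(path, ": need variant_id (or protein_change) and label columns")
    lab <- tolower(as.character(tab$label))
    if (!all(lab %in% c("positive", "negative", "true", "false", "1", "0")))
        stop(path, ": labels must be positive/negative (or logical)")
    tab$label <- lab %in% c("positive", "true", "1")
    if (!"provenance" %in% colnames(tab)) tab$provenance <- NA_character_
    tab[, c("variant_id", "label", "provenance")]
}

#' Read a paired region/gene log2-fold-change table
#'
#' @param path tab-separated file with columns `region_id`, `gene_id`,
#'   `region_l2fc`, `gene_l2fc` and optional `region_padj` / `gene_padj`.
#' @param padj_max when given and padj columns are present, keep only
#'   pairs with both adjusted p-values below it (e.g. 0.05).
#' @return data.frame of pairs.
#' @export
readPairsTable <- function(path, padj_max = NULL) {
    tab <- .readTsv(path)
    need <- c("region_id", "gene_id", "region_l2fc", "gene_l2fc")
    if (!all(need %in% colnames(tab)))
        stop(path, ": need columns ", paste(need, collapse = ", "))
    if (!is.null(padj_max)) {
        for (col in c("region_padj", "gene_padj"))
            if (col %in% colnames(tab))
                tab <- tab[is.finite(tab[[col]]) & tab[[col]] < padj_max, ,
                           drop = FALSE]
    }
    tab
}

#' Run the full analysis pipeline
#'
#' Orchestrates the package stages from a configuration list (or YAML
#' file): simulate a screen (or read counts), score it, call LOF variants
#' and intolerant residues, and optionally benchmark against a predictor
#' table, compute an ROC against labels, and the quadrant concordance of a
#' pairs table. All artifacts are written as tab-separated files under
#' `out_dir` together with a `run_report.yaml` echoing the configuration
#' and package version.
#'
#' @param config configuration list or path to a YAML file. Recognized
#'   keys: `simulate` (arguments to [simConfig()]), or `orf` + `counts` +
#'   `sample_sheet` paths; `scoring` (arguments to [scoreScreen()]);
#'   `lof_threshold`; `predictor` (list with `path`, `tool`); `labels`
#'   (path); `pairs` (list with `path`, optional `padj_max`, `l2fc_min`);
#'   `seed`.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return Invisibly, a list with the in-memory objects (`library`,
#'   `counts`, `scores`, `lof`, `residues`, and any optional stage
#'   results) plus the paths written.
#' @export
runPipeline <- function(config, out_dir, seed = NULL) {
    if (is.character(config))
        config <- yaml::read_yaml(config)
    if (!is.null(seed)) config$seed <- seed
    if (is.null(config$simulate) && is.null(config$counts))
        stop("configuration must provide either a 'simulate' block or ",
             "'counts' + 'sample_sheet' + 'orf' paths")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res <- list()
    if (!is.null(config$simulate)) {
        simargs <- config$simulate
        if (is.null(simargs$seed)) simargs$seed <- config$seed
        if (is.null(simargs$seed))
            stop("a seed is required to simulate")
        cfg <- do.call(simConfig, simargs)
        sim <- simulateScreen(cfg)
        res$simulation <- sim
        res$library <- sim@library
        res$counts <- simCounts(sim)
        writeCounts(res$counts, file.path(out_dir, "counts.tsv"))
        .writeTsv(as.data.frame(SummarizedExperiment::colData(res$counts)),
                  file.path(out_dir, "sample_sheet.tsv"), "sample sheet")
        .writeTsv(as.data.frame(simTruth(sim)),
                  file.path(out_dir, "sim_truth.tsv"),
                  "simulation ground truth")
    } else {
        orf <- readOrfFasta(config$orf, id = config$orf_id)
        res$library <- enumerateLibrary(orf,
            do.call(libraryScheme, config$scheme %||% list()))
        res$counts <- readCounts(config$counts, config$sample_sheet,
                                 library = res$library)
    }
    writeLibrary(res$library, file.path(out_dir, "library.tsv"))
    sc_args <- c(list(counts = res$counts, library = res$library),
                 config$scoring %||% list())
    res$scores <- do.call(scoreScreen, sc_args)
    writeScores(res$scores, file.path(out_dir, "scores.tsv"))
    .writeTsv(as.data.frame(baselineStats(res$scores)),
              file.path(out_dir, "baseline.tsv"), "rolling silent baseline")
    thr <- config$lof_threshold %||% 2
    res$lof <- callLof(res$scores, threshold = thr)
    .writeTsv(as.data.frame(res$lof), file.path(out_dir, "lof_calls.tsv"),
              sprintf("LOF calls at mean_z > %g", thr))
    res$residues <- tryCatch(residueIntolerance(res$scores),
                             error = function(e) e)
    if (!inherits(res$residues, "error")) {
        .writeTsv(as.data.frame(res$residues),
                  file.path(out_dir, "residue_intolerance.tsv"),
                  sprintf("residue intolerance (cutoff %.4f)",
                          S4Vectors::metadata(res$residues)$cutoff))
    }
    hm <- heatmapMatrix(res$scores, res$library)
    .writeTsv(data.frame(alt_aa = rownames(hm), hm, check.names = FALSE),
              file.path(out_dir, "heatmap_matrix.tsv"),
              "variant-effect heatmap matrix (columns = positions)")
    if (!is.null(config$predictor)) {
        pred <- readPredictorTable(config$predictor$path,
                                   config$predictor$tool,
                                   library = res$library)
        res$concordance_records <- mergeDmsPredictor(
            res$scores, res$library, pred, dms_threshold = thr)
        res$concordance <- concordanceSummary(res$concordance_records)
        .writeTsv(as.data.frame(res$concordance),
                  file.path(out_dir, "concordance.tsv"),
                  sprintf("DMS/%s concordance", config$predictor$tool))
    }
    if (!is.null(config$labels)) {
        labels <- readLabelTable(config$labels)
        res$roc <- rocAuc(labels, meanZ(res$scores))
        .writeTsv(as.data.frame(res$roc$curve),
                  file.path(out_dir, "roc_curve.tsv"),
                  sprintf("ROC curve, AUC = %.4f", res$roc$auc))
    }
    if (!is.null(config$pairs)) {
        pairs <- readPairsTable(config$pairs$path,
                                padj_max = config$pairs$padj_max)
        res$quadrant <- quadrantConcordance(
            pairs, l2fc_min = config$pairs$l2fc_min %||% 1)
        q <- res$quadrant
        .writeTsv(data.frame(t(c(q$quadrants, n = q$n,
                                 concordance_fraction =
                                     q$concordance_fraction,
                                 odds_ratio = q$odds_ratio,
                                 fisher_p = q$fisher_p))),
                  file.path(out_dir, "quadrant_concordance.tsv"),
                  "ATAC/RNA quadrant concordance")
    }
    report <- list(
        package = "dmsfunc",
        version = as.character(packageVersion("dmsfunc")),
        config = config,
        n_variants = length(res$library),
        n_lof = S4Vectors::metadata(res$lof)$n_lof)
    if (!inherits(res$residues, "error"))
        report$n_intolerant_residues <-
            S4Vectors::metadata(res$residues)$n_intolerant
    yaml::write_yaml(report, file.path(out_dir, "run_report.yaml"))
    invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
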