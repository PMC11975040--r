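#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowData<-
NULL

.CONSEQUENCES <- c("silent", "missense", "nonsense", "frameshift")

#' Codon-level variant library over an ORF
#'
#' A `DmsLibrary` couples a reference open reading frame with the table of
#' codon-level library members (silent, missense, nonsense and frameshift
#' alleles), one row per variant. Positions are 1-based residue indices.
#'
#' @slot orf_id single character, identifier of the reference ORF.
#' @slot orf_seq single character, the ORF nucleotide sequence (A/C/G/T,
#'   length divisible by 3, no internal stop codon in the reference frame).
#' @slot variants `DataFrame` with columns `variant_id`, `position`,
#'   `ref_codon`, `alt_codon` (`NA` for frameshifts), `fs_offset` (`NA` for
#'   substitutions), `ref_aa`, `alt_aa` (`"*"` for stop, `"fs"` for
#'   frameshifts) and `consequence`.
#'
#' @seealso [enumerateLibrary()], [readOrfFasta()]
#' @export
setClass("DmsLibrary",
    slots = c(orf_id = "character", orf_seq = "character",
              variants = "DataFrame"))

setValidity("DmsLibrary", function(object) {
    msg <- character()
    seq <- object@orf_seq
    if (length(seq) != 1L || nchar(seq) == 0L)
        return("orf_seq must be a single non-empty string")
    if (nchar(seq) %% 3L != 0L)
        msg <- c(msg, "ORF length must be divisible by 3")
    if (grepl("[^ACGT]", seq))
        msg <- c(msg, "ORF must be over the alphabet {A,C,G,T}")
    if (length(msg) == 0L) {
        aa <- .translateOrf(seq)
        if (any(aa[-length(aa)] == "*"))
            msg <- c(msg, "ORF contains an internal stop codon")
    }
    v <- object@variants
    need <- c("variant_id", "position", "ref_codon", "alt_codon",
              "fs_offset", "ref_aa", "alt_aa", "consequence")
    if (!all(need %in% colnames(v))) {
        msg <- c(msg, paste("variants must have columns:",
                            paste(need, collapse = ", ")))
    } else if (nrow(v) > 0L) {
        if (anyDuplicated(v$variant_id))
            msg <- c(msg, "variant_id values must be unique")
        if (!all(v$consequence %in% .CONSEQUENCES))
            msg <- c(msg, "unknown consequence class")
        L <- nchar(seq) %/% 3L
        if (any(v$position < 1L | v$position > L))
            msg <- c(msg, "variant position outside ORF")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn DmsLibrary number of variants in the library.
#' @param x,object a `DmsLibrary`.
#' @export
setMethod("length", "DmsLibrary", function(x) nrow(x@variants))

#' @describeIn DmsLibrary the variant table as a `DataFrame`.
#' @export
setMethod("variantTable", "DmsLibrary", function(x) x@variants)

#' @describeIn DmsLibrary the ORF nucleotide sequence.
#' @export
setMethod("orfSequence", "DmsLibrary", function(x) x@orf_seq)

#' @describeIn DmsLibrary the number of residues encoded by the ORF.
#' @export
setMethod("nResidues", "DmsLibrary", function(x) nchar(x@orf_seq) %/% 3L)

setMethod("show", "DmsLibrary", function(object) {
    tab <- table(factor(object@variants$consequence, levels = .CONSEQUENCES))
    cat("DmsLibrary:", object@orf_id, "\n")
    cat("  ORF:", nchar(object@orf_seq), "nt /",
        nResidues(object), "residues\n")
    cat("  variants:", nrow(object@variants),
        sprintf("(%s)", paste(names(tab), as.integer(tab), sep = "=",
                              collapse = ", ")), "\n")
})

#' Screen counts container
#'
#' Integer read counts per variant per sample from a pooled DMS screen,
#' stored as a `SummarizedExperiment` with one `counts` assay. Rows are
#' library variants; columns are sequenced samples described by `colData`
#' columns `sample_id`, `replicate_id` and `timepoint` (`"early"` or
#' `"late"`). Within a scoring run every replicate must contribute exactly
#' one early and one late sample.
#'
#' @seealso [ScreenCounts()], [readCounts()], [scoreScreen()]
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("a 'counts' assay is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be finite non-negative integers")
    if (ncol(cts) > 0L && any(colSums(cts) <= 0))
        msg <- c(msg, "every sample must have a positive total count")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "replicate_id", "timepoint")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, paste("colData must have columns:",
                            paste(need, collapse = ", ")))
    else if (!all(cd$timepoint %in% c("early", "late")))
        msg <- c(msg, "timepoint must be 'early' or 'late'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "variant ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, variants x samples, with variant ids as
#'   rownames and sample ids as colnames.
#' @param sampleInfo data.frame with columns `sample_id`, `replicate_id` and
#'   `timepoint`, one row per column of `counts`.
#' @param library optional [DmsLibrary-class]; when given, its variant table
#'   (matched on `variant_id`) is attached as `rowData`.
#' @return A [ScreenCounts-class] object.
#' @examples
#' m <- matrix(5L, 2, 2, dimnames = list(c("M1V", "M1L"), c("s1", "s2")))
#' si <- data.frame(sample_id = c("s1", "s2"), replicate_id = "r1",
#'                  timepoint = c("early", "late"))
#' ScreenCounts(m, si)
#' @export
ScreenCounts <- function(counts, sampleInfo, library = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    sampleInfo <- as.data.frame(sampleInfo)
    if (is.null(colnames(counts)))
        colnames(counts) <- sampleInfo$sample_id
    idx <- match(colnames(counts), sampleInfo$sample_id)
    if (anyNA(idx))
        stop("samples missing from the sample sheet: ",
             paste(setdiff(colnames(counts), sampleInfo$sample_id),
                   collapse = ", "))
    cd <- DataFrame(sampleInfo[idx, , drop = FALSE])
    rownames(cd) <- cd$sample_id
    rd <- NULL
    if (!is.null(library)) {
        v <- variantTable(library)
        m <- match(rownames(counts), v$variant_id)
        if (anyNA(m))
            stop("counts contain variants absent from the library: ",
                 paste(utils::head(rownames(counts)[is.na(m)], 5),
                       collapse = ", "))
        rd <- v[m, , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    if (!is.null(rd)) SummarizedExperiment::rowData(se) <- rd
    new("ScreenCounts", se)
}

#' Rolling silent-codon baseline
#'
#' Per-replicate, per-residue rolling mean and standard deviation of silent
#' variant log2 fold changes, used to standardize variant L2FCs into
#' functional z-scores. `stats` holds one row per (replicate, position) with
#' `rolling_mean`, `rolling_sd`, `n_silent` (silent variants collected),
#' `window_used` (half-width actually applied after any expansion) and
#' `sd_floored` (whether the replicate-wide silent SD was substituted).
#'
#' @slot stats `DataFrame`, see above.
#' @slot replicate_sd named numeric, replicate-wide silent L2FC SD.
#' @slot usable named logical, whether the replicate baseline is usable.
#' @slot params list of the parameters used (`half_width`, `min_silent`).
#' @seealso [silentBaseline()], [globalBaseline()]
#' @export
setClass("SilentBaseline",
    slots = c(stats = "DataFrame", replicate_sd = "numeric",
              usable = "logical", params = "list"))

setValidity("SilentBaseline", function(object) {
    need <- c("replicate_id", "position", "rolling_mean", "rolling_sd",
              "n_silent", "window_used", "sd_floored")
    if (!all(need %in% colnames(object@stats)))
        return(paste("stats must have columns:", paste(need, collapse = ", ")))
    ok <- object@stats$rolling_sd
    if (any(!is.na(ok) & ok <= 0))
        return("rolling_sd must be positive wherever defined")
    TRUE
})

#' @describeIn SilentBaseline the baseline statistics table.
#' @param x,object a `SilentBaseline`.
#' @export
setMethod("baselineStats", "SilentBaseline", function(x) x@stats)

setMethod("show", "SilentBaseline", function(object) {
    reps <- unique(object@stats$replicate_id)
    cat("SilentBaseline:", length(reps), "replicate(s),",
        length(unique(object@stats$position)), "positions\n")
    cat("  half_width:", object@params$half_width,
        " min_silent:", object@params$min_silent, "\n")
    cat("  sd floored at",
        sum(object@stats$sd_floored, na.rm = TRUE), "position(s)\n")
})

#' Per-variant functional scores
#'
#' Per-replicate z-scores together with their cross-replicate aggregate.
#' `scoreTable()` returns a `DataFrame` with `variant_id`, `position`,
#' `consequence`, `mean_z` (unweighted mean over replicates with a defined
#' z), `sd_z` (n-1 sample SD across replicates, `NA` when fewer than two),
#' `n_replicates` and `flag` (reason code for unscored variants).
#' `replicateZ()` returns the variants x replicates z matrix.
#'
#' @slot scores `DataFrame` as above.
#' @slot z numeric matrix, variants x replicates.
#' @slot baseline the [SilentBaseline-class] used (or a degenerate one).
#' @slot params list of scoring parameters.
#' @seealso [scoreScreen()], [aggregateReplicates()]
#' @export
setClass("FunctionalScores",
    slots = c(scores = "DataFrame", z = "matrix",
              baseline = "SilentBaseline", params = "list"))

setValidity("FunctionalScores", function(object) {
    msg <- character()
    need <- c("variant_id", "position", "consequence", "mean_z", "sd_z",
              "n_replicates", "flag")
    if (!all(need %in% colnames(object@scores)))
        msg <- c(msg, paste("scores must have columns:",
                            paste(need, collapse = ", ")))
    else if (nrow(object@scores) != nrow(object@z))
        msg <- c(msg, "scores and z must have the same number of rows")
    if (length(msg)) msg else TRUE
})

#' @describeIn FunctionalScores number of scored variants.
#' @param x,object a `FunctionalScores`.
#' @export
setMethod("length", "FunctionalScores", function(x) nrow(x@scores))

#' @describeIn FunctionalScores the per-variant score table.
#' @export
setMethod("scoreTable", "FunctionalScores", function(x) x@scores)

#' @describeIn FunctionalScores the variants x replicates z matrix.
#' @export
setMethod("replicateZ", "FunctionalScores", function(x) x@z)

#' @describeIn FunctionalScores named vector of cross-replicate mean z.
#' @export
setMethod("meanZ", "FunctionalScores", function(x)
    stats::setNames(x@scores$mean_z, x@scores$variant_id))

#' @describeIn FunctionalScores the silent baseline used for scoring.
#' @export
setMethod("baselineStats", "FunctionalScores", function(x)
    baselineStats(x@baseline))

setMethod("show", "FunctionalScores", function(object) {
    cat("FunctionalScores:", nrow(object@scores), "variants,",
        ncol(object@z), "replicate(s)\n")
    ok <- is.finite(object@scores$mean_z)
    cat("  scored:", sum(ok), " unscored:", sum(!ok), "\n")
    if (any(ok))
        cat(sprintf("  mean_z range: [%.3f, %.3f]\n",
                    min(object@scores$mean_z[ok]),
                    max(object@scores$mean_z[ok])))
})

#' Simulated screen bundle
#'
#' Output of [simulateScreen()]: the counts, the library, the ground-truth
#' effect table and an echo of the configuration, so recovery of planted
#' effects can be evaluated with [evaluateRecovery()].
#'
#' @slot counts a [ScreenCounts-class].
#' @slot library the [DmsLibrary-class] that was screened.
#' @slot truth `DataFrame` with `variant_id`, `effect_class`
#'   (`functional`/`lof`/`partial`), `theta` (residual activity of partial
#'   alleles) and `fitness` (relative fitness `w` at the configured
#'   suppression).
#' @slot config the [simConfig()] list used.
#' @export
setClass("DmsSimulation",
    slots = c(counts = "ScreenCounts", library = "DmsLibrary",
              truth = "DataFrame", config = "list"))

#' @describeIn DmsSimulation the simulated [ScreenCounts-class].
#' @param x,object a `DmsSimulation`.
#' @export
setMethod("simCounts", "DmsSimulation", function(x) x@counts)

#' @describeIn DmsSimulation the ground-truth effect table.
#' @export
setMethod("simTruth", "DmsSimulation", function(x) x@truth)

#' @describeIn DmsSimulation the simulated library.
#' @export
setMethod("variantTable", "DmsSimulation", function(x)
    variantTable(x@library))

setMethod("show", "DmsSimulation", function(object) {
    tab <- table(object@truth$effect_class)
    cat("DmsSimulation:", nrow(object@truth), "variants,",
        length(unique(SummarizedExperiment::colData(
            object@counts)$replicate_id)), "replicate(s)\n")
    cat("  effects:", paste(names(tab), as.integer(tab), sep = "=",
                            collapse = ", "), "\n")
    cat("  seed:", object@config$seed, "\n")
})
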