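#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.TOOLS <- c("CADD", "REVEL", "AlphaMissense")

#' Predictor pathogenicity thresholds
#'
#' Published stringent thresholds above which a computational predictor
#' calls an SNV pathogenic: CADD PHRED 20, REVEL 0.78, AlphaMissense 0.56.
#' Comparisons are inclusive (`score >= threshold`).
#'
#' @param CADD,REVEL,AlphaMissense positive threshold values.
#' @return Named numeric vector.
#' @export
pathogenicityThresholds <- function(CADD = 20, REVEL = 0.78,
                                    AlphaMissense = 0.56) {
    out <- c(CADD = CADD, REVEL = REVEL, AlphaMissense = AlphaMissense)
    if (any(!is.finite(out) | out <= 0))
        stop("thresholds must be positive reals")
    out
}

#' Classify predictor scores as pathogenic or benign
#'
#' @param score numeric vector of predictor scores.
#' @param tool one of `"CADD"`, `"REVEL"`, `"AlphaMissense"` (or any name
#'   present in `thresholds`).
#' @param thresholds named vector from [pathogenicityThresholds()].
#' @return Character vector over \{"pathogenic", "benign"\}; the boundary is
#'   inclusive (`>=` is pathogenic).
#' @examples
#' classifyPathogenic(c(25, 10), "CADD")        # pathogenic, benign
#' classifyPathogenic(0.78, "REVEL")            # pathogenic (boundary)
#' @export
classifyPathogenic <- function(score, tool,
                               thresholds = pathogenicityThresholds()) {
    if (length(tool) != 1L || !tool %in% names(thresholds))
        stop("unknown tool: ", paste(tool, collapse = ", "),
             " (expected one of ", paste(names(thresholds), collapse = ", "),
             ")")
    ifelse(score >= thresholds[[tool]], "pathogenic", "benign")
}

# Resolve one SNV (1-based CDS position, ref/alt base) to the library
# variant it encodes: exact alternate-codon match first, protein-level
# (position, alt_aa) match second.
.matchSnv <- function(cds_position, ref, alt, library) {
    v <- variantTable(library)
    codons <- .codonsOf(orfSequence(library))
    p <- (cds_position - 1L) %/% 3L + 1L
    off <- (cds_position - 1L) %% 3L + 1L
    if (p < 1L || p > length(codons))
        return(list(variant = NA_character_, reason = "outside_orf"))
    rc <- codons[p]
    if (substr(rc, off, off) != ref)
        return(list(variant = NA_character_, reason = "ref_mismatch"))
    if (ref == alt)
        return(list(variant = NA_character_, reason = "ref_equals_alt"))
    mc <- rc
    substr(mc, off, off) <- alt
    aa <- unname(Biostrings::GENETIC_CODE[mc])
    cand <- which(v$position == p & !is.na(v$alt_codon) & v$alt_codon == mc)
    if (!length(cand))
        cand <- which(v$position == p & v$consequence != "frameshift" &
                      v$alt_aa == aa)
    if (length(cand) > 1L)
        stop("SNV at CDS position ", cds_position, " (", ref, ">", alt,
             ") maps to multiple library variants: ",
             paste(v$variant_id[cand], collapse = ", "))
    if (!length(cand))
        return(list(variant = NA_character_, reason = "no_library_variant"))
    list(variant = v$variant_id[cand], reason = "ok")
}

#' Merge DMS scores with a predictor score table
#'
#' Each predictor SNV is resolved to the codon-level library variant it
#' encodes (exact alternate-codon match, falling back to the protein-level
#' change) and inherits that variant's cross-replicate mean z-score. SNVs
#' with no scored parent are dropped and tallied; frameshift variants are
#' never matched. The DMS side is dichotomized at `mean_z > dms_threshold`
#' (LOF vs tolerated), the predictor side at its tool threshold
#' (pathogenic vs benign); a record is concordant when LOF meets pathogenic
#' or tolerated meets benign.
#'
#' @param scores a [FunctionalScores-class].
#' @param library the [DmsLibrary-class] used for the screen.
#' @param predictor a predictor table from [readPredictorTable()] (or any
#'   data.frame with `cds_position`, `ref`, `alt`, `score` and a `tool`
#'   attribute or column).
#' @param thresholds from [pathogenicityThresholds()].
#' @param dms_threshold LOF threshold on the mean z-score (default 2).
#' @return `DataFrame` of concordance records (`cds_position`, `ref`,
#'   `alt`, `variant_id`, `consequence`, `mean_z`, `score`, `dms_class`,
#'   `predictor_class`, `concordant`); drop tallies are in `metadata()`.
#' @export
mergeDmsPredictor <- function(scores, library, predictor,
                              thresholds = pathogenicityThresholds(),
                              dms_threshold = 2) {
    pred <- as.data.frame(predictor)
    tool <- attr(predictor, "tool")
    if (is.null(tool) && "tool" %in% colnames(pred))
        tool <- pred$tool[1L]
    if (is.null(tool))
        stop("predictor table must carry its tool name")
    need <- c("cds_position", "ref", "alt", "score")
    if (!all(need %in% colnames(pred)))
        stop("predictor table must have columns: ",
             paste(need, collapse = ", "))
    mz <- meanZ(scores)
    n_unmatched <- 0L; n_unscored <- 0L
    recs <- vector("list", nrow(pred))
    for (i in seq_len(nrow(pred))) {
        hit <- .matchSnv(pred$cds_position[i], pred$ref[i], pred$alt[i],
                         library)
        if (is.na(hit$variant)) {
            n_unmatched <- n_unmatched + 1L
            next
        }
        z <- mz[[hit$variant]]
        if (is.null(z) || is.na(z)) {
            n_unscored <- n_unscored + 1L
            next
        }
        recs[[i]] <- data.frame(
            cds_position = pred$cds_position[i], ref = pred$ref[i],
            alt = pred$alt[i], variant_id = hit$variant, mean_z = z,
            score = pred$score[i])
    }
    recs <- recs[!vapply(recs, is.null, logical(1L))]
    if (!length(recs)) {
        out <- DataFrame(cds_position = integer(), ref = character(),
                         alt = character(), variant_id = character(),
                         consequence = character(), mean_z = numeric(),
                         score = numeric(), dms_class = character(),
                         predictor_class = character(),
                         concordant = logical())
    } else {
        df <- do.call(rbind, recs)
        v <- variantTable(library)
        df$consequence <- v$consequence[match(df$variant_id, v$variant_id)]
        df$dms_class <- ifelse(df$mean_z > dms_threshold, "LOF", "tolerated")
        df$predictor_class <- classifyPathogenic(df$score, tool, thresholds)
        df$concordant <- (df$dms_class == "LOF" &
                          df$predictor_class == "pathogenic") |
                         (df$dms_class == "tolerated" &
                          df$predictor_class == "benign")
        out <- DataFrame(df[, c("cds_position", "ref", "alt", "variant_id",
                                "consequence", "mean_z", "score",
                                "dms_class", "predictor_class",
                                "concordant")])
    }
    metadata(out) <- list(tool = tool, dms_threshold = dms_threshold,
                          n_unmatched = n_unmatched,
                          n_unscored = n_unscored)
    out
}

#' Concordance summary by consequence class
#'
#' @param records concordance records from [mergeDmsPredictor()].
#' @return `DataFrame` with one row per consequence class: `n_total`,
#'   `n_concordant`, `fraction` (in `[0, 1]`) and `percent`.
#' @export
concordanceSummary <- function(records) {
    records <- as.data.frame(records)
    if (!nrow(records))
        stop("no concordance records")
    out <- do.call(rbind, lapply(split(records, records$consequence),
        function(d) data.frame(consequence = d$consequence[1L],
                               n_total = nrow(d),
                               n_concordant = sum(d$concordant))))
    out$fraction <- out$n_concordant / out$n_total
    out$percent <- round(100 * out$fraction, 2L)
    rownames(out) <- NULL
    DataFrame(out[order(match(out$consequence, .CONSEQUENCES)), ,
                  drop = FALSE])
}

#' Fraction of predictor rows called pathogenic
#'
#' @param predictor predictor table (see [mergeDmsPredictor()]); a
#'   `consequence` column is required when `consequence_filter` is not
#'   `NULL`.
#' @param thresholds from [pathogenicityThresholds()].
#' @param tool tool name; defaults to the table's `tool` attribute.
#' @param consequence_filter consequence class to keep (default
#'   `"missense"`); `NULL` keeps all rows.
#' @return Fraction in `[0, 1]` of (filtered) rows at or above the tool
#'   threshold.
#' @export
fractionPathogenic <- function(predictor,
                               thresholds = pathogenicityThresholds(),
                               tool = attr(predictor, "tool"),
                               consequence_filter = "missense") {
    pred <- as.data.frame(predictor)
    if (is.null(tool) && "tool" %in% colnames(pred)) tool <- pred$tool[1L]
    if (!is.null(consequence_filter)) {
        if (!"consequence" %in% colnames(pred))
            stop("predictor table has no consequence column to filter on")
        pred <- pred[pred$consequence %in% consequence_filter, ,
                     drop = FALSE]
    }
    if (!nrow(pred))
        stop("no predictor rows left after filtering")
    mean(classifyPathogenic(pred$score, tool, thresholds) == "pathogenic")
}

#' ROC curve and AUC of a score against binary labels
#'
#' AUC is the tie-corrected (midrank) Mann-Whitney statistic: the
#' probability that a random positive outscores a random negative, ties
#' counting one half. The curve is a threshold sweep over the unique
#' observed scores.
#'
#' @param labels logical vector (TRUE = positive) aligned with `scores`,
#'   or a data.frame with `variant_id` and a logical/0-1 `label` column.
#' @param scores named numeric vector of scores (higher = more positive).
#' @return List with `auc`, `curve` (`DataFrame` of FPR/TPR points,
#'   monotone nondecreasing), `n_positive`, `n_negative`.
#' @examples
#' rocAuc(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.4, 0.5, 0.1))$auc  # 0.75
#' @export
rocAuc <- function(labels, scores) {
    if (is.data.frame(labels) || methods::is(labels, "DataFrame")) {
        labels <- as.data.frame(labels)
        lab <- as.logical(labels$label)
        names(lab) <- labels$variant_id
        common <- intersect(names(lab), names(scores))
        if (!length(common))
            stop("labels and scores share no variants")
        scores <- scores[common]
        labels <- lab[common]
    }
    keep <- is.finite(scores) & !is.na(labels)
    scores <- scores[keep]; labels <- as.logical(labels[keep])
    n1 <- sum(labels); n0 <- sum(!labels)
    if (n1 < 1L || n0 < 1L)
        stop("need at least one positive and one negative with scores")
    r <- rank(scores)  # midranks
    auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n1,
                  numeric(1L))
    fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n0,
                  numeric(1L))
    list(auc = auc,
         curve = DataFrame(threshold = c(Inf, thr), fpr = c(0, fpr),
                           tpr = c(0, tpr)),
         n_positive = n1, n_negative = n0)
}
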