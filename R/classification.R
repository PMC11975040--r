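#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.scoresInput <- function(scores) {
    if (methods::is(scores, "FunctionalScores"))
        return(as.data.frame(scoreTable(scores)))
    scores <- as.data.frame(scores)
    if (!all(c("variant_id", "mean_z") %in% colnames(scores)))
        stop("scores must be a FunctionalScores object or a table with ",
             "variant_id and mean_z columns")
    scores
}

#' Call loss-of-function variants
#'
#' A variant is called LOF when its cross-replicate mean z-score strictly
#' exceeds the threshold (enrichment after growth competition: functional
#' alleles suppress proliferation and deplete, LOF alleles do not).
#'
#' @param scores a [FunctionalScores-class] or a table with `variant_id`
#'   and `mean_z`.
#' @param threshold LOF threshold on the mean z-score (default 2, strict
#'   `>`).
#' @return `DataFrame` with `variant_id`, `mean_z`, `is_lof` and the
#'   threshold recorded in `metadata()$threshold`.
#' @examples
#' callLof(data.frame(variant_id = c("R377H", "R377*"),
#'                    mean_z = c(0.985, 0.296)))  # neither is LOF
#' @export
callLof <- function(scores, threshold = 2) {
    s <- .scoresInput(scores)
    out <- DataFrame(variant_id = s$variant_id, mean_z = s$mean_z,
                     is_lof = !is.na(s$mean_z) & s$mean_z > threshold)
    metadata(out) <- list(threshold = threshold,
                          n_lof = sum(out$is_lof))
    out
}

#' Rank residues by intolerance to missense mutation
#'
#' Each residue is summarized by the mean of the cross-replicate z-scores
#' of its available missense substitutions (at most 19 under a
#' one-codon-per-target-amino-acid library). The intolerance cutoff is two
#' n-1 standard deviations above the mean of the residue averages and is
#' recomputed from the supplied scores; residues whose average strictly
#' exceeds it are flagged intolerant. Residues with fewer than
#' `min_substitutions` scored substitutions are excluded from cutoff
#' estimation (and, under `cutoff_scope = "covered"`, from flagging).
#'
#' @inheritParams callLof
#' @param min_substitutions minimum scored missense substitutions for a
#'   residue to enter cutoff estimation (default 10).
#' @param cutoff_scope `"covered"` (default): only residues meeting
#'   `min_substitutions` enter the cutoff estimate; `"all"`: every residue
#'   with at least one scored substitution does.
#' @param n_sd number of SDs above the mean for the cutoff (default 2).
#' @return `DataFrame` with `position`, `mean_missense_z`,
#'   `n_substitutions` and `is_intolerant`; the cutoff and rule are stored
#'   in `metadata()`.
#' @export
residueIntolerance <- function(scores, min_substitutions = 10L,
                               cutoff_scope = c("covered", "all"),
                               n_sd = 2) {
    cutoff_scope <- match.arg(cutoff_scope)
    s <- .scoresInput(scores)
    if (!all(c("position", "consequence") %in% colnames(s)))
        stop("scores must carry position and consequence columns")
    s <- s[s$consequence == "missense" & is.finite(s$mean_z), , drop = FALSE]
    if (!nrow(s))
        stop("no scored missense variants")
    agg <- do.call(rbind, lapply(split(s$mean_z, s$position), function(x)
        c(mean = mean(x), n = length(x))))
    pos <- as.integer(rownames(agg))
    covered <- agg[, "n"] >= min_substitutions
    est <- if (cutoff_scope == "covered") agg[covered, "mean"]
           else agg[, "mean"]
    if (length(est) < 2L)
        stop("fewer than two residues available for cutoff estimation; ",
             "lower min_substitutions")
    cutoff <- mean(est) + n_sd * sd(est)
    out <- DataFrame(position = pos,
                     mean_missense_z = unname(agg[, "mean"]),
                     n_substitutions = unname(as.integer(agg[, "n"])),
                     is_intolerant = unname(agg[, "mean"] > cutoff &
                         (cutoff_scope == "all" | covered)))
    out <- out[order(out$position), , drop = FALSE]
    metadata(out) <- list(cutoff = cutoff,
                          cutoff_rule = sprintf(
                              "mean + %g*SD of residue averages (%s)",
                              n_sd, cutoff_scope),
                          n_intolerant = sum(out$is_intolerant))
    out
}

#' Positional profile of a consequence class
#'
#' Per-position mean of the cross-replicate z-scores of one consequence
#' class, with a centered moving average (truncated at the ORF ends) for
#' display along the coding sequence.
#'
#' @inheritParams callLof
#' @param consequence one of `"silent"`, `"missense"`, `"nonsense"`,
#'   `"frameshift"`.
#' @param smooth_half_width half-width of the centered moving average in
#'   residues (default 5; 0 returns the raw per-position means).
#' @return `DataFrame` with `position`, `mean_z` and `smoothed_z`, one row
#'   per position where the class has at least one scored variant.
#' @export
positionalProfile <- function(scores, consequence, smooth_half_width = 5L) {
    if (!consequence %in% .CONSEQUENCES)
        stop("unknown consequence class: ", consequence)
    s <- .scoresInput(scores)
    s <- s[s$consequence == consequence & is.finite(s$mean_z), ,
           drop = FALSE]
    if (!nrow(s))
        stop("no scored variants of class '", consequence, "'")
    m <- vapply(split(s$mean_z, s$position), mean, numeric(1L))
    pos <- as.integer(names(m))
    ord <- order(pos)
    pos <- pos[ord]; m <- unname(m[ord])
    sm <- vapply(seq_along(pos), function(i) {
        sel <- abs(pos - pos[i]) <= smooth_half_width
        mean(m[sel])
    }, numeric(1L))
    DataFrame(position = pos, mean_z = m, smoothed_z = sm)
}

#' Variant-effect heatmap matrix
#'
#' Arranges cross-replicate mean z-scores as a matrix with one row per
#' alternate amino acid (20 residues, stop `"*"`, frameshift `"fs"`) plus a
#' top `avg` row holding the residue average over missense substitutions,
#' and one column per residue position. Unobserved cells are `NA`.
#'
#' @inheritParams callLof
#' @param library the [DmsLibrary-class] (fixes the number of positions).
#' @return Numeric matrix, 23 rows x `nResidues(library)` columns.
#' @export
heatmapMatrix <- function(scores, library) {
    s <- .scoresInput(scores)
    v <- variantTable(library)
    s$alt_aa <- v$alt_aa[match(s$variant_id, v$variant_id)]
    L <- nResidues(library)
    rows <- c("avg", .AA20, "*", "fs")
    m <- matrix(NA_real_, length(rows), L,
                dimnames = list(rows, as.character(seq_len(L))))
    sub <- s[is.finite(s$mean_z) & s$consequence != "silent", , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
        aa <- if (sub$consequence[i] == "frameshift") "fs" else sub$alt_aa[i]
        if (is.null(aa) || is.na(aa)) next
        m[aa, sub$position[i]] <- sub$mean_z[i]
    }
    mis <- s[s$consequence == "missense" & is.finite(s$mean_z), ,
             drop = FALSE]
    if (nrow(mis)) {
        avg <- vapply(split(mis$mean_z, mis$position), mean, numeric(1L))
        m["avg", names(avg)] <- avg
    }
    m
}
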