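#' @importFrom stats sd setNames
NULL

#' Pseudocounted relative frequencies
#'
#' @param counts non-negative numeric vector of read counts for one sample.
#' @param pseudocount value added to every count before normalization
#'   (default 0.5, the common pooled-screen convention).
#' @return Numeric vector summing to 1.
#' @examples
#' toFrequencies(c(1, 1, 2), pseudocount = 0)  # 0.25 0.25 0.50
#' @export
toFrequencies <- function(counts, pseudocount = 0.5) {
    if (any(counts < 0) || any(!is.finite(counts)))
        stop("counts must be finite and non-negative")
    if (pseudocount < 0)
        stop("pseudocount must be non-negative")
    tot <- sum(counts) + length(counts) * pseudocount
    if (tot <= 0)
        stop("all-zero counts with pseudocount 0: frequencies undefined")
    (counts + pseudocount) / tot
}

#' Log2 fold change of late versus early frequencies
#'
#' @param early_freq,late_freq aligned positive frequency vectors (from
#'   [toFrequencies()]).
#' @return `log2(late_freq / early_freq)`, same names as the input.
#' @examples
#' computeL2fc(c(a = 0.25, b = 0.75), c(a = 0.5, b = 0.5))
#' @export
computeL2fc <- function(early_freq, late_freq) {
    if (length(early_freq) != length(late_freq))
        stop("early and late frequency vectors must be aligned")
    if (any(early_freq <= 0) || any(late_freq <= 0))
        stop("frequencies must be positive; was the pseudocount set to 0 ",
             "with zero counts present?")
    log2(late_freq / early_freq)
}

# One l2fc column per replicate from a validated ScreenCounts object.
.l2fcMatrix <- function(counts, pseudocount = 0.5) {
    cd <- as.data.frame(SummarizedExperiment::colData(counts))
    cts <- SummarizedExperiment::assay(counts, "counts")
    reps <- unique(cd$replicate_id)
    out <- matrix(NA_real_, nrow(cts), length(reps),
                  dimnames = list(rownames(cts), reps))
    for (r in reps) {
        e <- cd$sample_id[cd$replicate_id == r & cd$timepoint == "early"]
        l <- cd$sample_id[cd$replicate_id == r & cd$timepoint == "late"]
        if (length(e) != 1L || length(l) != 1L)
            stop("replicate '", r, "' must have exactly one early and one ",
                 "late sample (found ", length(e), "/", length(l), ")")
        out[, r] <- computeL2fc(toFrequencies(cts[, e], pseudocount),
                                toFrequencies(cts[, l], pseudocount))
    }
    out
}

#' Per-replicate variant log2 fold changes
#'
#' Convenience wrapper: pseudocounted relative frequencies per sample, then
#' `log2(late/early)` per replicate.
#'
#' @param counts a [ScreenCounts-class].
#' @param pseudocount see [toFrequencies()].
#' @return Numeric matrix, variants x replicates.
#' @export
l2fcTable <- function(counts, pseudocount = 0.5) {
    stopifnot(methods::is(counts, "ScreenCounts"))
    .l2fcMatrix(counts, pseudocount)
}

.silentValues <- function(l2fc, library) {
    v <- variantTable(library)
    idx <- match(rownames(l2fc), v$variant_id)
    if (anyNA(idx))
        stop("l2fc rows contain variants absent from the library: ",
             paste(utils::head(rownames(l2fc)[is.na(idx)], 5),
                   collapse = ", "))
    list(position = v$position[idx], consequence = v$consequence[idx])
}

# Collect silent l2fc values around position p, expanding the half-width
# symmetrically until min_silent values are captured or the ORF is covered.
.collectWindow <- function(p, sil_pos, half_width, min_silent, L) {
    h <- half_width
    repeat {
        sel <- abs(sil_pos - p) <= h
        if (sum(sel) >= min_silent) break
        if (p - h <= 1L && p + h >= L) break
        h <- h + 1L
    }
    list(sel = sel, h = h)
}

#' Rolling silent-codon baseline
#'
#' For every residue position and replicate, collects the log2 fold changes
#' of silent variants within `half_width` codons of the position (window
#' truncated at the ORF ends) and records their sample mean and n-1 SD.
#' Windows holding fewer than `min_silent` silent variants are expanded
#' symmetrically one codon at a time until satisfied or the whole ORF is
#' covered; positions still short of `min_silent` are marked unscorable.
#' Where the window SD is zero (or fewer than two values), the replicate-wide
#' silent SD is substituted and `sd_floored` set; if that SD is itself zero
#' the replicate baseline is flagged unusable.
#'
#' @param l2fc numeric matrix of per-replicate log2 fold changes (variants x
#'   replicates, variant ids as rownames), e.g. from [l2fcTable()].
#' @param library the [DmsLibrary-class] describing the variants.
#' @param half_width window half-width in codons (default 2, i.e. a
#'   5-codon window).
#' @param min_silent minimum silent variants per window before expansion
#'   stops (default 3).
#' @return A [SilentBaseline-class].
#' @examples
#' lib <- enumerateLibrary(c(demo = "ATGAAACTGCTGAAATGG"))
#' m <- matrix(rnorm(length(lib)), length(lib), 1,
#'             dimnames = list(variantTable(lib)$variant_id, "r1"))
#' silentBaseline(m, lib)
#' @export
silentBaseline <- function(l2fc, library, half_width = 2L, min_silent = 3L) {
    l2fc <- as.matrix(l2fc)
    info <- .silentValues(l2fc, library)
    L <- nResidues(library)
    reps <- colnames(l2fc)
    if (is.null(reps)) reps <- paste0("rep", seq_len(ncol(l2fc)))
    is_sil <- info$consequence == "silent"
    if (!any(is_sil))
        stop("library holds no silent variants: baseline is undefined")
    rows <- vector("list", length(reps))
    rep_sd <- setNames(rep(NA_real_, length(reps)), reps)
    usable <- setNames(rep(FALSE, length(reps)), reps)
    for (j in seq_along(reps)) {
        vals <- l2fc[, j]
        keep <- is_sil & is.finite(vals)
        sp <- info$position[keep]
        sv <- vals[keep]
        rep_sd[j] <- if (length(sv) >= 2L) sd(sv) else NA_real_
        m <- s <- rep(NA_real_, L)
        n <- integer(L); w <- integer(L); fl <- logical(L)
        for (p in seq_len(L)) {
            win <- .collectWindow(p, sp, half_width, min_silent, L)
            x <- sv[win$sel]
            n[p] <- length(x); w[p] <- win$h
            if (n[p] < min_silent) next  # unscorable
            m[p] <- mean(x)
            sdp <- if (n[p] >= 2L) sd(x) else NA_real_
            if (!is.finite(sdp) || sdp == 0) {
                sdp <- rep_sd[j]
                fl[p] <- TRUE
            }
            s[p] <- if (is.finite(sdp) && sdp > 0) sdp else NA_real_
        }
        usable[j] <- any(is.finite(s))
        rows[[j]] <- data.frame(replicate_id = reps[j], position = seq_len(L),
                                rolling_mean = m, rolling_sd = s,
                                n_silent = n, window_used = w,
                                sd_floored = fl)
    }
    new("SilentBaseline", stats = DataFrame(do.call(rbind, rows)),
        replicate_sd = rep_sd, usable = usable,
        params = list(half_width = half_width, min_silent = min_silent,
                      type = "rolling"))
}

#' Global silent baseline (windowing ablation)
#'
#' Diagnostic counterpart of [silentBaseline()]: the position-local rolling
#' mean is replaced by the replicate-wide silent mean, so any positional
#' trend in variant abundance is no longer absorbed. With
#' `scale = "local"` (default) the rolling SD is kept, which isolates the
#' effect of the windowed mean alone; `scale = "pooled"` also replaces the
#' SD with the replicate-wide silent SD, in which case a positional trend
#' additionally inflates the denominator.
#'
#' @inheritParams silentBaseline
#' @param scale `"local"` or `"pooled"`, see above.
#' @return A [SilentBaseline-class] usable wherever the rolling baseline is.
#' @export
globalBaseline <- function(l2fc, library, half_width = 2L, min_silent = 3L,
                           scale = c("local", "pooled")) {
    scale <- match.arg(scale)
    base <- silentBaseline(l2fc, library, half_width, min_silent)
    st <- as.data.frame(baselineStats(base))
    info <- .silentValues(as.matrix(l2fc), library)
    is_sil <- info$consequence == "silent"
    for (r in unique(st$replicate_id)) {
        vals <- as.matrix(l2fc)[, r]
        sv <- vals[is_sil & is.finite(vals)]
        sel <- st$replicate_id == r
        st$rolling_mean[sel] <- mean(sv)
        st$n_silent[sel] <- length(sv)
        if (scale == "pooled") {
            gsd <- if (length(sv) >= 2L) sd(sv) else NA_real_
            st$rolling_sd[sel] <- if (is.finite(gsd) && gsd > 0) gsd
                                  else NA_real_
            st$sd_floored[sel] <- TRUE
        }
    }
    new("SilentBaseline", stats = DataFrame(st),
        replicate_sd = base@replicate_sd, usable = base@usable,
        params = list(half_width = half_width, min_silent = min_silent,
                      type = paste0("global-", scale)))
}

#' Per-replicate functional z-scores
#'
#' Standardizes each variant's log2 fold change against the silent baseline
#' at the variant's own residue position:
#' `z = (l2fc - rolling_mean) / rolling_sd`. Frameshift variants use the
#' position of the codon holding their deletion. Variants at unscorable
#' positions get `NA`.
#'
#' @inheritParams silentBaseline
#' @param baseline a [SilentBaseline-class] from [silentBaseline()] or
#'   [globalBaseline()].
#' @param leave_one_out when `TRUE`, each silent variant's own window is
#'   recomputed without itself before standardization (off by default: the
#'   baseline window includes all silent codons it covers).
#' @return Numeric matrix of z-scores, variants x replicates.
#' @export
replicateZscores <- function(l2fc, baseline, library,
                             leave_one_out = FALSE) {
    l2fc <- as.matrix(l2fc)
    stopifnot(methods::is(baseline, "SilentBaseline"))
    info <- .silentValues(l2fc, library)
    st <- as.data.frame(baselineStats(baseline))
    L <- nResidues(library)
    z <- l2fc * NA_real_
    for (r in colnames(l2fc)) {
        sel <- st$replicate_id == r
        if (!any(sel))
            stop("baseline holds no replicate '", r, "'")
        mu <- st$rolling_mean[sel][info$position]
        sg <- st$rolling_sd[sel][info$position]
        z[, r] <- (l2fc[, r] - mu) / sg
        if (leave_one_out) {
            hw <- baseline@params$half_width
            ms <- baseline@params$min_silent
            vals <- l2fc[, r]
            sil <- which(info$consequence == "silent" & is.finite(vals))
            sp <- info$position[sil]
            for (k in seq_along(sil)) {
                i <- sil[k]
                win <- .collectWindow(info$position[i], sp[-k], hw, ms, L)
                x <- vals[sil[-k]][win$sel]
                if (length(x) < ms || length(x) < 2L) {
                    z[i, r] <- NA_real_
                    next
                }
                sdp <- sd(x)
                if (sdp == 0) sdp <- baseline@replicate_sd[[r]]
                z[i, r] <- if (is.finite(sdp) && sdp > 0)
                    (vals[i] - mean(x)) / sdp else NA_real_
            }
        }
    }
    z
}

#' Aggregate z-scores across replicates
#'
#' The final functional score of a variant is the unweighted mean of its
#' per-replicate z-scores; the n-1 sample SD across replicates measures
#' cross-context consistency and is `NA` with fewer than two defined
#' replicates.
#'
#' @param z numeric matrix (variants x replicates) or a single variant's
#'   named numeric vector of per-replicate z-scores.
#' @return `DataFrame` with `variant_id`, `mean_z`, `sd_z`, `n_replicates`
#'   and `flag` (`"ok"` or `"no_replicate_z"`).
#' @examples
#' aggregateReplicates(c(r1 = 1, r2 = 2, r3 = 3))  # mean 2, sd 1
#' @export
aggregateReplicates <- function(z) {
    if (is.null(dim(z)))
        z <- matrix(z, nrow = 1L,
                    dimnames = list("variant", names(z)))
    n <- rowSums(is.finite(z))
    mean_z <- ifelse(n >= 1L, rowMeans(z, na.rm = TRUE), NA_real_)
    sd_z <- apply(z, 1L, function(x) {
        x <- x[is.finite(x)]
        if (length(x) >= 2L) sd(x) else NA_real_
    })
    DataFrame(variant_id = rownames(z), mean_z = unname(mean_z),
              sd_z = unname(sd_z), n_replicates = unname(as.integer(n)),
              flag = unname(ifelse(n >= 1L, "ok", "no_replicate_z")))
}

#' Score a DMS screen
#'
#' Full scoring pipeline for one screen: pseudocounted frequencies, per-
#' replicate log2 fold changes, rolling silent baseline, per-replicate
#' z-scores and the cross-replicate aggregate.
#'
#' @param counts a [ScreenCounts-class]; every replicate must have exactly
#'   one early and one late sample.
#' @param library the [DmsLibrary-class] the screen was built from.
#' @inheritParams silentBaseline
#' @inheritParams toFrequencies
#' @param baseline `"rolling"` (default), or the ablations `"global-mean"` /
#'   `"global-pooled"` (see [globalBaseline()]).
#' @param leave_one_out see [replicateZscores()].
#' @return A [FunctionalScores-class].
#' @examples
#' sim <- simulateScreen(simConfig(orf_length = 30, seed = 1))
#' fs <- scoreScreen(simCounts(sim), sim@library)
#' head(scoreTable(fs))
#' @export
scoreScreen <- function(counts, library, pseudocount = 0.5, half_width = 2L,
                        min_silent = 3L,
                        baseline = c("rolling", "global-mean",
                                     "global-pooled"),
                        leave_one_out = FALSE) {
    stopifnot(methods::is(counts, "ScreenCounts"),
              methods::is(library, "DmsLibrary"))
    baseline <- match.arg(baseline)
    l2fc <- .l2fcMatrix(counts, pseudocount)
    bl <- switch(baseline,
        "rolling" = silentBaseline(l2fc, library, half_width, min_silent),
        "global-mean" = globalBaseline(l2fc, library, half_width,
                                       min_silent, scale = "local"),
        "global-pooled" = globalBaseline(l2fc, library, half_width,
                                         min_silent, scale = "pooled"))
    z <- replicateZscores(l2fc, bl, library, leave_one_out = leave_one_out)
    agg <- aggregateReplicates(z)
    v <- variantTable(library)
    idx <- match(agg$variant_id, v$variant_id)
    scores <- DataFrame(variant_id = agg$variant_id,
                        position = v$position[idx],
                        consequence = v$consequence[idx],
                        mean_z = agg$mean_z, sd_z = agg$sd_z,
                        n_replicates = agg$n_replicates, flag = agg$flag)
    rownames(scores) <- scores$variant_id
    new("FunctionalScores", scores = scores, z = z, baseline = bl,
        params = list(pseudocount = pseudocount, half_width = half_width,
                      min_silent = min_silent, baseline = baseline,
                      leave_one_out = leave_one_out))
}
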