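#' @importFrom stats dhyper
NULL

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in the 2x2 table
#' `rbind(c(a, b), c(c, d))`, by full enumeration of the hypergeometric
#' distribution over all tables with the observed margins: the p-value is
#' the total probability of tables whose probability does not exceed that
#' of the observed table (the standard "probability mass <= observed"
#' two-sided rule). Degenerate margins give p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisherExact2x2(5, 0, 0, 5)  # 2/choose(10,5) = 0.00794
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(!is.finite(cells)) || any(cells < 0) ||
        any(cells != round(cells)))
        stop("cell counts must be non-negative integers")
    m <- a + b      # row 1 margin
    n <- c + d      # row 2 margin
    k <- a + c      # column 1 margin
    if (m == 0L || n == 0L || k == 0L || (b + d) == 0L)
        return(1)
    lo <- max(0L, k - n)
    hi <- min(k, m)
    support <- lo:hi
    pmf <- dhyper(support, m, n, k)
    p_obs <- dhyper(a, m, n, k)
    # relative tolerance guards against ties broken by floating point
    p <- sum(pmf[pmf <= p_obs * (1 + 1e-7)])
    min(p, 1)
}

#' Quadrant concordance of paired log2 fold changes
#'
#' For paired region (e.g. chromatin accessibility) and gene (expression)
#' log2 fold changes, keeps pairs where both members exceed `l2fc_min` in
#' absolute value, counts the four sign quadrants, and reports the
#' concordance fraction (same sign) together with a two-sided Fisher exact
#' test of the 2x2 sign table (region up/down x gene up/down) against
#' independence of the two sign margins.
#'
#' @param pairs data.frame with columns `region_l2fc` and `gene_l2fc`
#'   (identifier columns such as `region_id`/`gene_id` are carried along but
#'   unused); optional `padj` columns may be pre-filtered with
#'   [readPairsTable()].
#' @param l2fc_min absolute log2-fold-change filter applied to both members
#'   (strict `>`, default 1).
#' @return List with `quadrants` (named counts `up_up`, `up_down`,
#'   `down_up`, `down_down`), `n`, `concordance_fraction`, `odds_ratio`
#'   (`a*d/(b*c)`, possibly infinite), `fisher_p` and `degenerate` (TRUE
#'   when a zero margin forced p = 1).
#' @examples
#' set.seed(1)
#' x <- rnorm(200, sd = 2)
#' quadrantConcordance(data.frame(region_l2fc = x,
#'                                gene_l2fc = x + rnorm(200)))
#' @export
quadrantConcordance <- function(pairs, l2fc_min = 1) {
    pairs <- as.data.frame(pairs)
    if (!all(c("region_l2fc", "gene_l2fc") %in% colnames(pairs)))
        stop("pairs must have region_l2fc and gene_l2fc columns")
    keep <- is.finite(pairs$region_l2fc) & is.finite(pairs$gene_l2fc) &
        abs(pairs$region_l2fc) > l2fc_min & abs(pairs$gene_l2fc) > l2fc_min
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs))
        stop("no pairs left after the |l2fc| > ", l2fc_min, " filter")
    r_up <- pairs$region_l2fc > 0
    g_up <- pairs$gene_l2fc > 0
    a <- sum(r_up & g_up); b <- sum(r_up & !g_up)
    c <- sum(!r_up & g_up); d <- sum(!r_up & !g_up)
    degenerate <- (a + b) == 0L || (c + d) == 0L ||
                  (a + c) == 0L || (b + d) == 0L
    list(quadrants = c(up_up = a, up_down = b, down_up = c, down_down = d),
         n = a + b + c + d,
         concordance_fraction = (a + d) / (a + b + c + d),
         odds_ratio = (a * d) / (b * c),
         fisher_p = fisherExact2x2(a, b, c, d),
         degenerate = degenerate)
}
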