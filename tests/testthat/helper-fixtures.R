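# In-code fixtures shared across test files.

# A hand-built library: positions/consequences fully under test control.
# The ORF is ATG followed by lysine codons (no internal stop, any length).
toy_library <- function(variants, L = max(variants$position)) {
    orf <- paste0("ATG", strrep("AAA", L - 1L))
    v <- S4Vectors::DataFrame(
        variant_id = variants$variant_id,
        position = as.integer(variants$position),
        ref_codon = "AAA",
        alt_codon = ifelse(variants$consequence == "frameshift",
                           NA_character_, "AAG"),
        fs_offset = ifelse(variants$consequence == "frameshift",
                           -1L, NA_integer_),
        ref_aa = "K",
        alt_aa = ifelse(variants$consequence == "silent", "K",
                 ifelse(variants$consequence == "nonsense", "*",
                 ifelse(variants$consequence == "frameshift", "fs", "R"))),
        consequence = variants$consequence)
    rownames(v) <- v$variant_id
    new("DmsLibrary", orf_id = "toy", orf_seq = orf, variants = v)
}

# l2fc matrix with given values for one replicate.
toy_l2fc <- function(library, values, replicate = "r1") {
    v <- variantTable(library)
    matrix(values, ncol = 1L,
           dimnames = list(v$variant_id, replicate))
}

# Independent recomputation of the rolling baseline at one position:
# re-collects silent l2fc values per window, expanding until min_silent.
oracle_rolling <- function(p, sil_pos, sil_val, half_width, min_silent, L) {
    h <- half_width
    repeat {
        x <- sil_val[abs(sil_pos - p) <= h]
        if (length(x) >= min_silent) break
        if (p - h <= 1 && p + h >= L) break
        h <- h + 1
    }
    if (length(x) < min_silent)
        return(c(mean = NA_real_, sd = NA_real_, n = length(x), h = h))
    c(mean = mean(x), sd = if (length(x) >= 2) sd(x) else NA_real_,
      n = length(x), h = h)
}

# Brute-force AUC: count positive-negative pairs, ties worth one half.
oracle_auc <- function(labels, scores) {
    pos <- scores[labels]; neg <- scores[!labels]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

# Brute-force two-sided Fisher p via binomial-coefficient enumeration of
# all tables with the observed margins (independent of dhyper).
oracle_fisher <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c; N <- m + n
    if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
    lo <- max(0, k - n); hi <- min(k, m)
    prob <- vapply(lo:hi, function(x)
        choose(m, x) * choose(n, k - x) / choose(N, k), numeric(1))
    p_obs <- choose(m, a) * choose(n, k - a) / choose(N, k)
    min(sum(prob[prob <= p_obs * (1 + 1e-7)]), 1)
}

default_sim_config <- function(seed, ...) {
    simConfig(seed = seed, ...)
}

null_sim_config <- function(seed, ...) {
    simConfig(suppression = 0, lof_fraction_missense = 0, seed = seed, ...)
}
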