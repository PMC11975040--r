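#' @importFrom stats rgamma rlnorm rmultinom runif rbinom
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
        stop("a single finite seed is required")
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Configuration of a synthetic DMS screen
#'
#' Describes a pooled proliferation screen in which re-expressed functional
#' alleles suppress growth: per doubling, a variant with residual activity
#' `e` grows by the factor `1 - e * s` relative to a loss-of-function
#' allele, so after `doublings` generations LOF variants enrich by
#' `doublings * log2(1/(1-s))` log2 units over functional ones.
#'
#' @param orf_length ORF length in residues (default 120; >= 10).
#' @param scheme [libraryScheme()] used for the library.
#' @param n_replicates replicate screen contexts (default 3). Replicates
#'   model distinct cell-line backgrounds: their suppression strengths are
#'   fixed, evenly spaced multiples of `suppression` spanning +/- 20%.
#' @param doublings population doublings between the early and late
#'   samples (default 6).
#' @param suppression growth deficit `s` in `[0, 1]` of fully functional
#'   variants per doubling (default 0.3).
#' @param lof_fraction_missense probability that a missense variant is LOF
#'   (default 0.015).
#' @param lof_cluster optional list of residue intervals `c(from, to)`;
#'   every missense variant inside is LOF (planted intolerant residues).
#' @param partial_effect_range interval for the residual activity `theta`
#'   of partial alleles (default `c(0.2, 0.8)`).
#' @param representation_sigma log-normal SD of initial library
#'   representation skew (default 0.5).
#' @param depth_early,depth_late sequencing depths in reads (default 5e5).
#' @param overdispersion gamma shape of the per-variant, per-replicate
#'   multiplicative noise on expected late abundance (mean 1; default 25,
#'   i.e. 20% CV).
#' @param positional_bias_amplitude amplitude (log2 units) of a smooth
#'   sinusoidal position-dependent offset on abundance change (default 0);
#'   exercises the rolling baseline.
#' @param nmd_escape_nterm residue up to which nonsense variants escape as
#'   partial alleles, mimicking downstream start-site read-through
#'   (default 0 = off; frameshifts are never rescued).
#' @param partial_cterm_start residue from which truncating variants
#'   (nonsense and frameshift) retain partial function (default `NULL` =
#'   off).
#' @param seed mandatory integer seed; regeneration with the same
#'   configuration is bit-identical.
#' @return Validated configuration list of class `"SimConfig"`.
#' @export
simConfig <- function(orf_length = 120L, scheme = libraryScheme(),
                      n_replicates = 3L, doublings = 6,
                      suppression = 0.3, lof_fraction_missense = 0.015,
                      lof_cluster = NULL,
                      partial_effect_range = c(0.2, 0.8),
                      representation_sigma = 0.5,
                      depth_early = 5e5, depth_late = 5e5,
                      overdispersion = 25,
                      positional_bias_amplitude = 0,
                      nmd_escape_nterm = 0L, partial_cterm_start = NULL,
                      seed) {
    if (missing(seed))
        stop("a seed is mandatory for reproducible simulation")
    cfg <- list(orf_length = as.integer(orf_length), scheme = scheme,
                n_replicates = as.integer(n_replicates),
                doublings = doublings, suppression = suppression,
                lof_fraction_missense = lof_fraction_missense,
                lof_cluster = lof_cluster,
                partial_effect_range = partial_effect_range,
                representation_sigma = representation_sigma,
                depth_early = depth_early, depth_late = depth_late,
                overdispersion = overdispersion,
                positional_bias_amplitude = positional_bias_amplitude,
                nmd_escape_nterm = as.integer(nmd_escape_nterm),
                partial_cterm_start = partial_cterm_start,
                seed = as.integer(seed))
    if (cfg$orf_length < 10L)
        stop("orf_length must be at least 10 residues")
    if (cfg$n_replicates < 1L)
        stop("need at least one replicate")
    probs <- c(cfg$suppression, cfg$lof_fraction_missense,
               cfg$partial_effect_range)
    if (any(probs < 0 | probs > 1))
        stop("suppression, lof_fraction_missense and partial_effect_range ",
             "must lie in [0, 1]")
    if (diff(cfg$partial_effect_range) < 0)
        stop("partial_effect_range must be an interval")
    if (cfg$depth_early <= 0 || cfg$depth_late <= 0)
        stop("sequencing depths must be positive")
    if (cfg$overdispersion <= 0)
        stop("overdispersion (gamma shape) must be positive")
    if (!is.null(cfg$lof_cluster)) {
        if (!is.list(cfg$lof_cluster))
            cfg$lof_cluster <- list(cfg$lof_cluster)
        for (iv in cfg$lof_cluster)
            if (length(iv) != 2L || iv[1L] > iv[2L] || iv[1L] < 1L ||
                iv[2L] > cfg$orf_length)
                stop("lof_cluster intervals must lie within the ORF")
    }
    class(cfg) <- c("SimConfig", "list")
    cfg
}

#' Generate a random stop-free ORF
#'
#' Random sense codons (uniform over the 61 non-stop codons) behind an ATG
#' start; deterministic for a given seed.
#'
#' @param n_residues ORF length in residues (>= 10).
#' @param seed integer seed.
#' @return Named character scalar usable with [enumerateLibrary()].
#' @export
generateOrf <- function(n_residues, seed) {
    n_residues <- as.integer(n_residues)
    if (n_residues < 10L)
        stop("n_residues must be at least 10")
    sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    .withSeed(seed, {
        codons <- c("ATG", sample(sense, n_residues - 1L, replace = TRUE))
        stats::setNames(paste(codons, collapse = ""),
                        sprintf("synthetic_orf_L%d_seed%d", n_residues,
                                seed))
    })
}

.inCluster <- function(position, cluster) {
    if (is.null(cluster)) return(rep(FALSE, length(position)))
    hit <- rep(FALSE, length(position))
    for (iv in cluster)
        hit <- hit | (position >= iv[1L] & position <= iv[2L])
    hit
}

#' Assign ground-truth effects to a variant library
#'
#' Silent variants are always functional. Missense variants are LOF with
#' probability `lof_fraction_missense`, or deterministically inside any
#' `lof_cluster` interval. Nonsense and frameshift variants are LOF, except
#' nonsense up to `nmd_escape_nterm` (start-site read-through) and any
#' truncating variant at or beyond `partial_cterm_start`, which become
#' partial alleles with residual activity `theta` drawn uniformly from
#' `partial_effect_range`. Relative fitness is `w = 1 - e * s` with
#' residual activity `e` (1 functional, 0 LOF, `theta` partial).
#'
#' @param library a [DmsLibrary-class].
#' @param config a [simConfig()]; its `seed` (offset by one) fixes the
#'   stochastic assignments.
#' @return `DataFrame` with `variant_id`, `effect_class`, `theta` and
#'   `fitness`.
#' @export
assignEffects <- function(library, config) {
    v <- variantTable(library)
    .withSeed(config$seed + 1L, {
        cls <- rep("functional", nrow(v))
        theta <- rep(1, nrow(v))
        mis <- v$consequence == "missense"
        planted <- mis & .inCluster(v$position, config$lof_cluster)
        random_lof <- mis & !planted &
            runif(nrow(v)) < config$lof_fraction_missense
        trunc <- v$consequence %in% c("nonsense", "frameshift")
        cls[trunc | planted | random_lof] <- "lof"
        theta[trunc | planted | random_lof] <- 0
        escape <- v$consequence == "nonsense" &
            v$position <= config$nmd_escape_nterm
        if (!is.null(config$partial_cterm_start))
            escape <- escape | (trunc &
                v$position >= config$partial_cterm_start)
        if (any(escape)) {
            cls[escape] <- "partial"
            theta[escape] <- runif(sum(escape),
                                   config$partial_effect_range[1L],
                                   config$partial_effect_range[2L])
        }
        out <- DataFrame(variant_id = v$variant_id, effect_class = cls,
                         theta = theta,
                         fitness = 1 - theta * config$suppression)
        rownames(out) <- out$variant_id
        out
    })
}

# Fixed per-replicate suppression multipliers: replicate contexts are
# distinct cell-line backgrounds, modeled as systematic (not resampled)
# deviations spanning +/- 20% of the configured suppression.
.replicateMultipliers <- function(n) {
    if (n == 1L) 1 else seq(0.8, 1.2, length.out = n)
}

#' Simulate a pooled DMS proliferation screen
#'
#' Draws a library representation from a log-normal skew, propagates each
#' variant through `doublings` generations of growth at its replicate-
#' specific fitness, applies a smooth positional bias and per-variant
#' gamma noise to the expected late abundance, and samples early and late
#' read counts multinomially at the configured depths. All randomness
#' derives from the single configured seed; identical configurations give
#' bit-identical output.
#'
#' @param config a [simConfig()].
#' @param orf optional pre-built ORF (named character); default generated
#'   from the config.
#' @param library optional pre-built [DmsLibrary-class]; default
#'   enumerated from `orf` under the configured scheme.
#' @return A [DmsSimulation-class].
#' @examples
#' sim <- simulateScreen(simConfig(orf_length = 30, seed = 42))
#' sim
#' @export
simulateScreen <- function(config, orf = NULL, library = NULL) {
    stopifnot(inherits(config, "SimConfig"))
    if (is.null(orf))
        orf <- generateOrf(config$orf_length, config$seed)
    if (is.null(library))
        library <- enumerateLibrary(orf, config$scheme)
    truth <- assignEffects(library, config)
    v <- variantTable(library)
    L <- nResidues(library)
    nv <- nrow(v)
    bias <- config$positional_bias_amplitude *
        sin(2 * pi * v$position / L)
    mult <- .replicateMultipliers(config$n_replicates)
    .withSeed(config$seed + 2L, {
        a0 <- rlnorm(nv, meanlog = 0, sdlog = config$representation_sigma)
        p_early <- a0 / sum(a0)
        counts <- NULL; cd <- NULL
        for (r in seq_len(config$n_replicates)) {
            s_r <- config$suppression * mult[r]
            w_r <- 1 - truth$theta * s_r
            noise <- rgamma(nv, shape = config$overdispersion,
                            rate = config$overdispersion)
            a_late <- a0 * w_r^config$doublings * 2^bias * noise
            early <- rmultinom(1L, size = config$depth_early,
                               prob = p_early)[, 1L]
            late <- rmultinom(1L, size = config$depth_late,
                              prob = a_late / sum(a_late))[, 1L]
            rep_id <- sprintf("rep%d", r)
            counts <- cbind(counts, early, late)
            colnames(counts)[ncol(counts) - 1:0] <-
                paste0(rep_id, c("_early", "_late"))
            cd <- rbind(cd, data.frame(
                sample_id = paste0(rep_id, c("_early", "_late")),
                replicate_id = rep_id, timepoint = c("early", "late")))
        }
        rownames(counts) <- v$variant_id
        sc <- ScreenCounts(counts, cd, library = library)
        new("DmsSimulation", counts = sc, library = library, truth = truth,
            config = unclass(config))
    })
}

#' Recovery of planted effects by the scoring pipeline
#'
#' Compares LOF calls at a z threshold with the simulation ground truth:
#' sensitivity is the fraction of true LOF variants called LOF,
#' specificity the fraction of true functional variants not called LOF
#' (partial alleles are excluded from both), with per-consequence z-score
#' summaries.
#'
#' @param scores a [FunctionalScores-class] for the simulated screen.
#' @param truth ground-truth table from [simTruth()] / [assignEffects()].
#' @param threshold LOF threshold (default 2).
#' @return List with `sensitivity`, `specificity`, `n_lof`, `n_functional`
#'   and `class_summary` (per consequence: n, mean and SD of mean z).
#' @export
evaluateRecovery <- function(scores, truth, threshold = 2) {
    s <- .scoresInput(scores)
    truth <- as.data.frame(truth)
    idx <- match(s$variant_id, truth$variant_id)
    if (anyNA(idx))
        stop("truth is missing scored variant(s): ",
             paste(utils::head(s$variant_id[is.na(idx)], 5),
                   collapse = ", "))
    eff <- truth$effect_class[idx]
    called <- !is.na(s$mean_z) & s$mean_z > threshold
    lof <- eff == "lof"; fun <- eff == "functional"
    cls <- lapply(split(s$mean_z, s$consequence), function(x) {
        x <- x[is.finite(x)]
        c(n = length(x), mean_z = mean(x), sd_z = sd(x))
    })
    list(sensitivity = if (any(lof)) mean(called[lof]) else NA_real_,
         specificity = if (any(fun)) mean(!called[fun]) else NA_real_,
         n_lof = sum(lof), n_functional = sum(fun),
         class_summary = cls)
}
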