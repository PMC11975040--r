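test_that("ORF generation is deterministic, stop-free and of the requested length", {
    a <- generateOrf(120, seed = 1)
    b <- generateOrf(120, seed = 1)
    expect_identical(a, b)
    expect_false(identical(unname(a), unname(generateOrf(120, seed = 2))))
    expect_equal(unname(nchar(generateOrf(10, seed = 2))), 30L)
    for (seed in 1:5) {
        orf <- generateOrf(40, seed = seed)
        aa <- translateCodon(substring(orf, seq(1, nchar(orf) - 2, 3),
                                       seq(3, nchar(orf), 3)))
        expect_false(any(aa == "*"))
        expect_identical(aa[1], "M")
    }
    expect_error(generateOrf(9, seed = 1), "at least 10")
})

test_that("effect assignment honors class rules, clusters and partial regions", {
    lib <- enumerateLibrary(generateOrf(60, seed = 4))
    v <- as.data.frame(variantTable(lib))
    # no random LOF, no clusters: all missense functional, truncations LOF
    cfg0 <- simConfig(orf_length = 60, lof_fraction_missense = 0, seed = 4)
    t0 <- as.data.frame(assignEffects(lib, cfg0))
    m <- merge(t0, v)
    expect_true(all(m$effect_class[m$consequence %in%
                                   c("silent", "missense")] == "functional"))
    expect_true(all(m$effect_class[m$consequence %in%
                                   c("nonsense", "frameshift")] == "lof"))
    expect_true(all(m$fitness[m$effect_class == "functional"] == 0.7))
    expect_true(all(m$fitness[m$effect_class == "lof"] == 1))
    # planted cluster: every missense inside is LOF
    cfgc <- simConfig(orf_length = 60, lof_cluster = list(c(10, 15)),
                      lof_fraction_missense = 0, seed = 4)
    tc <- merge(as.data.frame(assignEffects(lib, cfgc)), v)
    inside <- tc$consequence == "missense" & tc$position %in% 10:15
    expect_true(all(tc$effect_class[inside] == "lof"))
    expect_equal(sum(inside), 6 * 19)
    # C-terminal truncations become partial with fitness strictly inside
    cfgp <- simConfig(orf_length = 60, partial_cterm_start = 54,
                      lof_fraction_missense = 0, seed = 4)
    tp <- merge(as.data.frame(assignEffects(lib, cfgp)), v)
    cterm <- tp$consequence %in% c("nonsense", "frameshift") &
        tp$position >= 54
    expect_true(all(tp$effect_class[cterm] == "partial"))
    expect_true(all(tp$fitness[cterm] > 0.7 & tp$fitness[cterm] < 1))
    # N-terminal escape applies to nonsense only, never frameshift
    cfgn <- simConfig(orf_length = 60, nmd_escape_nterm = 5,
                      lof_fraction_missense = 0, seed = 4)
    tn <- merge(as.data.frame(assignEffects(lib, cfgn)), v)
    expect_true(all(tn$effect_class[tn$consequence == "nonsense" &
                                    tn$position <= 5] == "partial"))
    expect_true(all(tn$effect_class[tn$consequence == "frameshift" &
                                    tn$position <= 5] == "lof"))
    expect_error(simConfig(orf_length = 60, lof_cluster = list(c(55, 70)),
                           seed = 1), "within the ORF")
})

test_that("screen simulation is bit-identical for a fixed seed", {
    cfg <- simConfig(orf_length = 25, seed = 33)
    a <- simulateScreen(cfg); b <- simulateScreen(cfg)
    expect_identical(SummarizedExperiment::assay(simCounts(a), "counts"),
                     SummarizedExperiment::assay(simCounts(b), "counts"))
    expect_identical(as.data.frame(simTruth(a)),
                     as.data.frame(simTruth(b)))
    c <- simulateScreen(simConfig(orf_length = 25, seed = 34))
    expect_false(identical(
        SummarizedExperiment::assay(simCounts(a), "counts"),
        SummarizedExperiment::assay(simCounts(c), "counts")))
    # simulation does not disturb the caller's RNG stream
    set.seed(5); x1 <- runif(1)
    set.seed(5); invisible(simulateScreen(cfg)); x2 <- runif(1)
    expect_identical(x1, x2)
})

test_that("simulated samples follow the configured structure and depths", {
    cfg <- simConfig(orf_length = 20, n_replicates = 2,
                     depth_early = 1e4, depth_late = 2e4, seed = 6)
    sim <- simulateScreen(cfg)
    cd <- as.data.frame(SummarizedExperiment::colData(simCounts(sim)))
    expect_equal(nrow(cd), 4L)
    expect_equal(sort(unique(cd$replicate_id)), c("rep1", "rep2"))
    cts <- SummarizedExperiment::assay(simCounts(sim), "counts")
    expect_equal(unname(colSums(cts)[cd$timepoint == "early"]),
                 rep(1e4, 2))
    expect_equal(unname(colSums(cts)[cd$timepoint == "late"]),
                 rep(2e4, 2))
    tr <- as.data.frame(simTruth(sim))
    v <- as.data.frame(variantTable(sim@library))
    expect_true(all(tr$effect_class[
        v$consequence[match(tr$variant_id, v$variant_id)] == "silent"] ==
        "functional"))
})

test_that("recovery evaluation reports sensitivity and specificity against truth", {
    truth <- S4Vectors::DataFrame(
        variant_id = c("a", "b", "c", "d"),
        effect_class = c("lof", "lof", "functional", "functional"),
        theta = c(0, 0, 1, 1), fitness = c(1, 1, 0.7, 0.7))
    s <- data.frame(variant_id = c("a", "b", "c", "d"),
                    position = 1:4, consequence = "missense",
                    mean_z = c(5, 3, 0, -1))
    r <- evaluateRecovery(s, truth)
    expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
    s$mean_z <- c(-1, -1, -1, -1)
    expect_equal(evaluateRecovery(s, truth)$sensitivity, 0)
    expect_error(evaluateRecovery(
        data.frame(variant_id = "zz", position = 1,
                   consequence = "missense", mean_z = 1), truth),
        "missing scored variant")
})

test_that("the expected enrichment gap separates LOF from functional variants", {
    cfg <- simConfig(orf_length = 80, seed = 13)
    sim <- simulateScreen(cfg)
    l2fc <- l2fcTable(simCounts(sim))
    tr <- as.data.frame(simTruth(sim))
    m <- rowMeans(l2fc)[tr$variant_id]
    gap <- mean(m[tr$effect_class == "lof"]) -
        mean(m[tr$effect_class == "functional"])
    expect_equal(gap, 6 * log2(1 / 0.7), tolerance = 0.15 / 3)
})
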