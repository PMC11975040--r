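test_that("pseudocounted frequencies and log2 fold changes follow the definitions", {
    expect_equal(toFrequencies(c(1, 1, 2), pseudocount = 0),
                 c(0.25, 0.25, 0.5))
    expect_equal(toFrequencies(c(0, 0, 0), pseudocount = 0.5),
                 rep(1 / 3, 3))
    expect_equal(toFrequencies(c(10, 30, 60), pseudocount = 0.5),
                 c(10.5, 30.5, 60.5) / 101.5)
    expect_error(toFrequencies(c(0, 0), pseudocount = 0), "undefined")
    expect_error(toFrequencies(c(-1, 2)), "non-negative")

    f <- c(0.2, 0.3, 0.5)
    expect_equal(computeL2fc(f, f), c(0, 0, 0))
    expect_equal(computeL2fc(c(0.25, 0.75), c(0.5, 0.5))[1], 1)
    e <- toFrequencies(c(100, 9900), 0); l <- toFrequencies(c(25, 9975), 0)
    expect_equal(computeL2fc(e, l)[1], -2, tolerance = 1e-3)
    expect_error(computeL2fc(c(0, 1), c(0.5, 0.5)), "positive")
})

test_that("rolling baseline reproduces hand-computed window statistics", {
    lib <- toy_library(data.frame(
        variant_id = c("s1", "s2", "s3", "m2"),
        position = c(1, 2, 3, 2),
        consequence = c("silent", "silent", "silent", "missense")), L = 5)
    l2fc <- toy_l2fc(lib, c(-1, -2, -3, 0))
    bl <- silentBaseline(l2fc, lib, half_width = 2, min_silent = 3)
    st <- as.data.frame(baselineStats(bl))
    p2 <- st[st$position == 2, ]
    expect_equal(p2$rolling_mean, -2)
    expect_equal(p2$rolling_sd, 1)       # n-1 SD of {-1,-2,-3}
    expect_equal(p2$n_silent, 3L)
    expect_false(p2$sd_floored)
    # the missense variant at position 2 with l2fc 0 scores z = 2
    z <- replicateZscores(l2fc, bl, lib)
    expect_equal(unname(z["m2", "r1"]), 2)
    expect_equal(unname(z["s2", "r1"]), 0)
})

test_that("an all-equal silent baseline escalates to an unusable replicate", {
    lib <- toy_library(data.frame(
        variant_id = c("s1", "s2", "s3", "m1"),
        position = c(1, 2, 3, 2),
        consequence = c("silent", "silent", "silent", "missense")), L = 3)
    l2fc <- toy_l2fc(lib, c(-2, -2, -2, 1))
    bl <- silentBaseline(l2fc, lib)
    st <- as.data.frame(baselineStats(bl))
    expect_true(all(st$sd_floored))
    expect_true(all(is.na(st$rolling_sd)))
    z <- replicateZscores(l2fc, bl, lib)
    expect_true(all(is.na(z)))
    agg <- aggregateReplicates(z)
    expect_true(all(agg$flag == "no_replicate_z"))
})

test_that("sparse silent coverage expands the window until satisfied", {
    lib <- toy_library(data.frame(
        variant_id = c("s1", "s10", "m5"),
        position = c(1, 10, 5),
        consequence = c("silent", "silent", "missense")), L = 10)
    l2fc <- toy_l2fc(lib, c(-1, 1, 0))
    bl <- silentBaseline(l2fc, lib, half_width = 2, min_silent = 2)
    st <- as.data.frame(baselineStats(bl))
    p5 <- st[st$position == 5, ]
    expect_equal(p5$n_silent, 2L)
    expect_gt(p5$window_used, 2)
    expect_equal(p5$rolling_mean, 0)
    expect_error(silentBaseline(
        toy_l2fc(toy_library(data.frame(variant_id = "m1", position = 1,
                                        consequence = "missense"), L = 3),
                 0),
        toy_library(data.frame(variant_id = "m1", position = 1,
                               consequence = "missense"), L = 3)),
        "no silent")
})

test_that("rolling statistics match a brute-force per-window recomputation on random libraries", {
    set.seed(404)
    for (rep in 1:20) {
        L <- sample(8:40, 1)
        n_sil <- sample(4:15, 1)
        pos <- sort(sample(seq_len(L), n_sil, replace = TRUE))
        ids <- sprintf("s%d", seq_along(pos))
        lib <- toy_library(data.frame(variant_id = ids, position = pos,
                                      consequence = "silent"), L = L)
        vals <- rnorm(n_sil)
        l2fc <- toy_l2fc(lib, vals)
        hw <- sample(1:3, 1); ms <- sample(2:4, 1)
        bl <- silentBaseline(l2fc, lib, half_width = hw, min_silent = ms)
        st <- as.data.frame(baselineStats(bl))
        for (p in seq_len(L)) {
            o <- oracle_rolling(p, pos, vals, hw, ms, L)
            row <- st[st$position == p, ]
            expect_equal(row$rolling_mean, unname(o["mean"]),
                         tolerance = 1e-12)
            if (!is.na(o["sd"]) && o["sd"] > 0)
                expect_equal(row$rolling_sd, unname(o["sd"]),
                             tolerance = 1e-12)
            expect_equal(row$n_silent, unname(as.integer(o["n"])))
        }
    }
})

test_that("replicate aggregation uses the unweighted mean and n-1 SD over defined z", {
    agg <- aggregateReplicates(c(r1 = 1, r2 = 2, r3 = 3))
    expect_equal(agg$mean_z, 2); expect_equal(agg$sd_z, 1)
    expect_equal(agg$n_replicates, 3L)
    one <- aggregateReplicates(c(r1 = 2))
    expect_equal(one$mean_z, 2); expect_true(is.na(one$sd_z))
    part <- aggregateReplicates(c(r1 = 0.5, r2 = NA, r3 = 1.5))
    expect_equal(part$mean_z, 1); expect_equal(part$n_replicates, 2L)
    none <- aggregateReplicates(c(r1 = NA_real_))
    expect_true(is.na(none$mean_z))
    expect_identical(none$flag, "no_replicate_z")
})

test_that("z-scores are invariant to sequencing depth scaling and to additive l2fc shifts", {
    sim <- simulateScreen(simConfig(orf_length = 25, seed = 11))
    lib <- sim@library
    cts <- SummarizedExperiment::assay(simCounts(sim), "counts")
    cd <- as.data.frame(SummarizedExperiment::colData(simCounts(sim)))
    # exact invariance at pseudocount 0 when one sample is scaled 3x
    keep <- rowSums(cts == 0) == 0
    cts <- cts[keep, , drop = FALSE]
    sc1 <- ScreenCounts(cts, cd, library = lib)
    cts2 <- cts; cts2[, 2] <- cts2[, 2] * 3L
    sc2 <- ScreenCounts(cts2, cd, library = lib)
    z1 <- replicateZscores(l2fcTable(sc1, 0),
                           silentBaseline(l2fcTable(sc1, 0), lib), lib)
    z2 <- replicateZscores(l2fcTable(sc2, 0),
                           silentBaseline(l2fcTable(sc2, 0), lib), lib)
    expect_equal(z1, z2, tolerance = 1e-12)
    # near-invariance with the default pseudocount on a deep screen: the
    # residual is the differential pseudocount term ~(0.5/c)(1-1/k)/ln2,
    # scaled by 1/sd at the window
    deep <- simulateScreen(simConfig(orf_length = 25, seed = 11,
                                     depth_early = 5e6, depth_late = 5e6))
    dcts <- SummarizedExperiment::assay(simCounts(deep), "counts")
    expect_gte(min(dcts), 10)
    dcd <- as.data.frame(SummarizedExperiment::colData(simCounts(deep)))
    sc3 <- ScreenCounts(dcts, dcd, library = deep@library)
    dcts2 <- dcts; dcts2[, 2] <- dcts2[, 2] * 5L
    sc4 <- ScreenCounts(dcts2, dcd, library = deep@library)
    f3 <- scoreScreen(sc3, deep@library)
    f4 <- scoreScreen(sc4, deep@library)
    expect_lt(max(abs(replicateZ(f3) - replicateZ(f4)), na.rm = TRUE),
              1e-2)
    # location equivariance: adding c to every l2fc leaves z unchanged
    l2fc <- l2fcTable(sc1)
    bl <- silentBaseline(l2fc, lib)
    zs <- replicateZscores(l2fc, bl, lib)
    l2fc_shift <- l2fc + 0.7
    zs2 <- replicateZscores(l2fc_shift, silentBaseline(l2fc_shift, lib),
                            lib)
    expect_equal(zs, zs2, tolerance = 1e-10)
})

test_that("increasing a variant's late count strictly increases its z-score", {
    sim <- simulateScreen(simConfig(orf_length = 20, seed = 5))
    lib <- sim@library
    cts <- SummarizedExperiment::assay(simCounts(sim), "counts")
    cd <- as.data.frame(SummarizedExperiment::colData(simCounts(sim)))
    v <- variantTable(lib)
    target <- v$variant_id[v$consequence == "missense"][1]
    late1 <- grep("rep1_late", colnames(cts))
    z_at <- function(extra) {
        m <- cts
        m[target, late1] <- m[target, late1] + extra
        sc <- ScreenCounts(m, cd, library = lib)
        replicateZ(scoreScreen(sc, lib))[target, "rep1"]
    }
    zs <- vapply(c(0L, 200L, 1000L), z_at, numeric(1))
    expect_true(all(diff(zs) > 0))
})

test_that("leave-one-out mode removes the focal silent variant from its own window", {
    lib <- toy_library(data.frame(
        variant_id = sprintf("s%d", 1:5), position = 1:5,
        consequence = "silent"), L = 5)
    vals <- c(-1, 0, 1, 2, 5)
    l2fc <- toy_l2fc(lib, vals)
    bl <- silentBaseline(l2fc, lib, half_width = 2, min_silent = 3)
    z_loo <- replicateZscores(l2fc, bl, lib, leave_one_out = TRUE)
    # s3's window {1..5} minus itself = {-1,0,2,5}
    expect_equal(unname(z_loo["s3", 1]),
                 (1 - mean(c(-1, 0, 2, 5))) / sd(c(-1, 0, 2, 5)))
})
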