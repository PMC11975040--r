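test_that("codon translation matches the Biostrings translation oracle", {
    bases <- c("A", "C", "G", "T")
    all64 <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    oracle <- vapply(all64, function(cd)
        as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                           no.init.codon = TRUE)),
        character(1))
    expect_identical(translateCodon(all64), unname(oracle))
    expect_identical(translateCodon(c("ATG", "TGA", "TGG")),
                     c("M", "*", "W"))
    expect_error(translateCodon("AUG"), "3-mer")
    expect_error(translateCodon("AA"), "3-mer")
})

test_that("substitution classification agrees with a translate-and-compare oracle on all ordered codon pairs", {
    bases <- c("A", "C", "G", "T")
    all64 <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    aa <- vapply(all64, function(cd)
        as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                           no.init.codon = TRUE)),
        character(1))
    sense <- all64[aa != "*"]
    pairs <- expand.grid(ref = sense, alt = all64,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$ref != pairs$alt, ]
    got <- classifySubstitution(pairs$ref, pairs$alt)
    want <- ifelse(aa[pairs$alt] == "*", "nonsense",
            ifelse(aa[pairs$ref] == aa[pairs$alt], "silent", "missense"))
    expect_identical(got, unname(want))
    expect_identical(classifySubstitution("AAA", "AAG"), "silent")
    expect_identical(classifySubstitution("TGG", "CCG"), "missense")
    expect_identical(classifySubstitution("TGG", "TGA"), "nonsense")
    expect_error(classifySubstitution("TGA", "TGG"), "stop")
})

test_that("library enumeration yields the expected class composition", {
    orf <- c(demo = "ATGAAATGG")  # M-K-W
    mis <- enumerateLibrary(orf, libraryScheme(include_silent = FALSE,
                                               include_nonsense = FALSE,
                                               include_frameshift = FALSE))
    expect_equal(length(mis), 57L)  # 3 residues x 19
    v <- variantTable(mis)
    expect_true(all(table(v$position) == 19L))
    sil <- enumerateLibrary(orf, libraryScheme(include_missense = FALSE,
                                               include_nonsense = FALSE,
                                               include_frameshift = FALSE))
    # only AAA has a synonymous alternative (AAG); ATG and TGG have none
    expect_equal(length(sil), 1L)
    expect_identical(variantTable(sil)$alt_codon, "AAG")
    expect_warning(
        empty <- enumerateLibrary(orf, libraryScheme(FALSE, FALSE, FALSE,
                                                     FALSE)),
        "empty")
    expect_equal(length(empty), 0L)
})

test_that("every residue gets exactly 19 missense entries under one-codon-per-target-aa, and at most 19 otherwise", {
    for (seed in 1:3) {
        orf <- generateOrf(15, seed = seed)
        lib <- enumerateLibrary(orf)
        v <- variantTable(lib)
        mis <- v[v$consequence == "missense", ]
        expect_true(all(table(mis$position) == 19L))
        # no duplicate (position, alt) pairs anywhere
        key <- paste(v$position, ifelse(is.na(v$alt_codon), "fs",
                                        v$alt_codon))
        expect_false(anyDuplicated(key) > 0)
        all_cod <- enumerateLibrary(orf, libraryScheme(
            missense_codon_rule = "all-codons"))
        va <- variantTable(all_cod)
        va <- va[va$consequence == "missense", ]
        n_aa <- tapply(va$alt_aa, va$position,
                       function(x) length(unique(x)))
        expect_true(all(n_aa <= 19L))
    }
})

test_that("enumeration is deterministic and position-sorted", {
    orf <- generateOrf(12, seed = 9)
    a <- enumerateLibrary(orf)
    b <- enumerateLibrary(orf)
    expect_identical(as.data.frame(variantTable(a)),
                     as.data.frame(variantTable(b)))
    expect_true(!is.unsorted(variantTable(a)$position))
})

test_that("SNV expansion matches brute force over the nine single-base mutants", {
    orf <- c(demo = "ATGAAATGG")
    lib <- enumerateLibrary(orf, libraryScheme(
        missense_codon_rule = "one-codon-per-target-aa"))
    # K2K via AAG: one SNV (third base A>G)
    kk <- expandToSnvs(lib, "K2K")
    expect_equal(nrow(kk), 1L)
    expect_equal(kk$cds_position, 6L)
    expect_identical(kk$ref_base, "A"); expect_identical(kk$alt_base, "G")
    # K2N reachable via AAT and AAC
    kn <- expandToSnvs(lib, "K2N")
    expect_equal(nrow(kn), 2L)
    expect_setequal(kn$alt_codon, c("AAT", "AAC"))
    # K2P needs two substitutions
    expect_equal(nrow(expandToSnvs(lib, "K2P")), 0L)
    expect_error(expandToSnvs(lib, "fs2-1"), "frameshift")
})

test_that("re-translating expanded SNVs reproduces the parent consequence", {
    for (seed in 1:3) {
        lib <- enumerateLibrary(generateOrf(12, seed = seed))
        snvs <- expandToSnvs(lib)
        v <- variantTable(lib)
        idx <- match(snvs$parent_variant_id, v$variant_id)
        aa <- translateCodon(snvs$alt_codon)
        cons <- ifelse(aa == "*", "nonsense",
                ifelse(aa == v$ref_aa[idx], "silent", "missense"))
        expect_identical(cons, v$consequence[idx])
        expect_identical(aa, v$alt_aa[idx])
        # every SNV position sits inside the parent codon
        expect_true(all((snvs$cds_position - 1) %/% 3 + 1 ==
                        v$position[idx]))
    }
})
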