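#' @importFrom S4Vectors DataFrame
NULL

#' Library composition scheme
#'
#' Controls which consequence classes a codon-level variant library
#' contains and how codons are chosen for programmed changes. Under
#' `missense_codon_rule = "one-codon-per-target-aa"` every residue receives
#' exactly 19 missense entries (one codon per non-reference amino acid,
#' using the most-used human codon, ties broken alphabetically); under
#' `"all-codons"` every codon of every target amino acid is included.
#' Frameshifts are modeled as a single-nucleotide deletion at the first
#' base of the codon, one per position.
#'
#' @param include_silent,include_nonsense,include_frameshift logical flags.
#' @param include_missense logical flag.
#' @param missense_codon_rule `"one-codon-per-target-aa"` or `"all-codons"`.
#' @param synonymous_rule `"all-synonymous-codons"` (every synonymous codon
#'   of the reference becomes a silent entry) or `"one-per-position"`.
#' @return A named list of class `"LibraryScheme"`.
#' @examples
#' libraryScheme(include_frameshift = FALSE)
#' @export
libraryScheme <- function(include_silent = TRUE, include_missense = TRUE,
                          include_nonsense = TRUE, include_frameshift = TRUE,
                          missense_codon_rule = c("one-codon-per-target-aa",
                                                  "all-codons"),
                          synonymous_rule = c("all-synonymous-codons",
                                              "one-per-position")) {
    scheme <- list(include_silent = isTRUE(include_silent),
                   include_missense = isTRUE(include_missense),
                   include_nonsense = isTRUE(include_nonsense),
                   include_frameshift = isTRUE(include_frameshift),
                   missense_codon_rule = match.arg(missense_codon_rule),
                   synonymous_rule = match.arg(synonymous_rule))
    if (!any(unlist(scheme[1:4])))
        warning("all consequence classes disabled; the library will be empty")
    class(scheme) <- c("LibraryScheme", "list")
    scheme
}

.orfInput <- function(orf) {
    if (methods::is(orf, "DNAStringSet")) {
        if (length(orf) != 1L)
            stop("expected a single ORF sequence")
        return(list(id = if (is.null(names(orf))) "ORF" else names(orf)[1L],
                    seq = as.character(orf[[1L]])))
    }
    if (is.character(orf) && length(orf) == 1L)
        return(list(id = if (is.null(names(orf))) "ORF" else names(orf),
                    seq = toupper(unname(orf))))
    stop("orf must be a single character sequence or a DNAStringSet of 1")
}

.codonsOf <- function(seq) {
    substring(seq, seq(1L, nchar(seq) - 2L, by = 3L),
              seq(3L, nchar(seq), by = 3L))
}

#' Read a single ORF from a FASTA file
#'
#' @param path FASTA file path.
#' @param id record id to use; required when the file holds more than one
#'   record.
#' @return Named character scalar (name = record id, value = sequence).
#' @export
readOrfFasta <- function(path, id = NULL) {
    recs <- Biostrings::readDNAStringSet(path)
    if (length(recs) == 0L)
        stop("no sequences in ", path)
    if (!is.null(id)) {
        key <- sub("\\s.*$", "", names(recs))
        hit <- which(key == id)
        if (length(hit) != 1L)
            stop("record '", id, "' not found (or not unique) in ", path)
        recs <- recs[hit]
    } else if (length(recs) > 1L) {
        stop(path, " holds ", length(recs),
             " records; specify `id` to select one")
    }
    stats::setNames(as.character(recs[[1L]]),
                    sub("\\s.*$", "", names(recs)[1L]))
}

#' Enumerate a codon-level variant library
#'
#' Produces the deterministic, position-sorted variant table for an ORF
#' under a [libraryScheme()]. Variant ids follow the
#' `<refAA><position><altAA>` convention (stop rendered `"*"`, frameshifts
#' `fs<position><offset>`); when a scheme yields several codons for the same
#' protein-level change the alternate codon is appended (`"K2K.AAG"`) to
#' keep ids unique.
#'
#' @param orf single named character sequence (e.g. from [readOrfFasta()])
#'   or a `DNAStringSet` of length 1.
#' @param scheme a [libraryScheme()].
#' @return A [DmsLibrary-class].
#' @examples
#' lib <- enumerateLibrary(c(demo = "ATGAAATGG"),
#'                         libraryScheme(include_silent = FALSE,
#'                                       include_nonsense = FALSE,
#'                                       include_frameshift = FALSE))
#' length(lib)  # 3 residues x 19 missense = 57
#' @export
enumerateLibrary <- function(orf, scheme = libraryScheme()) {
    orf <- .orfInput(orf)
    if (nchar(orf$seq) %% 3L != 0L || grepl("[^ACGT]", orf$seq))
        stop("ORF must be A/C/G/T with length divisible by 3")
    codons <- .codonsOf(orf$seq)
    aas <- unname(Biostrings::GENETIC_CODE[codons])
    if (any(aas[-length(aas)] == "*"))
        stop("ORF contains an internal stop codon")
    syn <- split(names(Biostrings::GENETIC_CODE), unname(Biostrings::GENETIC_CODE))
    rows <- vector("list", length(codons))
    for (p in seq_along(codons)) {
        rc <- codons[p]; ra <- aas[p]
        if (ra == "*") next  # terminal stop codon is not mutagenized
        part <- list()
        if (scheme$include_silent) {
            alt <- sort(setdiff(syn[[ra]], rc))
            if (scheme$synonymous_rule == "one-per-position")
                alt <- utils::head(alt, 1L)
            if (length(alt))
                part$silent <- data.frame(position = p, ref_codon = rc,
                    alt_codon = alt, alt_aa = ra, consequence = "silent")
        }
        if (scheme$include_missense) {
            targets <- setdiff(.AA20, ra)
            alt <- if (scheme$missense_codon_rule == "one-codon-per-target-aa")
                unname(.PREFERRED_CODON[targets])
            else unlist(lapply(targets, function(a) sort(syn[[a]])),
                        use.names = FALSE)
            alt_aa <- unname(Biostrings::GENETIC_CODE[alt])
            part$missense <- data.frame(position = p, ref_codon = rc,
                alt_codon = alt, alt_aa = alt_aa, consequence = "missense")
        }
        if (scheme$include_nonsense)
            part$nonsense <- data.frame(position = p, ref_codon = rc,
                alt_codon = .PREFERRED_CODON[["*"]], alt_aa = "*",
                consequence = "nonsense")
        if (scheme$include_frameshift)
            part$frameshift <- data.frame(position = p, ref_codon = rc,
                alt_codon = NA_character_, alt_aa = "fs",
                consequence = "frameshift")
        rows[[p]] <- do.call(rbind, part)
    }
    v <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
    if (is.null(v))
        v <- data.frame(position = integer(), ref_codon = character(),
                        alt_codon = character(), alt_aa = character(),
                        consequence = character())
    v$ref_aa <- unname(Biostrings::GENETIC_CODE[v$ref_codon])
    if (nrow(v)) {
        ord <- order(v$position,
                     match(v$consequence, .CONSEQUENCES),
                     v$alt_aa, v$alt_codon, method = "radix")
        v <- v[ord, , drop = FALSE]
        v$fs_offset <- ifelse(v$consequence == "frameshift", -1L, NA_integer_)
        v$variant_id <- ifelse(v$consequence == "frameshift",
                               sprintf("fs%d%+d", v$position, v$fs_offset),
                               paste0(v$ref_aa, v$position, v$alt_aa))
        dup <- v$variant_id %in% v$variant_id[duplicated(v$variant_id)]
        v$variant_id[dup] <- paste0(v$variant_id[dup], ".", v$alt_codon[dup])
    } else {
        v$ref_aa <- character()
        v$fs_offset <- integer(); v$variant_id <- character()
    }
    vd <- DataFrame(v[, c("variant_id", "position", "ref_codon", "alt_codon",
                          "fs_offset", "ref_aa", "alt_aa", "consequence")])
    rownames(vd) <- vd$variant_id
    new("DmsLibrary", orf_id = orf$id, orf_seq = orf$seq, variants = vd)
}

#' Expand codon-level variants to single-nucleotide variants
#'
#' For each (non-frameshift) library variant, returns every single-base
#' substitution of its reference codon that reproduces the variant's
#' protein-level change (same position and alternate amino acid). The list
#' is empty when the amino-acid change needs two or more substitutions.
#'
#' @param library a [DmsLibrary-class].
#' @param variant_id optional character vector of variants to expand;
#'   default all non-frameshift variants. Requesting a frameshift variant is
#'   an error.
#' @param match `"consequence"` (default; any single-base change with the
#'   same translated outcome) or `"codon"` (only the change reaching the
#'   variant's programmed alternate codon).
#' @return `DataFrame` with `cds_position` (1-based nucleotide index),
#'   `ref_base`, `alt_base`, `alt_codon` (the mutated codon) and
#'   `parent_variant_id`.
#' @examples
#' lib <- enumerateLibrary(c(demo = "ATGAAATGG"))
#' expandToSnvs(lib, "K2N")  # two SNVs: AAA>AAT, AAA>AAC
#' @export
expandToSnvs <- function(library, variant_id = NULL,
                         match = c("consequence", "codon")) {
    match <- match.arg(match)
    v <- variantTable(library)
    if (!is.null(variant_id)) {
        idx <- base::match(variant_id, v$variant_id)
        if (anyNA(idx))
            stop("unknown variant id(s): ",
                 paste(variant_id[is.na(idx)], collapse = ", "))
        v <- v[idx, , drop = FALSE]
        if (any(v$consequence == "frameshift"))
            stop("SNV expansion is undefined for frameshift variants")
    } else {
        v <- v[v$consequence != "frameshift", , drop = FALSE]
    }
    bases <- c("A", "C", "G", "T")
    out <- vector("list", nrow(v))
    for (i in seq_len(nrow(v))) {
        rc <- v$ref_codon[i]
        cs <- strsplit(rc, "")[[1L]]
        hit <- list()
        for (b in 1:3) for (nb in setdiff(bases, cs[b])) {
            mut <- cs; mut[b] <- nb
            mc <- paste(mut, collapse = "")
            keep <- if (match == "codon") identical(mc, v$alt_codon[i])
                    else unname(Biostrings::GENETIC_CODE[mc]) == v$alt_aa[i]
            if (keep)
                hit[[length(hit) + 1L]] <- data.frame(
                    cds_position = (v$position[i] - 1L) * 3L + b,
                    ref_base = cs[b], alt_base = nb, alt_codon = mc,
                    parent_variant_id = v$variant_id[i])
        }
        if (length(hit)) out[[i]] <- do.call(rbind, hit)
    }
    out <- out[!vapply(out, is.null, logical(1L))]
    if (!length(out))
        return(DataFrame(cds_position = integer(), ref_base = character(),
                         alt_base = character(), alt_codon = character(),
                         parent_variant_id = character()))
    DataFrame(do.call(rbind, out))
}
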