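## Shared fixtures: one toy database and one set of demo genomes per test
## session, cached under tempdir().

toyDbDir <- local({
    dir <- NULL
    function() {
        if (is.null(dir)) {
            d <- file.path(tempdir(), "defloc-toydb")
            if (!dir.exists(file.path(d, "sys"))) makeToyDb(d)
            dir <<- d
        }
        dir
    }
})

toyModels <- function() loadModels(toyDbDir())
toyMeta <- function() loadHmmMeta(file.path(toyDbDir(), "hmm_meta.txt"))

## demo genome fixtures, generated once per plan under a fixed session seed
demoFixture <- local({
    cache <- list()
    function(name, seed = 1L) {
        key <- paste0(name, "_", seed)
        if (is.null(cache[[key]])) {
            plan <- demoPlans(seed)[[name]]
            cache[[key]] <<- makeGenome(
                plan, file.path(tempdir(), "defloc-fx", key))
        }
        cache[[key]]
    }
})

## parse + substitute + merge + detect for one demo fixture; the default
## uses the fabricated hit tables (no search engine involved)
detectFixture <- function(fx, substitute = TRUE, noncoding = TRUE) {
    g <- parseGffFaa(fx$gff, fx$faa)
    domtbl <- fx$domtbl
    if (substitute) {
        g <- substitutePseudogenes(
            g, Biostrings::readAAStringSet(fx$pseudo_proteins))
        domtbl <- fx$domtbl_substituted
    }
    hits <- filterHits(parseDomtbl(domtbl), toyMeta())
    if (noncoding)
        g <- mergeNoncoding(g, parseCmsearch(fx$cmsearch),
                            parseCrisprGff(fx$crispr_gff))
    detectSystems(g, hits, toyModels(), toyMeta())
}

## canonical "model:member;member" signature of a call list, for comparison
## against truth tables
callSignatures <- function(calls) {
    if (!length(calls)) return(character())
    sort(vapply(calls, function(x)
        paste0(modelName(x), ":",
               paste(sort(members(x)$locus_tag), collapse = ";")),
        character(1)))
}

truthSignatures <- function(truth, phase = "final") {
    tr <- truth[truth$phase == phase, , drop = FALSE]
    if (!nrow(tr)) return(character())
    sort(paste0(tr$model, ":", tr$locus_tags))
}

## minimal filtered-hit row for engine-level tests
hitRow <- function(target, family, ievalue = 1e-20, bits = 100,
                   accession = paste0("ACC_", family),
                   evalue = ievalue, tcov = 0.9, hcov = 0.9) {
    data.frame(target_name = target, hmm_accession = accession,
               hmm_name = paste0(family, "_hmm"), protein_family = family,
               full_seq_evalue = evalue, domain_ievalue = ievalue,
               bit_score = bits, target_len = 200L, hmm_len = 200L,
               ali_target_from = 1L, ali_target_to = 180L,
               ali_hmm_from = 1L, ali_hmm_to = 180L,
               target_coverage = tcov, hmm_coverage = hcov,
               stringsAsFactors = FALSE)
}

## bare genome with n equally spaced single-contig features
barGenome <- function(n, contig = "c1", prefix = "g") {
    if (n == 0)
        return(Genome("toy", data.frame(contig = contig, length = 1000L)))
    ft <- data.frame(
        contig = contig, locus_tag = sprintf("%s%03d", prefix, seq_len(n)),
        start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
        strand = "+", order_index = NA_integer_, kind = "CDS",
        protein_seq = "MATTERS", stringsAsFactors = FALSE)
    Genome("toy", data.frame(contig = contig,
                             length = max(ft$end) + 100L), ft)
}
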