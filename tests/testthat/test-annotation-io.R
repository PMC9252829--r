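makeGffPair <- function(dir, prodigal = FALSE) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gff <- file.path(dir, "g.gff")
    faa <- file.path(dir, "g.faa")
    p <- vapply(1:3, function(i) randomProtein(50), character(1))
    if (prodigal) {
        writeLines(c(
            "##gff-version  3",
            paste0("# Sequence Data: seqnum=1;seqlen=5000;seqhdr=\"ctgA\""),
            paste0("# Model Data: version=Prodigal.v2.6.3;run_type=Single"),
            sprintf("ctgA\tProdigal_v2.6.3\tCDS\t%d\t%d\t50.0\t+\t0\tID=1_%d;partial=00",
                    c(101L, 501L, 1001L), c(400L, 800L, 1300L), 1:3)),
            gff)
        writeLines(paste0(">ctgA_", 1:3, " # 101 # 400 # 1 # ID=1_", 1:3,
                          "\n", p), faa)
    } else {
        writeLines(c(
            "##gff-version 3",
            "##sequence-region ctgA 1 5000",
            sprintf("ctgA\tRefSeq\tCDS\t%d\t%d\t.\t%s\t0\tID=cds%d;locus_tag=TOY_%04d;product=protein %d",
                    c(101L, 501L, 1001L), c(400L, 800L, 1300L),
                    c("+", "-", "+"), 1:3, 1:3, 1:3)),
            gff)
        writeLines(paste0(">TOY_", sprintf("%04d", 1:3), "\n", p), faa)
    }
    list(gff = gff, faa = faa, proteins = p)
}

test_that("dialect detection is content-based", {
    d <- file.path(tempdir(), "dialects")
    dir.create(d, showWarnings = FALSE)
    pair <- makeGffPair(file.path(d, "refseq"))
    expect_identical(detectDialect(c(pair$gff, pair$faa)), "refseq_gff_faa")
    ## order of the two files must not matter
    expect_identical(detectDialect(c(pair$faa, pair$gff)), "refseq_gff_faa")
    ppair <- makeGffPair(file.path(d, "prod"), prodigal = TRUE)
    expect_identical(detectDialect(c(ppair$gff, ppair$faa)),
                     "prodigal_gff_faa")
    gbk <- writeToyGenbank(file.path(d, "x.gbk"), features = list(
        list(location = "1..90", locus_tag = "A",
             translation = randomProtein(29))))
    expect_identical(detectDialect(gbk), "genbank")
    rast <- writeToyGenbank(file.path(d, "r.gbk"), comment = "rasttk v1.3",
        features = list(list(location = "1..90", locus_tag = "A",
                             translation = randomProtein(29))))
    expect_identical(detectDialect(rast), "rast_genbank")
    fna <- file.path(d, "x.fna")
    writeLines(c(">ctg1", strrep("ACGT", 100)), fna)
    expect_identical(detectDialect(fna), "nucleotide_fasta")
    bad <- file.path(d, "x.txt")
    writeLines("not a biological file", bad)
    expect_error(detectDialect(bad), "unsupported format")
})

test_that("RefSeq-style GFF+FASTA pairs normalize to an ordered Genome", {
    pair <- makeGffPair(file.path(tempdir(), "pair1"))
    g <- parseGffFaa(pair$gff, pair$faa)
    ft <- features(g)
    expect_identical(nrow(ft), 3L)
    expect_identical(ft$order_index, 0:2)
    expect_identical(ft$kind, rep("CDS", 3))
    expect_identical(ft$protein_seq, unname(pair$proteins))
    expect_identical(ft$strand, c("+", "-", "+"))
    ## coordinates round-trip exactly (1-based inclusive)
    expect_identical(ft$start, c(101L, 501L, 1001L))
    expect_identical(ft$end, c(400L, 800L, 1300L))
})

test_that("Prodigal identifier fix-up reconciles every CDS to a protein", {
    pair <- makeGffPair(file.path(tempdir(), "pair2"), prodigal = TRUE)
    g <- parseGffFaa(pair$gff, pair$faa, dialect = "prodigal_gff_faa")
    ft <- features(g)
    expect_identical(ft$locus_tag, paste0("ctgA_", 1:3))
    expect_false(anyNA(ft$protein_seq))
})

test_that("unreconcilable protein/CDS sets raise an error naming offenders", {
    pair <- makeGffPair(file.path(tempdir(), "pair3"))
    orphan <- file.path(tempdir(), "pair3", "orphan.faa")
    writeLines(c(paste0(">TOY_0001\n", pair$proteins[[1]]),
                 paste0(">TOY_0002\n", pair$proteins[[2]]),
                 paste0(">GHOST_9\n", randomProtein(30))), orphan)
    expect_error(parseGffFaa(pair$gff, orphan), "reconciliation")
    expect_error(parseGffFaa(pair$gff, orphan), "TOY_0003")
    expect_error(parseGffFaa(pair$gff, orphan), "GHOST_9")
})

test_that("GenBank parsing matches the flat-file reference semantics", {
    ## expectations frozen from a reference flat-file parser (Biopython)
    ## run on this exact record layout: outer span for join(), '-' strand
    ## for complement(), pseudo features without translation
    p1 <- randomProtein(99); p2 <- randomProtein(99); p3 <- randomProtein(99)
    set.seed(41)
    seq <- paste(sample(c("a", "c", "g", "t"), 5000, replace = TRUE),
                 collapse = "")
    gbk <- writeToyGenbank(file.path(tempdir(), "toy1.gbk"),
        features = list(
            list(location = "101..400", locus_tag = "TOY_0001",
                 product = "protein one", translation = p1),
            list(location = "complement(501..800)", locus_tag = "TOY_0002",
                 product = "protein two", translation = p2),
            list(location = "join(1001..1150,1201..1350)",
                 locus_tag = "TOY_0003", product = "joined protein",
                 translation = p3),
            list(location = "2001..2300", locus_tag = "TOY_0004",
                 pseudo = TRUE,
                 inference = "COORDINATES: similar to AA sequence:RefSeq:WP_123456789.1")),
        sequence = seq)
    g <- parseGenbank(gbk)
    ft <- features(g)
    expect_identical(nrow(ft), 4L)
    expect_identical(ft$start, c(101L, 501L, 1001L, 2001L))
    expect_identical(ft$end, c(400L, 800L, 1350L, 2300L))
    expect_identical(ft$strand, c("+", "-", "+", "+"))
    expect_identical(ft$protein_seq[1:3], c(p1, p2, p3))
    expect_identical(ft$kind, c("CDS", "CDS", "CDS", "pseudogene"))
    expect_true(is.na(ft$protein_seq[[4]]))
    expect_identical(ft$inference_accession[[4]], "WP_123456789.1")
    expect_s4_class(g@sequence, "DNAStringSet")
})

test_that("GenBank and GFF+FASTA paths agree on equivalent records", {
    p <- vapply(1:3, function(i) randomProtein(50), character(1))
    gbk <- writeToyGenbank(file.path(tempdir(), "eq.gbk"),
        features = lapply(1:3, function(i) list(
            location = if (i == 2) "complement(501..800)" else
                sprintf("%d..%d", c(101L, 501L, 1001L)[i],
                        c(400L, 800L, 1300L)[i]),
            locus_tag = sprintf("TOY_%04d", i),
            product = paste("protein", i), translation = p[[i]])))
    pair <- makeGffPair(file.path(tempdir(), "eqpair"))
    ## write the same proteins into the pair
    writeLines(paste0(">TOY_", sprintf("%04d", 1:3), "\n", p), pair$faa)
    a <- features(parseGenbank(gbk))
    b <- features(parseGffFaa(pair$gff, pair$faa))
    for (col in c("locus_tag", "start", "end", "strand", "order_index",
                  "kind", "protein_seq", "pseudo_substituted"))
        expect_identical(a[[col]], b[[col]])
})

test_that("a CDS without translation is translated from ORIGIN or skipped", {
    nt <- "atgaaacgcattagcaccaccattaccaccaccatttaa"  # MKRISTTITTTI*
    pad <- paste(rep("a", 61), collapse = "")
    gbk <- writeToyGenbank(file.path(tempdir(), "notrans.gbk"),
        length = 100L,
        features = list(list(location = sprintf("1..%d", nchar(nt)),
                             locus_tag = "NT_1")),
        sequence = paste0(nt, substr(pad, 1, 100 - nchar(nt))))
    ft <- features(parseGenbank(gbk))
    expect_identical(ft$protein_seq[[1]], "MKRISTTITTTI")
    gbk2 <- writeToyGenbank(file.path(tempdir(), "notrans2.gbk"),
        features = list(list(location = "1..90", locus_tag = "NT_2")))
    expect_warning(g2 <- parseGenbank(gbk2), "skipping")
    expect_identical(nrow(features(g2)), 0L)
})

test_that("pseudogene substitution attaches proteins and is idempotent", {
    fx <- demoFixture("wadjet_pseudo")
    g <- parseGffFaa(fx$gff, fx$faa)
    ft <- features(g)
    stopifnot(sum(ft$kind == "pseudogene") == 1L)
    expect_true(is.na(ft$protein_seq[ft$kind == "pseudogene"]))
    lookup <- Biostrings::readAAStringSet(fx$pseudo_proteins)
    g2 <- substitutePseudogenes(g, lookup)
    ft2 <- features(g2)
    ps <- ft2$kind == "pseudogene"
    expect_true(all(ft2$pseudo_substituted[ps]))
    expect_false(anyNA(ft2$protein_seq[ps]))
    ## coordinates, strand and order unchanged
    expect_identical(ft2[, c("start", "end", "strand", "order_index")],
                     ft[, c("start", "end", "strand", "order_index")])
    ## idempotent
    g3 <- substitutePseudogenes(g2, lookup)
    expect_identical(features(g3), features(g2))
    ## unresolvable accession and empty lookup leave the genome unchanged
    expect_identical(features(substitutePseudogenes(g, character())),
                     features(g))
    fx2 <- demoFixture("wadjet")
    gplain <- parseGffFaa(fx2$gff, fx2$faa)
    expect_identical(features(substitutePseudogenes(gplain, lookup)),
                     features(gplain))
})

test_that("gene calling switches mode on the 100 kb threshold", {
    d <- file.path(tempdir(), "calling")
    dir.create(d, showWarnings = FALSE)
    modes <- character()
    stub <- function(fna, gff_out, faa_out, mode) {
        modes <<- c(modes, mode)
        p <- vapply(1:5, function(i) randomProtein(40), character(1))
        writeLines(c("##gff-version  3",
            "# Model Data: version=Prodigal.v2.6.3",
            sprintf("ctgZ\tProdigal_v2.6.3\tCDS\t%d\t%d\t1.0\t+\t0\tID=1_%d",
                    (1:5) * 200L, (1:5) * 200L + 122L, 1:5)), gff_out)
        writeLines(paste0(">ctgZ_", 1:5, "\n", p), faa_out)
    }
    big <- file.path(d, "big.fna")
    writeLines(c(">ctgZ", strrep("ACGT", 37501)), big)   # 150004 nt
    g <- callGenes(big, file.path(d, "big_out"), caller = stub)
    expect_identical(attr(g, "calling_mode"), "single")
    small <- file.path(d, "small.fna")
    writeLines(c(">ctgZ", strrep("ACGT", 5000)), small)  # 20 kb plasmid
    g2 <- callGenes(small, file.path(d, "small_out"), caller = stub)
    expect_identical(attr(g2, "calling_mode"), "meta")
    expect_identical(modes, c("single", "meta"))
    ## stub output flows through the Prodigal parser unchanged
    expect_identical(nrow(features(g2)), 5L)
    expect_error(callGenes(small, caller = "no_such_caller_xyz"),
                 "pre-annotated")
})
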