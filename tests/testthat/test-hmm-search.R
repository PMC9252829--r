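domtblLine <- function(target, hmm, acc, tlen = 200, qlen = 200,
                       fe = 1e-20, ie = fe, score = 150,
                       hfrom = 1, hto = 180, tfrom = 1, tto = 180) {
    paste(target, "-", tlen, hmm, acc, qlen, sprintf("%g", fe), score,
          "0.0", 1, 1, sprintf("%g", ie / 10), sprintf("%g", ie), score,
          "0.0", hfrom, hto, tfrom, tto, tfrom, tto, "0.95", "-")
}

test_that("domtbl parsing yields one reduced hit per target/HMM pair", {
    f <- tempfile()
    writeLines(c("# comment", "",
                 domtblLine("g1", "DrmA_seed", "PLDC00001"),
                 domtblLine("g2", "DrmB_seed", "PLDC00003"),
                 domtblLine("g3", "DrmC_seed", "PLDC00004")), f)
    hits <- parseDomtbl(f)
    expect_identical(nrow(hits), 3L)
    expect_identical(hits$target_name, c("g1", "g2", "g3"))
    ## coverage derives from alignment span over full length
    expect_equal(hits$target_coverage, rep(180 / 200, 3))
    expect_equal(hits$hmm_coverage, rep(180 / 200, 3))
})

test_that("the best domain per pair is kept (min iE-value, max bit score)", {
    ## brute-force expectation: min over the two domain iE-values
    f <- tempfile()
    writeLines(c(domtblLine("g1", "X_seed", "PLDCX", ie = 1e-3, score = 20),
                 domtblLine("g1", "X_seed", "PLDCX", ie = 1e-8,
                            score = 90, tfrom = 11, tto = 150)), f)
    hits <- parseDomtbl(f)
    expect_identical(nrow(hits), 1L)
    expect_equal(hits$domain_ievalue, 1e-8)
    expect_equal(hits$bit_score, 90)
    expect_equal(hits$target_coverage, 140 / 200)
    ## header-only file
    f2 <- tempfile()
    writeLines("# only comments", f2)
    expect_identical(nrow(parseDomtbl(f2)), 0L)
    ## malformed row carries the line number
    f3 <- tempfile()
    writeLines(c(domtblLine("ok", "X", "PX"), "too few fields"), f3)
    expect_error(parseDomtbl(f3), "line 2")
})

test_that("filtering enforces E-value ceilings and coverage floors", {
    meta <- data.frame(accession = c("PA", "PB", "PC"),
                       original_name = c("a", "b", "c"),
                       protein_family = c("FamA", "FamB", "FamC"),
                       evalue_max = c(NA, NA, 1e-10),
                       target_cov_min = NA_real_, hmm_cov_min = NA_real_,
                       citation = "t", stringsAsFactors = FALSE)
    defaults <- filterThresholds(1e-5, 0.4, 0.4)
    hits <- rbind(
        hitRow("g1", "FamA", ievalue = 1e-28, evalue = 1e-30,
               accession = "PA", tcov = 0.95, hcov = 0.90),  # retained
        hitRow("g2", "FamA", ievalue = 1e-20, accession = "PA",
               tcov = 0.95, hcov = 0.2),                     # low hmm cov
        hitRow("g3", "FamB", ievalue = 1e-3, accession = "PB"),  # big iE
        hitRow("g4", "FamC", ievalue = 1e-7, accession = "PC"),
        # per-HMM ceiling 1e-10 overrides the 1e-5 default -> removed
        hitRow("g5", "FamC", ievalue = 1e-12, accession = "PC"),
        hitRow("g6", "FamB", ievalue = 1e-9, accession = "PB",
               tcov = 0.39))                                 # low target cov
    out <- filterHits(hits, meta, defaults)
    expect_identical(out$target_name, c("g1", "g5"))
    ## brute-force re-evaluation of the predicate over the toy table
    eff_ceiling <- ifelse(hits$hmm_accession == "PC", 1e-10, 1e-5)
    manual <- hits$full_seq_evalue <= eff_ceiling &
        hits$domain_ievalue <= eff_ceiling &
        hits$target_coverage >= 0.4 & hits$hmm_coverage >= 0.4
    expect_identical(out$target_name, hits$target_name[manual])
})

test_that("filtering is a monotone, order-preserving subset operation", {
    meta <- toyMeta()
    fx <- demoFixture("disarm_reclass")
    hits <- parseDomtbl(fx$domtbl)
    loose <- filterHits(hits, meta, filterThresholds(1e-3, 0.2, 0.2))
    tight <- filterHits(hits, meta, filterThresholds(1e-8, 0.5, 0.5))
    ## subset of the input, order preserved
    expect_true(all(loose$target_name %in% hits$target_name))
    key <- function(h) paste(h$target_name, h$hmm_accession)
    expect_identical(key(loose),
                     key(hits)[key(hits) %in% key(loose)])
    ## tightening never grows the retained set
    expect_true(all(key(tight) %in% key(loose)))
    ## no retained hit violates its effective thresholds
    for (thr in list(filterThresholds(), filterThresholds(1e-12, 0.6, 0.6))) {
        kept <- filterHits(hits, meta, thr)
        expect_true(all(kept$full_seq_evalue <= thr$evalue_max))
        expect_true(all(kept$domain_ievalue <= thr$evalue_max))
        expect_true(all(kept$target_coverage >= thr$target_cov_min))
        expect_true(all(kept$hmm_coverage >= thr$hmm_cov_min))
    }
    ## unknown accessions are dropped with a warning
    strong <- filterHits(hits, meta)[1, ]
    rogue <- rbind(strong, strong)
    rogue$hmm_accession[2] <- "PLDC99999"
    expect_warning(out <- filterHits(rogue, meta), "PLDC99999")
    expect_identical(nrow(out), 1L)
})

test_that("in-process search finds planted family members strongly", {
    fx <- demoFixture("wadjet")
    g <- parseGffFaa(fx$gff, fx$faa)
    hits <- searchProteins(g, toyDbDir())
    expect_gt(nrow(hits), 0L)
    ## every planted Jet gene is recovered below 1e-10
    truth_tags <- strsplit(fx$truth$locus_tags[
        fx$truth$model == "wadjet_I"], ";")[[1]]
    planted <- hits[hits$target_name %in% truth_tags, ]
    expect_identical(length(unique(planted$target_name)), 4L)
    expect_true(all(planted$full_seq_evalue < 1e-10))
    ## decoy-only genome: any chance hits fail downstream filtering
    fx0 <- demoFixture("decoy_only")
    g0 <- parseGffFaa(fx0$gff, fx0$faa)
    hits0 <- filterHits(searchProteins(g0, toyDbDir()), toyMeta())
    expect_identical(nrow(hits0), 0L)
    ## an empty genome yields an empty hit list, not an error
    empty <- Genome("none", data.frame(contig = "c", length = 10L))
    expect_identical(nrow(searchProteins(empty, toyDbDir())), 0L)
})
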