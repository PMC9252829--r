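disarmModels <- function() toyModels()[c("DISARM_I", "DISARM_II",
                                         "DISARM_other")]

labelledCase <- function(n, assignments, ...) {
    ## assignments: named list locus index -> families
    g <- barGenome(n)
    tags <- features(g)$locus_tag
    rows <- list()
    for (i in names(assignments))
        for (fam in assignments[[i]])
            rows[[length(rows) + 1L]] <- hitRow(tags[[as.integer(i)]],
                                                fam, ...)
    hits <- do.call(rbind, rows)
    list(genome = g, hits = hits, tags = tags)
}

test_that("label assignment keeps the best hit per feature and family", {
    g <- barGenome(3)
    hits <- rbind(
        hitRow("g001", "DrmA", ievalue = 1e-4, bits = 40,
               accession = "PLDC00001"),
        hitRow("g001", "DrmA", ievalue = 1e-9, bits = 80,
               accession = "PLDC00002"),
        ## one gene may be labelled with several distinct families
        hitRow("g002", "DrmC", ievalue = 1e-12),
        hitRow("g002", "PtuA", ievalue = 1e-6))
    lab <- assignLabels(g, hits)
    drma <- lab$labels[lab$labels$family == "DrmA", ]
    expect_identical(nrow(drma), 1L)
    expect_equal(drma$domain_ievalue, 1e-9)
    expect_identical(drma$hmm_accession, "PLDC00002")
    ## input order must not matter
    lab2 <- assignLabels(g, hits[rev(seq_len(nrow(hits))), ])
    expect_identical(lab$labels, lab2$labels)
    expect_setequal(lab$labels$family[lab$labels$locus_tag == "g002"],
                    c("DrmC", "PtuA"))
    ## unlabelled features are carried through for gap counting
    expect_identical(nrow(lab$features), 3L)
    ## a hit on an unknown gene is an error
    expect_error(assignLabels(g, hitRow("ghost", "DrmA")), "ghost")
})

test_that("runs split where intervening unlabelled genes exceed the limit", {
    model1 <- SystemModel("t_I", core = c("A", "B", "C"),
                          minimum_core = 2, maximum_separation = 1)
    case <- labelledCase(16, list(`11` = "A", `12` = "B", `14` = "C"))
    lab <- assignLabels(case$genome, case$hits)
    ## ranks 10,11,13 (0-based) with one irrelevant gene at 12, sep 1
    runs <- findRuns(lab, model1)
    expect_length(runs, 1L)
    expect_identical(lab$features$locus_tag[runs[[1]]],
                     case$tags[c(11L, 12L, 14L)])
    ## gap of 4 intervening genes splits under separation 3
    model3 <- SystemModel("t_I", core = c("A", "B"), minimum_core = 1,
                          maximum_separation = 3)
    case2 <- labelledCase(20, list(`11` = "A", `16` = "B"))
    runs2 <- findRuns(assignLabels(case2$genome, case2$hits), model3)
    expect_length(runs2, 2L)
    ## a single relevant feature is a run of size one
    case3 <- labelledCase(5, list(`3` = "A"))
    runs3 <- findRuns(assignLabels(case3$genome, case3$hits), model3)
    expect_length(runs3, 1L)
    expect_length(runs3[[1]], 1L)
})

test_that("run evaluation applies prohibition before quorum", {
    disarm1 <- toyModels()[["DISARM_I"]]
    full <- labelledCase(7, list(`2` = "DrmA", `3` = "DrmB", `4` = "DrmC",
                                 `5` = "DrmD", `6` = "DrmMI"))
    lab <- assignLabels(full$genome, full$hits)
    run <- findRuns(lab, disarm1)[[1]]
    call <- evaluateRun(run, lab, disarm1)
    expect_s4_class(call, "SystemCall")
    expect_identical(nrow(members(call)), 5L)
    expect_true(all(members(call)$role == "core"))
    ## the same operon plus drmE is rejected as prohibited
    plus_e <- labelledCase(8, list(`2` = "DrmA", `3` = "DrmB", `4` = "DrmC",
                                   `5` = "DrmD", `6` = "DrmMI",
                                   `7` = "DrmE"))
    lab_e <- assignLabels(plus_e$genome, plus_e$hits)
    res <- evaluateRun(findRuns(lab_e, disarm1)[[1]], lab_e, disarm1)
    expect_false(res$accepted)
    expect_identical(res$reason, "prohibited")
    ## a missing core gene fails the quorum
    partial <- labelledCase(6, list(`2` = "DrmA", `3` = "DrmB",
                                    `4` = "DrmC", `5` = "DrmMI"))
    lab_p <- assignLabels(partial$genome, partial$hits)
    res_p <- evaluateRun(findRuns(lab_p, disarm1)[[1]], lab_p, disarm1)
    expect_false(res_p$accepted)
    expect_identical(res_p$reason, "quorum")
})

test_that("duplicated members of one family count once toward quorum", {
    m <- SystemModel("dup_I", core = c("A", "B"), minimum_core = 2,
                     minimum_total = 2)
    case <- labelledCase(4, list(`1` = "A", `2` = "A", `3` = "A"))
    lab <- assignLabels(case$genome, case$hits)
    res <- evaluateRun(findRuns(lab, m)[[1]], lab, m)
    expect_false(res$accepted)   # three copies of A are still one family
    case2 <- labelledCase(4, list(`1` = "A", `2` = "A", `3` = "B"))
    lab2 <- assignLabels(case2$genome, case2$hits)
    call <- evaluateRun(findRuns(lab2, m)[[1]], lab2, m)
    expect_s4_class(call, "SystemCall")
    ## all three genes are reported even though A counts once
    expect_identical(nrow(members(call)), 3L)
})

test_that("a drmE-containing DISARM locus reclassifies as type II", {
    fx <- demoFixture("disarm_reclass")
    calls <- detectFixture(fx, substitute = FALSE, noncoding = FALSE)
    named <- vapply(calls, modelName, character(1))
    expect_identical(sum(named == "DISARM_I"), 0L)
    expect_identical(sum(named == "DISARM_II"), 1L)
    ii <- calls[[which(named == "DISARM_II")]]
    expect_setequal(members(ii)$family,
                    c("DrmA", "DrmB", "DrmC", "DrmE", "DrmMII"))
})

test_that("pseudogene rescue recovers the canonical Wadjet call", {
    fx <- demoFixture("wadjet_pseudo")
    before <- detectFixture(fx, substitute = FALSE, noncoding = FALSE)
    expect_identical(callSignatures(before),
                     truthSignatures(fx$truth, "pre_substitution"))
    expect_false(any(vapply(before, modelName, "") == "wadjet_I"))
    after <- detectFixture(fx, substitute = TRUE, noncoding = FALSE)
    expect_identical(callSignatures(after), truthSignatures(fx$truth))
    wj <- after[[which(vapply(after, modelName, "") == "wadjet_I")]]
    expect_identical(sum(members(wj)$pseudo_substituted), 1L)
    expect_identical(length(unique(members(wj)$family)), 4L)
})

test_that("systems split across contigs surface as _other fragments", {
    fx <- demoFixture("split_wadjet")
    calls <- detectFixture(fx, substitute = FALSE, noncoding = FALSE)
    named <- vapply(calls, modelName, character(1))
    expect_identical(sum(named == "wadjet_I"), 0L)
    expect_identical(sum(named == "wadjet_other"), 2L)
    expect_identical(length(unique(vapply(calls, function(x) x@contig,
                                          character(1)))), 2L)
})

test_that("engine agrees with the brute-force oracle on random contigs", {
    models <- list(
        SystemModel("alpha_I", core = c("A", "B", "C"), prohibited = "X",
                    minimum_core = 3, maximum_separation = 2),
        SystemModel("alpha_other", core = c("A", "B", "C"),
                    minimum_core = 2, minimum_total = 2,
                    maximum_separation = 2, family = "alpha"),
        SystemModel("beta_I", core = c("D", "E"), accessory = "F",
                    minimum_core = 2, minimum_total = 2,
                    maximum_separation = 4))
    fams <- c("A", "B", "C", "D", "E", "F", "X")
    set.seed(202)
    for (i in 1:60) {
        case <- randomCase(sample(5:30, 1), fams)
        engine <- detectSystems(case$genome, case$hits, models, NULL)
        lab <- data.frame(locus_tag = case$hits$target_name,
                          family = case$hits$protein_family,
                          ievalue = case$hits$domain_ievalue,
                          stringsAsFactors = FALSE)
        oracle <- oracleDetect(features(case$genome), lab, models)
        expect_identical(callSignatures(engine), oracle)
    }
})

test_that("calls are local, monotone under member deletion, deterministic", {
    m <- SystemModel("loc_I", core = c("A", "B", "C"), minimum_core = 3,
                     maximum_separation = 2)
    case <- labelledCase(20, list(`3` = "A", `4` = "B", `5` = "C"))
    base <- detectSystems(case$genome, case$hits, list(m), NULL)
    expect_length(base, 1L)
    ## appending a far-away labelled feature changes no existing call
    far <- rbind(case$hits, hitRow("g015", "A"))
    with_far <- detectSystems(case$genome, far, list(m), NULL)
    expect_identical(callSignatures(with_far)[1], callSignatures(base)[1])
    ## deleting any core member of a minimal call removes the call
    for (drop_tag in c("g003", "g004", "g005")) {
        fewer <- case$hits[case$hits$target_name != drop_tag, ]
        expect_length(detectSystems(case$genome, fewer, list(m), NULL), 0L)
    }
    ## identical inputs give byte-identical ordered output
    a <- detectSystems(case$genome, case$hits, list(m), NULL)
    b <- detectSystems(case$genome, case$hits, list(m), NULL)
    expect_identical(lapply(a, members), lapply(b, members))
    ## accepted calls satisfy their model invariants, re-checked directly
    mem <- members(base[[1]])
    expect_gte(length(unique(mem$family[mem$role == "core"])), 3L)
    expect_true(all(diff(sort(mem$start)) >= 0))
})
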