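## Detection engine: label features from filtered HMM hits, build
## colocalized candidate runs per model, and evaluate quorum and
## prohibition rules.  Pure computation, no I/O.

#' Assign family labels to genome features from filtered hits
#'
#' Joins filtered profile-HMM hits onto the genome's features.  Per
#' (feature, family) only the best hit is kept: lowest domain independent
#' E-value, ties broken by bit score (descending) then accession
#' (ascending).  A feature may carry labels for several distinct families
#' (overlapping classifications are resolved downstream by the user, not
#' silently).  Non-coding features (ncRNAs, CRISPR arrays) carry exactly
#' their fixed token as a pre-assigned label.  Unlabelled features are
#' carried through — they matter for separation (gap) counting.
#'
#' @param genome a \linkS4class{Genome}.
#' @param hits filtered hit data.frame (from \code{\link{filterHits}};
#'   \code{protein_family} must be filled).
#' @param meta HMM metadata (used to fill \code{protein_family} if a caller
#'   passed hits that still lack it).
#' @return an object of class \code{"LabelledFeatures"}: list with
#'   \code{features} (the ordered feature table) and \code{labels}
#'   (data.frame: \code{locus_tag}, \code{family}, \code{provenance},
#'   evidence columns).
#' @export
assignLabels <- function(genome, hits, meta = NULL) {
    ft <- features(genome)
    if (nrow(hits)) {
        unknown <- setdiff(unique(hits$target_name), ft$locus_tag)
        if (length(unknown))
            stop("hit(s) reference unknown locus_tag(s): ",
                 paste(unknown, collapse = ", "))
        if (all(is.na(hits$protein_family)) && !is.null(meta))
            hits$protein_family <-
                meta$protein_family[match(hits$hmm_accession,
                                          meta$accession)]
        if (anyNA(hits$protein_family))
            stop("hits must carry protein_family (filter them first)")
        ord <- order(hits$target_name, hits$protein_family,
                     hits$domain_ievalue, -hits$bit_score,
                     hits$hmm_accession)
        hits <- hits[ord, , drop = FALSE]
        best <- hits[!duplicated(hits[, c("target_name",
                                          "protein_family")]), ,
                     drop = FALSE]
        hmm_labels <- data.frame(
            locus_tag = best$target_name,
            family = best$protein_family,
            provenance = "hmm",
            hmm_accession = best$hmm_accession,
            hmm_name = best$hmm_name,
            full_seq_evalue = best$full_seq_evalue,
            domain_ievalue = best$domain_ievalue,
            target_coverage = best$target_coverage,
            hmm_coverage = best$hmm_coverage,
            stringsAsFactors = FALSE)
    } else {
        hmm_labels <- NULL
    }
    nc <- ft[!is.na(ft$family_token), , drop = FALSE]
    nc_labels <- if (nrow(nc)) data.frame(
        locus_tag = nc$locus_tag, family = nc$family_token,
        provenance = "noncoding", hmm_accession = NA_character_,
        hmm_name = NA_character_, full_seq_evalue = NA_real_,
        domain_ievalue = NA_real_, target_coverage = NA_real_,
        hmm_coverage = NA_real_, stringsAsFactors = FALSE) else NULL
    labels <- rbind(hmm_labels, nc_labels)
    if (is.null(labels))
        labels <- data.frame(locus_tag = character(), family = character(),
                             provenance = character(),
                             hmm_accession = character(),
                             hmm_name = character(),
                             full_seq_evalue = numeric(),
                             domain_ievalue = numeric(),
                             target_coverage = numeric(),
                             hmm_coverage = numeric(),
                             stringsAsFactors = FALSE)
    rownames(labels) <- NULL
    structure(list(features = ft, labels = labels),
              class = "LabelledFeatures")
}

#' Find colocalized candidate runs for one model
#'
#' A run is a maximal ordered set of features carrying any of the model's
#' core, accessory or prohibited families in which consecutive members are
#' separated by at most \code{maximumSeparation} intervening features that
#' carry none of those families.  Separation is counted in annotated genes
#' (features), not base pairs.  Runs never span contig boundaries.
#'
#' @param labelled a \code{"LabelledFeatures"} object from
#'   \code{\link{assignLabels}}.
#' @param model a \linkS4class{SystemModel}.
#' @return list of integer vectors of feature row indices (rows of
#'   \code{labelled$features}), in genome order.
#' @export
findRuns <- function(labelled, model) {
    ft <- labelled$features
    fams <- c(coreFamilies(model), accessoryFamilies(model),
              prohibitedFamilies(model))
    carries <- labelled$features$locus_tag %in%
        labelled$labels$locus_tag[labelled$labels$family %in% fams]
    runs <- list()
    for (ctg in unique(ft$contig)) {
        on_ctg <- which(ft$contig == ctg)
        rel <- on_ctg[carries[on_ctg]]
        if (!length(rel)) next
        ## order_index difference minus one = intervening irrelevant genes
        pos <- ft$order_index[rel]
        gap <- diff(pos) - 1L
        grp <- cumsum(c(0L, gap > model@maximumSeparation))
        runs <- c(runs, unname(split(rel, grp)))
    }
    runs
}

#' Evaluate one candidate run against a model
#'
#' Rejection order follows the decision logic of the system definitions:
#' first prohibition (any run member labelled with a prohibited family
#' rejects the run), then quorum (fewer distinct core families than
#' \code{minimumCore}, or fewer distinct families overall than
#' \code{minimumTotal}).  Within one model each feature contributes exactly
#' one family — its best-scoring among the model's core and accessory
#' families — so duplicated genes of one family count once toward quorum
#' (copy-number invariance) while still being reported as members.
#'
#' @param run integer vector of feature row indices (from
#'   \code{\link{findRuns}}).
#' @param labelled the \code{"LabelledFeatures"} object the run refers to.
#' @param model a \linkS4class{SystemModel}.
#' @return a \linkS4class{SystemCall} (with \code{systemNumber} 0, assigned
#'   later), or a list \code{(accepted = FALSE, reason = "prohibited" |
#'   "quorum")}.
#' @export
evaluateRun <- function(run, labelled, model) {
    ft <- labelled$features[run, , drop = FALSE]
    lab <- labelled$labels[labelled$labels$locus_tag %in% ft$locus_tag, ,
                           drop = FALSE]
    if (any(lab$family %in% prohibitedFamilies(model)))
        return(list(accepted = FALSE, reason = "prohibited"))
    member_fams <- c(coreFamilies(model), accessoryFamilies(model))
    lab <- lab[lab$family %in% member_fams, , drop = FALSE]
    ## best family per feature: non-coding labels rank first (exact token
    ## match, no score), then lowest domain iE-value
    score <- ifelse(lab$provenance == "noncoding", -Inf, lab$domain_ievalue)
    lab <- lab[order(match(lab$locus_tag, ft$locus_tag), score,
                     lab$family), , drop = FALSE]
    chosen <- lab[!duplicated(lab$locus_tag), , drop = FALSE]
    role <- ifelse(chosen$family %in% coreFamilies(model),
                   "core", "accessory")
    n_core <- length(unique(chosen$family[role == "core"]))
    n_total <- length(unique(chosen$family))
    if (n_core < model@minimumCore || n_total < model@minimumTotal)
        return(list(accepted = FALSE, reason = "quorum"))
    fidx <- match(chosen$locus_tag, ft$locus_tag)
    members <- data.frame(
        locus_tag = chosen$locus_tag,
        family = chosen$family,
        role = role,
        hmm_accession = chosen$hmm_accession,
        hmm_name = chosen$hmm_name,
        full_seq_evalue = chosen$full_seq_evalue,
        domain_ievalue = chosen$domain_ievalue,
        target_coverage = chosen$target_coverage,
        hmm_coverage = chosen$hmm_coverage,
        start = ft$start[fidx], end = ft$end[fidx],
        strand = ft$strand[fidx],
        kind = ft$kind[fidx],
        pseudo_substituted = ft$pseudo_substituted[fidx],
        description = ft$description[fidx],
        stringsAsFactors = FALSE)
    members <- members[order(members$start, members$end,
                             members$locus_tag), , drop = FALSE]
    rownames(members) <- NULL
    new("SystemCall", systemNumber = 0L, modelName = modelName(model),
        contig = ft$contig[[1]], members = members,
        start = min(members$start), end = max(members$end))
}

## family grouping of a model name ('_other' and subtype suffixes removed
## only via the model's own family slot, known at detection time)
.callFamily <- function(call, models) {
    m <- models[[modelName(call)]]
    if (!is.null(m)) m@family else sub("_[^_]+$", "", modelName(call))
}

#' Detect defence systems in a genome
#'
#' Runs every system-definition model over the labelled feature table:
#' candidate runs are built per model (\code{\link{findRuns}}), evaluated
#' for prohibition and quorum (\code{\link{evaluateRun}}), and accepted
#' calls are numbered in (contig, span start) order.  Relaxed
#' \code{"_other"} models run alongside the canonical definitions; an
#' \code{"_other"} call is suppressed only when its member set is a subset
#' of an accepted canonical call of the same system family — every other
#' overlap, including cross-family, is reported side by side for the user
#' to resolve.
#'
#' @param genome a \linkS4class{Genome} (with non-coding features already
#'   merged, if any).
#' @param hits filtered hit data.frame (\code{\link{filterHits}}).
#' @param models list of \linkS4class{SystemModel} (\code{\link{loadModels}}).
#' @param meta HMM metadata (\code{\link{loadHmmMeta}}).
#' @return list of \linkS4class{SystemCall}, ordered and numbered.
#' @examples
#' db_dir <- file.path(tempdir(), "toydb2")
#' makeToyDb(db_dir)
#' models <- loadModels(db_dir)
#' meta <- loadHmmMeta(file.path(db_dir, "hmm_meta.txt"))
#' fx <- makeGenome(demoPlans(seed = 7)$disarm_typeI,
#'                  file.path(tempdir(), "fx1"), db_dir)
#' g <- parseGffFaa(fx$gff, fx$faa)
#' hits <- filterHits(parseDomtbl(fx$domtbl), meta)
#' detectSystems(g, hits, models, meta)
#' @export
detectSystems <- function(genome, hits, models, meta) {
    labelled <- assignLabels(genome, hits, meta)
    calls <- list()
    for (model in models) {
        for (run in findRuns(labelled, model)) {
            res <- evaluateRun(run, labelled, model)
            if (is(res, "SystemCall"))
                calls[[length(calls) + 1L]] <- res
        }
    }
    if (!length(calls)) return(list())
    named_models <- stats::setNames(models,
        vapply(models, modelName, character(1)))
    is_other <- vapply(calls, function(x)
        grepl("_other$", modelName(x)), logical(1))
    keep <- rep(TRUE, length(calls))
    for (i in which(is_other)) {
        fam_i <- .callFamily(calls[[i]], named_models)
        mem_i <- members(calls[[i]])$locus_tag
        for (j in which(!is_other)) {
            if (calls[[j]]@contig != calls[[i]]@contig) next
            if (.callFamily(calls[[j]], named_models) != fam_i) next
            if (all(mem_i %in% members(calls[[j]])$locus_tag)) {
                keep[i] <- FALSE
                break
            }
        }
    }
    calls <- calls[keep]
    ctg_rank <- match(vapply(calls, function(x) x@contig, character(1)),
                      genome@contigs$contig)
    ord <- order(ctg_rank,
                 vapply(calls, function(x) x@start, integer(1)),
                 vapply(calls, function(x) x@end, integer(1)),
                 vapply(calls, modelName, character(1)))
    calls <- calls[ord]
    for (i in seq_along(calls)) calls[[i]]@systemNumber <- i
    calls
}
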