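## Independent brute-force oracle for the detection engine: a plain
## re-derivation of run construction, prohibition, quorum and "_other"
## suppression, written against the rule definitions rather than sharing
## any code with the engine.

## labels: data.frame(locus_tag, family, ievalue); features ordered table
oracleDetect <- function(features, labels, models) {
    accepted <- list()
    for (model in models) {
        fams <- c(coreFamilies(model), accessoryFamilies(model),
                  prohibitedFamilies(model))
        sep <- model@maximumSeparation
        for (ctg in unique(features$contig)) {
            ft <- features[features$contig == ctg, , drop = FALSE]
            ft <- ft[order(ft$start, ft$end, ft$locus_tag), , drop = FALSE]
            relevant <- vapply(ft$locus_tag, function(lt)
                any(labels$family[labels$locus_tag == lt] %in% fams),
                logical(1))
            ## walk features, accumulating runs split at long gaps
            runs <- list(); current <- integer(); gap <- 0L
            for (i in seq_len(nrow(ft))) {
                if (relevant[[i]]) {
                    if (length(current) && gap > sep) {
                        runs[[length(runs) + 1L]] <- current
                        current <- integer()
                    }
                    current <- c(current, i); gap <- 0L
                } else if (length(current)) gap <- gap + 1L
            }
            if (length(current)) runs[[length(runs) + 1L]] <- current
            for (run in runs) {
                tags <- ft$locus_tag[run]
                lab <- labels[labels$locus_tag %in% tags, , drop = FALSE]
                if (any(lab$family %in% prohibitedFamilies(model))) next
                member_fams <- c(coreFamilies(model),
                                 accessoryFamilies(model))
                chosen <- vapply(tags, function(lt) {
                    sub <- lab[lab$locus_tag == lt &
                               lab$family %in% member_fams, , drop = FALSE]
                    if (!nrow(sub)) return(NA_character_)
                    sub <- sub[order(sub$ievalue, sub$family), ,
                               drop = FALSE]
                    sub$family[[1]]
                }, character(1))
                mem <- tags[!is.na(chosen)]
                chosen <- chosen[!is.na(chosen)]
                if (length(unique(chosen[chosen %in%
                        coreFamilies(model)])) < model@minimumCore) next
                if (length(unique(chosen)) < model@minimumTotal) next
                accepted[[length(accepted) + 1L]] <- list(
                    model = modelName(model),
                    family = model@family,
                    contig = ctg, members = sort(mem))
            }
        }
    }
    ## suppress an _other call whose member set is a subset of a canonical
    ## call of the same family
    is_other <- vapply(accepted, function(a)
        grepl("_other$", a$model), logical(1))
    keep <- rep(TRUE, length(accepted))
    for (i in which(is_other)) for (j in which(!is_other)) {
        if (accepted[[i]]$contig == accepted[[j]]$contig &&
            accepted[[i]]$family == accepted[[j]]$family &&
            all(accepted[[i]]$members %in% accepted[[j]]$members)) {
            keep[i] <- FALSE; break
        }
    }
    accepted <- accepted[keep]
    sort(vapply(accepted, function(a)
        paste0(a$model, ":", paste(a$members, collapse = ";")),
        character(1)))
}

## random labelled contig for property tests; returns list(genome, hits)
randomCase <- function(n_features, families, label_prob = 0.35) {
    g <- barGenome(n_features)
    tags <- features(g)$locus_tag
    rows <- list()
    for (lt in tags) {
        for (fam in families) {
            if (stats::runif(1) < label_prob / length(families)) {
                rows[[length(rows) + 1L]] <- hitRow(
                    lt, fam, ievalue = 10^stats::runif(1, -30, -6),
                    bits = round(stats::runif(1, 30, 300), 1))
            }
        }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else hitRow(
        tags[[1]], families[[1]])[0, ]
    list(genome = g, hits = hits)
}
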