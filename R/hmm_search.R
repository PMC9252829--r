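## Profile-HMM search: in-process delegation to HMMER3, parsing of
## per-domain tabular output, and E-value/coverage filtering of hits.

#' Default hit-filtering thresholds
#'
#' Global defaults for filtering profile-HMM hits: an E-value ceiling
#' applied to both the full-sequence E-value and the best domain's
#' independent E-value (the stricter reading), and floors on target and HMM
#' alignment coverage.  Per-HMM thresholds in the database metadata override
#' these; comparisons are inclusive (\code{<=} ceiling, \code{>=} floor).
#'
#' @param evalue_max full-sequence and domain E-value ceiling; default 1e-5.
#' @param target_cov_min minimum aligned fraction of the target protein;
#'   default 0.4.
#' @param hmm_cov_min minimum aligned fraction of the HMM; default 0.4.
#' @return a named list of class \code{"FilterThresholds"}.
#' @export
filterThresholds <- function(evalue_max = 1e-5, target_cov_min = 0.4,
                             hmm_cov_min = 0.4) {
    stopifnot(is.finite(evalue_max), evalue_max >= 0,
              target_cov_min >= 0, target_cov_min <= 1,
              hmm_cov_min >= 0, hmm_cov_min <= 1)
    structure(list(evalue_max = evalue_max,
                   target_cov_min = target_cov_min,
                   hmm_cov_min = hmm_cov_min),
              class = "FilterThresholds")
}

emptyHitTable <- function() {
    data.frame(target_name = character(), hmm_accession = character(),
               hmm_name = character(), protein_family = character(),
               full_seq_evalue = numeric(), domain_ievalue = numeric(),
               bit_score = numeric(), target_len = integer(),
               hmm_len = integer(), ali_target_from = integer(),
               ali_target_to = integer(), ali_hmm_from = integer(),
               ali_hmm_to = integer(), target_coverage = numeric(),
               hmm_coverage = numeric(), stringsAsFactors = FALSE)
}

## Reduce to one row per (target, HMM): best domain by independent E-value,
## ties broken by bit score (desc); final deterministic ordering by target,
## accession.
reduceHits <- function(hits) {
    if (!nrow(hits)) return(hits)
    ord <- order(hits$target_name, hits$hmm_accession,
                 hits$domain_ievalue, -hits$bit_score)
    hits <- hits[ord, , drop = FALSE]
    keep <- !duplicated(hits[, c("target_name", "hmm_accession")])
    hits <- hits[keep, , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Parse HMMER3 per-domain tabular output
#'
#' Reads a \code{--domtblout} file as written by \code{hmmsearch} (targets =
#' proteins, queries = profile HMMs).  Domains are reduced to one hit per
#' (target, HMM) pair — the domain with the lowest independent E-value, ties
#' broken by bit score — and alignment coverages are computed from the
#' alignment columns: \code{target_coverage = aligned target span / target
#' length}, \code{hmm_coverage = aligned HMM span / HMM length}.
#'
#' @param file path to the per-domain tabular file; \code{#} comment lines
#'   are tolerated.
#' @return data.frame of hits, one row per (target, HMM) pair, ordered by
#'   target then accession.
#' @export
parseDomtbl <- function(file) {
    lines <- readLines(file, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (!length(keep)) return(emptyHitTable())
    rows <- lapply(keep, function(i) {
        f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
        if (length(f) < 22L)
            stop("malformed domtbl row at line ", i, " of '", file,
                 "' (", length(f), " fields, expected >= 22)")
        num <- suppressWarnings(as.numeric(
            f[c(3, 6, 7, 13, 14, 16, 17, 18, 19)]))
        if (anyNA(num))
            stop("malformed domtbl row at line ", i, " of '", file,
                 "': non-numeric score/coordinate field")
        data.frame(
            target_name = f[[1]],
            hmm_name = f[[4]],
            hmm_accession = if (f[[5]] == "-") f[[4]] else f[[5]],
            target_len = as.integer(num[[1]]),
            hmm_len = as.integer(num[[2]]),
            full_seq_evalue = num[[3]],
            domain_ievalue = num[[4]],
            bit_score = num[[5]],
            ali_hmm_from = as.integer(num[[6]]),
            ali_hmm_to = as.integer(num[[7]]),
            ali_target_from = as.integer(num[[8]]),
            ali_target_to = as.integer(num[[9]]),
            stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, rows)
    hits$target_coverage <-
        (hits$ali_target_to - hits$ali_target_from + 1) / hits$target_len
    hits$hmm_coverage <-
        (hits$ali_hmm_to - hits$ali_hmm_from + 1) / hits$hmm_len
    hits$protein_family <- NA_character_
    hits <- hits[, names(emptyHitTable())]
    reduceHits(hits)
}

#' Search genome proteins against a profile-HMM database
#'
#' Writes the searchable proteins (CDS and substituted pseudogenes) to a
#' temporary FASTA and runs \code{hmmsearch --domtblout} against the given
#' profile file, then parses and reduces the result with
#' \code{\link{parseDomtbl}}.  The HMM scoring machinery itself is entirely
#' delegated to HMMER.
#'
#' @param genome a \linkS4class{Genome}.
#' @param hmm_db path to a (concatenated) HMMER3 profile file, or a database
#'   directory containing \code{hmm/}.
#' @param hmmsearch path to the \code{hmmsearch} executable.
#' @return hit data.frame as from \code{\link{parseDomtbl}} (empty when the
#'   genome has no searchable proteins).
#' @export
searchProteins <- function(genome, hmm_db, hmmsearch = "hmmsearch") {
    if (dir.exists(hmm_db)) {
        hmms <- list.files(file.path(hmm_db, "hmm"), pattern = "\\.hmm$",
                           full.names = TRUE)
        if (length(hmms) != 1L)
            stop("expected one concatenated .hmm file under ",
                 file.path(hmm_db, "hmm"))
        hmm_db <- hmms
    }
    ft <- features(genome)
    searchable <- ft[!is.na(ft$protein_seq), , drop = FALSE]
    if (!nrow(searchable)) return(emptyHitTable())
    if (!nzchar(Sys.which(hmmsearch)))
        stop("'", hmmsearch, "' not found on PATH; supply precomputed ",
             "per-domain tabular results instead")
    faa <- tempfile(fileext = ".faa")
    on.exit(unlink(faa), add = TRUE)
    aa <- Biostrings::AAStringSet(
        stats::setNames(searchable$protein_seq, searchable$locus_tag))
    Biostrings::writeXStringSet(aa, faa)
    domtbl <- tempfile(fileext = ".domtbl")
    on.exit(unlink(domtbl), add = TRUE)
    status <- system2(hmmsearch,
                      c("--domtblout", domtbl, "--noali", hmm_db, faa),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L)
        stop("hmmsearch failed with status ", status)
    parseDomtbl(domtbl)
}

## Effective thresholds per hit: per-HMM metadata overrides the defaults.
effectiveThresholds <- function(hits, meta, defaults) {
    idx <- match(hits$hmm_accession, meta$accession)
    pick <- function(col, default) {
        v <- meta[[col]][idx]
        ifelse(is.na(v), default, v)
    }
    data.frame(evalue_max = pick("evalue_max", defaults$evalue_max),
               target_cov_min = pick("target_cov_min",
                                     defaults$target_cov_min),
               hmm_cov_min = pick("hmm_cov_min", defaults$hmm_cov_min))
}

#' Filter profile-HMM hits on E-value and coverage
#'
#' Retains a hit iff its full-sequence E-value and best-domain independent
#' E-value are both at or below the effective ceiling AND its target and
#' HMM coverages are at or above the effective floors.  Effective thresholds
#' are the per-HMM values from the database metadata where present,
#' otherwise the supplied defaults.  Hits whose accession is absent from the
#' metadata are dropped with a warning (no family can be assigned to them).
#' The protein family evidenced by each retained hit is joined in from the
#' metadata.  The operation is a pure subset: order is preserved and no
#' fields other than \code{protein_family} change.
#'
#' @param hits hit data.frame from \code{\link{parseDomtbl}} or
#'   \code{\link{searchProteins}}.
#' @param meta HMM metadata from \code{\link{loadHmmMeta}}.
#' @param defaults a \code{\link{filterThresholds}} object.
#' @return the retained subset with \code{protein_family} filled in.
#' @export
filterHits <- function(hits, meta, defaults = filterThresholds()) {
    if (!nrow(hits)) return(hits)
    known <- hits$hmm_accession %in% meta$accession
    if (any(!known))
        warning("dropping ", sum(!known),
                " hit(s) with accession absent from hmm_meta: ",
                paste(unique(hits$hmm_accession[!known]), collapse = ", "),
                call. = FALSE)
    hits <- hits[known, , drop = FALSE]
    if (!nrow(hits)) { rownames(hits) <- NULL; return(hits) }
    eff <- effectiveThresholds(hits, meta, defaults)
    keep <- hits$full_seq_evalue <= eff$evalue_max &
        hits$domain_ievalue <= eff$evalue_max &
        hits$target_coverage >= eff$target_cov_min &
        hits$hmm_coverage >= eff$hmm_cov_min
    hits <- hits[keep, , drop = FALSE]
    hits$protein_family <-
        meta$protein_family[match(hits$hmm_accession, meta$accession)]
    rownames(hits) <- NULL
    hits
}
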