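## Non-coding system components: retron msr-msd ncRNAs from covariance-model
## search (Infernal cmsearch tabular output) and CRISPR arrays from a
## detector's GFF, spliced into the ordered feature table so they count
## toward system quorums like any gene.

#' Default parameters for the external non-coding detectors
#'
#' The parameter set passed through to the wrapped external tools: the
#' CRISPR array detector (CRISPRDetect-style) and the covariance-model
#' search (Infernal \code{cmsearch}).  These are configuration, recorded
#' here so a run log can state the effective settings; the package consumes
#' the tools' output files and never re-implements the detection.
#'
#' @return named list with elements \code{crispr} (array_quality_score_cutoff
#'   2.5, minimum_word_repeatation 3, word_length 11, minimum_no_of_repeats
#'   3, repeat_length_cutoff 11, max_gap_between_crisprs 250) and
#'   \code{cmsearch} (Z 10, FZ 500, evalue_max 0.01).
#' @export
defaultNoncodingParams <- function() {
    list(
        crispr = list(
            array_quality_score_cutoff = 2.5,
            minimum_word_repeatation = 3L,
            word_length = 11L,
            minimum_no_of_repeats = 3L,
            repeat_length_cutoff = 11L,
            max_gap_between_crisprs = 250L),
        cmsearch = list(Z = 10, FZ = 500, evalue_max = 0.01))
}

#' Parse Infernal cmsearch tabular output into ncRNA hits
#'
#' Reads the standard \code{cmsearch --tblout} format and retains only hits
#' passing the inclusion threshold (E-value at or below
#' \code{evalue_max}; the comparison is inclusive, so a hit at exactly the
#' threshold is kept).  Retained hits carry the fixed family token
#' \code{"ncRNA"} and can satisfy any model listing that token.
#'
#' @param file path to the cmsearch tabular output (\code{#} comments
#'   tolerated).
#' @param evalue_max inclusion threshold; default 0.01.
#' @return data.frame with columns \code{contig}, \code{start}, \code{end},
#'   \code{strand}, \code{cm_name}, \code{evalue}, \code{family_token}.
#' @export
parseCmsearch <- function(file, evalue_max = 0.01) {
    lines <- readLines(file, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    empty <- data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        cm_name = character(), evalue = numeric(),
                        family_token = character(),
                        stringsAsFactors = FALSE)
    if (!length(keep)) return(empty)
    rows <- lapply(keep, function(i) {
        f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
        ## tblout: 1 target, 2 t-acc, 3 query(cm), 4 q-acc, 5 mdl,
        ## 6 mdl-from, 7 mdl-to, 8 seq-from, 9 seq-to, 10 strand, 11 trunc,
        ## 12 pass, 13 gc, 14 bias, 15 score, 16 E-value, 17 inc, 18 desc
        if (length(f) < 17L)
            stop("malformed cmsearch row at line ", i, " of '", file, "'")
        sf <- suppressWarnings(as.integer(f[[8]]))
        st <- suppressWarnings(as.integer(f[[9]]))
        ev <- suppressWarnings(as.numeric(f[[16]]))
        if (is.na(sf) || is.na(st) || is.na(ev))
            stop("malformed cmsearch row at line ", i, " of '", file,
                 "': non-numeric coordinate or E-value")
        data.frame(contig = f[[1]],
                   start = min(sf, st), end = max(sf, st),
                   strand = if (f[[10]] == "-") "-" else "+",
                   cm_name = f[[3]], evalue = ev,
                   family_token = "ncRNA", stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, rows)
    hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
    rownames(hits) <- NULL
    hits
}

#' Parse a CRISPR array GFF into array records
#'
#' Accepts a CRISPR detector's GFF and keeps rows whose type denotes a
#' repeat region or array (\code{repeat_region}, \code{CRISPR},
#' \code{binding_site} variants included by some detectors); other rows
#' (e.g. per-repeat children) are skipped with a warning.  The repeat count
#' is taken from a \code{Note}/\code{rpt_unit}-style attribute when present.
#' Arrays carry the fixed family token \code{"CRISPR_array"}.
#'
#' @param file path to the GFF file.
#' @return data.frame with columns \code{contig}, \code{start}, \code{end},
#'   \code{strand}, \code{repeat_count}, \code{family_token}.
#' @export
parseCrisprGff <- function(file) {
    empty <- data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character(),
                        repeat_count = integer(), family_token = character(),
                        stringsAsFactors = FALSE)
    lines <- readLines(file, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) return(empty)
    array_types <- c("repeat_region", "CRISPR", "crispr_array",
                     "direct_repeat_region")
    rows <- list()
    skipped <- 0L
    for (ln in lines) {
        f <- strsplit(ln, "\t")[[1]]
        if (length(f) < 8L) { skipped <- skipped + 1L; next }
        if (!(f[[3]] %in% array_types)) { skipped <- skipped + 1L; next }
        attrs <- if (length(f) >= 9L) f[[9]] else ""
        rc <- NA_integer_
        m <- regmatches(attrs,
            regexec("(?i)(repeats?|rpt_unit[s]?|note)=\"?([0-9]+)",
                    attrs, perl = TRUE))[[1]]
        if (length(m) == 3L) rc <- as.integer(m[[3]])
        rows[[length(rows) + 1L]] <- data.frame(
            contig = f[[1]],
            start = as.integer(f[[4]]), end = as.integer(f[[5]]),
            strand = if (f[[7]] == "-") "-" else "+",
            repeat_count = rc, family_token = "CRISPR_array",
            stringsAsFactors = FALSE)
    }
    if (skipped)
        warning("skipped ", skipped,
                " non-array row(s) in CRISPR GFF", call. = FALSE)
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Splice non-coding components into a genome's feature order
#'
#' Each ncRNA hit and CRISPR array becomes a \code{GeneFeature} of the
#' matching kind, inserted into coordinate order on its contig;
#' \code{order_index} is recomputed for all features.  Non-coding features
#' carry their fixed family token pre-assigned (\code{family_token} column),
#' so they bypass HMM hit filtering entirely and contribute directly to any
#' model listing \code{"ncRNA"} or \code{"CRISPR_array"}.  An ncRNA
#' overlapping a CDS is kept alongside it as a separate ordered feature.
#'
#' @param genome a \linkS4class{Genome}.
#' @param ncrnas data.frame from \code{\link{parseCmsearch}} (or NULL).
#' @param arrays data.frame from \code{\link{parseCrisprGff}} (or NULL).
#' @return the updated \linkS4class{Genome}.
#' @export
mergeNoncoding <- function(genome, ncrnas = NULL, arrays = NULL) {
    addRows <- function(tbl, kind, tag_prefix, desc_fun) {
        if (is.null(tbl) || !nrow(tbl)) return(NULL)
        unknown <- setdiff(unique(tbl$contig), genome@contigs$contig)
        if (length(unknown))
            stop("non-coding features reference unknown contig(s): ",
                 paste(unknown, collapse = ", "))
        data.frame(
            contig = tbl$contig,
            locus_tag = sprintf("%s_%03d", tag_prefix, seq_len(nrow(tbl))),
            start = as.integer(tbl$start), end = as.integer(tbl$end),
            strand = tbl$strand, order_index = NA_integer_,
            kind = kind, protein_seq = NA_character_,
            pseudo_substituted = FALSE,
            inference_accession = NA_character_,
            family_token = tbl$family_token,
            description = desc_fun(tbl),
            stringsAsFactors = FALSE)
    }
    new_rows <- rbind(
        addRows(ncrnas, "ncRNA", paste0(genome@assemblyId, "_ncrna"),
                function(tbl) paste0("ncRNA (", tbl$cm_name, ")")),
        addRows(arrays, "CRISPR_array", paste0(genome@assemblyId, "_crispr"),
                function(tbl) ifelse(is.na(tbl$repeat_count),
                    "CRISPR array",
                    paste0("CRISPR array (", tbl$repeat_count, " repeats)"))))
    if (is.null(new_rows)) return(genome)
    ft <- rbind(genome@features, new_rows[, .FEATURE_COLUMNS])
    genome@features <- orderFeatures(ft, genome@contigs$contig)
    validObject(genome)
    genome
}
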