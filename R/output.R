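## Serialization: per-gene CSV, systems GFF3, and per-genome
## diversity/abundance summaries.

fmtEvalue <- function(x) ifelse(is.na(x), "", sprintf("%.2e", x))
fmtCov <- function(x) ifelse(is.na(x), "", sprintf("%.3f", x))

.CSV_COLUMNS <- c("system.number", "seqid", "system", "target.name",
    "hmm.accession", "hmm.name", "protein.name", "full.seq.E.value",
    "domain.iE.value", "target.coverage", "hmm.coverage", "start", "end",
    "strand", "target.description")

#' Write the per-gene systems CSV
#'
#' The main output: one row per member gene of every accepted system call.
#' Scoring columns carry the evidence behind each member's family label —
#' the full-sequence and domain E-values (\code{full.seq.E.value},
#' \code{domain.iE.value}) and the target and HMM alignment coverages
#' (\code{target.coverage}, \code{hmm.coverage}); large E-values and low
#' coverages warrant caution when interpreting a call.  Members that are
#' substituted pseudogenes carry the \code{pseudo_sub_} prefix on
#' \code{target.name}; non-coding members (ncRNAs, CRISPR arrays) carry
#' their family token as \code{protein.name} with empty score columns.
#' E-values are printed in scientific notation with 3 significant digits
#' and coverages with 3 decimals, so identical runs produce byte-identical
#' files.
#'
#' @param calls list of \linkS4class{SystemCall}.
#' @param genome the \linkS4class{Genome} the calls were made in.
#' @param path output file path.
#' @return number of data rows written (0 for a header-only file).
#' @export
writeSystemsCsv <- function(calls, genome, path) {
    rows <- lapply(calls, function(call) {
        m <- members(call)
        data.frame(
            `system.number` = call@systemNumber,
            seqid = call@contig,
            system = modelName(call),
            `target.name` = ifelse(m$pseudo_substituted,
                                   paste0("pseudo_sub_", m$locus_tag),
                                   m$locus_tag),
            `hmm.accession` = ifelse(is.na(m$hmm_accession), "",
                                     m$hmm_accession),
            `hmm.name` = ifelse(is.na(m$hmm_name), "", m$hmm_name),
            `protein.name` = m$family,
            `full.seq.E.value` = fmtEvalue(m$full_seq_evalue),
            `domain.iE.value` = fmtEvalue(m$domain_ievalue),
            `target.coverage` = fmtCov(m$target_coverage),
            `hmm.coverage` = fmtCov(m$hmm_coverage),
            start = m$start, end = m$end, strand = m$strand,
            `target.description` = ifelse(is.na(m$description), "",
                                          m$description),
            check.names = FALSE, stringsAsFactors = FALSE)
    })
    tbl <- if (length(rows)) do.call(rbind, rows) else
        stats::setNames(data.frame(matrix(nrow = 0, ncol =
            length(.CSV_COLUMNS))), .CSV_COLUMNS)
    utils::write.csv(tbl[, .CSV_COLUMNS], path, row.names = FALSE,
                     quote = TRUE)
    nrow(tbl)
}

#' Read back a systems CSV
#'
#' Inverse of \code{\link{writeSystemsCsv}} for regression checks and
#' downstream tabulation.
#'
#' @param path CSV file path.
#' @return data.frame with the columns written by
#'   \code{\link{writeSystemsCsv}}.
#' @export
readSystemsCsv <- function(path) {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Write the systems GFF3
#'
#' One parent row per system (its span) plus one child row per member gene,
#' with coordinates identical to the input annotation.
#'
#' @param calls list of \linkS4class{SystemCall}.
#' @param genome the source \linkS4class{Genome}.
#' @param path output file path.
#' @return number of feature rows written (parents + children).
#' @export
writeSystemsGff <- function(calls, genome, path) {
    lines <- c("##gff-version 3")
    for (i in seq_len(nrow(genome@contigs)))
        lines <- c(lines, sprintf("##sequence-region %s 1 %d",
                                  genome@contigs$contig[[i]],
                                  genome@contigs$length[[i]]))
    n <- 0L
    for (call in calls) {
        sys_id <- sprintf("system_%d", call@systemNumber)
        lines <- c(lines, paste(
            call@contig, "defloc", "defence_system",
            call@start, call@end, ".", ".", ".",
            sprintf("ID=%s;Name=%s", sys_id, modelName(call)),
            sep = "\t"))
        m <- members(call)
        child_type <- ifelse(m$kind == "CRISPR_array", "repeat_region",
                             m$kind)
        for (k in seq_len(nrow(m))) {
            lines <- c(lines, paste(
                call@contig, "defloc", child_type[[k]],
                m$start[[k]], m$end[[k]], ".", m$strand[[k]], ".",
                sprintf("ID=%s.%d;Parent=%s;Name=%s;protein_name=%s",
                        sys_id, k, sys_id, m$locus_tag[[k]], m$family[[k]]),
                sep = "\t"))
        }
        n <- n + 1L + nrow(m)
    }
    writeLines(lines, path)
    n
}

#' Summarize per-genome defence-system diversity and abundance
#'
#' Diversity is the number of unique types of defence systems within a host
#' genome; abundance is the total number of defence systems.  The type of a
#' canonical call is its model name; for a relaxed \code{"_other"} call the
#' \code{"_other"} suffix is a confidence marker rather than a type, so its
#' system family (name without the suffix) defines the type.  Summaries are
#' invariant under permutation of the call list.
#'
#' @param calls_by_genome named list: assembly id -> list of
#'   \linkS4class{SystemCall}.
#' @return data.frame with columns \code{assembly_id}, \code{diversity},
#'   \code{abundance} and a list-column \code{per_type_counts} (named
#'   integer vector per genome).
#' @export
summarizeSystems <- function(calls_by_genome) {
    rows <- lapply(names(calls_by_genome), function(aid) {
        calls <- calls_by_genome[[aid]]
        types <- vapply(calls, function(x)
            sub("_other$", "", modelName(x)), character(1))
        counts <- if (length(types)) {
            tab <- table(types)
            stats::setNames(as.integer(tab), names(tab))[
                order(names(tab))]
        } else stats::setNames(integer(), character())
        data.frame(assembly_id = aid,
                   diversity = length(counts),
                   abundance = length(calls),
                   per_type_counts = I(list(counts)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(data.frame(
        assembly_id = character(), diversity = integer(),
        abundance = integer(), per_type_counts = I(list()),
        stringsAsFactors = FALSE))))
    rownames(out) <- NULL
    out
}
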