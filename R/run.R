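## End-to-end pipeline: wire input parsing, hit filtering, non-coding
## merging and the detection engine together, and write the output set.
## The command line front end (inst/scripts/defloc.R) is a thin wrapper
## around runDefloc().

#' Run the full defence-system detection pipeline
#'
#' Executes detection on one genome: load the model database, parse the
#' annotation (GFF3+FASTA pair, GenBank flat file, or unannotated
#' nucleotide FASTA handed to the external gene caller), optionally
#' substitute pseudogene products, obtain profile-HMM hits (from a
#' precomputed per-domain table or by running \code{hmmsearch} in-process),
#' filter them, splice in CRISPR arrays and ncRNA hits, evaluate every
#' system model, and write \code{defence_systems.csv},
#' \code{defence_systems.gff}, \code{genome_summary.tsv} and a run log
#' stating the effective configuration (a run is reproducible from its
#' log).
#'
#' @param gff,faa paired GFF3 + amino-acid FASTA input.
#' @param gbk GenBank flat file input (alternative to \code{gff}/\code{faa}).
#' @param fna unannotated nucleotide FASTA input (gene calling is delegated
#'   to an external caller).
#' @param data model database directory (see \code{\link{loadModels}}).
#' @param crispr optional CRISPR array GFF (\code{\link{parseCrisprGff}}).
#' @param ncrna optional cmsearch tabular file (\code{\link{parseCmsearch}}).
#' @param domtbl optional precomputed HMMER3 per-domain tabular file; when
#'   absent, proteins are searched in-process against the database HMMs.
#' @param pseudo_proteins optional FASTA of inferred full-length proteins
#'   keyed by accession, used for pseudogene substitution.
#' @param fix_prodigal force the Prodigal identifier fix-up for the
#'   GFF/FASTA pair (otherwise the dialect is sniffed).
#' @param evalue,target_cov,hmm_cov global filtering thresholds
#'   (\code{\link{filterThresholds}} defaults).
#' @param max_separation global default for models that do not set their
#'   own colocalization limit.
#' @param ncrna_evalue inclusion threshold for ncRNA hits; default 0.01.
#' @param out_dir output directory (created if needed).
#' @return invisibly, list with \code{calls}, \code{genome},
#'   \code{summary}, \code{n_csv_rows} and the output \code{paths}.
#' @export
runDefloc <- function(gff = NULL, faa = NULL, gbk = NULL, fna = NULL,
                      data, crispr = NULL, ncrna = NULL, domtbl = NULL,
                      pseudo_proteins = NULL, fix_prodigal = FALSE,
                      evalue = 1e-5, target_cov = 0.4, hmm_cov = 0.4,
                      max_separation = 4L, ncrna_evalue = 0.01,
                      out_dir = ".") {
    modes <- c(gfffaa = !is.null(gff) && !is.null(faa),
               gbk = !is.null(gbk), fna = !is.null(fna))
    if (sum(modes) != 1L)
        stop("exactly one input mode required: --gff/--faa, --gbk or --fna")
    for (p in c(gff, faa, gbk, fna, crispr, ncrna, domtbl, pseudo_proteins))
        if (!file.exists(p)) stop("input file not found: ", p)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    models <- loadModels(data, default_separation = max_separation)
    meta <- loadHmmMeta(file.path(data, "hmm_meta.txt"))
    genome <- if (modes[["gfffaa"]]) {
        dialect <- if (fix_prodigal) "prodigal_gff_faa" else
            detectDialect(c(gff, faa))
        parseGffFaa(gff, faa, dialect = dialect)
    } else if (modes[["gbk"]]) {
        parseGenbank(gbk)
    } else {
        callGenes(fna)
    }
    if (!is.null(pseudo_proteins))
        genome <- substitutePseudogenes(
            genome, Biostrings::readAAStringSet(pseudo_proteins))
    thresholds <- filterThresholds(evalue, target_cov, hmm_cov)
    raw_hits <- if (!is.null(domtbl)) parseDomtbl(domtbl) else
        searchProteins(genome, data)
    hits <- filterHits(raw_hits, meta, thresholds)
    ncrnas <- if (!is.null(ncrna))
        parseCmsearch(ncrna, evalue_max = ncrna_evalue) else NULL
    arrays <- if (!is.null(crispr)) parseCrisprGff(crispr) else NULL
    genome <- mergeNoncoding(genome, ncrnas, arrays)
    calls <- detectSystems(genome, hits, models, meta)
    paths <- list(csv = file.path(out_dir, "defence_systems.csv"),
                  gff = file.path(out_dir, "defence_systems.gff"),
                  summary = file.path(out_dir, "genome_summary.tsv"),
                  log = file.path(out_dir, "run.log"))
    n_csv <- writeSystemsCsv(calls, genome, paths$csv)
    writeSystemsGff(calls, genome, paths$gff)
    summary <- summarizeSystems(
        stats::setNames(list(calls), assemblyId(genome)))
    per_type <- vapply(summary$per_type_counts, function(x)
        paste(sprintf("%s=%d", names(x), x), collapse = ";"), character(1))
    utils::write.table(
        data.frame(assembly_id = summary$assembly_id,
                   diversity = summary$diversity,
                   abundance = summary$abundance,
                   per_type = per_type, stringsAsFactors = FALSE),
        paths$summary, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(
        sprintf("defloc %s", as.character(utils::packageVersion("defloc"))),
        sprintf("database: %s (%d models, %d HMM meta rows)",
                normalizePath(data), length(models), nrow(meta)),
        sprintf("input: %s",
                paste(normalizePath(c(gff, faa, gbk, fna)),
                      collapse = " + ")),
        sprintf("crispr: %s", if (is.null(crispr)) "-" else
                normalizePath(crispr)),
        sprintf("ncrna: %s (inclusion E <= %g)",
                if (is.null(ncrna)) "-" else normalizePath(ncrna),
                ncrna_evalue),
        sprintf("hits: %s", if (is.null(domtbl)) "in-process hmmsearch"
                else normalizePath(domtbl)),
        sprintf("pseudogene substitution: %s",
                if (is.null(pseudo_proteins)) "off" else
                normalizePath(pseudo_proteins)),
        sprintf("thresholds: evalue_max=%g target_cov_min=%g hmm_cov_min=%g",
                thresholds$evalue_max, thresholds$target_cov_min,
                thresholds$hmm_cov_min),
        sprintf("default max_separation: %d", as.integer(max_separation)),
        sprintf("raw hits: %d; retained after filtering: %d",
                nrow(raw_hits), nrow(hits)),
        sprintf("systems called: %d (diversity %d)", length(calls),
                summary$diversity[[1]]),
        sprintf("csv rows: %d", n_csv)),
        paths$log)
    invisible(list(calls = calls, genome = genome, summary = summary,
                   n_csv_rows = n_csv, paths = paths))
}
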