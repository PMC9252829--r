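## Annotation input: dialect sniffing, GFF3+FASTA and GenBank parsing,
## pseudogene product substitution, and the external gene-caller wrapper.
## All coordinates are 1-based inclusive (GFF3 convention) and are carried
## through to every output unchanged.

#' @importFrom Biostrings readAAStringSet readDNAStringSet DNAStringSet
#'   AAStringSet translate subseq reverseComplement writeXStringSet
NULL

.ACCEPTED_FORMATS <- paste(
    "GFF3 + amino-acid FASTA pair (RefSeq or Prodigal dialect),",
    "GenBank flat file (incl. RASTtk), or nucleotide FASTA")

readHead <- function(path, n = 200L) {
    con <- file(path, open = "r")
    on.exit(close(con))
    readLines(con, n = n, warn = FALSE)
}

#' Detect the input annotation dialect
#'
#' Content-based (never extension-based) sniffing of the accepted input
#' formats.  A GenBank file containing the string \code{"rasttk"} is RAST
#' output; a GFF whose header mentions \code{"Prodigal"} selects the Prodigal
#' identifier fix-up; a FASTA over the nucleotide alphabet is an unannotated
#' genome destined for external gene calling.
#'
#' @param raw_files one file (GenBank or nucleotide FASTA) or two files
#'   (a GFF3 and an amino-acid FASTA, in either order).
#' @return one of \code{"refseq_gff_faa"}, \code{"prodigal_gff_faa"},
#'   \code{"rast_genbank"}, \code{"genbank"}, \code{"nucleotide_fasta"}.
#' @export
detectDialect <- function(raw_files) {
    for (f in raw_files)
        if (!file.exists(f)) stop("file not found: ", f)
    if (length(raw_files) == 2L) {
        heads <- lapply(raw_files, readHead)
        is_gff <- vapply(heads, function(h) {
            h <- h[nzchar(h)]
            any(grepl("^##gff-version", h)) ||
                any(vapply(strsplit(h[!startsWith(h, "#")], "\t"),
                           length, integer(1)) == 9L)
        }, logical(1))
        if (sum(is_gff) != 1L)
            stop("unsupported format: expected one GFF3 and one FASTA; ",
                 "accepted inputs are ", .ACCEPTED_FORMATS)
        gff_head <- heads[[which(is_gff)]]
        if (any(grepl("Prodigal", gff_head, fixed = TRUE)))
            return("prodigal_gff_faa")
        return("refseq_gff_faa")
    }
    if (length(raw_files) != 1L)
        stop("expected one or two input files")
    head_lines <- readHead(raw_files)
    nonblank <- head_lines[nzchar(trimws(head_lines))]
    if (!length(nonblank))
        stop("unsupported format: empty input; accepted inputs are ",
             .ACCEPTED_FORMATS)
    if (grepl("^LOCUS", nonblank[[1]])) {
        txt <- readLines(raw_files, warn = FALSE)
        if (any(grepl("rasttk", txt, fixed = TRUE)))
            return("rast_genbank")
        return("genbank")
    }
    if (startsWith(trimws(nonblank[[1]]), ">")) {
        seq_lines <- nonblank[!startsWith(trimws(nonblank), ">")]
        chars <- strsplit(toupper(paste(seq_lines, collapse = "")), "")[[1]]
        if (length(chars) &&
            mean(chars %in% c("A", "C", "G", "T", "U", "N")) > 0.9)
            return("nucleotide_fasta")
        stop("unsupported format: FASTA is not nucleotide ",
             "(a protein FASTA must be paired with its GFF3); ",
             "accepted inputs are ", .ACCEPTED_FORMATS)
    }
    stop("unsupported format; accepted inputs are ", .ACCEPTED_FORMATS)
}

## Extract a pseudogene's inferred-product accession from the PGAP-style
## `inference` attribute ("... similar to AA sequence:RefSeq:WP_000001.1"),
## falling back to a protein_id-style attribute.
inferenceAccession <- function(inference, protein_id = NA_character_) {
    acc <- rep(NA_character_, length(inference))
    hit <- !is.na(inference) & grepl("similar to AA sequence", inference)
    acc[hit] <- sub(".*similar to AA sequence[:[:space:]]*([^,;]*)",
                    "\\1", inference[hit])
    acc[hit] <- vapply(strsplit(acc[hit], ":"), function(x)
        gsub("\\s", "", x[[length(x)]]), character(1))
    use_pid <- is.na(acc) | !nzchar(acc)
    acc[use_pid] <- protein_id[use_pid]
    acc[!is.na(acc) & !nzchar(acc)] <- NA_character_
    acc
}

mcolOr <- function(df, col, default = NA_character_) {
    if (col %in% names(df)) {
        x <- df[[col]]
        if (is.list(x))
            x <- vapply(x, function(v)
                if (length(v)) as.character(v[[1]]) else default,
                character(1))
        as.character(x)
    } else rep(default, nrow(df))
}

#' Parse a GFF3 + amino-acid FASTA pair into a Genome
#'
#' Reads CDS and pseudogene rows from the GFF3, joins protein sequences from
#' the FASTA, collapses multi-interval CDS to their outer span, and assigns
#' per-contig order indices.  For the Prodigal dialect, FASTA identifiers of
#' the form \code{<contig>_<n>} are reconciled with the numeric GFF \code{ID}
#' suffixes so that every CDS finds its protein; for RAST-converted input,
#' \code{db_xref}-derived identifiers are already remapped to locus tags by
#' the GenBank reader.  Pseudogene rows (flagged \code{pseudo=true} or typed
#' \code{pseudogene}) carry no protein but retain the accession of the
#' inferred product when the annotation provides one.
#'
#' @param gff path to the GFF3 file.
#' @param faa path to the amino-acid FASTA file.
#' @param dialect \code{"refseq_gff_faa"} or \code{"prodigal_gff_faa"}
#'   (from \code{\link{detectDialect}}).
#' @param assembly_id assembly identifier; defaults to the GFF basename.
#' @return a \linkS4class{Genome}.
#' @export
parseGffFaa <- function(gff, faa, dialect = "refseq_gff_faa",
                        assembly_id = NULL) {
    if (is.null(assembly_id))
        assembly_id <- sub("\\.gff3?$", "", basename(gff))
    gr <- tryCatch(rtracklayer::import(gff, format = "gff3"),
                   error = function(e)
                       stop("parse error in GFF '", gff, "': ",
                            conditionMessage(e), call. = FALSE))
    df <- as.data.frame(gr, stringsAsFactors = FALSE)
    df$type <- as.character(df$type)
    df <- df[df$type %in% c("CDS", "pseudogene"), , drop = FALSE]
    if (!nrow(df))
        stop("no CDS or pseudogene rows in GFF '", gff, "'")
    pseudo_attr <- tolower(mcolOr(df, "pseudo", "false")) %in%
        c("true", "yes", "1")
    df$.kind <- ifelse(df$type == "pseudogene" | pseudo_attr,
                       "pseudogene", "CDS")
    ids <- mcolOr(df, "ID")
    if (dialect == "prodigal_gff_faa") {
        ## Prodigal GFF IDs are "<k>_<n>"; its FASTA headers are
        ## "<contig>_<n>" — rebuild locus tags from the contig + gene rank.
        n <- sub(".*_", "", ids)
        df$.locus_tag <- paste0(as.character(df$seqnames), "_", n)
    } else {
        lt <- mcolOr(df, "locus_tag")
        lt[is.na(lt)] <- ids[is.na(lt)]
        df$.locus_tag <- lt
    }
    if (any(is.na(df$.locus_tag)))
        stop("GFF rows without locus_tag or ID in '", gff, "'")
    ## collapse multi-interval CDS (shared locus tag) to the outer span
    agg <- do.call(rbind, lapply(split(df, df$.locus_tag), function(g) {
        data.frame(contig = as.character(g$seqnames[[1]]),
                   locus_tag = g$.locus_tag[[1]],
                   start = min(g$start), end = max(g$end),
                   strand = if (as.character(g$strand[[1]]) == "-")
                       "-" else "+",
                   kind = g$.kind[[1]],
                   inference_accession = inferenceAccession(
                       mcolOr(g, "inference")[[1]],
                       mcolOr(g, "protein_id")[[1]]),
                   description = mcolOr(g, "product")[[1]],
                   .name_attr = mcolOr(g, "Name")[[1]],
                   .protein_id = mcolOr(g, "protein_id")[[1]],
                   stringsAsFactors = FALSE)
    }))
    prots <- Biostrings::readAAStringSet(faa)
    names(prots) <- sub("\\s.*", "", names(prots))
    prots_chr <- sub("\\*+$", "", as.character(prots))
    cds <- agg$kind == "CDS"
    key <- agg$locus_tag
    if (dialect != "prodigal_gff_faa") {
        ## choose the identifier space that best matches the FASTA headers
        candidates <- list(locus_tag = agg$locus_tag,
                           name = agg$.name_attr,
                           protein_id = agg$.protein_id)
        m <- vapply(candidates, function(k)
            sum(!is.na(k) & k %in% names(prots_chr)), integer(1))
        key <- candidates[[which.max(m)]]
    }
    agg$.name_attr <- NULL
    agg$.protein_id <- NULL
    matched <- !is.na(key) & key %in% names(prots_chr)
    orphan_cds <- agg$locus_tag[cds & !matched]
    orphan_prot <- setdiff(names(prots_chr), key)
    if (length(orphan_cds) || length(orphan_prot))
        stop("annotation/FASTA reconciliation error in '", basename(gff),
             "': CDS without protein [",
             paste(orphan_cds, collapse = ", "),
             "]; proteins without CDS [",
             paste(orphan_prot, collapse = ", "), "]")
    agg$protein_seq <- NA_character_
    agg$protein_seq[cds] <- unname(prots_chr[key[cds]])
    agg$pseudo_substituted <- FALSE
    ## contig universe: GFF sequence-region pragmas when present, else spans
    pragmas <- grep("^##sequence-region", readHead(gff, 1000L), value = TRUE)
    if (length(pragmas)) {
        parts <- strsplit(trimws(pragmas), "\\s+")
        ctg <- data.frame(
            contig = vapply(parts, `[[`, character(1), 2L),
            length = as.integer(vapply(parts, `[[`, character(1), 4L)),
            stringsAsFactors = FALSE)
    } else {
        ctg <- stats::aggregate(end ~ contig, data = agg, FUN = max)
        names(ctg) <- c("contig", "length")
    }
    extra <- setdiff(unique(agg$contig), ctg$contig)
    if (length(extra))
        ctg <- rbind(ctg, data.frame(contig = extra,
            length = vapply(extra, function(ct)
                max(agg$end[agg$contig == ct]), integer(1))))
    Genome(assembly_id, ctg, agg)
}

## ---- GenBank flat files ------------------------------------------------
## Minimal flat-file reader for prokaryotic records: LOCUS header, CDS
## features with complement()/join() locations and locus_tag / db_xref /
## translation / pseudo / inference / product qualifiers, ORIGIN sequence.

parseGbLocation <- function(loc) {
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (!length(nums)) stop("unparseable GenBank location: ", loc)
    list(start = min(nums), end = max(nums), strand = strand)
}

parseGbQualifiers <- function(lines) {
    ## qualifier lines start with '/'; values may continue on following lines
    txt <- trimws(lines)
    txt <- txt[!grepl("^//", txt)]
    starts <- grep("^/[A-Za-z]", txt)
    quals <- list()
    for (i in seq_along(starts)) {
        from <- starts[i]
        to <- if (i < length(starts)) starts[i + 1] - 1L else length(txt)
        piece <- paste(txt[from:to], collapse = " ")
        m <- regmatches(piece, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", piece))[[1]]
        if (length(m) < 2L) next
        key <- m[[2]]
        val <- if (length(m) >= 4 && nzchar(m[[4]])) m[[4]] else "true"
        val <- gsub("^\"|\"$", "", val)
        if (key == "translation") val <- gsub(" ", "", val)
        quals[[length(quals) + 1L]] <- list(key = key, val = val)
    }
    quals
}

#' Parse a GenBank flat file into a Genome
#'
#' Reads CDS features (coordinates, strand, translations) from a GenBank
#' flat file, producing a \linkS4class{Genome} equivalent to the GFF3+FASTA
#' path.  Joined multi-interval CDS collapse to their outer span.  Features
#' flagged \code{/pseudo} become pseudogenes without a protein sequence.
#' For RASTtk records, \code{db_xref} identifiers stand in for locus tags.
#' The nucleotide sequence (ORIGIN) is retained for downstream non-coding
#' searches, and is used to translate a CDS that lacks a
#' \code{/translation}; a CDS with neither is skipped with a warning.
#'
#' @param gbk path to the GenBank flat file (possibly multi-record).
#' @param assembly_id assembly identifier; defaults to the file basename.
#' @return a \linkS4class{Genome}.
#' @export
parseGenbank <- function(gbk, assembly_id = NULL) {
    if (is.null(assembly_id))
        assembly_id <- sub("\\.(gbk|gbff|gb)$", "", basename(gbk))
    txt <- readLines(gbk, warn = FALSE)
    is_rast <- any(grepl("rasttk", txt, fixed = TRUE))
    rec_starts <- grep("^LOCUS", txt)
    if (!length(rec_starts))
        stop("parse error: no LOCUS line in '", gbk, "'")
    rec_ends <- c(rec_starts[-1] - 1L, length(txt))
    feat_rows <- list()
    ctg_rows <- list()
    seqs <- character()
    for (r in seq_along(rec_starts)) {
        rec <- txt[rec_starts[r]:rec_ends[r]]
        locus_fields <- strsplit(trimws(rec[[1]]), "\\s+")[[1]]
        contig <- locus_fields[[2]]
        ctg_len <- suppressWarnings(as.integer(locus_fields[[3]]))
        ## ORIGIN sequence
        org <- grep("^ORIGIN", rec)
        seq <- ""
        if (length(org)) {
            seq_lines <- rec[(org[[1]] + 1L):length(rec)]
            seq_lines <- seq_lines[!grepl("^//", seq_lines)]
            seq <- toupper(gsub("[^A-Za-z]", "",
                                paste(seq_lines, collapse = "")))
        }
        seqs[contig] <- seq
        if (is.na(ctg_len)) ctg_len <- nchar(seq)
        ctg_rows[[contig]] <- data.frame(contig = contig, length = ctg_len,
                                         stringsAsFactors = FALSE)
        ## FEATURES block: feature headers start at column 6
        fstart <- grep("^FEATURES", rec)
        if (!length(fstart)) next
        fend <- if (length(org)) org[[1]] - 1L else length(rec)
        block <- rec[(fstart[[1]] + 1L):fend]
        hdr <- grep("^ {5}\\S", block)
        for (i in seq_along(hdr)) {
            from <- hdr[i]
            to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(block)
            key <- trimws(substr(block[[from]], 1, 20))
            if (key != "CDS") next
            body <- block[from:to]
            qstart <- grep("^\\s*/", body)
            loc_lines <- if (length(qstart)) body[1:(qstart[[1]] - 1L)]
                         else body
            loc <- gsub("\\s", "", paste(
                c(sub("^ {5}\\S+\\s*", "", loc_lines[[1]]),
                  trimws(loc_lines[-1])), collapse = ""))
            pos <- parseGbLocation(loc)
            quals <- if (length(qstart))
                parseGbQualifiers(body[qstart[[1]]:length(body)])
                else list()
            qget <- function(k) {
                for (q in quals) if (q$key == k) return(q$val)
                NA_character_
            }
            locus_tag <- qget("locus_tag")
            if (is.na(locus_tag) && is_rast) locus_tag <- qget("db_xref")
            if (is.na(locus_tag)) locus_tag <- qget("protein_id")
            pseudo <- !is.na(qget("pseudo")) || !is.na(qget("pseudogene"))
            prot <- qget("translation")
            if (!pseudo && is.na(prot)) {
                if (nzchar(seq)) {
                    nt <- substr(seq, pos$start, pos$end)
                    dna <- Biostrings::DNAStringSet(nt)
                    if (pos$strand == "-")
                        dna <- Biostrings::reverseComplement(dna)
                    prot <- sub("\\*$", "", as.character(
                        Biostrings::translate(dna, if.fuzzy.codon = "X")))
                } else {
                    warning("skipping CDS ", locus_tag,
                            ": no translation and no nucleotide sequence",
                            call. = FALSE)
                    next
                }
            }
            feat_rows[[length(feat_rows) + 1L]] <- data.frame(
                contig = contig, locus_tag = locus_tag,
                start = pos$start, end = pos$end, strand = pos$strand,
                kind = if (pseudo) "pseudogene" else "CDS",
                protein_seq = if (pseudo) NA_character_ else prot,
                pseudo_substituted = FALSE,
                inference_accession = inferenceAccession(
                    qget("inference"),
                    if (pseudo) qget("protein_id") else NA_character_),
                description = qget("product"),
                stringsAsFactors = FALSE)
        }
    }
    ft <- do.call(rbind, feat_rows)
    if (is.null(ft)) ft <- emptyFeatureTable()
    ctg <- do.call(rbind, ctg_rows)
    sequence <- if (any(nzchar(seqs)))
        Biostrings::DNAStringSet(seqs[nzchar(seqs)]) else NULL
    Genome(assembly_id, ctg, ft, sequence = sequence)
}

#' Substitute pseudogene products from inferred full-length proteins
#'
#' Annotation pipelines flag frameshifted or otherwise broken genes as
#' pseudogenes and omit their proteins from the protein FASTA, so defence
#' systems containing a broken gene are normally missed.  Each pseudogene is
#' annotated with the accession of the full-length protein used to infer its
#' product; this operation attaches that protein sequence wherever the
#' lookup resolves it, marking the feature \code{pseudo_substituted} so that
#' downstream output flags it with the \code{pseudo_sub} prefix.
#' Coordinates, strand and gene order are untouched; unresolved pseudogenes
#' pass through unchanged (best effort).  The operation is idempotent.
#'
#' @param genome a \linkS4class{Genome}.
#' @param protein_lookup named character vector or \code{AAStringSet}
#'   mapping inferred-product accessions to protein sequences (may be
#'   empty).
#' @return the updated \linkS4class{Genome}.
#' @export
substitutePseudogenes <- function(genome, protein_lookup) {
    if (is(protein_lookup, "XStringSet")) {
        nm <- sub("\\s.*", "", names(protein_lookup))
        protein_lookup <- stats::setNames(as.character(protein_lookup), nm)
    }
    ft <- genome@features
    idx <- which(ft$kind == "pseudogene" & !ft$pseudo_substituted &
                 !is.na(ft$inference_accession) &
                 ft$inference_accession %in% names(protein_lookup))
    if (length(idx)) {
        ft$protein_seq[idx] <-
            unname(protein_lookup[ft$inference_accession[idx]])
        ft$pseudo_substituted[idx] <- TRUE
        genome@features <- ft
        validObject(genome)
    }
    genome
}

#' Call genes on an unannotated nucleotide FASTA
#'
#' Thin wrapper around an external gene caller (Prodigal by default).
#' Inputs longer than 100 kb are called in single-genome mode; shorter
#' inputs (plasmids, contigs) in anonymous/metagenomic mode, where the
#' caller's trained single-genome statistics would be unreliable.  The
#' resulting GFF/FASTA pair is fed through \code{\link{parseGffFaa}} with
#' the Prodigal dialect fix-up.
#'
#' @param fna path to the nucleotide FASTA.
#' @param out_dir directory for the intermediate GFF/FASTA pair.
#' @param caller name/path of the gene caller executable, or an R function
#'   \code{function(fna, gff_out, faa_out, mode)} (used by tests to stub the
#'   caller); mode is \code{"single"} or \code{"meta"}.
#' @param single_mode_min_nt total input length above which single-genome
#'   mode is used; default 100000.
#' @return a \linkS4class{Genome}; the calling mode used is attached as
#'   attribute \code{"calling_mode"}.
#' @export
callGenes <- function(fna, out_dir = tempfile("genecall"),
                      caller = "prodigal", single_mode_min_nt = 100000L) {
    dna <- Biostrings::readDNAStringSet(fna)
    mode <- if (sum(Biostrings::width(dna)) > single_mode_min_nt)
        "single" else "meta"
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gff_out <- file.path(out_dir, "called.gff")
    faa_out <- file.path(out_dir, "called.faa")
    if (is.function(caller)) {
        caller(fna, gff_out, faa_out, mode)
    } else {
        if (!nzchar(Sys.which(caller)))
            stop("gene caller '", caller, "' not found on PATH; ",
                 "provide pre-annotated input (GFF3 + protein FASTA ",
                 "or GenBank) instead")
        args <- c("-i", fna, "-f", "gff", "-o", gff_out, "-a", faa_out,
                  "-q", if (mode == "meta") c("-p", "meta"))
        status <- system2(caller, args, stdout = FALSE, stderr = FALSE)
        if (status != 0L)
            stop("gene caller failed with status ", status)
    }
    genome <- parseGffFaa(gff_out, faa_out, dialect = "prodigal_gff_faa",
                          assembly_id = sub("\\.(fna|fa|fasta)$", "",
                                            basename(fna)))
    attr(genome, "calling_mode") <- mode
    genome
}
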