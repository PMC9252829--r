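## Deterministic fixture generation: a toy model database (system
## definitions, HMM metadata, real HMMER3 profiles built from generated
## alignments) and synthetic genomes with planted defence systems, decoy
## genes, pseudogenes, ncRNAs and CRISPR arrays.  Every stage of the
## pipeline is testable from these fixtures without downloads.

## Evaluate expr with a temporarily seeded RNG, restoring any prior state.
withSeed <- function(seed, expr) {
    has_old <- exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_old) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Stable small hash of a family name, so seed sequences are reproducible
## independently of any plan seed.
.familyHash <- function(family) {
    v <- utf8ToInt(family)
    sum(v * seq_along(v) * 131L) %% 100000L
}

## The fixed reference protein for one family: all toy HMMs and planted
## genes derive from this sequence.
familySeedProtein <- function(family) {
    h <- .familyHash(family)
    len <- 180L + (h %% 120L)
    withSeed(900000L + h,
             paste(sample(.AA, len, replace = TRUE), collapse = ""))
}

## Point-substituted copy of a protein (default 5% of residues), drawn from
## the current RNG stream.
mutateProtein <- function(seq, rate = 0.05) {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars)
    k <- max(1L, round(rate * n))
    idx <- sample.int(n, k)
    chars[idx] <- sample(.AA, k, replace = TRUE)
    paste(chars, collapse = "")
}

## ---- toy database ------------------------------------------------------

## Family table of the demo database: one row per HMM.  DrmA carries two
## profiles (distinct clades of one family share a protein_family token).
toyHmmTable <- function() {
    fams <- c("DrmA", "DrmA", "DrmB", "DrmC", "DrmD", "DrmMI", "DrmE",
              "DrmMII", "JetA", "JetB", "JetC", "JetD", "RT", "ShdA",
              "PtxA", "PtxB", "PtxC", "PtxD", "Cas1")
    suffix <- ifelse(duplicated(fams), "alt", "seed")
    data.frame(
        accession = sprintf("PLDC%05d", seq_along(fams)),
        original_name = paste0(fams, "_", suffix),
        protein_family = fams,
        stringsAsFactors = FALSE)
}

## Declarative definitions of the demo models (shared by makeToyDb and the
## planted-truth computation in makeGenome).
toyModelSpecs <- function() {
    list(
        list(name = "DISARM_I", family = "DISARM",
             core = c("DrmA", "DrmB", "DrmC", "DrmD", "DrmMI"),
             prohibited = "DrmE", minimum_core = 5L),
        list(name = "DISARM_II", family = "DISARM",
             core = c("DrmA", "DrmB", "DrmC", "DrmE", "DrmMII"),
             minimum_core = 5L),
        list(name = "DISARM_other", family = "DISARM",
             core = c("DrmA", "DrmB", "DrmC", "DrmD", "DrmMI", "DrmE",
                      "DrmMII"),
             minimum_core = 2L, minimum_total = 2L),
        list(name = "wadjet_I", family = "wadjet",
             core = c("JetA", "JetB", "JetC", "JetD")),
        list(name = "wadjet_other", family = "wadjet",
             core = c("JetA", "JetB", "JetC", "JetD"),
             minimum_core = 2L, minimum_total = 2L),
        list(name = "retron_I", family = "retron",
             core = c("RT", "ncRNA"), minimum_core = 2L),
        list(name = "shield_I", family = "shield",
             core = "ShdA", minimum_core = 1L),
        list(name = "PT_other", family = "PT",
             core = c("PtxA", "PtxB", "PtxC", "PtxD"),
             minimum_core = 2L, minimum_total = 2L),
        list(name = "cas_array_I", family = "cas_array",
             core = c("Cas1", "CRISPR_array"), minimum_core = 2L))
}

## Rewrite volatile HMMER header lines so regeneration is byte-identical,
## and stamp the database accession onto each profile.
.fixHmmHeader <- function(hmm_file, accession) {
    lines <- readLines(hmm_file, warn = FALSE)
    lines[grepl("^DATE ", lines)] <- "DATE  Mon Jan  1 00:00:00 2024"
    name_at <- grep("^NAME ", lines)[[1]]
    lines <- append(lines, sprintf("ACC   %s", accession), after = name_at)
    writeLines(lines, hmm_file)
}

#' Build the toy demo model database
#'
#' Writes a small but complete database directory: nine system-definition
#' files under \code{sys/} (DISARM type I/II and relaxed \code{_other},
#' Wadjet canonical and \code{_other}, a two-component retron with an
#' \code{ncRNA} core token, a single-gene system, a \code{PT_other}-style
#' relaxed model, and a CRISPR-using model), the \code{hmm_meta.txt}
#' metadata table, and real HMMER3 profiles under \code{hmm/} built with
#' \code{hmmbuild} from generated 10-sequence alignments (5\% point
#' substitutions of each family's fixed seed protein).  Regeneration into
#' the same directory is byte-identical.
#'
#' @param dir target database directory (created if needed).
#' @param hmmbuild path to the \code{hmmbuild} executable; when it is not
#'   on PATH the \code{hmm/} profiles are skipped (parsing-only workflows
#'   and fabricated hit tables do not need them).
#' @return invisibly, list with \code{n_models} and \code{n_hmms}.
#' @export
makeToyDb <- function(dir, hmmbuild = "hmmbuild") {
    dir.create(file.path(dir, "sys"), recursive = TRUE,
               showWarnings = FALSE)
    specs <- toyModelSpecs()
    for (m in specs) {
        out <- m[!vapply(m, is.null, logical(1))]
        out$core <- as.list(out$core)
        if (!is.null(out$prohibited))
            out$prohibited <- as.list(out$prohibited)
        yaml::write_yaml(out, file.path(dir, "sys",
                                        paste0(m$name, ".yaml")))
    }
    tbl <- toyHmmTable()
    meta <- data.frame(
        accession = tbl$accession,
        `original.name` = tbl$original_name,
        `protein.family` = tbl$protein_family,
        `e.val.threshold` = NA_real_,
        `target.coverage.threshold` = NA_real_,
        `hmm.coverage.threshold` = NA_real_,
        citation = "synthetic toy profile",
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(meta, file.path(dir, "hmm_meta.txt"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
    n_hmms <- 0L
    if (nzchar(Sys.which(hmmbuild))) {
        dir.create(file.path(dir, "hmm"), showWarnings = FALSE)
        profiles <- character()
        for (i in seq_len(nrow(tbl))) {
            fam <- tbl$protein_family[[i]]
            seed_prot <- familySeedProtein(fam)
            msa <- withSeed(700000L + 7L * i, vapply(1:10, function(k)
                mutateProtein(seed_prot), character(1)))
            afa <- tempfile(fileext = ".afa")
            writeLines(paste0(">", tbl$original_name[[i]], "_", 1:10,
                              "\n", msa), afa)
            hmm <- tempfile(fileext = ".hmm")
            status <- system2(hmmbuild,
                c("--amino", "-n", tbl$original_name[[i]], hmm, afa),
                stdout = FALSE, stderr = FALSE)
            if (status != 0L)
                stop("hmmbuild failed for family ", fam)
            .fixHmmHeader(hmm, tbl$accession[[i]])
            profiles <- c(profiles, readLines(hmm, warn = FALSE))
            unlink(c(afa, hmm))
            n_hmms <- n_hmms + 1L
        }
        writeLines(profiles, file.path(dir, "hmm", "toy.hmm"))
    }
    invisible(list(n_models = length(specs), n_hmms = n_hmms))
}

## ---- genome plans ------------------------------------------------------

#' Describe a synthetic genome to generate
#'
#' A plan lists, per contig, the elements to plant in order along the
#' sequence: defence operons (with optional pseudogenized members and
#' declared expected calls), decoy genes, ncRNA hits and CRISPR arrays.
#' Coordinates are laid out left to right with randomized (seeded)
#' intergenic gaps, so plantings can never overlap; a contig too short for
#' its elements is a plan validation error at generation time.
#'
#' Element kinds:
#' \describe{
#'   \item{operon}{\code{families}: ordered gene families; \code{pseudo}:
#'     named character, family -> inferred-product accession, marking that
#'     member as a pseudogene; \code{expect}: list of expected-call entries
#'     \code{list(phase, model, extra_members = NULL)}, phase one of
#'     \code{"pre_substitution"}/\code{"final"}.}
#'   \item{decoys}{\code{n} random non-defence genes.}
#'   \item{ncrna}{\code{cm}: covariance model name; \code{evalue}.}
#'   \item{crispr}{\code{repeats}: repeat count.}
#' }
#'
#' @param assembly_id assembly identifier for the generated genome.
#' @param seed integer seed controlling layout, decoys and fabricated
#'   scores; identical (plan, seed) regenerates byte-identical files.
#' @param contigs list of \code{list(length =, elements = list(...))}.
#' @return the plan (class \code{"GenomePlan"}).
#' @export
genomePlan <- function(assembly_id, seed, contigs) {
    stopifnot(is.character(assembly_id), length(contigs) >= 1)
    structure(list(assembly_id = assembly_id, seed = as.integer(seed),
                   contigs = contigs), class = "GenomePlan")
}

#' The shipped demonstration plans
#'
#' Ten plans covering the detection scenarios the system definitions are
#' built around: a complete DISARM type I operon; the drmE-containing locus
#' that reclassifies as type II; a quorum-failing DISARM locus; a canonical
#' Wadjet operon; the frameshifted-jetC Wadjet locus rescued by pseudogene
#' substitution; a retron (protein + msr-msd ncRNA); a Cas1 + CRISPR-array
#' locus; a Wadjet system split across two contigs; a single-gene system;
#' and a decoy-only negative control.
#'
#' @param seed base seed; each plan derives its own offset from it.
#' @return named list of \code{\link{genomePlan}} objects.
#' @export
demoPlans <- function(seed = 1L) {
    seed <- as.integer(seed) %% 100000L
    op <- function(families, pseudo = NULL, expect = list())
        list(kind = "operon", families = families, pseudo = pseudo,
             expect = expect)
    exp_ <- function(model, phase = "final", extra_members = NULL)
        list(phase = phase, model = model, extra_members = extra_members)
    list(
        disarm_typeI = genomePlan("g_disarm1", seed + 11L, list(list(
            length = 60000L, elements = list(
                list(kind = "decoys", n = 8L),
                op(c("DrmA", "DrmB", "DrmC", "DrmD", "DrmMI"),
                   expect = list(exp_("DISARM_I"))),
                list(kind = "decoys", n = 12L))))),
        disarm_reclass = genomePlan("g_disarm2", seed + 12L, list(list(
            length = 60000L, elements = list(
                list(kind = "decoys", n = 6L),
                op(c("DrmA", "DrmB", "DrmC", "DrmD", "DrmMI", "DrmE",
                     "DrmMII"),
                   expect = list(exp_("DISARM_II"), exp_("DISARM_other"))),
                list(kind = "decoys", n = 10L))))),
        disarm_quorum = genomePlan("g_disarm3", seed + 13L, list(list(
            length = 50000L, elements = list(
                list(kind = "decoys", n = 5L),
                op(c("DrmA", "DrmB", "DrmC", "DrmMI"),
                   expect = list(exp_("DISARM_other"))),
                list(kind = "decoys", n = 9L))))),
        wadjet = genomePlan("g_wadjet1", seed + 14L, list(list(
            length = 50000L, elements = list(
                list(kind = "decoys", n = 7L),
                op(c("JetA", "JetB", "JetC", "JetD"),
                   expect = list(exp_("wadjet_I"))),
                list(kind = "decoys", n = 11L))))),
        wadjet_pseudo = genomePlan("g_wadjet2", seed + 15L, list(list(
            length = 50000L, elements = list(
                list(kind = "decoys", n = 6L),
                op(c("JetA", "JetB", "JetC", "JetD"),
                   pseudo = c(JetC = "WP_900000001.1"),
                   expect = list(
                       exp_("wadjet_other", phase = "pre_substitution"),
                       exp_("wadjet_I"))),
                list(kind = "decoys", n = 8L))))),
        retron = genomePlan("g_retron", seed + 16L, list(list(
            length = 40000L, elements = list(
                list(kind = "decoys", n = 5L),
                op("RT", expect = list(
                    exp_("retron_I",
                         extra_members = "g_retron_ncrna_001"))),
                list(kind = "ncrna", cm = "msr_msd_1", evalue = 1e-6),
                list(kind = "decoys", n = 6L),
                list(kind = "ncrna", cm = "msr_msd_2", evalue = 0.5))))),
        cas_crispr = genomePlan("g_cas", seed + 17L, list(list(
            length = 40000L, elements = list(
                list(kind = "decoys", n = 4L),
                op("Cas1", expect = list(
                    exp_("cas_array_I",
                         extra_members = "g_cas_crispr_001"))),
                list(kind = "crispr", repeats = 5L),
                list(kind = "decoys", n = 7L))))),
        split_wadjet = genomePlan("g_split", seed + 18L, list(
            list(length = 30000L, elements = list(
                list(kind = "decoys", n = 4L),
                op(c("JetA", "JetB"),
                   expect = list(exp_("wadjet_other"))),
                list(kind = "decoys", n = 3L))),
            list(length = 30000L, elements = list(
                list(kind = "decoys", n = 2L),
                op(c("JetC", "JetD"),
                   expect = list(exp_("wadjet_other"))),
                list(kind = "decoys", n = 5L))))),
        shield = genomePlan("g_shield", seed + 19L, list(list(
            length = 30000L, elements = list(
                list(kind = "decoys", n = 6L),
                op("ShdA", expect = list(exp_("shield_I"))),
                list(kind = "decoys", n = 4L))))),
        decoy_only = genomePlan("g_decoy", seed + 20L, list(list(
            length = 50000L, elements = list(
                list(kind = "decoys", n = 30L))))))
}

## ---- genome generation -------------------------------------------------

.fabricateDomtblRow <- function(locus_tag, tlen, hmm_name, accession,
                                hmm_len, strong = TRUE) {
    if (strong) {
        fe <- 10^stats::runif(1, -30, -10)
        t_from <- 1L + sample.int(max(1L, floor(0.03 * tlen)), 1L) - 1L
        t_to <- tlen - (sample.int(max(1L, floor(0.03 * tlen)), 1L) - 1L)
        h_from <- 1L + sample.int(max(1L, floor(0.03 * hmm_len)), 1L) - 1L
        h_to <- hmm_len - (sample.int(max(1L, floor(0.03 * hmm_len)),
                                      1L) - 1L)
        score <- round(stats::runif(1, 80, 300), 1)
    } else {
        fe <- 10^stats::runif(1, -3, 0.5)
        span <- max(10L, floor(0.28 * tlen))
        t_from <- sample.int(max(1L, tlen - span), 1L)
        t_to <- t_from + span - 1L
        h_span <- max(10L, floor(0.28 * hmm_len))
        h_from <- sample.int(max(1L, hmm_len - h_span), 1L)
        h_to <- h_from + h_span - 1L
        score <- round(stats::runif(1, 5, 18), 1)
    }
    ie <- fe * 10^stats::runif(1, 0, 1)
    paste(locus_tag, "-", tlen, hmm_name, accession, hmm_len,
          sprintf("%.1e", fe), score, "0.0", 1, 1,
          sprintf("%.1e", ie / 10), sprintf("%.1e", ie), score, "0.0",
          h_from, h_to, t_from, t_to,
          max(1L, t_from - 2L), min(tlen, t_to + 2L), "0.95", "-")
}

.cmsearchRow <- function(contig, cm, start, end, evalue) {
    paste(contig, "-", cm, "-", "cm", 1, 80, start, end, "+", "no", 1,
          "0.45", "0.0", round(max(5, -log10(max(evalue, 1e-30)) * 3), 1),
          sprintf("%.1e", evalue), if (evalue <= 0.01) "!" else "?", "-")
}

#' Generate a synthetic genome (and all pipeline inputs) from a plan
#'
#' Lays the planned elements along each contig and writes every format the
#' pipeline reads: the GFF3 annotation, the protein FASTA, a random
#' nucleotide FASTA, a fabricated per-domain HMM hit table (strong,
#' seeded log-uniform E-values for planted genes; weak sub-threshold hits
#' for a fraction of decoys), a second hit table that additionally covers
#' substituted pseudogenes, a cmsearch-style ncRNA table, a CRISPR-array
#' GFF, a synthetic inferred-protein FASTA for pseudogene substitution, and
#' the truth table of expected calls.  Planted proteins are 5\%-mutated
#' copies of the family seed proteins, so a real \code{hmmsearch} against
#' the toy database finds them; the fabricated tables allow testing without
#' any search engine.  Identical (plan, seed) reruns are byte-identical.
#'
#' @param plan a \code{\link{genomePlan}}.
#' @param dir output directory (created if needed).
#' @return list of file paths (\code{gff}, \code{faa}, \code{fna},
#'   \code{domtbl}, \code{domtbl_substituted}, \code{cmsearch},
#'   \code{crispr_gff}, \code{pseudo_proteins}, \code{truth_csv}) plus
#'   \code{truth} (data.frame: phase, model, contig, locus_tags) and
#'   \code{assembly_id}.
#' @export
makeGenome <- function(plan, dir) {
    stopifnot(inherits(plan, "GenomePlan"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    aid <- plan$assembly_id
    hmm_tbl <- toyHmmTable()
    specs <- toyModelSpecs()
    names(specs) <- vapply(specs, `[[`, character(1), "name")
    primary <- hmm_tbl[!duplicated(hmm_tbl$protein_family), ]
    rownames(primary) <- primary$protein_family
    gff <- c("##gff-version 3")
    faa <- character()
    domtbl <- character()
    domtbl_sub <- character()
    cms <- character()
    crispr <- c("##gff-version 3")
    pseudo_faa <- character()
    truth <- list()
    gene_counter <- 0L
    ncrna_counter <- 0L
    crispr_counter <- 0L
    withSeed(plan$seed, {
        for (ci in seq_along(plan$contigs)) {
            ctg <- plan$contigs[[ci]]
            contig <- sprintf("%s_ctg%d", aid, ci)
            gff <- c(gff, sprintf("##sequence-region %s 1 %d", contig,
                                  ctg$length))
            cursor <- 1L
            placeGene <- function(aa_len, operonic = FALSE) {
                gap <- if (operonic) sample(5:40, 1L) else
                    sample(40:200, 1L)
                start <- cursor + gap
                end <- start + 3L * aa_len + 2L
                cursor <<- end
                if (end > ctg$length)
                    stop("plan validation error: contig ", contig,
                         " too short for its planted elements")
                c(start = start, end = end)
            }
            for (el in ctg$elements) {
                if (el$kind == "decoys") {
                    for (k in seq_len(el$n)) {
                        gene_counter <- gene_counter + 1L
                        lt <- sprintf("%s_g%04d", aid, gene_counter)
                        aa_len <- sample(80:300, 1L)
                        pos <- placeGene(aa_len)
                        strand <- sample(c("+", "-"), 1L)
                        prot <- paste(sample(.AA, aa_len, replace = TRUE),
                                      collapse = "")
                        gff <- c(gff, paste(contig, "fixture", "CDS",
                            pos[["start"]], pos[["end"]], ".", strand, "0",
                            sprintf("ID=cds-%s;locus_tag=%s;product=hypothetical protein",
                                    lt, lt), sep = "\t"))
                        faa <- c(faa, paste0(">", lt), prot)
                        ## a fifth of decoys get weak, sub-threshold hits
                        if (stats::runif(1) < 0.2) {
                            fam <- sample(primary$protein_family, 1L)
                            row <- .fabricateDomtblRow(lt, aa_len,
                                primary[fam, "original_name"],
                                primary[fam, "accession"],
                                nchar(familySeedProtein(fam)),
                                strong = FALSE)
                            domtbl <- c(domtbl, row)
                            domtbl_sub <- c(domtbl_sub, row)
                        }
                    }
                } else if (el$kind == "operon") {
                    tags <- character(length(el$families))
                    for (k in seq_along(el$families)) {
                        fam <- el$families[[k]]
                        gene_counter <- gene_counter + 1L
                        lt <- sprintf("%s_g%04d", aid, gene_counter)
                        tags[[k]] <- lt
                        prot <- mutateProtein(familySeedProtein(fam))
                        aa_len <- nchar(prot)
                        pos <- placeGene(aa_len, operonic = k > 1L)
                        is_pseudo <- fam %in% names(el$pseudo)
                        attrs <- sprintf(
                            "ID=cds-%s;locus_tag=%s;product=%s protein",
                            lt, lt, fam)
                        if (is_pseudo) {
                            acc <- el$pseudo[[fam]]
                            attrs <- paste0(attrs, ";pseudo=true;",
                                "inference=COORDINATES: similar to AA ",
                                "sequence:RefSeq:", acc)
                            pseudo_faa <- c(pseudo_faa, paste0(">", acc),
                                            prot)
                        } else {
                            faa <- c(faa, paste0(">", lt), prot)
                        }
                        gff <- c(gff, paste(contig, "fixture", "CDS",
                            pos[["start"]], pos[["end"]], ".", "+", "0",
                            attrs, sep = "\t"))
                        ## fabricated hit rows for every HMM of the family
                        fam_hmms <- hmm_tbl[hmm_tbl$protein_family == fam, ]
                        for (h in seq_len(nrow(fam_hmms))) {
                            row <- .fabricateDomtblRow(lt, aa_len,
                                fam_hmms$original_name[[h]],
                                fam_hmms$accession[[h]],
                                nchar(familySeedProtein(fam)))
                            if (!is_pseudo) domtbl <- c(domtbl, row)
                            domtbl_sub <- c(domtbl_sub, row)
                        }
                    }
                    names(tags) <- NULL
                    fam_of_tag <- el$families
                    for (ex in el$expect) {
                        spec <- specs[[ex$model]]
                        member_fams <- c(spec$core, spec$accessory)
                        sel <- fam_of_tag %in% member_fams
                        if (identical(ex$phase, "pre_substitution"))
                            sel <- sel & !(fam_of_tag %in%
                                           names(el$pseudo))
                        truth[[length(truth) + 1L]] <- data.frame(
                            phase = ex$phase, model = ex$model,
                            contig = contig,
                            locus_tags = paste(sort(c(tags[sel],
                                ex$extra_members)), collapse = ";"),
                            stringsAsFactors = FALSE)
                    }
                } else if (el$kind == "ncrna") {
                    start <- cursor + sample(20:80, 1L)
                    end <- start + 160L
                    cursor <- end
                    if (el$evalue <= 0.01) ncrna_counter <- ncrna_counter + 1L
                    cms <- c(cms, .cmsearchRow(contig, el$cm, start, end,
                                               el$evalue))
                } else if (el$kind == "crispr") {
                    start <- cursor + sample(20:80, 1L)
                    end <- start + 61L * el$repeats
                    cursor <- end
                    crispr_counter <- crispr_counter + 1L
                    crispr <- c(crispr, paste(contig, "CRISPRDetect",
                        "repeat_region", start, end, ".", "+", ".",
                        sprintf("ID=crispr%d;Note=%d;rpt_family=CRISPR",
                                crispr_counter, el$repeats), sep = "\t"))
                } else stop("unknown plan element kind: ", el$kind)
            }
        }
        ## nucleotide sequences: random composition (the HMM stages only
        ## read the protein FASTA)
        fna <- character()
        for (ci in seq_along(plan$contigs)) {
            contig <- sprintf("%s_ctg%d", aid, ci)
            fna <- c(fna, paste0(">", contig),
                     paste(sample(c("A", "C", "G", "T"),
                                  plan$contigs[[ci]]$length,
                                  replace = TRUE), collapse = ""))
        }
        writeLines(fna, file.path(dir, paste0(aid, ".fna")))
    })
    paths <- list(
        gff = file.path(dir, paste0(aid, ".gff")),
        faa = file.path(dir, paste0(aid, ".faa")),
        fna = file.path(dir, paste0(aid, ".fna")),
        domtbl = file.path(dir, paste0(aid, ".domtbl")),
        domtbl_substituted = file.path(dir,
            paste0(aid, "_substituted.domtbl")),
        cmsearch = file.path(dir, paste0(aid, "_ncrna.tbl")),
        crispr_gff = file.path(dir, paste0(aid, "_crispr.gff")),
        pseudo_proteins = file.path(dir,
            paste0(aid, "_inferred_proteins_synthetic.faa")),
        truth_csv = file.path(dir, paste0(aid, "_truth.csv")))
    writeLines(gff, paths$gff)
    writeLines(faa, paths$faa)
    hdr <- paste0("# synthetic per-domain hit table for ", aid)
    writeLines(c(hdr, domtbl), paths$domtbl)
    writeLines(c(hdr, domtbl_sub), paths$domtbl_substituted)
    writeLines(c(paste0("# synthetic cmsearch tblout for ", aid), cms),
               paths$cmsearch)
    writeLines(crispr, paths$crispr_gff)
    writeLines(pseudo_faa, paths$pseudo_proteins)
    truth_df <- if (length(truth)) do.call(rbind, truth) else
        data.frame(phase = character(), model = character(),
                   contig = character(), locus_tags = character(),
                   stringsAsFactors = FALSE)
    utils::write.csv(truth_df, paths$truth_csv, row.names = FALSE)
    c(paths, list(truth = truth_df, assembly_id = aid))
}
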