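#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

## Family tokens that denote non-protein system components. They may appear in
## core/accessory/prohibited lists of any model but never require HMM evidence.
.NONPROTEIN_TOKENS <- c("ncRNA", "CRISPR_array")

#' SystemModel: a declarative defence-system definition
#'
#' A system-definition model describes one defence system type as sets of
#' gene families: \emph{core} families that define the system, optional
#' \emph{accessory} families, and \emph{prohibited} families whose presence in
#' a candidate gene cluster rejects the classification.  Quorum rules
#' (\code{minimumCore}, \code{minimumTotal}) state how many distinct core and
#' total families a cluster must contain, and \code{maximumSeparation} bounds
#' the number of intervening non-member genes allowed between consecutive
#' cluster members.  Models whose name ends in \code{"_other"} are relaxed
#' definitions used to catch fragmented or divergent systems.
#'
#' The tokens \code{"ncRNA"} and \code{"CRISPR_array"} are valid family
#' tokens in any list and denote non-coding components contributed by
#' covariance-model search and CRISPR array detection respectively.
#'
#' @slot name model identifier, e.g. \code{"DISARM_I"}.
#' @slot family grouping label shared by related models, e.g. \code{"DISARM"}.
#' @slot coreFamilies character vector of core family tokens.
#' @slot accessoryFamilies character vector of accessory family tokens.
#' @slot prohibitedFamilies character vector of prohibited family tokens.
#' @slot minimumCore minimum number of distinct core families required.
#' @slot minimumTotal minimum number of distinct (core + accessory) families.
#' @slot maximumSeparation maximum intervening unlabelled genes between
#'   consecutive cluster members.
#' @slot isOther \code{TRUE} when the model name ends in \code{"_other"}.
#'
#' @exportClass SystemModel
setClass("SystemModel",
    representation(
        name = "character",
        family = "character",
        coreFamilies = "character",
        accessoryFamilies = "character",
        prohibitedFamilies = "character",
        minimumCore = "integer",
        minimumTotal = "integer",
        maximumSeparation = "integer",
        isOther = "logical"
    )
)

setValidity("SystemModel", function(object) {
    msg <- character()
    if (!isSingleString(object@name) || !nzchar(object@name))
        msg <- c(msg, "'name' must be a non-empty string")
    if (length(object@coreFamilies) < 1L)
        msg <- c(msg, "at least one core family is required")
    if (anyDuplicated(object@coreFamilies))
        msg <- c(msg, "duplicated core family tokens")
    if (object@minimumCore > length(object@coreFamilies))
        msg <- c(msg, sprintf(
            "minimum_core (%d) exceeds the number of core families (%d)",
            object@minimumCore, length(object@coreFamilies)))
    if (object@minimumCore < 0L)
        msg <- c(msg, "minimum_core must be >= 0")
    if (object@minimumTotal < object@minimumCore)
        msg <- c(msg, "minimum_total must be >= minimum_core")
    if (object@maximumSeparation < 0L)
        msg <- c(msg, "maximum_separation must be >= 0")
    overlap <- c(
        intersect(object@coreFamilies, object@accessoryFamilies),
        intersect(object@coreFamilies, object@prohibitedFamilies),
        intersect(object@accessoryFamilies, object@prohibitedFamilies))
    if (length(overlap))
        msg <- c(msg, paste0("core/accessory/prohibited sets overlap: ",
                             paste(unique(overlap), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Genome: an ordered, normalized genome annotation
#'
#' Container for one genome assembly after input normalization.  Features are
#' held as a single ordered data.frame covering coding genes (CDS),
#' pseudogenes, and spliced-in non-coding components (ncRNAs, CRISPR arrays).
#' Coordinates are 1-based and inclusive (GFF3 convention) throughout.
#'
#' The \code{features} data.frame has columns \code{contig}, \code{locus_tag},
#' \code{start}, \code{end}, \code{strand}, \code{order_index} (0-based rank
#' along each contig), \code{kind} (one of CDS, pseudogene, ncRNA,
#' CRISPR_array), \code{protein_seq} (NA when absent),
#' \code{pseudo_substituted}, \code{inference_accession},
#' \code{family_token} (pre-assigned label for non-coding features, NA
#' otherwise) and \code{description}.
#'
#' @slot assemblyId assembly identifier.
#' @slot contigs data.frame with columns \code{contig} and \code{length}.
#' @slot features ordered feature data.frame (see Details).
#' @slot sequence \code{DNAStringSet} of contig sequences, possibly empty.
#'
#' @exportClass Genome
setClass("Genome",
    representation(
        assemblyId = "character",
        contigs = "data.frame",
        features = "data.frame",
        sequence = "ANY"
    )
)

.FEATURE_KINDS <- c("CDS", "pseudogene", "ncRNA", "CRISPR_array")

.FEATURE_COLUMNS <- c("contig", "locus_tag", "start", "end", "strand",
    "order_index", "kind", "protein_seq", "pseudo_substituted",
    "inference_accession", "family_token", "description")

setValidity("Genome", function(object) {
    msg <- character()
    ft <- object@features
    missing_cols <- setdiff(.FEATURE_COLUMNS, names(ft))
    if (length(missing_cols))
        return(paste0("features is missing columns: ",
                      paste(missing_cols, collapse = ", ")))
    if (!all(c("contig", "length") %in% names(object@contigs)))
        return("contigs must have columns 'contig' and 'length'")
    if (nrow(ft)) {
        if (anyDuplicated(ft$locus_tag))
            msg <- c(msg, "locus_tags are not unique within the genome")
        bad_contig <- setdiff(unique(ft$contig), object@contigs$contig)
        if (length(bad_contig))
            msg <- c(msg, paste0("features reference unknown contigs: ",
                                 paste(bad_contig, collapse = ", ")))
        if (any(ft$start > ft$end))
            msg <- c(msg, "feature start > end")
        if (!all(ft$kind %in% .FEATURE_KINDS))
            msg <- c(msg, "invalid feature kind")
        if (!all(ft$strand %in% c("+", "-")))
            msg <- c(msg, "strand must be '+' or '-'")
        cds <- ft$kind == "CDS"
        if (any(cds & is.na(ft$protein_seq)))
            msg <- c(msg, "CDS features must carry a protein sequence")
        ## a pseudogene carries a protein iff it was substituted
        ps <- ft$kind == "pseudogene"
        bad_ps <- ps & (is.na(ft$protein_seq) == ft$pseudo_substituted)
        if (any(bad_ps))
            msg <- c(msg,
                "pseudogene protein_seq present iff pseudo_substituted")
        ## order_index strictly increasing by start within each contig
        for (ctg in unique(ft$contig)) {
            sub <- ft[ft$contig == ctg, ]
            sub <- sub[order(sub$order_index), ]
            if (is.unsorted(sub$start))
                msg <- c(msg, sprintf(
                    "order_index does not follow start order on contig %s",
                    ctg))
            if (any(duplicated(sub$order_index)))
                msg <- c(msg, sprintf("duplicated order_index on contig %s",
                                      ctg))
        }
    }
    if (length(msg)) msg else TRUE
})

#' SystemCall: one accepted defence-system instance
#'
#' An accepted instance of a system-definition model in a genome.  Members are
#' the core and accessory genes (or non-coding components) of the cluster,
#' with the HMM evidence that labelled each one.
#'
#' The \code{members} data.frame has one row per member gene with columns
#' \code{locus_tag}, \code{family}, \code{role} (\code{"core"} or
#' \code{"accessory"}), \code{hmm_accession}, \code{hmm_name},
#' \code{full_seq_evalue}, \code{domain_ievalue}, \code{target_coverage},
#' \code{hmm_coverage}, \code{start}, \code{end}, \code{strand},
#' \code{pseudo_substituted} and \code{description}.
#'
#' @slot systemNumber integer, unique per genome, assigned in coordinate order.
#' @slot modelName name of the accepted model.
#' @slot contig contig identifier carrying the system.
#' @slot members per-member evidence data.frame (see Details).
#' @slot start,end span of the system (min member start, max member end).
#'
#' @exportClass SystemCall
setClass("SystemCall",
    representation(
        systemNumber = "integer",
        modelName = "character",
        contig = "character",
        members = "data.frame",
        start = "integer",
        end = "integer"
    )
)

setValidity("SystemCall", function(object) {
    msg <- character()
    need <- c("locus_tag", "family", "role", "start", "end")
    if (!all(need %in% names(object@members)))
        return("members lacks required columns")
    if (nrow(object@members) == 0L)
        msg <- c(msg, "a SystemCall must have at least one member")
    if (!all(object@members$role %in% c("core", "accessory")))
        msg <- c(msg, "member roles must be 'core' or 'accessory'")
    if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "SystemModel", function(object) {
    cat(sprintf("SystemModel '%s' (family %s%s)\n", object@name,
                object@family, if (object@isOther) ", relaxed" else ""))
    cat("  core:       ", paste(object@coreFamilies, collapse = ", "), "\n")
    if (length(object@accessoryFamilies))
        cat("  accessory:  ", paste(object@accessoryFamilies,
                                    collapse = ", "), "\n")
    if (length(object@prohibitedFamilies))
        cat("  prohibited: ", paste(object@prohibitedFamilies,
                                    collapse = ", "), "\n")
    cat(sprintf("  quorum: >=%d core, >=%d total; max separation %d genes\n",
                object@minimumCore, object@minimumTotal,
                object@maximumSeparation))
})

setMethod("show", "Genome", function(object) {
    kinds <- table(factor(object@features$kind, levels = .FEATURE_KINDS))
    cat(sprintf("Genome '%s': %d contig(s), %d feature(s)\n",
                object@assemblyId, nrow(object@contigs),
                nrow(object@features)))
    cat("  ", paste(sprintf("%s: %d", names(kinds), as.integer(kinds)),
                    collapse = ", "), "\n")
})

setMethod("show", "SystemCall", function(object) {
    cat(sprintf("SystemCall #%d %s on %s [%d-%d], %d member(s): %s\n",
                object@systemNumber, object@modelName, object@contig,
                object@start, object@end, nrow(object@members),
                paste(object@members$family, collapse = ", ")))
})

## ---- accessors --------------------------------------------------------

#' Accessors for defloc S4 objects
#'
#' Small accessor generics for the central classes: model identity and family
#' lists of a \linkS4class{SystemModel}; the feature table, contig table and
#' assembly id of a \linkS4class{Genome}; the member table and model name of
#' a \linkS4class{SystemCall}.
#'
#' @param x a \code{SystemModel}, \code{Genome} or \code{SystemCall}.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases modelName coreFamilies accessoryFamilies prohibitedFamilies
#'   features contigs assemblyId members systemNumber
NULL

#' @rdname accessors
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))
#' @rdname accessors
#' @export
setGeneric("coreFamilies", function(x) standardGeneric("coreFamilies"))
#' @rdname accessors
#' @export
setGeneric("accessoryFamilies",
           function(x) standardGeneric("accessoryFamilies"))
#' @rdname accessors
#' @export
setGeneric("prohibitedFamilies",
           function(x) standardGeneric("prohibitedFamilies"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname accessors
#' @export
setGeneric("assemblyId", function(x) standardGeneric("assemblyId"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("systemNumber", function(x) standardGeneric("systemNumber"))

#' @rdname accessors
setMethod("modelName", "SystemModel", function(x) x@name)
#' @rdname accessors
setMethod("modelName", "SystemCall", function(x) x@modelName)
#' @rdname accessors
setMethod("coreFamilies", "SystemModel", function(x) x@coreFamilies)
#' @rdname accessors
setMethod("accessoryFamilies", "SystemModel",
          function(x) x@accessoryFamilies)
#' @rdname accessors
setMethod("prohibitedFamilies", "SystemModel",
          function(x) x@prohibitedFamilies)
#' @rdname accessors
setMethod("features", "Genome", function(x) x@features)
#' @rdname accessors
setMethod("contigs", "Genome", function(x) x@contigs)
#' @rdname accessors
setMethod("assemblyId", "Genome", function(x) x@assemblyId)
#' @rdname accessors
setMethod("members", "SystemCall", function(x) x@members)
#' @rdname accessors
setMethod("systemNumber", "SystemCall", function(x) x@systemNumber)

## ---- constructors ------------------------------------------------------

#' Construct a SystemModel
#'
#' @param name model identifier; an \code{"_other"} suffix marks a relaxed
#'   model.
#' @param core character vector of core family tokens.
#' @param accessory,prohibited character vectors (may be empty).
#' @param minimum_core,minimum_total quorum counts; when \code{NULL} they
#'   default to "all core families required" (\code{length(core)}), the
#'   strictest reading in which any missing core gene rejects the system.
#' @param maximum_separation intervening-gene limit; default 4.
#' @param family grouping label; defaults to the name with any trailing
#'   \code{"_<subtype>"} or \code{"_other"} stripped.
#' @return a validated \linkS4class{SystemModel}.
#' @export
SystemModel <- function(name, core, accessory = character(),
                        prohibited = character(),
                        minimum_core = NULL, minimum_total = NULL,
                        maximum_separation = 4L, family = NULL) {
    core <- as.character(core)
    if (is.null(minimum_core)) minimum_core <- length(core)
    if (is.null(minimum_total)) minimum_total <- minimum_core
    if (is.null(family)) family <- sub("_[^_]+$", "", name)
    new("SystemModel",
        name = name,
        family = family,
        coreFamilies = core,
        accessoryFamilies = as.character(accessory),
        prohibitedFamilies = as.character(prohibited),
        minimumCore = as.integer(minimum_core),
        minimumTotal = as.integer(minimum_total),
        maximumSeparation = as.integer(maximum_separation),
        isOther = grepl("_other$", name))
}

## Build the canonical empty feature table; all Genome constructors funnel
## through this so column types stay consistent.
emptyFeatureTable <- function() {
    data.frame(
        contig = character(), locus_tag = character(),
        start = integer(), end = integer(), strand = character(),
        order_index = integer(), kind = character(),
        protein_seq = character(), pseudo_substituted = logical(),
        inference_accession = character(), family_token = character(),
        description = character(), stringsAsFactors = FALSE)
}

## Assign order_index per contig: features sorted by start, ties by end then
## locus_tag (determinism).  Returns the table re-ordered accordingly.
orderFeatures <- function(ft, contig_order) {
    if (!nrow(ft)) {
        ft$order_index <- integer()
        return(ft)
    }
    ft$contig <- as.character(ft$contig)
    contig_f <- factor(ft$contig, levels = contig_order)
    ord <- order(contig_f, ft$start, ft$end, ft$locus_tag)
    ft <- ft[ord, , drop = FALSE]
    ft$order_index <- as.integer(
        stats::ave(seq_len(nrow(ft)), ft$contig, FUN = seq_along) - 1L)
    rownames(ft) <- NULL
    ft
}

#' Construct a Genome
#'
#' @param assembly_id assembly identifier.
#' @param contigs data.frame with columns \code{contig} and \code{length}.
#' @param features feature data.frame; missing optional columns are filled
#'   with defaults and \code{order_index} is (re)assigned from coordinates.
#' @param sequence optional \code{DNAStringSet} of contig sequences.
#' @return a validated \linkS4class{Genome}.
#' @export
Genome <- function(assembly_id, contigs, features = emptyFeatureTable(),
                   sequence = NULL) {
    features <- as.data.frame(features, stringsAsFactors = FALSE)
    defaults <- list(protein_seq = NA_character_,
                     pseudo_substituted = FALSE,
                     inference_accession = NA_character_,
                     family_token = NA_character_,
                     description = NA_character_)
    for (col in names(defaults)) {
        if (is.null(features[[col]]))
            features[[col]] <- if (nrow(features))
                rep(defaults[[col]], nrow(features)) else defaults[[col]][0]
    }
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    features <- orderFeatures(features, as.character(contigs$contig))
    features <- features[, .FEATURE_COLUMNS, drop = FALSE]
    new("Genome", assemblyId = assembly_id,
        contigs = data.frame(contig = as.character(contigs$contig),
                             length = as.integer(contigs$length),
                             stringsAsFactors = FALSE),
        features = features,
        sequence = sequence)
}
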