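## Model database: system-definition YAML files + HMM metadata table.
##
## Layout of a database directory:
##   sys/<model_name>.yaml   one system definition per file
##   hmm_meta.txt            TSV: accession, original.name, protein.family,
##                           e.val.threshold, target.coverage.threshold,
##                           hmm.coverage.threshold, citation
##   hmm/                    concatenated HMMER3 text profiles

#' Load system-definition models from a database directory
#'
#' Reads every \code{sys/*.yaml} file under \code{db_dir} into a
#' \linkS4class{SystemModel}.  Each file holds flat keys: \code{core},
#' \code{accessory}, \code{prohibited} (lists of family tokens),
#' \code{minimum_core}, \code{minimum_total}, \code{maximum_separation} and
#' optionally \code{family}.  When quorum keys are omitted all core families
#' are required (a missing core gene then rejects the system); when
#' \code{maximum_separation} is omitted the global default applies.
#'
#' @param db_dir database directory containing a \code{sys/} subdirectory.
#' @param default_separation maximum intervening genes used for models that
#'   do not set their own; default 4.
#' @return list of \code{SystemModel}, sorted by name.
#' @examples
#' db <- makeToyDb(file.path(tempdir(), "toydb"))
#' models <- loadModels(file.path(tempdir(), "toydb"))
#' models[["DISARM_I"]]
#' @export
loadModels <- function(db_dir, default_separation = 4L) {
    sys_dir <- file.path(db_dir, "sys")
    if (!dir.exists(sys_dir))
        stop("no 'sys/' directory under ", db_dir)
    files <- list.files(sys_dir, pattern = "\\.ya?ml$", full.names = TRUE)
    if (!length(files))
        stop("no model definition files (*.yaml) under ", sys_dir)
    models <- lapply(files, function(f) {
        spec <- tryCatch(yaml::read_yaml(f), error = function(e)
            stop("malformed model file '", f, "': ", conditionMessage(e),
                 call. = FALSE))
        name <- spec$name
        if (is.null(name))
            name <- sub("\\.ya?ml$", "", basename(f))
        if (is.null(spec$core) || !length(spec$core))
            stop("validation error in model '", name,
                 "': no core families listed (file ", f, ")", call. = FALSE)
        sep <- spec$maximum_separation
        if (is.null(sep)) sep <- default_separation
        tryCatch(
            SystemModel(
                name = name,
                core = unlist(spec$core),
                accessory = unlist(spec$accessory),
                prohibited = unlist(spec$prohibited),
                minimum_core = spec$minimum_core,
                minimum_total = spec$minimum_total,
                maximum_separation = sep,
                family = spec$family),
            error = function(e)
                stop("validation error in model '", name, "' (file ", f,
                     "): ", conditionMessage(e), call. = FALSE))
    })
    names(models) <- vapply(models, modelName, character(1))
    models[order(names(models))]
}

#' Load the HMM metadata table
#'
#' Reads \code{hmm_meta.txt}, the tab-separated table mapping each profile
#' HMM accession to the protein family it evidences and to optional per-HMM
#' score thresholds that override the global defaults during hit filtering.
#' Several HMMs may evidence the same family (e.g. many clade-specific
#' profiles of one protein).  Unknown columns are ignored.
#'
#' @param path path to the TSV file (header row required; columns
#'   \code{accession}, \code{original.name}, \code{protein.family},
#'   \code{e.val.threshold}, \code{target.coverage.threshold},
#'   \code{hmm.coverage.threshold}, \code{citation}).
#' @return data.frame keyed by \code{accession} with columns
#'   \code{accession}, \code{original_name}, \code{protein_family},
#'   \code{evalue_max}, \code{target_cov_min}, \code{hmm_cov_min},
#'   \code{citation}; absent thresholds are \code{NA} (global defaults apply
#'   downstream).
#' @export
loadHmmMeta <- function(path) {
    if (!file.exists(path))
        stop("HMM metadata file not found: ", path)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             check.names = FALSE,
                             na.strings = c("NA", ""))
    required <- c("accession", "protein.family")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols))
        stop("hmm_meta is missing columns: ",
             paste(missing_cols, collapse = ", "))
    pick <- function(col) if (col %in% names(raw)) raw[[col]] else
        rep(NA, nrow(raw))
    meta <- data.frame(
        accession = as.character(raw$accession),
        original_name = as.character(pick("original.name")),
        protein_family = as.character(raw$protein.family),
        evalue_max = as.numeric(pick("e.val.threshold")),
        target_cov_min = as.numeric(pick("target.coverage.threshold")),
        hmm_cov_min = as.numeric(pick("hmm.coverage.threshold")),
        citation = as.character(pick("citation")),
        stringsAsFactors = FALSE)
    if (anyDuplicated(meta$accession))
        stop("duplicate HMM accession(s): ",
             paste(unique(meta$accession[duplicated(meta$accession)]),
                   collapse = ", "))
    if (any(is.na(meta$protein_family) | !nzchar(meta$protein_family)))
        stop("hmm_meta rows with missing protein.family: ",
             paste(meta$accession[is.na(meta$protein_family) |
                                  !nzchar(meta$protein_family)],
                   collapse = ", "))
    bad_cov <- function(x) !is.na(x) & (x < 0 | x > 1)
    if (any(bad_cov(meta$target_cov_min) | bad_cov(meta$hmm_cov_min)))
        stop("coverage thresholds must lie in [0, 1]")
    if (any(!is.na(meta$evalue_max) & !is.finite(meta$evalue_max)))
        stop("e.val.threshold must be finite")
    rownames(meta) <- meta$accession
    meta
}

#' Cross-validate models against the HMM metadata
#'
#' Reports every protein family token referenced by any model for which no
#' HMM provides evidence.  The non-protein tokens \code{"ncRNA"} and
#' \code{"CRISPR_array"} are exempt: they are contributed by covariance-model
#' and CRISPR-array detection, not by HMM search.  Findings are warnings
#' only; detection can still run (the uncovered family simply never labels a
#' gene).
#'
#' @param models list of \linkS4class{SystemModel} from \code{loadModels}.
#' @param meta HMM metadata data.frame from \code{loadHmmMeta}.
#' @return data.frame with columns \code{model} and \code{family}, one row
#'   per uncovered reference (zero rows when coverage is complete).
#' @export
crossValidateDb <- function(models, meta) {
    covered <- unique(meta$protein_family)
    rows <- lapply(models, function(m) {
        fams <- setdiff(
            unique(c(coreFamilies(m), accessoryFamilies(m),
                     prohibitedFamilies(m))),
            c(covered, .NONPROTEIN_TOKENS))
        if (!length(fams)) return(NULL)
        data.frame(model = modelName(m), family = fams,
                   stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, c(rows, list(
        data.frame(model = character(), family = character(),
                   stringsAsFactors = FALSE))))
    rownames(report) <- NULL
    if (nrow(report))
        warning("model families with no evidencing HMM: ",
                paste(sprintf("%s (%s)", report$family, report$model),
                      collapse = ", "), call. = FALSE)
    report
}
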