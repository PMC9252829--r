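## Toy GenBank flat-file builder for annotation-input tests.  Records are
## assembled from explicit feature descriptions so GFF-equivalent pairs can
## be written for the same data.

foldQualifier <- function(key, value, indent = 21L) {
    line <- sprintf("/%s=\"%s\"", key, value)
    out <- character()
    while (nchar(line) > 0) {
        out <- c(out, paste0(strrep(" ", indent), substr(line, 1, 58)))
        line <- substr(line, 59, nchar(line))
    }
    out
}

## features: list of list(location=, locus_tag=, translation=NULL,
##                        pseudo=FALSE, inference=NULL, product=NULL)
writeToyGenbank <- function(path, contig = "ctgA", length = 5000L,
                            features = list(), sequence = NULL,
                            comment = NULL) {
    lines <- c(sprintf(
        "LOCUS       %s                 %d bp    DNA     linear   BCT 01-JAN-2024",
        contig, length),
        "DEFINITION  synthetic toy record.",
        if (!is.null(comment)) c("COMMENT     ", paste0("            ",
                                                        comment)),
        "FEATURES             Location/Qualifiers",
        sprintf("     source          1..%d", length))
    for (f in features) {
        lines <- c(lines, sprintf("     CDS             %s", f$location))
        lines <- c(lines, foldQualifier("locus_tag", f$locus_tag))
        if (!is.null(f$product))
            lines <- c(lines, foldQualifier("product", f$product))
        if (isTRUE(f$pseudo))
            lines <- c(lines, "                     /pseudo")
        if (!is.null(f$inference))
            lines <- c(lines, foldQualifier("inference", f$inference))
        if (!is.null(f$translation))
            lines <- c(lines, foldQualifier("translation", f$translation))
    }
    if (!is.null(sequence)) {
        lines <- c(lines, "ORIGIN")
        seq <- tolower(sequence)
        for (i in seq(1, nchar(seq), by = 60)) {
            chunk <- substr(seq, i, min(i + 59, nchar(seq)))
            blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                                pmin(seq(10, nchar(chunk) + 9, 10),
                                     nchar(chunk)))
            lines <- c(lines, sprintf("%9d %s", i,
                                      paste(blocks, collapse = " ")))
        }
    }
    lines <- c(lines, "//")
    writeLines(lines, path)
    path
}

randomProtein <- function(n) paste(
    sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
             "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
    collapse = "")
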