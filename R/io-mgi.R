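#' Read lethality flags from an MGI phenotype report
#'
#' Scans a tab-delimited MGI phenotypic-allele style report and flags a
#' gene as essential (lethal) whenever any of its rows' phenotype text
#' contains the substring \code{"lethality"}, case-insensitively. Rows with
#' too few columns are skipped with a warning. One record per gene symbol
#' is returned, duplicates collapsed by logical OR. Which columns hold the
#' gene symbol and the phenotype text varies across MGI report versions, so
#' both indices are arguments.
#'
#' @param path path to the tab-delimited report; lines starting with
#'   \code{#} are ignored.
#' @param symbolCol 1-based index of the gene-symbol column.
#' @param phenotypeCol 1-based index of the phenotype-description column.
#' @return data.frame with columns \code{gene_symbol} (character) and
#'   \code{is_lethal} (logical).
#' @examples
#' tf <- tempfile()
#' writeLines(c("Kl\tpreweaning lethality", "Actb\tabnormal gait"), tf)
#' readMgiLethality(tf, symbolCol = 1, phenotypeCol = 2)
#' @export
readMgiLethality <- function(path, symbolCol = 7L, phenotypeCol = 11L) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    need <- max(symbolCol, phenotypeCol)
    ok <- lengths(parts) >= need
    if (any(!ok))
        warning(sum(!ok), " malformed row(s) skipped in ", basename(path))
    sym <- vapply(parts[ok], `[[`, character(1), symbolCol)
    phen <- vapply(parts[ok], `[[`, character(1), phenotypeCol)
    lethal <- grepl("lethality", phen, ignore.case = TRUE)
    keep <- nzchar(sym)
    agg <- tapply(lethal[keep], sym[keep], any)
    data.frame(gene_symbol = names(agg),
               is_lethal = as.logical(agg),
               row.names = NULL, stringsAsFactors = FALSE)
}
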