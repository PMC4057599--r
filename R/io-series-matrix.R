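#' Read a GEO series-matrix (or bare TSV) expression table
#'
#' Parses the probe-by-sample table of a GEO Series Matrix file and splits
#' its columns into one \linkS4class{StateExpression} per biological state.
#' The table is located between the \code{!series_matrix_table_begin} /
#' \code{!series_matrix_table_end} marker lines; when no markers are present
#' the file is treated as a bare tab-separated table (first column = probe
#' identifier, lines starting with \code{!} or \code{#} ignored), so
#' synthetic fixtures and real downloads go through one reader. Values are
#' used exactly as printed — no re-normalisation. Probes with a missing or
#' blank value in any selected column of a state are dropped from that
#' state's matrix only; probe identifiers (including redundant probes for
#' one gene) are kept verbatim.
#'
#' @param path path to the series-matrix or TSV file.
#' @param sampleGroups named list mapping each state label to the sample
#'   (column) identifiers belonging to it.
#' @return Named list of \linkS4class{StateExpression}, one per state.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("ID_REF\ts1\ts2\ts3\ts4",
#'              "p1\t1\t2\t3\t4", "p2\t2\t1\t4\t3"), tf)
#' mats <- readSeriesMatrix(tf, list(A = c("s1", "s2"), B = c("s3", "s4")))
#' dim(mats$A)
#' @export
readSeriesMatrix <- function(path, sampleGroups) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (!is.list(sampleGroups) || is.null(names(sampleGroups)) ||
        !all(nzchar(names(sampleGroups))))
        stop("'sampleGroups' must be a named list of sample-id vectors")
    lines <- readLines(path, warn = FALSE)
    begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(begin) == 1L && length(end) == 1L) {
        if (end <= begin + 1L)
            stop("series-matrix table markers enclose no table")
        tbl <- lines[(begin + 1L):(end - 1L)]
    } else if (length(begin) == 0L && length(end) == 0L) {
        tbl <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
        if (length(tbl) < 2L)
            stop("no expression table found in ", path)
    } else {
        stop("unbalanced series-matrix table markers in ", path)
    }
    df <- utils::read.delim(text = tbl, header = TRUE, sep = "\t",
        quote = "\"", check.names = FALSE, colClasses = "character",
        blank.lines.skip = TRUE)
    probes <- df[[1L]]
    samples <- colnames(df)[-1L]
    if (anyDuplicated(probes))
        stop("duplicate probe identifiers in table")
    missing_ids <- setdiff(unlist(sampleGroups, use.names = FALSE), samples)
    if (length(missing_ids))
        stop("sample id(s) not present in table header: ",
             paste(missing_ids, collapse = ", "))
    out <- lapply(names(sampleGroups), function(state) {
        cols <- as.character(sampleGroups[[state]])
        sub <- df[, cols, drop = FALSE]
        vals <- suppressWarnings(
            vapply(sub, as.numeric, numeric(nrow(sub))))
        if (nrow(sub) == 1L) vals <- matrix(vals, nrow = 1L,
            dimnames = list(NULL, cols))
        blank <- vapply(sub, function(x) !nzchar(trimws(x)), logical(nrow(sub)))
        if (nrow(sub) == 1L) blank <- matrix(blank, nrow = 1L)
        keep <- rowSums(is.na(vals) | blank) == 0L
        if (!any(keep))
            warning("state '", state, "': every probe has missing values")
        StateExpression(vals[keep, , drop = FALSE], state,
            probeIds = probes[keep], sampleIds = cols)
    })
    stats::setNames(out, names(sampleGroups))
}

#' Write a StateExpression as a series-matrix or bare TSV file
#'
#' Serialises the expression table in either the marker-delimited GEO
#' dialect (with quoted identifiers, as downloaded files have) or as a bare
#' TSV; both are accepted back by \code{\link{readSeriesMatrix}}.
#'
#' @param x a \linkS4class{StateExpression}, or a named list of them to be
#'   written side by side (columns concatenated; shared probes only).
#' @param path output file path.
#' @param geoStyle logical; write marker lines and quoted identifiers.
#' @return Invisibly, \code{path}.
#' @export
writeSeriesMatrix <- function(x, path, geoStyle = TRUE) {
    if (is(x, "StateExpression")) x <- list(x)
    mats <- lapply(x, exprsValues)
    probes <- Reduce(intersect, lapply(mats, rownames))
    m <- do.call(cbind, lapply(mats, function(v) v[probes, , drop = FALSE]))
    con <- file(path, "w")
    on.exit(close(con))
    q <- function(v) if (geoStyle) paste0('"', v, '"') else v
    if (geoStyle) {
        writeLines(c("!Series_title\t\"synthetic two-state fixture\"",
                     "!series_matrix_table_begin"), con)
    }
    writeLines(paste(c(q("ID_REF"), q(colnames(m))), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(m)), function(i)
        paste(c(q(probes[i]),
                format(m[i, ], trim = TRUE, digits = 15)), collapse = "\t"),
        character(1))
    writeLines(body, con)
    if (geoStyle) writeLines("!series_matrix_table_end", con)
    invisible(path)
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path tab-separated file with gene symbol in column 1 and term
#'   identifier in column 2; lines starting with \code{!} or \code{#} are
#'   ignored.
#' @return data.frame with columns \code{gene} and \code{term}, duplicates
#'   removed.
#' @export
readGeneTerms <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^[!#]", lines) & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2L
    if (any(!ok))
        warning(sum(!ok), " malformed annotation line(s) skipped")
    df <- data.frame(
        gene = vapply(parts[ok], `[[`, character(1), 1L),
        term = vapply(parts[ok], `[[`, character(1), 2L),
        stringsAsFactors = FALSE)
    unique(df)
}
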