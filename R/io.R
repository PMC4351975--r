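#' Read a probes x samples expression table
#'
#' Tab-delimited text with a header row of sample IDs and the probe ID in
#' the first column; comment lines starting with '#' are skipped. Ragged
#' rows, duplicate probe or sample IDs and non-numeric cells are rejected
#' with the offending line or probe named.
#'
#' @param path input file.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    if (!length(lines)) stop("empty file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nc <- lengths(fields)
    if (any(nc != nc[1]))
        stop("ragged row at line ", which(nc != nc[1])[1], " of ", path)
    header <- fields[[1]]
    sampleIds <- header[-1]
    if (anyDuplicated(sampleIds))
        stop("duplicate sample ID: ",
             sampleIds[duplicated(sampleIds)][1])
    body <- fields[-1]
    probeIds <- vapply(body, `[[`, character(1), 1)
    if (anyDuplicated(probeIds))
        stop("duplicate probe ID: ", probeIds[duplicated(probeIds)][1])
    vals <- vapply(body, function(f) {
        v <- suppressWarnings(as.numeric(f[-1]))
        v
    }, numeric(length(sampleIds)))
    x <- t(rbind(vals))
    if (anyNA(x)) {
        bad <- which(apply(is.na(x), 1, any))[1]
        stop("non-numeric cell at line ", bad + 1, " of ", path)
    }
    dimnames(x) <- list(probeIds, sampleIds)
    x
}

#' Write a probes x samples matrix as tab-delimited text
#'
#' First column \code{probe_id}, header row of sample IDs; optional
#' comment header lines (prefixed with '#') record parameters.
#'
#' @param x numeric matrix.
#' @param path output file.
#' @param comments character vector of comment lines (without the '#').
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path, comments = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comments))
        writeLines(paste0("# ", comments), con)
    writeLines(paste(c("probe_id", colnames(x)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(x)), function(i)
        paste(c(rownames(x)[i],
                format(x[i, ], digits = 15, trim = TRUE,
                       scientific = FALSE)),
              collapse = "\t"), character(1))
    writeLines(body, con)
    invisible(path)
}

#' Write a result data.frame as tab-delimited text
#'
#' @param df data.frame.
#' @param path output file.
#' @param comments optional comment lines recording parameters.
#' @return invisibly, \code{path}.
#' @export
writeResultTable <- function(df, path, comments = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comments))
        writeLines(paste0("# ", comments), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a tab-delimited result table (skipping comment lines)
#'
#' @param path input file.
#' @return data.frame.
#' @export
readResultTable <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a module partition as two-column text
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param path output file.
#' @param comments optional comment lines.
#' @return invisibly, \code{path}.
#' @export
writePartition <- function(partition, path, comments = NULL) {
    lab <- moduleLabels(partition)
    writeResultTable(data.frame(probe_id = names(lab),
                                module = unname(lab)),
                     path, comments)
}

#' Read a module partition written by \code{writePartition}
#'
#' @param path input file.
#' @param minModuleSize recorded minimum module size.
#' @return a \linkS4class{ModulePartition}.
#' @export
readPartition <- function(path, minModuleSize = 2) {
    df <- readResultTable(path)
    new("ModulePartition",
        labels = setNames(df$module, df$probe_id),
        minModuleSize = as.integer(minModuleSize))
}
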