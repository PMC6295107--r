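#' Read a phenotype table
#'
#' TSV/CSV with a header; must contain the sample id, time and status
#' columns. Declared covariate columns are coerced to numeric. Row order
#' is preserved.
#'
#' @param path file path (tab-separated unless the extension is `.csv`).
#' @param idCol,timeCol,statusCol column names.
#' @param covariateCols covariate column names (default: every other
#'   column).
#' @return data frame with columns `sample_id`, `time`, `status` and the
#'   covariates.
#' @export
readPhenotypes <- function(path, idCol = "sample_id", timeCol = "time",
                           statusCol = "status", covariateCols = NULL) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    for (nm in c(idCol, timeCol, statusCol))
        if (!nm %in% colnames(df))
            stopf("phenotype file lacks column '%s'", nm)
    if (is.null(covariateCols))
        covariateCols <- setdiff(colnames(df),
                                 c(idCol, timeCol, statusCol))
    tm <- suppressWarnings(as.numeric(df[[timeCol]]))
    bad <- which(is.na(tm) & !is.na(df[[timeCol]]))
    if (length(bad))
        stopf("non-numeric time at row %d", bad[1])
    if (any(is.na(tm)) || any(tm <= 0))
        stopf("time must be numeric and strictly positive (row %d)",
              which(is.na(tm) | tm <= 0)[1])
    st <- df[[statusCol]]
    if (!all(st %in% c(0, 1)))
        stopf("status must be 0 or 1 (row %d)",
              which(!st %in% c(0, 1))[1])
    out <- data.frame(sample_id = as.character(df[[idCol]]),
                      time = tm, status = as.integer(st),
                      stringsAsFactors = FALSE)
    for (nm in covariateCols) {
        v <- suppressWarnings(as.numeric(df[[nm]]))
        if (any(is.na(v) & !is.na(df[[nm]])))
            stopf("non-numeric covariate '%s'", nm)
        out[[nm]] <- v
    }
    out
}

#' Read a genotype table
#'
#' TSV/CSV with a `sample_id` column followed by one column per SNP,
#' additively coded 0/1/2 with `NA` allowed.
#'
#' @param path file path.
#' @param idCol sample id column name.
#' @return numeric matrix (subjects x SNPs) with sample ids as row names.
#' @export
readGenotypes <- function(path, idCol = "sample_id") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!idCol %in% colnames(df))
        stopf("genotype file lacks column '%s'", idCol)
    ids <- as.character(df[[idCol]])
    g <- as.matrix(df[, setdiff(colnames(df), idCol), drop = FALSE])
    storage.mode(g) <- "numeric"
    bad <- which(!(g %in% c(0, 1, 2)) & !is.na(g), arr.ind = TRUE)
    if (nrow(bad))
        stopf("invalid genotype value at (row %d, %s)", bad[1, 1],
              colnames(g)[bad[1, 2]])
    storage.mode(g) <- "integer"
    rownames(g) <- ids
    g
}

#' Read and join genotype and phenotype files
#'
#' Joins by sample id (never by row order); subjects present in only one
#' file are dropped with a warning reporting the count.
#'
#' @param genoPath,phenoPath file paths.
#' @param ... passed to [readPhenotypes()].
#' @return a [SnpSurvivalExperiment-class].
#' @export
readSurvivalData <- function(genoPath, phenoPath, ...) {
    ph <- readPhenotypes(phenoPath, ...)
    g <- readGenotypes(genoPath)
    common <- intersect(ph$sample_id, rownames(g))
    dropped <- length(union(ph$sample_id, rownames(g))) - length(common)
    if (dropped > 0)
        warning(sprintf("%d subject(s) present in only one file dropped",
                        dropped), call. = FALSE)
    if (!length(common)) stopf("no common sample ids")
    ph <- ph[match(common, ph$sample_id), , drop = FALSE]
    covs <- ph[, setdiff(colnames(ph), c("sample_id", "time", "status")),
               drop = FALSE]
    SnpSurvivalExperiment(g[common, , drop = FALSE],
                          time = ph$time, status = ph$status,
                          covariates = if (ncol(covs)) covs else NULL,
                          sampleIds = common)
}

#' Write scan results to a TSV file
#'
#' One row per SNP combination with columns `snp1..snpk`, `beta`, `se`,
#' `W`, `q_hat`, `p_raw`, `p_corrected`, `p_bonferroni`, `rank`, sorted
#' by corrected p-value (ties broken lexicographically by SNP names).
#'
#' @param scan an [UMMDRScan-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeResults <- function(scan, path) {
    stopifnot(methods::is(scan, "UMMDRScan"))
    if (!nrow(scan@results)) stopf("empty result set; nothing written")
    r <- resultsTable(scan)
    df <- as.data.frame(r)
    snpCols <- grep("^snp[0-9]+$", colnames(df), value = TRUE)
    out <- df[, c(snpCols, "beta", "se", "W", "qHat", "pRaw",
                  "pCorrected", "pBonferroni", "rank")]
    colnames(out) <- c(snpCols, "beta", "se", "W", "q_hat", "p_raw",
                       "p_corrected", "p_bonferroni", "rank")
    writeTsv(out, path)
    invisible(path)
}

writeTsv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1)) &
        !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Write a dataset as genotype + phenotype TSV files
#'
#' The inverse of [readSurvivalData()]: numeric values are written with 12
#' significant digits so a write/read round trip reproduces the dataset.
#'
#' @param x a [SnpSurvivalExperiment-class].
#' @param genoPath,phenoPath output paths.
#' @return invisibly, the two paths.
#' @export
writeSurvivalData <- function(x, genoPath, phenoPath) {
    ids <- colnames(x)
    g <- data.frame(sample_id = ids, genotypeMatrix(x),
                    check.names = FALSE)
    writeTsv(g, genoPath)
    covs <- covariateMatrix(x)
    ph <- data.frame(sample_id = ids, time = survTime(x),
                     status = eventStatus(x), check.names = FALSE)
    for (nm in colnames(covs)) ph[[nm]] <- covs[, nm]
    writeTsv(ph, phenoPath)
    invisible(c(genoPath, phenoPath))
}

#' Read run configuration from YAML or JSON
#'
#' Flat keys matching the [ummdrControl()] arguments.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return an `ummdrControl` list.
#' @export
readRunConfig <- function(path) {
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    known <- names(formals(ummdrControl))
    unknown <- setdiff(names(cfg), known)
    if (length(unknown))
        stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
    do.call(ummdrControl, cfg)
}
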