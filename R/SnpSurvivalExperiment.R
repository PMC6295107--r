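#' Construct a SnpSurvivalExperiment
#'
#' Bundles an additively coded genotype matrix with survival follow-up and
#' adjusting covariates into a single validated container (a
#' \linkS4class{SummarizedExperiment} with SNPs as rows and subjects as
#' columns).
#'
#' @param genotypes numeric matrix of minor-allele counts, subjects in rows
#'   and SNPs in columns; entries must be 0, 1, 2 or `NA`. Column names are
#'   the SNP identifiers.
#' @param time positive numeric vector of observed times (event or
#'   censoring), one per subject.
#' @param status event indicator per subject: 1 = event, 0 = censored.
#' @param covariates optional numeric matrix or data frame of adjusting
#'   covariates (one row per subject).
#' @param sampleIds optional subject identifiers; defaults to the genotype
#'   row names, or `s1..sn`.
#'
#' @return a [SnpSurvivalExperiment-class] object.
#'
#' @examples
#' g <- matrix(rbinom(40, 2, 0.3), nrow = 10,
#'             dimnames = list(NULL, paste0("rs", 1:4)))
#' x <- SnpSurvivalExperiment(g, time = rexp(10) + 0.1,
#'                            status = rbinom(10, 1, 0.7),
#'                            covariates = data.frame(z = rnorm(10)))
#' survTime(x)
#' dim(genotypeMatrix(x))
#' @export
SnpSurvivalExperiment <- function(genotypes, time, status, covariates = NULL,
                                  sampleIds = NULL) {
    genotypes <- as.matrix(genotypes)
    n <- nrow(genotypes)
    if (is.null(colnames(genotypes)))
        colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
    if (is.null(sampleIds))
        sampleIds <- rownames(genotypes)
    if (is.null(sampleIds))
        sampleIds <- paste0("s", seq_len(n))
    sampleIds <- as.character(sampleIds)
    if (length(time) != n || length(status) != n || length(sampleIds) != n)
        stopf("time, status, sampleIds and genotype rows must all have length %d", n)
    cd <- S4Vectors::DataFrame(time = as.numeric(time),
                               status = as.integer(status),
                               row.names = sampleIds)
    covNames <- character()
    if (!is.null(covariates)) {
        covariates <- as.data.frame(covariates)
        if (nrow(covariates) != n)
            stopf("covariates must have %d rows", n)
        nonnum <- !vapply(covariates, is.numeric, logical(1))
        if (any(nonnum))
            stopf("non-numeric covariate column(s): %s",
                  paste(names(covariates)[nonnum], collapse = ", "))
        covNames <- colnames(covariates)
        for (nm in covNames) cd[[nm]] <- as.numeric(covariates[[nm]])
    }
    gm <- t(genotypes)
    colnames(gm) <- sampleIds
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(genotype = gm), colData = cd)
    S4Vectors::metadata(se)$covariateNames <- covNames
    methods::new("SnpSurvivalExperiment", se)
}

#' @rdname SnpSurvivalExperiment
#' @export
setMethod("survTime", "SnpSurvivalExperiment", function(x)
    SummarizedExperiment::colData(x)$time)

#' @rdname SnpSurvivalExperiment
#' @export
setMethod("eventStatus", "SnpSurvivalExperiment", function(x)
    SummarizedExperiment::colData(x)$status)

#' @rdname SnpSurvivalExperiment
#' @export
setMethod("covariateMatrix", "SnpSurvivalExperiment", function(x) {
    cn <- S4Vectors::metadata(x)$covariateNames
    cd <- SummarizedExperiment::colData(x)
    m <- matrix(0, nrow = nrow(cd), ncol = length(cn),
                dimnames = list(rownames(cd), cn))
    for (nm in cn) m[, nm] <- cd[[nm]]
    m
})

#' @rdname SnpSurvivalExperiment
#' @export
setMethod("genotypeMatrix", "SnpSurvivalExperiment", function(x)
    t(SummarizedExperiment::assay(x, "genotype")))

#' @rdname SnpSurvivalExperiment
#' @export
setMethod("snpNames", "SnpSurvivalExperiment", function(x) rownames(x))

setMethod("show", "SnpSurvivalExperiment", function(object) {
    st <- eventStatus(object)
    cat(sprintf("SnpSurvivalExperiment: %d subjects x %d SNPs\n",
                ncol(object), nrow(object)))
    cat(sprintf("  events: %d, censored: %d (%.1f%%)\n",
                sum(st == 1), sum(st == 0),
                100 * mean(st == 0)))
    cn <- S4Vectors::metadata(object)$covariateNames
    cat("  covariates:",
        if (length(cn)) paste(cn, collapse = ", ") else "(none)", "\n")
})
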