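#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DataFrame
NULL

#' SNP genotypes with a censored survival phenotype
#'
#' A \linkS4class{SummarizedExperiment} whose single assay, `"genotype"`,
#' holds additively coded SNP genotypes (0/1/2 minor-allele counts, `NA`
#' allowed) with SNPs as rows and subjects as columns. Survival follow-up
#' time (`time`, strictly positive), the event indicator (`status`, 1 =
#' event, 0 = censored) and any adjusting covariates live in `colData`;
#' the covariate column names are recorded in
#' `metadata(x)$covariateNames`.
#'
#' @seealso [SnpSurvivalExperiment()] for construction from plain matrices,
#'   [readSurvivalData()] for construction from TSV files.
#' @export
setClass("SnpSurvivalExperiment", contains = "SummarizedExperiment")

setValidity("SnpSurvivalExperiment", function(object) {
    msg <- character()
    if (!"genotype" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'genotype' is required")
    else {
        g <- SummarizedExperiment::assay(object, "genotype")
        bad <- !(g %in% c(0, 1, 2)) & !is.na(g)
        if (any(bad))
            msg <- c(msg, "genotype entries must be 0, 1, 2 or NA")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("time", "status") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'time' and 'status'")
    } else {
        tm <- cd$time
        st <- cd$status
        if (!is.numeric(tm) || any(!is.finite(tm)) || any(tm <= 0))
            msg <- c(msg, "time must be finite and strictly positive")
        if (!all(st %in% c(0, 1)))
            msg <- c(msg, "status must be 0 or 1")
    }
    cn <- S4Vectors::metadata(object)$covariateNames
    if (length(cn) && !all(cn %in% colnames(cd)))
        msg <- c(msg, "covariateNames not all present in colData")
    if (length(msg)) msg else TRUE
})

#' Fitted Cox proportional hazards model
#'
#' Breslow-ties partial-likelihood fit. `covariance` is the inverse of the
#' observed information at the maximum. A non-converged fit (monotone
#' likelihood / separation) carries capped coefficients and
#' `converged = FALSE`.
#'
#' @slot coefficients named numeric vector of log hazard ratios.
#' @slot covariance estimated covariance matrix of the coefficients.
#' @slot loglik maximized partial log-likelihood.
#' @slot converged logical convergence flag.
#' @slot nEvents number of events used in the fit.
#' @slot n number of subjects used in the fit.
#' @export
setClass("CoxFit", representation(
    coefficients = "numeric",
    covariance = "matrix",
    loglik = "numeric",
    converged = "logical",
    nEvents = "integer",
    n = "integer"
))

setValidity("CoxFit", function(object) {
    p <- length(object@coefficients)
    if (!all(dim(object@covariance) == c(p, p)))
        return("covariance dimension does not match coefficients")
    d <- diag(object@covariance)
    if (any(is.finite(d) & d < -1e-8))
        return("covariance diagonal must be nonnegative")
    TRUE
})

#' Nelson-Aalen / Breslow cumulative hazard
#'
#' A right-continuous step function: `values[i]` is the cumulative hazard
#' at `eventTimes[i]`, with value 0 before the first event time. Evaluate
#' at arbitrary times with [cumhazAt()].
#'
#' @slot eventTimes strictly increasing positive event times.
#' @slot values nondecreasing nonnegative cumulative hazard values.
#' @export
setClass("CumHazard", representation(
    eventTimes = "numeric",
    values = "numeric"
))

setValidity("CumHazard", function(object) {
    if (length(object@eventTimes) != length(object@values))
        return("eventTimes and values must have equal length")
    if (is.unsorted(object@eventTimes, strictly = TRUE))
        return("eventTimes must be strictly increasing")
    if (any(diff(c(0, object@values)) < -1e-12))
        return("values must be nondecreasing and nonnegative")
    TRUE
})

#' Genotype cell table for one SNP combination
#'
#' Partition of the (non-missing) subjects into the 3^k genotype cells of a
#' k-SNP combination, with the martingale-residual sum and subject count
#' per cell. Cells are indexed in row-major order of the genotype tuples
#' (0,...,0), (0,...,1), ..., (2,...,2).
#'
#' @slot combination the k SNP names.
#' @slot cellIndex per-subject cell index in 1..3^k (NA when the subject is
#'   missing a genotype in the combination).
#' @slot counts subject count per cell.
#' @slot residualSums martingale-residual sum per cell.
#' @slot tuples genotype tuple label per cell, e.g. "1|2".
#' @export
setClass("CellTable", representation(
    combination = "character",
    cellIndex = "integer",
    counts = "integer",
    residualSums = "numeric",
    tuples = "character"
))

setValidity("CellTable", function(object) {
    ncell <- 3L^length(object@combination)
    if (length(object@counts) != ncell ||
        length(object@residualSums) != ncell ||
        length(object@tuples) != ncell)
        return("cell vectors must have length 3^k")
    if (sum(object@counts) != sum(!is.na(object@cellIndex)))
        return("counts must partition the non-missing subjects")
    TRUE
})

#' High/low-risk labeling of genotype cells
#'
#' MDR-style reduction of a [CellTable-class]: each cell is labeled
#' high-risk (`"H"`) when its residual sum is strictly positive, low-risk
#' (`"L"`) otherwise (ties and empty cells are low). `S` is the per-subject
#' indicator: 1 for subjects in a high-risk cell, 0 in a low-risk cell, NA
#' for subjects missing a genotype in the combination.
#'
#' @slot combination the k SNP names.
#' @slot label per-cell "H"/"L" label.
#' @slot S per-subject high-risk indicator.
#' @slot nHighCells number of cells labeled "H".
#' @export
setClass("RiskLabeling", representation(
    combination = "character",
    label = "character",
    S = "integer",
    nHighCells = "integer"
))

setValidity("RiskLabeling", function(object) {
    if (!all(object@label %in% c("H", "L")))
        return("labels must be 'H' or 'L'")
    if (!all(object@S %in% c(0L, 1L) | is.na(object@S)))
        return("S must be 0, 1 or NA")
    if (object@nHighCells != sum(object@label == "H"))
        return("nHighCells inconsistent with labels")
    TRUE
})

#' Results of a Cox UM-MDR scan
#'
#' One row per evaluated SNP combination: the step-2 Wald test of the
#' high-risk indicator, the estimated non-centrality, raw and corrected
#' p-values, the Bonferroni-adjusted corrected p-value and the rank by
#' corrected p-value.
#'
#' @slot results a [S4Vectors::DataFrame] with columns `snp1..snpk`,
#'   `beta`, `se`, `W`, `qHat`, `pRaw`, `pCorrected`, `pBonferroni`,
#'   `rank`, `degenerate`.
#' @slot control the [ummdrControl()] list used for the scan.
#' @export
setClass("UMMDRScan", representation(
    results = "DataFrame",
    control = "list"
))

#' Two-locus penetrance model
#'
#' A 3x3 matrix of penetrances \eqn{f_{ik} = P(\mathrm{high\ risk} \mid
#' SNP1 = i, SNP2 = k)} with no single-locus marginal effect (pure
#' epistasis), together with the minor allele frequency used for the HWE
#' genotype weights, the implied prevalence \eqn{K} and the heritability
#' \eqn{h^2 = \sum_{ik} P(G_{ik}) (f_{ik} - K)^2 / (K (1 - K))}.
#'
#' @slot f 3x3 penetrance matrix (rows: SNP1 genotype 0/1/2; columns:
#'   SNP2 genotype 0/1/2).
#' @slot maf minor allele frequency shared by the two loci.
#' @slot K prevalence (HWE-weighted mean penetrance).
#' @slot h2 heritability.
#' @export
setClass("PenetranceModel", representation(
    f = "matrix",
    maf = "numeric",
    K = "numeric",
    h2 = "numeric"
))

setValidity("PenetranceModel", function(object) {
    if (!all(dim(object@f) == c(3, 3)))
        return("f must be 3x3")
    if (any(object@f < -1e-12) || any(object@f > 1 + 1e-12))
        return("penetrances must lie in [0,1]")
    if (object@maf <= 0 || object@maf > 0.5)
        return("maf must be in (0, 0.5]")
    TRUE
})

#' Cox-MDR cross-validated best-pair selection
#'
#' @slot bestPair the selected SNP pair.
#' @slot cvScore mean balanced testing accuracy of the best pair over folds.
#' @slot cvConsistency number of folds whose training-best pair equals the
#'   overall best pair.
#' @slot nFolds number of cross-validation folds.
#' @slot scores per-pair DataFrame of mean testing score and consistency.
#' @export
setClass("CVSelection", representation(
    bestPair = "character",
    cvScore = "numeric",
    cvConsistency = "integer",
    nFolds = "integer",
    scores = "DataFrame"
))
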