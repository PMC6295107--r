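#' Enumerate SNP combinations
#'
#' All \eqn{\binom{m}{k}} unordered combinations of `k` SNPs, in
#' lexicographic order of SNP names.
#'
#' @param snpNames character vector of SNP names.
#' @param k combination order (number of SNPs per combination).
#' @return character matrix with one row per combination and `k` columns.
#' @examples
#' nrow(enumerateCombinations(paste0("rs", 1:10), 2))  # 45
#' @export
enumerateCombinations <- function(snpNames, k) {
    k <- as.integer(k)
    m <- length(snpNames)
    if (k < 1L) stopf("k must be >= 1")
    if (k > m) stopf("k = %d exceeds the number of SNPs (%d)", k, m)
    t(utils::combn(sort(snpNames), k))
}

# Row-major cell index for a genotype submatrix (subjects x k), 1..3^k,
# NA when any genotype in the combination is missing.
cellIndexFor <- function(G) {
    k <- ncol(G)
    idx <- as.integer(G %*% (3^((k - 1):0))) + 1L
    idx
}

cellTuples <- function(k) {
    vapply(0:(3L^k - 1L), function(i) {
        digits <- integer(k)
        for (j in k:1) {
            digits[j] <- i %% 3L
            i <- i %/% 3L
        }
        paste(digits, collapse = "|")
    }, character(1))
}

#' Build the genotype cell table for a SNP combination
#'
#' Assigns every subject with complete genotypes in the combination to one
#' of the 3^k genotype cells and accumulates the per-cell sum of the
#' supplied martingale residuals. Subjects missing a genotype in the
#' combination are excluded for this combination only.
#'
#' @param x a [SnpSurvivalExperiment-class].
#' @param combination character vector of k SNP names.
#' @param residuals per-subject martingale residuals (defaults to
#'   baseline-only residuals computed from `x`).
#' @return a [CellTable-class].
#' @export
buildCells <- function(x, combination,
                       residuals = martingaleResiduals(x)) {
    geno <- genotypeMatrix(x)
    missing <- setdiff(combination, colnames(geno))
    if (length(missing))
        stopf("unknown SNP name(s): %s", paste(missing, collapse = ", "))
    G <- geno[, combination, drop = FALSE]
    idx <- cellIndexFor(G)
    k <- length(combination)
    ncell <- 3L^k
    ok <- !is.na(idx)
    counts <- tabulate(idx[ok], nbins = ncell)
    sums <- numeric(ncell)
    if (any(ok)) {
        s <- rowsum(residuals[ok], idx[ok])
        sums[as.integer(rownames(s))] <- s[, 1]
    }
    methods::new("CellTable", combination = as.character(combination),
                 cellIndex = idx, counts = as.integer(counts),
                 residualSums = sums, tuples = cellTuples(k))
}

#' Classify genotype cells into high and low risk
#'
#' The MDR reduction step: a cell is labeled high-risk (`"H"`) when its
#' martingale-residual sum is strictly positive — its subjects experienced
#' more events than the null model predicts — and low-risk (`"L"`)
#' otherwise. A residual sum of exactly zero carries no evidence of
#' elevated risk, so ties and empty cells are low-risk. The per-subject
#' indicator `S` is 1 in high-risk cells and 0 in low-risk cells.
#'
#' @param cells a [CellTable-class].
#' @return a [RiskLabeling-class].
#' @export
classifyCells <- function(cells) {
    stopifnot(methods::is(cells, "CellTable"))
    high <- cells@residualSums > 0
    label <- ifelse(high, "H", "L")
    S <- ifelse(is.na(cells@cellIndex), NA_integer_,
                as.integer(high[cells@cellIndex]))
    methods::new("RiskLabeling", combination = cells@combination,
                 label = label, S = S, nHighCells = sum(high))
}

setMethod("show", "CellTable", function(object) {
    cat(sprintf("CellTable for (%s): %d/%d non-empty cells, %d subjects\n",
                paste(object@combination, collapse = ", "),
                sum(object@counts > 0), length(object@counts),
                sum(object@counts)))
})

setMethod("show", "RiskLabeling", function(object) {
    cat(sprintf("RiskLabeling for (%s): %d high-risk cells, %d/%d subjects high-risk\n",
                paste(object@combination, collapse = ", "),
                object@nHighCells, sum(object@S == 1L, na.rm = TRUE),
                sum(!is.na(object@S))))
})
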