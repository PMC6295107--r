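#' Cox-MDR best-pair selection by cross-validation
#'
#' The original Cox-MDR search: martingale residuals from the step-1 null
#' Cox model define a per-subject pseudo-class \eqn{c_i = 1\{M_i > 0\}}
#' (earlier-than-expected event). For every SNP pair, each cross-validation
#' fold labels the genotype cells high/low risk from the training
#' residual sums and predicts the high-risk indicator S on the test fold;
#' the testing score is the balanced accuracy of S against the
#' pseudo-class. The best pair maximizes the mean testing score over
#' folds, with ties broken by higher cross-validation consistency and
#' then lexicographically.
#'
#' Cells empty in a training fold are labeled low-risk. A class absent
#' from a test fold contributes recall 0.5 (chance level) to the balanced
#' accuracy.
#'
#' @param x a [SnpSurvivalExperiment-class].
#' @param control an [ummdrControl()] list (`seed` and
#'   `adjustCovariatesStep1` are used).
#' @param nFolds number of folds (default 10), stratified by event status.
#' @return a [CVSelection-class].
#' @export
coxmdrSelect <- function(x, control = ummdrControl(), nFolds = 10L) {
    time <- survTime(x)
    status <- eventStatus(x)
    n <- length(time)
    nFolds <- as.integer(nFolds)
    if (n < nFolds) stopf("need at least %d subjects for %d folds", nFolds,
                          nFolds)
    geno <- genotypeMatrix(x)
    if (ncol(geno) < 2L) stopf("at least 2 SNPs are required")
    covs <- covariateMatrix(x)
    mode <- if (control$adjustCovariatesStep1) "adjusted" else "baseline"
    M <- residualsVec(time, status, covs, mode)
    cls <- as.integer(M > 0)
    combos <- enumerateCombinations(colnames(geno), 2L)
    C <- nrow(combos)
    cellIdx <- vapply(seq_len(C), function(j)
        cellIndexFor(geno[, combos[j, ], drop = FALSE]), integer(n))

    if (nFolds == 1L) {
        # degenerate mode: train and test on the full data (oracle check)
        folds <- rep(1L, n)
        attr(folds, "resubstitution") <- TRUE
    } else {
    folds <- NULL
    for (attempt in seq_len(10L)) {
        f <- stratifiedFolds(status, nFolds,
                             deriveSeed(control$seed, 211L, attempt))
        if (all(vapply(seq_len(nFolds), function(k)
            sum(status[f == k]) > 0, logical(1)))) {
            folds <- f
            break
        }
    }
    if (is.null(folds))
        stopf("could not build %d folds that all contain events", nFolds)
    }
    resub <- isTRUE(attr(folds, "resubstitution"))

    testScore <- matrix(NA_real_, nFolds, C)
    trainScore <- matrix(NA_real_, nFolds, C)
    for (k in seq_len(nFolds)) {
        test <- folds == k
        train <- if (resub) test else !test
        for (j in seq_len(C)) {
            idx <- cellIdx[, j]
            okTr <- train & !is.na(idx)
            okTe <- test & !is.na(idx)
            sums <- numeric(9)
            rs <- rowsum(M[okTr], idx[okTr])
            sums[as.integer(rownames(rs))] <- rs[, 1]
            high <- sums > 0                     # empty training cell -> L
            testScore[k, j] <- balancedAccuracy(high[idx[okTe]],
                                                cls[okTe])
            trainScore[k, j] <- balancedAccuracy(high[idx[okTr]],
                                                 cls[okTr])
        }
    }
    meanScore <- colMeans(testScore, na.rm = TRUE)
    foldBest <- apply(trainScore, 1, function(v) which.max(v))
    consistency <- vapply(seq_len(C), function(j)
        sum(foldBest == j), integer(1))
    key <- apply(combos, 1, paste, collapse = "\r")
    best <- order(-meanScore, -consistency, key)[1]
    scores <- S4Vectors::DataFrame(snp1 = combos[, 1], snp2 = combos[, 2],
                                   cvScore = meanScore,
                                   cvConsistency = consistency)
    methods::new("CVSelection",
                 bestPair = combos[best, ],
                 cvScore = meanScore[best],
                 cvConsistency = consistency[best],
                 nFolds = nFolds,
                 scores = scores)
}

# Balanced accuracy of predicted high-risk indicator vs pseudo-class;
# an absent class contributes chance-level recall 0.5.
balancedAccuracy <- function(pred, truth) {
    pred <- as.integer(pred)
    r1 <- if (any(truth == 1L)) mean(pred[truth == 1L] == 1L) else 0.5
    r0 <- if (any(truth == 0L)) mean(pred[truth == 0L] == 0L) else 0.5
    (r1 + r0) / 2
}

stratifiedFolds <- function(status, nFolds, seed) {
    n <- length(status)
    folds <- integer(n)
    withSeed(seed, {
        for (s in unique(status)) {
            idx <- which(status == s)
            folds[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
        }
    })
    folds
}

setMethod("show", "CVSelection", function(object) {
    cat(sprintf("CVSelection: best pair (%s) cvScore %.4f consistency %d/%d\n",
                paste(object@bestPair, collapse = ", "), object@cvScore,
                object@cvConsistency, object@nFolds))
})

#' Cox-MDR power at one simulation grid point
#'
#' Fraction of simulated replicates in which cross-validated Cox-MDR
#' selects the true disease-causal pair as its best model.
#'
#' @param maf minor allele frequency of the simulated SNPs.
#' @param h2 heritability of the penetrance model.
#' @param censorFraction target censoring fraction.
#' @param nReplicates number of simulated datasets.
#' @param scenario `"no_marginal"` or `"marginal"` (adds a main effect
#'   `delta = 0.5` of a third, non-causal SNP).
#' @param n,nSnps cohort size and SNP count per dataset.
#' @param control an [ummdrControl()] list; `seed` drives everything.
#' @param penetrance optional fixed [PenetranceModel-class]; generated
#'   from `(maf, h2)` when omitted.
#' @return the selection frequency, with per-replicate results in
#'   attribute `"selected"`.
#' @export
coxmdrPower <- function(maf, h2, censorFraction = 0, nReplicates = 100L,
                        scenario = c("no_marginal", "marginal"),
                        n = 400L, nSnps = 10L,
                        control = ummdrControl(), penetrance = NULL) {
    scenario <- match.arg(scenario)
    if (is.null(penetrance))
        penetrance <- generatePenetrance(maf, h2,
                                         seed = deriveSeed(control$seed, 7L))
    delta <- if (scenario == "marginal") 0.5 else 0
    baseSc <- scenarioConfig(n = n, maf = maf, h2 = h2,
                             censorFraction = censorFraction,
                             delta = delta, nSnps = nSnps,
                             seed = control$seed)
    cb <- if (censorFraction > 0)
        calibrateCensoring(baseSc, censorFraction, penetrance) else Inf
    hits <- logical(nReplicates)
    for (r in seq_len(nReplicates)) {
        sc <- baseSc
        sc$seed <- deriveSeed(control$seed, 311L, r)
        sim <- simulateSurvival(sc, penetrance, censorBound = cb)
        ctl <- control
        ctl$seed <- deriveSeed(control$seed, 313L, r)
        sel <- coxmdrSelect(sim, ctl)
        causal <- sort(S4Vectors::metadata(sim)$causalPair)
        hits[r] <- identical(sort(sel@bestPair), causal)
    }
    structure(mean(hits), selected = hits)
}
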