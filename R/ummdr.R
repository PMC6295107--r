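#' Wald statistic for one model term
#'
#' \eqn{W = \hat\beta^2 / \widehat{Var}(\hat\beta)}.
#'
#' @param fit a [CoxFit-class].
#' @param term name of the coefficient to test.
#' @return list with `beta`, `se` and `W`.
#' @export
waldStatistic <- function(fit, term) {
    stopifnot(methods::is(fit, "CoxFit"))
    if (!term %in% names(coef(fit)))
        stopf("term '%s' not in fit", term)
    beta <- coef(fit)[[term]]
    se <- sqrt(vcov(fit)[term, term])
    if (!is.finite(se) || se <= 0)
        stopf("standard error of '%s' is zero or non-finite", term)
    list(beta = beta, se = se, W = (beta / se)^2)
}

#' Non-central chi-square corrected p-value
#'
#' Upper-tail probability of a 1-df non-central chi-square with
#' non-centrality `q` at the observed Wald statistic `W`. With `q = 0`
#' this is the ordinary central chi-square p-value. The non-centrality
#' absorbs the upward shift of the Wald statistic that the data-driven
#' MDR classification step induces under the null.
#'
#' @param W nonnegative Wald statistic(s).
#' @param q nonnegative non-centrality parameter(s).
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' correctedPvalue(qchisq(0.95, 1), 0)    # 0.05
#' correctedPvalue(qchisq(0.95, 1), 2.2)  # ~0.32: same W, weaker evidence
#' @export
correctedPvalue <- function(W, q) {
    if (any(!is.finite(W)) || any(W < 0)) stopf("W must be nonnegative")
    if (any(!is.finite(q)) || any(q < 0)) stopf("q must be nonnegative")
    stats::pchisq(W, df = 1, ncp = q, lower.tail = FALSE)
}

# q-hat = max(0, mean(W) - 1): the mean of a non-central chi-square(1, q)
# is q + 1, so the permutation mean of W estimates q + 1.
qhatFromW <- function(W) {
    W <- W[is.finite(W)]
    if (!length(W)) return(NA_real_)
    max(0, mean(W) - 1)
}

# ---- internal scan machinery ------------------------------------------

# Per-subject residuals for an outcome (time, status) with the step-1 null
# model fixed by `mode`; covariates stay attached to the subjects.
residualsVec <- function(time, status, covs, mode, ord = order(time)) {
    status <- as.integer(status)
    if (mode == "baseline") {
        eta <- numeric(length(time))
        ch <- breslow_cumhaz_at_cpp(time, status, eta, ord - 1L)
        return(status - ch)
    }
    if (is.null(covs) || ncol(covs) == 0)
        stopf("adjusted null model requires covariates")
    f <- cox_newton_cpp(covs[ord, , drop = FALSE], time[ord], status[ord])
    eta <- as.numeric(covs %*% f$coefficients)
    status - breslow_cumhaz_at_cpp(time, status, eta, ord - 1L) * exp(eta)
}

# High-risk indicator matrix (subjects x combinations) for a residual
# vector: cell sums > 0 define the high-risk cells of each combination.
indicatorMatrix <- function(cellIdx, ncell, M) {
    indicator_matrix_cpp(cellIdx, M, as.integer(ncell))
}

# Fit the step-2 Cox model for every combination and return a 4 x C matrix
# (beta, se, W, converged). Degenerate combinations (constant S) get NA.
fitWald <- function(time, status, covs, geno, combos, S, adjustMain) {
    C <- nrow(combos)
    out <- matrix(NA_real_, 4, C,
                  dimnames = list(c("beta", "se", "W", "converged"), NULL))
    colRange <- function(s) {
        s <- s[!is.na(s)]
        length(s) && min(s) != max(s)
    }
    nonDegen <- vapply(seq_len(C), function(j) colRange(S[, j]), logical(1))
    anyMissing <- anyNA(S)
    if (!adjustMain && !anyMissing) {
        use <- which(nonDegen)
        if (length(use)) {
            ord <- order(time)
            out[, use] <- cox_wald_scan_cpp(
                S[ord, use, drop = FALSE],
                covs[ord, , drop = FALSE],
                time[ord], as.integer(status[ord]))
        }
        return(out)
    }
    for (j in which(nonDegen)) {
        s <- S[, j]
        ok <- !is.na(s)
        X <- cbind(S = s[ok], covs[ok, , drop = FALSE])
        if (adjustMain) {
            mains <- geno[ok, combos[j, ], drop = FALSE]
            keep <- apply(mains, 2, function(v) min(v) != max(v))
            X <- cbind(X, mains[, keep, drop = FALSE])
        }
        if (sum(status[ok]) < 1L) next
        if (qr(X)$rank < ncol(X)) next
        ord <- order(time[ok])
        f <- tryCatch(
            cox_newton_cpp(X[ord, , drop = FALSE], time[ok][ord],
                           as.integer(status[ok][ord])),
            error = function(e) NULL)
        if (is.null(f)) next
        beta <- f$coefficients[1]
        se <- sqrt(f$covariance[1, 1])
        out[, j] <- c(beta, se,
                      if (is.finite(se) && se > 0) (beta / se)^2 else NA_real_,
                      as.numeric(isTRUE(f$converged)))
    }
    out
}

# Observed and permuted Wald statistics for all combinations.
scanCore <- function(time, status, covs, geno, combos, control) {
    n <- length(time)
    mode <- if (control$adjustCovariatesStep1) "adjusted" else "baseline"
    ncell <- 3L^ncol(combos)
    cellIdx <- vapply(seq_len(nrow(combos)), function(j)
        cellIndexFor(geno[, combos[j, ], drop = FALSE]),
        integer(n))
    if (!is.matrix(cellIdx)) cellIdx <- matrix(cellIdx, nrow = n)
    M <- residualsVec(time, status, covs, mode)
    Sobs <- indicatorMatrix(cellIdx, ncell, M)
    obs <- fitWald(time, status, covs, geno, combos, Sobs,
                   control$adjustMainEffects)
    B <- control$nPerm
    Wperm <- matrix(NA_real_, B, nrow(combos))
    for (b in seq_len(B)) {
        perm <- withSeed(deriveSeed(control$seed, 101L, b),
                         sample.int(n))
        tb <- time[perm]
        sb <- status[perm]
        # baseline-only residuals depend on (time, status) alone, so the
        # permuted residual vector is just a permutation of the original
        Mb <- if (mode == "baseline") M[perm]
              else residualsVec(tb, sb, covs, mode)
        Sb <- indicatorMatrix(cellIdx, ncell, Mb)
        Wperm[b, ] <- fitWald(tb, sb, covs, geno, combos, Sb,
                              control$adjustMainEffects)["W", ]
    }
    list(obs = obs, Wperm = Wperm, residuals = M, S = Sobs)
}

#' Estimate the non-centrality parameter by trait permutation
#'
#' Permutes the survival outcome (time and status jointly) against the
#' fixed genotype/covariate rows, re-runs both steps of the procedure on
#' each permuted dataset, and estimates the non-centrality of the null
#' Wald distribution as \eqn{\hat q = \max(0, \hat\mu - 1)} with
#' \eqn{\hat\mu} the mean permuted Wald statistic — either per combination
#' or pooled over all combinations, per `control$noncentrality`.
#'
#' @param x a [SnpSurvivalExperiment-class].
#' @param control an [ummdrControl()] list.
#' @param combinations optional combination matrix (rows of SNP names);
#'   defaults to all combinations of order `control$interactionOrder`.
#' @return numeric vector of `qHat` per combination (a single common value
#'   is recycled in pooled mode), with the permuted Wald statistics in
#'   attribute `"Wperm"`.
#' @export
estimateNoncentrality <- function(x, control = ummdrControl(),
                                  combinations = NULL) {
    combos <- combinations
    if (is.null(combos))
        combos <- enumerateCombinations(snpNames(x),
                                        control$interactionOrder)
    if (!is.matrix(combos)) combos <- matrix(combos, nrow = 1)
    core <- scanCore(survTime(x), eventStatus(x), covariateMatrix(x),
                     genotypeMatrix(x), combos, control)
    q <- qhatColumns(core$Wperm, control$noncentrality)
    attr(q, "Wperm") <- core$Wperm
    q
}

# Full two-step scan on plain vectors/matrices; returns the result columns
# as a list. scanPairs() wraps this into the S4 container; the simulation
# harnesses call it directly.
ummdrScanRaw <- function(time, status, covs, geno, combos, control) {
    core <- scanCore(time, status, covs, geno, combos, control)
    C <- nrow(combos)
    W <- core$obs["W", ]
    degenerate <- !is.finite(W)
    qHat <- qhatColumns(core$Wperm, control$noncentrality)
    # a combination degenerate in every permutation has no permutation
    # information; its non-centrality defaults to 0
    qHat[!is.finite(qHat)] <- 0
    Wsafe <- ifelse(degenerate, 0, W)
    pRaw <- ifelse(degenerate, 1,
                   stats::pchisq(Wsafe, df = 1, lower.tail = FALSE))
    pCorrected <- ifelse(degenerate, 1, correctedPvalue(Wsafe, qHat))
    key <- apply(combos, 1, paste, collapse = "\r")
    o <- order(pCorrected, key)
    rk <- integer(C)
    rk[o] <- seq_len(C)
    list(combos = combos, beta = core$obs["beta", ], se = core$obs["se", ],
         W = W, qHat = qHat, pRaw = pRaw, pCorrected = pCorrected,
         pBonferroni = pmin(1, pCorrected * C), rank = rk,
         degenerate = degenerate)
}

qhatColumns <- function(Wperm, mode) {
    if (mode == "pooled") {
        rep(qhatFromW(as.vector(Wperm)), ncol(Wperm))
    } else {
        apply(Wperm, 2, qhatFromW)
    }
}

#' Scan all SNP combinations with Cox UM-MDR
#'
#' The full two-step procedure for every combination of
#' `control$interactionOrder` SNPs. Step 1 classifies the combination's
#' genotype cells into high/low risk by the sign of their
#' martingale-residual sums under a null Cox model and produces the
#' per-subject high-risk indicator S. Step 2 fits
#' \eqn{\lambda(t \mid S, Z) = \lambda_0(t) \exp(\beta S + \gamma' Z)}
#' (optionally plus the SNPs' additive main effects) and tests
#' \eqn{H_0: \beta = 0} with the Wald statistic. Because S was constructed
#' from the outcome, the null distribution of the statistic is a
#' non-central chi-square; the non-centrality is estimated from
#' `control$nPerm` trait permutations and used for the corrected p-value.
#'
#' Combinations whose indicator is constant (all subjects high- or all
#' low-risk) are flagged degenerate and reported with p-value 1 so that
#' ranks stay comparable across datasets.
#'
#' @param x a [SnpSurvivalExperiment-class].
#' @param control an [ummdrControl()] list.
#' @return an [UMMDRScan-class]; see [resultsTable()].
#' @examples
#' sim <- simulateNullDataset(n = 120, nSnps = 4, maf = 0.3, seed = 7)
#' scan <- scanPairs(sim, ummdrControl(seed = 7))
#' resultsTable(scan)[1:3, ]
#' @export
scanPairs <- function(x, control = ummdrControl()) {
    combos <- enumerateCombinations(snpNames(x), control$interactionOrder)
    r <- ummdrScanRaw(survTime(x), eventStatus(x), covariateMatrix(x),
                      genotypeMatrix(x), combos, control)
    snps <- as.list(as.data.frame(combos, stringsAsFactors = FALSE))
    names(snps) <- paste0("snp", seq_len(ncol(combos)))
    df <- do.call(S4Vectors::DataFrame, c(snps, list(
        beta = r$beta, se = r$se, W = r$W, qHat = r$qHat,
        pRaw = r$pRaw, pCorrected = r$pCorrected,
        pBonferroni = r$pBonferroni, rank = r$rank,
        degenerate = r$degenerate)))
    methods::new("UMMDRScan", results = df,
                 control = unclass(control))
}

#' @describeIn UMMDRScan-class the per-combination result table, ordered
#'   by corrected p-value (ties broken lexicographically by SNP names).
#' @export
setMethod("resultsTable", "UMMDRScan", function(object) {
    object@results[order(object@results$rank), ]
})

setMethod("show", "UMMDRScan", function(object) {
    r <- object@results
    cat(sprintf("UMMDRScan: %d combinations (order %d), %d degenerate\n",
                nrow(r), object@control$interactionOrder,
                sum(r$degenerate)))
    top <- resultsTable(object)[seq_len(min(5, nrow(r))), ]
    cat("Top combinations by corrected p-value:\n")
    print(as.data.frame(top))
})

#' Interaction Wald test in a Cox model
#'
#' Fits \eqn{\lambda_0(t) \exp(\gamma' Z + \theta_1 SNP1 + \theta_2 SNP2 +
#' \beta\, SNP1 \times SNP2)} with additive genotype codings and tests the
#' product term — the semi-parametric alternative used to confirm
#' epistasis candidates from a scan.
#'
#' @param x a [SnpSurvivalExperiment-class].
#' @param snp1,snp2 SNP names.
#' @param covariates covariate names to adjust for (default: all).
#' @return list with `beta`, `se`, `p.value` and the full [CoxFit-class].
#' @export
interactionWaldTest <- function(x, snp1, snp2, covariates = NULL) {
    geno <- genotypeMatrix(x)
    for (nm in c(snp1, snp2))
        if (!nm %in% colnames(geno)) stopf("unknown SNP '%s'", nm)
    covs <- covariateMatrix(x)
    if (!is.null(covariates)) covs <- covs[, covariates, drop = FALSE]
    g1 <- geno[, snp1]
    g2 <- geno[, snp2]
    prod <- g1 * g2
    if (max(prod, na.rm = TRUE) == min(prod, na.rm = TRUE))
        stopf("product column %s x %s is constant (collinear)", snp1, snp2)
    X <- cbind(covs, SNP1 = g1, SNP2 = g2, interaction = prod)
    fit <- coxFit(X, time = survTime(x), status = eventStatus(x))
    w <- waldStatistic(fit, "interaction")
    list(beta = w$beta, se = w$se,
         p.value = stats::pchisq(w$W, 1, lower.tail = FALSE),
         fit = fit)
}

#' Log-rank test of the risk groups implied by a SNP pair
#'
#' Fits the interaction model of [interactionWaldTest()], computes each
#' subject's linear-predictor risk score, splits the cohort at the median
#' score (ties to the low-risk group) and compares the two groups'
#' survival curves with a log-rank test.
#'
#' @inheritParams interactionWaldTest
#' @return list with `statistic`, `p.value`, the binary `group` vector
#'   (1 = high-risk) and the interaction `fit`.
#' @export
riskGroupLogrank <- function(x, snp1, snp2, covariates = NULL) {
    it <- interactionWaldTest(x, snp1, snp2, covariates)
    fit <- it$fit
    geno <- genotypeMatrix(x)
    covs <- covariateMatrix(x)
    if (!is.null(covariates)) covs <- covs[, covariates, drop = FALSE]
    X <- cbind(covs, SNP1 = geno[, snp1], SNP2 = geno[, snp2],
               interaction = geno[, snp1] * geno[, snp2])
    score <- as.numeric(X %*% coef(fit)[colnames(X)])
    group <- as.integer(score > stats::median(score))
    if (all(group == group[1]))
        return(list(statistic = NA_real_, p.value = 1,
                    group = group, fit = fit, degenerate = TRUE))
    lr <- logrankTest(survTime(x), eventStatus(x), group)
    list(statistic = lr$statistic, p.value = lr$p.value,
         group = group, fit = fit, degenerate = FALSE)
}
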