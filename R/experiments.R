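#' Family-wise type-I error of the pairwise scan under the null
#'
#' For every (MAF, censoring fraction) grid cell, repeatedly simulates a
#' cohort with no genetic effect (survival depends only on the covariate
#' z), scans all SNP pairs, and records a family-wise rejection when the
#' smallest p-value over the pairs falls below the Bonferroni threshold
#' `alpha / #pairs`. The raw rate uses the central chi-square p-values
#' (no non-centrality correction, i.e. q forced to 0); the corrected rate
#' uses the non-central chi-square p-values.
#'
#' @param mafs minor allele frequencies to simulate.
#' @param censorFractions target censoring fractions.
#' @param nReplicates null datasets per grid cell.
#' @param n,nSnps cohort size and SNP count.
#' @param gamma covariate effect of the null generating model.
#' @param control an [ummdrControl()] list; `alpha`, `nPerm`,
#'   `noncentrality` and `seed` are used.
#' @param keepPvalues also return the per-pair p-values of every
#'   replicate (for Q-Q / uniformity diagnostics).
#' @return data frame with one row per grid cell: `maf`,
#'   `censorFraction`, `rawRate`, `correctedRate`, `nReplicates`,
#'   `mcSeRaw`, `mcSeCorrected` (Monte-Carlo standard errors
#'   `sqrt(r(1-r)/n)`). When `keepPvalues = TRUE` the matrices of pooled
#'   raw/corrected p-values are attached as attribute `"pvalues"`.
#' @export
runTypeIGrid <- function(mafs = c(0.05, 0.10, 0.20, 0.30, 0.40),
                         censorFractions = c(0, 0.1, 0.3, 0.5),
                         nReplicates = 1000L, n = 400L, nSnps = 10L,
                         gamma = 1.0, control = ummdrControl(),
                         keepPvalues = FALSE) {
    grid <- expand.grid(maf = mafs, censorFraction = censorFractions,
                        KEEP.OUT.ATTRS = FALSE)
    rows <- vector("list", nrow(grid))
    pvals <- if (keepPvalues) vector("list", nrow(grid))
    nPairs <- choose(nSnps, 2)
    thr <- control$alpha / nPairs
    for (g in seq_len(nrow(grid))) {
        maf <- grid$maf[g]
        cf <- grid$censorFraction[g]
        cellSeed <- deriveSeed(control$seed, 401L, g)
        sc <- scenarioConfig(n = n, maf = maf, h2 = 0, alpha = 0,
                             gamma = gamma, censorFraction = cf,
                             nSnps = nSnps, seed = cellSeed)
        cb <- if (cf > 0) calibrateCensoring(sc, cf) else Inf
        rawRej <- corrRej <- logical(nReplicates)
        praw <- pcorr <- if (keepPvalues)
            matrix(NA_real_, nReplicates, nPairs)
        combos <- enumerateCombinations(paste0("rs", seq_len(nSnps)), 2L)
        for (r in seq_len(nReplicates)) {
            scr <- sc
            scr$seed <- deriveSeed(cellSeed, 1L, r)
            sim <- simulateCohortRaw(scr, penetrance = NULL,
                                     censorBound = cb)
            ctl <- control
            ctl$seed <- deriveSeed(cellSeed, 2L, r)
            res <- ummdrScanRaw(sim$time, sim$status,
                                cbind(z = sim$z), sim$geno, combos, ctl)
            rawRej[r] <- min(res$pRaw) <= thr
            corrRej[r] <- min(res$pCorrected) <= thr
            if (keepPvalues) {
                praw[r, ] <- res$pRaw
                pcorr[r, ] <- res$pCorrected
            }
        }
        rr <- mean(rawRej)
        cr <- mean(corrRej)
        rows[[g]] <- data.frame(
            maf = maf, censorFraction = cf,
            rawRate = rr, correctedRate = cr,
            nReplicates = nReplicates,
            mcSeRaw = sqrt(rr * (1 - rr) / nReplicates),
            mcSeCorrected = sqrt(cr * (1 - cr) / nReplicates))
        if (keepPvalues)
            pvals[[g]] <- list(maf = maf, censorFraction = cf,
                               pRaw = praw, pCorrected = pcorr)
    }
    out <- do.call(rbind, rows)
    attr(out, "seed") <- control$seed
    if (keepPvalues) attr(out, "pvalues") <- pvals
    out
}

#' Power of Cox UM-MDR and Cox-MDR at simulation grid points
#'
#' For each (MAF, heritability, censoring fraction, scenario) point,
#' simulates cohorts containing a causal epistatic SNP pair and measures
#' three powers: `pBonfPower` (the causal pair's Bonferroni-corrected
#' p-value is at most `alpha`), `pRankPower` (the causal pair ranks first
#' by corrected p-value), and `coxmdrPower` (cross-validated Cox-MDR
#' selects the causal pair as its best model). In the `"marginal"`
#' scenario a third SNP carries a main effect (`delta = 0.5`) and the
#' step-2 model of the scan adjusts for the combination's SNP main
#' effects.
#'
#' @param mafs,h2s,censorFractions grid axes.
#' @param scenario `"no_marginal"` or `"marginal"`.
#' @param nReplicates simulated datasets per grid point.
#' @param nModels penetrance models generated per (maf, h2) point.
#' @param n,nSnps cohort size and SNP count.
#' @param control an [ummdrControl()] list.
#' @param runCoxmdr set `FALSE` to skip the comparator.
#' @return data frame with one row per (grid point, model).
#' @export
runPowerGrid <- function(mafs = 0.2, h2s = 0.4, censorFractions = 0,
                         scenario = c("no_marginal", "marginal"),
                         nReplicates = 100L, nModels = 1L,
                         n = 400L, nSnps = 10L,
                         control = ummdrControl(), runCoxmdr = TRUE) {
    scenario <- match.arg(scenario)
    delta <- if (scenario == "marginal") 0.5 else 0
    grid <- expand.grid(maf = mafs, h2 = h2s,
                        censorFraction = censorFractions,
                        model = seq_len(nModels),
                        KEEP.OUT.ATTRS = FALSE)
    rows <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
        maf <- grid$maf[g]
        h2 <- grid$h2[g]
        cf <- grid$censorFraction[g]
        mdl <- grid$model[g]
        pointSeed <- deriveSeed(control$seed, 501L, g)
        pen <- generatePenetrance(maf, h2,
                                  seed = deriveSeed(pointSeed, mdl))
        sc <- scenarioConfig(n = n, maf = maf, h2 = h2, delta = delta,
                             censorFraction = cf, nSnps = nSnps,
                             seed = pointSeed)
        cb <- if (cf > 0) calibrateCensoring(sc, cf, pen) else Inf
        bonf <- rankHit <- cmHit <- logical(nReplicates)
        for (r in seq_len(nReplicates)) {
            scr <- sc
            scr$seed <- deriveSeed(pointSeed, 3L, r)
            sim <- simulateSurvival(scr, pen, censorBound = cb)
            causal <- sort(S4Vectors::metadata(sim)$causalPair)
            ctl <- control
            ctl$adjustMainEffects <- control$adjustMainEffects ||
                scenario == "marginal"
            ctl$seed <- deriveSeed(pointSeed, 4L, r)
            res <- scanPairs(sim, ctl)@results
            ci <- which(res$snp1 == causal[1] & res$snp2 == causal[2])
            bonf[r] <- res$pBonferroni[ci] <= control$alpha
            rankHit[r] <- res$rank[ci] == 1L
            if (runCoxmdr) {
                ctl2 <- control
                ctl2$seed <- deriveSeed(pointSeed, 5L, r)
                sel <- coxmdrSelect(sim, ctl2)
                cmHit[r] <- identical(sort(sel@bestPair), causal)
            }
        }
        rows[[g]] <- data.frame(
            maf = maf, h2 = h2, model = mdl, censorFraction = cf,
            scenario = scenario,
            pBonfPower = mean(bonf), pRankPower = mean(rankHit),
            coxmdrPower = if (runCoxmdr) mean(cmHit) else NA_real_,
            nReplicates = nReplicates)
    }
    out <- do.call(rbind, rows)
    attr(out, "seed") <- control$seed
    out
}

#' Null p-value uniformity diagnostics
#'
#' Pools the per-pair raw and corrected p-values of null replicates at one
#' grid point and compares both to the Uniform(0, 1) distribution:
#' sorted observed values paired with uniform plotting positions (for a
#' Q-Q plot) plus Kolmogorov-Smirnov statistics and p-values. Under the
#' non-centrality correction the pooled p-values should be approximately
#' uniform; without it they are left-inflated.
#'
#' @param maf,censorFraction null grid point.
#' @param nReplicates null datasets to pool (each contributes one p-value
#'   per pair).
#' @param n,nSnps,gamma,control as in [runTypeIGrid()].
#' @return list with `table` (data frame `expected`, `observedRaw`,
#'   `observedCorrected`), `ksRaw` and `ksCorrected` (`htest` objects).
#' @export
qqNullPvalues <- function(maf = 0.2, censorFraction = 0.3,
                          nReplicates = 23L, n = 400L, nSnps = 10L,
                          gamma = 1.0, control = ummdrControl()) {
    if (nReplicates < 1L) stopf("nReplicates must be >= 1")
    res <- runTypeIGrid(mafs = maf, censorFractions = censorFraction,
                        nReplicates = nReplicates, n = n, nSnps = nSnps,
                        gamma = gamma, control = control,
                        keepPvalues = TRUE)
    pv <- attr(res, "pvalues")[[1]]
    praw <- sort(as.vector(pv$pRaw))
    pcorr <- sort(as.vector(pv$pCorrected))
    m <- length(praw)
    tab <- data.frame(expected = stats::ppoints(m),
                      observedRaw = praw,
                      observedCorrected = pcorr)
    list(table = tab,
         ksRaw = suppressWarnings(stats::ks.test(praw, "punif")),
         ksCorrected = suppressWarnings(stats::ks.test(pcorr, "punif")))
}
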