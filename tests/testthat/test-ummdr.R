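test_that("Wald statistic follows its definition", {
    x <- toyDataset(n = 100, seed = 3)
    fit <- coxFit(x, columns = c("z", "rs1"))
    w <- waldStatistic(fit, "rs1")
    expect_equal(w$W, (w$beta / w$se)^2, tolerance = 1e-10)
    expect_equal(w$beta, coef(fit)[["rs1"]])
    expect_error(waldStatistic(fit, "nope"), "not in fit")
})

test_that("q-hat is the clamped mean-minus-one of permuted statistics", {
    qf <- coxummdr:::qhatFromW
    expect_equal(qf(c(1, 1, 1, 1, 1)), 0)
    expect_equal(qf(c(0.2, 0.4, 0.6, 0.2, 0.1)), 0)      # clamped
    expect_equal(qf(c(2, 4, 3, 5, 2)), 2.2)
    expect_true(is.na(qf(rep(NA_real_, 3))))
})

test_that("corrected p-values match the normal-tail oracle", {
    expect_equal(correctedPvalue(qchisq(0.95, 1), 0), 0.05,
                 tolerance = 1e-10)
    expect_equal(correctedPvalue(0, 5), 1)
    # independent oracle: (Z + sqrt(q))^2 > W  <=>  Z < -sqrt(W)-sqrt(q)
    # or Z > sqrt(W)-sqrt(q)
    oracle <- function(W, q)
        pnorm(-sqrt(W) - sqrt(q)) + pnorm(sqrt(W) - sqrt(q),
                                          lower.tail = FALSE)
    set.seed(5)
    for (i in 1:50) {
        W <- runif(1, 0, 15)
        q <- runif(1, 0, 8)
        expect_equal(correctedPvalue(W, q), oracle(W, q),
                     tolerance = 1e-6)
    }
    expect_equal(correctedPvalue(3.841, 2.2), oracle(3.841, 2.2),
                 tolerance = 1e-6)
    expect_error(correctedPvalue(-1, 0), "nonnegative")
    expect_error(correctedPvalue(1, -2), "nonnegative")
})

test_that("corrected p-values are monotone in q and in W", {
    W <- 4
    qs <- seq(0, 6, by = 0.5)
    expect_true(all(diff(correctedPvalue(rep(W, length(qs)), qs)) > 0))
    Ws <- seq(0.1, 10, by = 0.5)
    expect_true(all(diff(correctedPvalue(Ws, rep(2, length(Ws)))) < 0))
    # corrected >= raw whenever q > 0
    expect_gte(correctedPvalue(3, 1.5), correctedPvalue(3, 0))
})

test_that("a null scan is structurally sound", {
    sim <- simulateNullDataset(n = 150, nSnps = 10, maf = 0.3, seed = 31)
    scan <- scanPairs(sim, ummdrControl(seed = 31))
    r <- scan@results
    expect_equal(nrow(r), 45)
    expect_setequal(r$rank, 1:45)
    expect_true(all(r$pBonferroni >= 0 & r$pBonferroni <= 1))
    expect_true(all(r$pCorrected >= r$pRaw - 1e-12 | r$qHat == 0))
    expect_true(all(r$W[!r$degenerate] >= 0))
    expect_equal(r$W[!r$degenerate],
                 (r$beta[!r$degenerate] / r$se[!r$degenerate])^2,
                 tolerance = 1e-10)
    # results table is sorted by corrected p-value
    tab <- resultsTable(scan)
    expect_true(!is.unsorted(tab$pCorrected))
})

test_that("scans are reproducible from the control seed", {
    sim <- simulateNullDataset(n = 100, nSnps = 5, maf = 0.3, seed = 8)
    s1 <- scanPairs(sim, ummdrControl(seed = 99))
    s2 <- scanPairs(sim, ummdrControl(seed = 99))
    expect_identical(as.data.frame(s1@results),
                     as.data.frame(s2@results))
})

test_that("a monomorphic pair is degenerate with p = 1", {
    set.seed(12)
    g <- cbind(rs1 = rep(0L, 80), rs2 = rep(2L, 80),
               rs3 = rbinom(80, 2, 0.4))
    x <- SnpSurvivalExperiment(g, time = rexp(80) + 0.01,
                               status = rbinom(80, 1, 0.8),
                               covariates = data.frame(z = rnorm(80)))
    scan <- scanPairs(x, ummdrControl(seed = 12))
    r <- as.data.frame(scan@results)
    row <- r[r$snp1 == "rs1" & r$snp2 == "rs2", ]
    expect_true(row$degenerate)
    expect_equal(row$pCorrected, 1)
    expect_equal(row$pBonferroni, 1)
})

test_that("the causal pair dominates a strong-epistasis scan", {
    pen <- generatePenetrance(0.2, 0.4, seed = 2)
    hits <- 0L
    nRep <- 20L
    for (r in seq_len(nRep)) {
        sc <- scenarioConfig(n = 400, maf = 0.2, h2 = 0.4,
                             seed = 5000 + r)
        sim <- simulateSurvival(sc, pen)
        res <- scanPairs(sim, ummdrControl(
            seed = r, adjustCovariatesStep1 = TRUE))@results
        causal <- sort(S4Vectors::metadata(sim)$causalPair)
        ci <- which(res$snp1 == causal[1] & res$snp2 == causal[2])
        hits <- hits + (res$rank[ci] == 1L)
    }
    expect_gte(hits, 0.7 * nRep)
})

test_that("per-combination and pooled non-centrality modes both work", {
    sim <- simulateNullDataset(n = 120, nSnps = 5, maf = 0.3, seed = 44)
    qPer <- estimateNoncentrality(sim, ummdrControl(seed = 44))
    qPool <- estimateNoncentrality(
        sim, ummdrControl(seed = 44, noncentrality = "pooled"))
    expect_length(qPer, 10)
    expect_length(qPool, 10)
    expect_equal(length(unique(round(qPool, 12))), 1)
    Wp <- attr(qPer, "Wperm")
    expect_equal(dim(Wp), c(5, 10))
    # pooled estimate equals max(0, mean of all permuted W - 1)
    expect_equal(unique(round(qPool, 12)),
                 round(max(0, mean(Wp) - 1), 12))
})

test_that("interaction Wald test recovers a true product effect", {
    set.seed(61)
    n <- 2000
    g1 <- rbinom(n, 2, 0.3)
    g2 <- rbinom(n, 2, 0.3)
    z <- rnorm(n)
    eta <- 0.3 * z + 1.0 * g1 * g2
    tt <- -log(runif(n)) * exp(-eta)
    x <- SnpSurvivalExperiment(cbind(rs1 = g1, rs2 = g2),
                               time = tt, status = rep(1L, n),
                               covariates = data.frame(z = z))
    it <- interactionWaldTest(x, "rs1", "rs2")
    expect_lt(abs(it$beta - 1), 3 * it$se)

    # constant SNP -> collinear product
    x0 <- SnpSurvivalExperiment(cbind(rs1 = g1, rs2 = rep(0L, n)),
                                time = tt, status = rep(1L, n),
                                covariates = data.frame(z = z))
    expect_error(interactionWaldTest(x0, "rs1", "rs2"), "constant")
})

test_that("interaction Wald test holds its size without a product effect", {
    set.seed(62)
    nRej <- 0L
    nRep <- 300L
    for (r in seq_len(nRep)) {
        n <- 300
        g1 <- rbinom(n, 2, 0.3)
        g2 <- rbinom(n, 2, 0.3)
        z <- rnorm(n)
        tt <- -log(runif(n)) * exp(-(0.3 * g1 + 0.3 * g2 + 0.5 * z))
        x <- SnpSurvivalExperiment(cbind(rs1 = g1, rs2 = g2),
                                   time = tt, status = rep(1L, n),
                                   covariates = data.frame(z = z))
        p <- tryCatch(interactionWaldTest(x, "rs1", "rs2")$p.value,
                      error = function(e) NA_real_)
        nRej <- nRej + isTRUE(p <= 0.05)
    }
    rate <- nRej / nRep
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.09)
})

test_that("median risk-score split matches a hand computation", {
    g <- cbind(rs1 = c(0L, 1L, 2L, 2L), rs2 = c(0L, 1L, 1L, 2L))
    x <- SnpSurvivalExperiment(g, time = c(4, 3, 2, 1),
                               status = rep(1L, 4))
    rg <- riskGroupLogrank(x, "rs1", "rs2")
    cf <- coef(rg$fit)
    score <- as.numeric(cbind(g[, 1], g[, 2], g[, 1] * g[, 2]) %*%
                        cf[c("SNP1", "SNP2", "interaction")])
    expect_equal(rg$group, as.integer(score > median(score)))
})

test_that("an informative pair increases the log-rank separation", {
    pen <- generatePenetrance(0.2, 0.4, seed = 9)
    diffs <- numeric(30)
    for (r in 1:30) {
        sc <- scenarioConfig(n = 300, maf = 0.2, h2 = 0.4,
                             seed = 7000 + r)
        sim <- simulateSurvival(sc, pen)
        # covariate-only reference split
        z <- covariateMatrix(sim)[, "z"]
        grp0 <- as.integer(z > median(z))
        lr0 <- logrankTest(survTime(sim), eventStatus(sim), grp0)
        lr1 <- riskGroupLogrank(sim, "rs1", "rs2")
        diffs[r] <- lr1$statistic - lr0$statistic
    }
    expect_gt(median(diffs), 0)
})
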