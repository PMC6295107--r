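test_that("combination enumeration is complete and lexicographic", {
    expect_equal(nrow(enumerateCombinations(paste0("rs", 1:10), 2)), 45)
    expect_equal(nrow(enumerateCombinations(c("a", "b", "c"), 3)), 1)
    c52 <- enumerateCombinations(c("rs5", "rs3", "rs1", "rs4", "rs2"), 2)
    expect_equal(nrow(c52), 10)
    expect_equal(c52[1, ], c("rs1", "rs2"))
    expect_error(enumerateCombinations(c("a", "b"), 3), "exceeds")
})

test_that("cell tables partition subjects and accumulate residual sums", {
    g <- matrix(c(0, 1, 0, 2, 1, 2,
                  0, 1, 0, 2, 1, 2), 6, 2,
                dimnames = list(NULL, c("rs1", "rs2")))
    x <- SnpSurvivalExperiment(g, time = 1:6, status = rep(1, 6))
    M <- c(0.67, 0.17, -0.83, 0.5, -0.2, -0.4)
    ct <- buildCells(x, c("rs1", "rs2"), residuals = M)
    expect_equal(sum(ct@counts), 6)
    expect_equal(sum(ct@counts > 0), 3)
    expect_equal(sum(ct@residualSums), sum(M), tolerance = 1e-10)

    # hand arithmetic: cells (0,0)={1,3}, (1,1)={2,5}... here (0,0)
    # holds subjects 1,3 -> sum -0.16; (1,1) holds 2,5 -> -0.03;
    # (2,2) holds 4,6 -> 0.1
    expect_equal(ct@residualSums[ct@counts > 0],
                 c(0.67 - 0.83, 0.17 - 0.2, 0.5 - 0.4),
                 tolerance = 1e-10)

    # all subjects in one cell
    g1 <- matrix(1, 6, 2, dimnames = list(NULL, c("rs1", "rs2")))
    x1 <- SnpSurvivalExperiment(g1, time = 1:6, status = rep(1, 6))
    ct1 <- buildCells(x1, c("rs1", "rs2"), residuals = M)
    expect_equal(sum(ct1@counts > 0), 1)
    # cell (1,1) has row-major index 5 and holds the full residual sum
    expect_equal(ct1@residualSums[5], sum(M), tolerance = 1e-10)

    # missing genotype excludes the subject for this combination only
    g2 <- g
    g2[3, 1] <- NA
    x2 <- SnpSurvivalExperiment(g2, time = 1:6, status = rep(1, 6))
    ct2 <- buildCells(x2, c("rs1", "rs2"), residuals = M)
    expect_equal(sum(ct2@counts), 5)
    expect_error(buildCells(x, c("rs1", "nope")), "unknown SNP")
})

test_that("classification follows the sign rule with ties low-risk", {
    g <- matrix(c(0, 1, 0, 1, 2, 2,
                  0, 1, 0, 1, 2, 2), 6, 2,
                dimnames = list(NULL, c("rs1", "rs2")))
    x <- SnpSurvivalExperiment(g, time = 1:6, status = rep(1, 6))
    # cells: (0,0)={1,3} sum -0.16; (1,1)={2,4} sum 0.67;
    #        (2,2)={5,6} sum -0.60
    M <- c(0.67, 0.17, -0.83, 0.5, -0.2, -0.4)
    lab <- classifyCells(buildCells(x, c("rs1", "rs2"), residuals = M))
    nonEmpty <- lab@label[tabulate(
        buildCells(x, c("rs1", "rs2"), residuals = M)@cellIndex,
        nbins = 9) > 0]
    expect_equal(nonEmpty, c("L", "H", "L"))
    expect_equal(lab@S, c(0L, 1L, 0L, 1L, 0L, 0L))

    # a zero residual sum is low-risk; empty cells are low-risk
    # (cells {1,3}, {2,4}, {5,6} each sum to exactly 0)
    M0 <- c(1, -1, -1, 1, 0.5, -0.5)
    lab0 <- classifyCells(buildCells(x, c("rs1", "rs2"), residuals = M0))
    expect_equal(sum(lab0@label == "H"), 0)
    expect_true(all(lab0@S == 0L))

    # all residuals positive -> every subject high-risk
    labp <- classifyCells(buildCells(x, c("rs1", "rs2"),
                                     residuals = rep(0.2, 6)))
    expect_true(all(labp@S == 1L))
})

test_that("negating residuals flips every non-tied non-empty label", {
    x <- toyDataset(n = 40, m = 3, seed = 8)
    M <- martingaleResiduals(x)
    ct <- buildCells(x, c("rs1", "rs2"), residuals = M)
    ctNeg <- buildCells(x, c("rs1", "rs2"), residuals = -M)
    lab <- classifyCells(ct)@label
    labNeg <- classifyCells(ctNeg)@label
    flip <- ct@counts > 0 & abs(ct@residualSums) > 1e-12
    expect_true(all(lab[flip] != labNeg[flip]))
    expect_true(all(labNeg[!flip] == "L"))
})

test_that("the high-risk indicator is invariant to subject reordering", {
    x <- toyDataset(n = 50, m = 3, seed = 19)
    M <- martingaleResiduals(x)
    S1 <- classifyCells(buildCells(x, c("rs1", "rs3"), residuals = M))@S
    perm <- sample(50)
    xp <- SnpSurvivalExperiment(genotypeMatrix(x)[perm, ],
                                time = survTime(x)[perm],
                                status = eventStatus(x)[perm],
                                covariates = data.frame(
                                    z = covariateMatrix(x)[perm, "z"]))
    Mp <- martingaleResiduals(xp)
    S2 <- classifyCells(buildCells(xp, c("rs1", "rs3"),
                                   residuals = Mp))@S
    expect_equal(S2, S1[perm])
})

test_that("under the null the high-risk fraction has no pair dependence", {
    # residuals independent of genotype: mean S close for all pairs
    set.seed(77)
    fracs <- matrix(NA_real_, 30, 3)
    for (r in 1:30) {
        x <- toyDataset(n = 80, m = 3, seed = 1000 + r)
        M <- martingaleResiduals(x)
        prs <- list(c("rs1", "rs2"), c("rs1", "rs3"), c("rs2", "rs3"))
        fracs[r, ] <- vapply(prs, function(p)
            mean(classifyCells(buildCells(x, p, residuals = M))@S),
            numeric(1))
    }
    m <- colMeans(fracs)
    expect_lt(max(m) - min(m), 0.1)
})
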