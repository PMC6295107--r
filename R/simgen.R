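#' Simulation scenario configuration
#'
#' Collects the generative parameters of one simulated cohort: survival
#' times follow a Cox model \eqn{\lambda(t \mid x, z) = \lambda_0(t)
#' \exp(\alpha x + \gamma z + \delta\, SNP3)} with a Weibull baseline
#' \eqn{\Lambda_0(t) = (t / \mathrm{scale})^{\mathrm{shape}}}, where x is
#' the latent high-risk state drawn from the penetrance of the causal SNP
#' pair, z is a standard normal adjusting covariate and SNP3 optionally
#' carries a marginal main effect. Censoring times are Uniform(0, c) with
#' c calibrated to the target censoring fraction.
#'
#' @param n cohort size.
#' @param maf minor allele frequency (shared by all SNPs).
#' @param h2 heritability of the penetrance model (informational).
#' @param alpha log hazard ratio of the latent high-risk state.
#' @param gamma log hazard ratio of the covariate z.
#' @param delta marginal log hazard ratio of SNP3 (0 = no marginal effect).
#' @param weibullShape,weibullScale Weibull baseline parameters.
#' @param censorFraction target expected censoring fraction in `[0, 1)`;
#'   0 disables censoring.
#' @param nSnps number of simulated unlinked SNPs.
#' @param seed integer seed.
#' @return a validated list of class `scenarioConfig`.
#' @export
scenarioConfig <- function(n = 400L, maf = 0.2, h2 = 0.1,
                           alpha = 1.0, gamma = 1.0, delta = 0.0,
                           weibullShape = 5, weibullScale = 2,
                           censorFraction = 0, nSnps = 10L, seed = 1L) {
    if (n < 2) stopf("n must be >= 2")
    if (weibullShape <= 0 || weibullScale <= 0)
        stopf("Weibull shape and scale must be positive")
    if (censorFraction < 0 || censorFraction >= 1)
        stopf("censorFraction must be in [0, 1)")
    if (maf <= 0 || maf > 0.5) stopf("maf must be in (0, 0.5]")
    structure(list(n = as.integer(n), maf = maf, h2 = h2, alpha = alpha,
                   gamma = gamma, delta = delta,
                   weibullShape = weibullShape,
                   weibullScale = weibullScale,
                   censorFraction = censorFraction,
                   nSnps = as.integer(nSnps), seed = as.integer(seed)),
              class = "scenarioConfig")
}

# HWE genotype probabilities for minor allele frequency p, genotype = count
# of minor alleles.
hweProbs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

# Heritability of a 3x3 penetrance table under HWE cell weights:
# h2 = sum_ik P(G_ik) (f_ik - K)^2 / (K (1 - K)).
penetranceH2 <- function(f, maf) {
    P <- outer(hweProbs(maf), hweProbs(maf))
    K <- sum(P * f)
    sum(P * (f - K)^2) / (K * (1 - K))
}

#' Generate a pure-epistasis two-locus penetrance model
#'
#' Random search for a 3x3 penetrance table with a prescribed heritability
#' and no single-locus marginal effects. Each proposal starts from a
#' random table, is projected onto the pure-interaction space (so that
#' every single-SNP marginal penetrance equals the prevalence K exactly,
#' under HWE genotype weights) and is rescaled about K to hit the target
#' heritability; proposals with penetrances outside `[0, 1]` are
#' rejected. Different seeds yield different tables at the same
#' `(maf, h2)`, mirroring the catalogues of epistasis models used in MDR
#' power studies.
#'
#' @param maf minor allele frequency in (0, 0.5].
#' @param h2 target heritability in (0, 1).
#' @param seed integer seed.
#' @param maxProposals proposals before giving up.
#' @return a [PenetranceModel-class]; its stored `h2` is recomputed from
#'   the accepted table.
#' @export
generatePenetrance <- function(maf, h2, seed = 1L, maxProposals = 1e6) {
    if (maf <= 0 || maf > 0.5) stopf("maf must be in (0, 0.5]")
    if (h2 <= 0 || h2 >= 1) stopf("h2 must be in (0, 1)")
    p1 <- hweProbs(maf)
    P <- outer(p1, p1)
    withSeed(seed, {
        for (i in seq_len(maxProposals)) {
            K <- stats::runif(1, 0.05, 0.95)
            f0 <- matrix(stats::runif(9), 3, 3)
            # weighted two-way projection: remove both marginal effects
            m1 <- as.numeric(f0 %*% p1)          # marginal over SNP2
            m2 <- as.numeric(crossprod(f0, p1))  # marginal over SNP1
            K0 <- sum(P * f0)
            # interaction residual f - m1_i - m2_k + K0: zero weighted
            # marginals for both SNPs and zero weighted mean
            fI <- sweep(sweep(f0, 1, m1), 2, m2) + K0
            v <- sum(P * fI^2)
            if (v < 1e-12) next
            s <- sqrt(h2 * K * (1 - K) / v)
            f <- K + s * fI
            if (any(f < 0) || any(f > 1)) next
            return(methods::new("PenetranceModel", f = f, maf = maf,
                                K = sum(P * f),
                                h2 = penetranceH2(f, maf)))
        }
    })
    stopf("no penetrance table found for (maf = %g, h2 = %g)", maf, h2)
}

#' @describeIn PenetranceModel-class the 3x3 penetrance matrix.
#' @export
setMethod("penetrance", "PenetranceModel", function(object) object@f)

#' @describeIn PenetranceModel-class heritability of the table.
#' @export
setMethod("heritability", "PenetranceModel", function(object) object@h2)

#' @describeIn PenetranceModel-class prevalence K of the latent high-risk
#'   state.
#' @export
setMethod("prevalence", "PenetranceModel", function(object) object@K)

setMethod("show", "PenetranceModel", function(object) {
    cat(sprintf("PenetranceModel: maf %.2f, K %.3f, h2 %.4f\n",
                object@maf, object@K, object@h2))
    print(round(object@f, 3))
})

#' Simulate unlinked HWE genotypes
#'
#' Independent diallelic loci; genotypes are minor-allele counts drawn
#' with the Hardy-Weinberg probabilities \eqn{((1-p)^2, 2p(1-p), p^2)}.
#'
#' @param n number of subjects.
#' @param nSnps number of SNPs.
#' @param maf minor allele frequency, scalar or one per SNP.
#' @param seed integer seed.
#' @return integer matrix (subjects x SNPs) with columns `rs1..rsm`.
#' @export
simulateGenotypes <- function(n, nSnps, maf, seed = 1L) {
    maf <- rep_len(maf, nSnps)
    if (any(maf <= 0) || any(maf > 0.5)) stopf("maf must be in (0, 0.5]")
    withSeed(seed, {
        g <- vapply(maf, function(p) stats::rbinom(n, 2L, p), integer(n))
    })
    if (!is.matrix(g)) g <- matrix(g, nrow = n)
    colnames(g) <- paste0("rs", seq_len(nSnps))
    g
}

# Inverse-transform Weibull event time: Lambda0(t) = (t/scale)^shape, so
# T = scale * (-log(U) * exp(-eta))^(1/shape) has hazard
# lambda0(t) exp(eta).
weibullTime <- function(u, eta, shape, scale) {
    scale * (-log(u) * exp(-eta))^(1 / shape)
}

#' Simulate a cohort with two-locus epistatic survival risk
#'
#' Generates genotypes under HWE/linkage equilibrium, draws the latent
#' high-risk state x of each subject from the penetrance of the causal
#' pair (the first two SNPs), and produces survival times from the
#' Cox-Weibull model of [scenarioConfig()]. When
#' `scenario$censorFraction > 0`, censoring times are Uniform(0, c) with
#' c calibrated by [calibrateCensoring()].
#'
#' @param scenario a [scenarioConfig()].
#' @param penetrance a [PenetranceModel-class], or `NULL` for a null
#'   cohort (x = 0 for everyone; survival depends only on z).
#' @param censorBound optional pre-calibrated censoring bound c; when
#'   `NULL` it is calibrated here (experiment loops calibrate once per
#'   grid cell and pass it through).
#' @return a [SnpSurvivalExperiment-class] with covariate `z`. Simulation
#'   truth is recorded in `metadata()`: `causalPair`, `x`, `penetrance`,
#'   `censorBound`.
#' @export
simulateSurvival <- function(scenario, penetrance = NULL,
                             censorBound = NULL) {
    raw <- simulateCohortRaw(scenario, penetrance, censorBound)
    xobj <- SnpSurvivalExperiment(raw$geno, time = raw$time,
                                  status = raw$status,
                                  covariates = data.frame(z = raw$z))
    S4Vectors::metadata(xobj)$causalPair <-
        if (is.null(penetrance)) character()
        else colnames(raw$geno)[1:2]
    S4Vectors::metadata(xobj)$x <- raw$x
    S4Vectors::metadata(xobj)$penetrance <- penetrance
    S4Vectors::metadata(xobj)$censorBound <- raw$censorBound
    S4Vectors::metadata(xobj)$scenario <- scenario
    xobj
}

# Container-free cohort generation; simulateSurvival() wraps the result,
# the simulation harnesses consume it directly.
simulateCohortRaw <- function(scenario, penetrance = NULL,
                              censorBound = NULL) {
    stopifnot(inherits(scenario, "scenarioConfig"))
    n <- scenario$n
    geno <- simulateGenotypes(n, scenario$nSnps, scenario$maf,
                              seed = deriveSeed(scenario$seed, 1L))
    cc <- if (scenario$censorFraction <= 0) Inf
          else if (!is.null(censorBound)) censorBound
          else calibrateCensoring(scenario, scenario$censorFraction,
                                  penetrance = penetrance)
    withSeed(deriveSeed(scenario$seed, 2L), {
        z <- stats::rnorm(n)
        x <- if (is.null(penetrance)) rep(0L, n) else {
            fx <- penetrance@f[cbind(geno[, 1] + 1L, geno[, 2] + 1L)]
            stats::rbinom(n, 1L, fx)
        }
        eta <- scenario$alpha * x + scenario$gamma * z +
            scenario$delta * geno[, 3]
        Tt <- weibullTime(stats::runif(n), eta, scenario$weibullShape,
                          scenario$weibullScale)
        if (is.finite(cc)) {
            Ct <- stats::runif(n, 0, cc)
            time <- pmin(Tt, Ct)
            status <- as.integer(Tt <= Ct)
        } else {
            time <- Tt
            status <- rep(1L, n)
        }
    })
    list(geno = geno, z = z, x = x, time = time, status = status,
         censorBound = cc)
}

#' Calibrate the uniform censoring bound
#'
#' Finds c such that Uniform(0, c) censoring yields the target expected
#' censoring fraction \eqn{P(T > C)} under the scenario's event-time
#' distribution, by bisection on a Monte-Carlo estimate (fixed internal
#' seed; `nDraws` event times reused across bisection steps).
#'
#' @param scenario a [scenarioConfig()].
#' @param targetFraction target censoring fraction in (0, 1).
#' @param penetrance optional [PenetranceModel-class] for the latent
#'   high-risk state (as in [simulateSurvival()]).
#' @param nDraws Monte-Carlo sample size per evaluation.
#' @param tol tolerance on the achieved fraction.
#' @return the bound c.
#' @export
calibrateCensoring <- function(scenario, targetFraction,
                               penetrance = NULL, nDraws = 5e4,
                               tol = 0.005) {
    if (targetFraction <= 0 || targetFraction >= 1)
        stopf("targetFraction must be in (0, 1)")
    # event times and censoring quantiles drawn once, reused across steps
    sim <- withSeed(deriveSeed(scenario$seed, 9L), {
        if (is.null(penetrance)) {
            x <- rep(0L, nDraws)
        } else {
            g1 <- stats::rbinom(nDraws, 2L, scenario$maf)
            g2 <- stats::rbinom(nDraws, 2L, scenario$maf)
            x <- stats::rbinom(nDraws, 1L,
                               penetrance@f[cbind(g1 + 1L, g2 + 1L)])
        }
        g3 <- stats::rbinom(nDraws, 2L, scenario$maf)
        z <- stats::rnorm(nDraws)
        eta <- scenario$alpha * x + scenario$gamma * z +
            scenario$delta * g3
        list(T = weibullTime(stats::runif(nDraws), eta,
                             scenario$weibullShape,
                             scenario$weibullScale),
             u = stats::runif(nDraws))
    })
    frac <- function(cc) mean(sim$T > cc * sim$u)  # censored: T > C
    lo <- 1e-8
    hi <- max(sim$T) * 2
    while (frac(hi) > targetFraction) {
        hi <- hi * 2
        if (hi > 1e6) stopf("target censoring fraction unreachable")
    }
    for (i in seq_len(200)) {
        mid <- (lo + hi) / 2
        fm <- frac(mid)
        if (abs(fm - targetFraction) <= tol && i > 20) break
        if (fm > targetFraction) lo <- mid else hi <- mid
    }
    mid
}

#' Simulate a null cohort (no genetic effect)
#'
#' Survival depends only on the covariate z (\eqn{\lambda_0(t)
#' \exp(\gamma z)}); all SNPs are independent of the outcome. This is the
#' generating model of the type-I error study.
#'
#' @param n,nSnps,maf,censorFraction,gamma,seed see [scenarioConfig()].
#' @return a [SnpSurvivalExperiment-class].
#' @export
simulateNullDataset <- function(n = 400L, nSnps = 10L, maf = 0.2,
                                censorFraction = 0, gamma = 1.0,
                                seed = 1L) {
    sc <- scenarioConfig(n = n, maf = maf, h2 = 0, alpha = 0,
                         gamma = gamma, delta = 0,
                         censorFraction = censorFraction, nSnps = nSnps,
                         seed = seed)
    simulateSurvival(sc, penetrance = NULL)
}
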