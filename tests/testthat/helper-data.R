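# Small in-code fixtures shared across test files.

# Deterministic toy cohort: n subjects, m SNPs, exponential-ish times.
toyDataset <- function(n = 60, m = 4, seed = 11, censorProb = 0.3,
                       maf = 0.3) {
    set.seed(seed)
    g <- matrix(rbinom(n * m, 2, maf), n, m,
                dimnames = list(NULL, paste0("rs", seq_len(m))))
    z <- rnorm(n)
    tt <- round(rexp(n, exp(0.5 * z)), 4) + 1e-3
    st <- rbinom(n, 1, 1 - censorProb)
    if (sum(st) == 0) st[1] <- 1L
    SnpSurvivalExperiment(g, time = tt, status = st,
                          covariates = data.frame(z = z))
}

# Brute-force Breslow partial log-likelihood for a single-covariate model,
# used as an independent grid-search oracle for coxFit.
breslowLoglik <- function(beta, time, status, x) {
    ord <- order(time)
    tt <- time[ord]; st <- status[ord]; xx <- x[ord]
    ll <- 0
    for (s in unique(tt[st == 1])) {
        ev <- which(tt == s & st == 1)
        atRisk <- which(tt >= s)
        ll <- ll + beta * sum(xx[ev]) -
            length(ev) * log(sum(exp(beta * xx[atRisk])))
    }
    ll
}

# Independent 9-cell summation for penetrance-model verification.
bruteForcePenetranceCheck <- function(model) {
    p <- c((1 - model@maf)^2, 2 * model@maf * (1 - model@maf),
           model@maf^2)
    K <- 0
    for (i in 1:3) for (k in 1:3) K <- K + p[i] * p[k] * model@f[i, k]
    v <- 0
    for (i in 1:3) for (k in 1:3)
        v <- v + p[i] * p[k] * (model@f[i, k] - K)^2
    marg1 <- marg2 <- numeric(3)
    for (i in 1:3) {
        for (k in 1:3) {
            marg1[i] <- marg1[i] + p[k] * model@f[i, k]
            marg2[i] <- marg2[i] + p[k] * model@f[k, i]
        }
    }
    list(K = K, h2 = v / (K * (1 - K)), marg1 = marg1, marg2 = marg2)
}
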