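test_that("Nelson-Aalen matches hand-computed d/r sums", {
    na <- nelsonAalen(c(1, 2, 3), c(1, 1, 1))
    expect_equal(cumhazAt(na, c(1, 2, 3)),
                 c(1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1))
    # right-continuity and zero before the first event
    expect_equal(cumhazAt(na, c(0.5, 1.5)), c(0, 1 / 3))

    # Breslow tie handling: two events share the full risk set
    na2 <- nelsonAalen(c(1, 1, 2), c(1, 1, 1))
    expect_equal(cumhazAt(na2, c(1, 2)), c(2 / 3, 2 / 3 + 1))

    # no events -> identically zero
    na0 <- nelsonAalen(c(1, 2, 3), c(0, 0, 0))
    expect_equal(cumhazAt(na0, c(0.1, 5)), c(0, 0))

    expect_error(nelsonAalen(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("cumulative hazard is invariant to subject order", {
    set.seed(4)
    tt <- round(rexp(30), 2) + 0.01
    st <- rbinom(30, 1, 0.7)
    perm <- sample(30)
    grid <- seq(0, max(tt), length.out = 50)
    expect_equal(cumhazAt(nelsonAalen(tt, st), grid),
                 cumhazAt(nelsonAalen(tt[perm], st[perm]), grid))
})

test_that("coxFit maximizes the Breslow partial likelihood (grid oracle)", {
    set.seed(21)
    for (i in 1:3) {
        n <- 20
        x <- rbinom(n, 1, 0.5)
        tt <- round(rexp(n, exp(0.7 * x)), 2) + 0.01
        st <- rbinom(n, 1, 0.8)
        if (sum(st) == 0 || min(x) == max(x)) next
        fit <- coxFit(cbind(x = x), time = tt, status = st)
        grid <- seq(-5, 5, by = 1e-4)
        ll <- vapply(grid, breslowLoglik, numeric(1), time = tt,
                     status = st, x = x)
        expect_equal(unname(coef(fit)["x"]), grid[which.max(ll)],
                     tolerance = 1e-3)
    }
})

test_that("coxFit agrees with survival::coxph under Breslow ties", {
    set.seed(9)
    n <- 120
    g <- rbinom(n, 2, 0.3)
    z <- rnorm(n)
    tt <- round(rexp(n, exp(0.4 * g + 0.6 * z)), 1) + 0.1  # forces ties
    st <- rbinom(n, 1, 0.75)
    f1 <- coxFit(cbind(g = g, z = z), time = tt, status = st)
    f2 <- survival::coxph(survival::Surv(tt, st) ~ g + z,
                          ties = "breslow")
    expect_equal(unname(coef(f1)), unname(coef(f2)), tolerance = 1e-6)
    expect_equal(unname(vcov(f1)), unname(vcov(f2)), tolerance = 1e-6)
    expect_equal(logLik(f1), f2$loglik[2], tolerance = 1e-8)
})

test_that("coxFit is zero under exchange symmetry and rejects bad designs", {
    # mirrored event times across two groups
    tt <- c(1, 2, 3, 1, 2, 3)
    st <- rep(1, 6)
    gr <- rep(0:1, each = 3)
    fit <- coxFit(cbind(g = gr), time = tt, status = st)
    expect_equal(unname(coef(fit)["g"]), 0, tolerance = 1e-8)

    expect_error(coxFit(cbind(one = rep(1, 6)), time = tt, status = st),
                 "constant column")
    expect_error(coxFit(cbind(a = gr, b = 2 * gr), time = tt, status = st),
                 "collinear")
    expect_error(coxFit(cbind(g = gr), time = tt, status = rep(0, 6)),
                 "at least one event")
})

test_that("coxFit recovers a known coefficient at large n", {
    set.seed(33)
    n <- 2000
    x <- rbinom(n, 1, 0.5)
    u <- runif(n)
    tt <- -log(u) * exp(-1.0 * x)   # true beta = 1, Exp baseline
    fit <- coxFit(cbind(x = x), time = tt, status = rep(1, n))
    se <- sqrt(vcov(fit)["x", "x"])
    expect_lt(abs(coef(fit)["x"] - 1), 3 * se)
})

test_that("martingale residuals match hand values and their invariants", {
    x <- SnpSurvivalExperiment(
        matrix(0:2, 3, 1, dimnames = list(NULL, "rs1")),
        time = c(1, 2, 3), status = c(1, 1, 1))
    m <- martingaleResiduals(x)
    expect_equal(m, c(1 - 1 / 3, 1 - 5 / 6, 1 - 11 / 6),
                 ignore_attr = TRUE)
    expect_equal(sum(m), 0, tolerance = 1e-12)

    # censored before the first event time -> residual 0
    x2 <- SnpSurvivalExperiment(
        matrix(0, 3, 1, dimnames = list(NULL, "rs1")),
        time = c(0.5, 2, 3), status = c(0, 1, 1))
    expect_equal(martingaleResiduals(x2)[1], 0, ignore_attr = TRUE)

    # zero-sum and upper bound across random datasets
    for (s in 1:100) {
        xs <- toyDataset(n = 25, seed = s)
        ms <- martingaleResiduals(xs)
        expect_lt(abs(sum(ms)), 1e-8)
        expect_true(all(ms <= 1 + 1e-12))
    }
})

test_that("adjusted martingale residuals match survival::coxph", {
    x <- toyDataset(n = 80, seed = 14)
    m <- martingaleResiduals(x, "adjusted")
    cph <- survival::coxph(
        survival::Surv(survTime(x), eventStatus(x)) ~ covariateMatrix(x),
        ties = "breslow")
    expect_equal(m, unname(residuals(cph, type = "martingale")),
                 tolerance = 1e-8)
})

test_that("log-rank test matches the hand-computed O-E oracle", {
    # toy: times 1..4, all events, groups A,A,B,B
    tt <- 1:4
    st <- rep(1, 4)
    gr <- c(0, 0, 1, 1)
    # hand O-E for group B (expected share of each death = r_B / r):
    #   t=1: r=4, r_B=2, O=0, E=1/2, v=(1/2)(1/2)=1/4
    #   t=2: r=3, r_B=2, O=0, E=2/3, v=(2/3)(1/3)=2/9
    #   t=3: r=2, r_B=2, O=1, E=1,   v=0
    #   t=4: r=1, r_B=1, O=1, E=1,   v=0
    U <- 2 - (1 / 2 + 2 / 3 + 1 + 1)     # = -7/6
    V <- 1 / 4 + 2 / 9
    lr <- logrankTest(tt, st, gr)
    expect_equal(lr$statistic, U^2 / V, tolerance = 1e-8)
    expect_equal(lr$p.value,
                 pchisq(U^2 / V, 1, lower.tail = FALSE))

    # identical event patterns in both groups -> statistic 0, p 1
    lr0 <- logrankTest(c(1, 2, 1, 2), c(1, 1, 1, 1), c(0, 0, 1, 1))
    expect_equal(lr0$statistic, 0, tolerance = 1e-12)
    expect_equal(lr0$p.value, 1, tolerance = 1e-12)

    # chi-square calibration: statistic at the 95% quantile -> p = 0.05
    expect_equal(pchisq(qchisq(0.95, 1), 1, lower.tail = FALSE), 0.05)
    expect_error(logrankTest(tt, st, rep(0, 4)), "two non-empty groups")
})
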