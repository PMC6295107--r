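#' Nelson-Aalen estimator of the cumulative hazard
#'
#' \eqn{\hat\Lambda(t) = \sum_{s \le t} d_s / r_s} over distinct event
#' times \eqn{s}, with \eqn{d_s} events and \eqn{r_s} subjects at risk at
#' \eqn{s}. Ties are handled in the Breslow convention (one risk set per
#' distinct event time). This is the baseline cumulative hazard of a Cox
#' model with no covariates, the quantity behind baseline-only martingale
#' residuals.
#'
#' @param time positive observed times.
#' @param status event indicator (1 = event, 0 = censored).
#' @return a [CumHazard-class] step function.
#' @examples
#' na <- nelsonAalen(c(1, 2, 3), c(1, 1, 1))
#' cumhazAt(na, c(0.5, 1, 2.5, 3))  # 0, 1/3, 5/6, 11/6
#' @export
nelsonAalen <- function(time, status) {
    if (any(time < 0)) stopf("time must be nonnegative")
    if (!all(status %in% c(0, 1))) stopf("status must be 0 or 1")
    breslowCumhaz(time, status, eta = rep(0, length(time)))
}

# Breslow baseline cumulative hazard for linear predictor eta:
# Lambda0(t) = sum_{event times s <= t} d_s / sum_{t_j >= s} exp(eta_j).
# With eta == 0 this is the Nelson-Aalen estimator.
breslowCumhaz <- function(time, status, eta) {
    ord <- order(time)
    tt <- time[ord]
    st <- status[ord]
    w <- exp(eta[ord])
    # risk-set denominator at each sorted time (reverse cumsum); under
    # Breslow ties every member of a tied block shares the risk set of the
    # block's first position
    denom <- rev(cumsum(rev(w)))
    ev <- st == 1
    if (!any(ev))
        return(methods::new("CumHazard", eventTimes = numeric(),
                            values = numeric()))
    first <- !duplicated(tt)
    dAt <- rowsum(as.numeric(ev), tt)[, 1]       # events per distinct time
    rAt <- denom[first]
    keep <- dAt > 0
    etimes <- tt[first][keep]
    increments <- dAt[keep] / rAt[keep]
    methods::new("CumHazard", eventTimes = unname(etimes),
                 values = unname(cumsum(increments)))
}

#' @rdname cumhazAt
#' @export
setMethod("cumhazAt", "CumHazard", function(object, t) {
    if (!length(object@eventTimes)) return(rep(0, length(t)))
    idx <- findInterval(t, object@eventTimes)
    unname(c(0, object@values)[idx + 1L])
})

setMethod("show", "CumHazard", function(object) {
    cat(sprintf("CumHazard with %d event times\n",
                length(object@eventTimes)))
    if (length(object@eventTimes))
        cat(sprintf("  range: Lambda(%g) = %.4g ... Lambda(%g) = %.4g\n",
                    object@eventTimes[1], object@values[1],
                    max(object@eventTimes), max(object@values)))
})

#' Fit a Cox proportional hazards model (Breslow ties)
#'
#' Maximizes the Breslow partial likelihood by Newton-Raphson with step
#' halving. The covariance is the inverse observed information at the
#' maximum. Monotone likelihood (separation) is reported via
#' `converged = FALSE` with coefficients capped at +/-15.
#'
#' Either pass a design matrix `X` directly, or a
#' [SnpSurvivalExperiment-class] together with `columns` naming SNP and/or
#' covariate columns to assemble the design from.
#'
#' @param x a [SnpSurvivalExperiment-class] or a numeric design matrix with
#'   named columns.
#' @param columns when `x` is an experiment: character vector of design
#'   columns, matched first against covariate names, then SNP names.
#' @param time,status survival outcome when `x` is a matrix.
#' @param maxit maximum Newton iterations.
#' @return a [CoxFit-class].
#' @examples
#' set.seed(1)
#' tm <- rexp(50); gr <- rep(0:1, 25)
#' fit <- coxFit(cbind(group = gr), time = tm, status = rep(1, 50))
#' coef(fit)
#' @export
coxFit <- function(x, columns = NULL, time = NULL, status = NULL,
                   maxit = 50L) {
    if (methods::is(x, "SnpSurvivalExperiment")) {
        time <- survTime(x)
        status <- eventStatus(x)
        X <- designMatrix(x, columns)
    } else {
        X <- as.matrix(x)
        if (is.null(colnames(X)))
            colnames(X) <- paste0("x", seq_len(ncol(X)))
    }
    keep <- stats::complete.cases(X) & !is.na(time) & !is.na(status)
    X <- X[keep, , drop = FALSE]
    time <- time[keep]
    status <- as.integer(status[keep])
    if (sum(status) < 1L)
        stopf("at least one event is required to fit a Cox model")
    constant <- apply(X, 2, function(v) max(v) == min(v))
    if (any(constant))
        stopf("constant column: %s",
              paste(colnames(X)[constant], collapse = ", "))
    if (qr(X)$rank < ncol(X))
        stopf("collinear design matrix (rank %d < %d columns)",
              qr(X)$rank, ncol(X))
    ord <- order(time)
    fit <- cox_newton_cpp(X[ord, , drop = FALSE], time[ord], status[ord],
                          maxit = as.integer(maxit))
    beta <- as.numeric(fit$coefficients)
    names(beta) <- colnames(X)
    cov <- fit$covariance
    dimnames(cov) <- list(colnames(X), colnames(X))
    methods::new("CoxFit", coefficients = beta, covariance = cov,
                 loglik = as.numeric(fit$loglik),
                 converged = isTRUE(fit$converged),
                 nEvents = sum(status), n = length(time))
}

# Assemble a named design matrix from covariates and/or SNP columns.
designMatrix <- function(x, columns) {
    covs <- covariateMatrix(x)
    geno <- genotypeMatrix(x)
    if (is.null(columns)) columns <- colnames(covs)
    cols <- lapply(columns, function(nm) {
        if (nm %in% colnames(covs)) covs[, nm]
        else if (nm %in% colnames(geno)) geno[, nm]
        else stopf("unknown design column '%s'", nm)
    })
    m <- do.call(cbind, cols)
    colnames(m) <- columns
    m
}

#' @describeIn coxFit coefficient accessor.
#' @param object a `CoxFit`.
#' @export
setMethod("coef", "CoxFit", function(object) object@coefficients)

#' @describeIn coxFit covariance accessor.
#' @export
setMethod("vcov", "CoxFit", function(object) object@covariance)

#' @describeIn coxFit maximized partial log-likelihood.
#' @export
setMethod("logLik", "CoxFit", function(object) object@loglik)

setMethod("show", "CoxFit", function(object) {
    cat(sprintf("CoxFit (%d subjects, %d events)%s\n", object@n,
                object@nEvents,
                if (object@converged) "" else "  [NOT converged]"))
    se <- sqrt(diag(object@covariance))
    tab <- data.frame(coef = object@coefficients, se = se,
                      z = object@coefficients / se)
    print(round(tab, 4))
})

#' Martingale residuals
#'
#' \eqn{M_i = \delta_i - \hat\Lambda_0(t_i)\, e^{\hat\eta_i}} with the
#' Breslow baseline cumulative hazard evaluated at each subject's own
#' observed time. In `"baseline"` mode \eqn{\hat\eta_i = 0} and
#' \eqn{\hat\Lambda_0} reduces to the Nelson-Aalen estimator — the null
#' model used for the MDR classification step. In `"adjusted"` mode the
#' null model first fits the adjusting covariates.
#'
#' Residuals lie in \eqn{(-\infty, 1]}; for a baseline-only fit they sum
#' to zero.
#'
#' @param x a [SnpSurvivalExperiment-class].
#' @param nullModel `"baseline"` (default) or `"adjusted"`.
#' @return numeric vector of residuals, one per subject.
#' @export
martingaleResiduals <- function(x, nullModel = c("baseline", "adjusted")) {
    nullModel <- match.arg(nullModel)
    time <- survTime(x)
    status <- eventStatus(x)
    if (nullModel == "baseline") {
        eta <- rep(0, length(time))
    } else {
        covs <- covariateMatrix(x)
        if (ncol(covs) == 0)
            stopf("adjusted null model requires covariates")
        fit <- coxFit(covs, time = time, status = status)
        eta <- as.numeric(covs %*% coef(fit))
    }
    ch <- breslowCumhaz(time, status, eta)
    status - cumhazAt(ch, time) * exp(eta)
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the survival curves of two
#' groups, with its upper-tail p-value.
#'
#' @param time,status survival outcome.
#' @param group binary group membership (two distinct values).
#' @return list with `statistic` and `p.value`.
#' @export
logrankTest <- function(time, status, group) {
    g <- as.factor(group)
    if (nlevels(droplevels(g)) != 2L)
        stopf("exactly two non-empty groups are required")
    if (sum(status) < 1L) stopf("at least one event is required")
    sd <- survival::survdiff(survival::Surv(time, status) ~ g)
    stat <- as.numeric(sd$chisq)
    list(statistic = stat,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
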