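#' Control parameters for a Cox UM-MDR analysis
#'
#' @param interactionOrder number of SNPs per combination (k); the default
#'   2 scans all pairs.
#' @param nPerm number of trait permutations used to estimate the
#'   non-centrality parameter of the Wald statistic's null distribution.
#'   A handful suffices (default 5): the permuted Wald statistics are
#'   averaged, not used as an empirical reference distribution.
#' @param noncentrality `"per_combination"` estimates one non-centrality
#'   parameter per SNP combination; `"pooled"` pools the permuted
#'   statistics of all combinations into a single common estimate.
#' @param adjustMainEffects include the additive main effects of the
#'   combination's SNPs in the step-2 Cox model (recommended when SNPs may
#'   carry marginal effects).
#' @param adjustCovariatesStep1 compute the step-1 classification residuals
#'   from a covariate-adjusted null Cox model instead of the baseline-only
#'   (no-covariate) null model.
#' @param alpha nominal significance level.
#' @param seed integer seed governing every randomized step (permutations,
#'   cross-validation folds).
#' @param tiesMethod tie handling in all Cox computations; only
#'   `"breslow"` is implemented.
#' @return a validated list of class `ummdrControl`.
#' @export
ummdrControl <- function(interactionOrder = 2L,
                         nPerm = 5L,
                         noncentrality = c("per_combination", "pooled"),
                         adjustMainEffects = FALSE,
                         adjustCovariatesStep1 = FALSE,
                         alpha = 0.05,
                         seed = 1L,
                         tiesMethod = "breslow") {
    noncentrality <- match.arg(noncentrality)
    tiesMethod <- match.arg(tiesMethod)
    interactionOrder <- as.integer(interactionOrder)
    nPerm <- as.integer(nPerm)
    if (interactionOrder < 1L) stopf("interactionOrder must be >= 1")
    if (nPerm < 1L) stopf("nPerm must be >= 1")
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
        stopf("alpha must be in (0, 1)")
    structure(list(interactionOrder = interactionOrder,
                   nPerm = nPerm,
                   noncentrality = noncentrality,
                   adjustMainEffects = isTRUE(adjustMainEffects),
                   adjustCovariatesStep1 = isTRUE(adjustCovariatesStep1),
                   alpha = as.numeric(alpha),
                   seed = as.integer(seed),
                   tiesMethod = tiesMethod),
              class = "ummdrControl")
}

#' @export
print.ummdrControl <- function(x, ...) {
    cat("ummdrControl:\n")
    for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
    invisible(x)
}
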