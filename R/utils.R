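#' Derive a reproducible child seed
#'
#' Deterministically maps a base seed plus one or more stream indices
#' (replicate number, permutation number, grid-cell index, ...) to a new
#' 32-bit seed. Used everywhere randomness is split across independent work
#' units so that results are identical at any execution order.
#'
#' @param seed integer base seed.
#' @param ... integer stream indices.
#' @return a single integer in `[1, 2147483646]`.
#' @export
deriveSeed <- function(seed, ...) {
    idx <- as.double(c(...))
    s <- as.double(as.integer(seed) %% 2147483647L)
    if (length(idx)) {
        for (k in seq_along(idx)) {
            # constants are primes; products stay well below 2^53
            s <- (s * 7919 + idx[k] * 104729 + k * 31) %% 2147483646
        }
    } else {
        s <- (s * 7919 + 17) %% 2147483646
    }
    as.integer(s) + 1L
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
        if (had) {
            assign(".Random.seed", old, envir = genv)
        } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
            rm(".Random.seed", envir = genv)
        }
    })
    set.seed(as.integer(seed))
    expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
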