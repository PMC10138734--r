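# internal helpers shared across modules

# round half away from zero at `digits` decimals (stats::median of percent
# identities must compare reproducibly; base round() is round-half-even).
# The 1e-9 guard absorbs binary representation error just below the .5
# boundary.
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# one named pseudo-random stream per simulator: a fixed integer seed plus a
# stream label yield a deterministic sub-seed, and the surrounding RNG state
# is restored afterwards so simulator calls do not perturb each other.
streamSeed <- function(seed, stream) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    v <- utf8ToInt(stream)
    h <- sum(v * seq_along(v)) %% 65521
    as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483629)
}

withStream <- function(seed, stream, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(streamSeed(seed, stream))
    force(expr)
}

# tiny FNV-1a over a character scalar; used to stamp parameter digests into
# output headers without an external hashing dependency
fnv1a <- function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
        h <- bitwXor(as.integer(h %% 2^31), b)
        h <- (h * 16777619) %% 2^31
    }
    sprintf("%08x", as.integer(h))
}

.featureIds <- function(gr, default_prefix = "feature") {
    ids <- names(gr)
    if (is.null(ids) && !is.null(mcols(gr)$id)) ids <- mcols(gr)$id
    if (is.null(ids) && !is.null(mcols(gr)$name)) ids <- mcols(gr)$name
    if (is.null(ids)) ids <- paste0(default_prefix, seq_along(gr))
    as.character(ids)
}
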