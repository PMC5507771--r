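# Internal helpers shared across modules.

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
# seed = NULL means "use the current stream" (no save/restore).
withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(eval.parent(substitute(expr)))
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("seed must be a single integer")
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    eval.parent(substitute(expr))
}

# 32-bit FNV-1a hash of a character string, reduced below 2^31 so the result
# is a valid R seed. Used to derive stable per-stage / per-cell seeds.
fnvHash <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    h <- 2166136261 %% 2^31
    m <- 16777619
    for (b in utf8ToInt(x)) {
        # xor the low byte (FNV-1a step), exactly representable in doubles
        low <- h %% 256
        h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
        # multiply mod 2^31 without losing double precision
        a <- h %/% 65536; c <- h %% 65536
        h <- (((a * m) %% 32768) * 65536 + c * m) %% 2^31
    }
    as.integer(h %% (2^31 - 1))
}

# Stable seed for a (master seed, label) pair, below 2^31.
deriveSeed <- function(seed, label) {
    as.integer((as.numeric(seed) + as.numeric(fnvHash(label))) %% (2^31 - 1))
}

# Trapezoidal area under y(t).
trapz <- function(t, y) {
    sum(diff(t) * (head(y, -1L) + tail(y, -1L)) / 2)
}

# Short hash of an R object (by its deparsed form) for config fingerprints.
configHash <- function(x) {
    sprintf("%08x", fnvHash(paste(deparse(x), collapse = "\n")))
}
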