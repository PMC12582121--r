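# Seed plumbing: all generator randomness flows from one master seed through
# named substreams, so each stage is reproducible in isolation and adding a
# stage never perturbs another stage's draws.

.STREAMS <- c(screen = 1L, annotation = 2L, sites = 3L, expression = 4L,
              titration = 5L, mass = 6L, decay = 7L, control = 8L,
              pipeline = 9L)

streamSeed <- function(seed, stream) {
    stream <- match.arg(stream, names(.STREAMS))
    idx <- .STREAMS[[stream]]
    old <- .saveRNG()
    on.exit(.restoreRNG(old), add = TRUE)
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max - 1L, length(.STREAMS))[idx]
}

.saveRNG <- function() {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv())
    else NULL
}

.restoreRNG <- function(state) {
    if (is.null(state)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", state, envir = globalenv())
    }
    invisible(NULL)
}

# Evaluate `expr` under the RNG substream `stream` of `seed`, leaving the
# caller's RNG state untouched.
withStream <- function(seed, stream, expr) {
    old <- .saveRNG()
    on.exit(.restoreRNG(old), add = TRUE)
    set.seed(streamSeed(seed, stream))
    expr
}

.assertScalarNumeric <- function(x, name, positive = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
    if (positive && x <= 0)
        stop(sprintf("'%s' must be positive", name), call. = FALSE)
    invisible(x)
}
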