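# internal helpers shared across modules

.edgeKey <- function(from, to) paste(from, to, sep = "\t")

# run expr under a temporary RNG state; the caller's stream is untouched
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(if (had) assign(".Random.seed", old, envir = env)
            else if (exists(".Random.seed", envir = env, inherits = FALSE))
                rm(".Random.seed", envir = env))
    set.seed(seed)
    expr
}

# deterministic per-stream child seed; adding streams never perturbs earlier
# ones. Kept below 2^31 so set.seed() accepts it.
.childSeed <- function(seed, k) {
    as.integer((as.numeric(seed) + as.numeric(k) * 104729) %% 2147483647)
}

.assertScalarNumeric <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
        stop("'", name, "' must be a single finite number", call. = FALSE)
}
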