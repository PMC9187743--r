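# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stream index.
# Multiplier kept small so seed * 69069 stays exactly representable in a
# double; result always lies in [1, 2^31 - 2].
childSeed <- function(seed, stream) {
    stopifnot(is.numeric(seed), length(seed) == 1L)
    as.integer((abs(seed) * 69069 + 12345 + stream) %% 2147483646) + 1L
}

.setSeedIfGiven <- function(seed) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    invisible(NULL)
}

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
        stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
            call. = FALSE)
    invisible(x)
}

# Strict TSV reader used by all table readers.
.readTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
        stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = TRUE)
    invisible(path)
}
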