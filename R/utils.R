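#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded package
#' functions never disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Deterministic child seed for animal/replicate i, kept inside 32-bit range.
childSeed <- function(seed, i) {
    as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483587)
}

#' Build and parse n-gram keys
#'
#' N-grams are keyed as dash-separated original syllable IDs, e.g. `"16-2"`
#' for the bigram (16, 2).
#'
#' @param mat Integer matrix, one n-gram per row.
#' @param keys Character vector of keys.
#' @return `ngramKey`: character keys; `parseNgramKey`: integer matrix.
#' @keywords internal
ngramKey <- function(mat) {
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
    apply(mat, 1L, paste, collapse = "-")
}

#' @rdname ngramKey
#' @keywords internal
parseNgramKey <- function(keys) {
    if (length(keys) == 0L) return(matrix(integer(0), ncol = 0L))
    parts <- strsplit(keys, "-", fixed = TRUE)
    n <- lengths(parts)
    if (length(unique(n)) != 1L)
        stop("n-gram keys of mixed order")
    matrix(as.integer(unlist(parts)), ncol = n[1L], byrow = TRUE)
}

# Order n-gram keys lexicographically by their numeric components.
orderNgramKeys <- function(keys) {
    if (length(keys) == 0L) return(character(0))
    m <- parseNgramKey(keys)
    keys[do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))]
}

stopIfNotProb <- function(p, what = "p") {
    if (length(p) == 0L) stop("'", what, "' is empty")
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("'", what, "' values must lie in [0, 1]")
    invisible(p)
}
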