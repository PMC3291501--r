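# Internal helpers shared across modules.

#' Evaluate an expression with a private RNG stream
#'
#' Saves and restores the caller's `.Random.seed`, so that every simulation
#' operation is a pure function of its inputs and its `seed` argument.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
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

# 0-based half-open [start, end) -> IRanges (1-based inclusive).
.ir0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# IRanges -> 0-based half-open columns.
.from_ir0 <- function(ir)
    data.frame(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))

# Lexicographic "a < b" on character vectors (element-wise, then length).
.lexLess <- function(a, b) {
    n <- min(length(a), length(b))
    if (n > 0L) {
        for (i in seq_len(n)) {
            if (a[i] < b[i]) return(TRUE)
            if (a[i] > b[i]) return(FALSE)
        }
    }
    length(a) < length(b)
}

# stopifnot with a clearer message.
.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Rounded percentage in the printed-report convention
#'
#' Computes `100 * numerator / denominator` rounded half-up to the requested
#' number of decimal places (the convention used in the package's summary
#' tables; unlike [round()], 0.5 always rounds away from zero).
#'
#' @param numerator,denominator Non-negative numbers in the same unit.
#' @param decimals Number of decimal places (default 1).
#' @return A single numeric percentage.
#' @examples
#' percentOf(126, 377)        # 33.4
#' percentOf(59899, 67047)    # 89.3
#' @export
percentOf <- function(numerator, denominator, decimals = 1L) {
    .check(is.numeric(denominator) && all(denominator > 0),
           "'denominator' must be > 0")
    x <- 100 * numerator / denominator
    f <- 10^decimals
    floor(x * f + 0.5) / f
}
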