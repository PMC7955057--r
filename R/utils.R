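## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so package functions never perturb user code.
with_seed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
        stop("'seed' must be a single finite number", call. = FALSE)
    }
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
                rm(".Random.seed", envir = globalenv())
            },
            add = TRUE
        )
    }
    set.seed(as.integer(seed))
    expr
}

## Derive a per-stage child seed from a global seed; offsets are fixed per
## stage so toggling one stage never shifts another's random stream.
child_seed <- function(seed, offset) {
    (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L
}

## Row-wise mean/sd over a matrix with NAs, n-1 denominator.
row_stats <- function(x) {
    n <- rowSums(!is.na(x))
    mu <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums((x - mu)^2, na.rm = TRUE)
    sd <- sqrt(ss / pmax(n - 1, 1))
    sd[n < 2] <- NA_real_
    mu[n < 1] <- NA_real_
    list(n = n, mean = mu, sd = sd)
}

## Fast per-row Pearson correlation of each row of `x` against vector `y`
## (pairwise complete rows are not needed here: callers pass complete data).
row_cor <- function(x, y) {
    xc <- x - rowMeans(x)
    yc <- y - mean(y)
    num <- as.vector(xc %*% yc)
    den <- sqrt(rowSums(xc^2) * sum(yc^2))
    r <- num / den
    r[den == 0] <- NA_real_
    r
}

## Per-row OLS slope of each row of `x` on `y`.
row_slope <- function(x, y) {
    yc <- y - mean(y)
    ssy <- sum(yc^2)
    if (ssy == 0) {
        return(rep(NA_real_, nrow(x)))
    }
    as.vector((x - rowMeans(x)) %*% yc) / ssy
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
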