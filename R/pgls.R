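#' Longevity quotient from lifespan and body mass
#'
#' The longevity quotient (LQ) is the ratio of a species' observed maximum
#' lifespan to the lifespan expected under a mass allometry for a
#' nonflying placental mammal, `expected = a * mass^b`. The allometric
#' coefficients are study configuration and must be supplied explicitly.
#'
#' @param max_lifespan observed maximum lifespan, years (> 0).
#' @param body_mass body mass, grams (> 0).
#' @param allometry named numeric `c(a, b)`.
#' @return Numeric LQ (vectorized).
#' @examples
#' computeLQ(60, 500, allometry = c(a = 10, b = 0)) # 6
#' @export
computeLQ <- function(max_lifespan, body_mass, allometry) {
    if (any(max_lifespan <= 0) || any(body_mass <= 0)) {
        stopf("max_lifespan and body_mass must be > 0")
    }
    if (length(allometry) != 2) stopf("allometry must be c(a, b)")
    a <- allometry[[1]]
    b <- allometry[[2]]
    max_lifespan / (a * body_mass^b)
}

#' Per-species mean methylation rates at age DMPs
#'
#' For each species with at least `min_rate_samples` known-age samples,
#' computes per-probe rates of methylation change as the OLS slope of beta
#' on age (beta-units/year), then averages them over the
#' hypermethylating and (separately) hypomethylating probes of `dmps`.
#' Hypomethylation rates are signed and typically negative.
#'
#' @param x a [MethylAgingExperiment-class].
#' @param dmps a `dmpSet` (e.g. from [selectAgeDMPs()]).
#' @param min_rate_samples minimum per-species sample count (default 10).
#' @return data.frame with `species`, `n_samples`, `mean_hyper_rate`,
#'   `mean_hypo_rate`.
#' @export
methylationRates <- function(x, dmps, min_rate_samples = 10) {
    if (nrow(dmps) == 0) stopf("empty DMP set")
    b <- betaValues(x)
    smp <- sampleTable(x)
    hyper <- dmps$probe_id[dmps$direction == "hyper"]
    hypo <- dmps$probe_id[dmps$direction == "hypo"]
    tab <- table(smp$species)
    keep <- names(tab)[tab >= min_rate_samples]
    dropped <- setdiff(names(tab), keep)
    if (length(dropped)) {
        message(sprintf("%d species below %d samples excluded from rate table",
                        length(dropped), min_rate_samples))
    }
    res <- lapply(sort(keep), function(sp) {
        sel <- smp$species == sp
        slopes <- row_slope(b[, sel, drop = FALSE], smp$age[sel])
        names(slopes) <- rownames(b)
        data.frame(
            species = sp, n_samples = sum(sel),
            mean_hyper_rate = mean(slopes[hyper], na.rm = TRUE),
            mean_hypo_rate = mean(slopes[hypo], na.rm = TRUE),
            stringsAsFactors = FALSE
        )
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Brownian-motion phylogenetic covariance
#'
#' Under Brownian trait evolution the covariance of two tips equals their
#' shared root-to-tip path length. Computed via [ape::vcv()] and reordered
#' to `species_order`.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param species_order character vector of tip names defining row/column
#'   order (default: tree tip order).
#' @return Symmetric positive semi-definite covariance matrix with the
#'   root-to-tip distances on the diagonal.
#' @export
brownianCovariance <- function(tree, species_order = tree$tip.label) {
    missing <- setdiff(species_order, tree$tip.label)
    if (length(missing)) {
        stopf("species missing from tree: %s", paste(missing, collapse = ", "))
    }
    C <- ape::vcv(tree)
    C[species_order, species_order, drop = FALSE]
}

#' Phylogenetic generalized least squares fit
#'
#' Solves the GLS problem with a fixed residual covariance `C`
#' (typically from [brownianCovariance()]):
#' `bhat = (X' C^-1 X)^-1 X' C^-1 y`, residual scale
#' `sigma2 = r' C^-1 r / (n - p)`, coefficient covariance
#' `sigma2 * (X' C^-1 X)^-1`, two-sided Student t tests on `n - p` df, and
#' the t-derived effect-size correlation
#' `r = sign(t) * sqrt(t^2 / (t^2 + df))`. Rescaling all branch lengths by
#' a constant leaves estimates and tests unchanged (absorbed by `sigma2`).
#'
#' @param y numeric response, one value per species.
#' @param X design matrix including an intercept column (a plain vector is
#'   promoted to intercept + slope design).
#' @param C covariance matrix aligned with `y`.
#' @return An object of class `pglsFit`: list with `coefficients` (table
#'   of estimate, se, t, p, r), `sigma2`, `df`, `logLik` and the model
#'   frame dimensions.
#' @examples
#' tr <- simulateTree(8, seed = 2)
#' C <- brownianCovariance(tr)
#' y <- rnorm(8)
#' x <- rnorm(8)
#' pglsFit(y, x, C)
#' @export
pglsFit <- function(y, X, C) {
    if (is.null(dim(X))) {
        X <- cbind(`(Intercept)` = 1, x = X)
    }
    X <- as.matrix(X)
    n <- length(y)
    p <- ncol(X)
    if (n <= p) stopf("need more species than coefficients (n = %d, p = %d)", n, p)
    stopifnot(nrow(X) == n, nrow(C) == n, ncol(C) == n)
    L <- tryCatch(chol(C), error = function(e) {
        stopf("covariance matrix is not positive definite")
    })
    ## whiten: solve L' w = v  =>  w' w = v' C^-1 v
    yw <- backsolve(L, y, transpose = TRUE)
    Xw <- backsolve(L, X, transpose = TRUE)
    XtX <- crossprod(Xw)
    qrx <- qr(XtX)
    if (qrx$rank < p) stopf("rank-deficient design (X' C^-1 X singular)")
    bhat <- solve(qrx, crossprod(Xw, yw))
    res <- yw - Xw %*% bhat
    df <- n - p
    sigma2 <- sum(res^2) / df
    covb <- sigma2 * solve(qrx)
    se <- sqrt(diag(covb))
    tval <- as.vector(bhat) / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    reff <- sign(tval) * sqrt(tval^2 / (tval^2 + df))
    ll <- -0.5 * (n * log(2 * pi * sum(res^2) / n) + n +
                      2 * sum(log(diag(L))))
    out <- list(
        coefficients = data.frame(
            estimate = as.vector(bhat), se = se, t = tval, p = pval,
            r = reff, row.names = colnames(X)
        ),
        sigma2 = sigma2, df = df, n = n, logLik = ll
    )
    class(out) <- "pglsFit"
    out
}

#' @export
print.pglsFit <- function(x, ...) {
    cat(sprintf("PGLS fit (n = %d, residual df = %d)\n", x$n, x$df))
    print(format(x$coefficients, digits = 4))
    invisible(x)
}

#' Regress species longevity on mean methylation rate under phylogeny
#'
#' Convenience wrapper joining a [methylationRates()] table with the
#' species traits and fitting [pglsFit()] under the Brownian covariance of
#' the tree pruned to the included species. Two models are supported:
#' `response = "lq"` fits `LQ ~ rate`; `response = "log_lifespan"` fits
#' `log(max_lifespan) ~ rate + log(body_mass)`.
#'
#' @param x a [MethylAgingExperiment-class] with species table and tree.
#' @param rates data.frame from [methylationRates()].
#' @param rate_column `"mean_hyper_rate"` or `"mean_hypo_rate"`.
#' @param response `"lq"` (default) or `"log_lifespan"`.
#' @return A `pglsFit`.
#' @export
longevityPGLS <- function(x, rates,
                          rate_column = c("mean_hyper_rate", "mean_hypo_rate"),
                          response = c("lq", "log_lifespan")) {
    rate_column <- match.arg(rate_column)
    response <- match.arg(response)
    st <- speciesTable(x)
    tr <- phyloTree(x)
    if (is.null(tr)) stopf("experiment has no phylogeny")
    df <- merge(rates, st, by = "species")
    df <- df[order(df$species), , drop = FALSE]
    C <- brownianCovariance(
        ape::keep.tip(tr, df$species), species_order = df$species
    )
    if (response == "lq") {
        y <- df$lq
        X <- cbind(`(Intercept)` = 1, rate = df[[rate_column]])
    } else {
        y <- log(df$max_lifespan)
        X <- cbind(`(Intercept)` = 1, rate = df[[rate_column]],
                   log_mass = log(df$body_mass))
    }
    pglsFit(y, X, C)
}
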