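#' Fit a penalized-regression epigenetic clock
#'
#' Regresses transformed chronological age, `sqrt(age + 1)`, on beta values
#' with an elastic net (objective
#' `(1/2n) sum(y - b0 - Xb)^2 + lambda * (alpha * |b|_1 +
#' (1 - alpha) * |b|_2^2 / 2)`, as implemented by [glmnet::glmnet()]).
#' Predictors are standardized internally; coefficients are returned on the
#' original beta scale. Unless a fixed `lambda` is supplied, the penalty is
#' chosen as the minimizer of a seeded k-fold internal cross-validation
#' error over glmnet's log-spaced path.
#'
#' @param x a [MethylAgingExperiment-class] with known ages.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (default 0.5, the
#'   midpoint between ridge and lasso).
#' @param folds internal cross-validation folds for the penalty search
#'   (default 10; reduced with a warning when there are fewer samples).
#' @param seed integer seed controlling fold assignment.
#' @param probe_mask optional character vector restricting the predictors
#'   to a probe subset (e.g. probes mapped in at least one training
#'   species); default all probes.
#' @param lambda optional fixed penalty (skips the internal CV; `0` gives
#'   the unpenalized least-squares fit).
#' @param standardize standardize predictors internally (default `TRUE`).
#' @return An object of class `clockModel`: list with `intercept`,
#'   `coefficients` (named vector, nonzero entries only), `alpha`,
#'   `lambda`, `training_probe_set`, `training_means` (per-probe means used
#'   to impute missing probes at prediction time), and
#'   `transform = "sqrt_age_plus_1"`.
#' @examples
#' sim <- simulateMethylData(syntheticConfig(n_species = 4, n_probes = 200,
#'     samples_per_species = c(10, 15), seed = 3))
#' model <- fitClock(sim$experiment, seed = 1)
#' length(model$coefficients)
#' @export
fitClock <- function(x, alpha = 0.5, folds = 10, seed = 1L,
                     probe_mask = NULL, lambda = NULL, standardize = TRUE) {
    smp <- sampleTable(x)
    if (any(smp$age < 0)) stopf("ages must be >= 0")
    b <- betaValues(x)
    if (!is.null(probe_mask)) {
        probe_mask <- intersect(rownames(b), probe_mask)
        if (length(probe_mask) == 0) stopf("probe_mask matches no probes")
        b <- b[probe_mask, , drop = FALSE]
    }
    X <- t(b)
    y <- sqrt(smp$age + 1)
    n <- length(y)

    model <- list(
        alpha = alpha, transform = "sqrt_age_plus_1",
        training_probe_set = rownames(b),
        training_means = colMeans(X, na.rm = TRUE)
    )
    class(model) <- "clockModel"

    if (stats::var(y) == 0) {
        warnf("constant response; returning intercept-only clock")
        model$intercept <- y[1]
        model$coefficients <- stats::setNames(numeric(0), character(0))
        model$lambda <- NA_real_
        return(model)
    }

    if (is.null(lambda)) {
        if (n < 3) {
            ## too few samples for any internal CV: take the least
            ## penalized end of the default path
            warnf("n = %d too small for internal CV; using path-end lambda", n)
            fit <- glmnet::glmnet(X, y, alpha = alpha,
                                  standardize = standardize)
            lam <- min(fit$lambda)
            co <- stats::coef(fit, s = lam)
        } else {
            if (n < folds) {
                warnf("reducing folds from %d to %d (n = %d)", folds, n, n)
                folds <- n
            }
            foldid <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
            cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                                       standardize = standardize)
            lam <- cvfit$lambda.min
            co <- stats::coef(cvfit, s = "lambda.min")
        }
    } else {
        ## fixed-lambda fit along a short warm-start path ending at the
        ## target, with a tight convergence threshold so that lambda = 0
        ## reproduces ordinary least squares on full-rank designs
        lmax <- max(abs(crossprod(scale(X, scale = FALSE), y - mean(y)))) /
            (n * max(alpha, 1e-3))
        lmax <- max(lmax, lambda * 1.01, .Machine$double.eps)
        path <- unique(sort(c(exp(seq(log(lmax), log(max(
            lambda, lmax * 1e-4
        ) + 1e-12), length.out = 25)), lambda), decreasing = TRUE))
        fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = path,
                              standardize = standardize,
                              thresh = 1e-14, maxit = 10^7)
        lam <- lambda
        co <- stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y,
                          alpha = alpha, standardize = standardize,
                          thresh = 1e-14, maxit = 10^7)
    }
    co <- as.matrix(co)[, 1]
    nz <- co[-1][co[-1] != 0]
    model$intercept <- unname(co[1])
    model$coefficients <- nz
    model$lambda <- lam
    model
}

#' @export
print.clockModel <- function(x, ...) {
    cat(sprintf(
        "Epigenetic clock (elastic net, alpha = %.2f, lambda = %.4g)\n",
        x$alpha, x$lambda
    ))
    cat(sprintf("  %d nonzero CpG coefficients of %d candidate probes\n",
                length(x$coefficients), length(x$training_probe_set)))
    cat(sprintf("  response transform: %s\n", x$transform))
    invisible(x)
}

#' Predict chronological age from a fitted clock
#'
#' Forms the linear predictor on the `sqrt(age + 1)` scale, clamps it below
#' at 1, and back-transforms by `age = yhat^2 - 1`, so predictions are
#' always >= 0. Model probes missing from the input are imputed at their
#' training means; more than 20% missing is an error.
#'
#' @param model a `clockModel` from [fitClock()].
#' @param x a [MethylAgingExperiment-class] or beta matrix
#'   (probes x samples).
#' @return Named numeric vector of predicted ages in years.
#' @export
predictAge <- function(model, x) {
    b <- if (is(x, "MethylAgingExperiment")) betaValues(x) else as.matrix(x)
    need <- names(model$coefficients)
    if (length(need)) {
        missing <- setdiff(need, rownames(b))
        if (length(missing) > 0.2 * length(need)) {
            stopf("%d of %d clock probes missing (> 20%%)",
                  length(missing), length(need))
        }
        if (length(missing)) {
            message(sprintf("imputing %d missing clock probes at training means",
                            length(missing)))
            imp <- matrix(model$training_means[missing], length(missing),
                          ncol(b), dimnames = list(missing, colnames(b)))
            b <- rbind(b, imp)
        }
        raw <- model$intercept +
            as.vector(crossprod(b[need, , drop = FALSE], model$coefficients))
    } else {
        raw <- rep(model$intercept, ncol(b))
    }
    raw <- pmax(raw, 1)
    stats::setNames(raw^2 - 1, colnames(b))
}

#' Cross-validate an epigenetic clock
#'
#' `scheme = "loo"` leaves out one sample at a time; `scheme = "loso"`
#' leaves out all samples of one species at a time, predicting each
#' held-out species from a clock trained on the remaining species. Every
#' fold refits the full model, including the internal penalty selection, on
#' its training portion; the per-fold probe mask is the set of probes
#' mapped in at least one training species (from the `mapped_species`
#' annotation).
#'
#' @param x a [MethylAgingExperiment-class].
#' @param scheme `"loo"` or `"loso"`.
#' @param group optional character vector of species to restrict the
#'   analysis to (a taxonomic subset).
#' @param alpha,folds,seed passed to [fitClock()]; the fold seed is varied
#'   deterministically across CV folds.
#' @return An object of class `clockCV`: list with `predictions`
#'   (data.frame `sample_id`, `species`, `observed_age`, `predicted_age`),
#'   `r` (Pearson correlation of observed and predicted age, in years),
#'   `mae` (median absolute error, years), `per_species_bias` (mean
#'   predicted - observed, years), and `scheme`.
#' @export
crossValidateClock <- function(x, scheme = c("loo", "loso"), group = NULL,
                               alpha = 0.5, folds = 10, seed = 1L) {
    scheme <- match.arg(scheme)
    if (!is.null(group)) {
        x <- x[, sampleTable(x)$species %in% group]
    }
    smp <- sampleTable(x)
    n <- nrow(smp)
    sp <- smp$species
    if (scheme == "loo" && n < 3) stopf("loo requires >= 3 samples")
    if (scheme == "loso" && length(unique(sp)) < 2) {
        stopf("loso requires >= 2 species")
    }
    fold_of <- switch(scheme,
        loo = seq_len(n),
        loso = match(sp, unique(sp))
    )
    mapped <- mapped_species_list(x)
    pred <- rep(NA_real_, n)
    for (f in unique(fold_of)) {
        test <- fold_of == f
        train_species <- unique(sp[!test])
        if (length(train_species) < 1) {
            stopf("fold %s leaves no training species", f)
        }
        mask <- rownames(x)[vapply(mapped, function(m) {
            any(m %in% train_species)
        }, logical(1))]
        if (length(mask) == 0) stopf("no probes mapped in training species")
        model <- fitClock(x[, !test], alpha = alpha, folds = folds,
                          seed = child_seed(seed, 100L + f),
                          probe_mask = mask)
        pred[test] <- predictAge(model, x[, test, drop = FALSE])
    }
    obs <- smp$age
    bias <- tapply(pred - obs, sp, mean)
    out <- list(
        predictions = data.frame(
            sample_id = smp$sample_id, species = sp, observed_age = obs,
            predicted_age = pred, stringsAsFactors = FALSE
        ),
        r = stats::cor(obs, pred),
        mae = stats::median(abs(pred - obs)),
        per_species_bias = bias[unique(sp)],
        scheme = scheme
    )
    class(out) <- "clockCV"
    out
}

#' @export
print.clockCV <- function(x, ...) {
    cat(sprintf(
        "%s cross-validation over %d samples: r = %.3f, MAE = %.2f years\n",
        toupper(x$scheme), nrow(x$predictions), x$r, x$mae
    ))
    invisible(x)
}

#' Export clock coefficients to a TSV file
#'
#' Writes a two-column table (`probe_id`, `weight`) preceded by comment
#' header lines recording the intercept, alpha, lambda and transform.
#'
#' @param model a `clockModel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportClock <- function(model, path) {
    hdr <- sprintf("# %s\t%s", c("intercept", "alpha", "lambda", "transform"),
                   c(format(model$intercept, digits = 12), model$alpha,
                     format(model$lambda, digits = 12), model$transform))
    writeLines(c(hdr, "probe_id\tweight",
                 sprintf("%s\t%s", names(model$coefficients),
                         format(model$coefficients, digits = 12))), path)
    invisible(path)
}
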