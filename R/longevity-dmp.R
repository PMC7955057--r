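## Per-site random-intercept mixed model, fit by maximum likelihood with
## the single variance ratio lambda = tau2/sigma2 profiled out. With a
## species-blocked random intercept, V = I + lambda * J_blocks has a
## closed-form inverse (Sherman-Morrison per block), so each likelihood
## evaluation reduces to group-sum corrections of crossproducts. The same
## design is shared by every probe, so design-only quantities are
## precomputed once.

.mixed_design <- function(samples) {
    cls <- samples$longevity_class
    if (!all(cls %in% c("long", "short"))) {
        stopf("all samples must carry a 'long' or 'short' longevity_class")
    }
    short <- as.numeric(cls == "short") ## short = 1, long = 0
    ta <- sqrt(samples$age + 1)
    X <- cbind(`(Intercept)` = 1, age_t = ta, class_short = short,
               `age_t:class_short` = ta * short)
    groups <- as.integer(factor(samples$species))
    n_g <- tabulate(groups)
    list(X = X, groups = groups, n_g = n_g,
         group_of = split(seq_along(groups), groups))
}

## Profile log-likelihood machinery for one design (full or reduced).
.mixed_precompute <- function(X, groups, n_groups) {
    Sx <- rowsum(X, groups) ## n_groups x p group sums
    list(X = X, XtX = crossprod(X), Sx = Sx, n = nrow(X), p = ncol(X))
}

## Given lambda and a probe's response summaries, return the profiled ML
## log-likelihood and (optionally) the GLS coefficient solve.
.mixed_eval <- function(lambda, pre, n_g, Xty, Sy, yty, coef = FALSE) {
    cs <- lambda / (1 + lambda * n_g) ## per-group Sherman-Morrison weight
    A <- pre$XtX - crossprod(pre$Sx * cs, pre$Sx)
    bvec <- Xty - as.vector(crossprod(pre$Sx, cs * Sy))
    yCy <- yty - sum(cs * Sy^2)
    sol <- tryCatch(solve(A, bvec), error = function(e) NULL)
    if (is.null(sol)) {
        return(list(ll = -Inf, ok = FALSE))
    }
    rss <- yCy - sum(bvec * sol)
    rss <- max(rss, 1e-300)
    n <- pre$n
    logdetV <- sum(log1p(lambda * n_g))
    ll <- -0.5 * (n * log(2 * pi * rss / n) + n + logdetV)
    out <- list(ll = ll, ok = TRUE)
    if (coef) {
        out$beta <- sol
        out$sigma2 <- rss / n
        out$rss <- rss
        out$A <- A
    }
    out
}

## Maximize the profile likelihood over lambda in [0, 1e4]; the boundary
## lambda = 0 is evaluated explicitly so tau2-hat = 0 is exact.
.mixed_profile <- function(pre, n_g, Xty, Sy, yty) {
    f <- function(l) .mixed_eval(l, pre, n_g, Xty, Sy, yty)$ll
    opt <- stats::optimize(f, interval = c(0, 1e4), maximum = TRUE,
                           tol = 1e-8)
    ll0 <- f(0)
    if (ll0 >= opt$objective) {
        lambda <- 0
        ll <- ll0
    } else {
        lambda <- opt$maximum
        ll <- opt$objective
    }
    ev <- .mixed_eval(lambda, pre, n_g, Xty, Sy, yty, coef = TRUE)
    ev$lambda <- lambda
    ev$ll <- ll
    ev
}

#' Fit the per-site longevity mixed model
#'
#' Fits, by maximum likelihood, the random-intercept model
#' `beta ~ sqrt(age + 1) * longevity_class + (1 | species)` for a single
#' CpG site: fixed effects for transformed age, longevity class (coded
#' short = 1, long = 0) and their interaction, plus a species random
#' intercept with variance `tau2`. The variance ratio `tau2/sigma2` is
#' profiled by bounded one-dimensional search on \[0, 1e4\]. The
#' interaction is tested by a likelihood-ratio test against the
#' no-interaction model (both ML), `chi^2(1)`.
#'
#' A positive interaction means a steeper positive age slope in
#' short-lived species relative to long-lived species.
#'
#' @param beta_site numeric vector of beta values, one per sample.
#' @param samples data.frame with `species`, `age` and `longevity_class`
#'   (`"long"`/`"short"`) per sample.
#' @return An object of class `mixedFit`: list with `fixed` (data.frame of
#'   estimate, se per fixed effect), `tau2`, `sigma2`, `lambda`,
#'   `logLik`, `logLik0` (no-interaction model), `lrt`, `interaction_p`,
#'   `converged`.
#' @export
fitSiteMixedModel <- function(beta_site, samples) {
    des <- .mixed_design(samples)
    pre_full <- .mixed_precompute(des$X, des$groups)
    pre_red <- .mixed_precompute(des$X[, 1:3, drop = FALSE], des$groups)
    .fit_one_site(beta_site, des, pre_full, pre_red)
}

.fit_one_site <- function(y, des, pre_full, pre_red) {
    if (anyNA(y)) {
        return(structure(list(converged = FALSE), class = "mixedFit"))
    }
    Sy <- as.vector(rowsum(y, des$groups))
    yty <- sum(y^2)
    Xty_full <- as.vector(crossprod(pre_full$X, y))
    full <- .mixed_profile(pre_full, des$n_g, Xty_full, Sy, yty)
    red <- .mixed_profile(pre_red, des$n_g, Xty_full[1:3], Sy, yty)
    if (!full$ok || !red$ok) {
        return(structure(list(converged = FALSE), class = "mixedFit"))
    }
    n <- pre_full$n
    p <- pre_full$p
    ## degenerate response: no variation at all
    if (stats::var(y) < .Machine$double.eps) {
        fixed <- data.frame(estimate = c(mean(y), 0, 0, 0),
                            se = rep(NA_real_, 4),
                            row.names = colnames(pre_full$X))
        return(structure(list(
            fixed = fixed, tau2 = 0, sigma2 = 0, lambda = 0,
            logLik = full$ll, logLik0 = red$ll, lrt = 0,
            interaction_p = 1, converged = TRUE
        ), class = "mixedFit"))
    }
    covb <- tryCatch(full$rss / (n - p) * solve(full$A),
                     error = function(e) NULL)
    if (is.null(covb)) {
        return(structure(list(converged = FALSE), class = "mixedFit"))
    }
    lrt <- max(0, 2 * (full$ll - red$ll))
    structure(list(
        fixed = data.frame(estimate = as.vector(full$beta),
                           se = sqrt(diag(covb)),
                           row.names = colnames(pre_full$X)),
        tau2 = full$lambda * full$sigma2, sigma2 = full$sigma2,
        lambda = full$lambda, logLik = full$ll, logLik0 = red$ll,
        lrt = lrt,
        interaction_p = stats::pchisq(lrt, 1, lower.tail = FALSE),
        converged = TRUE
    ), class = "mixedFit")
}

#' @export
print.mixedFit <- function(x, ...) {
    if (!isTRUE(x$converged)) {
        cat("mixed-model fit: did not converge\n")
        return(invisible(x))
    }
    cat(sprintf(
        "random-intercept ML fit: tau2 = %.3g, sigma2 = %.3g, LRT p = %.3g\n",
        x$tau2, x$sigma2, x$interaction_p
    ))
    print(format(x$fixed, digits = 4))
    invisible(x)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment with the harmonic-sum correction
#' `c(m) = sum(1/j, j = 1..m)`, valid under arbitrary dependence:
#' `adj_(i) = min(1, min_{j >= i} p_(j) * m * c(m) / j)`. Input order is
#' preserved. Delegates to [stats::p.adjust()] with `method = "BY"`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' byAdjust(c(0.01, 0.02, 0.03)) # all 0.055
#' @export
byAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1)) {
        stopf("p-values must lie in [0, 1]")
    }
    stats::p.adjust(p, method = "BY")
}

#' Identify longevity-associated DMPs
#'
#' Fits the per-site mixed model at every probe for the samples of species
#' with an assigned longevity class, adjusts the interaction p-values by
#' Benjamini-Yekutieli FDR across all converged probes, and classifies
#' significant probes by the signs of the age main effect and interaction:
#' age +, interaction + is "short gains faster"; age -, interaction - is
#' "short loses faster"; the discordant combinations are classified
#' symmetrically as "long gains faster" (age +, interaction -) and "long
#' loses faster" (age -, interaction +).
#'
#' @param x a [MethylAgingExperiment-class] whose species table assigns
#'   `longevity_class` (`long`/`short`; `unassigned` species are dropped
#'   from this analysis).
#' @param fdr_q FDR threshold (default 0.05).
#' @return List with `calls` (data.frame per converged probe: fixed-effect
#'   estimates, `tau2`, `sigma2`, `interaction_p`, `p_adj`,
#'   `direction_class`, `significant`), `dmps` (a `dmpSet` of significant
#'   probes with hyper/hypo direction from the age main effect sign) and
#'   `n_nonconverged`.
#' @export
identifyLongevityDMPs <- function(x, fdr_q = 0.05) {
    st <- speciesTable(x)
    use_sp <- st$species[st$longevity_class %in% c("long", "short")]
    if (length(unique(st$longevity_class[st$species %in% use_sp])) < 2) {
        stopf("need species of both longevity classes")
    }
    xs <- x[, sampleTable(x)$species %in% use_sp]
    smp <- sampleTable(xs)
    smp$longevity_class <-
        st$longevity_class[match(smp$species, st$species)]
    for (cl in c("long", "short")) {
        nsp <- length(unique(smp$species[smp$longevity_class == cl]))
        if (nsp < 1) stopf("no species in class '%s'", cl)
        if (nsp < 2) {
            warnf("class '%s' has a single species; random effect confounded",
                  cl)
        }
    }
    des <- .mixed_design(smp)
    pre_full <- .mixed_precompute(des$X, des$groups)
    pre_red <- .mixed_precompute(des$X[, 1:3, drop = FALSE], des$groups)
    b <- betaValues(xs)
    fits <- lapply(seq_len(nrow(b)), function(i) {
        .fit_one_site(b[i, ], des, pre_full, pre_red)
    })
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    n_nc <- sum(!conv)
    if (n_nc) {
        message(sprintf("%d probes failed to converge; excluded from FDR", n_nc))
    }
    if (!any(conv)) stopf("no probe converged")
    idx <- which(conv)
    getf <- function(f, what) f$fixed$estimate[match(what, rownames(f$fixed))]
    calls <- data.frame(
        probe_id = rownames(b)[idx],
        age_effect = vapply(fits[idx], getf, numeric(1), "age_t"),
        class_effect = vapply(fits[idx], getf, numeric(1), "class_short"),
        interaction = vapply(fits[idx], getf, numeric(1),
                             "age_t:class_short"),
        tau2 = vapply(fits[idx], `[[`, numeric(1), "tau2"),
        sigma2 = vapply(fits[idx], `[[`, numeric(1), "sigma2"),
        interaction_p = vapply(fits[idx], `[[`, numeric(1),
                               "interaction_p"),
        stringsAsFactors = FALSE
    )
    calls$p_adj <- byAdjust(calls$interaction_p)
    calls$significant <- calls$p_adj < fdr_q
    age_pos <- calls$age_effect >= 0
    int_pos <- calls$interaction >= 0
    calls$direction_class <- ifelse(
        age_pos & int_pos, "short gains faster",
        ifelse(!age_pos & !int_pos, "short loses faster",
               ifelse(age_pos, "long gains faster", "long loses faster"))
    )
    sig <- calls[calls$significant, , drop = FALSE]
    dmps <- structure(
        data.frame(
            probe_id = sig$probe_id,
            direction = ifelse(sig$age_effect >= 0, "hyper", "hypo"),
            stringsAsFactors = FALSE
        ),
        provenance = "longevity", fdr_q = fdr_q,
        class = c("dmpSet", "data.frame")
    )
    list(calls = calls, dmps = dmps, n_nonconverged = n_nc)
}
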