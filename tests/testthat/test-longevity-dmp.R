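## Balanced two-class design builder: `nsp` species per class, `n` samples
## per species, true model on the sqrt(age + 1) scale.
mixed_fixture <- function(nsp = 2, n = 30, b_age = 0.01, b_int = 0.02,
                          b_class = 0, tau = 0, sigma = 0.01, seed = 1,
                          max_age = 20) {
    set.seed(seed)
    species <- rep(sprintf("sp%d", seq_len(2 * nsp)), each = n)
    cls <- rep(c("long", "short"), each = nsp * n)
    age <- runif(2 * nsp * n, 0, max_age)
    short <- as.numeric(cls == "short")
    ta <- sqrt(age + 1)
    u <- rnorm(2 * nsp, 0, tau)[as.integer(factor(species))]
    y <- 0.4 + b_age * ta + b_class * short + b_int * ta * short + u +
        rnorm(length(age), 0, sigma)
    samples <- data.frame(
        sample_id = sprintf("s%04d", seq_along(age)), species = species,
        age = age, longevity_class = cls, stringsAsFactors = FALSE
    )
    list(y = pmin(pmax(y, 0), 1), samples = samples)
}

test_that("with tau2 = 0 and one species per class the fit matches OLS", {
    fx <- mixed_fixture(nsp = 1, n = 60, tau = 0, sigma = 0.01, seed = 2)
    expect_warning(fit <- fitSiteMixedModel(fx$y, fx$samples),
                   NA) ## single-species warning only raised by the caller
    ta <- sqrt(fx$samples$age + 1)
    short <- as.numeric(fx$samples$longevity_class == "short")
    ols <- lm(fx$y ~ ta * short)
    expect_lt(max(abs(fit$fixed$estimate - unname(coef(ols)))), 1e-4)
    expect_lt(fit$tau2, 1e-5)
})

test_that("the interaction parameter is recovered on a balanced design", {
    fx <- mixed_fixture(nsp = 2, n = 30, b_age = 0.01, b_int = 0.02,
                        tau = 0.02, sigma = 0.01, seed = 7)
    fit <- fitSiteMixedModel(fx$y, fx$samples)
    est <- fit$fixed["age_t:class_short", "estimate"]
    se <- fit$fixed["age_t:class_short", "se"]
    expect_lt(abs(est - 0.02), 3 * se)
    expect_gt(fit$tau2, 0)
    expect_lt(fit$interaction_p, 0.05)
})

test_that("mixed-model ML fit agrees with an independent lme ML fit", {
    fx <- mixed_fixture(nsp = 3, n = 20, b_age = 0.01, b_int = 0.015,
                        tau = 0.03, sigma = 0.015, seed = 9)
    fit <- fitSiteMixedModel(fx$y, fx$samples)
    df <- fx$samples
    df$y <- fx$y
    df$ta <- sqrt(df$age + 1)
    df$short <- as.numeric(df$longevity_class == "short")
    lfit <- nlme::lme(y ~ ta * short, random = ~ 1 | species, data = df,
                      method = "ML")
    expect_equal(fit$fixed$estimate, unname(nlme::fixef(lfit)),
                 tolerance = 1e-4)
    vc <- as.numeric(nlme::VarCorr(lfit)[, "Variance"])
    expect_equal(fit$tau2, vc[1], tolerance = 1e-3)
    expect_equal(fit$sigma2, vc[2], tolerance = 1e-3)
    expect_equal(as.numeric(fit$logLik), as.numeric(stats::logLik(lfit)),
                 tolerance = 1e-6)
})

test_that("a constant response yields a degenerate, calibrated fit", {
    fx <- mixed_fixture(nsp = 2, n = 10, seed = 3)
    fit <- fitSiteMixedModel(rep(0.5, nrow(fx$samples)), fx$samples)
    expect_equal(fit$interaction_p, 1)
    expect_equal(fit$tau2, 0)
    expect_equal(fit$fixed["(Intercept)", "estimate"], 0.5)
})

test_that("the likelihood ratio statistic is nonnegative", {
    for (s in 1:8) {
        fx <- mixed_fixture(nsp = 2, n = 12, b_int = 0, tau = 0.02,
                            sigma = 0.02, seed = 100 + s)
        fit <- fitSiteMixedModel(fx$y, fx$samples)
        expect_gte(fit$lrt, 0)
        expect_gte(fit$logLik, fit$logLik0 - 1e-6)
    }
})

test_that("BY adjustment matches the hand-computed step-up form", {
    expect_equal(byAdjust(0.02), 0.02) ## m = 1, c(1) = 1
    ## m = 3, c(3) = 11/6: p * 3 * (11/6) / rank, cummin from the top
    expect_equal(byAdjust(c(0.01, 0.02, 0.03)), rep(0.055, 3))
    expect_equal(byAdjust(c(1, 1, 1)), c(1, 1, 1))
    ## order preserved
    p <- c(0.4, 0.001, 0.2)
    expect_equal(byAdjust(p), byAdjust(rev(p))[3:1])
    ## monotone in sorted raw p, and never below Benjamini-Hochberg
    set.seed(4)
    p <- runif(50)
    adj <- byAdjust(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
    expect_true(all(adj >= p.adjust(p, "BH") - 1e-15))
    expect_error(byAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("longevity DMP classification follows the sign rule", {
    cfg <- syntheticConfig(
        n_species = 6, n_probes = 250, samples_per_species = c(25, 30),
        frac_longevity = 0.2, frac_age_hyper = 0, frac_age_hypo = 0,
        frac_sex = 0, frac_unmapped = 0, class_rate_ratio = 4,
        species_sd = 0.05, noise_sd = 0.02, seed = 55
    )
    sim <- simulateMethylData(cfg)
    res <- identifyLongevityDMPs(sim$experiment, fdr_q = 0.05)
    expect_true(all(res$calls$significant == (res$calls$p_adj < 0.05)))
    ## quoted sign rule and its symmetric extension
    cl <- res$calls
    expect_true(all(
        cl$direction_class[cl$age_effect >= 0 & cl$interaction >= 0] ==
            "short gains faster"
    ))
    expect_true(all(
        cl$direction_class[cl$age_effect < 0 & cl$interaction < 0] ==
            "short loses faster"
    ))
    expect_true(all(
        cl$direction_class[cl$age_effect >= 0 & cl$interaction < 0] ==
            "long gains faster"
    ))
    ## longevity-archetype probes drift faster in short-lived species, so
    ## they dominate the significant calls
    truth <- sim$truth
    sig <- cl$probe_id[cl$significant]
    expect_gt(length(sig), 0)
    arch <- truth$archetype[match(sig, truth$probe_id)]
    expect_gt(mean(arch == "longevity"), 0.8)
    ## and most true longevity probes are recovered
    lon <- truth$probe_id[truth$archetype == "longevity"]
    expect_gt(mean(lon %in% sig), 0.6)
})

test_that("no class effect means near-nominal false positive calls", {
    cfg <- syntheticConfig(
        n_species = 6, n_probes = 800, samples_per_species = c(20, 25),
        frac_longevity = 0, frac_age_hyper = 0.1, frac_age_hypo = 0.1,
        frac_sex = 0, frac_unmapped = 0, seed = 66
    )
    sim <- simulateMethylData(cfg)
    res <- identifyLongevityDMPs(sim$experiment, fdr_q = 0.05)
    m <- nrow(res$calls)
    fp <- mean(res$calls$significant)
    expect_lte(fp, 0.05 + 2 * sqrt(0.05 * 0.95 / m))
})

test_that("class coverage problems are reported", {
    sim <- small_sim(seed = 77, n_species = 4, n_probes = 30,
                     samples = c(6, 8))
    st <- speciesTable(sim$experiment)
    st$longevity_class <- "long"
    sim$experiment@speciesTable <- S4Vectors::DataFrame(st)
    expect_error(identifyLongevityDMPs(sim$experiment), "both")
})
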