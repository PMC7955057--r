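test_that("lambda = 0 full-rank fit reproduces ordinary least squares", {
    set.seed(4)
    n <- 60
    p <- 10
    b <- matrix(runif(n * p, 0.2, 0.8), p, n)
    x <- tiny_experiment(b, ages = runif(n, 0, 20))
    m <- fitClock(x, alpha = 0.5, lambda = 0, seed = 1)
    y <- sqrt(sampleTable(x)$age + 1)
    ols <- coef(lm(y ~ t(betaValues(x))))
    got <- c(m$intercept,
             setNames(numeric(p), rownames(betaValues(x))))
    got[names(m$coefficients)] <- m$coefficients
    expect_lt(max(abs(got - ols)), 1e-6)

    ## residuals of own-model predictions are orthogonal to predictors
    raw <- sqrt(predictAge(m, x) + 1)
    res <- y - raw
    expect_lt(max(abs(betaValues(x) %*% res)), 1e-5)
})

test_that("alpha = 1 orthonormal-design fit equals soft-thresholding", {
    n <- 50
    p <- 8
    X <- orthonormal_design(n, p, seed = 5)
    c0 <- 0.1
    b <- t(X * c0 + 0.5) ## affine map into valid beta range
    set.seed(6)
    yt <- as.vector(X %*% c(2, -1.5, 0, 0, 0.8, 0, 0, 0.3)) / 10 +
        rnorm(n, 0, 0.3)
    yt <- yt - min(yt) + 1.2
    x <- tiny_experiment(b, ages = yt^2 - 1)
    lam <- 0.05
    m <- fitClock(x, alpha = 1, lambda = lam, seed = 1)
    y <- sqrt(sampleTable(x)$age + 1)
    z <- crossprod(X, y - mean(y)) / n
    oracle <- sign(z) * pmax(abs(z) - lam, 0)
    got <- setNames(numeric(p), rownames(betaValues(x)))
    got[names(m$coefficients)] <- m$coefficients
    ## coefficients are reported on the original (affine) scale
    expect_lt(max(abs(got * c0 - oracle)), 1e-8)
})

test_that("degenerate responses give intercept-only clocks", {
    b <- matrix(runif(40, 0.3, 0.7), 4, 10)
    x <- tiny_experiment(b, ages = rep(0, 10))
    expect_warning(m <- fitClock(x, seed = 1), "constant")
    expect_length(m$coefficients, 0)
    expect_equal(unname(predictAge(m, x)), rep(0, 10))
})

test_that("prediction back-transforms, clamps and imputes as documented", {
    m <- structure(list(
        intercept = 3, coefficients = setNames(numeric(0), character(0)),
        alpha = 0.5, lambda = 0.1, training_probe_set = character(0),
        training_means = numeric(0), transform = "sqrt_age_plus_1"
    ), class = "clockModel")
    b <- matrix(0.5, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
    expect_equal(unname(predictAge(m, b)), c(8, 8, 8)) ## 3^2 - 1

    m$intercept <- 0.2 ## raw prediction below 1 clamps to age 0
    expect_equal(unname(predictAge(m, b)), c(0, 0, 0))

    ## missing model probes are imputed at training means (<= 20%)
    set.seed(10)
    b2 <- matrix(runif(150, 0.2, 0.8), 15, 10,
                 dimnames = list(sprintf("cg%02d", 1:15),
                                 sprintf("s%02d", 1:10)))
    x <- tiny_experiment(b2, ages = rowSums(t(b2))[1:10] + 1:10)
    full <- fitClock(x, alpha = 0, lambda = 0.01, seed = 1)
    drop_one <- names(full$coefficients)[1]
    b3 <- b2[setdiff(rownames(b2), drop_one), ]
    expect_message(p3 <- predictAge(full, b3), "imputing")
    expect_length(p3, 10)
    ## > 20% of model probes missing is an error
    nkeep <- floor(length(full$coefficients) * 0.5)
    b4 <- b2[setdiff(rownames(b2), names(full$coefficients)[1:nkeep]), ]
    expect_error(predictAge(full, b4), "missing")
})

test_that("prediction is invariant to probe and sample ordering", {
    sim <- small_sim(seed = 31, n_species = 4, n_probes = 150,
                     samples = c(12, 14))
    x <- sim$experiment
    m <- fitClock(x, seed = 2)
    p1 <- predictAge(m, x)
    shuffled <- betaValues(x)[sample(nrow(x)), sample(ncol(x))]
    p2 <- predictAge(m, shuffled)
    expect_equal(p2[names(p1)], p1)
})

test_that("fold assignment and fitting are reproducible under a seed", {
    sim <- small_sim(seed = 17, n_species = 4, n_probes = 120,
                     samples = c(10, 12))
    m1 <- fitClock(sim$experiment, seed = 7)
    m2 <- fitClock(sim$experiment, seed = 7)
    expect_identical(m1$lambda, m2$lambda)
    expect_identical(m1$coefficients, m2$coefficients)
})

test_that("LOO on three samples yields exactly one prediction each", {
    b <- matrix(runif(30, 0.3, 0.7), 10, 3)
    x <- tiny_experiment(b, ages = c(1, 5, 9))
    suppressWarnings(cv <- crossValidateClock(x, "loo", seed = 1))
    expect_equal(nrow(cv$predictions), 3)
    expect_false(anyNA(cv$predictions$predicted_age))
    expect_error(crossValidateClock(x[, 1:2], "loo", seed = 1), ">= 3")
})

test_that("LOO prediction tracks age on well-powered synthetic data", {
    sim <- small_sim(seed = 23, n_species = 5, n_probes = 400,
                     samples = c(14, 16), noise_sd = 0.03)
    cv <- crossValidateClock(sim$experiment, "loo", seed = 3)
    expect_gt(cv$r, 0.8)
    train_model <- fitClock(sim$experiment, seed = 3)
    train_mae <- median(abs(
        predictAge(train_model, sim$experiment) -
            sampleTable(sim$experiment)$age
    ))
    expect_gte(cv$mae, train_mae * 0.5) ## CV error not absurdly optimistic
})

test_that("LOSO underestimates age for a slow-aging species", {
    cfg <- syntheticConfig(
        n_species = 6, n_probes = 500, samples_per_species = c(18, 22),
        noise_sd = 0.03, rate_lq_exponent = 0,
        rate_multiplier = c(sp03 = 0.5), seed = 41
    )
    sim <- simulateMethylData(cfg)
    cv <- crossValidateClock(sim$experiment, "loso", seed = 5)
    ## the species aging at half the cohort drift rate reads as younger
    expect_lt(cv$per_species_bias[["sp03"]], 0)
    expect_error(
        crossValidateClock(sim$experiment[, sampleTable(sim$experiment)$species == "sp01"],
                           "loso", seed = 1),
        ">= 2 species"
    )
})

test_that("clock export writes a parseable coefficient table", {
    sim <- small_sim(seed = 19, n_species = 3, n_probes = 100,
                     samples = c(10, 12))
    m <- fitClock(sim$experiment, seed = 1)
    f <- withr::local_tempfile(fileext = ".tsv")
    exportClock(m, f)
    lines <- readLines(f)
    expect_true(any(grepl("^# intercept", lines)))
    tab <- read.delim(f, comment.char = "#")
    expect_identical(names(tab), c("probe_id", "weight"))
    expect_equal(nrow(tab), length(m$coefficients))
})
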