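test_that("beta computation from intensities follows the clamped formula", {
    expect_equal(betaFromIntensities(900, 0), 0.9)
    expect_equal(betaFromIntensities(0, 400), 0)
    expect_equal(betaFromIntensities(-50, -50), 0)
    expect_error(betaFromIntensities(Inf, 1), "finite")
    expect_error(betaFromIntensities(NA, 1), "finite")

    ## monotone nondecreasing in M, nonincreasing in U
    M <- seq(-100, 2000, by = 37)
    bM <- betaFromIntensities(M, 500)
    expect_true(all(diff(bM) >= 0))
    bU <- betaFromIntensities(500, M)
    expect_true(all(diff(bU) <= 0))
    expect_true(all(bM >= 0 & bM < 1))
})

test_that("dataset bundles round-trip losslessly through TSV/Newick", {
    sim <- small_sim(seed = 2, n_species = 4, n_probes = 80,
                     samples = c(12, 15))
    dir <- withr::local_tempdir()
    writeMethylDataset(sim$experiment, dir, truth = sim$truth)
    back <- readMethylDataset(dir)
    expect_equal(betaValues(back), betaValues(sim$experiment),
                 tolerance = 1e-9)
    ## loader preserves probe and sample order
    expect_identical(rownames(back), rownames(sim$experiment))
    expect_identical(colnames(back), colnames(sim$experiment))
    expect_equal(sampleTable(back)$age, sampleTable(sim$experiment)$age)
    expect_equal(speciesTable(back)$lq, speciesTable(sim$experiment)$lq)
    expect_identical(sort(phyloTree(back)$tip.label),
                     sort(phyloTree(sim$experiment)$tip.label))

    ## byte-stable writer
    dir2 <- withr::local_tempdir()
    writeMethylDataset(sim$experiment, dir2)
    expect_identical(readLines(file.path(dir, "beta.tsv")),
                     readLines(file.path(dir2, "beta.tsv")))
})

test_that("loader drops unmatched samples and prunes extra tree tips", {
    sim <- small_sim(seed = 3, n_species = 4, n_probes = 40,
                     samples = c(10, 12))
    dir <- withr::local_tempdir()
    writeMethylDataset(sim$experiment, dir)
    ## remove one sample from the metadata only
    smp <- read.delim(file.path(dir, "samples.tsv"))
    write.table(smp[-1, ], file.path(dir, "samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    expect_warning(back <- readMethylDataset(dir), "without metadata")
    expect_equal(ncol(back), ncol(sim$experiment) - 1L)

    ## a tree with an extra tip gets pruned to the species present
    tr <- phyloTree(sim$experiment)
    nw <- sub(";$", "", ape::write.tree(tr))
    writeLines(sprintf("(%s:0.1,(zz1:0.5,zz2:0.5):0.1);", nw),
               file.path(dir, "tree.nwk"))
    expect_warning(
        expect_message(back2 <- readMethylDataset(dir), "pruning"),
        "without metadata"
    )
    expect_setequal(phyloTree(back2)$tip.label, speciesTable(back2)$species)
})

test_that("probe QC statistics are exact on hand-computable cases", {
    b <- rbind(
        cg1 = c(0.5, 0.5, 0.5),
        cg2 = c(0.4, 0.6, NA),
        cg3 = c(0, 0, 0)
    )
    qc <- probeQCStats(b)
    expect_equal(qc$mean, c(0.5, 0.5, 0))
    expect_equal(qc$sd[1], 0)
    ## n-1 denominator: sd({0.4, 0.6}) = 0.1414..., cv = 28.28%
    expect_equal(qc$sd[2], sqrt(0.02), tolerance = 1e-12)
    expect_equal(qc$cv[2], 100 * sqrt(0.02) / 0.5, tolerance = 1e-12)
    expect_equal(qc$cv[1], 0)
    ## cv undefined at mean zero, flagged
    expect_true(is.na(qc$cv[3]))
    expect_false(qc$cv_defined[3])

    ## missing values are excluded, not propagated
    b2 <- cbind(b, c(NA, NA, NA))
    qc2 <- probeQCStats(b2)
    expect_equal(qc2$mean, qc$mean)
    expect_equal(qc2$sd, qc$sd)

    ## invariant to sample column order
    qc3 <- probeQCStats(b[, c(3, 1, 2)])
    expect_equal(qc3$mean, qc$mean)
    expect_equal(qc3$sd, qc$sd)
    expect_error(probeQCStats(b[, 1, drop = FALSE]), "2 samples")
})

test_that("outlier detection flags a noise sample among correlated peers", {
    set.seed(42)
    n <- 10
    np <- 200
    base <- runif(np, 0.2, 0.8)
    b <- sapply(seq_len(n), function(i) {
        pmin(pmax(base + rnorm(np, 0, 0.02), 0), 1)
    })
    b[, 7] <- runif(np) ## one sample replaced by uniform noise
    rownames(b) <- sprintf("cg%03d", seq_len(np))
    colnames(b) <- sprintf("s%03d", seq_len(n))
    x <- tiny_experiment(b, ages = seq_len(n))
    flagged <- detectOutlierSamples(x, threshold = 3)
    expect_identical(flagged, "s007")

    ## identical samples: nothing to flag
    b2 <- matrix(rep(base, 5), np, 5,
                 dimnames = list(rownames(b), sprintf("t%d", 1:5)))
    x2 <- tiny_experiment(b2, ages = 1:5)
    expect_length(detectOutlierSamples(x2, threshold = 3), 0)

    ## infinite threshold flags nothing
    expect_length(detectOutlierSamples(x, threshold = Inf), 0)

    ## species with < 3 samples are skipped with a message
    x3 <- tiny_experiment(b[, 1:2], ages = 1:2)
    expect_message(out <- detectOutlierSamples(x3), "skipped")
    expect_length(out, 0)

    dropped <- dropSamples(x, "s007")
    expect_false("s007" %in% colnames(dropped))
})

test_that("the container enforces its invariants", {
    b <- matrix(0.5, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
    smp <- data.frame(sample_id = c("s1", "s2"), species = "x", age = 1:2)
    expect_s4_class(MethylAgingExperiment(b, smp), "MethylAgingExperiment")
    bad <- b
    bad[1, 1] <- 1.5
    expect_error(MethylAgingExperiment(bad, smp), "\\[0, 1\\]")
    smp_bad <- smp
    smp_bad$age[1] <- -1
    expect_error(MethylAgingExperiment(b, smp_bad), ">= 0")
    expect_error(MethylAgingExperiment(b, smp[1, ]), "missing")
})

test_that("quantile normalization is an explicit opt-in hook", {
    sim <- small_sim(seed = 9, n_species = 3, n_probes = 50,
                     samples = c(5, 6))
    x <- sim$experiment
    expect_identical(betaValues(normalizeBetas(x)), betaValues(x))
    xq <- normalizeBetas(x, method = "quantile")
    b <- betaValues(xq)
    expect_true(all(b >= 0 & b <= 1))
    ## after quantile normalization all samples share sorted values
    expect_equal(unname(sort(b[, 1])), unname(sort(b[, 2])),
                 tolerance = 1e-8)
})
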