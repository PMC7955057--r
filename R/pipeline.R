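#' Pipeline configuration
#'
#' Bundles the analysis thresholds, stage toggles and the global seed for
#' [runPipeline()]. A single global seed is expanded into per-stage child
#' seeds by a fixed offset scheme, so disabling one stage does not shift
#' another stage's random stream.
#'
#' @param synthetic a [syntheticConfig()] describing the dataset to
#'   simulate (ignored when `input_dir` is given).
#' @param input_dir optional directory with a pre-existing dataset bundle
#'   (see [readMethylDataset()]); when `NULL` the simulate stage runs.
#' @param output_dir directory for stage outputs and the run manifest.
#' @param min_samples_meta minimum per-species samples for the age
#'   meta-analysis (default 15).
#' @param min_rate_samples minimum per-species samples for the rate table
#'   (default 10).
#' @param top_k number of age DMPs (default 2000).
#' @param fdr_q BY FDR threshold for longevity DMPs (default 0.05).
#' @param alpha,folds elastic-net mixing and internal CV folds
#'   (defaults 0.5 and 10).
#' @param outlier_threshold robust z-score cut-off for sample QC.
#' @param stages character vector of stage names to run, in pipeline
#'   order; any of `"qc"`, `"clock_cv"`, `"age_meta"`, `"rates"`,
#'   `"pgls"`, `"longevity_dmp"`, `"enrich"`.
#' @param cv_scheme clock CV scheme(s) to run (`"loo"`, `"loso"`).
#' @param seed global integer seed.
#' @return A validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           input_dir = NULL,
                           output_dir = tempfile("methylaging_run_"),
                           min_samples_meta = 15,
                           min_rate_samples = 10,
                           top_k = 2000,
                           fdr_q = 0.05,
                           alpha = 0.5,
                           folds = 10,
                           outlier_threshold = 3,
                           stages = c("qc", "clock_cv", "age_meta", "rates",
                                      "pgls", "longevity_dmp", "enrich"),
                           cv_scheme = c("loo", "loso"),
                           seed = 1L) {
    cfg <- list(
        synthetic = synthetic, input_dir = input_dir,
        output_dir = output_dir,
        min_samples_meta = min_samples_meta,
        min_rate_samples = min_rate_samples, top_k = top_k,
        fdr_q = fdr_q, alpha = alpha, folds = folds,
        outlier_threshold = outlier_threshold,
        stages = stages, cv_scheme = cv_scheme, seed = as.integer(seed)
    )
    thr <- c(cfg$min_samples_meta, cfg$min_rate_samples, cfg$top_k,
             cfg$fdr_q, cfg$alpha, cfg$folds)
    if (any(thr <= 0)) stopf("all thresholds must be positive")
    bad <- setdiff(stages, c("qc", "clock_cv", "age_meta", "rates", "pgls",
                             "longevity_dmp", "enrich"))
    if (length(bad)) stopf("unknown stages: %s", paste(bad, collapse = ", "))
    class(cfg) <- "pipelineConfig"
    cfg
}

## Hash of the analysis-relevant configuration (paths excluded, so runs
## into different directories compare equal), via serialization to a
## temporary file and md5.
.config_hash <- function(cfg) {
    cfg <- unclass(cfg)
    cfg$output_dir <- NULL
    cfg$input_dir <- NULL
    f <- tempfile()
    on.exit(unlink(f))
    saveRDS(cfg, f, version = 2, compress = FALSE)
    unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate (or load) -> qc -> clock cross-validation
#' -> age meta-analysis -> methylation rates -> PGLS -> longevity DMPs ->
#' enrichment, skipping disabled stages. Stage outputs are written as TSV
#' under `output_dir`, and a JSON manifest records the configuration hash,
#' seed, package version and per-stage summary numbers. Rerunning with an
#' identical configuration reproduces identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @return The manifest, invisibly (list; also written to
#'   `manifest.json`). Stage results are attached in the `results`
#'   attribute.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    log_stage <- function(stage, fmt, ...) {
        message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    }
    manifest <- list(
        config_hash = .config_hash(config), seed = config$seed,
        package_version = as.character(utils::packageVersion("methylaging")),
        stages = list()
    )
    results <- list()

    if (is.null(config$input_dir)) {
        log_stage("simulate", "generating synthetic dataset")
        sim <- simulateMethylData(config$synthetic)
        x <- sim$experiment
        results$truth <- sim$truth
        manifest$stages$simulate <- list(
            n_probes = nrow(x), n_samples = ncol(x),
            n_species = nrow(speciesTable(x))
        )
    } else {
        log_stage("load", "reading dataset from %s", config$input_dir)
        x <- readMethylDataset(config$input_dir)
        manifest$stages$load <- list(
            n_probes = nrow(x), n_samples = ncol(x)
        )
    }

    if ("qc" %in% config$stages) {
        qc <- probeQCStats(x)
        out <- detectOutlierSamples(x, threshold = config$outlier_threshold)
        if (length(out)) x <- dropSamples(x, out)
        log_stage("qc", "%d outlier samples removed", length(out))
        .write_tsv(qc, file.path(config$output_dir, "probe_qc.tsv"))
        manifest$stages$qc <- list(
            n_outliers = length(out),
            median_probe_mean = stats::median(qc$mean, na.rm = TRUE)
        )
        results$qc <- qc
    } else {
        log_stage("qc", "disabled; downstream stages use the unfiltered matrix")
        manifest$stages$qc <- list(enabled = FALSE)
    }

    if ("clock_cv" %in% config$stages) {
        for (scheme in config$cv_scheme) {
            cv <- crossValidateClock(
                x, scheme = scheme, alpha = config$alpha,
                folds = config$folds, seed = child_seed(config$seed, 10L)
            )
            log_stage("clock_cv", "%s: r = %.3f, MAE = %.2f yr", scheme,
                      cv$r, cv$mae)
            .write_tsv(cv$predictions, file.path(
                config$output_dir, sprintf("clock_cv_%s.tsv", scheme)
            ))
            manifest$stages[[paste0("clock_cv_", scheme)]] <-
                list(r = cv$r, mae = cv$mae)
            results[[paste0("cv_", scheme)]] <- cv
        }
    }

    meta <- NULL
    dmps <- NULL
    if ("age_meta" %in% config$stages) {
        meta <- ageMetaAnalysis(x, min_samples = config$min_samples_meta)
        dmps <- selectAgeDMPs(meta, k = config$top_k)
        log_stage("age_meta", "%d probes ranked; top %d: %d hyper / %d hypo",
                  nrow(meta), nrow(dmps), sum(dmps$direction == "hyper"),
                  sum(dmps$direction == "hypo"))
        .write_tsv(meta, file.path(config$output_dir, "age_meta.tsv"))
        .write_tsv(dmps, file.path(config$output_dir, "age_dmps.tsv"))
        manifest$stages$age_meta <- list(
            n_ranked = nrow(meta),
            n_hyper = sum(dmps$direction == "hyper"),
            n_hypo = sum(dmps$direction == "hypo")
        )
        results$age_meta <- meta
        results$age_dmps <- dmps
    }

    rates <- NULL
    if ("rates" %in% config$stages) {
        if (is.null(dmps)) stopf("stage 'rates' requires stage 'age_meta'")
        rates <- methylationRates(x, dmps,
                                  min_rate_samples = config$min_rate_samples)
        log_stage("rates", "rates for %d species", nrow(rates))
        .write_tsv(rates, file.path(config$output_dir, "rates.tsv"))
        manifest$stages$rates <- list(n_species = nrow(rates))
        results$rates <- rates
    }

    if ("pgls" %in% config$stages) {
        if (is.null(rates)) stopf("stage 'pgls' requires stage 'rates'")
        if (is.null(phyloTree(x))) stopf("pgls enabled but no tree available")
        fits <- list(
            hyper = longevityPGLS(x, rates, "mean_hyper_rate"),
            hypo = longevityPGLS(x, rates, "mean_hypo_rate")
        )
        for (d in names(fits)) {
            co <- fits[[d]]$coefficients["rate", ]
            log_stage("pgls", "%s rate: slope = %.3g, r = %.3f, p = %.3g",
                      d, co$estimate, co$r, co$p)
            manifest$stages[[paste0("pgls_", d)]] <- list(
                slope = co$estimate, r = co$r, t = co$t, p = co$p
            )
        }
        results$pgls <- fits
    }

    if ("longevity_dmp" %in% config$stages) {
        ld <- identifyLongevityDMPs(x, fdr_q = config$fdr_q)
        log_stage("longevity_dmp", "%d significant longevity DMPs",
                  nrow(ld$dmps))
        .write_tsv(ld$calls,
                   file.path(config$output_dir, "longevity_dmps.tsv"))
        manifest$stages$longevity_dmp <- list(
            n_significant = nrow(ld$dmps),
            n_nonconverged = ld$n_nonconverged
        )
        results$longevity <- ld
    }

    if ("enrich" %in% config$stages) {
        if (is.null(dmps)) stopf("stage 'enrich' requires stage 'age_meta'")
        ann <- probeAnnotation(x)
        re <- regionEnrichment(dmps, ann, category = "promoter")
        genes <- assignGenes(dmps, ann, region_filter = "promoter")
        log_stage("enrich", "promoter: hyper p = %.3g, %d genes called",
                  if (is.null(re$hyper)) NA else re$hyper$p, nrow(genes))
        .write_tsv(genes, file.path(config$output_dir, "gene_calls.tsv"))
        manifest$stages$enrich <- list(
            promoter_hyper_p = if (is.null(re$hyper)) NA else re$hyper$p,
            promoter_hypo_p = if (is.null(re$hypo)) NA else re$hypo$p,
            n_genes = nrow(genes)
        )
        results$enrichment <- re
        results$gene_calls <- genes
    }

    jsonlite::write_json(
        manifest, file.path(config$output_dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    attr(manifest, "results") <- results
    invisible(manifest)
}
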