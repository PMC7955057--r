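#' Per-probe quality-control statistics
#'
#' Computes each probe's mean, sample standard deviation (n-1 denominator)
#' and coefficient of variation (percent, `100 * sd / mean`) over
#' non-missing beta values. Unmapped control probes are expected to sit
#' near mean 0.5 with a CV close to zero, like SNP control probes.
#'
#' @param x a [MethylAgingExperiment-class] or a numeric beta matrix
#'   (probes x samples) with at least 2 samples.
#' @return data.frame with `probe_id`, `n`, `mean`, `sd`, `cv` (percent;
#'   `NA` with `cv_defined = FALSE` when the mean is 0 or fewer than two
#'   values are present).
#' @examples
#' b <- rbind(cg1 = c(0.4, 0.6), cg2 = c(0.5, 0.5))
#' probeQCStats(b)
#' @export
probeQCStats <- function(x) {
    b <- if (is(x, "MethylAgingExperiment")) betaValues(x) else as.matrix(x)
    if (ncol(b) < 2) stopf("at least 2 samples required")
    st <- row_stats(b)
    cv <- 100 * st$sd / st$mean
    defined <- !is.na(st$sd) & !is.na(st$mean) & st$mean > 0
    cv[!defined] <- NA_real_
    data.frame(
        probe_id = rownames(b) %||% as.character(seq_len(nrow(b))),
        n = st$n, mean = st$mean, sd = st$sd, cv = cv,
        cv_defined = defined, stringsAsFactors = FALSE
    )
}

#' Detect outlier samples by within-species correlation
#'
#' For each species with at least three samples, computes every sample's
#' mean Pearson correlation to the other samples of the same species and
#' flags samples whose mean correlation falls more than `threshold` robust
#' SDs (MAD x 1.4826) below the species median. Species with fewer than
#' three samples are skipped with a message. This is a deterministic,
#' scale-free stand-in for per-species cluster-based outlier screening.
#'
#' @param x a [MethylAgingExperiment-class].
#' @param threshold robust z-score cut-off (default 3).
#' @return Character vector of flagged sample identifiers (possibly empty).
#' @export
detectOutlierSamples <- function(x, threshold = 3) {
    b <- betaValues(x)
    smp <- sampleTable(x)
    flagged <- character()
    for (sp in unique(smp$species)) {
        ids <- smp$sample_id[smp$species == sp]
        if (length(ids) < 3) {
            message(sprintf("species %s has < 3 samples; outlier QC skipped", sp))
            next
        }
        cc <- suppressWarnings(stats::cor(b[, ids, drop = FALSE],
                                          use = "pairwise.complete.obs"))
        diag(cc) <- NA
        mc <- rowMeans(cc, na.rm = TRUE)
        med <- stats::median(mc)
        sdr <- stats::mad(mc, constant = 1.4826)
        if (!is.finite(sdr) || sdr == 0) next
        low <- mc < med - threshold * sdr
        flagged <- c(flagged, ids[which(low)])
    }
    flagged
}

#' Drop flagged samples from an experiment
#'
#' @param x a [MethylAgingExperiment-class].
#' @param sample_ids identifiers to remove.
#' @return The experiment without the given samples, with per-species
#'   sample counts refreshed.
#' @export
dropSamples <- function(x, sample_ids) {
    keep <- !(colnames(x) %in% sample_ids)
    out <- x[, keep]
    st <- speciesTable(out)
    if (nrow(st)) {
        tab <- table(sampleTable(out)$species)
        st$n_samples <- as.integer(tab[st$species])
        st$n_samples[is.na(st$n_samples)] <- 0L
        out@speciesTable <- DataFrame(st)
    }
    out
}
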