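#' Per-species age-methylation correlations
#'
#' For every species with at least `min_samples` known-age samples,
#' computes each probe's Pearson correlation between beta value and
#' untransformed age (years), plus the Fisher z-transform deviate
#' `z = atanh(r) * sqrt(n - 3)`, which is standard normal under the null
#' of no age association. Probes constant within a species are excluded
#' (`NA`) for that species.
#'
#' @param x a [MethylAgingExperiment-class].
#' @param min_samples minimum per-species sample count (default 15).
#' @return List with matrices `r` and `z` (probes x qualifying species)
#'   and vector `n` of per-species sample counts. Species below the
#'   threshold are omitted (reported once via `message()`).
#' @export
speciesAgeCorrelations <- function(x, min_samples = 15) {
    b <- betaValues(x)
    smp <- sampleTable(x)
    tab <- table(smp$species)
    keep <- names(tab)[tab >= min_samples]
    dropped <- setdiff(names(tab), keep)
    if (length(dropped)) {
        message(sprintf("%d species below %d samples excluded from meta-analysis",
                        length(dropped), min_samples))
    }
    if (length(keep) == 0) stopf("no species with >= %d samples", min_samples)
    keep <- sort(keep)
    r <- vapply(keep, function(sp) {
        sel <- smp$species == sp
        row_cor(b[, sel, drop = FALSE], smp$age[sel])
    }, numeric(nrow(b)))
    r <- matrix(r, nrow = nrow(b), ncol = length(keep),
                dimnames = list(rownames(b), keep))
    n <- as.integer(tab[keep])
    names(n) <- keep
    ## Fisher transform; exactly collinear probes (|r| = 1) are clipped so
    ## they rank at the top rather than producing non-finite deviates
    rc <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    z <- sweep(atanh(rc), 2, sqrt(n - 3), `*`)
    z[is.na(r)] <- NA
    list(r = r, z = z, n = n)
}

#' Stouffer's unweighted z combination
#'
#' Combines k standard-normal deviates as `Z = sum(z) / sqrt(k)` with
#' two-sided p-value `2 * (1 - Phi(|Z|))`.
#'
#' @param z numeric vector of finite deviates (NAs dropped).
#' @return List with `Z`, `p` and `k` (number of contributing values);
#'   `Z = NA` when no finite value remains.
#' @examples
#' stoufferCombine(c(2, 2, 2, 2)) # Z = 4
#' @export
stoufferCombine <- function(z) {
    z <- z[is.finite(z)]
    k <- length(z)
    if (k == 0) {
        return(list(Z = NA_real_, p = NA_real_, k = 0L))
    }
    Z <- sum(z) / sqrt(k)
    list(Z = Z, p = 2 * stats::pnorm(abs(Z), lower.tail = FALSE), k = k)
}

#' Meta-analysis of age-methylation association across species
#'
#' Runs [speciesAgeCorrelations()] and combines the per-species deviates of
#' each probe with Stouffer's unweighted z-test. Probes with no qualifying
#' species are omitted from the ranking. Direction is the majority sign of
#' the contributing per-species correlations, with ties broken by the sign
#' of the combined Z.
#'
#' @param x a [MethylAgingExperiment-class].
#' @param min_samples minimum per-species sample count (default 15).
#' @return data.frame (class `ageMeta`) with one row per ranked probe:
#'   `probe_id`, `k_species`, `Z`, `p`, `rank` (1 = most significant, by
#'   |Z| descending with probe_id tie-break), `direction` (`hyper`/`hypo`),
#'   plus one `r_<species>` column per contributing species. Sorted by
#'   rank.
#' @export
ageMetaAnalysis <- function(x, min_samples = 15) {
    corr <- speciesAgeCorrelations(x, min_samples = min_samples)
    z <- corr$z
    k <- rowSums(is.finite(z))
    Z <- rowSums(z, na.rm = TRUE) / sqrt(pmax(k, 1))
    Z[k == 0] <- NA
    p <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
    pos <- rowSums(corr$r > 0, na.rm = TRUE)
    neg <- rowSums(corr$r < 0, na.rm = TRUE)
    direction <- ifelse(pos > neg, "hyper",
                 ifelse(neg > pos, "hypo",
                        ifelse(Z >= 0, "hyper", "hypo")))
    out <- data.frame(
        probe_id = rownames(z), k_species = k, Z = Z, p = p,
        direction = direction, stringsAsFactors = FALSE
    )
    rdf <- as.data.frame(corr$r)
    names(rdf) <- paste0("r_", colnames(corr$r))
    out <- cbind(out, rdf)
    out <- out[k > 0, , drop = FALSE]
    ord <- order(-abs(out$Z), out$probe_id)
    out <- out[ord, , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    class(out) <- c("ageMeta", "data.frame")
    out
}

#' Select top-ranked age DMPs
#'
#' Returns the `k` most significant probes of an [ageMetaAnalysis()] result
#' (by |Z| descending, probe_id tie-break) with their majority-rule
#' directions.
#'
#' @param meta an `ageMeta` result.
#' @param k number of probes to select (default 2000).
#' @return An object of class `dmpSet`: data.frame `probe_id`, `direction`,
#'   with attributes `provenance = "age"` and `k`.
#' @export
selectAgeDMPs <- function(meta, k = 2000) {
    if (k > nrow(meta)) {
        warnf("k = %d exceeds %d ranked probes; returning all", k, nrow(meta))
        k <- nrow(meta)
    }
    sel <- meta[seq_len(k), c("probe_id", "direction"), drop = FALSE]
    rownames(sel) <- NULL
    structure(sel, provenance = "age", k = k,
              class = c("dmpSet", "data.frame"))
}
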