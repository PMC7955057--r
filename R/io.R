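#' Beta value from methylated/unmethylated intensities
#'
#' Computes the methylation fraction from the fluorescence intensities of
#' the methylated (M) and unmethylated (U) channels as
#' `Max(M, 0) / (Max(M, 0) + Max(U, 0) + 100)`. Negative intensities are
#' clamped to zero; the +100 offset keeps the denominator positive, so the
#' result lies in \[0, 1).
#'
#' @param M,U numeric vectors of fluorescence intensities (recycled).
#' @return Numeric vector of beta values in \[0, 1).
#' @examples
#' betaFromIntensities(900, 0)   # 0.9
#' betaFromIntensities(-50, -50) # 0
#' @export
betaFromIntensities <- function(M, U) {
    if (!is.numeric(M) || !is.numeric(U) || anyNA(M) || anyNA(U) ||
        any(!is.finite(M)) || any(!is.finite(U))) {
        stopf("M and U must be finite numeric values")
    }
    m <- pmax(M, 0)
    u <- pmax(U, 0)
    m / (m + u + 100)
}

.write_tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
}

.read_tsv <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    utils::read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "", quote = "")
}

#' Write a MethylAgingExperiment to a directory of plain-text files
#'
#' Writes `beta.tsv` (first column `probe_id`, one column per sample),
#' `samples.tsv`, `probes.tsv`, `species.tsv`, `tree.nwk` (when a phylogeny
#' is present) and optionally `truth.tsv`. All writers are byte-stable for
#' identical inputs.
#'
#' @param x a [MethylAgingExperiment-class].
#' @param dir output directory (created if needed).
#' @param truth optional ground-truth data.frame (from
#'   [simulateMethylData()]).
#' @return `dir`, invisibly.
#' @export
writeMethylDataset <- function(x, dir, truth = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    b <- betaValues(x)
    .write_tsv(
        data.frame(probe_id = rownames(b),
                   signif(b, 10), ## fixed precision keeps files byte-stable
                   check.names = FALSE, stringsAsFactors = FALSE),
        file.path(dir, "beta.tsv")
    )
    .write_tsv(sampleTable(x), file.path(dir, "samples.tsv"))
    .write_tsv(probeAnnotation(x), file.path(dir, "probes.tsv"))
    .write_tsv(speciesTable(x), file.path(dir, "species.tsv"))
    if (!is.null(phyloTree(x))) {
        ape::write.tree(phyloTree(x), file.path(dir, "tree.nwk"))
    }
    if (!is.null(truth)) .write_tsv(truth, file.path(dir, "truth.tsv"))
    invisible(dir)
}

#' Read a methylation aging dataset from plain-text files
#'
#' Loads the file bundle written by [writeMethylDataset()] (or equivalently
#' formatted tab-separated files) and enforces cross-referential integrity:
#' beta-matrix samples without metadata (and vice versa) are dropped with a
#' warning, species absent from the tree abort with an error, and tree tips
#' without samples are pruned. Probe order in the beta file is preserved.
#'
#' @param dir directory containing the bundle; individual paths may be
#'   overridden.
#' @param beta,samples,probes,species,tree file paths (defaults relative to
#'   `dir`; `probes`, `species` and `tree` are optional and skipped when the
#'   file does not exist).
#' @return A [MethylAgingExperiment-class].
#' @export
readMethylDataset <- function(dir = ".",
                              beta = file.path(dir, "beta.tsv"),
                              samples = file.path(dir, "samples.tsv"),
                              probes = file.path(dir, "probes.tsv"),
                              species = file.path(dir, "species.tsv"),
                              tree = file.path(dir, "tree.nwk")) {
    bdf <- .read_tsv(beta)
    if (colnames(bdf)[1] != "probe_id") {
        stopf("beta matrix must have 'probe_id' as its first column")
    }
    bm <- as.matrix(bdf[, -1, drop = FALSE])
    storage.mode(bm) <- "double"
    rownames(bm) <- bdf$probe_id
    smp <- .read_tsv(samples)

    common <- intersect(colnames(bm), smp$sample_id)
    if (length(common) == 0) stopf("no overlapping samples between beta matrix and metadata")
    drop_b <- setdiff(colnames(bm), common)
    drop_s <- setdiff(smp$sample_id, common)
    if (length(drop_b)) {
        warnf("dropping %d beta-matrix samples without metadata", length(drop_b))
    }
    if (length(drop_s)) {
        warnf("dropping %d metadata rows without beta columns", length(drop_s))
    }
    bm <- bm[, common, drop = FALSE]
    smp <- smp[match(common, smp$sample_id), , drop = FALSE]

    ann <- if (file.exists(probes)) {
        pa <- .read_tsv(probes)
        keep <- rownames(bm) %in% pa$probe_id
        if (!all(keep)) {
            warnf("dropping %d probes without annotation", sum(!keep))
            bm <- bm[keep, , drop = FALSE]
        }
        pa
    } else NULL

    sp <- if (file.exists(species)) .read_tsv(species) else NULL
    tr <- if (file.exists(tree)) ape::read.tree(tree) else NULL
    if (!is.null(tr)) {
        present <- unique(smp$species)
        if (!is.null(sp)) present <- union(present, sp$species)
        extra <- setdiff(tr$tip.label, present)
        if (length(extra)) {
            message(sprintf("pruning %d tree tips without samples", length(extra)))
            tr <- ape::drop.tip(tr, extra)
        }
    }
    MethylAgingExperiment(bm, smp, probes = ann, species = sp, tree = tr)
}

#' Optional beta-value normalization hook
#'
#' The pipeline consumes pre-normalized beta values by default
#' (`method = "none"`). `method = "quantile"` applies per-sample quantile
#' normalization via [limma::normalizeQuantiles()] and re-clamps to
#' \[0, 1\].
#'
#' @param x a [MethylAgingExperiment-class].
#' @param method `"none"` (default) or `"quantile"`.
#' @return The experiment with its beta assay normalized.
#' @export
normalizeBetas <- function(x, method = c("none", "quantile")) {
    method <- match.arg(method)
    if (method == "none") return(x)
    b <- limma::normalizeQuantiles(betaValues(x))
    assays(x)[["beta"]] <- pmin(pmax(b, 0), 1)
    x
}
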