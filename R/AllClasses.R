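#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData rowData<- colData<-
NULL

setOldClass("phylo")
setClassUnion("phyloOrNULL", c("phylo", "NULL"))

#' MethylAgingExperiment: container for cross-species methylation aging data
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a beta-value
#' assay (probes x samples, methylation fractions in \[0, 1\]), probe
#' annotation in `rowData()`, sample metadata in `colData()`, a per-species
#' trait table, and an optional phylogeny whose tip labels match the species
#' names.
#'
#' Probe annotation columns (see [probeAnnotation()]): `chromosome`,
#' `position` (1-based bp), `strand`, `nearest_gene`, `dist_to_tss` (signed
#' bp, negative upstream of the TSS in transcription direction), `region`
#' (one of promoter, five_prime_utr, exon, intron, three_prime_utr,
#' intergenic; promoter if and only if `dist_to_tss` lies in the configured
#' promoter window, by default -10000..+1000), and `mapped_species`
#' (comma-separated species with a unique probe alignment).
#'
#' Sample columns (see [sampleTable()]): `species`, `age` (years, >= 0),
#' `sex` (`F`, `M` or `unknown`), `exact_age`, `source`.
#'
#' Species columns (see [speciesTable()]): `species`, `max_lifespan` (years),
#' `body_mass` (grams), `lq` (longevity quotient), `longevity_class`
#' (`long`, `short` or `unassigned`), `n_samples`.
#'
#' @slot speciesTable `DataFrame` of per-species traits.
#' @slot tree a `phylo` object or `NULL`.
#'
#' @aliases MethylAgingExperiment-class
#' @export
setClass(
    "MethylAgingExperiment",
    contains = "SummarizedExperiment",
    slots = c(speciesTable = "DataFrame", tree = "phyloOrNULL")
)

.validMAE <- function(object) {
    msg <- character()
    if (!"beta" %in% names(assays(object))) {
        msg <- c(msg, "assay 'beta' is required")
    } else {
        b <- assay(object, "beta")
        bad <- !is.na(b) & (b < 0 | b > 1 | !is.finite(b))
        if (any(bad)) {
            msg <- c(msg, sprintf(
                "%d beta values outside [0, 1] or non-finite", sum(bad)
            ))
        }
    }
    if (anyDuplicated(rownames(object))) {
        msg <- c(msg, "duplicate probe identifiers")
    }
    if (anyDuplicated(colnames(object))) {
        msg <- c(msg, "duplicate sample identifiers")
    }
    cd <- colData(object)
    if (!all(c("species", "age") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'species' and 'age'")
    } else {
        if (any(!is.na(cd$age) & cd$age < 0)) {
            msg <- c(msg, "sample ages must be >= 0")
        }
        st <- object@speciesTable
        if (nrow(st) > 0 && !all(cd$species %in% st$species)) {
            msg <- c(msg, "all sample species must appear in speciesTable")
        }
        tr <- object@tree
        if (!is.null(tr) && nrow(st) > 0 && !all(st$species %in% tr$tip.label)) {
            missing <- setdiff(st$species, tr$tip.label)
            msg <- c(msg, sprintf(
                "species missing from tree tips: %s",
                paste(missing, collapse = ", ")
            ))
        }
    }
    if (length(msg)) msg else TRUE
}

setValidity("MethylAgingExperiment", .validMAE)

#' Construct a MethylAgingExperiment
#'
#' @param beta numeric matrix of methylation fractions, probes x samples,
#'   with probe row names and sample column names.
#' @param samples data.frame or `DataFrame` of per-sample metadata with at
#'   least `sample_id` (matching `colnames(beta)`), `species` and `age`.
#' @param probes optional data.frame of probe annotation with `probe_id`
#'   matching `rownames(beta)`.
#' @param species optional data.frame of per-species traits with a
#'   `species` column.
#' @param tree optional `ape::phylo` phylogeny whose tips cover the species.
#'
#' @return A [MethylAgingExperiment-class] object.
#' @examples
#' beta <- matrix(runif(12), 3, 4,
#'     dimnames = list(paste0("cg", 1:3), paste0("s", 1:4)))
#' samples <- data.frame(sample_id = paste0("s", 1:4),
#'     species = "sp1", age = c(1, 2, 3, 4))
#' mae <- MethylAgingExperiment(beta, samples)
#' mae
#' @export
MethylAgingExperiment <- function(beta, samples, probes = NULL,
                                  species = NULL, tree = NULL) {
    beta <- as.matrix(beta)
    samples <- as.data.frame(samples)
    if (is.null(samples$sample_id)) {
        stopf("'samples' must contain a sample_id column")
    }
    if (is.null(colnames(beta))) {
        stopf("'beta' must have sample column names")
    }
    if (is.null(rownames(beta))) {
        stopf("'beta' must have probe row names")
    }
    idx <- match(colnames(beta), samples$sample_id)
    if (anyNA(idx)) {
        stopf("samples missing from metadata: %s",
              paste(colnames(beta)[is.na(idx)], collapse = ", "))
    }
    cd <- DataFrame(samples[idx, , drop = FALSE])
    rownames(cd) <- cd$sample_id
    rd <- if (is.null(probes)) {
        DataFrame(probe_id = rownames(beta))
    } else {
        probes <- as.data.frame(probes)
        pidx <- match(rownames(beta), probes$probe_id)
        if (anyNA(pidx)) {
            stopf("probes missing from annotation: %s",
                  paste(rownames(beta)[is.na(pidx)], collapse = ", "))
        }
        DataFrame(probes[pidx, , drop = FALSE])
    }
    rownames(rd) <- rownames(beta)
    st <- if (is.null(species)) {
        DataFrame(species = unique(cd$species))
    } else {
        DataFrame(as.data.frame(species))
    }
    if (!is.null(tree) && !inherits(tree, "phylo")) {
        stopf("'tree' must be a phylo object")
    }
    se <- SummarizedExperiment(
        assays = SimpleList(beta = beta), rowData = rd, colData = cd
    )
    new("MethylAgingExperiment", se, speciesTable = st, tree = tree)
}

setMethod("show", "MethylAgingExperiment", function(object) {
    cat(sprintf(
        "MethylAgingExperiment: %d probes x %d samples, %d species%s\n",
        nrow(object), ncol(object), nrow(object@speciesTable),
        if (is.null(object@tree)) "" else " (with phylogeny)"
    ))
    ages <- colData(object)$age
    if (length(ages)) {
        cat(sprintf("ages: %.2f-%.2f years\n",
                    min(ages, na.rm = TRUE), max(ages, na.rm = TRUE)))
    }
    callNextMethod()
})
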