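#' Accessors for MethylAgingExperiment
#'
#' `betaValues()` returns the beta-value matrix (probes x samples);
#' `sampleTable()`, `probeAnnotation()` and `speciesTable()` return the
#' corresponding metadata as plain data.frames; `phyloTree()` returns the
#' phylogeny (or `NULL`).
#'
#' @param x a [MethylAgingExperiment-class].
#' @return See the individual descriptions.
#' @name accessors
#' @examples
#' sim <- simulateMethylData(syntheticConfig(n_species = 4, n_probes = 50,
#'     seed = 1))
#' dim(betaValues(sim$experiment))
#' head(sampleTable(sim$experiment))
NULL

#' @rdname accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setMethod("betaValues", "MethylAgingExperiment", function(x) {
    assay(x, "beta")
})

#' @rdname accessors
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @rdname accessors
#' @export
setMethod("sampleTable", "MethylAgingExperiment", function(x) {
    as.data.frame(colData(x))
})

#' @rdname accessors
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))

#' @rdname accessors
#' @export
setMethod("probeAnnotation", "MethylAgingExperiment", function(x) {
    as.data.frame(rowData(x))
})

#' @rdname accessors
#' @export
setGeneric("speciesTable", function(x) standardGeneric("speciesTable"))

#' @rdname accessors
#' @export
setMethod("speciesTable", "MethylAgingExperiment", function(x) {
    as.data.frame(x@speciesTable)
})

#' @rdname accessors
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

#' @rdname accessors
#' @export
setMethod("phyloTree", "MethylAgingExperiment", function(x) x@tree)

## Parse the comma-separated mapped_species annotation column into a list of
## species-name vectors; probes with an empty entry map nowhere.
mapped_species_list <- function(x) {
    ms <- probeAnnotation(x)$mapped_species
    if (is.null(ms)) {
        ## no mapping information: treat every probe as mapped everywhere
        return(rep(list(speciesTable(x)$species), nrow(x)))
    }
    strsplit(ifelse(is.na(ms), "", ms), ",", fixed = TRUE)
}
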