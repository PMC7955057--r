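#' Assign DMPs to nearest genes with majority-rule direction
#'
#' Maps each DMP probe to its annotated nearest gene (optionally after
#' restricting to a genomic region category, e.g. promoters) and counts
#' hyper- and hypomethylating probes per gene. A gene is called `hyper`
#' when it has more hypermethylated than hypomethylated probes nearest its
#' TSS, `hypo` in the converse case, and `unassigned` on ties (excluded
#' from directional gene lists).
#'
#' @param dmps a `dmpSet` with `probe_id` and `direction`.
#' @param annotation probe annotation data.frame (e.g.
#'   [probeAnnotation()]), with `probe_id`, `nearest_gene` and `region`.
#' @param region_filter optional region category (e.g. `"promoter"`).
#' @return data.frame with `gene`, `n_hyper`, `n_hypo`, `direction`,
#'   ordered by gene symbol.
#' @export
assignGenes <- function(dmps, annotation, region_filter = NULL) {
    idx <- match(dmps$probe_id, annotation$probe_id)
    unann <- is.na(idx)
    if (any(unann)) {
        message(sprintf("dropping %d unannotated DMP probes", sum(unann)))
    }
    df <- data.frame(
        gene = annotation$nearest_gene[idx[!unann]],
        region = annotation$region[idx[!unann]],
        direction = dmps$direction[!unann],
        stringsAsFactors = FALSE
    )
    if (!is.null(region_filter)) {
        df <- df[df$region %in% region_filter, , drop = FALSE]
    }
    if (nrow(df) == 0) {
        return(data.frame(gene = character(), n_hyper = integer(),
                          n_hypo = integer(), direction = character(),
                          stringsAsFactors = FALSE))
    }
    tab <- table(df$gene, factor(df$direction, levels = c("hyper", "hypo")))
    out <- data.frame(
        gene = rownames(tab),
        n_hyper = as.integer(tab[, "hyper"]),
        n_hypo = as.integer(tab[, "hypo"]),
        stringsAsFactors = FALSE
    )
    out$direction <- ifelse(out$n_hyper > out$n_hypo, "hyper",
                     ifelse(out$n_hypo > out$n_hyper, "hypo", "unassigned"))
    out[order(out$gene), , drop = FALSE]
}

#' Hypergeometric overlap test between two identifier lists
#'
#' Tests whether lists A and B overlap more than expected by chance within
#' a common background universe, using the upper-tail hypergeometric
#' probability `P(X >= k)` (one-sided Fisher's exact test; a two-sided
#' variant is available by flag). Both lists are intersected with the
#' background first. The odds ratio comes from the 2x2 table, with a 0.5
#' continuity correction applied when any cell is zero.
#'
#' @param list_a,list_b character vectors of identifiers.
#' @param background character vector: the universe.
#' @param alternative `"greater"` (default, upper tail) or `"two.sided"`
#'   (via [stats::fisher.test()]).
#' @return An object of class `overlapTest`: list with `N`, `K`, `n`, `k`,
#'   `odds_ratio`, `p`, `alternative`.
#' @examples
#' overlapTest(letters[1:5], letters[2:5], letters[1:10])
#' @export
overlapTest <- function(list_a, list_b, background,
                        alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    background <- unique(background)
    if (length(background) == 0) stopf("empty background")
    a <- intersect(unique(list_a), background)
    b <- intersect(unique(list_b), background)
    dropped <- (length(unique(list_a)) - length(a)) +
        (length(unique(list_b)) - length(b))
    if (dropped) {
        message(sprintf("%d list entries outside the background dropped",
                        dropped))
    }
    N <- length(background)
    K <- length(a)
    n <- length(b)
    k <- length(intersect(a, b))
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2, 2)
    if (alternative == "greater") {
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
        p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    }
    ct <- if (any(tab == 0)) 0.5 else 0
    or <- ((k + ct) * (N - K - n + k + ct)) /
        ((K - k + ct) * (n - k + ct))
    structure(list(N = N, K = K, n = n, k = k, odds_ratio = or, p = p,
                   alternative = alternative),
              class = "overlapTest")
}

#' @export
print.overlapTest <- function(x, ...) {
    cat(sprintf(
        "overlap: k = %d of (K = %d, n = %d) in N = %d; OR = %.3g, p = %.3g (%s)\n",
        x$k, x$K, x$n, x$N, x$odds_ratio, x$p, x$alternative
    ))
    invisible(x)
}

#' Region-category enrichment of a DMP set
#'
#' Tests whether the hyper-direction and hypo-direction probes of a DMP
#' set are over-represented in a genomic region category (e.g. promoters)
#' relative to the full annotated probe background, with one upper-tail
#' hypergeometric test per direction. Directions with no probes are
#' skipped with a message.
#'
#' @param dmps a `dmpSet`.
#' @param annotation probe annotation with `probe_id` and `region`.
#' @param category region category to test (must occur in the annotation).
#' @return Named list with elements `hyper` and `hypo`, each an
#'   `overlapTest` (or `NULL` when skipped).
#' @export
regionEnrichment <- function(dmps, annotation, category = "promoter") {
    if (!category %in% annotation$region) {
        stopf("region category '%s' absent from annotation", category)
    }
    background <- annotation$probe_id
    in_cat <- annotation$probe_id[annotation$region == category]
    out <- list(hyper = NULL, hypo = NULL)
    for (d in c("hyper", "hypo")) {
        ids <- dmps$probe_id[dmps$direction == d]
        if (length(ids) == 0) {
            message(sprintf("no %s-direction DMPs; test skipped", d))
            next
        }
        out[[d]] <- overlapTest(ids, in_cat, background)
    }
    out
}

#' Read a one-column gene-symbol list
#'
#' Gene lists (e.g. externally curated age, tumor or immunity gene sets)
#' are plain text, one symbol per line; symbols are upper-cased and
#' de-duplicated.
#'
#' @param path file path.
#' @return Character vector of gene symbols.
#' @export
readGeneList <- function(path) {
    g <- readLines(path, warn = FALSE)
    g <- toupper(trimws(g))
    unique(g[nzchar(g)])
}
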