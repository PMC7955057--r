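## Shared fixture builders; all randomness is seeded inside each helper so
## tests are order-independent.

## Small simulated dataset with every archetype represented.
small_sim <- function(seed = 11, n_species = 6, n_probes = 300,
                      samples = c(16, 20), ...) {
    simulateMethylData(syntheticConfig(
        n_species = n_species, n_probes = n_probes,
        samples_per_species = samples, seed = seed, ...
    ))
}

## Minimal hand-built experiment: one species, linear age gradient.
tiny_experiment <- function(beta, ages, species = "sp1") {
    n <- ncol(beta)
    if (is.null(colnames(beta))) colnames(beta) <- sprintf("s%03d", seq_len(n))
    if (is.null(rownames(beta))) rownames(beta) <- sprintf("cg%03d", seq_len(nrow(beta)))
    smp <- data.frame(
        sample_id = colnames(beta),
        species = rep_len(species, n),
        age = ages, stringsAsFactors = FALSE
    )
    MethylAgingExperiment(beta, smp)
}

## Orthonormal mean-zero design of size n x p, rescaled so that
## crossprod(X)/n == I exactly; used for the closed-form lasso oracle.
orthonormal_design <- function(n, p, seed = 5) {
    set.seed(seed)
    Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
    Q * sqrt(n)
}

## Brute-force Brownian covariance oracle: pairwise depth of the most
## recent common ancestor by exhaustive root-to-tip path walking.
bruteforce_vcv <- function(tree) {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    parent <- integer(max(tree$edge))
    elen <- numeric(max(tree$edge))
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    elen[tree$edge[, 2]] <- tree$edge.length
    path_to_root <- function(node) {
        path <- node
        while (node != root) {
            node <- parent[node]
            path <- c(path, node)
        }
        path
    }
    depth <- function(node) {
        d <- 0
        while (node != root) {
            d <- d + elen[node]
            node <- parent[node]
        }
        d
    }
    C <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
    for (i in seq_len(ntip)) {
        pi <- path_to_root(i)
        for (j in seq_len(ntip)) {
            mrca <- intersect(pi, path_to_root(j))[1]
            C[i, j] <- depth(mrca)
        }
    }
    C
}

## Exhaustive hypergeometric upper-tail oracle: enumerate all C(N, n)
## draws of list B and count those overlapping list A in >= k elements.
bruteforce_overlap_p <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K) ## items 1..K are "list A"
    mean(hits >= k)
}
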