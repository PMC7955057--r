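#' Configuration for the synthetic methylation aging generator
#'
#' Builds and validates the parameter set for [simulateMethylData()]. The
#' defaults emulate a multi-species known-age methylation study: a few dozen
#' species on an ultrametric phylogeny, 10-60 wing-biopsy-like samples per
#' species, thousands of CpG probes of which subsets drift with age
#' (hypermethylating or hypomethylating, logistic-bounded in \[0, 1\]) at
#' rates inversely scaled by the species longevity quotient, plus
#' longevity-class-dependent, sex-associated, unmapped-control and inert
#' probes.
#'
#' Methylation trajectories are generated on the logit scale,
#' `logit(mu) = b0 + s * r_s * age + u_species`, with direction `s` in
#' \{+1, -1, 0\} and species rate `r_s = base_rate * LQ^(-rate_lq_exponent) *
#' rate_multiplier\[species\]`, so beta values stay in bounds at any age; in
#' the small-slope regime the linear-scale rate is approximately
#' `r_s * mu * (1 - mu)`.
#'
#' @param n_species number of species (tree tips).
#' @param tree_depth root-to-tip depth of the simulated ultrametric tree,
#'   in arbitrary time units.
#' @param samples_per_species integer range `c(min, max)`; the per-species
#'   sample count is drawn uniformly from this range.
#' @param n_probes total number of CpG probes.
#' @param frac_age_hyper,frac_age_hypo,frac_longevity,frac_sex,frac_unmapped
#'   proportions of probes assigned to each informative archetype; the
#'   remainder are inert ("null") probes. Must sum to at most 1.
#' @param base_rate logit-scale drift per year for a species with LQ = 1.
#' @param rate_lq_exponent exponent of the inverse LQ scaling of drift rate
#'   (1 means rate proportional to 1/LQ; 0 removes the longevity effect).
#' @param probe_rate_range multiplicative per-probe rate heterogeneity,
#'   drawn uniformly from this range.
#' @param class_rate_ratio for longevity-archetype probes, the drift-rate
#'   multiplier of short-lived relative to long-lived species (short-class
#'   probes drift `class_rate_ratio` times faster).
#' @param sex_effect logit-scale offset added for female samples at
#'   sex-archetype probes.
#' @param species_sd SD of the per-probe, per-species random logit offset.
#' @param noise_sd SD of the Gaussian measurement noise added on the beta
#'   scale (observed beta is clamped to \[0, 1\]).
#' @param lq_range `c(min, max)` range into which simulated longevity
#'   quotients are mapped; min must be >= 0.1.
#' @param age_frac ages are drawn uniformly on `[0, age_frac * max
#'   lifespan]` per species (sampled animals are rarely at record age).
#' @param promoter_frac baseline fraction of probes annotated to
#'   promoters.
#' @param promoter_bias_hyper odds multiplier for promoter membership of
#'   hypermethylating age- and longevity-archetype probes (default 4),
#'   emulating the promoter concentration of hypermethylating sites
#'   observed on mammalian methylation arrays; set to 1 for no coupling.
#' @param mapped_prob probability that a non-control probe is mapped in any
#'   given species' genome.
#' @param rate_multiplier optional named vector of per-species drift-rate
#'   multipliers (e.g. to slow one species' epigenetic aging).
#' @param allometry `c(a, b)` of the lifespan-mass allometry
#'   `expected_lifespan = a * mass_grams^b` used to convert simulated LQ
#'   into a maximum lifespan.
#' @param seed integer seed; mandatory, all randomness derives from it.
#'
#' @return A validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(n_species = 20,
                            tree_depth = 1,
                            samples_per_species = c(10, 60),
                            n_probes = 3000,
                            frac_age_hyper = 0.1,
                            frac_age_hypo = 0.1,
                            frac_longevity = 0.05,
                            frac_sex = 0.02,
                            frac_unmapped = 0.05,
                            base_rate = 0.03,
                            rate_lq_exponent = 1,
                            probe_rate_range = c(2 / 3, 1.5),
                            class_rate_ratio = 3,
                            sex_effect = 1,
                            species_sd = 0.15,
                            noise_sd = 0.03,
                            lq_range = c(0.8, 5),
                            age_frac = 0.8,
                            promoter_frac = 0.3,
                            promoter_bias_hyper = 4,
                            mapped_prob = 0.9,
                            rate_multiplier = NULL,
                            allometry = c(a = 4.88, b = 0.153),
                            seed = 1L) {
    cfg <- list(
        n_species = as.integer(n_species), tree_depth = tree_depth,
        samples_per_species = as.integer(samples_per_species),
        n_probes = as.integer(n_probes),
        frac_age_hyper = frac_age_hyper, frac_age_hypo = frac_age_hypo,
        frac_longevity = frac_longevity, frac_sex = frac_sex,
        frac_unmapped = frac_unmapped,
        base_rate = base_rate, rate_lq_exponent = rate_lq_exponent,
        probe_rate_range = probe_rate_range,
        class_rate_ratio = class_rate_ratio, sex_effect = sex_effect,
        species_sd = species_sd, noise_sd = noise_sd,
        lq_range = lq_range, age_frac = age_frac,
        promoter_frac = promoter_frac,
        promoter_bias_hyper = promoter_bias_hyper,
        mapped_prob = mapped_prob,
        rate_multiplier = rate_multiplier, allometry = allometry,
        seed = as.integer(seed)
    )
    fr <- with(cfg, frac_age_hyper + frac_age_hypo + frac_longevity +
                   frac_sex + frac_unmapped)
    if (any(unlist(cfg[grep("^frac_", names(cfg))]) < 0) || fr > 1) {
        stopf("probe archetype proportions must be >= 0 and sum to <= 1")
    }
    if (cfg$n_species < 2) stopf("n_species must be >= 2")
    if (cfg$base_rate < 0 || cfg$species_sd < 0 || cfg$noise_sd < 0) {
        stopf("rate and SD parameters must be >= 0")
    }
    if (length(cfg$lq_range) != 2 || cfg$lq_range[1] < 0.1 ||
        diff(cfg$lq_range) < 0) {
        stopf("lq_range must be c(min, max) with min >= 0.1")
    }
    if (length(cfg$samples_per_species) != 2 ||
        cfg$samples_per_species[1] < 1 ||
        diff(cfg$samples_per_species) < 0) {
        stopf("samples_per_species must be an increasing range of counts")
    }
    class(cfg) <- "syntheticConfig"
    cfg
}

#' Simulate an ultrametric species phylogeny
#'
#' Draws a random coalescent topology via [ape::rcoal()] and rescales all
#' node depths so every tip sits exactly `tree_depth` from the root.
#'
#' @param n_species number of tips (>= 2).
#' @param tree_depth root-to-tip distance.
#' @param seed integer seed.
#' @return An ultrametric rooted `phylo` with tips `sp01`, `sp02`, ...
#' @examples
#' tr <- simulateTree(6, tree_depth = 1, seed = 7)
#' max(ape::node.depth.edgelength(tr))
#' @export
simulateTree <- function(n_species, tree_depth = 1, seed) {
    if (n_species < 2) stopf("n_species must be >= 2")
    tr <- with_seed(seed, ape::rcoal(
        n_species,
        tip.label = sprintf("sp%02d", seq_len(n_species))
    ))
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * tree_depth / depth
    tr
}

#' Simulate species life-history traits on a phylogeny
#'
#' Longevity quotients (LQ) are drawn with phylogenetic signal — a Brownian
#' motion trait on the tree, affine-mapped into `lq_range` — so related
#' species have related longevity. Body mass is log-uniform; maximum
#' lifespan is `lq * a * mass^b` under the supplied allometry. Longevity
#' classes are assigned by LQ terciles: top third `long`, bottom third
#' `short`, middle `unassigned` (overridable).
#'
#' @param tree a `phylo` phylogeny.
#' @param lq_range `c(min, max)` target LQ range.
#' @param allometry named `c(a, b)` lifespan-mass allometry.
#' @param mass_range `c(min, max)` body mass range in grams.
#' @param class_override optional named character vector
#'   (species -> class) overriding the tercile assignment.
#' @param seed integer seed.
#' @return data.frame with columns `species`, `max_lifespan`, `body_mass`,
#'   `lq`, `longevity_class`.
#' @export
simulateSpeciesTraits <- function(tree, lq_range = c(0.8, 5),
                                  allometry = c(a = 4.88, b = 0.153),
                                  mass_range = c(5, 1200),
                                  class_override = NULL, seed) {
    n <- length(tree$tip.label)
    with_seed(seed, {
        bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
        mass <- exp(stats::runif(n, log(mass_range[1]), log(mass_range[2])))
        span <- diff(range(bm))
        lq <- if (span == 0 || diff(lq_range) == 0) {
            rep(mean(lq_range), n)
        } else {
            lq_range[1] + (bm - min(bm)) / span * diff(lq_range)
        }
        names(lq) <- tree$tip.label
        lifespan <- lq * allometry[["a"]] * mass^allometry[["b"]]
        cls <- rep("unassigned", n)
        if (diff(range(lq)) > 0) {
            q <- stats::quantile(lq, c(1 / 3, 2 / 3), names = FALSE)
            cls[lq <= q[1]] <- "short"
            cls[lq >= q[2]] <- "long"
        }
        if (!is.null(class_override)) {
            cls[match(names(class_override), tree$tip.label)] <-
                unname(class_override)
        }
        data.frame(
            species = tree$tip.label, max_lifespan = unname(lifespan),
            body_mass = unname(mass), lq = unname(lq),
            longevity_class = cls, stringsAsFactors = FALSE
        )
    })
}

## Archetype labels in generation order.
.archetypes <- c("age_hyper", "age_hypo", "longevity", "sex", "unmapped",
                 "null")

#' Simulate a full cross-species methylation aging dataset
#'
#' Generates a [MethylAgingExperiment-class] with the statistical structure
#' the downstream analyses assume, together with a ground-truth table. See
#' [syntheticConfig()] for the generative model. Briefly: ages are uniform
#' on `[0, age_frac * max_lifespan]`; age-archetype probes drift on the
#' logit scale at a rate inversely scaled by species LQ;
#' longevity-archetype probes drift faster in short-lived than long-lived
#' species; sex-archetype probes carry a logit offset by sex; unmapped
#' control probes fluctuate around 0.5 with no biology; observed beta is
#' the logistic mean plus Gaussian noise clamped to \[0, 1\].
#'
#' @param config a [syntheticConfig()] object.
#' @param tree optional phylogeny; simulated from `config` when missing.
#' @param species optional species trait table (as from
#'   [simulateSpeciesTraits()]); simulated when missing. Tips must match
#'   the tree.
#' @return A list with elements `experiment` (the
#'   [MethylAgingExperiment-class]) and `truth` (data.frame: `probe_id`,
#'   `archetype`, `direction` in \{-1, 0, +1\}, and one `rate_<species>`
#'   column per species giving the true logit-scale slope per year).
#' @examples
#' sim <- simulateMethylData(syntheticConfig(n_species = 4, n_probes = 100,
#'     samples_per_species = c(5, 8), seed = 42))
#' table(sim$truth$archetype)
#' @export
simulateMethylData <- function(config, tree = NULL, species = NULL) {
    stopifnot(inherits(config, "syntheticConfig"))
    if (is.null(tree)) {
        tree <- simulateTree(config$n_species, config$tree_depth,
                             seed = child_seed(config$seed, 1L))
    }
    if (is.null(species)) {
        species <- simulateSpeciesTraits(
            tree, lq_range = config$lq_range, allometry = config$allometry,
            seed = child_seed(config$seed, 2L)
        )
    }
    if (!setequal(species$species, tree$tip.label)) {
        stopf("species table does not match tree tips")
    }
    with_seed(child_seed(config$seed, 3L), {
        .simulate_dataset_impl(config, tree, species)
    })
}

.simulate_dataset_impl <- function(config, tree, species) {
    nsp <- nrow(species)
    sp_names <- species$species

    ## --- samples ---------------------------------------------------------
    rng <- config$samples_per_species
    pool <- rng[1]:rng[2]
    n_s <- pool[sample.int(length(pool), nsp, replace = TRUE)]
    sp_of <- rep(sp_names, n_s)
    n <- length(sp_of)
    max_ls <- species$max_lifespan[match(sp_of, sp_names)]
    age <- stats::runif(n, 0, config$age_frac * max_ls)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    samples <- data.frame(
        sample_id = sprintf("s%04d", seq_len(n)), species = sp_of,
        age = age, sex = sex, exact_age = TRUE, source = "synthetic",
        stringsAsFactors = FALSE
    )

    ## --- probe archetypes ------------------------------------------------
    np <- config$n_probes
    counts <- c(
        age_hyper = round(config$frac_age_hyper * np),
        age_hypo = round(config$frac_age_hypo * np),
        longevity = round(config$frac_longevity * np),
        sex = round(config$frac_sex * np),
        unmapped = round(config$frac_unmapped * np)
    )
    counts <- c(counts, null = np - sum(counts))
    archetype <- rep(.archetypes, counts[.archetypes])
    probe_id <- sprintf("cg%05d", seq_len(np))

    ## species drift-rate scale: r_s = base_rate * LQ^-k * multiplier
    mult <- rep(1, nsp)
    names(mult) <- sp_names
    if (!is.null(config$rate_multiplier)) {
        mult[names(config$rate_multiplier)] <- config$rate_multiplier
    }
    r_sp <- config$base_rate * species$lq^(-config$rate_lq_exponent) * mult
    cls <- species$longevity_class
    ## longevity probes: class-dependent rate, LQ-independent otherwise
    r_cls <- config$base_rate *
        ifelse(cls == "short", config$class_rate_ratio,
               ifelse(cls == "long", 1, (1 + config$class_rate_ratio) / 2))

    direction <- integer(np)
    direction[archetype == "age_hyper"] <- 1L
    direction[archetype == "age_hypo"] <- -1L
    direction[archetype == "longevity"] <-
        sample(c(-1L, 1L), sum(archetype == "longevity"), replace = TRUE)

    ## baseline logit; drifting probes start with room to drift
    b0 <- stats::runif(np, -1.5, 1.5)
    b0[direction == 1L] <- stats::runif(sum(direction == 1L), -3, -0.5)
    b0[direction == -1L] <- stats::runif(sum(direction == -1L), 0.5, 3)

    probe_mult <- stats::runif(np, config$probe_rate_range[1],
                               config$probe_rate_range[2])

    ## per-probe per-species logit slope matrix (np x nsp)
    rate <- matrix(0, np, nsp, dimnames = list(probe_id, sp_names))
    is_age <- archetype %in% c("age_hyper", "age_hypo")
    rate[is_age, ] <- outer(
        (direction * probe_mult)[is_age], r_sp
    )
    is_lon <- archetype == "longevity"
    rate[is_lon, ] <- outer((direction * probe_mult)[is_lon], r_cls)

    ## species random offsets on the logit scale (not for controls)
    u <- matrix(stats::rnorm(np * nsp, 0, config$species_sd), np, nsp)
    ctrl <- archetype == "unmapped"
    u[ctrl, ] <- 0

    sp_idx <- match(sp_of, sp_names)
    eta <- b0 + rate[, sp_idx, drop = FALSE] *
        rep(age, each = np) + u[, sp_idx, drop = FALSE]
    ## sex-archetype probes: logit offset for females
    is_sex <- archetype == "sex"
    if (any(is_sex)) {
        eta[is_sex, sex == "F"] <- eta[is_sex, sex == "F"] +
            config$sex_effect
    }
    mu <- stats::plogis(eta)
    mu[ctrl, ] <- 0.5
    beta <- mu + matrix(stats::rnorm(np * n, 0, config$noise_sd), np, n)
    beta <- pmin(pmax(beta, 0), 1)
    dimnames(beta) <- list(probe_id, samples$sample_id)

    ## --- probe annotation -------------------------------------------------
    ann <- .simulate_annotation(probe_id, archetype, direction, config,
                                sp_names)

    ## --- species table ----------------------------------------------------
    species$n_samples <- n_s

    truth <- data.frame(
        probe_id = probe_id, archetype = archetype, direction = direction,
        stringsAsFactors = FALSE
    )
    rt <- as.data.frame(rate)
    names(rt) <- paste0("rate_", sp_names)
    truth <- cbind(truth, rt)

    experiment <- MethylAgingExperiment(
        beta, samples, probes = ann, species = species, tree = tree
    )
    metadata(experiment)$synthetic_config <- unclass(config)
    list(experiment = experiment, truth = truth)
}

## Synthetic gene/TSS/region annotation honouring the promoter-window
## invariant: region == "promoter" iff dist_to_tss in [-10000, +1000].
.simulate_annotation <- function(probe_id, archetype, direction, config,
                                 sp_names) {
    np <- length(probe_id)
    n_genes <- max(20L, ceiling(np / 5))
    genes <- sprintf("GENE%04d", seq_len(n_genes))
    nearest <- sample(genes, np, replace = TRUE)
    ## hypermethylating informative probes carry increased promoter odds
    biased <- direction == 1L & archetype %in% c("age_hyper", "longevity")
    odds <- config$promoter_frac / (1 - config$promoter_frac) *
        ifelse(biased, config$promoter_bias_hyper %||% 1, 1)
    promoter <- stats::runif(np) < odds / (1 + odds)
    other_regions <- c("five_prime_utr", "exon", "intron",
                       "three_prime_utr", "intergenic")
    region <- ifelse(promoter, "promoter",
                     sample(other_regions, np, replace = TRUE))
    dist <- integer(np)
    dist[promoter] <- sample(-10000:1000, sum(promoter), replace = TRUE)
    n_out <- sum(!promoter)
    out_up <- sample(c(TRUE, FALSE), n_out, replace = TRUE)
    dist[!promoter] <- ifelse(
        out_up,
        -sample(10001:100000, n_out, replace = TRUE),
        sample(1001:100000, n_out, replace = TRUE)
    )
    mapped <- matrix(stats::runif(np * length(sp_names)) < config$mapped_prob,
                     np, length(sp_names))
    ## every non-control probe is mapped somewhere
    none <- !rowSums(mapped)
    mapped[cbind(which(none), sample(length(sp_names), sum(none),
                                     replace = TRUE))] <- TRUE
    mapped[archetype == "unmapped", ] <- FALSE
    mapped_str <- vapply(seq_len(np), function(i) {
        paste(sp_names[mapped[i, ]], collapse = ",")
    }, character(1))
    data.frame(
        probe_id = probe_id,
        chromosome = sample(sprintf("chr%d", 1:12), np, replace = TRUE),
        position = sample.int(1e8, np),
        strand = sample(c("+", "-"), np, replace = TRUE),
        nearest_gene = nearest,
        dist_to_tss = dist,
        region = region,
        mapped_species = mapped_str,
        stringsAsFactors = FALSE
    )
}
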