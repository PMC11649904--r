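#' Parameters for the synthetic multimodal cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size, class
#' imbalance, per-modality feature counts, pathway (set) structure, planted
#' effect sizes, within-set correlation, missingness and sparse per-sample
#' modality coverage.
#'
#' Defaults describe a desk-scale cohort with the structural properties the
#' pipeline assumes: about one case to three controls, six molecular layers
#' plus a small mixed clinical table, one planted pathway per molecular
#' modality with a one-standard-deviation mean shift, equicorrelated within-set
#' noise, 2% scattered missingness and 80% per-sample modality coverage.
#'
#' @param n_samples cohort size (default 400).
#' @param case_fraction probability a sample is a case (default 0.25).
#' @param n_features named integer vector of feature counts per modality.
#' @param n_gene_sets number of sets per modality (default 10).
#' @param set_size integer range of set sizes, inclusive (default c(10, 20)).
#' @param planted_sets number of signal-bearing sets per molecular modality
#'   (default 1).
#' @param effect_size class-mean shift, in SD units, for members of planted
#'   sets (default 1).
#' @param within_cor equicorrelation of features within a set, in `[0,1)`
#'   (default 0.3).
#' @param missing_fraction fraction of cells set missing completely at random
#'   (default 0.02).
#' @param coverage named or scalar probability each sample is measured in each
#'   modality (default 0.8; clinical fixed at 1).
#' @param maf_range minor-allele-frequency range for simulated SNPs
#'   (default c(0.05, 0.5)).
#' @param snps_per_gene,cpgs_per_gene annotation fan-out for the genomic and
#'   methylomic layers (defaults 2).
#' @param seed integer seed.
#' @return A named list of class `simParams`.
#' @seealso [simulateCohort()]
#' @export
simParams <- function(n_samples = 400L,
                      case_fraction = 0.25,
                      n_features = c(genomic = 200L, transcriptomic = 200L,
                                     proteomic = 100L, metabolomic = 100L,
                                     methylomic = 200L, inflammatory = 60L,
                                     clinical = 8L),
                      n_gene_sets = 10L,
                      set_size = c(10L, 20L),
                      planted_sets = 1L,
                      effect_size = 1,
                      within_cor = 0.3,
                      missing_fraction = 0.02,
                      coverage = 0.8,
                      maf_range = c(0.05, 0.5),
                      snps_per_gene = 2L,
                      cpgs_per_gene = 2L,
                      seed = 1L) {
    if (case_fraction <= 0 || case_fraction >= 1)
        stop("case_fraction must be in (0,1)")
    if (effect_size < 0) stop("effect_size must be >= 0")
    if (within_cor < 0 || within_cor >= 1)
        stop("within_cor must be in [0,1)")
    cov <- coverage
    if (length(cov) == 1L)
        cov <- stats::setNames(rep(cov, length(n_features)), names(n_features))
    if (any(cov <= 0) || any(cov > 1))
        stop("coverage probabilities must be in (0,1]")
    if ("clinical" %in% names(cov)) cov[["clinical"]] <- 1
    p <- list(n_samples = as.integer(n_samples),
              case_fraction = case_fraction, n_features = n_features,
              n_gene_sets = as.integer(n_gene_sets),
              set_size = as.integer(set_size),
              planted_sets = as.integer(planted_sets),
              effect_size = effect_size, within_cor = within_cor,
              missing_fraction = missing_fraction, coverage = cov,
              maf_range = maf_range, snps_per_gene = as.integer(snps_per_gene),
              cpgs_per_gene = as.integer(cpgs_per_gene),
              seed = as.integer(seed))
    class(p) <- "simParams"
    p
}

featurePrefix <- c(genomic = "rs", transcriptomic = "tx", proteomic = "pr",
                   metabolomic = "mb", methylomic = "cg", inflammatory = "ip",
                   clinical = "cl")

# Universe of *set-level* identifiers per modality: genes for genomic and
# methylomic layers (sets annotate genes, not SNPs/CpGs), features otherwise.
setUniverse <- function(params, mod) {
    nf <- params$n_features[[mod]]
    pre <- featurePrefix[[mod]]
    if (mod == "genomic")
        sprintf("geneG%03d", seq_len(nf %/% params$snps_per_gene))
    else if (mod == "methylomic")
        sprintf("geneM%03d", seq_len(nf %/% params$cpgs_per_gene))
    else sprintf("%s%04d", pre, seq_len(nf))
}

#' Simulate gene-set collections over the synthetic feature universe
#'
#' Draws non-overlapping sets with sizes uniform in `set_size` over each
#' molecular modality's set-level universe (genes for the genomic and
#' methylomic layers, features otherwise). Deterministic given the params
#' seed.
#'
#' @param params a [simParams()] list.
#' @param modalities which modalities to build sets for (default: all
#'   molecular modalities present in `params$n_features`).
#' @return Named list of [GeneSetList-class], one per modality.
#' @export
simulateGeneSets <- function(params,
                             modalities = setdiff(names(params$n_features),
                                                  "clinical")) {
    withSeed(deriveSeed(params$seed, "genesets"), {
        out <- list()
        for (mod in modalities) {
            univ <- setUniverse(params, mod)
            size_range <- seq(params$set_size[1], params$set_size[2])
            sizes <- size_range[sample.int(length(size_range),
                                           params$n_gene_sets,
                                           replace = TRUE)]
            fits <- which(cumsum(sizes) <= length(univ))
            if (!length(fits))
                stop(sprintf(
                    "modality %s: requested set sizes exceed a universe of %d",
                    mod, length(univ)))
            # keep as many non-overlapping sets as the universe accommodates
            sizes <- sizes[seq_len(max(fits))]
            pool <- sample(univ)
            sets <- list()
            at <- 1L
            for (i in seq_along(sizes)) {
                sets[[sprintf("%s_set%02d", mod, i)]] <-
                    sort(pool[at:(at + sizes[i] - 1L)])
                at <- at + sizes[i]
            }
            out[[mod]] <- GeneSetList(sets,
                                      rep(paste(mod, "synthetic set"),
                                          length(sets)))
        }
        out
    })
}

# Continuous block with unit marginal variance. Members of planted sets get
# a class-mean shift of effect_size SD plus equicorrelated within-set noise
# (a shared factor modelling the co-regulation of a perturbed pathway);
# everything else -- including all sets when effect_size is 0 -- is pure
# independent noise, the null the gene-permutation enrichment test assumes.
simContinuous <- function(n, features, sets, planted, effect, rho, y, seed) {
    withSeed(seed, {
        m <- matrix(stats::rnorm(n * length(features)), n, length(features),
                    dimnames = list(names(y), features))
        if (effect > 0) {
            for (s in planted) {
                mem <- intersect(sets[[s]], features)
                if (length(mem) >= 2L && rho > 0)
                    m[, mem] <- sqrt(1 - rho) * m[, mem] +
                        sqrt(rho) * stats::rnorm(n)
                m[, mem] <- m[, mem] + effect * y
            }
        }
        m
    })
}

# Genotypes at HWE; planted SNPs drawn from the genotype distribution
# conditional on case status under a liability-threshold model.
simGenotypes <- function(n, snps, maf, planted_snps, effect, case_fraction,
                         y, seed) {
    withSeed(seed, {
        m <- matrix(0, n, length(snps), dimnames = list(names(y), snps))
        thr <- stats::qnorm(1 - case_fraction)
        for (j in seq_along(snps)) {
            p <- maf[j]
            hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)  # P(g = 0,1,2)
            if (snps[j] %in% planted_snps && effect > 0) {
                a <- min(effect * 0.35, 0.9)  # per-SNP liability loading
                gstd <- (0:2 - 2 * p) / sqrt(2 * p * (1 - p))
                pcase <- stats::pnorm((a * gstd - thr) / sqrt(1 - a^2))
                pg1 <- hwe * pcase / sum(hwe * pcase)
                pg0 <- hwe * (1 - pcase) / sum(hwe * (1 - pcase))
                g <- integer(n)
                ncase <- sum(y == 1)
                g[y == 1] <- sample(0:2, ncase, TRUE, pg1)
                g[y == 0] <- sample(0:2, n - ncase, TRUE, pg0)
            } else {
                g <- sample(0:2, n, TRUE, hwe)
            }
            m[, j] <- g
        }
        m
    })
}

#' Simulate a synthetic multimodal cohort with planted pathway signal
#'
#' Generates per-modality feature matrices, a phenotype table (binary label
#' plus consistent MNSI-style scores), gene-set collections, SNP/CpG-to-gene
#' annotation maps and a ground-truth record. Members of planted sets in
#' continuous modalities receive a class-mean shift of `effect_size` SD with
#' equicorrelated within-set noise; planted SNPs are drawn from a
#' liability-threshold model at Hardy-Weinberg equilibrium; scattered
#' missingness is applied completely at random and whole-modality blocks are
#' dropped per sample at `1 - coverage` (clinical always retained).
#'
#' @param params a [simParams()] list.
#' @return A list with elements `matrices` (named list of
#'   [FeatureMatrix-class]), `phenotype` (data.frame: sample_id, label,
#'   mnsi_baseline, mnsi_followup), `genesets` (per-modality
#'   [GeneSetList-class]), `annotation` (list with `snp` and `cpg` maps,
#'   data.frames of feature_id, gene_id), `clinical_raw` (mixed data.frame
#'   before one-hot encoding) and `truth` (planted set ids, per-feature
#'   effects, latent risk).
#' @examples
#' sim <- simulateCohort(simParams(n_samples = 60, coverage = 1,
#'                                 missing_fraction = 0))
#' names(sim$matrices)
#' @export
simulateCohort <- function(params = simParams()) {
    mods <- names(params$n_features)
    samp <- sprintf("S%04d", seq_len(params$n_samples))
    y <- withSeed(deriveSeed(params$seed, "labels"), {
        stats::rbinom(params$n_samples, 1L, params$case_fraction)
    })
    if (all(y == 1L) || all(y == 0L))
        stop("degenerate class draw: all samples in one class")
    names(y) <- samp

    gsl <- simulateGeneSets(params)
    truth <- list(planted_sets = list(), effects = list(),
                  latent_risk = NULL)
    mats <- list()
    ann <- list()

    # MNSI-style scores consistent with the labels
    pheno <- withSeed(deriveSeed(params$seed, "mnsi"), {
        base <- ifelse(y == 1L, sample(3:8, length(y), TRUE),
                       sample(0:2, length(y), TRUE))
        fup <- pmin(10, pmax(0, base + sample(-1:2, length(y), TRUE)))
        fup[stats::runif(length(y)) < 0.15] <- NA  # lost to follow-up
        data.frame(sample_id = samp, label = as.integer(y),
                   mnsi_baseline = base, mnsi_followup = fup,
                   stringsAsFactors = FALSE)
    })

    for (mod in mods) {
        nf <- params$n_features[[mod]]
        pre <- featurePrefix[[mod]]
        feats <- sprintf("%s%04d", pre, seq_len(nf))
        sets <- if (!is.null(gsl[[mod]])) geneSets(gsl[[mod]]) else list()
        planted <- if (length(sets))
            names(sets)[seq_len(min(params$planted_sets, length(sets)))]
        else character()
        seed_m <- deriveSeed(params$seed, paste0("modality_", mod))

        if (mod == "genomic") {
            genes <- setUniverse(params, mod)
            map <- data.frame(
                feature_id = feats[seq_len(length(genes) * params$snps_per_gene)],
                gene_id = rep(genes, each = params$snps_per_gene),
                stringsAsFactors = FALSE)
            planted_genes <- unlist(sets[planted], use.names = FALSE)
            planted_snps <- map$feature_id[map$gene_id %in% planted_genes]
            maf <- withSeed(deriveSeed(params$seed, "maf"), {
                stats::runif(nf, params$maf_range[1], params$maf_range[2])
            })
            m <- simGenotypes(params$n_samples, feats, maf, planted_snps,
                              params$effect_size, params$case_fraction, y,
                              seed_m)
            ann$snp <- map
            eff <- stats::setNames(rep(0, nf), feats)
            eff[planted_snps] <- params$effect_size
        } else if (mod == "methylomic") {
            genes <- setUniverse(params, mod)
            map <- data.frame(
                feature_id = feats[seq_len(length(genes) * params$cpgs_per_gene)],
                gene_id = rep(genes, each = params$cpgs_per_gene),
                stringsAsFactors = FALSE)
            # translate gene sets into CpG-level planting
            gene_sets_cpg <- lapply(sets, function(g)
                map$feature_id[map$gene_id %in% g])
            m <- simContinuous(params$n_samples, feats, gene_sets_cpg,
                               planted, params$effect_size,
                               params$within_cor, y, seed_m)
            m <- m * 2  # M-value-like spread
            ann$cpg <- map
            eff <- stats::setNames(rep(0, nf), feats)
            eff[unlist(gene_sets_cpg[planted], use.names = FALSE)] <-
                params$effect_size
        } else if (mod == "clinical") {
            m <- NULL  # built below as a mixed table
            eff <- NULL
        } else {
            m <- simContinuous(params$n_samples, feats, sets, planted,
                               params$effect_size, params$within_cor, y,
                               seed_m)
            eff <- stats::setNames(rep(0, nf), feats)
            eff[intersect(unlist(sets[planted], use.names = FALSE), feats)] <-
                params$effect_size
        }
        if (!is.null(m)) {
            mats[[mod]] <- m
            truth$planted_sets[[mod]] <- planted
            truth$effects[[mod]] <- eff
        }
    }

    # Clinical: small mixed table; some variables track the phenotype.
    clinical_raw <- withSeed(deriveSeed(params$seed, "clinical"), {
        n <- params$n_samples
        risk <- params$effect_size * y + stats::rnorm(n)
        df <- data.frame(
            age = round(70 + 3 * scale(risk + stats::rnorm(n))[, 1], 1),
            waist = round(95 + 10 * scale(risk + stats::rnorm(n, sd = 2))[, 1], 1),
            height = round(stats::rnorm(n, 168, 8), 1),
            glucose = round(stats::rnorm(n, 5.5, 0.8), 2),
            smoker = factor(ifelse(stats::runif(n) < 0.25, "yes", "no")),
            sex = factor(ifelse(stats::runif(n) < 0.5, "female", "male")),
            neuro_illness = factor(ifelse(
                stats::runif(n) < stats::plogis(-2.2 +
                    0.8 * params$effect_size * y), "yes", "no")),
            activity = factor(sample(c("low", "medium", "high"), n, TRUE)),
            row.names = samp, stringsAsFactors = TRUE)
        df
    })
    mats$clinical <- featureValues(oneHotEncode(clinical_raw))
    truth$latent_risk <- y + 0  # mean-shift model: risk is carried by labels

    # scattered missingness (MCAR), not on clinical
    if (params$missing_fraction > 0) {
        mats[setdiff(names(mats), "clinical")] <- withSeed(
            deriveSeed(params$seed, "mcar"), {
                lapply(mats[setdiff(names(mats), "clinical")], function(m) {
                    idx <- which(stats::runif(length(m)) <
                                 params$missing_fraction)
                    m[idx] <- NA
                    m
                })
            })
    }

    fms <- lapply(names(mats), function(mod) FeatureMatrix(mats[[mod]], mod))
    names(fms) <- names(mats)

    # block (whole-modality) missingness
    cov <- params$coverage[names(fms)]
    cov[is.na(cov)] <- 1
    names(cov) <- names(fms)
    fms <- applyBlockMissingness(fms, cov,
                                 seed = deriveSeed(params$seed, "coverage"))

    list(matrices = fms, phenotype = pheno, genesets = gsl,
         annotation = ann, clinical_raw = clinical_raw, truth = truth)
}

#' Drop whole modality blocks per sample
#'
#' Each sample retains each modality independently with the given coverage
#' probability (dropped samples are removed from that modality's matrix).
#' Every sample is guaranteed to retain at least one modality.
#'
#' @param matrices named list of [FeatureMatrix-class] over a shared sample
#'   universe.
#' @param coverage named (or scalar) retention probability per modality,
#'   each in (0, 1].
#' @param seed integer seed.
#' @return Named list of [FeatureMatrix-class] with rows dropped.
#' @export
applyBlockMissingness <- function(matrices, coverage, seed) {
    if (length(coverage) == 1L)
        coverage <- stats::setNames(rep(coverage, length(matrices)),
                                    names(matrices))
    if (any(coverage <= 0))
        stop("coverage must be > 0 for every modality")
    samp <- Reduce(union, lapply(matrices, sampleIDs))
    withSeed(seed, {
        keep <- matrix(TRUE, length(samp), length(matrices),
                       dimnames = list(samp, names(matrices)))
        for (mod in names(matrices)) {
            p <- coverage[[mod]]
            if (p < 1)
                keep[, mod] <- stats::runif(length(samp)) < p
        }
        none <- which(rowSums(keep) == 0L)
        for (i in none)  # guarantee at least one retained modality
            keep[i, sample(length(matrices), 1L)] <- TRUE
        out <- lapply(names(matrices), function(mod) {
            ids <- intersect(sampleIDs(matrices[[mod]]),
                             samp[keep[, mod]])
            matrices[[mod]][ids, ]
        })
        names(out) <- names(matrices)
        out
    })
}
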