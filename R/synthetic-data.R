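#' Build a simulation configuration
#'
#' Defines the study conditions of the two-cohort generator. The defaults
#' emulate the design of the motivating study: two cohorts of 99 and 37
#' subjects, ~1000 probes of which five blocks of 50 form co-expression
#' modules through a latent factor, with trait correlations of moderate
#' strength planted on three of the modules.
#'
#' Each planted module is driven by a standard-normal latent factor per
#' sample; member probes load on it with the cohort-specific loading
#' \code{lambdaA}/\code{lambdaB} and receive residual noise with standard
#' deviation \code{noiseSd * sqrt(1 - lambda^2)}, so at the default
#' \code{noiseSd = 1} every probe has unit variance and the within-module
#' correlation equals \code{lambda^2}. \code{delta} is an additive mean
#' shift applied to member probes in cohort B (differential expression on
#' the log-like scale). Background probes are pure noise.
#'
#' @param nSamplesA,nSamplesB cohort sample sizes.
#' @param nProbes total probe count.
#' @param moduleSpecs data.frame with columns \code{size}, \code{lambdaA},
#'   \code{lambdaB}, \code{rhoTrait}, \code{delta}; one row per planted
#'   module.
#' @param noiseSd residual noise scale.
#' @param covariateEffects named numeric: linear \code{age} and \code{sex}
#'   effects added to module probes.
#' @param baseline additive baseline of the log-like expression scale.
#' @param seed master seed.
#' @return a \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @export
simulationConfig <- function(nSamplesA = 99, nSamplesB = 37,
                             nProbes = 1000,
                             moduleSpecs = defaultModuleSpecs(),
                             noiseSd = 1,
                             covariateEffects = c(age = 0.01, sex = 0.2),
                             baseline = 8,
                             seed = 1) {
    new("SimulationConfig",
        nSamplesA = as.integer(nSamplesA),
        nSamplesB = as.integer(nSamplesB),
        nProbes = as.integer(nProbes),
        moduleSpecs = as.data.frame(moduleSpecs),
        noiseSd = as.numeric(noiseSd),
        covariateEffects = covariateEffects,
        baseline = as.numeric(baseline),
        seed = as.integer(seed))
}

#' Default planted-module table
#'
#' Five modules of 50 probes with loading 0.8 in both cohorts; the first
#' three carry trait correlations 0.6, 0.4 and -0.5, the last two are
#' trait-null; no mean shifts.
#'
#' @return data.frame usable as \code{moduleSpecs}.
#' @export
defaultModuleSpecs <- function() {
    data.frame(
        size = rep(50L, 5),
        lambdaA = 0.8,
        lambdaB = 0.8,
        rhoTrait = c(0.6, 0.4, -0.5, 0, 0),
        delta = 0
    )
}

## deterministic sub-seed per cohort, kept within 32-bit integer range
.subSeed <- function(seed, k) {
    as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Generate two synthetic cohorts with planted structure
#'
#' Draws expression, covariates and phenotypes for two cohorts under the
#' latent-factor model described in \code{\link{simulationConfig}}, and
#' returns the planted ground truth alongside. Expression is produced on a
#' log-like additive scale (assay \code{"exprs"}) together with an
#' exponentiated intensity-scale version (assay \code{"intensity"},
#' \code{2^exprs}) for fold-change work, and a uniform detection p-value
#' stub (assay \code{"detectionP"}).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{cohortA}, \code{cohortB} (each a
#'   \link[SummarizedExperiment]{SummarizedExperiment} with covariates and
#'   phenotypes in \code{colData}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' sim <- generateCohorts(simulationConfig(nProbes = 100,
#'     moduleSpecs = defaultModuleSpecs()[1:2, ], seed = 7))
#' dim(SummarizedExperiment::assay(sim$cohortA))
#' @export
generateCohorts <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    ms <- config@moduleSpecs
    nMod <- nrow(ms)
    modNames <- if (nMod) paste0("M", seq_len(nMod)) else character(0)
    probes <- sprintf("probe_%04d", seq_len(config@nProbes))

    partition <- rep("noise", config@nProbes)
    names(partition) <- probes
    if (nMod) {
        idx <- 1L
        for (m in seq_len(nMod)) {
            partition[idx:(idx + ms$size[m] - 1L)] <- modNames[m]
            idx <- idx + ms$size[m]
        }
    }

    drawCohort <- function(n, lambdas, deltas, which, seedOffset) {
        set.seed(.subSeed(config@seed, seedOffset))
        sampleIds <- sprintf("%s%03d", which, seq_len(n))
        age <- pmin(pmax(round(rnorm(n, 41, 10)), 20), 70)
        sex <- ifelse(rbinom(n, 1, 0.5) == 1, "M", "F")
        sexNum <- as.numeric(sex == "M")
        fac <- matrix(rnorm(nMod * n), nrow = max(nMod, 0), ncol = n,
                      dimnames = if (nMod) list(modNames, sampleIds))
        X <- matrix(0, nrow = config@nProbes, ncol = n,
                    dimnames = list(probes, sampleIds))
        bAge <- config@covariateEffects[["age"]]
        bSex <- config@covariateEffects[["sex"]]
        for (g in seq_len(config@nProbes)) {
            lab <- partition[g]
            if (lab == "noise") {
                X[g, ] <- config@baseline +
                    rnorm(n, sd = config@noiseSd)
            } else {
                m <- match(lab, modNames)
                lam <- lambdas[m]
                X[g, ] <- config@baseline + deltas[m] +
                    lam * fac[m, ] +
                    bAge * age + bSex * sexNum +
                    rnorm(n, sd = config@noiseSd * sqrt(1 - lam^2))
            }
        }
        trait <- if (nMod) {
            traitFromFactors(fac, setNames(ms$rhoTrait, modNames))
        } else rnorm(n)
        bmi <- rnorm(n, 28, 5)
        phen <- S4Vectors::DataFrame(
            age = age, sex = sex,
            S_I = trait,
            BMI = bmi,
            AIRg = exp(rnorm(n, 6, 0.5)),
            HOMA_IR = pmax(0.2, 2.5 - trait + rnorm(n, sd = 0.8)),
            row.names = sampleIds)
        se <- SummarizedExperiment::SummarizedExperiment(
            assays = list(
                exprs = X,
                intensity = 2^X,
                detectionP = matrix(runif(length(X), 0, 0.005),
                                    nrow = nrow(X),
                                    dimnames = dimnames(X))),
            colData = phen)
        list(se = se, factors = fac)
    }

    a <- drawCohort(config@nSamplesA, ms$lambdaA, rep(0, nMod), "A", 1L)
    b <- drawCohort(config@nSamplesB, ms$lambdaB, ms$delta, "B", 2L)

    deProbes <- if (nMod && any(ms$delta != 0)) {
        names(partition)[partition %in% modNames[ms$delta != 0]]
    } else character(0)
    truth <- new("SyntheticTruth",
        partition = partition,
        traitLoadings = if (nMod) setNames(ms$rhoTrait, modNames)
                        else numeric(0),
        dcModules = matrix(c(ms$lambdaA, ms$lambdaB), ncol = 2,
                           dimnames = list(modNames,
                                           c("lambdaA", "lambdaB"))),
        deProbes = deProbes,
        factorsA = a$factors,
        factorsB = b$factors)
    list(cohortA = a$se, cohortB = b$se, truth = truth)
}

#' Construct a trait with specified correlations to latent factors
#'
#' Builds a phenotype as a loading-weighted mix of the (independent,
#' unit-variance) module factors plus independent noise scaled so that the
#' population correlation of the trait with factor m equals
#' \code{loadings[m]}. The returned vector is standardized to sample mean 0
#' and variance 1, which leaves all correlations unchanged.
#'
#' @param factors modules x samples matrix of factor scores.
#' @param loadings numeric vector of target correlations, one per module
#'   (each in (-1, 1), squared sum < 1).
#' @param seed optional seed for the noise component; when \code{NULL} the
#'   current RNG stream is used.
#' @return numeric trait vector, one value per sample.
#' @examples
#' f <- matrix(rnorm(2000), nrow = 1)
#' tr <- traitFromFactors(f, 0.5, seed = 1)
#' cor(tr, f[1, ])
#' @export
traitFromFactors <- function(factors, loadings, seed = NULL) {
    factors <- rbind(factors)
    if (any(abs(loadings) >= 1))
        stop("trait loadings must lie in (-1, 1)")
    if (length(loadings) != nrow(factors))
        stop("one loading per factor row required")
    s2 <- sum(loadings^2)
    if (s2 >= 1)
        stop("sum of squared trait loadings must be < 1")
    if (!is.null(seed)) set.seed(as.integer(seed))
    n <- ncol(factors)
    raw <- drop(crossprod(factors, loadings)) +
        sqrt(1 - s2) * rnorm(n)
    as.numeric(scale(raw))
}

#' Write a synthetic data set to tab-delimited files
#'
#' Writes per-cohort expression (probes x samples, first column the probe
#' ID), detection p-values, covariates and phenotypes, plus the ground
#' truth as JSON.
#'
#' @param sim result of \code{\link{generateCohorts}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
writeCohortData <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (which in c("A", "B")) {
        se <- sim[[paste0("cohort", which)]]
        for (what in c("exprs", "intensity", "detectionP")) {
            f <- file.path(dir, sprintf("cohort%s_%s.tsv", which, what))
            writeExpressionMatrix(
                SummarizedExperiment::assay(se, what), f)
            files <- c(files, f)
        }
        cd <- as.data.frame(SummarizedExperiment::colData(se))
        f <- file.path(dir, sprintf("cohort%s_samples.tsv", which))
        writeResultTable(cbind(sample_id = rownames(cd), cd), f)
        files <- c(files, f)
    }
    tr <- sim$truth
    f <- file.path(dir, "truth.json")
    jsonlite::write_json(list(
        partition = as.list(tr@partition),
        traitLoadings = as.list(tr@traitLoadings),
        dcModules = as.data.frame(tr@dcModules),
        deProbes = tr@deProbes), f, auto_unbox = TRUE, digits = NA)
    invisible(c(files, f))
}

#' Module partition of the planted ground truth
#'
#' Converts a \linkS4class{SyntheticTruth} into a
#' \linkS4class{ModulePartition} (background probes become gray), e.g. to
#' benchmark module statistics on the planted modules directly.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @return a \linkS4class{ModulePartition}.
#' @export
truthPartition <- function(truth) {
    lab <- truth@partition
    lab[lab == "noise"] <- "gray"
    minSize <- if (any(lab != "gray")) min(table(lab[lab != "gray"]))
               else 2L
    new("ModulePartition", labels = lab,
        minModuleSize = as.integer(max(2L, minSize)))
}
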