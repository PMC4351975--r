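#' @import methods
#' @importFrom stats cor sd quantile rnorm runif rbinom pt phyper p.adjust
#'   hclust as.dist cutree prcomp complete.cases lm.fit setNames qnorm var
#'   median
#' @importFrom utils head read.delim write.table packageVersion combn
NULL

#' Configuration for the two-cohort synthetic generator
#'
#' Holds the study-design parameters of the latent-factor generator: cohort
#' sizes, probe count, per-module specifications (size, within-module factor
#' loading in each cohort, trait correlation, between-cohort mean shift),
#' residual noise level, linear covariate effects and the master seed.
#'
#' @slot nSamplesA,nSamplesB number of samples in cohorts A and B.
#' @slot nProbes total number of probes; probes beyond the planted modules
#'   are background noise.
#' @slot moduleSpecs data.frame with columns \code{size}, \code{lambdaA},
#'   \code{lambdaB}, \code{rhoTrait}, \code{delta}.
#' @slot noiseSd residual noise scale (module probes receive
#'   \code{noiseSd * sqrt(1 - lambda^2)} so total variance is
#'   \code{noiseSd^2} when loadings are in [0,1]).
#' @slot covariateEffects named numeric, linear effects of \code{age} and
#'   \code{sex} added to module probes.
#' @slot baseline additive baseline on the log-like expression scale.
#' @slot seed master seed; all randomness derives from it.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(
        nSamplesA = "integer",
        nSamplesB = "integer",
        nProbes = "integer",
        moduleSpecs = "data.frame",
        noiseSd = "numeric",
        covariateEffects = "numeric",
        baseline = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    ms <- object@moduleSpecs
    need <- c("size", "lambdaA", "lambdaB", "rhoTrait", "delta")
    if (!all(need %in% names(ms)))
        msg <- c(msg, paste("moduleSpecs must have columns:",
                            paste(need, collapse = ", ")))
    if (object@nSamplesA < 1L || object@nSamplesB < 1L)
        msg <- c(msg, "sample counts must be positive")
    if (object@nProbes < 1L)
        msg <- c(msg, "nProbes must be positive")
    if (all(need %in% names(ms)) && nrow(ms) > 0) {
        if (sum(ms$size) > object@nProbes)
            msg <- c(msg, "sum of module sizes exceeds nProbes")
        if (any(ms$size < 1))
            msg <- c(msg, "module sizes must be positive")
        if (any(ms$lambdaA < 0 | ms$lambdaA > 1 |
                ms$lambdaB < 0 | ms$lambdaB > 1))
            msg <- c(msg, "factor loadings must lie in [0, 1]")
        if (any(abs(ms$rhoTrait) >= 1))
            msg <- c(msg, "trait correlations must lie in (-1, 1)")
        if (sum(ms$rhoTrait^2) >= 1)
            msg <- c(msg, "sum of squared trait correlations must be < 1")
    }
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be > 0")
    if (!all(c("age", "sex") %in% names(object@covariateEffects)))
        msg <- c(msg, "covariateEffects must name 'age' and 'sex'")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic two-cohort data set
#'
#' @slot partition named character, probe -> planted module label
#'   (background probes are labelled \code{"noise"}).
#' @slot traitLoadings named numeric, module -> planted trait correlation.
#' @slot dcModules matrix (modules x 2) of cohort loadings
#'   \code{lambdaA}, \code{lambdaB}.
#' @slot deProbes probes carrying a non-zero planted mean shift.
#' @slot factorsA,factorsB latent factor scores (modules x samples).
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(
        partition = "character",
        traitLoadings = "numeric",
        dcModules = "matrix",
        deProbes = "character",
        factorsA = "matrix",
        factorsB = "matrix"
    )
)

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (is.null(names(object@partition)) ||
        anyDuplicated(names(object@partition)))
        msg <- c(msg, "partition must be named with unique probe IDs")
    if (!all(object@deProbes %in% names(object@partition)))
        msg <- c(msg, "deProbes must be a subset of the probes")
    if (length(msg)) msg else TRUE
})

#' Module assignment of probes
#'
#' Probe-to-module map in the usual colour vocabulary: modules are named by
#' descending size (turquoise, blue, brown, ...), with numbered fallbacks
#' once colours run out; \code{"gray"} marks probes assigned to no module.
#'
#' @slot labels named character vector, probe -> module colour.
#' @slot minModuleSize smallest admissible module size.
#' @exportClass ModulePartition
setClass("ModulePartition",
    representation(labels = "character", minModuleSize = "integer")
)

setValidity("ModulePartition", function(object) {
    msg <- character()
    if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
        msg <- c(msg, "labels must be named with unique probe IDs")
    if (anyNA(object@labels))
        msg <- c(msg, "labels must not contain NA")
    sz <- table(object@labels[object@labels != "gray"])
    if (length(sz) && any(sz < object@minModuleSize))
        msg <- c(msg, "non-gray module smaller than minModuleSize")
    if (length(msg)) msg else TRUE
})

#' Weighted co-expression network of one cohort
#'
#' @slot beta soft-threshold power.
#' @slot correlation probes x probes Pearson correlation.
#' @slot adjacency unsigned power adjacency |r|^beta with unit diagonal.
#' @slot tom topological overlap matrix.
#' @exportClass WeightedNetwork
setClass("WeightedNetwork",
    representation(
        beta = "numeric",
        correlation = "matrix",
        adjacency = "matrix",
        tom = "matrix"
    )
)

setValidity("WeightedNetwork", function(object) {
    msg <- character()
    a <- object@adjacency
    t <- object@tom
    if (!identical(dim(a), dim(object@correlation)) ||
        !identical(dim(a), dim(t)))
        msg <- c(msg, "correlation, adjacency and tom must share dimensions")
    if (nrow(a) > 0) {
        if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
            msg <- c(msg, "adjacency must lie in [0, 1]")
        if (min(t) < -1e-12 || max(t) > 1 + 1e-12)
            msg <- c(msg, "tom must lie in [0, 1]")
    }
    if (object@beta < 1)
        msg <- c(msg, "beta must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Module eigengenes
#'
#' First principal component of each module's standardized expression,
#' scaled to unit variance and sign-oriented so that the mean correlation
#' with the module's members is positive.
#'
#' @slot eigengenes samples x modules matrix.
#' @slot varExplained named numeric, fraction of module variance carried by
#'   the first component.
#' @exportClass EigengeneSet
setClass("EigengeneSet",
    representation(eigengenes = "matrix", varExplained = "numeric")
)

setValidity("EigengeneSet", function(object) {
    msg <- character()
    if (ncol(object@eigengenes) != length(object@varExplained))
        msg <- c(msg, "one varExplained entry per eigengene required")
    ve <- object@varExplained
    if (length(ve) && (any(ve <= 0) || any(ve > 1 + 1e-8)))
        msg <- c(msg, "varExplained must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Mutual-information network of one module
#'
#' Pairwise mutual-information edges surviving a permutation-null
#' significance screen; edges removed by the data processing inequality are
#' retained with a flag for audit.
#'
#' @slot nodes module probes.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{mi}
#'   (nats), \code{p} (permutation p), \code{removedByDPI}.
#' @slot miThreshold permutation-null MI significance threshold (nats).
#' @slot dpiTolerance DPI tolerance used (1 disables pruning).
#' @exportClass MINetwork
setClass("MINetwork",
    representation(
        nodes = "character",
        edges = "data.frame",
        miThreshold = "numeric",
        dpiTolerance = "numeric"
    )
)

setValidity("MINetwork", function(object) {
    msg <- character()
    e <- object@edges
    need <- c("from", "to", "mi", "p", "removedByDPI")
    if (!all(need %in% names(e)))
        msg <- c(msg, paste("edges must have columns:",
                            paste(need, collapse = ", ")))
    else if (nrow(e)) {
        if (any(e$mi < 0)) msg <- c(msg, "mi must be non-negative")
        if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be module nodes")
    }
    if (length(msg)) msg else TRUE
})
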