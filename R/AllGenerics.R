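#' Accessors for conetdiff classes
#'
#' Small accessor generics: \code{moduleLabels} returns the probe -> module
#' map of a \linkS4class{ModulePartition}; \code{moduleSizes} the per-module
#' member counts (gray excluded); \code{moduleMembers} a named list of probe
#' sets; \code{netAdjacency}, \code{netTOM}, \code{netCorrelation} and
#' \code{softPower} the matrices and power of a
#' \linkS4class{WeightedNetwork}; \code{connectivity} the whole-network
#' connectivity k_i (self excluded); \code{eigengenes} and
#' \code{varianceExplained} the components of an
#' \linkS4class{EigengeneSet}; \code{miEdges} the edge table of an
#' \linkS4class{MINetwork}.
#'
#' @param x the object.
#' @param ... passed to methods.
#' @return see the individual descriptions above.
#' @name accessors
#' @aliases moduleLabels moduleSizes moduleMembers netAdjacency netTOM
#'   netCorrelation softPower connectivity eigengenes varianceExplained
#'   miEdges
NULL

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x, ...) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(x, ...) standardGeneric("moduleSizes"))

#' @rdname accessors
#' @export
setGeneric("moduleMembers", function(x, ...) standardGeneric("moduleMembers"))

#' @rdname accessors
#' @export
setGeneric("netAdjacency", function(x, ...) standardGeneric("netAdjacency"))

#' @rdname accessors
#' @export
setGeneric("netTOM", function(x, ...) standardGeneric("netTOM"))

#' @rdname accessors
#' @export
setGeneric("netCorrelation",
    function(x, ...) standardGeneric("netCorrelation"))

#' @rdname accessors
#' @export
setGeneric("softPower", function(x, ...) standardGeneric("softPower"))

#' @rdname accessors
#' @export
setGeneric("connectivity", function(x, ...) standardGeneric("connectivity"))

#' @rdname accessors
#' @export
setGeneric("eigengenes", function(x, ...) standardGeneric("eigengenes"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained",
    function(x, ...) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setGeneric("miEdges", function(x, ...) standardGeneric("miEdges"))

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModulePartition", function(x, ...) x@labels)

#' @rdname accessors
#' @export
setMethod("moduleSizes", "ModulePartition", function(x, ...) {
    lab <- x@labels[x@labels != "gray"]
    if (!length(lab)) return(integer(0))
    sz <- table(lab)
    sort(structure(as.integer(sz), names = names(sz)), decreasing = TRUE)
})

#' @rdname accessors
#' @export
setMethod("moduleMembers", "ModulePartition", function(x, ...) {
    lab <- x@labels[x@labels != "gray"]
    split(names(lab), lab)[names(moduleSizes(x))]
})

#' @rdname accessors
#' @export
setMethod("netAdjacency", "WeightedNetwork", function(x, ...) x@adjacency)

#' @rdname accessors
#' @export
setMethod("netTOM", "WeightedNetwork", function(x, ...) x@tom)

#' @rdname accessors
#' @export
setMethod("netCorrelation", "WeightedNetwork",
    function(x, ...) x@correlation)

#' @rdname accessors
#' @export
setMethod("softPower", "WeightedNetwork", function(x, ...) x@beta)

#' @rdname accessors
#' @export
setMethod("connectivity", "WeightedNetwork", function(x, ...) {
    rowSums(x@adjacency) - diag(x@adjacency)
})

#' @rdname accessors
#' @export
setMethod("eigengenes", "EigengeneSet", function(x, ...) x@eigengenes)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "EigengeneSet",
    function(x, ...) x@varExplained)

#' @rdname accessors
#' @param prunedOnly drop edges removed by the data processing inequality.
#' @export
setMethod("miEdges", "MINetwork", function(x, prunedOnly = TRUE, ...) {
    e <- x@edges
    if (prunedOnly && nrow(e)) e <- e[!e$removedByDPI, , drop = FALSE]
    e
})

setMethod("show", "SimulationConfig", function(object) {
    ms <- object@moduleSpecs
    cat("SimulationConfig:", object@nSamplesA, "+", object@nSamplesB,
        "samples,", object@nProbes, "probes,", nrow(ms),
        "planted modules\n")
    if (nrow(ms)) {
        cat("  module sizes:", paste(ms$size, collapse = ", "), "\n")
        cat("  loadings A/B:",
            paste(sprintf("%.2f/%.2f", ms$lambdaA, ms$lambdaB),
                  collapse = ", "), "\n")
    }
    cat("  noiseSd:", object@noiseSd, " seed:", object@seed, "\n")
    invisible(NULL)
})

setMethod("show", "ModulePartition", function(object) {
    sz <- moduleSizes(object)
    cat("ModulePartition:", length(object@labels), "probes,",
        length(sz), "modules,",
        sum(object@labels == "gray"), "gray\n")
    if (length(sz))
        cat("  largest:", paste(sprintf("%s (%d)", head(names(sz), 5),
                                        head(sz, 5)), collapse = ", "), "\n")
    invisible(NULL)
})

setMethod("show", "WeightedNetwork", function(object) {
    cat("WeightedNetwork:", nrow(object@adjacency), "probes, beta =",
        object@beta, "\n")
    k <- connectivity(object)
    if (length(k))
        cat("  connectivity: mean", signif(mean(k), 4), " max",
            signif(max(k), 4), "\n")
    invisible(NULL)
})

setMethod("show", "EigengeneSet", function(object) {
    cat("EigengeneSet:", ncol(object@eigengenes), "modules x",
        nrow(object@eigengenes), "samples\n")
    invisible(NULL)
})

setMethod("show", "MINetwork", function(object) {
    e <- object@edges
    cat("MINetwork:", length(object@nodes), "nodes,",
        if (nrow(e)) sum(!e$removedByDPI) else 0L, "edges (",
        if (nrow(e)) sum(e$removedByDPI) else 0L, "removed by DPI )\n")
    invisible(NULL)
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@partition), "probes,",
        nrow(object@dcModules), "planted modules,",
        length(object@deProbes), "DE probes\n")
    invisible(NULL)
})
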