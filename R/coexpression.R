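## Ordered colour vocabulary for module labels, largest module first.
## Numbered fallbacks ("turquoise2", ...) are generated once the base list
## is exhausted.
.moduleColors <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black",
    "pink", "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

.colorLabels <- function(k) {
    base <- .moduleColors
    if (k <= length(base)) return(base[seq_len(k)])
    extra <- k - length(base)
    reps <- ceiling(extra / length(base))
    fallback <- as.vector(t(outer(seq_len(reps) + 1, base,
                                  function(i, col) paste0(col, i))))
    c(base, fallback[seq_len(extra)])
}

.checkCorInput <- function(x) {
    ## Accept either an expression matrix (probes x samples) or a
    ## precomputed correlation matrix.
    if (isSymmetric(unname(x)) && nrow(x) == ncol(x) &&
        all(abs(x) <= 1 + 1e-12) &&
        all(abs(diag(x) - 1) < 1e-12)) {
        return(x)
    }
    sds <- apply(x, 1, sd)
    if (any(sds == 0))
        stop("constant probes (correlation undefined): ",
             paste(head(rownames(x)[sds == 0], 5), collapse = ", "))
    cor(t(x))
}

#' Unsigned power adjacency
#'
#' Computes the soft-thresholded network adjacency a_ij = |r_ij|^beta from
#' Pearson correlations among probes. The diagonal is set to 1 by
#' convention and excluded from all connectivity sums.
#'
#' @param x probes x samples expression matrix, SummarizedExperiment, or a
#'   precomputed correlation matrix (square, symmetric, unit diagonal).
#' @param beta soft-threshold power (>= 1).
#' @return probes x probes adjacency matrix in [0, 1].
#' @examples
#' powerAdjacency(matrix(c(1, -0.5, -0.5, 1), 2), beta = 5)[1, 2]
#' @export
powerAdjacency <- function(x, beta) {
    stopifnot(beta >= 1)
    if (is(x, "SummarizedExperiment")) x <- .exprMatrix(x)
    r <- .checkCorInput(x)
    if (anyNA(r))
        stop("non-finite correlations for probes: ",
             paste(head(rownames(r)[apply(is.na(r), 1, any)], 5),
                   collapse = ", "))
    a <- abs(r)^beta
    diag(a) <- 1
    a
}

#' Topological overlap matrix
#'
#' Transforms an unsigned adjacency into the topological overlap
#' similarity: TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' l_ij sums the shared-neighbour adjacency a_iu * a_uj over u != i, j and
#' k_i is the connectivity excluding the self-term. TOM_ii = 1.
#'
#' @param adjacency square symmetric matrix in [0, 1].
#' @return TOM matrix of the same dimension, values in [0, 1].
#' @export
tomSimilarity <- function(adjacency) {
    if (!isSymmetric(unname(adjacency)))
        stop("adjacency must be symmetric")
    if (min(adjacency) < -1e-12 || max(adjacency) > 1 + 1e-12)
        stop("adjacency values must lie in [0, 1]")
    a <- adjacency
    diag(a) <- 0
    l <- a %*% a
    k <- rowSums(a)
    kmin <- outer(k, k, pmin)
    tom <- (l + a) / (kmin + 1 - a)
    diag(tom) <- 1
    tom[tom < 0] <- 0
    tom[tom > 1] <- 1
    dimnames(tom) <- dimnames(adjacency)
    tom
}

#' Scale-free topology fit of a connectivity vector
#'
#' Bins connectivities into 10 equal-width bins, drops empty bins, and
#' regresses log10(frequency) on log10(mean connectivity). The signed fit
#' index is -sign(slope) * R^2, so positive values indicate the decreasing
#' degree distribution expected of a scale-free network. The truncated fit
#' adds a linear connectivity term to the regression.
#'
#' @param k vector of connectivities.
#' @param nBreaks number of equal-width bins.
#' @return list with \code{scaleFreeR2}, \code{truncatedR2},
#'   \code{slope}.
#' @export
scaleFreeFitIndex <- function(k, nBreaks = 10) {
    br <- seq(min(k), max(k), length.out = nBreaks + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    meanK <- tapply(k, bin, mean)
    ok <- !is.na(freq) & !is.na(meanK) & meanK > 0
    if (sum(ok) < 3)
        return(list(scaleFreeR2 = NA_real_, truncatedR2 = NA_real_,
                    slope = NA_real_))
    lf <- log10(freq[ok]); lk <- log10(meanK[ok])
    r2of <- function(fit) {
        1 - sum(residuals(fit)^2) / sum((lf - mean(lf))^2)
    }
    fit <- stats::lm(lf ~ lk)
    slope <- unname(coef(fit)[2])
    tfit <- stats::lm(lf ~ lk + I(meanK[ok]))
    list(scaleFreeR2 = -sign(slope) * r2of(fit),
         truncatedR2 = r2of(tfit),
         slope = slope)
}

#' Soft-threshold power selection
#'
#' Evaluates candidate powers against the scale-free topology criterion:
#' for each beta the unsigned adjacency is formed, connectivities computed,
#' and the signed scale-free fit index obtained from the binned log-log
#' regression (see \code{\link{scaleFreeFitIndex}}). The recommended power
#' is the smallest one whose signed R^2 reaches \code{targetR2}.
#'
#' @param x probes x samples matrix or SummarizedExperiment.
#' @param powers candidate integer powers.
#' @param targetR2 required signed fit index (default 0.8).
#' @param nBreaks bins for the degree regression.
#' @return list with \code{table} (one row per power: scaleFreeR2,
#'   truncatedR2, meanK, medianK, maxK) and \code{powerEstimate} (NA when
#'   no power meets the target).
#' @export
pickSoftThreshold <- function(x, powers = 1:20, targetR2 = 0.8,
                              nBreaks = 10) {
    if (is(x, "SummarizedExperiment")) x <- .exprMatrix(x)
    r <- .checkCorInput(x)
    if (nrow(r) < 20) stop("at least 20 probes required")
    stopifnot(all(powers >= 1))
    rows <- lapply(powers, function(b) {
        a <- abs(r)^b
        diag(a) <- 0
        k <- rowSums(a)
        f <- scaleFreeFitIndex(k, nBreaks)
        data.frame(power = b, scaleFreeR2 = f$scaleFreeR2,
                   truncatedR2 = f$truncatedR2, slope = f$slope,
                   meanK = mean(k), medianK = median(k), maxK = max(k))
    })
    tab <- do.call(rbind, rows)
    hit <- which(!is.na(tab$scaleFreeR2) & tab$scaleFreeR2 >= targetR2)
    list(table = tab,
         powerEstimate = if (length(hit)) tab$power[min(hit)] else NA)
}

#' Build a weighted co-expression network
#'
#' Convenience constructor computing correlation, power adjacency and TOM
#' for one cohort.
#'
#' @param resid probes x samples residual matrix or SummarizedExperiment.
#' @param beta soft-threshold power.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
buildCoexpressionNetwork <- function(resid, beta = 5) {
    if (is(resid, "SummarizedExperiment")) resid <- .exprMatrix(resid)
    r <- .checkCorInput(resid)
    a <- abs(r)^beta
    diag(a) <- 1
    new("WeightedNetwork", beta = as.numeric(beta), correlation = r,
        adjacency = a, tom = tomSimilarity(a))
}

## Recursive tree-variant cut on an hclust object.
## Splits at a merge node when the node lies above cutHeight (static cut)
## or when the height gap to both children exceeds gapThreshold and each
## child subtree could form a module on its own.
.cutTree <- function(h, cutHeight, minSize, gapThreshold) {
    n <- length(h$order)
    nodeSize <- integer(nrow(h$merge))
    subtreeLeaves <- vector("list", nrow(h$merge))
    for (i in seq_len(nrow(h$merge))) {
        kids <- h$merge[i, ]
        leaves <- integer(0)
        for (kid in kids) {
            leaves <- c(leaves,
                        if (kid < 0) -kid else subtreeLeaves[[kid]])
        }
        subtreeLeaves[[i]] <- leaves
        nodeSize[i] <- length(leaves)
    }
    childHeight <- function(kid) if (kid < 0) 0 else h$height[kid]
    childSize <- function(kid) if (kid < 0) 1L else nodeSize[kid]
    recurse <- function(node) {
        if (node < 0) return(list(-node))
        kids <- h$merge[node, ]
        hN <- h$height[node]
        gaps <- hN - vapply(kids, childHeight, numeric(1))
        sizes <- vapply(kids, childSize, integer(1))
        split <- hN > cutHeight ||
            (all(gaps > gapThreshold) && all(sizes >= minSize))
        if (!split) return(list(subtreeLeaves[[node]]))
        c(recurse(kids[1]), recurse(kids[2]))
    }
    recurse(nrow(h$merge))
}

#' Detect modules by average-linkage clustering of topological overlap
#'
#' Clusters probes by average-linkage hierarchical clustering of the
#' dissimilarity 1 - TOM, cuts the dendrogram statically at
#' \code{hierCutoff}, and refines branches with the tree-variant dynamic
#' cut: a branch is split further where the merge-height gap to both
#' children exceeds \code{1 - hierCutoff} and both children are large
#' enough to stand as modules. Clusters smaller than \code{minModuleSize}
#' are labelled gray; surviving modules are named by descending size from
#' the standard colour vocabulary.
#'
#' @param tom TOM matrix (or a \linkS4class{WeightedNetwork}).
#' @param hierCutoff static cut height on the 1 - TOM dissimilarity.
#' @param minModuleSize smallest admissible module (>= 2).
#' @return list with \code{partition} (a \linkS4class{ModulePartition})
#'   and \code{dendrogram} (the hclust object).
#' @export
clusterModules <- function(tom, hierCutoff = 0.99, minModuleSize = 10) {
    if (is(tom, "WeightedNetwork")) tom <- netTOM(tom)
    stopifnot(hierCutoff > 0, hierCutoff <= 1, minModuleSize >= 2)
    probes <- rownames(tom)
    if (is.null(probes)) probes <- sprintf("probe_%04d", seq_len(nrow(tom)))
    if (minModuleSize > nrow(tom)) {
        warning("minModuleSize exceeds the probe count; all probes gray")
        part <- new("ModulePartition",
                    labels = setNames(rep("gray", nrow(tom)), probes),
                    minModuleSize = as.integer(minModuleSize))
        return(list(partition = part, dendrogram = NULL))
    }
    d <- as.dist(1 - tom)
    h <- hclust(d, method = "average")
    clusters <- .cutTree(h, cutHeight = hierCutoff,
                         minSize = as.integer(minModuleSize),
                         gapThreshold = 1 - hierCutoff)
    labels <- setNames(rep("gray", length(probes)), probes)
    keep <- clusters[vapply(clusters, length, 1L) >= minModuleSize]
    if (length(keep)) {
        ## order by size, ties broken by smallest member index for
        ## determinism
        ord <- order(-vapply(keep, length, 1L),
                     vapply(keep, min, 1L))
        keep <- keep[ord]
        cols <- .colorLabels(length(keep))
        for (i in seq_along(keep)) labels[keep[[i]]] <- cols[i]
    }
    part <- new("ModulePartition", labels = labels,
                minModuleSize = as.integer(minModuleSize))
    list(partition = part, dendrogram = h)
}

#' Whole-network and intramodular connectivity
#'
#' Per probe: total connectivity (adjacency row sum excluding self), and
#' within-module connectivity under both the adjacency and the TOM. The
#' per-module hub is the member with the highest TOM-based within-module
#' connectivity, ties broken by probe ID order.
#'
#' @param network a \linkS4class{WeightedNetwork}.
#' @param partition a \linkS4class{ModulePartition} covering the network
#'   probes.
#' @return list with \code{probes} (data.frame: module, kTotal,
#'   kWithinAdjacency, kWithinTOM) and \code{hubs} (named character,
#'   module -> hub probe).
#' @export
intramodularConnectivity <- function(network, partition) {
    a <- netAdjacency(network)
    tm <- netTOM(network)
    lab <- moduleLabels(partition)
    probes <- rownames(a)
    if (!all(probes %in% names(lab)))
        stop("partition does not cover all network probes")
    lab <- lab[probes]
    kTot <- rowSums(a) - diag(a)
    kwa <- kwt <- numeric(length(probes))
    names(kwa) <- names(kwt) <- probes
    for (m in unique(lab)) {
        idx <- which(lab == m)
        kwa[idx] <- rowSums(a[idx, idx, drop = FALSE]) -
            diag(a)[idx]
        kwt[idx] <- rowSums(tm[idx, idx, drop = FALSE]) -
            diag(tm)[idx]
    }
    hubs <- character(0)
    for (m in setdiff(unique(lab), "gray")) {
        idx <- which(lab == m)
        ord <- order(-kwt[idx], probes[idx])
        hubs[m] <- probes[idx][ord[1]]
    }
    list(
        probes = data.frame(probe = probes, module = unname(lab),
                            kTotal = unname(kTot),
                            kWithinAdjacency = unname(kwa),
                            kWithinTOM = unname(kwt),
                            row.names = probes),
        hubs = hubs)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same probes;
#' used to score recovery of planted modules.
#'
#' @param a,b label vectors (named or in matching order).
#' @return the adjusted Rand index.
#' @export
adjustedRandIndex <- function(a, b) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    stopifnot(length(a) == length(b))
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumIJ <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    n <- comb2(length(a))
    expected <- sumI * sumJ / n
    maxIndex <- (sumI + sumJ) / 2
    if (maxIndex == expected) return(1)
    (sumIJ - expected) / (maxIndex - expected)
}
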