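## Gaussian normal scores of a vector (mid-ranks for ties)
.normalScores <- function(x) {
    qnorm((rank(x) - 0.5) / length(x))
}

## MI cap used when the transformed correlation is numerically 1
.MI_CAP_R2 <- 1 - 1e-12

#' Mutual information between two sample vectors
#'
#' Default estimator: rank-transform both vectors to Gaussian scores
#' (Gaussian copula) and evaluate the closed form -0.5 * ln(1 - rho^2) on
#' the correlation of the transformed values, in nats. The alternative is
#' equal-frequency binning with the Miller-Madow bias correction. A
#' degenerate pair (correlation numerically 1) returns the finite cap
#' value with attribute \code{capped = TRUE}; a constant vector yields 0
#' with a warning.
#'
#' @param x,y numeric vectors of equal length (>= 20 for a stable
#'   estimate).
#' @param method \code{"copula"} (default) or \code{"binning"}.
#' @param bins bin count for the binning estimator; default
#'   \code{floor(sqrt(n / 5))}, minimum 2.
#' @return MI estimate in nats.
#' @examples
#' set.seed(1)
#' x <- rnorm(1000); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(1000)
#' estimateMI(x, y)          # about -0.5 * log(1 - 0.36)
#' @export
estimateMI <- function(x, y, method = c("copula", "binning"),
                       bins = NULL) {
    method <- match.arg(method)
    stopifnot(length(x) == length(y))
    n <- length(x)
    if (sd(x) == 0 || sd(y) == 0) {
        warning("constant vector; MI set to 0")
        return(0)
    }
    if (method == "copula") {
        r <- cor(.normalScores(x), .normalScores(y))
        r2 <- min(r^2, .MI_CAP_R2)
        mi <- -0.5 * log(1 - r2)
        if (r^2 >= .MI_CAP_R2) attr(mi, "capped") <- TRUE
        return(mi)
    }
    if (is.null(bins)) bins <- max(2L, floor(sqrt(n / 5)))
    cutEq <- function(v) {
        q <- unique(quantile(v, probs = seq(0, 1, length.out = bins + 1)))
        cut(v, q, include.lowest = TRUE)
    }
    tab <- table(cutEq(x), cutEq(y))
    pxy <- tab / n
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
    ## Miller-Madow correction removes the upward plug-in bias
    mi <- mi - (sum(nz) - sum(px > 0) - sum(py > 0) + 1) / (2 * n)
    max(mi, 0)
}

#' Mutual-information network of a module with DPI pruning
#'
#' ARACNE-style network for one module: (1) pairwise copula MI among the
#' module probes; (2) keep edges whose MI exceeds the permutation-null
#' threshold at level \code{miPMax} (the null pools, over \code{nPermMI}
#' sample permutations, the MI of each probe against its own permuted
#' copy); (3) prune indirect edges with the data processing inequality -
#' in every fully connected triangle the weakest edge is removed when its
#' MI falls below \code{(1 - dpiTolerance)} times the second-weakest.
#' Removal decisions use the original MI values, so the result does not
#' depend on processing order; removed edges stay in the table flagged for
#' audit. \code{dpiTolerance = 1} disables pruning.
#'
#' @param resid probes x samples residual matrix or SummarizedExperiment.
#' @param moduleProbes probes of the module (>= 3).
#' @param miPMax significance level of the permutation-null MI screen.
#' @param nPermMI number of sample permutations for the null.
#' @param dpiTolerance DPI tolerance in [0, 1]; 0 = strict.
#' @param seed RNG seed.
#' @return an \linkS4class{MINetwork}.
#' @export
buildAracne <- function(resid, moduleProbes, miPMax = 0.05,
                        nPermMI = 100, dpiTolerance = 0.15, seed = 1) {
    x <- .exprMatrix(resid)
    if (length(moduleProbes) < 3)
        stop("module must have at least 3 probes")
    if (!all(moduleProbes %in% rownames(x)))
        stop("module probes missing from the expression matrix")
    xm <- x[moduleProbes, , drop = FALSE]
    n <- ncol(xm)
    z <- t(apply(xm, 1, .normalScores))
    r <- cor(t(z))
    r2 <- pmin(r^2, .MI_CAP_R2)
    mi <- -0.5 * log(1 - r2)
    diag(mi) <- 0

    set.seed(as.integer(seed))
    nullMI <- numeric(0)
    for (b in seq_len(nPermMI)) {
        idx <- sample.int(n)
        rn <- vapply(seq_len(nrow(z)),
                     function(g) cor(z[g, ], z[g, idx]), numeric(1))
        nullMI <- c(nullMI, -0.5 * log(1 - pmin(rn^2, .MI_CAP_R2)))
    }
    thr <- quantile(nullMI, probs = 1 - miPMax, names = FALSE)

    m <- length(moduleProbes)
    pairs <- which(upper.tri(mi), arr.ind = TRUE)
    keep <- mi[pairs] > thr
    pairs <- pairs[keep, , drop = FALSE]
    empP <- vapply(mi[cbind(pairs[, 1], pairs[, 2])], function(v)
        (1 + sum(nullMI >= v)) / (1 + length(nullMI)), numeric(1))
    edges <- data.frame(
        from = moduleProbes[pairs[, 1]],
        to = moduleProbes[pairs[, 2]],
        mi = mi[cbind(pairs[, 1], pairs[, 2])],
        p = empP,
        removedByDPI = rep(FALSE, nrow(pairs)),
        stringsAsFactors = FALSE)

    if (nrow(edges) && dpiTolerance < 1) {
        adj <- matrix(0, m, m, dimnames = list(moduleProbes, moduleProbes))
        adj[cbind(pairs[, 1], pairs[, 2])] <- edges$mi
        adj[cbind(pairs[, 2], pairs[, 1])] <- edges$mi
        removed <- matrix(FALSE, m, m)
        for (i in seq_len(m - 2)) for (j in (i + 1):(m - 1)) {
            if (adj[i, j] == 0) next
            for (k in (j + 1):m) {
                if (adj[i, k] == 0 || adj[j, k] == 0) next
                w <- c(adj[i, j], adj[i, k], adj[j, k])
                lo <- which.min(w)
                second <- min(w[-lo])
                if (w[lo] < (1 - dpiTolerance) * second) {
                    if (lo == 1) removed[i, j] <- TRUE
                    else if (lo == 2) removed[i, k] <- TRUE
                    else removed[j, k] <- TRUE
                }
            }
        }
        edges$removedByDPI <- removed[cbind(pairs[, 1], pairs[, 2])]
    }
    new("MINetwork", nodes = moduleProbes, edges = edges,
        miThreshold = unname(thr), dpiTolerance = dpiTolerance)
}

#' Key-driver nomination by N-hop neighbourhood size
#'
#' Counts, for every node of the (post-DPI) mutual-information network, the
#' distinct nodes reachable within \code{hops} edges (NHNN, self excluded),
#' and nominates as key drivers the nodes whose NHNN strictly exceeds
#' mean(NHNN) + sd(NHNN), with the sample (n - 1) standard deviation.
#' Degree is reported alongside; edges are treated as undirected.
#'
#' @param network an \linkS4class{MINetwork}, or a two-column edge
#'   data.frame with columns \code{from}, \code{to}.
#' @param hops neighbourhood depth (default 2).
#' @param nodes node universe when passing a plain edge table.
#' @return data.frame per node: \code{nhnn}, \code{degree},
#'   \code{threshold}, \code{isDriver}.
#' @export
keyDrivers <- function(network, hops = 2, nodes = NULL) {
    stopifnot(hops >= 1)
    if (is(network, "MINetwork")) {
        e <- miEdges(network, prunedOnly = TRUE)
        nodes <- network@nodes
    } else {
        e <- network
        if (is.null(nodes)) nodes <- unique(c(e$from, e$to))
    }
    if (nrow(e) == 0) {
        return(data.frame(node = nodes, nhnn = 0L, degree = 0L,
                          threshold = NA_real_, isDriver = FALSE,
                          row.names = nodes))
    }
    g <- igraph::graph_from_data_frame(
        e[, c("from", "to")], directed = FALSE,
        vertices = data.frame(name = nodes))
    nhnn <- igraph::ego_size(g, order = hops, mindist = 1)
    deg <- igraph::degree(g)
    thr <- mean(nhnn) + sd(nhnn)
    data.frame(node = nodes,
               nhnn = as.integer(nhnn),
               degree = as.integer(deg),
               threshold = thr,
               isDriver = nhnn > thr,
               row.names = nodes)
}
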