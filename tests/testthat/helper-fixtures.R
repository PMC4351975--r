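## Shared fixtures and independent oracles used across the test files.
## Everything is generated in code; no data files.

suppressPackageStartupMessages(library(SummarizedExperiment))

## Matrix of p variables x n samples whose *sample* correlation equals
## Sigma exactly (empirical whitening followed by a Cholesky colouring).
makeExactCorrData <- function(n, Sigma, seed = 1, prefix = "g") {
    set.seed(seed)
    p <- nrow(Sigma)
    stopifnot(n > p)
    X <- matrix(rnorm(n * p), n, p)
    X <- scale(X, center = TRUE, scale = FALSE)
    Y <- X %*% solve(chol(cov(X))) %*% chol(Sigma)
    out <- t(Y)
    dimnames(out) <- list(paste0(prefix, seq_len(p)),
                          paste0("s", seq_len(n)))
    out
}

## Two blocks of perfectly correlated probes (r = 1 within, exactly 0
## between), built by duplicating two empirically uncorrelated profiles.
twoBlockExpr <- function(sizes = c(30, 20), n = 50, seed = 1) {
    base <- makeExactCorrData(n, diag(2), seed)
    x <- rbind(
        matrix(rep(base[1, ], each = sizes[1]), nrow = sizes[1]),
        matrix(rep(base[2, ], each = sizes[2]), nrow = sizes[2]))
    dimnames(x) <- list(sprintf("g%02d", seq_len(sum(sizes))),
                        colnames(base))
    x
}

## All permutations of 1..n as a list (insertion construction; independent
## of the recursion used inside the package).
allPermutations <- function(n) {
    res <- list(1L)
    for (k in 2:n) {
        nxt <- list()
        for (p in res) for (pos in 0:(k - 1)) {
            nxt[[length(nxt) + 1L]] <- append(p, k, after = pos)
        }
        res <- nxt
    }
    res
}

## Plain breadth-first neighbourhood count (oracle for keyDrivers).
## edges: data.frame with from/to; returns #nodes within `hops`, self
## excluded.
bfsNeighborhoodSize <- function(edges, nodes, start, hops) {
    adj <- lapply(setNames(nodes, nodes), function(v)
        c(edges$to[edges$from == v], edges$from[edges$to == v]))
    visited <- start
    frontier <- start
    for (h in seq_len(hops)) {
        nxt <- setdiff(unique(unlist(adj[frontier])), visited)
        if (!length(nxt)) break
        visited <- c(visited, nxt)
        frontier <- nxt
    }
    length(visited) - 1L
}

## Random symmetric adjacency with values in [0, 1] and unit diagonal.
randomAdjacency <- function(p, seed) {
    set.seed(seed)
    a <- matrix(runif(p * p), p, p)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", seq_len(p)), paste0("g", seq_len(p)))
    a
}

## Direct loop evaluation of the TOM formula (oracle for tomSimilarity).
tomByHand <- function(a) {
    p <- nrow(a)
    out <- diag(p)
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(p)) {
            if (u != i && u != j) l <- l + a[i, u] * a[u, j]
        }
        ki <- sum(a[i, -i])
        kj <- sum(a[j, -j])
        out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    dimnames(out) <- dimnames(a)
    out
}

## A ModulePartition built from explicit member lists.
partitionFromSets <- function(sets, grayProbes = character(0),
                              minModuleSize = 2) {
    lab <- c(unlist(lapply(names(sets), function(m)
        setNames(rep(m, length(sets[[m]])), sets[[m]]))),
        setNames(rep("gray", length(grayProbes)), grayProbes))
    new("ModulePartition", labels = lab,
        minModuleSize = as.integer(minModuleSize))
}

## Markov-chain Gaussian triple X -> Y -> Z with step correlation rho.
markovTriple <- function(n, rho = 0.8, seed = 1) {
    set.seed(seed)
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    z <- rho * y + sqrt(1 - rho^2) * rnorm(n)
    m <- rbind(X = x, Y = y, Z = z)
    colnames(m) <- paste0("s", seq_len(n))
    m
}

## Trait vector whose *sample* correlation with each factor row equals the
## requested loading exactly (empirical whitening of the factor scores).
exactTraitForFactors <- function(factors, loadings, seed = 1) {
    set.seed(seed)
    n <- ncol(factors)
    M <- scale(t(factors), center = TRUE, scale = FALSE)
    S <- cov(M)
    U0 <- chol(S)
    a <- solve(t(U0), loadings * sqrt(diag(S)))
    stopifnot(sum(a^2) < 1)
    Uw <- M %*% solve(U0)             # identity sample covariance
    z <- rnorm(n)
    z <- residuals(lm(z ~ Uw))        # orthogonal to the factors
    z <- z / sd(z) * sqrt((n - 1) / n)
    z <- z - mean(z)
    e <- z / sqrt(sum(z^2) / (n - 1))
    tr <- drop(Uw %*% a) + sqrt(1 - sum(a^2)) * e
    drop(scale(tr))
}
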