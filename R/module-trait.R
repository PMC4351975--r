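#' Module eigengenes
#'
#' Summarizes each non-gray module by the first principal component of its
#' standardized member expression across samples. The eigengene is scaled
#' to unit variance and sign-oriented so that its mean correlation with the
#' module members is positive, which makes the result invariant to
#' sign-flips of individual probes. A singleton module's eigengene is its
#' z-scored profile. Member probes with zero variance are dropped; a module
#' whose probes are all constant is an error.
#'
#' @param resid probes x samples residual matrix or SummarizedExperiment.
#' @param partition a \linkS4class{ModulePartition}.
#' @return an \linkS4class{EigengeneSet}.
#' @export
moduleEigengenes <- function(resid, partition) {
    x <- .exprMatrix(resid)
    lab <- moduleLabels(partition)
    if (!all(rownames(x) %in% names(lab)))
        stop("partition does not cover all probes")
    lab <- lab[rownames(x)]
    mods <- names(moduleSizes(partition))
    if (!length(mods)) stop("no non-gray modules in the partition")
    eg <- matrix(NA_real_, nrow = ncol(x), ncol = length(mods),
                 dimnames = list(colnames(x), mods))
    ve <- setNames(numeric(length(mods)), mods)
    for (m in mods) {
        xm <- x[lab == m, , drop = FALSE]
        sds <- apply(xm, 1, sd)
        if (all(sds == 0))
            stop("module '", m, "' has only constant probes")
        if (any(sds == 0))
            xm <- xm[sds > 0, , drop = FALSE]
        xs <- t(scale(t(xm)))
        if (nrow(xs) == 1) {
            e <- drop(xs)
            ve[m] <- 1
        } else {
            sv <- svd(xs)
            e <- sv$v[, 1]
            ve[m] <- sv$d[1]^2 / sum(sv$d^2)
        }
        if (mean(cor(e, t(xs))) < 0) e <- -e
        eg[, m] <- e / sd(e)
    }
    new("EigengeneSet", eigengenes = eg, varExplained = ve)
}

#' Module-trait correlation with permutation FDR
#'
#' Correlates each module eigengene with each phenotype (Pearson by
#' default) and estimates a false discovery rate by permuting the trait
#' values across samples. The same permutation is applied jointly to all
#' modules so their correlation structure is preserved. At each observed
#' p-value t the FDR is the plug-in ratio of the mean number of null
#' p-values <= t per permutation to the observed number of p-values <= t,
#' capped at 1 and smoothed to be monotone non-decreasing in t. A module is
#' associated when p <= \code{pMax} and fdr <= \code{fdrMax}.
#'
#' @param eig an \linkS4class{EigengeneSet}.
#' @param pheno data.frame of phenotypes (samples in eigengene row order).
#' @param traits phenotype columns to test (default: all numeric columns).
#' @param nPerm number of trait permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param pMax,fdrMax gates for the associated flag.
#' @return data.frame per module x trait: \code{r}, \code{p}, \code{fdr},
#'   \code{associated}.
#' @export
moduleTraitCorrelation <- function(eig, pheno, traits = NULL,
                                   nPerm = 1000, seed = 1,
                                   method = c("pearson", "spearman"),
                                   pMax = 0.05, fdrMax = 0.05) {
    method <- match.arg(method)
    stopifnot(nPerm >= 100)
    eg <- eigengenes(eig)
    if (is.null(traits))
        traits <- names(pheno)[vapply(pheno, is.numeric, TRUE)]
    n <- nrow(eg)
    if (n < 5) stop("at least 5 paired observations required")
    if (nrow(pheno) != n)
        stop("phenotype rows must match eigengene samples")
    corP <- function(e, y) {
        ok <- is.finite(e) & is.finite(y)
        m <- sum(ok)
        if (m < 5 || sd(y[ok]) == 0 || sd(e[ok]) == 0)
            return(c(NA_real_, NA_real_))
        if (method == "spearman") {
            e <- rank(e[ok]); y <- rank(y[ok])
        } else {
            e <- e[ok]; y <- y[ok]
        }
        r <- cor(e, y)
        tt <- r * sqrt((m - 2) / max(1 - r^2, 1e-15))
        c(r, 2 * pt(-abs(tt), m - 2))
    }
    out <- do.call(rbind, lapply(traits, function(tr) {
        y <- as.numeric(pheno[[tr]])
        est <- t(apply(eg, 2, corP, y = y))
        data.frame(module = colnames(eg), trait = tr,
                   r = est[, 1], p = est[, 2],
                   fdr = NA_real_, associated = FALSE)
    }))
    set.seed(as.integer(seed))
    nullP <- matrix(NA_real_, nrow = nPerm, ncol = nrow(out))
    for (b in seq_len(nPerm)) {
        idx <- sample.int(n)
        col <- 1L
        for (tr in traits) {
            y <- as.numeric(pheno[[tr]])[idx]
            for (m in seq_len(ncol(eg))) {
                nullP[b, col] <- corP(eg[, m], y)[2]
                col <- col + 1L
            }
        }
    }
    obs <- out$p
    ok <- which(!is.na(obs))
    if (length(ok)) {
        nullOK <- nullP[, ok, drop = FALSE]
        fdrAt <- vapply(obs[ok], function(t) {
            ## add-one convention: a finite permutation sample can bound
            ## the expected null count away from zero but never certify it
            exp0 <- (1 + sum(nullOK <= t, na.rm = TRUE)) / nPerm
            min(1, exp0 / max(1, sum(obs[ok] <= t)))
        }, numeric(1))
        ## enforce monotonicity in the observed p threshold
        ord <- order(obs[ok])
        sm <- fdrAt[ord]
        if (length(sm) > 1)
            for (i in rev(seq_along(sm))[-1]) sm[i] <- min(sm[i], sm[i + 1])
        fdrAt[ord] <- sm
        out$fdr[ok] <- fdrAt
    }
    out$associated <- !is.na(out$p) & out$p <= pMax &
        !is.na(out$fdr) & out$fdr <= fdrMax
    rownames(out) <- NULL
    out
}
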