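## Coerce a SummarizedExperiment or matrix to a plain probes x samples matrix
.exprMatrix <- function(x, assay = "exprs") {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, assay)
    if (!is.matrix(x)) x <- as.matrix(x)
    if (is.null(rownames(x)))
        rownames(x) <- sprintf("probe_%04d", seq_len(nrow(x)))
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("S%03d", seq_len(ncol(x)))
    storage.mode(x) <- "double"
    x
}

.covariateFrame <- function(x, cov = NULL) {
    if (is.null(cov) && is(x, "SummarizedExperiment"))
        cov <- as.data.frame(SummarizedExperiment::colData(x))
    if (is.null(cov))
        stop("covariates required: pass 'cov' or a SummarizedExperiment")
    cov
}

#' Filter probes on detection p-values
#'
#' Retains the probes called detected (detection p below \code{pMax}) in at
#' least a fraction \code{sampleFrac} of samples; the defaults implement
#' the usual array rule of p <= 0.01 in 90\% of samples. Probe order is
#' preserved.
#'
#' @param expr probes x samples expression matrix or SummarizedExperiment.
#' @param detectionP matrix of detection p-values aligned with \code{expr};
#'   defaults to the \code{"detectionP"} assay when \code{expr} is a
#'   SummarizedExperiment.
#' @param pMax detection p-value cutoff.
#' @param sampleFrac required fraction of samples (0 < sampleFrac <= 1).
#' @return the filtered object, same class as \code{expr}.
#' @export
filterProbes <- function(expr, detectionP = NULL, pMax = 0.01,
                         sampleFrac = 0.9) {
    stopifnot(sampleFrac > 0, sampleFrac <= 1)
    if (is.null(detectionP)) {
        if (!is(expr, "SummarizedExperiment"))
            stop("detectionP required when expr is a plain matrix")
        detectionP <- SummarizedExperiment::assay(expr, "detectionP")
    }
    x <- .exprMatrix(expr)
    detectionP <- as.matrix(detectionP)
    if (!identical(dim(x), dim(detectionP)))
        stop("detectionP dimensions do not match the expression matrix")
    keep <- rowMeans(detectionP <= pMax) >= sampleFrac
    if (is(expr, "SummarizedExperiment")) expr[keep, ]
    else x[keep, , drop = FALSE]
}

#' Remove covariate effects by linear regression
#'
#' Replaces each probe's values by the ordinary-least-squares residuals of
#' expression ~ age + sex. Covariate columns that are constant across
#' samples are dropped (they are absorbed by the intercept); if the design
#' is rank deficient after the drop, the collinear columns are named in the
#' error. Residuals are exactly orthogonal to the retained covariates, and
#' the operation is idempotent.
#'
#' @param expr probes x samples matrix or SummarizedExperiment.
#' @param cov data.frame with columns \code{age} and \code{sex} (rows in
#'   sample order); taken from \code{colData} when \code{expr} is a
#'   SummarizedExperiment.
#' @return object of the same class with residual expression; for a
#'   SummarizedExperiment the \code{"exprs"} assay is replaced and a
#'   \code{scaleTag} of \code{"residual"} recorded in the metadata.
#' @export
adjustCovariates <- function(expr, cov = NULL) {
    cov <- .covariateFrame(expr, cov)
    x <- .exprMatrix(expr)
    if (nrow(cov) != ncol(x))
        stop("covariate rows must match expression samples")
    design <- cbind(`(Intercept)` = 1,
                    age = as.numeric(cov$age),
                    sex = as.numeric(factor(cov$sex)) - 1)
    keep <- c(TRUE, apply(design[, -1, drop = FALSE], 2,
                          function(v) var(v) > 0))
    design <- design[, keep, drop = FALSE]
    qd <- qr(design)
    if (qd$rank < ncol(design)) {
        bad <- colnames(design)[qd$pivot[(qd$rank + 1):ncol(design)]]
        stop("collinear covariate columns: ", paste(bad, collapse = ", "))
    }
    res <- t(qr.resid(qd, t(x)))
    dimnames(res) <- dimnames(x)
    if (is(expr, "SummarizedExperiment")) {
        SummarizedExperiment::assay(expr, "exprs") <- res
        S4Vectors::metadata(expr)$scaleTag <- "residual"
        expr
    } else res
}

#' Two-group differential expression
#'
#' Tests each probe for a mean difference between cohorts with a two-sided
#' two-sample t-test on the covariate-adjusted residuals (pooled variance
#' by default, Welch via \code{varEqual = FALSE}), and computes the fold
#' change as the ratio of group means on the intensity scale (cohort B over
#' cohort A). A probe is significant when the fold change passes the
#' reciprocal gate (>= \code{fcMin} or <= 1/\code{fcMin}) and p <=
#' \code{pMax}.
#'
#' @param intensityA,intensityB probes x samples intensity matrices (or
#'   SummarizedExperiments; assay \code{"intensity"}).
#' @param residA,residB matching residual matrices used for the test
#'   (assay \code{"exprs"}); default to the intensity inputs' residual
#'   assay when SummarizedExperiments are given.
#' @param fcMin fold-change gate (default 1.2).
#' @param pMax p-value gate (default 0.05).
#' @param varEqual pooled-variance Student test (default) or Welch.
#' @return data.frame per probe: \code{foldChange}, \code{t}, \code{df},
#'   \code{p}, \code{direction} (up/down in B), \code{significant}.
#' @export
differentialExpression <- function(intensityA, intensityB,
                                   residA = NULL, residB = NULL,
                                   fcMin = 1.2, pMax = 0.05,
                                   varEqual = TRUE) {
    if (is.null(residA) && is(intensityA, "SummarizedExperiment"))
        residA <- .exprMatrix(intensityA, "exprs")
    if (is.null(residB) && is(intensityB, "SummarizedExperiment"))
        residB <- .exprMatrix(intensityB, "exprs")
    ia <- .exprMatrix(intensityA, "intensity")
    ib <- .exprMatrix(intensityB, "intensity")
    ra <- .exprMatrix(residA)
    rb <- .exprMatrix(residB)
    if (!identical(rownames(ia), rownames(ib)) ||
        !identical(rownames(ia), rownames(ra)) ||
        !identical(rownames(ia), rownames(rb)))
        stop("probe sets must be identical across inputs")
    nA <- ncol(ra); nB <- ncol(rb)
    if (nA < 2 || nB < 2) stop("each group needs >= 2 samples")
    mA <- rowMeans(ia); mB <- rowMeans(ib)
    if (any(mA <= 0) || any(mB <= 0))
        stop("fold change undefined: non-positive group mean intensity")
    fc <- mB / mA
    dA <- rowMeans(ra); dB <- rowMeans(rb)
    vA <- apply(ra, 1, var); vB <- apply(rb, 1, var)
    if (varEqual) {
        sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
        se <- sqrt(sp2 * (1 / nA + 1 / nB))
        df <- rep(nA + nB - 2, length(se))
    } else {
        se <- sqrt(vA / nA + vB / nB)
        df <- (vA / nA + vB / nB)^2 /
            ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    }
    tt <- ifelse(se > 0, (dB - dA) / se, 0)
    p <- ifelse(se > 0, 2 * pt(-abs(tt), df), 1)
    data.frame(
        probe = rownames(ia),
        foldChange = fc,
        t = tt,
        df = df,
        p = p,
        direction = ifelse(fc >= 1, "up", "down"),
        significant = (fc >= fcMin | fc <= 1 / fcMin) & p <= pMax,
        row.names = rownames(ia))
}

## Exhaustive two-sided permutation p-value for Spearman's rho (small n)
.spearmanExactP <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(cor(rx, ry))
    perms <- .permutations(n)
    rhos <- abs(apply(perms, 1, function(idx) cor(rx, ry[idx])))
    mean(rhos >= obs - 1e-12)
}

## All permutations of 1..n as a matrix (n! rows); n <= 9
.permutations <- function(n) {
    if (n == 1) return(matrix(1L, 1, 1))
    sub <- .permutations(n - 1L)
    out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
    r <- 0L
    for (k in seq_len(n)) {
        block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
        out[r + seq_len(nrow(sub)), ] <- block
        r <- r + nrow(sub)
    }
    out
}

#' Spearman correlation of each probe with a trait
#'
#' Screens every probe against one phenotype with Spearman's rank
#' correlation (mid-ranks for ties), using pairwise-complete observations.
#' Two-sided p-values come from the exhaustive permutation distribution for
#' n <= 9 paired observations and from the t-approximation otherwise;
#' Benjamini-Hochberg q-values are computed across probes and a probe is
#' flagged associated when q <= \code{qMax}. Constant probes (or a constant
#' trait) yield NA and are excluded from the FDR ranking.
#'
#' @param resid probes x samples residual matrix or SummarizedExperiment.
#' @param pheno data.frame of phenotypes, or NULL to use \code{colData}.
#' @param trait name of the phenotype column to screen.
#' @param qMax FDR gate for the associated flag.
#' @return data.frame per probe: \code{rho}, \code{p}, \code{q},
#'   \code{n}, \code{associated}.
#' @export
traitCorrelation <- function(resid, pheno = NULL, trait = "S_I",
                             qMax = 0.05) {
    pheno <- .covariateFrame(resid, pheno)
    x <- .exprMatrix(resid)
    if (!trait %in% names(pheno)) stop("unknown trait: ", trait)
    tv <- as.numeric(pheno[[trait]])
    if (length(tv) != ncol(x))
        stop("phenotype rows must match expression samples")
    out <- data.frame(probe = rownames(x), rho = NA_real_, p = NA_real_,
                      q = NA_real_, n = NA_integer_, associated = FALSE,
                      row.names = rownames(x))
    for (g in seq_len(nrow(x))) {
        ok <- is.finite(x[g, ]) & is.finite(tv)
        xs <- x[g, ok]; ys <- tv[ok]
        n <- length(xs)
        out$n[g] <- n
        if (n < 4 || sd(xs) == 0 || sd(ys) == 0) next
        rho <- cor(rank(xs), rank(ys))
        out$rho[g] <- rho
        if (n <= 9) {
            out$p[g] <- .spearmanExactP(xs, ys)
        } else {
            tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
            out$p[g] <- 2 * pt(-abs(tt), n - 2)
        }
    }
    out$q <- bhFDR(out$p)
    out$associated <- !is.na(out$q) & out$q <= qMax
    out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; NAs are excluded from the
#' ranking and returned as NA.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same length and order as \code{p}.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p) {
    if (!length(p)) return(numeric(0))
    stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
    p.adjust(p, method = "BH")
}

#' Joint covariate adjustment of two cohorts
#'
#' Fits the covariate regression once across the pooled samples of both
#' cohorts and returns each cohort's residuals. Between-cohort mean
#' differences survive this adjustment (unlike adjusting each cohort
#' separately, which centres both groups), so these residuals are the
#' right input for between-cohort differential expression.
#'
#' @param exprA,exprB probes x samples matrices or SummarizedExperiments
#'   with identical probe sets and disjoint sample IDs.
#' @param covA,covB covariate tables; taken from \code{colData} when the
#'   inputs are SummarizedExperiments.
#' @return list with residual objects \code{A} and \code{B}, same classes
#'   as the inputs.
#' @export
adjustCovariatesJoint <- function(exprA, exprB, covA = NULL, covB = NULL) {
    covA <- .covariateFrame(exprA, covA)
    covB <- .covariateFrame(exprB, covB)
    xa <- .exprMatrix(exprA)
    xb <- .exprMatrix(exprB)
    if (!identical(rownames(xa), rownames(xb)))
        stop("probe sets must be identical across cohorts")
    merged <- cbind(xa, xb)
    cov <- data.frame(age = c(covA$age, covB$age),
                      sex = c(as.character(covA$sex),
                              as.character(covB$sex)))
    res <- adjustCovariates(merged, cov)
    ra <- res[, seq_len(ncol(xa)), drop = FALSE]
    rb <- res[, ncol(xa) + seq_len(ncol(xb)), drop = FALSE]
    wrap <- function(se, r) {
        if (is(se, "SummarizedExperiment")) {
            SummarizedExperiment::assay(se, "exprs") <- r
            S4Vectors::metadata(se)$scaleTag <- "residual"
            se
        } else r
    }
    list(A = wrap(exprA, ra), B = wrap(exprB, rb))
}
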