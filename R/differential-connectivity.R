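## Per-module sum of pairwise connectivity within one cohort.
## measure: unsigned power adjacency (default), |r|, or TOM.
.moduleConnectivitySum <- function(x, members, beta,
                                   measure = c("adjacency", "correlation",
                                               "tom")) {
    measure <- match.arg(measure)
    r <- cor(t(x[members, , drop = FALSE]))
    w <- switch(measure,
        adjacency = abs(r)^beta,
        correlation = abs(r),
        tom = {
            a <- abs(r)^beta
            diag(a) <- 1
            tomSimilarity(a)
        })
    diag(w) <- 0
    sum(w) / 2
}

#' Modular differential connectivity between two cohorts
#'
#' For each module, the ratio of the summed pairwise connectivity of its
#' gene pairs in cohort A to that of the same pairs in cohort B, with
#' connectivity measured as the unsigned power adjacency |r|^beta computed
#' within each cohort (|r| or TOM via \code{measure}). MDC > 1 is a gain of
#' co-regulation in cohort A relative to B, MDC < 1 a loss. Modules with
#' fewer than 3 members are skipped.
#'
#' @param residA,residB probes x samples residual matrices or
#'   SummarizedExperiments for the two cohorts.
#' @param partition a \linkS4class{ModulePartition} (typically derived from
#'   cohort A).
#' @param beta soft-threshold power used for the networks.
#' @param measure pairwise connectivity measure.
#' @return named numeric vector of MDC values, one per module.
#' @export
modularDifferentialConnectivity <- function(residA, residB, partition,
                                            beta = 5,
                                            measure = "adjacency") {
    xa <- .exprMatrix(residA)
    xb <- .exprMatrix(residB)
    members <- moduleMembers(partition)
    members <- members[vapply(members, length, 1L) >= 3]
    vapply(members, function(g) {
        if (!all(g %in% rownames(xa)) || !all(g %in% rownames(xb)))
            stop("both cohorts must contain all module probes")
        num <- .moduleConnectivitySum(xa, g, beta, measure)
        den <- .moduleConnectivitySum(xb, g, beta, measure)
        if (den == 0) {
            warning("zero connectivity in cohort B; MDC undefined")
            return(NA_real_)
        }
        num / den
    }, numeric(1))
}

#' MDC with the dual-permutation FDR
#'
#' Assesses each module's differential connectivity against two nulls: (1)
#' shuffled samples - cohort membership of the pooled samples is permuted
#' and both module connectivities recomputed (networks with non-random
#' nodes but random connections); (2) shuffled gene labels - module
#' memberships are reassigned randomly among probes, preserving module
#' sizes (networks with random nodes but non-random connections). Under
#' each null the per-module FDR at the observed statistic |log MDC| is the
#' plug-in ratio of expected null exceedances to observed exceedances
#' across modules, capped at 1; the final FDR is the larger of the two
#' estimates. Calls: gain when MDC > 1 and final FDR <= \code{fdrCutoff},
#' loss when MDC < 1 and final FDR <= \code{fdrCutoff}, none otherwise.
#'
#' @param residA,residB cohort residual matrices or SummarizedExperiments.
#' @param partition a \linkS4class{ModulePartition}.
#' @param beta soft-threshold power.
#' @param nPerm permutations per null (>= 50).
#' @param seed RNG seed.
#' @param fdrCutoff call threshold on the final FDR.
#' @param measure pairwise connectivity measure (see
#'   \code{\link{modularDifferentialConnectivity}}).
#' @return data.frame per module: \code{size}, \code{mdc},
#'   \code{fdrShuffledSamples}, \code{fdrShuffledLabels},
#'   \code{fdrFinal}, \code{call}.
#' @export
mdcPermutationFDR <- function(residA, residB, partition, beta = 5,
                              nPerm = 100, seed = 1, fdrCutoff = 0.2,
                              measure = "adjacency") {
    stopifnot(nPerm >= 50)
    xa <- .exprMatrix(residA)
    xb <- .exprMatrix(residB)
    members <- moduleMembers(partition)
    members <- members[vapply(members, length, 1L) >= 3]
    if (!length(members)) stop("no modules of size >= 3")
    mods <- names(members)
    obs <- modularDifferentialConnectivity(residA, residB, partition,
                                           beta, measure)[mods]
    stat <- abs(log(obs))

    set.seed(as.integer(seed))
    nA <- ncol(xa)
    pooled <- cbind(xa, xb)
    nTot <- ncol(pooled)
    allProbes <- rownames(xa)

    mdcFor <- function(a, b, memb) {
        vapply(memb, function(g) {
            num <- .moduleConnectivitySum(a, g, beta, measure)
            den <- .moduleConnectivitySum(b, g, beta, measure)
            if (den == 0) NA_real_ else num / den
        }, numeric(1))
    }

    nullS <- matrix(NA_real_, nPerm, length(mods))
    nullG <- matrix(NA_real_, nPerm, length(mods))
    for (b in seq_len(nPerm)) {
        idx <- sample.int(nTot)
        pa <- pooled[, idx[seq_len(nA)], drop = FALSE]
        pb <- pooled[, idx[(nA + 1):nTot], drop = FALSE]
        nullS[b, ] <- abs(log(mdcFor(pa, pb, members)))
        permProbes <- sample(allProbes)
        shuffled <- members
        at <- 1L
        for (i in seq_along(shuffled)) {
            len <- length(shuffled[[i]])
            shuffled[[i]] <- permProbes[at:(at + len - 1L)]
            at <- at + len
        }
        nullG[b, ] <- abs(log(mdcFor(xa, xb, shuffled)))
    }

    plugInFDR <- function(nullMat) {
        vapply(stat, function(t) {
            if (is.na(t)) return(NA_real_)
            ## add-one convention, as in the module-trait permutation FDR
            exp0 <- (1 + sum(nullMat >= t, na.rm = TRUE)) / nPerm
            min(1, exp0 / max(1, sum(stat >= t, na.rm = TRUE)))
        }, numeric(1))
    }
    fdrS <- plugInFDR(nullS)
    fdrG <- plugInFDR(nullG)
    fdrFinal <- pmax(fdrS, fdrG)
    call <- rep("none", length(mods))
    call[!is.na(obs) & obs > 1 & fdrFinal <= fdrCutoff] <- "gain"
    call[!is.na(obs) & obs < 1 & fdrFinal <= fdrCutoff] <- "loss"
    data.frame(
        module = mods,
        size = vapply(members, length, 1L),
        mdc = unname(obs),
        fdrShuffledSamples = fdrS,
        fdrShuffledLabels = fdrG,
        fdrFinal = fdrFinal,
        call = call,
        row.names = mods)
}
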