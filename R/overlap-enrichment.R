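## Hypergeometric upper-tail P(X >= k) for overlap k between sets of sizes
## sA and sB drawn from a universe of N, evaluated in log space so that
## extreme significance (p ~ 1e-300) stays representable.
.hyperUpperTail <- function(k, sA, sB, N) {
    if (k <= 0) return(list(p = 1, log10p = 0))
    lp <- phyper(k - 1, sA, N - sA, sB, lower.tail = FALSE, log.p = TRUE)
    list(p = exp(lp), log10p = lp / log(10))
}

#' Cross-network module overlap by Fisher's exact test
#'
#' For every pair of (non-gray) modules from two partitions defined on a
#' shared probe universe, tests over-representation of the member overlap
#' with the one-sided hypergeometric upper tail, computed in log space. A
#' pair is significant when its p-value is at or below the Bonferroni
#' threshold alpha / (m_A * m_B).
#'
#' @param partA,partB \linkS4class{ModulePartition}s (or named label
#'   vectors) on the same universe.
#' @param universe probe universe; defaults to the union of labelled
#'   probes. May be given as a count for convenience.
#' @param alpha family-wise error target for the Bonferroni threshold.
#' @return data.frame per module pair: \code{moduleA}, \code{moduleB},
#'   \code{overlap}, \code{sizeA}, \code{sizeB}, \code{universeN},
#'   \code{fetP}, \code{log10P}, \code{bonferroniThreshold},
#'   \code{significant}.
#' @export
moduleOverlap <- function(partA, partB, universe = NULL, alpha = 0.05) {
    la <- if (is(partA, "ModulePartition")) moduleLabels(partA) else partA
    lb <- if (is(partB, "ModulePartition")) moduleLabels(partB) else partB
    if (is.null(universe)) universe <- union(names(la), names(lb))
    N <- if (is.numeric(universe) && length(universe) == 1) {
        as.integer(universe)
    } else length(universe)
    setsA <- split(names(la), la)
    setsA <- setsA[setdiff(names(setsA), "gray")]
    setsB <- split(names(lb), lb)
    setsB <- setsB[setdiff(names(setsB), "gray")]
    if (!length(setsA) || !length(setsB))
        stop("both partitions need at least one non-gray module")
    if (max(vapply(c(setsA, setsB), length, 1L)) > N)
        stop("universe smaller than a module")
    thr <- alpha / (length(setsA) * length(setsB))
    rows <- list()
    for (a in names(setsA)) for (b in names(setsB)) {
        k <- length(intersect(setsA[[a]], setsB[[b]]))
        ht <- .hyperUpperTail(k, length(setsA[[a]]), length(setsB[[b]]), N)
        rows[[length(rows) + 1L]] <- data.frame(
            moduleA = a, moduleB = b, overlap = k,
            sizeA = length(setsA[[a]]), sizeB = length(setsB[[b]]),
            universeN = N, fetP = ht$p, log10P = ht$log10p,
            bonferroniThreshold = thr,
            significant = ht$p <= thr)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Hypergeometric overlap p-value
#'
#' One-sided upper-tail p-value for an overlap of \code{k} members between
#' sets of sizes \code{sizeA} and \code{sizeB} in a universe of
#' \code{universeN}; log-space evaluation.
#'
#' @param k observed overlap.
#' @param sizeA,sizeB set sizes.
#' @param universeN universe size.
#' @return list with \code{p} and \code{log10p}.
#' @examples
#' overlapTestP(57, 441, 268, 17434)$p
#' @export
overlapTestP <- function(k, sizeA, sizeB, universeN) {
    stopifnot(k <= min(sizeA, sizeB), sizeA <= universeN,
              sizeB <= universeN)
    .hyperUpperTail(k, sizeA, sizeB, universeN)
}

#' Gene-signature enrichment of modules
#'
#' Tests each module for over-representation of each signature gene set by
#' the one-sided hypergeometric upper tail, with Bonferroni correction over
#' all modules x signatures tested. Signature members outside the universe
#' are trimmed with a warning.
#'
#' @param partition a \linkS4class{ModulePartition} or named label vector.
#' @param signatures named list of probe sets.
#' @param universe probe universe (default: the partition's probes).
#' @return data.frame per module x signature: \code{overlap},
#'   \code{moduleSize}, \code{signatureSize}, \code{fetP}, \code{log10P},
#'   \code{correctedP}.
#' @export
signatureEnrichment <- function(partition, signatures, universe = NULL) {
    lab <- if (is(partition, "ModulePartition")) moduleLabels(partition)
           else partition
    if (is.null(universe)) universe <- names(lab)
    N <- length(universe)
    mods <- split(names(lab), lab)
    mods <- mods[setdiff(names(mods), "gray")]
    trimmed <- lapply(signatures, intersect, universe)
    dropped <- sum(vapply(signatures, length, 1L)) -
        sum(vapply(trimmed, length, 1L))
    if (dropped > 0)
        warning(dropped, " signature members outside the universe trimmed")
    nTests <- length(mods) * length(trimmed)
    rows <- list()
    for (m in names(mods)) for (s in names(trimmed)) {
        sig <- trimmed[[s]]
        if (!length(sig)) {
            rows[[length(rows) + 1L]] <- data.frame(
                module = m, signature = s, overlap = NA_integer_,
                moduleSize = length(mods[[m]]), signatureSize = 0L,
                fetP = NA_real_, log10P = NA_real_,
                correctedP = NA_real_)
            next
        }
        k <- length(intersect(mods[[m]], sig))
        ht <- .hyperUpperTail(k, length(mods[[m]]), length(sig), N)
        rows[[length(rows) + 1L]] <- data.frame(
            module = m, signature = s, overlap = k,
            moduleSize = length(mods[[m]]), signatureSize = length(sig),
            fetP = ht$p, log10P = ht$log10p,
            correctedP = min(1, ht$p * nTests))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Classify modules as conserved or cohort-specific
#'
#' Applies the conservation rule to one focal partition (cohort A): a
#' module is \emph{conserved} when it has a cross-network partner at or
#' below the Bonferroni overlap threshold \emph{and} is enriched
#' (corrected p <= \code{enrichAlpha}) for the trait-associated gene
#' signatures of both cohorts; \emph{specific} when enriched for exactly
#' one cohort's signature; \emph{neither} otherwise. A specific module
#' without any significant partner is additionally flagged highly
#' specific.
#'
#' @param overlaps output of \code{\link{moduleOverlap}} with the focal
#'   cohort as \code{moduleA}.
#' @param enrichA,enrichB outputs of \code{\link{signatureEnrichment}} of
#'   the focal partition against each cohort's trait-associated gene
#'   signatures.
#' @param enrichAlpha corrected-p gate for signature enrichment.
#' @return data.frame per module: \code{status}, \code{highlySpecific},
#'   \code{bestPartner}, \code{bestPartnerP}, \code{enrichedA},
#'   \code{enrichedB}.
#' @export
classifyConservation <- function(overlaps, enrichA, enrichB,
                                 enrichAlpha = 0.05) {
    mods <- unique(overlaps$moduleA)
    enrFlag <- function(enr, m) {
        rows <- enr[enr$module == m, , drop = FALSE]
        if (!nrow(rows))
            stop("missing enrichment rows for module '", m, "'")
        any(!is.na(rows$correctedP) & rows$correctedP <= enrichAlpha)
    }
    out <- do.call(rbind, lapply(mods, function(m) {
        sub <- overlaps[overlaps$moduleA == m, , drop = FALSE]
        best <- sub[which.min(sub$fetP), , drop = FALSE]
        hasPartner <- any(sub$significant)
        eA <- enrFlag(enrichA, m)
        eB <- enrFlag(enrichB, m)
        status <- if (hasPartner && eA && eB) "conserved"
            else if (xor(eA, eB)) "specific"
            else "neither"
        data.frame(module = m, status = status,
                   highlySpecific = status == "specific" && !hasPartner,
                   bestPartner = best$moduleB, bestPartnerP = best$fetP,
                   enrichedA = eA, enrichedB = eB)
    }))
    rownames(out) <- NULL
    out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: one set per line, name, description, then
#' members.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- lapply(lines, function(l) {
        parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
        if (length(parts) < 3)
            stop("malformed GMT line: ", substr(l, 1, 40))
        parts[-(1:2)]
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
    sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set description (recycled).
#' @return invisibly, \code{path}.
#' @export
writeGMT <- function(sets, path, description = "na") {
    description <- rep_len(description, length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], description[i], sets[[i]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
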