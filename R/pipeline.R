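#' Default pipeline parameters
#'
#' Network and testing parameters used throughout the pipeline: power
#' beta = 5, dendrogram cut 0.99 with minimum module size 10, 1.2-fold /
#' p <= 0.05 differential expression, FDR 0.05 screens, 100-permutation
#' FDRs, 2-hop key-driver neighbourhoods with DPI tolerance 0.15.
#'
#' @return named list of parameters.
#' @export
defaultPipelineParams <- function() {
    list(beta = 5, hierCutoff = 0.99, minModuleSize = 10,
         fcMin = 1.2, pMax = 0.05, qMax = 0.05,
         nPerm = 100, mdcFdrCutoff = 0.2,
         hops = 2, dpiTolerance = 0.15, miPMax = 0.05, nPermMI = 100,
         alpha = 0.05, trait = "S_I", seed = 1)
}

## md5 of every file in a named character vector of paths
.hashFiles <- function(paths) {
    h <- tools::md5sum(paths)
    setNames(as.vector(h), basename(paths))
}

#' Run the full two-cohort network analysis
#'
#' Orchestrates the stages end to end on in-memory cohorts: covariate
#' adjustment, differential expression, per-probe trait correlation,
#' network construction and module detection per cohort, module eigengenes
#' and module-trait statistics, modular differential connectivity of the
#' cohort-A modules, cross-network overlap, trait-gene signature
#' enrichment with conservation calls, and key-driver analysis of the
#' largest cohort-A modules. All results are written to \code{outDir} as
#' tab-delimited tables with a parameter comment header, together with a
#' JSON manifest (inputs hashed, parameters, seed, stage outputs,
#' package version). A rerun with the same inputs and seed reproduces the
#' outputs bit-identically.
#'
#' @param cohortA,cohortB \link[SummarizedExperiment]{SummarizedExperiment}
#'   objects as produced by \code{\link{generateCohorts}} (assays
#'   \code{exprs}, \code{intensity}; covariates and phenotypes in
#'   \code{colData}).
#' @param outDir output directory.
#' @param params parameter list; see \code{\link{defaultPipelineParams}}.
#'   Partial lists are merged over the defaults.
#' @param kdaModules how many of the largest cohort-A modules to run
#'   key-driver analysis on.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(cohortA, cohortB, outDir,
                        params = list(), kdaModules = 2) {
    p <- utils::modifyList(defaultPipelineParams(), params)
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    stamp <- sprintf("seed=%d beta=%g hierCutoff=%g minModuleSize=%d",
                     p$seed, p$beta, p$hierCutoff, p$minModuleSize)
    files <- character(0)
    put <- function(df, name) {
        f <- file.path(outDir, name)
        writeResultTable(df, f, comments = stamp)
        files <<- c(files, f)
        f
    }
    stages <- character(0)

    ## 1. preprocess: one covariate regression across the pooled samples,
    ## so between-cohort differences survive into the residuals
    adj <- adjustCovariatesJoint(cohortA, cohortB)
    resA <- adj$A
    resB <- adj$B
    de <- differentialExpression(cohortA, cohortB,
                                 .exprMatrix(resA), .exprMatrix(resB),
                                 fcMin = p$fcMin, pMax = p$pMax)
    put(de, "differential_expression.tsv")
    tcA <- traitCorrelation(resA, trait = p$trait, qMax = p$qMax)
    tcB <- traitCorrelation(resB, trait = p$trait, qMax = p$qMax)
    put(tcA, "trait_correlation_A.tsv")
    put(tcB, "trait_correlation_B.tsv")
    stages <- c(stages, "preprocess")

    ## 2. coexpression per cohort
    netA <- buildCoexpressionNetwork(resA, beta = p$beta)
    netB <- buildCoexpressionNetwork(resB, beta = p$beta)
    cmA <- clusterModules(netA, p$hierCutoff, p$minModuleSize)
    cmB <- clusterModules(netB, p$hierCutoff, p$minModuleSize)
    writePartition(cmA$partition,
                   file.path(outDir, "modules_A.tsv"), stamp)
    writePartition(cmB$partition,
                   file.path(outDir, "modules_B.tsv"), stamp)
    files <- c(files, file.path(outDir, c("modules_A.tsv",
                                          "modules_B.tsv")))
    connA <- intramodularConnectivity(netA, cmA$partition)
    put(connA$probes, "connectivity_A.tsv")
    stages <- c(stages, "coexpression")

    ## 3. module-trait statistics
    phenoA <- as.data.frame(SummarizedExperiment::colData(cohortA))
    phenoB <- as.data.frame(SummarizedExperiment::colData(cohortB))
    egA <- moduleEigengenes(resA, cmA$partition)
    mtA <- moduleTraitCorrelation(egA, phenoA, traits = p$trait,
                                  nPerm = max(100, p$nPerm),
                                  seed = p$seed)
    put(mtA, "module_trait_A.tsv")
    egB <- moduleEigengenes(resB, cmB$partition)
    mtB <- moduleTraitCorrelation(egB, phenoB, traits = p$trait,
                                  nPerm = max(100, p$nPerm),
                                  seed = p$seed)
    put(mtB, "module_trait_B.tsv")
    stages <- c(stages, "module_trait")

    ## 4. differential connectivity of cohort-A modules
    mdc <- mdcPermutationFDR(resA, resB, cmA$partition, beta = p$beta,
                             nPerm = max(50, p$nPerm), seed = p$seed,
                             fdrCutoff = p$mdcFdrCutoff)
    put(mdc, "mdc.tsv")
    stages <- c(stages, "differential_connectivity")

    ## 5. overlap, enrichment, conservation
    ov <- moduleOverlap(cmA$partition, cmB$partition, alpha = p$alpha)
    put(ov, "module_overlap.tsv")
    sigs <- list(
        trait_genes_A = tcA$probe[tcA$associated],
        trait_genes_B = tcB$probe[tcB$associated])
    universe <- names(moduleLabels(cmA$partition))
    enrA <- signatureEnrichment(cmA$partition, sigs["trait_genes_A"],
                                universe)
    enrB <- signatureEnrichment(cmA$partition, sigs["trait_genes_B"],
                                universe)
    put(enrA, "enrichment_traitA.tsv")
    put(enrB, "enrichment_traitB.tsv")
    cons <- tryCatch(
        classifyConservation(ov, enrA, enrB, enrichAlpha = p$alpha),
        error = function(e) NULL)
    if (!is.null(cons)) put(cons, "conservation.tsv")
    stages <- c(stages, "overlap_enrichment")

    ## 6. key-driver analysis of the largest cohort-A modules
    sz <- moduleSizes(cmA$partition)
    kdaTargets <- head(names(sz)[sz >= 3], kdaModules)
    kd <- list()
    for (m in kdaTargets) {
        net <- buildAracne(resA, moduleMembers(cmA$partition)[[m]],
                           miPMax = p$miPMax, nPermMI = p$nPermMI,
                           dpiTolerance = p$dpiTolerance, seed = p$seed)
        tab <- keyDrivers(net, hops = p$hops)
        tab$module <- m
        kd[[m]] <- tab
    }
    if (length(kd)) put(do.call(rbind, kd), "key_drivers.tsv")
    stages <- c(stages, "aracne_kda")

    manifest <- list(
        package = "conetdiff",
        version = as.character(utils::packageVersion("conetdiff")),
        parameters = p,
        stages = stages,
        outputs = as.list(.hashFiles(files)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
}

#' Read pipeline parameters from a YAML config file
#'
#' Reads a flat key-value YAML file of pipeline parameters (see
#' \code{\link{defaultPipelineParams}} for the recognized keys) and merges
#' it over the defaults; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return named parameter list usable as \code{params} in
#'   \code{\link{runPipeline}}.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    known <- names(defaultPipelineParams())
    bad <- setdiff(names(cfg), known)
    if (length(bad))
        stop("unknown pipeline parameters: ", paste(bad, collapse = ", "))
    utils::modifyList(defaultPipelineParams(), cfg)
}
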