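#' @include AllClasses.R
NULL

#' Combine signal profiles from several libraries
#'
#' Position-wise sum over profile sets sharing one reference universe;
#' used e.g. to pool the two control-library replicates before target
#' validation.
#'
#' @param ... Two or more [SignalProfileSet-class] objects.
#' @param libraryId Identifier for the combined set.
#' @return A [SignalProfileSet-class].
#' @export
combineProfiles <- function(..., libraryId = "combined") {
    sets <- list(...)
    if (length(sets) == 1L && is.list(sets[[1]])) sets <- sets[[1]]
    if (length(sets) < 2L) stop("need >= 2 profile sets")
    ids <- names(profiles(sets[[1]]))
    for (s in sets[-1])
        if (!identical(names(profiles(s)), ids))
            stop("profile sets must share one reference universe")
    prof <- lapply(ids, function(id)
        Reduce(`+`, lapply(sets, function(s) profiles(s)[[id]])))
    names(prof) <- ids
    SignalProfileSet(prof, libraryId = libraryId,
        totalMass = sum(vapply(sets, totalMass, numeric(1))),
        unmatchedTags = sum(vapply(sets, function(s) s@unmatchedTags,
                                   numeric(1))),
        skippedTags = sum(vapply(sets, function(s) s@skippedTags,
                                 numeric(1))))
}

#' Squared Pearson correlation between layer fold changes
#'
#' Correlates the degradation-layer and transcription-layer log2 fold
#' changes over the genes present in both call tables.
#'
#' @param dCalls,rCalls data.frames from [diffCalls()].
#' @return List: `r_squared`, `r`, `n` and `scatter` (data.frame
#'   `gene_id`, `d_log2fc`, `r_log2fc`).
#' @export
jointFCCorrelation <- function(dCalls, rCalls) {
    shared <- intersect(dCalls$gene_id, rCalls$gene_id)
    if (length(shared) < 3L) stop("need >= 3 shared genes")
    d <- dCalls$log2fc[match(shared, dCalls$gene_id)]
    r <- rCalls$log2fc[match(shared, rCalls$gene_id)]
    rho <- stats::cor(d, r)
    list(r_squared = rho ^ 2, r = rho, n = length(shared),
         scatter = data.frame(gene_id = shared, d_log2fc = d,
                              r_log2fc = r))
}

.geneCountsFromProfiles <- function(profileSet, transcripts) {
    ft <- featureTable(transcripts)
    mass <- vapply(profiles(profileSet)[ft$transcript_id], sum, numeric(1))
    v <- rowsum(mass, ft$gene_id)[, 1]
    v[unique(ft$gene_id)]
}

#' Run the full degradome analysis pipeline
#'
#' Orchestrates quantification (tag mapping, profiles, RPM with replicate
#' correlation QC), two-library differential testing on both layers
#' (replicate counts summed per condition), decay classification,
#' sequence features, degradome-validated miRNA target identification
#' (against the pooled control-library profiles), and hairpin processing
#' classification. Any stage can be toggled off.
#'
#' @param transcripts A [TranscriptSet-class].
#' @param pareLibraries Named list of tag sets (`Dc_rep1`, `Dc_rep2`,
#'   `Dd_rep1`, `Dd_rep2`), each a [Biostrings::DNAStringSet].
#' @param rnaseqCounts Gene x library count matrix with control columns
#'   matching `^Rc` and treated columns `^Rd`.
#' @param mirnas Named [Biostrings::DNAStringSet] of mature miRNAs
#'   (needed for the `targets` stage).
#' @param hairpins A [HairpinSet-class] (needed for the `hairpins` stage).
#' @param hairpinTags Tag set mapped onto the hairpins (defaults to the
#'   pooled control libraries).
#' @param stages Character vector of stages to run, a subset of
#'   `c("quantify", "differential", "classify", "features", "targets",
#'   "hairpins")`. Later stages require the earlier ones they consume.
#' @param params List of threshold overrides: `maxMismatch`, `fcThresh`,
#'   `pThresh`, `eps`, `maxScore`, `minReads`, `offsetTolerance`,
#'   `dominance`, `minTotal`, `window`, `computeMfei`, `foldEngine`.
#' @return List with per-stage results (`profiles`, `rpm`, `replicateR2`,
#'   `dCalls`, `rCalls`, `decay`, `typeSummary`, `jointFC`, `features`,
#'   `targets`, `hairpinCalls`) and a `manifest` recording parameters and
#'   per-stage row counts.
#' @examples
#' sim <- simulateExperiment(simConfig(nGenes = 30, nMirnas = 3,
#'     nPlantedTargets = 5, pareDepth = 4000, rnaseqDepth = 2e4,
#'     nHairpins = 6, seed = 11))
#' res <- runPipeline(sim$transcripts, sim$pareLibraries,
#'     sim$rnaseqCounts, sim$mirnas, sim$hairpins, sim$hairpinTags)
#' res$manifest$stages
#' @export
runPipeline <- function(transcripts, pareLibraries, rnaseqCounts,
                        mirnas = NULL, hairpins = NULL, hairpinTags = NULL,
                        stages = c("quantify", "differential", "classify",
                                   "features", "targets", "hairpins"),
                        params = list()) {
    p <- utils::modifyList(list(
        maxMismatch = 1L, fcThresh = 1, pThresh = 0.001, eps = 0.5,
        maxScore = 4, minReads = 2, offsetTolerance = 0L,
        dominance = 2.0, minTotal = 5, window = 1L,
        computeMfei = FALSE, foldEngine = "fallback"), params)
    out <- list()
    manifest <- list(parameters = p, stages = list())
    note <- function(stage, n) manifest$stages[[stage]] <<- n

    if ("quantify" %in% stages) {
        out$profiles <- lapply(names(pareLibraries), function(nm) {
            asg <- mapTags(pareLibraries[[nm]], transcripts,
                           maxMismatch = p$maxMismatch)
            buildProfiles(asg, transcripts, libraryId = nm)
        })
        names(out$profiles) <- names(pareLibraries)
        out$rpm <- lapply(out$profiles, geneRPM, transcripts = transcripts)
        cIdx <- grep("^Dc", names(out$rpm)); tIdx <- grep("^Dd", names(out$rpm))
        mC <- mergeReplicates(out$rpm[cIdx])
        mT <- mergeReplicates(out$rpm[tIdx])
        out$rpmControl <- mC$mean; out$rpmTreated <- mT$mean
        out$replicateR2 <- c(control = mC$r_squared,
                             treated = mT$r_squared)
        note("quantify", length(out$profiles))
    }
    if ("differential" %in% stages) {
        if (is.null(out$profiles))
            stop("stage 'differential' needs stage 'quantify'")
        gc_ <- Reduce(`+`, lapply(out$profiles[grep("^Dc",
            names(out$profiles))], .geneCountsFromProfiles, transcripts))
        gt_ <- Reduce(`+`, lapply(out$profiles[grep("^Dd",
            names(out$profiles))], .geneCountsFromProfiles, transcripts))
        out$dCalls <- diffCalls(gc_, gt_, layer = "D", eps = p$eps,
                                fcThresh = p$fcThresh, pThresh = p$pThresh)
        rc <- rowSums(rnaseqCounts[, grep("^Rc", colnames(rnaseqCounts)),
                                   drop = FALSE])
        rt <- rowSums(rnaseqCounts[, grep("^Rd", colnames(rnaseqCounts)),
                                   drop = FALSE])
        out$rCalls <- diffCalls(rc, rt, layer = "R", eps = p$eps,
                                fcThresh = p$fcThresh, pThresh = p$pThresh)
        out$jointFC <- jointFCCorrelation(out$dCalls, out$rCalls)
        note("differential", nrow(out$dCalls) + nrow(out$rCalls))
    }
    if ("classify" %in% stages) {
        if (is.null(out$dCalls))
            stop("stage 'classify' needs stage 'differential'")
        out$decay <- classifyDecay(out$dCalls, out$rCalls)
        out$typeSummary <- summarizeTypes(out$decay)
        note("classify", sum(!is.na(out$decay$class_letter)))
    }
    if ("features" %in% stages) {
        regions <- if (isTRUE(p$computeMfei)) c("mrna", "utr5", "utr3")
                   else character()
        out$features <- computeFeatures(transcripts,
                                        engine = p$foldEngine,
                                        regions = regions)
        note("features", nrow(out$features))
    }
    if ("targets" %in% stages && !is.null(mirnas)) {
        if (is.null(out$profiles))
            stop("stage 'targets' needs stage 'quantify'")
        dcProf <- combineProfiles(out$profiles[grep("^Dc",
            names(out$profiles))], libraryId = "Dc")
        out$targets <- findTargets(mirnas, transcripts, dcProf,
                                   maxScore = p$maxScore,
                                   minReads = p$minReads,
                                   offsetTolerance = p$offsetTolerance)
        note("targets", nrow(out$targets))
    }
    if ("hairpins" %in% stages && !is.null(hairpins)) {
        tags <- hairpinTags
        if (is.null(tags))
            tags <- do.call(c, unname(
                pareLibraries[grep("^Dc", names(pareLibraries))]))
        hpProf <- profileHairpins(tags, hairpins,
                                  transcripts = transcripts,
                                  libraryId = "hairpins")
        out$hairpinProfiles <- hpProf
        out$hairpinCalls <- classifyHairpins(hpProf, hairpins,
                                             minTotal = p$minTotal,
                                             dominance = p$dominance,
                                             window = p$window)
        note("hairpins", nrow(out$hairpinCalls))
    }
    out$manifest <- manifest
    out
}
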