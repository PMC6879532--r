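## Orchestration: session-level analysis chain, cohort assembly, cohort
## statistics, and the file-based runner with a JSON run report.

#' Pipeline options
#'
#' @param channels channels to carry through spectral analysis (the index
#'   needs only Fz; add channels for full band tables).
#' @param bandpass band-pass edges, Hz.
#' @param notches notch frequencies, Hz.
#' @param thresholds artifact thresholds, see
#'   \code{\link{artifactThresholds}}.
#' @param kaiserBeta Kaiser taper shape.
#' @param relDomain \code{"linear"} or \code{"log10"} relative-PSD domain.
#' @param trim per-tail trimmed-mean fraction for epoch aggregation.
#' @param alpha significance level used throughout the statistics chain.
#' @param mahalanobisP chi-squared tail probability for outlier screening.
#' @param eigenCutoff PCA eigenvalue retention cutoff.
#' @return Named list of options.
#' @export
pipelineOptions <- function(channels = "Fz",
                            bandpass = c(0.5, 65),
                            notches = c(50, 60, 100, 120),
                            thresholds = artifactThresholds(),
                            kaiserBeta = 8,
                            relDomain = "linear",
                            trim = 0.05,
                            alpha = 0.05,
                            mahalanobisP = 0.001,
                            eigenCutoff = 0.80) {
    list(channels = channels, bandpass = bandpass, notches = notches,
         thresholds = thresholds, kaiserBeta = kaiserBeta,
         relDomain = relDomain, trim = trim, alpha = alpha,
         mahalanobisP = mahalanobisP, eigenCutoff = eigenCutoff)
}

#' Analyze one session
#'
#' The per-recording chain: linked-mastoid re-referencing (when mastoids are
#' present and the recording is raw), zero-phase band-pass and notch
#' filtering, artifact detection, zero-insertion decontamination, overlay
#' PSD with rejection rules, band averaging, per-epoch STMLI at Fz, and
#' trimmed-mean aggregation per task.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param markers marker \code{data.frame}.
#' @param participantId,group identifiers for the summaries.
#' @param options see \code{\link{pipelineOptions}}.
#' @return List with \code{summaries} (participant x task rows),
#'   \code{epochs} (per-epoch STMLI), \code{bands} (band table), and
#'   \code{artifacts} (event log).
#' @export
analyzeSession <- function(rec, markers, participantId, group,
                           options = pipelineOptions()) {
    if (referenceType(rec) == "raw" &&
        all(c("M1", "M2") %in% channelLabels(rec)))
        rec <- rereferenceLinkedMastoids(rec)
    need <- setdiff(options$channels, channelLabels(rec))
    if (length(need))
        stop("required channel(s) missing: ", paste(need, collapse = ", "))
    keep <- union(options$channels, character())
    rec <- EEGRecording(samples(rec)[keep, , drop = FALSE],
                        samplingRate(rec), referenceType(rec))
    rec <- bandpassFilter(rec, options$bandpass[1], options$bandpass[2])
    rec <- notchFilter(rec, options$notches)
    mask <- detectArtifacts(rec, options$thresholds)
    rec <- decontaminate(rec, mask)
    bands <- bandTable(rec, markers, channels = options$channels,
                       kaiserBeta = options$kaiserBeta,
                       relDomain = options$relDomain)
    epochs <- stmliFromBands(bands, channel = "Fz")
    summaries <- summarizeStmli(epochs, participantId, group,
                                trim = options$trim)
    list(summaries = summaries, epochs = epochs, bands = bands,
         artifacts = artifactEvents(mask))
}

#' Analyze an in-memory cohort of synthetic sessions
#'
#' @param sessions list of \linkS4class{SyntheticSession}.
#' @param options see \code{\link{pipelineOptions}}.
#' @return A \linkS4class{CohortTable}.
#' @export
analyzeCohort <- function(sessions, options = pipelineOptions()) {
    summaries <- lapply(sessions, function(s)
        analyzeSession(recording(s), markers(s), participantId(s),
                       groupLabel(s), options)$summaries)
    buildCohortTable(do.call(rbind, summaries))
}

#' Cohort-level statistics
#'
#' The full group-comparison chain on a cohort table: listwise-complete
#' rows, Mahalanobis outlier screening, the group x task mixed ANOVA with
#' Mauchly/Greenhouse-Geisser handling, per-task group descriptives with
#' Levene-gated t-test p-values, KMO/Bartlett diagnostics, varimax PCA,
#' Anderson-Rubin scores, and (when exactly two components are retained) the
#' group x component mixed ANOVA.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param options see \code{\link{pipelineOptions}}.
#' @return List with \code{screen}, \code{anova}, \code{taskTable},
#'   \code{kmo}, \code{pca}, \code{scores}, \code{componentAnova} (or NULL),
#'   and \code{exclusions}.
#' @export
cohortStatistics <- function(cohort, options = pipelineOptions()) {
    stopifnot(is(cohort, "CohortTable"))
    mat <- cohortMatrix(cohort)
    groups <- groupLabels(cohort)
    if (length(unique(groups)) < 2L)
        stop("group statistics need two groups; cohort has one")
    complete <- complete.cases(mat)
    exclusions <- list(incomplete = rownames(mat)[!complete])
    mat <- mat[complete, , drop = FALSE]
    groups <- groups[complete]

    screen <- mahalanobisScreen(mat, p = options$mahalanobisP)
    keep <- !rownames(mat) %in% screen$excludedIds
    exclusions$mahalanobis <- screen$excludedIds
    mat <- mat[keep, , drop = FALSE]
    groups <- groups[keep]
    if (length(unique(groups)) < 2L)
        stop("screening left a single group; statistics refused")

    aov2x9 <- mixedAnova(mat, groups, alpha = options$alpha)

    gl <- unique(groups)
    taskTable <- do.call(rbind, lapply(colnames(mat), function(task) {
        g1 <- mat[groups == gl[1], task]
        g2 <- mat[groups == gl[2], task]
        tt <- leveneGatedTTest(g1, g2, alpha = options$alpha)
        data.frame(task = task,
                   M1 = mean(g1), SE1 = sd(g1) / sqrt(length(g1)),
                   M2 = mean(g2), SE2 = sd(g2) / sqrt(length(g2)),
                   p = tt$p, stringsAsFactors = FALSE)
    }))

    kmo <- kmoBartlett(mat)
    pca <- pcaVarimax(mat, eigenCutoff = options$eigenCutoff)
    scores <- andersonRubinScores(mat, pca$loadings)
    compAov <- NULL
    if (pca$nRetained == 2L)
        compAov <- componentMixedAnova(scores, groups,
                                       alpha = options$alpha)
    list(screen = screen, anova = aov2x9, taskTable = taskTable,
         kmo = kmo, pca = pca, scores = scores,
         componentAnova = compAov, exclusions = exclusions,
         groupsUsed = groups)
}

#' Run configuration
#'
#' @param manifest cohort manifest CSV (\code{participant_id}, \code{group},
#'   \code{edf_path}, \code{markers_path}).
#' @param outDir output directory for CSV/JSON artifacts.
#' @param options see \code{\link{pipelineOptions}}.
#' @return Named list.
#' @export
runConfig <- function(manifest, outDir, options = pipelineOptions()) {
    list(manifest = manifest, outDir = outDir, options = options)
}

#' Read a run configuration from YAML
#'
#' Top-level keys \code{manifest} and \code{out_dir}; optional nested keys
#' under \code{preprocess:} (bandpass, notches, thresholds), \code{spectral:}
#' (kaiser_beta, rel_domain, channels) and \code{stats:} (alpha, trim,
#' mahalanobis_p, eigen_cutoff) override the defaults.
#'
#' @param path YAML file.
#' @return A \code{\link{runConfig}} list.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$manifest) || is.null(y$out_dir))
        stop("config needs 'manifest' and 'out_dir'")
    opt <- pipelineOptions()
    pre <- y$preprocess
    if (!is.null(pre$bandpass)) opt$bandpass <- as.numeric(pre$bandpass)
    if (!is.null(pre$notches)) opt$notches <- as.numeric(pre$notches)
    if (!is.null(pre$thresholds))
        opt$thresholds <- utils::modifyList(opt$thresholds, pre$thresholds)
    sp <- y$spectral
    if (!is.null(sp$kaiser_beta)) opt$kaiserBeta <- sp$kaiser_beta
    if (!is.null(sp$rel_domain)) opt$relDomain <- sp$rel_domain
    if (!is.null(sp$channels)) opt$channels <- sp$channels
    st <- y$stats
    if (!is.null(st$alpha)) opt$alpha <- st$alpha
    if (!is.null(st$trim)) opt$trim <- st$trim
    if (!is.null(st$mahalanobis_p)) opt$mahalanobisP <- st$mahalanobis_p
    if (!is.null(st$eigen_cutoff)) opt$eigenCutoff <- st$eigen_cutoff
    runConfig(y$manifest, y$out_dir, opt)
}

#' Run the full pipeline from a cohort manifest
#'
#' Reads every session's EDF and markers, runs the per-session chain,
#' assembles the cohort table, runs the cohort statistics, writes the
#' cohort CSVs and a JSON run report to \code{config$outDir}, and returns
#' the report. Any stage failure aborts with a message naming the stage and
#' the offending file. Deterministic given the config and input files.
#'
#' @param config see \code{\link{runConfig}} / \code{\link{readRunConfig}}.
#' @return The run report (list), invisibly.
#' @export
runPipeline <- function(config) {
    mf <- read.csv(config$manifest, stringsAsFactors = FALSE)
    if (!nrow(mf)) stop("manifest is empty")
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    summaries <- vector("list", nrow(mf))
    artifactCounts <- vector("list", nrow(mf))
    for (i in seq_len(nrow(mf))) {
        rec <- tryCatch(readEDF(mf$edf_path[i]), error = function(e)
            stop("stage 'read_edf' failed for ", mf$edf_path[i], ": ",
                 conditionMessage(e), call. = FALSE))
        mk <- tryCatch(readMarkers(mf$markers_path[i], rec),
            error = function(e)
                stop("stage 'read_markers' failed for ", mf$markers_path[i],
                     ": ", conditionMessage(e), call. = FALSE))
        res <- tryCatch(
            analyzeSession(rec, mk, mf$participant_id[i], mf$group[i],
                           config$options),
            error = function(e)
                stop("stage 'analyze' failed for ", mf$participant_id[i],
                     ": ", conditionMessage(e), call. = FALSE))
        summaries[[i]] <- res$summaries
        tab <- table(res$artifacts$class)
        artifactCounts[[i]] <- setNames(as.integer(tab), names(tab))
    }
    long <- do.call(rbind, summaries)
    cohort <- buildCohortTable(long)
    stats <- tryCatch(cohortStatistics(cohort, config$options),
        error = function(e)
            stop("stage 'statistics' failed: ", conditionMessage(e),
                 call. = FALSE))
    write.csv(long, file.path(config$outDir, "cohort_long.csv"),
              row.names = FALSE)
    wide <- data.frame(participant_id = colnames(
                           SummarizedExperiment::assay(cohort, "stmli")),
                       group = groupLabels(cohort),
                       t(SummarizedExperiment::assay(cohort, "stmli")),
                       check.names = FALSE)
    write.csv(wide, file.path(config$outDir, "cohort_wide.csv"),
              row.names = FALSE)
    report <- list(
        n_sessions = nrow(mf),
        options = config$options[c("bandpass", "notches", "kaiserBeta",
                                   "relDomain", "trim", "alpha",
                                   "mahalanobisP", "eigenCutoff")],
        exclusions = stats$exclusions,
        artifact_events = artifactCounts,
        anova = list(effects = stats$anova$effects,
                     epsilon = stats$anova$epsilon,
                     ggApplied = stats$anova$ggApplied,
                     mauchly = stats$anova$mauchly),
        task_table = stats$taskTable,
        kmo_bartlett = stats$kmo,
        pca = list(eigenvalues = stats$pca$eigenvalues,
                   nRetained = stats$pca$nRetained,
                   loadings = as.data.frame(stats$pca$loadings),
                   totalVariancePct = stats$pca$totalVariancePct),
        component_anova = if (!is.null(stats$componentAnova))
            list(effects = stats$componentAnova$effects) else NULL)
    jsonlite::write_json(report,
                         file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    invisible(report)
}
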