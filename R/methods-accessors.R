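#' @describeIn EEGRecording-class the channels x time sample matrix (uV).
#' @param x an object.
#' @export
setMethod("samples", "EEGRecording", function(x) x@samples)

#' @describeIn EEGRecording-class channel labels, in matrix row order.
#' @export
setMethod("channelLabels", "EEGRecording", function(x) rownames(x@samples))

#' @describeIn EEGRecording-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@samplingRate)

#' @describeIn EEGRecording-class reference state flag.
#' @export
setMethod("referenceType", "EEGRecording", function(x) x@reference)

#' @describeIn EEGRecording-class number of samples per channel.
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@samples))

setMethod("show", "EEGRecording", function(object) {
    cat(sprintf(
        "EEGRecording: %d channel(s) x %d samples (%.1f s @ %g Hz), %s reference\n",
        nrow(object@samples), ncol(object@samples),
        ncol(object@samples) / object@samplingRate,
        object@samplingRate, object@reference))
    cat("  channels:", paste(rownames(object@samples), collapse = ", "), "\n")
})

#' @describeIn ArtifactMask-class the per-event log.
#' @param x an object.
#' @export
setMethod("artifactEvents", "ArtifactMask", function(x) x@events)

#' @describeIn ArtifactMask-class the logical channels x time mask.
#' @export
setMethod("artifactMask", "ArtifactMask", function(x) x@mask)

setMethod("show", "ArtifactMask", function(object) {
    cat(sprintf("ArtifactMask: %d event(s), %.2f%% of samples flagged\n",
        nrow(object@events), 100 * mean(object@mask)))
    if (nrow(object@events)) {
        tab <- table(object@events$class)
        cat("  by class:",
            paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
    }
})

#' @describeIn SyntheticSession-class the simulated recording.
#' @param x an object.
#' @export
setMethod("recording", "SyntheticSession", function(x) x@recording)

#' @describeIn SyntheticSession-class the task marker table.
#' @export
setMethod("markers", "SyntheticSession", function(x) x@markers)

#' @describeIn SyntheticSession-class analytic per-task relative band powers.
#' @export
setMethod("groundTruth", "SyntheticSession", function(x) x@truth)

#' @describeIn SyntheticSession-class group label.
#' @export
setMethod("groupLabel", "SyntheticSession", function(x) x@group)

#' @describeIn SyntheticSession-class participant identifier.
#' @export
setMethod("participantId", "SyntheticSession", function(x) x@participantId)

setMethod("show", "SyntheticSession", function(object) {
    cat(sprintf("SyntheticSession %s (group: %s)\n",
        object@participantId, object@group))
    show(object@recording)
    cat(sprintf("  %d task interval(s)\n", nrow(object@markers)))
})

#' @describeIn CohortTable-class participants x tasks STMLI matrix.
#' @param x an object.
#' @export
setMethod("cohortMatrix", "CohortTable", function(x)
    t(SummarizedExperiment::assay(x, "stmli")))

#' @describeIn CohortTable-class per-participant group labels (column order).
#' @export
setMethod("groupLabels", "CohortTable", function(x)
    as.character(SummarizedExperiment::colData(x)$group))
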