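#' @import methods
#' @importFrom stats rnorm runif fft mahalanobis qchisq qt pt pf pchisq
#'   cov cor var sd median aggregate setNames complete.cases rbinom
#' @importFrom utils read.csv write.csv head
NULL

.SCALP_CHANNELS <- c("Fz", "F3", "F4", "Cz", "C3", "C4", "POz", "P3", "P4")
.MASTOID_CHANNELS <- c("M1", "M2")
.TASK_NAMES <- c("VC", "CS", "DP", "NFQ", "PS", "HRT", "EHC", "TC", "GNG")
.BAND_DEFS <- list(
    theta     = 3:7,
    alpha     = 8:12,
    low_beta  = 13:19,
    high_beta = 20:29,
    gamma     = 30:40
)
.ARTIFACT_CLASSES <- c("spike", "excursion", "saturation", "EMG", "blink")

#' Multi-channel EEG recording
#'
#' Container for a multi-channel EEG time series in microvolts. Rows of the
#' sample matrix are channels (row names are the channel labels), columns are
#' samples. The \code{reference} slot records whether linked-mastoid
#' re-referencing has been applied, so it cannot be applied twice silently.
#'
#' @slot samples numeric matrix, channels x time, in microvolts.
#' @slot samplingRate sampling rate in Hz.
#' @slot reference one of \code{"raw"} or \code{"linked-mastoid"}.
#'
#' @aliases EEGRecording-class
#' @exportClass EEGRecording
setClass("EEGRecording",
    slots = c(
        samples = "matrix",
        samplingRate = "numeric",
        reference = "character"
    )
)

setValidity("EEGRecording", function(object) {
    msg <- character()
    if (!is.numeric(object@samples))
        msg <- c(msg, "'samples' must be a numeric matrix")
    if (is.null(rownames(object@samples)))
        msg <- c(msg, "'samples' must have channel labels as row names")
    else if (anyDuplicated(rownames(object@samples)))
        msg <- c(msg, "channel labels must be unique")
    if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
        msg <- c(msg, "'samplingRate' must be a single positive number")
    if (!object@reference %in% c("raw", "linked-mastoid"))
        msg <- c(msg, "'reference' must be 'raw' or 'linked-mastoid'")
    if (length(object@samples) && !all(is.finite(object@samples)))
        msg <- c(msg, "all samples must be finite")
    if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix (row names = channel labels),
#'   or a named list of equal-length numeric vectors.
#' @param samplingRate sampling rate in Hz.
#' @param reference reference state flag, \code{"raw"} by default.
#' @return An \linkS4class{EEGRecording}.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(512), 2, 256,
#'     dimnames = list(c("Fz", "Cz"), NULL)), samplingRate = 256)
#' rec
#' @export
EEGRecording <- function(samples, samplingRate, reference = "raw") {
    if (is.list(samples))
        samples <- do.call(rbind, samples)
    storage.mode(samples) <- "double"
    new("EEGRecording", samples = samples, samplingRate = samplingRate,
        reference = reference)
}

#' Artifact mask
#'
#' Sample-level boolean mask (channels x time, aligned with a recording) plus
#' an event log with one row per detected artifact event.
#'
#' @slot mask logical matrix, channels x time; \code{TRUE} marks contaminated
#'   samples.
#' @slot events \code{data.frame} with columns \code{channel}, \code{class}
#'   (spike, excursion, saturation, EMG, blink), \code{start}, \code{end}
#'   (0-based, half-open sample interval).
#'
#' @aliases ArtifactMask-class
#' @exportClass ArtifactMask
setClass("ArtifactMask",
    slots = c(mask = "matrix", events = "data.frame")
)

setValidity("ArtifactMask", function(object) {
    msg <- character()
    if (!is.logical(object@mask))
        msg <- c(msg, "'mask' must be a logical matrix")
    ev <- object@events
    need <- c("channel", "class", "start", "end")
    if (!all(need %in% names(ev)))
        msg <- c(msg, "'events' needs columns channel, class, start, end")
    else if (nrow(ev)) {
        if (!all(ev$class %in% .ARTIFACT_CLASSES))
            msg <- c(msg, "unknown artifact class in event log")
        if (any(ev$start < 0L) || any(ev$end > ncol(object@mask)) ||
            any(ev$start >= ev$end))
            msg <- c(msg, "events must lie within the recording, start < end")
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic-cohort simulation configuration
#'
#' Parameters of the synthetic EEG generator: montage and sampling, cohort
#' sizes, task layout, the 1/f background, per-group/task/band oscillator RMS
#' amplitudes, between-participant amplitude variability, and artifact event
#' rates. Build with \code{\link{simulationConfig}}.
#'
#' @slot samplingRate Hz.
#' @slot channelLabels scalp + mastoid channel labels.
#' @slot nNoConcussion,nConcussion group sizes.
#' @slot taskNames the nine task labels.
#' @slot taskDuration seconds per task.
#' @slot interTaskGap seconds between consecutive tasks.
#' @slot backgroundSd total RMS of the 1/f background, microvolts.
#' @slot backgroundExponent spectral slope alpha of the 1/f^alpha background.
#' @slot bandFreqs named oscillator center frequencies (Hz).
#' @slot bandAmplitudes named list (one element per group) of task x band
#'   matrices of oscillator RMS amplitudes in microvolts.
#' @slot subjectAmplitudeSd sdlog of the per-participant lognormal amplitude
#'   multiplier, per band.
#' @slot artifactRates events per minute for each artifact class.
#' @slot railValue amplifier rail used by the saturation artifact, microvolts.
#' @slot seed master seed.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    slots = c(
        samplingRate = "numeric",
        channelLabels = "character",
        nNoConcussion = "integer",
        nConcussion = "integer",
        taskNames = "character",
        taskDuration = "numeric",
        interTaskGap = "numeric",
        backgroundSd = "numeric",
        backgroundExponent = "numeric",
        bandFreqs = "numeric",
        bandAmplitudes = "list",
        subjectAmplitudeSd = "numeric",
        artifactRates = "numeric",
        railValue = "numeric",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be positive")
    if (length(object@taskNames) != 9L)
        msg <- c(msg, "exactly 9 tasks are required")
    if (object@taskDuration <= 2)
        msg <- c(msg, "taskDuration must exceed 2 s")
    if (object@interTaskGap < 0)
        msg <- c(msg, "interTaskGap must be >= 0")
    if (object@nNoConcussion < 2L || object@nConcussion < 0L)
        msg <- c(msg, "need >= 2 participants in the reference group")
    for (g in names(object@bandAmplitudes)) {
        amp <- object@bandAmplitudes[[g]]
        if (!is.matrix(amp) ||
            !identical(rownames(amp), object@taskNames) ||
            !identical(colnames(amp), names(object@bandFreqs)))
            msg <- c(msg, sprintf(
                "bandAmplitudes[['%s']] must be a task x band matrix", g))
        else if (any(amp < 0))
            msg <- c(msg, "oscillator amplitudes must be >= 0")
    }
    if (any(object@artifactRates < 0))
        msg <- c(msg, "artifact rates must be >= 0")
    if (length(msg)) msg else TRUE
})

#' One synthetic EEG session
#'
#' A simulated recording with its task markers, the analytic ground-truth
#' relative band powers implied by the generating amplitudes, the true
#' artifact mask, and cohort bookkeeping.
#'
#' @slot recording an \linkS4class{EEGRecording} (raw reference, mastoids
#'   included).
#' @slot markers \code{data.frame} with \code{task}, \code{start_sample},
#'   \code{end_sample} (0-based, half-open).
#' @slot truth \code{data.frame}: per task, the analytic relative power of
#'   each band over the 1--40 Hz analysis range.
#' @slot truthMask logical matrix marking the samples carrying injected
#'   artifacts (channels x time).
#' @slot group group label, \code{"none"} or \code{"concussion"}.
#' @slot participantId participant identifier.
#'
#' @aliases SyntheticSession-class
#' @exportClass SyntheticSession
setClass("SyntheticSession",
    slots = c(
        recording = "EEGRecording",
        markers = "data.frame",
        truth = "data.frame",
        truthMask = "matrix",
        group = "character",
        participantId = "character"
    )
)

#' Cohort table of STMLI summaries
#'
#' A \linkS4class{SummarizedExperiment} with tasks as rows and participants as
#' columns. Assay \code{"stmli"} holds the per-participant-per-task trimmed
#' mean STMLI (NA where a task produced no valid epochs); assay
#' \code{"nEpochs"} the number of epochs entering each summary.
#' \code{colData} carries \code{participant_id} and \code{group}.
#'
#' @aliases CohortTable-class
#' @exportClass CohortTable
#' @import SummarizedExperiment
setClass("CohortTable", contains = "SummarizedExperiment")

setValidity("CohortTable", function(object) {
    msg <- character()
    if (!"stmli" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'stmli' is required")
    if (!"group" %in% names(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain 'group'")
    if (length(msg)) msg else TRUE
})
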