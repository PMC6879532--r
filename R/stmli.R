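## The short-term memory load index: relative theta power divided by
## relative gamma power at the frontal midline channel Fz, computed per
## 1-second epoch and aggregated per participant x task with a 5% per-tail
## trimmed mean.

#' STMLI ratio
#'
#' \code{stmliRatio} is the index itself: relative theta divided by relative
#' gamma. It is invariant to any common rescaling of the relative-PSD
#' vector, so linear vs x100 relative-power conventions cancel.
#'
#' @param theta,gamma relative band powers at Fz (vectors allowed).
#' @return theta / gamma; \code{NA} where gamma is zero.
#' @examples
#' stmliRatio(1.21, 2.54)
#' @export
stmliRatio <- function(theta, gamma) {
    out <- theta / gamma
    out[gamma == 0] <- NA_real_
    out
}

#' Per-epoch STMLI from a band table
#'
#' Filters a \code{\link{bandTable}} result to the valid Fz epochs and
#' computes the theta/gamma ratio per epoch. Epochs with zero relative gamma
#' power (possible only on degenerate input) are dropped, with a message.
#'
#' @param bands \code{data.frame} from \code{\link{bandTable}}.
#' @param channel channel carrying the index (the frontal midline, Fz).
#' @return \code{data.frame}: \code{task}, \code{epoch}, \code{stmli}.
#' @export
stmliFromBands <- function(bands, channel = "Fz") {
    if (!channel %in% bands$channel)
        stop("channel '", channel, "' absent from the band table")
    b <- bands[bands$channel == channel & bands$valid, , drop = FALSE]
    ratio <- stmliRatio(b$theta, b$gamma)
    drop <- is.na(ratio)
    if (any(drop))
        message(sum(drop), " epoch(s) dropped: zero relative gamma power")
    data.frame(task = b$task[!drop], epoch = b$epoch[!drop],
               stmli = ratio[!drop], stringsAsFactors = FALSE)
}

#' Five percent per-tail trimmed mean
#'
#' Removes \code{floor(trim * n)} smallest and largest values and averages
#' the rest (the EXAMINE-style per-tail convention); with fewer than
#' \code{1/trim} values nothing is trimmed.
#'
#' @param values numeric vector, at least one value.
#' @param trim per-tail trimming fraction.
#' @return The trimmed mean.
#' @examples
#' trimmedMean(c(rep(1, 19), 1000))  # one value trimmed per tail -> 1
#' @export
trimmedMean <- function(values, trim = 0.05) {
    if (!length(values)) stop("empty input")
    mean(values, trim = trim)
}

#' Aggregate per-epoch STMLI per participant x task
#'
#' @param epochRatios result of \code{\link{stmliFromBands}}.
#' @param participantId,group identifiers attached to the summaries.
#' @param trim per-tail trimming fraction.
#' @return \code{data.frame}: \code{participant_id}, \code{group},
#'   \code{task}, \code{stmli}, \code{n_epochs_used},
#'   \code{n_epochs_trimmed}.
#' @export
summarizeStmli <- function(epochRatios, participantId, group,
                           trim = 0.05) {
    if (!nrow(epochRatios))
        return(data.frame(participant_id = character(), group = character(),
                          task = character(), stmli = numeric(),
                          n_epochs_used = integer(),
                          n_epochs_trimmed = integer(),
                          stringsAsFactors = FALSE))
    sp <- split(epochRatios$stmli, epochRatios$task)
    data.frame(participant_id = participantId, group = group,
               task = names(sp),
               stmli = vapply(sp, trimmedMean, 0, trim = trim),
               n_epochs_used = vapply(sp, function(v)
                   length(v) - 2L * as.integer(floor(trim * length(v))), 0L),
               n_epochs_trimmed = vapply(sp, function(v)
                   2L * as.integer(floor(trim * length(v))), 0L),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the cohort table
#'
#' Builds the participants x 9-tasks matrix of STMLI summaries as a
#' \linkS4class{CohortTable}. Tasks a participant lacks valid epochs for are
#' explicit \code{NA} cells; the participant is retained.
#'
#' @param summaries row-bound output of \code{\link{summarizeStmli}} across
#'   participants.
#' @param taskNames row (task) order of the table.
#' @return A \linkS4class{CohortTable}.
#' @export
buildCohortTable <- function(summaries, taskNames = .TASK_NAMES) {
    if (!nrow(summaries)) stop("no summaries supplied")
    if (anyDuplicated(summaries[, c("participant_id", "task")]))
        stop("duplicate (participant, task) summaries")
    ids <- unique(summaries$participant_id)
    grp <- summaries$group[match(ids, summaries$participant_id)]
    mk <- function(col, default) {
        m <- matrix(default, length(taskNames), length(ids),
                    dimnames = list(taskNames, ids))
        i <- cbind(match(summaries$task, taskNames),
                   match(summaries$participant_id, ids))
        m[i] <- summaries[[col]]
        m
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(stmli = mk("stmli", NA_real_),
                      nEpochs = mk("n_epochs_used", 0L)),
        colData = S4Vectors::DataFrame(participant_id = ids, group = grp,
                                       row.names = ids))
    new("CohortTable", se)
}
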