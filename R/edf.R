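## Minimal EDF (European Data Format, 16-bit) codec. Signals are stored in
## 1-second data records as little-endian int16; physical range is fixed at
## -3276.8..3276.7 uV against digital -32768..32767, i.e. 0.1 uV/bit.

.EDF_PHYS_MIN <- -3276.8
.EDF_PHYS_MAX <- 3276.7
.EDF_DIG_MIN <- -32768L
.EDF_DIG_MAX <- 32767L

.edf_pad <- function(x, width) {
    x <- substr(as.character(x), 1L, width)
    formatC(x, width = -width, flag = " ")
}

.edf_field <- function(con, width, n = 1L) {
    raw <- readChar(con, width * n, useBytes = TRUE)
    vapply(seq_len(n), function(i)
        trimws(substr(raw, (i - 1L) * width + 1L, i * width)), "")
}

#' Write an EEG recording to an EDF file
#'
#' Samples are quantized to 0.1 uV steps (16-bit, physical range
#' +/-3276.8 uV). The record duration is one second; recordings whose length
#' is not a whole number of seconds are zero-padded to the next full record.
#' Values outside the physical range are clipped with a warning.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readEDF}}
#' @export
writeEDF <- function(rec, path) {
    stopifnot(is(rec, "EEGRecording"))
    x <- samples(rec)
    fs <- samplingRate(rec)
    if (fs != round(fs))
        stop("writeEDF supports integer sampling rates only")
    spr <- as.integer(fs)
    nch <- nrow(x)
    nrec <- as.integer(ceiling(ncol(x) / spr))
    if (ncol(x) < nrec * spr)
        x <- cbind(x, matrix(0, nch, nrec * spr - ncol(x)))
    if (any(x < .EDF_PHYS_MIN | x > .EDF_PHYS_MAX)) {
        warning("samples outside the EDF physical range were clipped")
        x <- pmin(pmax(x, .EDF_PHYS_MIN), .EDF_PHYS_MAX)
    }
    gain <- (.EDF_PHYS_MAX - .EDF_PHYS_MIN) / (.EDF_DIG_MAX - .EDF_DIG_MIN)
    dig <- round((x - .EDF_PHYS_MIN) / gain) + .EDF_DIG_MIN

    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- paste0(
        .edf_pad("0", 8L),
        .edf_pad("X X X X", 80L),
        .edf_pad(paste("Startdate X X X", rec@reference), 80L),
        .edf_pad("01.01.00", 8L),
        .edf_pad("00.00.00", 8L),
        .edf_pad(256L * (nch + 1L), 8L),
        .edf_pad("", 44L),
        .edf_pad(nrec, 8L),
        .edf_pad("1", 8L),
        .edf_pad(nch, 4L),
        paste(.edf_pad(rownames(x), 16L), collapse = ""),
        paste(.edf_pad(rep("", nch), 80L), collapse = ""),
        paste(.edf_pad(rep("uV", nch), 8L), collapse = ""),
        paste(.edf_pad(rep(sprintf("%.1f", .EDF_PHYS_MIN), nch), 8L),
              collapse = ""),
        paste(.edf_pad(rep(sprintf("%.1f", .EDF_PHYS_MAX), nch), 8L),
              collapse = ""),
        paste(.edf_pad(rep(.EDF_DIG_MIN, nch), 8L), collapse = ""),
        paste(.edf_pad(rep(.EDF_DIG_MAX, nch), 8L), collapse = ""),
        paste(.edf_pad(rep("", nch), 80L), collapse = ""),
        paste(.edf_pad(rep(spr, nch), 8L), collapse = ""),
        paste(.edf_pad(rep("", nch), 32L), collapse = "")
    )
    writeChar(hdr, con, eos = NULL, useBytes = TRUE)
    ## record-major, signal-blocked layout
    idx <- matrix(seq_len(nrec * spr), nrow = spr)
    for (r in seq_len(nrec)) {
        block <- t(dig[, idx[, r], drop = FALSE])  # spr x nch
        writeBin(as.integer(block), con, size = 2L, endian = "little")
    }
    invisible(path)
}

#' Read an EDF file into an EEGRecording
#'
#' Supports EDF files whose signals share a common sampling rate (a mismatch
#' is an error). Annotation channels are not supported.
#'
#' @param path an EDF file.
#' @return An \linkS4class{EEGRecording} with \code{"raw"} reference.
#' @export
readEDF <- function(path) {
    if (!file.exists(path))
        stop("EDF file not found: ", path)
    con <- file(path, "rb")
    on.exit(close(con))
    .edf_field(con, 8L)                       # version
    .edf_field(con, 80L); .edf_field(con, 80L)
    .edf_field(con, 8L); .edf_field(con, 8L)
    .edf_field(con, 8L)                       # header bytes
    .edf_field(con, 44L)
    nrec <- as.integer(.edf_field(con, 8L))
    recdur <- as.numeric(.edf_field(con, 8L))
    nch <- as.integer(.edf_field(con, 4L))
    if (nch < 1L) stop("EDF file declares no signals")
    labels <- .edf_field(con, 16L, nch)
    .edf_field(con, 80L, nch)
    .edf_field(con, 8L, nch)                  # physical dimension
    physMin <- as.numeric(.edf_field(con, 8L, nch))
    physMax <- as.numeric(.edf_field(con, 8L, nch))
    digMin <- as.numeric(.edf_field(con, 8L, nch))
    digMax <- as.numeric(.edf_field(con, 8L, nch))
    .edf_field(con, 80L, nch)
    spr <- as.integer(.edf_field(con, 8L, nch))
    .edf_field(con, 32L, nch)
    if (length(unique(spr)) != 1L)
        stop("EDF signals have differing samples-per-record; unsupported")
    fs <- spr[1L] / recdur
    n <- nrec * spr[1L]
    out <- matrix(0, nch, n, dimnames = list(labels, NULL))
    gain <- (physMax - physMin) / (digMax - digMin)
    for (r in seq_len(nrec)) {
        block <- readBin(con, "integer", n = nch * spr[1L], size = 2L,
                         signed = TRUE, endian = "little")
        block <- matrix(block, nrow = spr[1L])
        cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
        out[, cols] <- t(block) * gain + (physMin - digMin * gain)
    }
    EEGRecording(out, samplingRate = fs, reference = "raw")
}

#' Read / write task marker tables
#'
#' Markers delimit the nine task intervals as 0-based, half-open sample
#' ranges \code{[start_sample, end_sample)}.
#'
#' @param path CSV file with header \code{task,start_sample,end_sample}.
#' @param rec optional \linkS4class{EEGRecording} to validate bounds against.
#' @return \code{data.frame} with columns \code{task}, \code{start_sample},
#'   \code{end_sample}.
#' @export
readMarkers <- function(path, rec = NULL) {
    mk <- read.csv(path, stringsAsFactors = FALSE)
    validateMarkers(mk, rec)
    mk
}

#' @rdname readMarkers
#' @param markers marker \code{data.frame} to write.
#' @export
writeMarkers <- function(markers, path) {
    write.csv(markers, path, row.names = FALSE)
    invisible(path)
}

#' @rdname readMarkers
#' @param markers marker \code{data.frame}.
#' @export
validateMarkers <- function(markers, rec = NULL) {
    need <- c("task", "start_sample", "end_sample")
    if (!all(need %in% names(markers)))
        stop("markers need columns task, start_sample, end_sample")
    if (nrow(markers)) {
        if (any(markers$start_sample < 0) ||
            any(markers$start_sample >= markers$end_sample))
            stop("marker intervals must satisfy 0 <= start < end")
        if (!is.null(rec) && any(markers$end_sample > nSamples(rec)))
            stop("marker interval extends beyond the recording")
        o <- order(markers$start_sample)
        s <- markers$start_sample[o]; e <- markers$end_sample[o]
        if (any(s[-1L] < e[-length(e)]))
            stop("marker intervals overlap")
    }
    invisible(TRUE)
}

#' Re-reference to linked mastoids
#'
#' Subtracts the average of the two mastoid channels (M1, M2) from every
#' scalp channel, drops the mastoids, and flags the recording as
#' linked-mastoid referenced. Calling it on an already re-referenced
#' recording is an error, not a silent re-application.
#'
#' @param rec an \linkS4class{EEGRecording} with \code{"raw"} reference and
#'   both mastoid channels present.
#' @param mastoids the two mastoid channel labels.
#' @return The re-referenced \linkS4class{EEGRecording}.
#' @examples
#' x <- rbind(Fz = rnorm(256), M1 = rnorm(256), M2 = rnorm(256))
#' rereferenceLinkedMastoids(EEGRecording(x, 256))
#' @export
rereferenceLinkedMastoids <- function(rec, mastoids = c("M1", "M2")) {
    stopifnot(is(rec, "EEGRecording"))
    if (referenceType(rec) != "raw")
        stop("recording is already linked-mastoid referenced")
    labs <- channelLabels(rec)
    if (!all(mastoids %in% labs))
        stop("mastoid channel(s) missing: ",
             paste(setdiff(mastoids, labs), collapse = ", "))
    x <- samples(rec)
    ref <- colMeans(x[mastoids, , drop = FALSE])
    keep <- setdiff(labs, mastoids)
    out <- sweep(x[keep, , drop = FALSE], 2L, ref, "-")
    EEGRecording(out, samplingRate = samplingRate(rec),
                 reference = "linked-mastoid")
}
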