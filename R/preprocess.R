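## Zero-phase filtering chain and rule-based artifact handling. All filters
## are applied forward-backward (signal::filtfilt), so designed single-pass
## magnitudes are squared; design edges/widths below account for that.

## Butterworth cutoff widening so the zero-phase (squared) magnitude is
## -3 dB at the nominal edge: |H|^2 = 1/(1+(f/fc)^(2n)) = 10^(-3/20).
.butter_edge_factor <- function(order) {
    (10^(3 / 20) - 1)^(1 / (2 * order))
}

#' Zero-phase band-pass filter
#'
#' Order-4 Butterworth high-pass and low-pass sections applied
#' forward-backward. The design cutoffs are widened so the overall
#' zero-phase response is 3 dB down at \code{low} and \code{high}.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param low,high band edges in Hz (default 0.5--65).
#' @return The filtered \linkS4class{EEGRecording}.
#' @examples
#' rec <- EEGRecording(rbind(Fz = sin(2 * pi * 10 * (0:2559) / 256)), 256)
#' out <- bandpassFilter(rec)
#' @export
bandpassFilter <- function(rec, low = 0.5, high = 65) {
    stopifnot(is(rec, "EEGRecording"))
    fs <- samplingRate(rec)
    if (!(0 < low && low < high && high < fs / 2))
        stop("require 0 < low < high < Nyquist")
    ## widen design cutoffs in the bilinear-warped (analog) domain so the
    ## squared (zero-phase) magnitude is -3 dB at the nominal edges
    k <- .butter_edge_factor(4)
    warp <- function(f) tan(pi * f / fs)
    unwarp <- function(w) fs / pi * atan(w)
    hpEdge <- unwarp(warp(low) * k)
    lpEdge <- unwarp(warp(high) / k)
    hp <- .cached_filter(paste0("hp", hpEdge), fs, function()
        signal::butter(4, hpEdge / (fs / 2), type = "high"))
    lp <- .cached_filter(paste0("lp", lpEdge), fs, function()
        signal::butter(4, lpEdge / (fs / 2), type = "low"))
    x <- samples(rec)
    for (i in seq_len(nrow(x)))
        x[i, ] <- signal::filtfilt(lp, signal::filtfilt(hp, x[i, ]))
    EEGRecording(x, fs, referenceType(rec))
}

## second-order notch at f0 with stopband width bw (Hz); the bandwidth
## parameter is prewarped so it holds in Hz at any center frequency
.notch_biquad <- function(f0, bw, fs) {
    w0 <- 2 * pi * f0 / fs
    al <- tan(pi * bw / fs)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + al, -2 * cos(w0), 1 - al)
    signal::Arma(b = b / a[1], a = a / a[1])
}

#' Zero-phase notch filters
#'
#' One second-order notch per line frequency, applied forward-backward. The
#' stopband width (default 3.2 Hz) is constant in Hz so that the zero-phase
#' response is at least 20 dB down within +/-0.5 Hz of each notch while
#' changing the signal by less than 1 dB at +/-5 Hz.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param freqs notch center frequencies in Hz; each must be below Nyquist.
#'   An empty vector is the identity.
#' @param width stopband width in Hz.
#' @return The filtered \linkS4class{EEGRecording}.
#' @export
notchFilter <- function(rec, freqs = c(50, 60, 100, 120), width = 3.2) {
    stopifnot(is(rec, "EEGRecording"))
    fs <- samplingRate(rec)
    if (any(freqs >= fs / 2))
        stop("notch frequency at or above Nyquist")
    if (!length(freqs)) return(rec)
    x <- samples(rec)
    for (f0 in freqs) {
        ## two cascaded half-width sections: steeper skirts than one biquad
        ## of the full width, which is what lets the 120 Hz notch satisfy
        ## both bounds this close to Nyquist
        flt <- .cached_filter(paste0("notch", f0, "w", width), fs,
                              function() .notch_biquad(f0, width / 2, fs))
        for (i in seq_len(nrow(x)))
            x[i, ] <- signal::filtfilt(flt, signal::filtfilt(flt, x[i, ]))
    }
    EEGRecording(x, fs, referenceType(rec))
}

#' Default artifact-detection thresholds
#'
#' One auditable rule per artifact class: amplifier saturation (sustained
#' rail-level amplitude), spikes (sample-to-sample jumps), excursions
#' (departure from a 1-s running median), EMG (high-frequency RMS in short
#' windows), and blinks (low-frequency frontal deflections, grown by
#' hysteresis around each threshold crossing). All values in uV/seconds.
#'
#' @param rail saturation amplitude threshold.
#' @param railRun minimum consecutive samples at rail.
#' @param spikeJump successive-difference threshold.
#' @param excursion deviation-from-running-median threshold.
#' @param excursionWin running-median window, seconds.
#' @param emgRms sliding-RMS threshold for the 30 Hz-and-up component.
#' @param emgWin RMS window, seconds.
#' @param emgHysteresis fraction of \code{emgRms} to which a detected burst
#'   is extended around the crossing.
#' @param blinkPeak peak threshold for the 0.5--8 Hz frontal component. The
#'   low band passes only part of a brief deflection's peak (about 80
#'   percent for a 0.4-s blink), so the default sits below the smallest
#'   blink amplitude the rule is meant to catch (about 100 uV).
#' @param blinkHysteresis fraction of \code{blinkPeak} to which a detected
#'   blink is extended around the crossing.
#' @param blinkPad extra padding for blink events, seconds; blink
#'   deflections have sub-threshold onset/offset tails of roughly this
#'   length.
#' @param pad padding added around every event, seconds.
#' @return Named list of thresholds.
#' @export
artifactThresholds <- function(rail = 1000, railRun = 4, spikeJump = 40,
                               excursion = 200, excursionWin = 1,
                               emgRms = 30, emgWin = 0.25,
                               emgHysteresis = 0.5,
                               blinkPeak = 75, blinkHysteresis = 0.2,
                               blinkPad = 0.1,
                               pad = 0.025) {
    list(rail = rail, railRun = railRun, spikeJump = spikeJump,
         excursion = excursion, excursionWin = excursionWin,
         emgRms = emgRms, emgWin = emgWin, emgHysteresis = emgHysteresis,
         blinkPeak = blinkPeak, blinkHysteresis = blinkHysteresis,
         blinkPad = blinkPad, pad = pad)
}

## runs of TRUE in a logical vector -> matrix of (start, end) 0-based
## half-open intervals
.runs <- function(flag) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(start = starts[r$values], end = ends[r$values])
}

.grow_runs <- function(runs, keepFlag) {
    ## extend each run while keepFlag stays TRUE on either side
    kr <- .runs(keepFlag)
    if (!nrow(runs) || !nrow(kr)) return(runs)
    out <- runs
    for (i in seq_len(nrow(runs))) {
        hit <- which(kr[, "start"] < runs[i, "end"] &
                     kr[, "end"] > runs[i, "start"])
        if (length(hit)) {
            out[i, "start"] <- min(kr[hit, "start"], runs[i, "start"])
            out[i, "end"] <- max(kr[hit, "end"], runs[i, "end"])
        }
    }
    out
}

#' Detect artifacts
#'
#' Scans a (filtered) recording channel by channel with the rule set of
#' \code{\link{artifactThresholds}} and returns a sample-level
#' \linkS4class{ArtifactMask} plus a per-event log. Events are padded by
#' \code{thresholds$pad} seconds on both sides.
#'
#' @param rec an \linkS4class{EEGRecording} (band-pass and notch filtered).
#' @param thresholds see \code{\link{artifactThresholds}}.
#' @return An \linkS4class{ArtifactMask}.
#' @export
detectArtifacts <- function(rec, thresholds = artifactThresholds()) {
    stopifnot(is(rec, "EEGRecording"))
    th <- thresholds
    fs <- samplingRate(rec)
    x <- samples(rec)
    N <- ncol(x)
    padN <- as.integer(round(th$pad * fs))
    mask <- matrix(FALSE, nrow(x), N, dimnames = dimnames(x))
    events <- list()
    frontal <- intersect(c("Fz", "F3", "F4"), rownames(x))

    lp8 <- .cached_filter("lp8", fs, function()
        signal::butter(3, 8 / (fs / 2), type = "low"))
    hp30 <- .cached_filter("hp30", fs, function()
        signal::butter(3, 30 / (fs / 2), type = "high"))
    emgN <- max(1L, as.integer(round(th$emgWin * fs)))
    medN <- as.integer(round(th$excursionWin * fs))
    if (medN %% 2L == 0L) medN <- medN + 1L

    blinkPadN <- as.integer(round(th$blinkPad * fs))
    add_events <- function(ch, class, runs) {
        if (!nrow(runs)) return()
        extra <- padN + if (class == "blink") blinkPadN else 0L
        runs[, "start"] <- pmax(0L, runs[, "start"] - extra)
        runs[, "end"] <- pmin(N, runs[, "end"] + extra)
        for (i in seq_len(nrow(runs)))
            mask[ch, (runs[i, "start"] + 1L):runs[i, "end"]] <<- TRUE
        events[[length(events) + 1L]] <<- data.frame(
            channel = ch, class = class,
            start = runs[, "start"], end = runs[, "end"],
            stringsAsFactors = FALSE)
    }

    for (ch in rownames(x)) {
        v <- x[ch, ]
        ## saturation: sustained rail-level amplitude
        sat <- .runs(abs(v) >= th$rail)
        if (nrow(sat))
            sat <- sat[sat[, "end"] - sat[, "start"] >= th$railRun, ,
                       drop = FALSE]
        add_events(ch, "saturation", sat)
        ## spikes: successive-difference jumps
        jump <- c(FALSE, abs(diff(v)) > th$spikeJump)
        add_events(ch, "spike", .runs(jump))
        ## excursions from the running median
        med <- stats::runmed(v, medN, endrule = "constant")
        add_events(ch, "excursion", .runs(abs(v - med) > th$excursion))
        ## EMG: sliding RMS of the high-frequency component with hysteresis
        hf <- signal::filtfilt(hp30, v)
        cs <- c(0, cumsum(hf^2))
        half1 <- emgN %/% 2L
        lo <- pmax(seq_len(N) - half1, 1L)
        hi <- pmin(seq_len(N) + (emgN - half1 - 1L), N)
        env <- sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
        emg <- .grow_runs(.runs(env > th$emgRms),
                          env > th$emgHysteresis * th$emgRms)
        add_events(ch, "EMG", emg)
        ## blinks: low-frequency frontal deflections with hysteresis growth
        if (ch %in% frontal) {
            lf <- signal::filtfilt(lp8, v)
            seed <- .runs(abs(lf) > th$blinkPeak)
            seed <- .grow_runs(seed,
                abs(lf) > th$blinkHysteresis * th$blinkPeak)
            add_events(ch, "blink", seed)
        }
    }
    events <- if (length(events)) do.call(rbind, events) else
        data.frame(channel = character(), class = character(),
                   start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
    new("ArtifactMask", mask = mask, events = events)
}

#' Decontaminate by zero insertion
#'
#' Replaces every masked sample with exactly zero; unmasked samples are
#' untouched (bitwise), so downstream overlay rejection can count inserted
#' zeros. Idempotent.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param mask an \linkS4class{ArtifactMask} aligned with \code{rec} (or a
#'   logical channels x time matrix).
#' @return The decontaminated \linkS4class{EEGRecording}.
#' @export
decontaminate <- function(rec, mask) {
    stopifnot(is(rec, "EEGRecording"))
    m <- if (is(mask, "ArtifactMask")) artifactMask(mask) else mask
    x <- samples(rec)
    if (!identical(dim(m), dim(x)))
        stop("mask shape does not match the recording")
    x[m] <- 0
    EEGRecording(x, samplingRate(rec), referenceType(rec))
}
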