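## Overlay-based PSD estimation. Each 1-second epoch is analyzed through
## three 50%-overlapping 1-second overlays (256 samples each at 256 Hz),
## Kaiser-tapered and FFT'd into 1-Hz bins 1-40. Overlays carrying more than
## 128 inserted zeros are rejected; an epoch with fewer than two usable
## overlays is invalid. Relative power divides each bin by the 1-40 Hz sum.

.REL_BINS <- 1:40

#' Power spectrum of one 256-sample overlay
#'
#' Kaiser-tapered periodogram in 1-Hz bins 1--40. Powers carry a Parseval
#' normalization (total one-sided power equals the mean square amplitude),
#' so a sinusoid of RMS amplitude A at a bin center contributes total power
#' A^2 across its main lobe regardless of the taper. The
#' number of exact zeros (inserted by decontamination) is counted before
#' tapering; an overlay with more than 128 zeros is flagged invalid.
#'
#' @param window numeric vector of exactly \code{samplingRate} samples (one
#'   second; 256 at the default rate).
#' @param samplingRate Hz; must equal the window length so bins are 1 Hz.
#' @param kaiserBeta Kaiser taper shape parameter.
#' @return List with \code{psd} (named vector, bins 1--40), \code{zeroCount},
#'   and \code{valid}.
#' @examples
#' ov <- overlayPSD(sqrt(2) * sin(2 * pi * 10 * (0:255) / 256))
#' sum(ov$psd)  # ~1: unit RMS
#' @export
overlayPSD <- function(window, samplingRate = 256, kaiserBeta = 8) {
    n <- as.integer(samplingRate)
    if (length(window) != n)
        stop("overlay must contain exactly ", n, " samples")
    zc <- sum(window == 0)
    w <- signal::kaiser(n, kaiserBeta)
    X <- fft(w * window)
    psd <- 2 * Mod(X[.REL_BINS + 1L])^2 / (n * sum(w^2))
    list(psd = setNames(psd, .REL_BINS), zeroCount = zc,
         valid = zc <= n %/% 2L)
}

#' Combine overlays into an epoch spectrum
#'
#' Averages the power spectra of the epoch's valid overlays (those with at
#' most 128 inserted zeros) and normalizes to relative power. An epoch with
#' fewer than two valid overlays -- including the three-overlay case with two
#' rejections -- is invalid. In \code{"linear"} mode relative bins divide by
#' the 1--40 Hz power sum (and sum to one); \code{"log10"} is the
#' log-relative convention, minus log10 of the linear relative bin
#' (unit-free, positive, monotone decreasing in the linear value).
#'
#' @param overlays list of 1--3 results of \code{\link{overlayPSD}}.
#' @param mode \code{"linear"} or \code{"log10"}.
#' @return List with \code{relBins} (named vector, NA-filled when invalid),
#'   \code{valid}, and \code{nOverlaysUsed}.
#' @export
epochSpectrum <- function(overlays, mode = c("linear", "log10")) {
    mode <- match.arg(mode)
    if (!length(overlays))
        stop("at least one overlay is required")
    if (length(overlays) > 3L)
        stop("an epoch has at most three overlays")
    ok <- vapply(overlays, `[[`, TRUE, "valid")
    if (sum(ok) < 2L)
        return(list(relBins = setNames(rep(NA_real_, 40L), .REL_BINS),
                    valid = FALSE, nOverlaysUsed = 0L))
    psd <- rowMeans(vapply(overlays[ok], `[[`, numeric(40L), "psd"))
    rel <- .relativize(psd, mode)
    list(relBins = setNames(rel, .REL_BINS), valid = TRUE,
         nOverlaysUsed = sum(ok))
}

## "linear": each bin divided by the 1-40 Hz sum (bins sum to one).
## "log10": the log-relative convention, -log10 of the linear relative bin;
## unit-free and positive (every relative bin is below one), with the
## magnitude scale vendor stacks report for band-averaged values. Note the
## transform is monotone decreasing, so effects on the theta/gamma index
## reverse direction relative to the linear convention.
.relativize <- function(psd, mode) {
    if (any(psd <= 0)) return(rep(NA_real_, length(psd)))
    rel <- psd / sum(psd)
    if (mode == "log10") -log10(rel) else rel
}

#' Average relative bins into canonical bands
#'
#' Band values are plain means of the constituent 1-Hz relative bins:
#' theta 3--7, alpha 8--12, low beta 13--19, high beta 20--29,
#' gamma 30--40 Hz.
#'
#' @param relBins named (1--40) vector of relative PSD bins, or the result
#'   of \code{\link{epochSpectrum}}.
#' @return Named numeric vector \code{theta}, \code{alpha}, \code{low_beta},
#'   \code{high_beta}, \code{gamma}.
#' @examples
#' bandAverage(setNames(rep(1 / 40, 40), 1:40))
#' @export
bandAverage <- function(relBins) {
    if (is.list(relBins)) {
        if (!isTRUE(relBins$valid)) stop("epoch is invalid")
        relBins <- relBins$relBins
    }
    vapply(.BAND_DEFS, function(b) mean(relBins[b]), 0)
}

#' Tile task intervals into 1-second epochs
#'
#' Consecutive non-overlapping one-second epochs tile each marker interval;
#' a trailing partial second is discarded (with a warning for intervals
#' shorter than one second).
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param markers marker \code{data.frame} (see \code{\link{readMarkers}}).
#' @return \code{data.frame} with \code{task}, \code{epoch} (1-based within
#'   task), \code{start_sample} (0-based).
#' @export
epochTasks <- function(rec, markers) {
    validateMarkers(markers, rec)
    fs <- as.integer(samplingRate(rec))
    out <- lapply(seq_len(nrow(markers)), function(i) {
        nEp <- (markers$end_sample[i] - markers$start_sample[i]) %/% fs
        if (nEp < 1L) {
            warning("task ", markers$task[i],
                    " is shorter than one second; no epochs")
            return(NULL)
        }
        data.frame(task = markers$task[i], epoch = seq_len(nEp),
                   start_sample = markers$start_sample[i] +
                       (seq_len(nEp) - 1L) * fs,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(task = character(), epoch = integer(),
                          start_sample = integer(), stringsAsFactors = FALSE)
    out
}

#' Per-epoch relative band powers for a recording
#'
#' Runs the full overlay scheme over every task interval: for the epoch
#' starting at t, overlays start at t-0.5 s, t, and t+0.5 s, clamped to the
#' task interval (boundary epochs proceed with the two available overlays).
#' Returns one row per task x epoch x channel with the five band-averaged
#' relative powers and validity bookkeeping.
#'
#' @param rec a decontaminated \linkS4class{EEGRecording}.
#' @param markers marker \code{data.frame}.
#' @param channels channels to analyze (default: all in \code{rec}).
#' @param kaiserBeta Kaiser taper shape parameter.
#' @param relDomain \code{"linear"} or \code{"log10"} relative-power domain.
#' @return \code{data.frame}: \code{task}, \code{epoch}, \code{channel},
#'   \code{valid}, \code{n_overlays}, \code{theta}, \code{alpha},
#'   \code{low_beta}, \code{high_beta}, \code{gamma}.
#' @export
bandTable <- function(rec, markers, channels = NULL, kaiserBeta = 8,
                      relDomain = c("linear", "log10")) {
    relDomain <- match.arg(relDomain)
    validateMarkers(markers, rec)
    fs <- as.integer(samplingRate(rec))
    if (is.null(channels)) channels <- channelLabels(rec)
    miss <- setdiff(channels, channelLabels(rec))
    if (length(miss))
        stop("channel(s) missing from recording: ",
             paste(miss, collapse = ", "))
    x <- samples(rec)
    half <- fs %/% 2L
    w <- signal::kaiser(fs, kaiserBeta)
    wg2 <- fs * sum(w^2)

    res <- list()
    for (i in seq_len(nrow(markers))) {
        s0 <- markers$start_sample[i]
        nEp <- (markers$end_sample[i] - s0) %/% fs
        if (nEp < 1L) next
        J <- 2L * nEp - 1L
        ovStart <- s0 + half * (seq_len(J) - 1L)      # 0-based
        idx <- outer(seq_len(fs), ovStart, `+`)        # 1-based columns
        for (ch in channels) {
            Wm <- matrix(x[ch, idx], nrow = fs)
            zc <- colSums(Wm == 0)
            ovValid <- zc <= half
            P <- 2 * Mod(stats::mvfft(Wm * w)[.REL_BINS + 1L, ,
                                              drop = FALSE])^2 / wg2
            valid <- logical(nEp)
            nOv <- integer(nEp)
            bands <- matrix(NA_real_, nEp, 5L)
            for (e in seq_len(nEp)) {
                js <- intersect(c(2L * e - 2L, 2L * e - 1L, 2L * e),
                                seq_len(J))
                ok <- js[ovValid[js]]
                nOv[e] <- length(ok)
                if (length(ok) < 2L) next
                rel <- .relativize(rowMeans(P[, ok, drop = FALSE]),
                                   relDomain)
                valid[e] <- !anyNA(rel)
                if (valid[e])
                    bands[e, ] <- vapply(.BAND_DEFS,
                                         function(b) mean(rel[b]), 0)
            }
            res[[length(res) + 1L]] <- data.frame(
                task = markers$task[i], epoch = seq_len(nEp), channel = ch,
                valid = valid, n_overlays = nOv,
                theta = bands[, 1L], alpha = bands[, 2L],
                low_beta = bands[, 3L], high_beta = bands[, 4L],
                gamma = bands[, 5L], stringsAsFactors = FALSE)
        }
    }
    rows <- res
    if (!length(rows))
        return(data.frame(task = character(), epoch = integer(),
                          channel = character(), valid = logical(),
                          n_overlays = integer(), theta = numeric(),
                          alpha = numeric(), low_beta = numeric(),
                          high_beta = numeric(), gamma = numeric(),
                          stringsAsFactors = FALSE))
    do.call(rbind, rows)
}
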