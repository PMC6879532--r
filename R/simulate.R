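## Synthetic task-EEG generator. Each channel is 1/f^alpha Gaussian
## background plus fixed-frequency band oscillators (theta 5 Hz, alpha 10 Hz,
## gamma 35 Hz) with per-epoch random phase, contaminated by blink / EMG /
## spike / saturation events. Relative band powers implied by the generating
## parameters are recorded analytically as ground truth.

#' Build a simulation configuration
#'
#' Defaults encode the emulated study conditions: 56 participants without and
#' 17 with a concussion history, nine 60-second tasks at 256 Hz on a
#' 9-scalp-channel + 2-mastoid montage, a 10 uV RMS 1/f background, band
#' oscillator RMS amplitudes theta 4 / alpha 3 / gamma 2 uV, and a 25 percent
#' gamma-amplitude elevation in the concussion group on the four
#' visuo-motor-loaded tasks (PS, HRT, EHC, GNG), which lowers that group's
#' theta/gamma index. Between-participant amplitude variability is a
#' lognormal multiplier per band (sdlog 0.05).
#'
#' @param samplingRate Hz.
#' @param nNoConcussion,nConcussion group sizes.
#' @param taskDuration seconds per task (all nine tasks equal).
#' @param interTaskGap seconds of task-free recording between tasks.
#' @param backgroundSd RMS of the 1/f background per channel, uV.
#' @param backgroundExponent slope alpha of the 1/f^alpha background PSD.
#' @param thetaAmp,alphaAmp,gammaAmp baseline oscillator RMS amplitudes, uV.
#' @param concussionGammaFactor multiplicative gamma elevation for the
#'   concussion group on \code{concussionGammaTasks}.
#' @param concussionGammaTasks tasks carrying the group contrast.
#' @param bandAmplitudes optional full specification: named list with
#'   elements \code{none} and \code{concussion}, each a 9-task x 3-band
#'   matrix of RMS amplitudes; overrides the shortcut arguments.
#' @param subjectAmplitudeSd sdlog of the per-participant, per-band lognormal
#'   amplitude multiplier.
#' @param artifactRates events/minute for blink, EMG, spike, saturation.
#' @param railValue amplifier rail for saturation artifacts, uV.
#' @param seed master seed (integer).
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(taskDuration = 10, seed = 7)
#' cfg
#' @export
simulationConfig <- function(samplingRate = 256,
                             nNoConcussion = 56,
                             nConcussion = 17,
                             taskDuration = 60,
                             interTaskGap = 2,
                             backgroundSd = 10,
                             backgroundExponent = 1,
                             thetaAmp = 4, alphaAmp = 3, gammaAmp = 2,
                             concussionGammaFactor = 1.25,
                             concussionGammaTasks = c("PS", "HRT", "EHC", "GNG"),
                             bandAmplitudes = NULL,
                             subjectAmplitudeSd = 0.05,
                             artifactRates = c(blink = 4, EMG = 2,
                                               spike = 1, saturation = 0.5),
                             railValue = 1000,
                             seed = 1L) {
    bandFreqs <- c(theta = 5, alpha = 10, gamma = 35)
    if (is.null(bandAmplitudes)) {
        base <- matrix(rep(c(thetaAmp, alphaAmp, gammaAmp),
                           each = length(.TASK_NAMES)),
                       nrow = length(.TASK_NAMES),
                       dimnames = list(.TASK_NAMES, names(bandFreqs)))
        conc <- base
        conc[concussionGammaTasks, "gamma"] <-
            conc[concussionGammaTasks, "gamma"] * concussionGammaFactor
        bandAmplitudes <- list(none = base, concussion = conc)
    }
    rates <- c(blink = 0, EMG = 0, spike = 0, saturation = 0)
    rates[names(artifactRates)] <- artifactRates
    new("SimulationConfig",
        samplingRate = samplingRate,
        channelLabels = c(.SCALP_CHANNELS, .MASTOID_CHANNELS),
        nNoConcussion = as.integer(nNoConcussion),
        nConcussion = as.integer(nConcussion),
        taskNames = .TASK_NAMES,
        taskDuration = taskDuration,
        interTaskGap = interTaskGap,
        backgroundSd = backgroundSd,
        backgroundExponent = backgroundExponent,
        bandFreqs = bandFreqs,
        bandAmplitudes = bandAmplitudes,
        subjectAmplitudeSd = subjectAmplitudeSd,
        artifactRates = rates,
        railValue = railValue,
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d + %d participants, 9 x %g s tasks @ %g Hz, seed %d\n",
        object@nNoConcussion, object@nConcussion, object@taskDuration,
        object@samplingRate, object@seed))
})

## integral of f^-alpha over [lo, hi]
.pl_integral <- function(lo, hi, alpha) {
    if (abs(alpha - 1) < 1e-12) log(hi / lo)
    else (hi^(1 - alpha) - lo^(1 - alpha)) / (1 - alpha)
}

## analytic background power (uV^2) in [lo, hi] Hz for a 1/f^alpha process
## normalized to total variance sd^2 over [fmin, nyquist]
.background_band_power <- function(lo, hi, sd, alpha, fmin, nyq) {
    sd^2 * .pl_integral(lo, hi, alpha) / .pl_integral(fmin, nyq, alpha)
}

## analytic relative band powers over the 1-40 Hz analysis range for one
## task's oscillator amplitudes (already participant-scaled)
.analytic_truth <- function(amps, bandFreqs, sd, alpha, nyq) {
    edges <- lapply(.BAND_DEFS, function(b) c(min(b) - 0.5, max(b) + 0.5))
    bg <- vapply(edges, function(e)
        .background_band_power(e[1], e[2], sd, alpha, 0.5, nyq), 0)
    osc <- setNames(numeric(length(.BAND_DEFS)), names(.BAND_DEFS))
    for (bn in names(bandFreqs)) {
        target <- names(which(vapply(.BAND_DEFS, function(b)
            bandFreqs[[bn]] >= min(b) - 0.5 && bandFreqs[[bn]] < max(b) + 0.5,
            TRUE)))
        osc[target] <- osc[target] + amps[[bn]]^2
    }
    tot <- .background_band_power(0.5, 40.5, sd, alpha, 0.5, nyq) + sum(osc)
    (bg + osc) / tot
}

## shape white-noise columns into 1/f^alpha noise, sd-scaled per column
.shape_pink <- function(W, fs, sd, alpha) {
    n <- nrow(W)
    if (!ncol(W)) return(W)
    X <- stats::mvfft(W)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f <- pmin(f, fs - f)                     # two-sided frequency axis
    ## the background extends half an octave below the 0.5 Hz analysis edge
    ## so that tapered spectral estimates of bin 1 see balanced leakage
    shape <- numeric(n)
    pass <- f >= 0.125
    shape[pass] <- f[pass]^(-alpha / 2)
    Y <- Re(stats::mvfft(X * shape, inverse = TRUE)) / n
    sds <- sqrt(colMeans(Y^2) - colMeans(Y)^2)
    sweep(Y, 2L, sds, "/") * sd
}

#' Simulate one synthetic EEG session
#'
#' Generates a full nine-task recording for one participant: per-channel
#' 1/f background, band oscillators with per-epoch random phase on all scalp
#' channels, near-zero mastoid channels, and injected artifacts. The result
#' carries the task markers, the analytic relative band-power ground truth
#' per task, and the true artifact mask. Identical
#' \code{(config, group, participantSeed)} gives bit-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param group \code{"none"} or \code{"concussion"}.
#' @param participantSeed integer seed for this session.
#' @param participantId identifier stored in the session.
#' @param channels scalp channels to materialize (mastoids are always
#'   included). The default materializes the full montage. Restricting
#'   channels is a performance device for large simulation studies that
#'   analyze Fz only; the random-number stream, and hence every generated
#'   sample on the retained channels, is identical to the full-montage run.
#' @return A \linkS4class{SyntheticSession}.
#' @examples
#' cfg <- simulationConfig(taskDuration = 4, artifactRates = c(blink = 0))
#' ses <- simulateSession(cfg, "none", participantSeed = 11)
#' markers(ses)
#' @export
simulateSession <- function(config, group, participantSeed,
                            participantId = sprintf("P%06d", participantSeed),
                            channels = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    if (!group %in% names(config@bandAmplitudes))
        stop("unknown group label: ", group)
    if (config@taskDuration <= 0) stop("non-positive task duration")
    set.seed(as.integer(participantSeed))

    fs <- config@samplingRate
    pad <- as.integer(fs)                    # 1 s head/tail padding
    nT <- as.integer(round(config@taskDuration * fs))
    gap <- as.integer(round(config@interTaskGap * fs))
    nTask <- length(config@taskNames)
    N <- 2L * pad + nTask * nT + (nTask - 1L) * gap
    starts <- pad + (seq_len(nTask) - 1L) * (nT + gap)  # 0-based
    mk <- data.frame(task = config@taskNames,
                     start_sample = starts,
                     end_sample = starts + nT,
                     stringsAsFactors = FALSE)

    scalp <- if (is.null(channels)) .SCALP_CHANNELS else
        intersect(.SCALP_CHANNELS, channels)
    chans <- c(scalp, .MASTOID_CHANNELS)
    x <- matrix(0, length(chans), N, dimnames = list(chans, NULL))
    ## white noise is drawn for every scalp channel in montage order so the
    ## stream is invariant to the materialized subset
    W <- matrix(rnorm(N * length(.SCALP_CHANNELS)), N)
    colnames(W) <- .SCALP_CHANNELS
    x[scalp, ] <- t(.shape_pink(W[, scalp, drop = FALSE], fs,
                                config@backgroundSd,
                                config@backgroundExponent))
    for (ch in .MASTOID_CHANNELS)
        x[ch, ] <- rnorm(N, sd = 0.1)

    ## per-participant band amplitude multipliers
    mult <- exp(rnorm(length(config@bandFreqs), 0, config@subjectAmplitudeSd))
    names(mult) <- names(config@bandFreqs)

    amps <- config@bandAmplitudes[[group]]
    nEp <- nT %/% as.integer(fs)
    truth <- vector("list", nTask)
    for (ti in seq_len(nTask)) {
        task <- config@taskNames[ti]
        osc <- numeric(nT)
        tt <- seq_len(nT) - 1L
        for (bn in names(config@bandFreqs)) {
            A <- amps[task, bn] * mult[[bn]]
            if (A <= 0) next
            phases <- runif(ceiling(nT / fs)) * 2 * pi
            ph <- rep(phases, each = as.integer(fs))[seq_len(nT)]
            osc <- osc + sqrt(2) * A *
                sin(2 * pi * config@bandFreqs[[bn]] * tt / fs + ph)
        }
        cols <- (starts[ti] + 1L):(starts[ti] + nT)
        x[scalp, cols] <- sweep(x[scalp, cols, drop = FALSE], 2L, osc, "+")
        truth[[ti]] <- .analytic_truth(
            setNames(as.list(amps[task, ] * mult[names(config@bandFreqs)]),
                     colnames(amps)),
            config@bandFreqs, config@backgroundSd,
            config@backgroundExponent, fs / 2)
    }
    truth <- data.frame(task = config@taskNames,
                        do.call(rbind, truth),
                        stringsAsFactors = FALSE)

    inj <- .inject_artifacts(x, fs, config@artifactRates, config@railValue,
                             pad)
    new("SyntheticSession",
        recording = EEGRecording(inj$x, samplingRate = fs),
        markers = mk, truth = truth, truthMask = inj$mask,
        group = group, participantId = participantId)
}

## add artifact events in place; returns modified samples + truth mask.
## all random draws happen whether or not the target channel is
## materialized, so the stream is invariant to the channel subset.
.inject_artifacts <- function(x, fs, rates, rail, pad) {
    N <- ncol(x)
    mask <- matrix(FALSE, nrow(x), N, dimnames = dimnames(x))
    minutes <- N / fs / 60
    lo <- pad + 1L
    hi <- N - pad
    frontal <- c("Fz", "F3", "F4")
    emg_bp <- .cached_filter("emg_sim", fs, function()
        signal::butter(4, c(20, 100) / (fs / 2), type = "pass"))
    place <- function(len) {
        if (hi - len < lo) return(NA_integer_)
        as.integer(floor(runif(1, lo, hi - len)))
    }
    have <- rownames(x)
    for (class in names(rates)) {
        nEv <- stats::rpois(1, rates[[class]] * minutes)
        for (i in seq_len(nEv)) {
            switch(class,
                blink = {
                    L <- as.integer(round(0.4 * fs))
                    s <- place(L)
                    A <- runif(1, 100, 300)
                    if (is.na(s)) next
                    shape <- A * (1 - cos(2 * pi * seq(0, 1, length.out = L))) / 2
                    idx <- s:(s + L - 1L)
                    for (ch in intersect(frontal, have)) {
                        sc <- if (ch == "Fz") 1 else 0.8
                        x[ch, idx] <- x[ch, idx] + sc * shape
                        mask[ch, idx] <- TRUE
                    }
                },
                EMG = {
                    L <- as.integer(round(runif(1, 1, 3) * fs))
                    s <- place(L)
                    ch <- sample(.SCALP_CHANNELS, 1)
                    white <- rnorm(L + 2L * fs)
                    if (is.na(s) || !ch %in% have) next
                    burst <- signal::filtfilt(emg_bp, white)
                    burst <- burst[(fs + 1L):(fs + L)]
                    burst <- burst * 60 / stats::sd(burst)
                    idx <- s:(s + L - 1L)
                    x[ch, idx] <- x[ch, idx] + burst
                    mask[ch, idx] <- TRUE
                },
                spike = {
                    s <- place(1L)
                    ch <- sample(.SCALP_CHANNELS, 1)
                    sgn <- sample(c(-1, 1), 1)
                    if (is.na(s) || !ch %in% have) next
                    x[ch, s] <- x[ch, s] + sgn * 200
                    mask[ch, s] <- TRUE
                },
                saturation = {
                    L <- as.integer(round(0.5 * fs))
                    s <- place(L)
                    ch <- sample(.SCALP_CHANNELS, 1)
                    sgn <- sample(c(-1, 1), 1)
                    if (is.na(s) || !ch %in% have) next
                    idx <- s:(s + L - 1L)
                    x[ch, idx] <- sgn * rail
                    mask[ch, idx] <- TRUE
                })
        }
    }
    list(x = x, mask = mask)
}

#' Simulate a full cohort
#'
#' Draws one session per participant with per-participant seeds derived
#' deterministically from \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param channels scalp channels to materialize per session (see
#'   \code{\link{simulateSession}}).
#' @return A list with \code{sessions} (list of
#'   \linkS4class{SyntheticSession}) and \code{manifest} (\code{data.frame}
#'   with \code{participant_id}, \code{group}).
#' @examples
#' cfg <- simulationConfig(nNoConcussion = 2, nConcussion = 2,
#'     taskDuration = 4, seed = 3)
#' coh <- simulateCohort(cfg)
#' coh$manifest
#' @export
simulateCohort <- function(config, channels = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    n <- config@nNoConcussion + config@nConcussion
    groups <- c(rep("none", config@nNoConcussion),
                rep("concussion", config@nConcussion))
    set.seed(config@seed)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    ids <- sprintf("P%03d", seq_len(n))
    sessions <- vector("list", n)
    for (i in seq_len(n))
        sessions[[i]] <- simulateSession(config, groups[i], seeds[i], ids[i],
                                         channels = channels)
    list(sessions = sessions,
         manifest = data.frame(participant_id = ids, group = groups,
                               stringsAsFactors = FALSE))
}

#' Write a simulated cohort to disk
#'
#' One EDF plus one markers CSV and one ground-truth CSV per session, and a
#' cohort manifest CSV (\code{participant_id, group, edf_path,
#' markers_path, truth_path}).
#'
#' @param cohort result of \code{\link{simulateCohort}}.
#' @param dir output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    mf <- cohort$manifest
    mf$edf_path <- file.path(dir, paste0(mf$participant_id, ".edf"))
    mf$markers_path <- file.path(dir, paste0(mf$participant_id,
                                             "_markers.csv"))
    mf$truth_path <- file.path(dir, paste0(mf$participant_id, "_truth.csv"))
    for (i in seq_len(nrow(mf))) {
        ses <- cohort$sessions[[i]]
        writeEDF(recording(ses), mf$edf_path[i])
        writeMarkers(markers(ses), mf$markers_path[i])
        write.csv(groundTruth(ses), mf$truth_path[i], row.names = FALSE)
    }
    path <- file.path(dir, "manifest.csv")
    write.csv(mf, path, row.names = FALSE)
    invisible(path)
}
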