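# fixtures are built in code; nothing is read from disk

# single-channel recording holding a pure sinusoid
sineRecording <- function(freq, seconds = 20, fs = 256, amp = 1,
                          channel = "Fz") {
  t <- seq(0, seconds - 1 / fs, by = 1 / fs)
  x <- matrix(amp * sin(2 * pi * freq * t), nrow = 1,
              dimnames = list(channel, NULL))
  EEGRecording(x, fs)
}

# interior RMS, away from filtfilt edge transients
interiorRms <- function(rec, fs = samplingRate(rec)) {
  v <- samples(rec)[1, ]
  n <- length(v)
  sqrt(mean(v[(2 * fs):(n - 2 * fs)]^2))
}

# small simulation config used across tests
smallConfig <- function(seed = 7, ...) {
  simulationConfig(nNoConcussion = 3, nConcussion = 2, taskDuration = 4,
                   interTaskGap = 1, artifactRates = c(blink = 0),
                   seed = seed, ...)
}

# markers for a single ad-hoc task interval
oneTaskMarkers <- function(startSample, endSample, task = "VC") {
  data.frame(task = task, start_sample = startSample,
             end_sample = endSample, stringsAsFactors = FALSE)
}

# a synthetic overlay result with a prescribed zero count
fakeOverlay <- function(zeroCount, level = 1) {
  list(psd = setNames(rep(level, 40), 1:40), zeroCount = zeroCount,
       valid = zeroCount <= 128)
}
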