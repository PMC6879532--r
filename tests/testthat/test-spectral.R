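test_that("a bin-centered sinusoid concentrates its power", {
  ov <- overlayPSD(sin(2 * pi * 10 * (0:255) / 256))
  expect_equal(as.integer(names(which.max(ov$psd))), 10L)
  # taper main lobe spans the peak bin and its direct neighbors
  expect_gt(sum(ov$psd[9:11]) / sum(ov$psd), 0.95)
  # Parseval normalization: unit-RMS sinusoid -> unit total power,
  # irrespective of the taper shape
  for (beta in c(4, 8, 12)) {
    ov2 <- overlayPSD(sqrt(2) * sin(2 * pi * 10 * (0:255) / 256),
                      kaiserBeta = beta)
    expect_equal(sum(ov2$psd), 1, tolerance = 1e-4)
  }
  expect_error(overlayPSD(rnorm(100)), "exactly")
})

test_that("overlay zero-count rule rejects at exactly 129 inserted zeros", {
  set.seed(9)
  base <- rnorm(256) + 10
  for (zc in c(0, 1, 64, 127, 128)) {
    w <- base; if (zc > 0) w[seq_len(zc)] <- 0
    expect_true(overlayPSD(w)$valid, label = paste("zeros:", zc))
  }
  for (zc in c(129, 130, 200, 256)) {
    w <- base; w[seq_len(zc)] <- 0
    expect_false(overlayPSD(w)$valid, label = paste("zeros:", zc))
  }
  allzero <- overlayPSD(rep(0, 256))
  expect_equal(allzero$zeroCount, 256)
  expect_false(allzero$valid)
})

test_that("white-noise spectrum is flat on average", {
  set.seed(10)
  n <- 5000
  P <- matrix(0, 40, n)
  for (i in seq_len(n))
    P[, i] <- overlayPSD(rnorm(256))$psd
  m <- rowMeans(P)
  expect_lt(max(abs(m / mean(m) - 1)), 0.05)
})

test_that("epoch spectra follow the 2-of-3 rejection rule", {
  # all valid
  e <- epochSpectrum(list(fakeOverlay(0), fakeOverlay(10), fakeOverlay(128)))
  expect_true(e$valid); expect_equal(e$nOverlaysUsed, 3L)
  # one of three rejected: valid on the remaining two
  e2 <- epochSpectrum(list(fakeOverlay(200), fakeOverlay(0), fakeOverlay(0)))
  expect_true(e2$valid); expect_equal(e2$nOverlaysUsed, 2L)
  # two of three rejected: invalid even though one overlay survives
  e3 <- epochSpectrum(list(fakeOverlay(129), fakeOverlay(129),
                           fakeOverlay(10)))
  expect_false(e3$valid)
  # boundary epoch with two available overlays proceeds
  e4 <- epochSpectrum(list(fakeOverlay(0), fakeOverlay(0)))
  expect_true(e4$valid)
  # a single available overlay is not enough
  e5 <- epochSpectrum(list(fakeOverlay(0)))
  expect_false(e5$valid)
  expect_error(epochSpectrum(list()), "at least one")
})

test_that("relative bins conserve mass and ignore overall scale", {
  flat <- epochSpectrum(list(fakeOverlay(0), fakeOverlay(0)))
  expect_equal(unname(flat$relBins), rep(1 / 40, 40))
  set.seed(3)
  w <- rnorm(256) + 2
  ovs <- list(overlayPSD(w), overlayPSD(rev(w)), overlayPSD(w * 0.5))
  e <- epochSpectrum(ovs)
  expect_lt(abs(sum(e$relBins) - 1), 1e-9)
  scaled <- lapply(ovs, function(o) { o$psd <- o$psd * 7; o })
  expect_equal(epochSpectrum(scaled)$relBins, e$relBins)
})

test_that("band averages are means of their constituent bins", {
  flat <- setNames(rep(1 / 40, 40), 1:40)
  expect_equal(unname(bandAverage(flat)), rep(0.025, 5))
  ind5 <- setNames(c(rep(0, 4), 1, rep(0, 35)), 1:40)
  b <- bandAverage(ind5)
  expect_equal(b[["theta"]], 0.2)
  expect_equal(b[["gamma"]], 0)
  ind35 <- setNames(replace(rep(0, 40), 35, 1), 1:40)
  b2 <- bandAverage(ind35)
  expect_equal(b2[["gamma"]], 1 / 11)
  expect_equal(b2[["theta"]], 0)
  expect_error(bandAverage(list(valid = FALSE, relBins = flat)), "invalid")
})

test_that("task intervals tile into whole one-second epochs", {
  fs <- 256
  rec <- EEGRecording(rbind(Fz = rnorm(fs * 40)), fs)
  exact <- epochTasks(rec, oneTaskMarkers(0, fs * 10))
  expect_equal(nrow(exact), 10L)
  frac <- epochTasks(rec, oneTaskMarkers(0, round(fs * 10.7)))
  expect_equal(nrow(frac), 10L)                 # 0.7 s dropped
  expect_warning(sub <- epochTasks(rec, oneTaskMarkers(0, round(fs * 0.9))),
                 "shorter")
  expect_equal(nrow(sub), 0L)
  expect_error(epochTasks(rec, oneTaskMarkers(0, fs * 100)), "beyond")
})

test_that("bandTable agrees with composing the primitive operations", {
  set.seed(14)
  fs <- 256
  x <- rnorm(fs * 6, sd = 10) + 4 * sin(2 * pi * 5 * (0:(fs * 6 - 1)) / fs)
  rec <- EEGRecording(rbind(Fz = x), fs)
  mk <- oneTaskMarkers(fs, fs * 5)               # 4 epochs, offset start
  bt <- bandTable(rec, mk, channels = "Fz")
  for (e in seq_len(4)) {
    s0 <- fs + (e - 1) * fs                      # 0-based epoch start
    offs <- c(-128, 0, 128)
    ovs <- list()
    for (o in offs) {
      st <- s0 + o
      if (st >= fs && st + 256 <= fs * 5)
        ovs[[length(ovs) + 1]] <- overlayPSD(x[(st + 1):(st + 256)])
    }
    es <- epochSpectrum(ovs)
    expect_equal(bt$valid[e], es$valid)
    if (es$valid) {
      ba <- bandAverage(es)
      expect_equal(unlist(bt[e, c("theta", "alpha", "low_beta",
                                  "high_beta", "gamma")]),
                   ba, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
  # epoch bookkeeping: valid + invalid = tiled
  expect_equal(sum(bt$valid) + sum(!bt$valid), 4L)
})

test_that("epoch boundary overlays are clamped to the task interval", {
  set.seed(15)
  fs <- 256
  x <- rnorm(fs * 10) + 3
  rec <- EEGRecording(rbind(Fz = x), fs)
  bt <- bandTable(rec, oneTaskMarkers(0, fs * 3), channels = "Fz")
  expect_equal(bt$n_overlays, c(2L, 3L, 2L))
  one <- bandTable(rec, oneTaskMarkers(0, fs), channels = "Fz")
  expect_false(one$valid[1])                     # single overlay: invalid
})
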