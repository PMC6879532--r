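test_that("band-pass gain matches the designed response", {
  passb <- sineRecording(10)
  expect_lt(abs(interiorRms(bandpassFilter(passb)) /
                interiorRms(passb) - 1), 0.05)
  stopb <- sineRecording(0.1, seconds = 60)
  expect_lt(interiorRms(bandpassFilter(stopb)) / interiorRms(stopb), 0.10)
  # ~3 dB at both nominal edges
  for (f in c(0.5, 65)) {
    r <- sineRecording(f, seconds = 60)
    g <- interiorRms(bandpassFilter(r)) / interiorRms(r)
    expect_lt(abs(20 * log10(g) + 3), 0.3)
  }
  dc <- EEGRecording(rbind(Fz = rep(50, 256 * 20)), 256)
  out <- samples(bandpassFilter(dc))[1, (5 * 256):(15 * 256)]
  expect_lt(mean(abs(out)), 0.5)
  expect_error(bandpassFilter(sineRecording(5), 65, 0.5), "low < high")
})

test_that("notches attenuate the line and spare the neighborhood", {
  for (f0 in c(50, 60, 100, 120)) {
    for (df in c(-0.5, 0, 0.5)) {
      r <- sineRecording(f0 + df, seconds = 60)
      g <- interiorRms(notchFilter(r, f0)) / interiorRms(r)
      expect_lt(20 * log10(g), -20)
    }
    for (df in c(-5, 5)) {
      r <- sineRecording(f0 + df, seconds = 60)
      g <- interiorRms(notchFilter(r, f0)) / interiorRms(r)
      expect_lt(abs(20 * log10(g)), 1)
    }
  }
  r35 <- sineRecording(35, seconds = 30)
  g <- interiorRms(notchFilter(r35)) / interiorRms(r35)
  expect_lt(abs(20 * log10(g)), 1)
  expect_identical(notchFilter(r35, numeric()), r35)
  expect_error(notchFilter(r35, 130), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(4)
  x <- rnorm(256 * 8)
  r1 <- EEGRecording(rbind(Fz = x), 256)
  r5 <- EEGRecording(rbind(Fz = 5 * x), 256)
  expect_equal(5 * samples(bandpassFilter(r1)), samples(bandpassFilter(r5)),
               tolerance = 1e-6)
  expect_equal(5 * samples(notchFilter(r1)), samples(notchFilter(r5)),
               tolerance = 1e-6)
})

test_that("every injected artifact class is recalled at >= 90% of samples", {
  for (cls in c("blink", "EMG", "spike", "saturation")) {
    rates <- setNames(numeric(4), c("blink", "EMG", "spike", "saturation"))
    rates[cls] <- 6
    cfg <- simulationConfig(nNoConcussion = 2, nConcussion = 2,
                            taskDuration = 20, artifactRates = rates,
                            seed = 1)
    recall <- vapply(1:2, function(s) {
      ses <- simulateSession(cfg, "none", s)
      rec <- notchFilter(bandpassFilter(
        rereferenceLinkedMastoids(recording(ses))))
      dm <- artifactMask(detectArtifacts(rec))
      tm <- ses@truthMask[channelLabels(rec), ]
      sum(dm & tm) / max(1, sum(tm))
    }, 0)
    expect_true(all(recall >= 0.9),
                label = sprintf("%s recall %.3f", cls, min(recall)))
  }
})

test_that("clean recordings are almost never flagged", {
  cfg <- simulationConfig(nNoConcussion = 2, nConcussion = 2,
                          taskDuration = 20,
                          artifactRates = c(blink = 0), seed = 2)
  ses <- simulateSession(cfg, "none", 77)
  rec <- notchFilter(bandpassFilter(rereferenceLinkedMastoids(recording(ses))))
  m <- detectArtifacts(rec)
  expect_lt(mean(artifactMask(m)), 0.01)
  zero <- EEGRecording(rbind(Fz = rep(0, 2560)), 256)
  expect_equal(nrow(artifactEvents(detectArtifacts(zero))), 0L)
})

test_that("an isolated spike produces one localized spike event", {
  set.seed(11)
  n <- 256 * 20
  x <- rnorm(n, sd = 5)
  x[2560] <- x[2560] + 200
  rec <- notchFilter(bandpassFilter(EEGRecording(rbind(Cz = x), 256)))
  ev <- artifactEvents(detectArtifacts(rec))
  sp <- ev[ev$class == "spike", ]
  expect_gte(nrow(sp), 1L)
  # every spike event hugs the injected sample (filter ringing may split
  # the exceedance into a few nearby runs)
  expect_true(all(sp$start >= 2559 - 256 & sp$end <= 2560 + 256))
  expect_true(any(sp$start <= 2559 & sp$end >= 2560))  # 0-based, half-open
})

test_that("decontamination zeroes exactly the masked samples, idempotently", {
  set.seed(6)
  x <- rbind(Fz = rnorm(1000), Cz = rnorm(1000))
  rec <- EEGRecording(x, 256)
  m <- matrix(FALSE, 2, 1000, dimnames = list(c("Fz", "Cz"), NULL))
  expect_identical(samples(decontaminate(rec, m)), x)   # empty mask
  m[1, 101:300] <- TRUE
  out <- decontaminate(rec, m)
  expect_true(all(samples(out)[1, 101:300] == 0))
  expect_identical(samples(out)[1, -(101:300)], x[1, -(101:300)])
  expect_identical(samples(out)[2, ], x[2, ])           # bitwise untouched
  expect_identical(samples(decontaminate(out, m)), samples(out))
  full <- matrix(TRUE, 2, 1000, dimnames = dimnames(m))
  expect_true(all(samples(decontaminate(rec, full)) == 0))
  expect_error(decontaminate(rec, m[, 1:10]), "shape")
})

test_that("heavy contamination of an overlay rejects it downstream", {
  # 130 zeroed samples out of 256 crosses the >128 insertion rule
  set.seed(8)
  x <- rbind(Fz = rnorm(256 * 4) + 5)
  rec <- EEGRecording(x, 256)
  m <- matrix(FALSE, 1, ncol(x), dimnames = list("Fz", NULL))
  m[1, 257:(257 + 129)] <- TRUE            # 130 samples of epoch 2
  dec <- decontaminate(rec, m)
  ov <- overlayPSD(samples(dec)[1, 257:512])
  expect_equal(ov$zeroCount, 130)
  expect_false(ov$valid)
})
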