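# Synthetic polysomnography generator: determinism, injected waveform
# geometry, rate structure, spectral shape.

test_that("identical config and seed give bit-identical output", {
  cfg <- smallConfig(11, nChannels = 3, cycleMinutes = 4)
  a <- generateRecording(cfg)
  b <- generateRecording(cfg)
  expect_identical(signalMatrix(a$recording), signalMatrix(b$recording))
  expect_identical(stages(a$hypnogram), stages(b$hypnogram))
  expect_identical(a$groundTruth$slowWaveEvents, b$groundTruth$slowWaveEvents)
})

test_that("zero rates give empty ground truth and pure background", {
  cfg <- smallConfig(5, nChannels = 2, cycleMinutes = 4,
                     swRateCycle1 = 0, spindleProbability = 0)
  gen <- generateRecording(cfg)
  expect_identical(nrow(gen$groundTruth$slowWaveEvents), 0L)
  expect_identical(nrow(gen$groundTruth$spindleEvents), 0L)
  expect_equal(ncol(signalMatrix(gen$recording)),
               cfg$nCycles * cfg$cycleMinutes * 60 * cfg$samplingRate)
})

test_that("injected slow wave has the requested trough-to-peak delay", {
  x <- numeric(20 * SR)
  y <- injectSlowWave(x, tCenter = 10, tau = 0.2, amplitude = 100, sr = SR)
  delay <- which.max(y) - which.min(y)
  expect_lte(abs(delay - 0.2 * SR), 1)   # 51 +- 1 samples
  y4 <- injectSlowWave(x, tCenter = 10, tau = 0.4, amplitude = 100, sr = SR)
  expect_lte(abs((which.max(y4) - which.min(y4)) / SR - 0.4), 1 / SR)
  expect_identical(injectSlowWave(x, 10, 0.3, 0, SR), x)   # zero amplitude
  expect_error(injectSlowWave(x, 10, -0.1, 50, SR), "tau")
  expect_error(injectSlowWave(x, 19.9, 0.5, 50, SR), "fit")
})

test_that("waveform amplitudes satisfy the detection criteria space", {
  tpl <- slowWaveTemplate(0.4, 120, SR)
  expect_lt(min(tpl$samples), -40)
  expect_gt(max(tpl$samples) - min(tpl$samples), 75)
  expect_error(slowWaveTemplate(0.4, 120, SR, negDuration = 0.2,
                                posDuration = 0.3), "inconsistent")
})

test_that("background spectrum follows the configured 1/f slope", {
  cfg <- smallConfig(7, nChannels = 1, cycleMinutes = 4, swRateCycle1 = 0,
                     spindleProbability = 0, noiseExponent = 1)
  x <- signalMatrix(generateRecording(cfg)$recording)[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = SR), spans = 31,
                          plot = FALSE, taper = 0.1)
  sel <- sp$freq > 0.5 & sp$freq < 30
  slope <- stats::coef(stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel])))[2]
  expect_equal(unname(slope), -1, tolerance = 0.3)
})

test_that("per-cycle event counts follow the exponential rate structure", {
  nSeeds <- 20
  counts <- matrix(0, nSeeds, 3, dimnames = list(NULL, NULL))
  cfg0 <- NULL
  for (s in seq_len(nSeeds)) {
    cfg <- syntheticConfig(nChannels = 1, cycleMinutes = 8, swRateCycle1 = 4,
                           decayRateSlow = 0.8, decayRateFast = 0.8,
                           swAmplitude = 0, noiseSd = 0,
                           spindleProbability = 0, seed = 1000 + s)
    cfg0 <- cfg
    ev <- generateRecording(cfg)$groundTruth$slowWaveEvents
    counts[s, ] <- vapply(1:3, function(cy)
      length(unique(ev$event_id[ev$cycle == cy])), numeric(1))
  }
  hyp <- switchwave:::.blockHypnogram(cfg0)
  nremMin <- vapply(1:3, function(cy)
    sum(cleanNremEpochs(hyp) & cycleIndices(hyp) == cy) *
      epochLength(hyp) / 60, numeric(1))
  lambda <- 2 * cfg0$swRateCycle1 * nremMin * exp(-0.8 * (0:2))  # both classes
  tot <- colSums(counts)
  # pooled Poisson counts within 3 SD of expectation, monotone decreasing
  for (cy in 1:3) {
    expect_lt(abs(tot[cy] - nSeeds * lambda[cy]),
              3 * sqrt(nSeeds * lambda[cy]))
  }
  expect_true(all(diff(tot) < 0))
})

test_that("all ground-truth events lie inside artifact-free NREM epochs", {
  gen <- generateRecording(smallConfig(13, nChannels = 3, cycleMinutes = 6))
  hyp <- gen$hypnogram
  ev <- gen$groundTruth$slowWaveEvents
  clean <- cleanNremEpochs(hyp)
  epOf <- function(t) pmin(floor(t / epochLength(hyp)) + 1L, nEpochs(hyp))
  expect_true(all(clean[epOf(ev$neg_peak_time)]))
  expect_true(all(clean[epOf(ev$pos_peak_time)]))
  expect_true(all(ev$tau > 0))
})

test_that("the detector recovers injected waves with high recall", {
  gen <- generateRecording(smallConfig(21, nChannels = 4, cycleMinutes = 8))
  sr <- samplingRate(gen$recording)
  filt <- bandpassDelta(gen$recording)
  waves <- detectSlowWaves(filt, gen$hypnogram, sr)
  gt <- gen$groundTruth$slowWaveEvents
  hits <- vapply(seq_len(nrow(gt)), function(i) {
    any(waves$channel == gt$channel[i] &
        abs(waves$neg_peak_time - gt$neg_peak_time[i]) < 0.25)
  }, logical(1))
  recall <- mean(hits)
  expect_gte(recall, 0.9)
  # matched waves carry the planted transition delay
  m <- merge(waves, gt, by = "channel")
  m <- m[abs(m$neg_peak_time.x - m$neg_peak_time.y) < 0.2, ]
  expect_lt(median(abs(m$tau_s - m$tau)), 0.05)
})
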