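# Slow-wave detection criteria, equivariance and density.

detectOne <- function(...) {
  cw <- makeCandidateWave(...)
  detectSlowWaves(cw$x, allN2Hyp(30), SR)
}

test_that("a wave meeting all four criteria is detected with correct geometry", {
  cw <- makeCandidateWave(negDur = 0.4, posDur = 0.5, negAmp = -50, posAmp = 40)
  w <- detectSlowWaves(cw$x, allN2Hyp(30), SR)
  expect_identical(nrow(w), 1L)
  expect_equal(w$neg_duration, 0.4, tolerance = 0.01)
  expect_equal(w$pos_duration, 0.5, tolerance = 0.01)
  expect_equal(w$neg_peak_amp, -50, tolerance = 0.5)
  expect_equal(w$neg_peak_time, cw$negPeak, tolerance = 2 / SR)
  expect_equal(w$pos_peak_time, cw$posPeak, tolerance = 2 / SR)
  expect_equal(w$tau_s, cw$posPeak - cw$negPeak, tolerance = 2 / SR)
  expect_equal(w$f_tau_hz, 1 / (2 * w$tau_s))
  expect_equal(w$T_s, 0.9, tolerance = 0.01)
})

test_that("each criterion rejects on its own boundary", {
  # negative peak above -40 uV
  expect_identical(nrow(detectOne(negAmp = -35, posAmp = 55)), 0L)
  # peak-to-peak at 70 uV (< 75)
  expect_identical(nrow(detectOne(negAmp = -45, posAmp = 25)), 0L)
  # negative deflection too short (100 ms < 125 ms)
  expect_identical(nrow(detectOne(negDur = 0.1)), 0L)
  # negative deflection too long (> 1500 ms)
  expect_identical(nrow(detectOne(negDur = 1.6)), 0L)
  # positive deflection too long (1100 ms > 1000 ms)
  expect_identical(nrow(detectOne(posDur = 1.1)), 0L)
})

test_that("waves outside artifact-free N2/N3 epochs are excluded", {
  cw <- makeCandidateWave()
  hypW <- Hypnogram(rep("W", 1), epochLength = 30)
  expect_identical(nrow(detectSlowWaves(cw$x[1:(30 * SR)], hypW, SR)), 0L)
  hypArt <- Hypnogram(rep("N2", 1), artifact = TRUE, epochLength = 30)
  expect_identical(nrow(detectSlowWaves(cw$x[1:(30 * SR)], hypArt, SR)), 0L)
})

test_that("detection is translation-equivariant", {
  cw <- makeCandidateWave()
  k <- 64L
  x2 <- c(numeric(k), cw$x[1:(length(cw$x) - k)])
  w1 <- detectSlowWaves(cw$x, allN2Hyp(30), SR)
  w2 <- detectSlowWaves(x2, allN2Hyp(30), SR)
  expect_identical(nrow(w2), 1L)
  expect_equal(w2$neg_peak_time - w1$neg_peak_time, k / SR, tolerance = 1e-6)
  expect_equal(w2$pos_peak_time - w1$pos_peak_time, k / SR, tolerance = 1e-6)
  expect_equal(w2$tau_s, w1$tau_s, tolerance = 1e-6)
})

test_that("an unaligned hypnogram raises an error", {
  cw <- makeCandidateWave()
  expect_error(detectSlowWaves(cw$x, allN2Hyp(300), SR), "align")
})

test_that("low-amplitude background yields zero detections", {
  cfg <- smallConfig(3, nChannels = 2, cycleMinutes = 4, swRateCycle1 = 0,
                     spindleProbability = 0, noiseSd = 2)
  gen <- generateRecording(cfg)
  filt <- bandpassDelta(gen$recording)
  w <- detectSlowWaves(filt, gen$hypnogram, samplingRate(gen$recording))
  expect_identical(nrow(w), 0L)
})

test_that("every detected wave satisfies the type invariants", {
  gen <- generateRecording(smallConfig(17, nChannels = 3, cycleMinutes = 6))
  filt <- bandpassDelta(gen$recording)
  w <- detectSlowWaves(filt, gen$hypnogram, samplingRate(gen$recording))
  expect_gt(nrow(w), 20)
  expect_true(all(w$neg_peak_amp < -40))
  expect_true(all(w$pos_peak_amp - w$neg_peak_amp > 75))
  expect_true(all(w$neg_duration >= 0.125 & w$neg_duration <= 1.5))
  expect_true(all(w$pos_duration <= 1.0))
  expect_true(all(w$tau_s > 0))
  expect_equal(w$f_tau_hz, 1 / (2 * w$tau_s))
  expect_equal(w$frequency_hz, 1 / w$T_s)
})

test_that("slow-wave density is count per artifact-free NREM minute", {
  hyp <- Hypnogram(rep("N2", 120))   # 60 min
  waves <- data.frame(channel = rep("Fz", 120))
  expect_equal(unname(slowWaveDensity(waves, hyp)["Fz"]), 2.0)
  expect_equal(unname(slowWaveDensity(waves[0, , drop = FALSE], hyp)),
               numeric(0))
  hyp2 <- Hypnogram(rep("N2", 240))  # doubled NREM time halves density
  expect_equal(unname(slowWaveDensity(waves, hyp2)["Fz"]), 1.0)
  # cluster pooling
  wavesC <- data.frame(channel = c(rep("F3", 30), rep("Fz", 60), rep("F4", 30)))
  d <- slowWaveDensity(wavesC, hyp, clusters = list(frontal = c("F3", "Fz", "F4")))
  expect_equal(unname(d["frontal"]), 2.0)
  hypW <- Hypnogram(rep("W", 10))
  expect_error(slowWaveDensity(waves, hypW), "N2/N3")
})
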