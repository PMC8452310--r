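# Time-to-phase maps, transition metrics and phase-point sampling.

test_that("phase map of a sinusoidal wave matches the closed-form phase", {
  sw <- sinusoidWave(f = 1)
  pm <- computePhaseMap(sw$x, sw$wave, SR, prefiltered = TRUE)
  expect_true(pm@ok)
  expect_equal(pm@zeroTime, sw$wave$pos_peak_time, tolerance = 1 / SR)
  # phase 0 at the positive peak, -pi at the preceding negative peak
  atTime <- function(tt) approx(pm@times, pm@phases, xout = tt)$y
  expect_equal(atTime(sw$wave$pos_peak_time), 0, tolerance = 0.02)
  expect_equal(atTime(sw$wave$neg_peak_time), -pi, tolerance = 0.05)
  # closed form: phase advances linearly at 2*pi*f, anchored at the peak
  interior <- pm@times > sw$t0 + 0.05 & pm@times < sw$t0 + 1 / sw$f - 0.05
  expected <- 2 * pi * sw$f * (pm@times - sw$wave$pos_peak_time)
  expect_lt(max(abs(pm@phases[interior] - expected[interior])), 0.1)
  # phases are monotone and inside the admissible range
  expect_true(all(diff(pm@phases) >= 0))
  expect_true(all(pm@phases >= -3 * pi / 2 - 1e-9 & pm@phases <= pi / 2 + 1e-9))
})

test_that("phase maps are invariant to amplitude scaling", {
  sw <- sinusoidWave(A = 100)
  pm1 <- computePhaseMap(sw$x, sw$wave, SR, prefiltered = TRUE)
  pm2 <- computePhaseMap(5 * sw$x, sw$wave, SR, prefiltered = TRUE)
  expect_equal(pm1@phases, pm2@phases, tolerance = 1e-9)
})

test_that("a wave at the signal edge raises an error", {
  sw <- sinusoidWave(t0 = 0.2, seconds = 5)
  expect_error(computePhaseMap(sw$x, sw$wave, SR, prefiltered = TRUE), "edge")
})

test_that("transition delay and frequency follow their definitions", {
  w <- data.frame(neg_peak_time = 1.0, pos_peak_time = 1.3)
  expect_equal(transitionDelay(w), 0.3)
  expect_equal(transitionDelay(data.frame(neg_peak_time = 2, pos_peak_time = 2.5)),
               0.5)
  expect_error(transitionDelay(data.frame(neg_peak_time = 2, pos_peak_time = 1.5)))
  expect_equal(transitionFrequency(0.2), 2.5)
  expect_equal(transitionFrequency(0.5), 1.0)
  expect_equal(transitionFrequency(5 / 12), 1.2)
  expect_error(transitionFrequency(0), "positive")
  taus <- seq(0.05, 2, by = 0.05)
  expect_equal(transitionFrequency(taus) * 2 * taus, rep(1, length(taus)))
  expect_true(all(diff(transitionFrequency(taus)) < 0))
})

test_that("wave frequency is the inverse total duration", {
  expect_equal(waveFrequency(1.0), 1.0)
  expect_equal(waveFrequency(0.8), 1.25)
  expect_equal(waveFrequency(2.0), 0.5)
  expect_error(waveFrequency(0), "positive")
})

test_that("transition frequency equals wave frequency only for centred peaks", {
  # symmetric template: peaks at lobe centres, tau = T/2, so f_tau = 1/T
  hyp <- allN2Hyp(30)
  cw <- makeCandidateWave(negDur = 0.5, posDur = 0.5, negAmp = -60, posAmp = 50)
  w <- detectSlowWaves(cw$x, hyp, SR)
  expect_identical(nrow(w), 1L)
  expect_equal(w$f_tau_hz, w$frequency_hz, tolerance = 0.02)
  # skewed positive lobe: peak early in the lobe, tau < T/2, f_tau > 1/T
  n <- 30 * SR
  t <- (seq_len(n) - 1) / SR
  s0 <- 10; Ln <- 0.5; rise <- 0.1; fall <- 0.5
  u <- s0 + Ln; s1 <- u + rise + fall
  guard <- 0.3; eps <- 0.5
  xs <- numeric(n)
  pre <- t >= s0 - guard & t < s0
  xs[pre] <- eps * sin(pi * (s0 - t[pre]) / guard)
  neg <- t >= s0 & t < u
  xs[neg] <- -60 * sin(pi * (t[neg] - s0) / Ln)
  up <- t >= u & t < u + rise
  xs[up] <- 50 * sin(pi * (t[up] - u) / (2 * rise))
  dn <- t >= u + rise & t < s1
  xs[dn] <- 50 * cos(pi * (t[dn] - u - rise) / (2 * fall))
  post <- t >= s1 & t < s1 + guard
  xs[post] <- -eps * sin(pi * (t[post] - s1) / guard)
  ws <- detectSlowWaves(xs, hyp, SR)
  expect_identical(nrow(ws), 1L)
  expect_equal(ws$tau_s, Ln / 2 + rise, tolerance = 0.02)
  expect_gt(ws$f_tau_hz, 1.2 * ws$frequency_hz)
})

test_that("phase points are the six specification constants with correct times", {
  sw <- sinusoidWave(f = 1)
  pm <- computePhaseMap(sw$x, sw$wave, SR, prefiltered = TRUE)
  pts <- samplePhasePoints(pm)
  expect_identical(pts$label, c("a", "b", "c", "d", "e", "f"))
  expect_equal(pts$phase, c(-pi, -3 * pi / 4, -pi / 2, -pi / 4, 0, pi / 4))
  # time at phase 0 equals the positive peak time
  expect_equal(pts$time[pts$label == "e"], sw$wave$pos_peak_time,
               tolerance = 1.5 / SR)
  # linear phase of a sinusoid: the five transition points evenly spaced
  gaps <- diff(pts$time[1:5])
  expect_equal(gaps, rep(1 / sw$f / 8, 4), tolerance = 0.02)
  # a map not covering +pi/4 yields NA for phase f only
  short <- new("PhaseMap", times = pm@times[pm@phases <= 0.1],
               phases = pm@phases[pm@phases <= 0.1],
               zeroTime = pm@zeroTime, ok = TRUE)
  ptsS <- samplePhasePoints(short)
  expect_true(is.na(ptsS$time[ptsS$label == "f"]))
  expect_true(all(is.finite(ptsS$time[ptsS$label != "f"])))
})
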