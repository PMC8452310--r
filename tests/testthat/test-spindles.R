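# Spindle detection and slow-wave co-occurrence tagging.

# Sigma-band fixture whose upper envelope quartile is spindle-dominated, as
# on real NREM data: a train of background bursts covers > 25% of the
# recording so the 75th-percentile threshold sits above the noise floor,
# plus one target burst under test at t = 110 s.
sigmaFixture <- function(targetDuration = NULL, seconds = 120, noiseSd = 1,
                         seed = 99, amplitude = 20) {
  set.seed(seed)
  n <- seconds * SR
  x <- rnorm(n, sd = noiseSd)
  for (on in seq(2, 98, by = 3))
    x <- injectSpindle(x, on, 1, amplitude, SR)
  if (!is.null(targetDuration))
    x <- injectSpindle(x, 110, targetDuration, amplitude, SR)
  bandpassSigma(x, sr = SR)
}

targetEvents <- function(sp) sp[sp$onset > 105 & sp$onset < 118, , drop = FALSE]

test_that("an injected 13 Hz burst is detected with roughly its duration", {
  x <- sigmaFixture(targetDuration = 1)
  sp <- detectSpindles(x, allN2Hyp(120), SR)
  tg <- targetEvents(sp)
  expect_identical(nrow(tg), 1L)
  expect_equal(tg$duration, 1, tolerance = 0.4)
  expect_lt(abs(tg$onset - 110), 0.4)
  # the 33 background bursts are detected too
  expect_gte(nrow(sp), 30)
})

test_that("bursts outside the 0.5-3 s duration window are rejected", {
  tooShort <- sigmaFixture(targetDuration = 0.3)
  expect_identical(nrow(targetEvents(detectSpindles(tooShort, allN2Hyp(120),
                                                    SR))), 0L)
  # a long burst stays above threshold for more than the 3 s maximum
  tooLong <- sigmaFixture(targetDuration = 4.5)
  expect_identical(nrow(targetEvents(detectSpindles(tooLong, allN2Hyp(120),
                                                    SR))), 0L)
})

test_that("the percentile threshold makes detection scale-covariant", {
  x <- sigmaFixture(targetDuration = 2)
  a <- detectSpindles(x, allN2Hyp(120), SR)
  b <- detectSpindles(10 * x, allN2Hyp(120), SR)
  expect_equal(a$onset, b$onset)
  expect_equal(a$offset, b$offset)
  expect_equal(b$peak_envelope, 10 * a$peak_envelope, tolerance = 1e-9)
})

test_that("spindle detection requires artifact-free N2/N3 time", {
  x <- sigmaFixture(targetDuration = 1)
  hypW <- Hypnogram(rep("W", 4), epochLength = 30)
  expect_error(detectSpindles(x, hypW, SR), "N2/N3")
})

test_that("co-occurrence follows the wave-phase window of the spindle onset", {
  sw <- sinusoidWave()
  phaseSig <- matrix(sw$x, nrow = 1, dimnames = list("ch1", NULL))
  waves <- sw$wave
  waves$has_spindle <- NA
  P <- 1 / sw$f
  # onset at the wave's midpoint up-crossing: phase -pi/2, inside [-pi, pi/2]
  spIn <- data.frame(channel = "ch1", onset = sw$t0 + P / 2, offset = sw$t0 + 1)
  tagged <- tagCooccurrence(waves, spIn, phaseSig, SR)
  expect_true(tagged$has_spindle)
  # onset just after the wave start: phase near -3*pi/2, outside the window
  spOut <- data.frame(channel = "ch1", onset = sw$t0 + 0.02,
                      offset = sw$t0 + 0.5)
  expect_false(tagCooccurrence(waves, spOut, phaseSig, SR)$has_spindle)
  # no spindles at all
  none <- tagCooccurrence(waves, spIn[0, , drop = FALSE], phaseSig, SR)
  expect_false(none$has_spindle)
  # other-channel spindles do not count
  spOther <- data.frame(channel = "ch2", onset = sw$t0 + P / 2,
                        offset = sw$t0 + 1)
  expect_false(tagCooccurrence(waves, spOther, phaseSig, SR)$has_spindle)
  expect_error(tagCooccurrence(waves, spIn, NULL, SR), "phaseSignal")
})
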