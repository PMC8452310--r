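# Shared fixtures, built in code at test time.

SR <- 256

# Hypnogram of all-N2 clean epochs covering n seconds.
allN2Hyp <- function(seconds, cycle = 1L) {
  n <- ceiling(seconds / 30)
  Hypnogram(rep("N2", n), cycleIndex = rep(cycle, n))
}

# A single candidate wave embedded so that its zero crossings delimit it
# exactly: a small positive ramp closes a down-crossing at the wave start
# and a small negative ramp after the positive lobe closes the candidate.
# Returns the signal and the nominal geometry.
makeCandidateWave <- function(sr = SR, negDur = 0.4, posDur = 0.5,
                              negAmp = -50, posAmp = 40, pad = 2,
                              guard = 0.3, eps = 0.5, seconds = 30) {
  n <- round(seconds * sr)
  t <- (seq_len(n) - 1) / sr
  s0 <- pad + guard              # wave start (down-crossing)
  u <- s0 + negDur               # up-crossing
  s1 <- u + posDur               # wave end (down-crossing)
  x <- numeric(n)
  pre <- t >= s0 - guard & t < s0
  x[pre] <- eps * sin(pi * (s0 - t[pre]) / guard)
  neg <- t >= s0 & t < u
  x[neg] <- negAmp * sin(pi * (t[neg] - s0) / negDur)
  pos <- t >= u & t < s1
  x[pos] <- posAmp * sin(pi * (t[pos] - u) / posDur)
  post <- t >= s1 & t < s1 + guard
  x[post] <- -eps * sin(pi * (t[post] - s1) / guard)
  list(x = x, s0 = s0, u = u, s1 = s1,
       negPeak = s0 + negDur / 2, posPeak = u + posDur / 2)
}

# Single-cycle sinusoidal "slow wave": -A*sin(2*pi*f*(t - t0)) over one
# period, with the wave row describing it for phase-map tests.
sinusoidWave <- function(sr = SR, f = 1, A = 100, t0 = 10, seconds = 30) {
  n <- round(seconds * sr)
  t <- (seq_len(n) - 1) / sr
  x <- -A * sin(2 * pi * f * (t - t0))
  P <- 1 / f
  wave <- data.frame(channel = "ch1", start_s = t0, end_s = t0 + P,
                     neg_peak_time = t0 + P / 4, pos_peak_time = t0 + 3 * P / 4,
                     tau_s = P / 2, f_tau_hz = f, T_s = P)
  list(x = x, wave = wave, f = f, t0 = t0)
}

# Small, fast synthetic config for pipeline-level tests.
smallConfig <- function(seed, nChannels = 4, cycleMinutes = 6, ...) {
  syntheticConfig(nChannels = nChannels, cycleMinutes = cycleMinutes,
                  seed = seed, ...)
}

# Seeded bimodal transition-frequency sample: 0.55 N(0.9, 0.2^2) +
# 0.45 N(1.8, 0.35^2) Hz, truncated to positive support.
bimodalSample <- function(n = 2000, seed = 42, w = 0.55,
                          mu = c(0.9, 1.8), s = c(0.2, 0.35)) {
  set.seed(seed)
  n1 <- rbinom(1, n, w)
  x <- c(rnorm(n1, mu[1], s[1]), rnorm(n - n1, mu[2], s[2]))
  x[x > 0.05]
}
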