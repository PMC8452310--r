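# Gaussian mixture fitting, AIC model selection, crossing frequency and
# wave labeling.

test_that("a single component reduces to the closed-form MLE", {
  set.seed(3)
  x <- rnorm(500, 1.2, 0.3)
  fit <- fitMixture(x, k = 1)
  expect_equal(mixtureMeans(fit), mean(x))
  expect_equal(mixtureSds(fit), sqrt(mean((x - mean(x))^2)))
  expect_equal(mixtureWeights(fit), 1)
})

test_that("EM recovers the generating parameters of a bimodal sample", {
  x <- bimodalSample()
  fit <- fitMixture(x, k = 2, seed = 7)
  expect_lt(abs(mixtureMeans(fit)[1] - 0.9), 0.05)
  expect_lt(abs(mixtureMeans(fit)[2] - 1.8), 0.05)
  expect_lt(abs(mixtureWeights(fit)[1] - 0.55), 0.05)
  expect_lt(abs(sum(mixtureWeights(fit)) - 1), 1e-9)
  expect_true(mixtureMeans(fit)[1] < fStar(fit) &
              fStar(fit) < mixtureMeans(fit)[2])
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  x <- bimodalSample(n = 600, seed = 9)
  set.seed(1)
  res <- switchwave:::.emOnce(x, 2, maxIter = 200, tol = 1e-8,
                              varFloor = 1e-4)
  expect_true(all(diff(res$llTrace) > -1e-8))
})

test_that("EM agrees with an independent mixture implementation", {
  library(mclust)
  x <- bimodalSample(seed = 11)
  fit <- fitMixture(x, k = 2, seed = 3)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(mc$parameters$mean)), mixtureMeans(fit),
               tolerance = 0.02)
  ord <- order(mc$parameters$mean)
  expect_equal(as.numeric(mc$parameters$pro[ord]), mixtureWeights(fit),
               tolerance = 0.02)
})

test_that("AIC selects two components on bimodal and one on unimodal samples", {
  kB <- selectComponents(bimodalSample(seed = 5), kMax = 3, seed = 2)
  expect_identical(as.integer(kB), 2L)
  set.seed(6)
  xu <- rnorm(2000, 1.2, 0.3)
  kU <- selectComponents(xu[xu > 0], kMax = 3, seed = 2)
  expect_identical(as.integer(kU), 1L)
  expect_identical(as.integer(selectComponents(bimodalSample(seed = 5),
                                               kMax = 1, seed = 2)), 1L)
  aic <- attr(kB, "aicByK")
  expect_identical(names(aic), c("1", "2", "3"))
})

test_that("input contracts are enforced", {
  expect_error(fitMixture(rnorm(10, 1, 0.1), k = 2), "at least")
  expect_error(fitMixture(c(rep(1, 60), -1), k = 2), "positive")
})

test_that("the crossing frequency solves the weighted density equation", {
  # equal weights and sds: the crossing is the midpoint
  expect_equal(crossingFrequency(weights = c(0.5, 0.5), means = c(1, 2),
                                 sds = c(0.3, 0.3)), 1.5)
  # general case against a dense grid-search oracle
  w <- c(0.6, 0.4); mu <- c(0.9, 1.8); s <- c(0.2, 0.35)
  fs <- crossingFrequency(weights = w, means = mu, sds = s)
  grid <- seq(mu[1], mu[2], by = 1e-4)
  oracle <- grid[which.min(abs(w[1] * dnorm(grid, mu[1], s[1]) -
                               w[2] * dnorm(grid, mu[2], s[2])))]
  expect_lt(abs(fs - oracle), 2e-4)
  # translation equivariance in the symmetric case
  f1 <- crossingFrequency(weights = c(0.5, 0.5), means = c(1, 2),
                          sds = c(0.25, 0.25))
  f2 <- crossingFrequency(weights = c(0.5, 0.5), means = c(1.5, 2.5),
                          sds = c(0.25, 0.25))
  expect_equal(f2 - f1, 0.5)
  expect_error(crossingFrequency(weights = c(0.5, 0.5), means = c(1, 1),
                                 sds = c(0.3, 0.3)), "identical")
})

test_that("labeling rule and density-ratio definition coincide", {
  x <- bimodalSample(seed = 13)
  fit <- fitMixture(x, k = 2, seed = 5)
  w <- mixtureWeights(fit); mu <- mixtureMeans(fit); s <- mixtureSds(fit)
  fs <- fStar(fit)
  grid <- seq(mu[1] + 1e-3, mu[2] - 1e-3, length.out = 400)
  slowDominates <- w[1] * dnorm(grid, mu[1], s[1]) >=
                   w[2] * dnorm(grid, mu[2], s[2])
  expect_identical(slowDominates, grid < fs)
})

test_that("waves are labeled by strict comparison with f*", {
  waves <- data.frame(f_tau_hz = c(1.0, 2.0, 1.2))
  lab <- classifyWaves(waves, 1.2)
  expect_identical(lab$switcher, c("slow", "fast", "fast"))  # tie is fast
  expect_error(classifyWaves(data.frame(f_tau_hz = c(1, NA)), 1.2))
})

test_that("switcher probability is the slow fraction and tracks the weight", {
  waves <- data.frame(switcher = c(rep("slow", 60), rep("fast", 40)))
  expect_equal(switcherProbability(waves), 0.6)
  expect_equal(switcherProbability(data.frame(switcher = rep("slow", 5))), 1.0)
  expect_error(switcherProbability(data.frame(switcher = character())))
  # Monte-Carlo consistency with the mixture weight on a large sample
  x <- bimodalSample(n = 4000, seed = 21)
  fit <- fitMixture(x, k = 2, seed = 2)
  lab <- classifyWaves(data.frame(f_tau_hz = x), fStar(fit))
  expect_lt(abs(switcherProbability(lab) - mixtureWeights(fit)[1]), 0.04)
})
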