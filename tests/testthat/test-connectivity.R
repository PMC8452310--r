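# Phase-lag-index connectivity: directed pli, symmetrization, null
# threshold and global connectivity index.

test_that("directed pli matches its definition on basic lag structures", {
  phi <- runif(50, -pi, pi)
  expect_equal(eventPli(phi, phi), 0)            # zero lag is invisible
  expect_equal(eventPli(phi, phi - pi / 4), 1)   # constant positive lag
  expect_equal(eventPli(phi, phi + pi / 4), -1)
  # brute-force sign-sum oracle on a four-event instance
  d <- c(pi / 4, pi / 4, -pi / 4, -pi / 4)
  expect_equal(eventPli(rep(0, 4), -d), (1 + 1 - 1 - 1) / 4)
})

test_that("pli agrees with a brute-force oracle on small random instances", {
  set.seed(31)
  for (rep in 1:25) {
    N <- sample(2:10, 1)
    a <- runif(N, -pi, pi)
    b <- runif(N, -pi, pi)
    acc <- 0
    for (k in seq_len(N)) acc <- acc + sign(sin(a[k] - b[k]))
    expect_equal(eventPli(a, b), acc / N)
    expect_lte(abs(eventPli(a, b)), 1)
    # invariant under common phase offsets; antisymmetric under swap
    off <- runif(1, -pi, pi)
    expect_equal(eventPli(a + off, b + off), eventPli(a, b), tolerance = 1e-9)
    expect_equal(eventPli(b, a), -eventPli(a, b), tolerance = 1e-12)
  }
})

test_that("symmetrization averages the directions and handles gaps", {
  expect_equal(symmetrizePli(0.6, 0.4), 0.5)
  expect_equal(symmetrizePli(1, 1), 1)
  expect_equal(symmetrizePli(0.7, -0.7), 0)
  expect_equal(symmetrizePli(NA, 0.4), 0.4)
  expect_equal(symmetrizePli(0.6, NA), 0.6)
})

test_that("true propagation with constant delay reinforces across directions", {
  set.seed(8)
  N <- 200
  phiA <- runif(N, -pi, pi)
  lag <- 0.4
  datA <- cbind(A = phiA, B = phiA - lag)          # B lags A
  datB <- cbind(A = phiA, B = phiA - lag)
  pd <- list(A = datA, B = datB)
  D <- directedPliMatrix(pd)
  expect_equal(D["A", "B"], 1)
  expect_equal(D["B", "A"], -1)
  S <- symmetricPliMatrix(D)
  expect_equal(S["A", "B"], 1)
  expect_equal(S["A", "B"], S["B", "A"])
  expect_equal(diag(S), c(A = 0, B = 0))
})

test_that("the max-statistics threshold separates planted lag from noise", {
  set.seed(15)
  N <- 200
  channels <- c("A", "B", "C", "D")
  # A and B share a constant lag; C and D are independent phases
  phiA <- runif(N, -pi, pi)
  mkmat <- function() cbind(A = phiA, B = phiA - 0.5,
                            C = runif(N, -pi, pi), D = runif(N, -pi, pi))
  pd <- list(A = mkmat(), B = mkmat(), C = mkmat(), D = mkmat())
  D <- directedPliMatrix(pd)
  S <- symmetricPliMatrix(D)
  thr <- nullThreshold(pd, nPerm = 300, p = 0.01, seed = 4)
  expect_gt(abs(S["A", "B"]), thr)      # planted pair exceeds threshold
  mask <- abs(S) > thr; diag(mask) <- FALSE
  expect_false(mask["C", "D"])          # independent pair does not
  gciVal <- globalConnectivityIndex(S, mask)
  expect_gte(gciVal, abs(S["A", "B"]))
})

test_that("observed values below threshold give an empty mask and zero gci", {
  set.seed(22)
  N <- 40
  channels <- c("A", "B", "C")
  mk <- function() {
    m <- cbind(runif(N, -pi, pi), runif(N, -pi, pi), runif(N, -pi, pi))
    colnames(m) <- channels
    m
  }
  pd <- list(A = mk(), B = mk(), C = mk())
  S <- symmetricPliMatrix(directedPliMatrix(pd))
  thr <- nullThreshold(pd, nPerm = 400, p = 0.01, seed = 6)
  mask <- abs(S) > thr; diag(mask) <- FALSE
  expect_false(any(mask))
  expect_equal(globalConnectivityIndex(S, mask), 0)
})

test_that("the global connectivity index sums |PLI| over significant pairs", {
  S <- matrix(0, 3, 3)
  S[1, 2] <- S[2, 1] <- 0.5
  S[1, 3] <- S[3, 1] <- -0.3
  mask0 <- matrix(FALSE, 3, 3)
  expect_equal(globalConnectivityIndex(S, mask0), 0)
  mask2 <- mask0; mask2[1, 2] <- mask2[2, 1] <- TRUE
  mask3 <- mask2; mask3[1, 3] <- mask3[3, 1] <- TRUE
  expect_equal(globalConnectivityIndex(S, mask2), 0.5)
  expect_equal(globalConnectivityIndex(S, mask3), 0.8)   # adding a pair grows it
})

test_that("nullThreshold requires a seed and warns on few permutations", {
  pd <- list(A = cbind(A = runif(25, -pi, pi), B = runif(25, -pi, pi)))
  expect_error(nullThreshold(pd, nPerm = 200, p = 0.01), "seed")
  expect_warning(nullThreshold(pd, nPerm = 50, p = 0.01, seed = 1), "perm")
})
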