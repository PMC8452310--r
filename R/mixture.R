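# Gaussian mixture modelling of the transition-frequency distribution.
#
# The per-subject distribution of transition frequencies is modelled as a
# weighted sum of Gaussians fitted by EM; the Akaike information criterion
# selects the number of components (two on real sleep data: slow and fast
# switchers), and the crossing frequency f* of the two weighted component
# densities is the classification boundary.

.mixLogLik <- function(x, w, mu, sd) {
  dens <- vapply(seq_along(w), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                 numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}

# k-means++-style initial means: first centre uniform, later centres drawn
# with probability proportional to squared distance from the nearest centre.
.kppInit <- function(x, k) {
  centres <- numeric(k)
  centres[1] <- x[sample.int(length(x), 1L)]
  if (k > 1L) for (j in 2L:k) {
    d2 <- vapply(x, function(xi) min((xi - centres[1:(j - 1L)])^2), numeric(1))
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / length(x), length(x))
    centres[j] <- x[sample.int(length(x), 1L, prob = p)]
  }
  sort(centres)
}

.emOnce <- function(x, k, maxIter, tol, varFloor) {
  n <- length(x)
  mu <- .kppInit(x, k)
  assign <- apply(abs(outer(x, mu, "-")), 1L, which.min)
  w <- as.numeric(tabulate(assign, k)) / n
  w[w <= 0] <- 1 / n
  w <- w / sum(w)
  sd <- vapply(seq_len(k), function(j) {
    xi <- x[assign == j]
    s <- if (length(xi) > 1L) stats::sd(xi) else stats::sd(x) / k
    max(s, sqrt(varFloor))
  }, numeric(1))
  ll <- -Inf
  llTrace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    # E step
    resp <- vapply(seq_len(k), function(j) w[j] * stats::dnorm(x, mu[j], sd[j]),
                   numeric(n))
    if (is.null(dim(resp))) resp <- matrix(resp, nrow = n)
    rs <- rowSums(resp)
    rs[rs == 0] <- .Machine$double.xmin
    resp <- resp / rs
    # M step
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sd <- sqrt(pmax(colSums(resp * (outer(x, mu, "-")^2)) / nk, varFloor))
    llNew <- .mixLogLik(x, w, mu, sd)
    llTrace <- c(llTrace, llNew)
    # relative convergence: gain small compared to the log-likelihood scale
    if (is.finite(ll) && llNew - ll < tol * max(1, abs(llNew))) {
      converged <- TRUE; ll <- llNew; break
    }
    ll <- llNew
  }
  ord <- order(mu)
  list(w = w[ord] / sum(w), mu = mu[ord], sd = sd[ord], logLik = ll,
       converged = converged, iterations = iter, llTrace = llTrace)
}

#' Fit a Gaussian mixture to transition frequencies by EM
#'
#' Maximum-likelihood fit of a `k`-component Gaussian mixture via
#' expectation-maximization with k-means++-style initialization, multiple
#' restarts, a variance floor against degenerate spikes, and convergence on
#' the log-likelihood gain. Components are returned sorted by mean; for
#' `k = 2` the crossing frequency f* of the two weighted densities is
#' computed (see [crossingFrequency()]). `k = 1` reduces to the closed-form
#' sample MLE.
#'
#' @param x transition frequencies in Hz (finite, positive).
#' @param k number of components.
#' @param minN minimum sample size accepted.
#' @param nRestarts EM restarts; the best log-likelihood wins.
#' @param maxIter maximum EM iterations per restart.
#' @param tol convergence threshold on the log-likelihood gain (nats).
#' @param varFloor variance floor in Hz^2.
#' @param seed optional RNG seed for the restarts (caller RNG restored).
#' @return a [SwitcherMixture] object.
#' @examples
#' set.seed(7)
#' x <- c(rnorm(300, 0.9, 0.2), rnorm(200, 1.8, 0.35))
#' fitMixture(x, k = 2, seed = 1)
#' @export
fitMixture <- function(x, k = 2, minN = 50, nRestarts = 10, maxIter = 3000,
                       tol = 1e-6, varFloor = 1e-4, seed = NULL) {
  x <- as.numeric(x)
  if (length(x) < minN)
    stop("need at least ", minN, " transition-frequency values, got ", length(x))
  if (any(!is.finite(x)) || any(x <= 0))
    stop("transition frequencies must be finite and positive")
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) {
    mu <- mean(x)
    sd <- sqrt(mean((x - mu)^2))   # MLE (1/n) variance
    ll <- .mixLogLik(x, 1, mu, sd)
    return(new("SwitcherMixture", weights = 1, means = mu, sds = sd,
               fStar = NA_real_, logLik = ll,
               aicByK = stats::setNames(2 * 2 - 2 * ll, "1"),
               nObs = length(x), iterations = 0L))
  }
  best <- with_seed(seed, {
    fits <- lapply(seq_len(nRestarts), function(r)
      .emOnce(x, k, maxIter, tol, varFloor))
    fits[[which.max(vapply(fits, `[[`, numeric(1), "logLik"))]]
  })
  if (!best$converged)
    stop("EM did not converge in ", maxIter, " iterations; ",
         "final log-likelihood gain ",
         format(diff(utils::tail(best$llTrace, 2))), " nats")
  fStar <- if (k == 2L)
    tryCatch(crossingFrequency(weights = best$w, means = best$mu,
                               sds = best$sd),
             error = function(e) NA_real_)
  else NA_real_
  nPar <- 3 * k - 1
  new("SwitcherMixture", weights = best$w, means = best$mu, sds = best$sd,
      fStar = fStar, logLik = best$logLik,
      aicByK = stats::setNames(2 * nPar - 2 * best$logLik, as.character(k)),
      nObs = length(x), iterations = best$iterations)
}

#' Select the number of mixture components by AIC
#'
#' Fits mixtures with 1 to `kMax` components, computes
#' `AIC = 2 * (free parameters) - 2 * logLik` (a k-component Gaussian
#' mixture has `3k - 1` free parameters), and returns the smallest
#' component count whose AIC lies within `sparsityDelta` of the minimum:
#' the lower the criterion with a sparse decomposition, the better. The
#' default band of 2 AIC units is the conventional equivalence range
#' within which models are considered interchangeable, in which case the
#' sparser decomposition wins; `sparsityDelta = 0` gives the plain argmin.
#' On sleep transition-frequency distributions two components are
#' necessary and sufficient; the AIC trace is attached as attribute
#' `"aicByK"`.
#'
#' @inheritParams fitMixture
#' @param kMax largest component count considered.
#' @param sparsityDelta AIC-units band for preferring sparser models.
#' @return integer: the selected k, with attribute `aicByK`.
#' @export
selectComponents <- function(x, kMax = 5, minN = 50, nRestarts = 10,
                             maxIter = 3000, tol = 1e-6, varFloor = 1e-4,
                             sparsityDelta = 2, seed = NULL) {
  aic <- vapply(seq_len(kMax), function(k) {
    fit <- fitMixture(x, k = k, minN = minN, nRestarts = nRestarts,
                      maxIter = maxIter, tol = tol, varFloor = varFloor,
                      seed = if (is.null(seed)) NULL else splitSeed(seed, k))
    unname(fit@aicByK)
  }, numeric(1))
  names(aic) <- as.character(seq_len(kMax))
  k <- min(which(aic <= min(aic) + sparsityDelta))
  structure(as.integer(k), aicByK = aic)
}

#' Crossing frequency of the two weighted Gaussian components
#'
#' Solves `w1 * g1(f) = w2 * g2(f)` analytically (a quadratic in f after
#' taking logs) and returns the root lying strictly between the component
#' means: the separation line between slow and fast switchers.
#'
#' @param model a two-component [SwitcherMixture]; alternatively pass
#'   `weights`, `means` and `sds` directly.
#' @param weights,means,sds mixture parameters (two components, means
#'   increasing) used when `model` is missing.
#' @return f* in Hz.
#' @examples
#' crossingFrequency(weights = c(0.5, 0.5), means = c(1, 2), sds = c(0.3, 0.3))
#' @export
crossingFrequency <- function(model, weights, means, sds) {
  if (!missing(model)) {
    weights <- model@weights; means <- model@means; sds <- model@sds
  }
  if (length(means) != 2L)
    stop("crossing frequency is defined for a two-component mixture")
  if (abs(means[1] - means[2]) < 1e-12 && abs(sds[1] - sds[2]) < 1e-12)
    stop("identical components have no crossing frequency")
  m1 <- means[1]; m2 <- means[2]
  s1 <- sds[1]; s2 <- sds[2]
  w1 <- weights[1]; w2 <- weights[2]
  # (f-m1)^2/(2 s1^2) - (f-m2)^2/(2 s2^2) = log(w1 s2 / (w2 s1))
  a <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  b <- m2 / s2^2 - m1 / s1^2
  cc <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) - log(w1 * s2 / (w2 * s1))
  roots <- if (abs(a) < 1e-14) {
    if (abs(b) < 1e-14) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) numeric(0)
    else c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
  }
  inside <- roots[roots > m1 & roots < m2]
  if (!length(inside))
    stop("no crossing of the weighted densities between the component means")
  inside[1]
}

#' Label slow waves as slow or fast switchers
#'
#' A wave is a slow switcher when its transition frequency lies strictly
#' below the subject's crossing frequency f*, and a fast switcher otherwise
#' (ties at `f_tau == f*` are fast).
#'
#' @param waves data.frame with column `f_tau_hz`.
#' @param fStar crossing frequency in Hz (from the subject's own fit).
#' @return `waves` with the `switcher` column set to `"slow"`/`"fast"`.
#' @export
classifyWaves <- function(waves, fStar) {
  if (!is.finite(fStar)) stop("fStar must be a finite frequency")
  if (is.null(waves$f_tau_hz) || any(!is.finite(waves$f_tau_hz)))
    stop("all waves need a finite transition frequency before labeling")
  waves$switcher <- ifelse(waves$f_tau_hz < fStar, "slow", "fast")
  waves
}

#' Probability of producing a slow switcher
#'
#' Fraction of labeled waves that are slow switchers; on large samples this
#' matches the mixture weight of the slow component up to sampling error.
#'
#' @param waves data.frame with a filled `switcher` column.
#' @return numeric in `[0, 1]`.
#' @export
switcherProbability <- function(waves) {
  if (!nrow(waves)) stop("no labeled waves")
  if (any(!waves$switcher %in% c("slow", "fast")))
    stop("waves must be labeled before computing switcher probability")
  mean(waves$switcher == "slow")
}
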