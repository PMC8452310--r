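# Across-cycle modulation of the switcher classes.
#
# The per-cycle percentage of each switcher class is its event count in the
# cycle relative to the class total across the night. The decline over the
# first cycles is modelled as an exponential decay a*exp(-r*t) or an
# exponential reduction a - b*exp(r*t), with the 1-based cycle index as
# time t. Fits are least squares with the amplitude parameters profiled
# out (solved linearly for fixed r) and a one-dimensional optimization
# over the rate, which is exact on noise-free model-generated data.

#' Per-cycle percentages of each switcher class
#'
#' For class c and cycle j: `100 * count(c, j) / count(c, all cycles)`.
#' Percentages of a class sum to 100 over the cycles of the night.
#'
#' @param waves data.frame of labeled waves (columns `switcher`, `cycle`).
#' @param nCycles number of cycles of the night; defaults to the largest
#'   cycle index among the waves.
#' @return data.frame with columns `class`, `cycle`, `count`, `percentage`.
#' @export
cyclePercentages <- function(waves, nCycles = NULL) {
  waves <- waves[waves$cycle > 0, , drop = FALSE]
  classes <- c("slow", "fast")
  if (!all(waves$switcher %in% classes))
    stop("waves must be labeled slow/fast before computing cycle percentages")
  if (is.null(nCycles)) nCycles <- max(waves$cycle)
  out <- expand.grid(class = classes, cycle = seq_len(nCycles),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$class, out$cycle), ]
  out$count <- mapply(function(cl, cy)
    sum(waves$switcher == cl & waves$cycle == cy), out$class, out$cycle)
  totals <- tapply(out$count, out$class, sum)
  if (any(totals == 0))
    stop("switcher class with zero waves: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  out$percentage <- 100 * out$count / as.numeric(totals[out$class])
  rownames(out) <- NULL
  out
}

.decaySSE <- function(r, t, p) {
  e <- exp(-r * t)
  a <- sum(p * e) / sum(e * e)
  list(sse = sum((p - a * e)^2), a = a)
}

.reductionSSE <- function(r, t, p) {
  e <- exp(r * t)
  X <- cbind(1, -e)
  fit <- tryCatch(stats::lm.fit(X, p), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients)))
    return(list(sse = Inf, a = NA_real_, b = NA_real_))
  list(sse = sum(fit$residuals^2),
       a = fit$coefficients[1], b = fit$coefficients[2])
}

.fitForm <- function(t, p, form, rMax = 20) {
  sseFun <- if (form == "decay") .decaySSE else .reductionSSE
  obj <- function(r) {
    v <- sseFun(r, t, p)$sse
    if (!is.finite(v)) 1e300 else v   # keep optimize() off Inf
  }
  opt <- stats::optimize(obj, c(0, rMax), tol = 1e-10)
  # polish around the optimum (optimize can stall on flat stretches)
  lo <- max(0, opt$minimum - 1e-3)
  hi <- min(rMax, opt$minimum + 1e-3)
  opt2 <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
  r <- if (opt2$objective < opt$objective) opt2$minimum else opt$minimum
  pars <- sseFun(r, t, p)
  fitted <- if (form == "decay") pars$a * exp(-r * t)
            else pars$a - pars$b * exp(r * t)
  sst <- sum((p - mean(p))^2)
  r2 <- if (sst < 1e-12) as.numeric(pars$sse < 1e-12) else 1 - pars$sse / sst
  new("DecayFit", form = form, rate = r, amplitude = unname(pars$a),
      offsetScale = if (form == "reduction") unname(pars$b) else NA_real_,
      rSquared = max(0, min(1, r2)), cycles = t, percentages = p,
      fitted = fitted)
}

#' Fit the across-cycle exponential decline of a switcher class
#'
#' Least-squares fit of the per-cycle percentages to a decay
#' \eqn{a e^{-rt}} or a reduction \eqn{a - b e^{rt}} over the cycle index
#' t. With `form = "auto"` both are fitted and the higher-R-squared form is
#' returned, with ties (both exact) resolved toward the more parsimonious
#' decay form. Constant percentages yield a decay with r = 0.
#'
#' @param percentages per-cycle percentages of one class.
#' @param cycles cycle indices (1-based time); defaults to
#'   `seq_along(percentages)`.
#' @param form `"auto"`, `"decay"` or `"reduction"`.
#' @return a [DecayFit] object.
#' @examples
#' p <- 100 * exp(-1.6 * (1:3)) / sum(exp(-1.6 * (1:3)))
#' fitDecay(p)   # recovers r = 1.6, R^2 = 1
#' @export
fitDecay <- function(percentages, cycles = seq_along(percentages),
                     form = c("auto", "decay", "reduction")) {
  form <- match.arg(form)
  p <- as.numeric(percentages)
  t <- as.numeric(cycles)
  if (length(p) < 3L) stop("at least 3 cycles are required for a decay fit")
  if (any(!is.finite(p))) stop("percentages must be finite")
  if (form != "auto") return(.fitForm(t, p, form))
  fd <- .fitForm(t, p, "decay")
  fr <- .fitForm(t, p, "reduction")
  if (fr@rSquared > fd@rSquared + 1e-9) fr else fd
}
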